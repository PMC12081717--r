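test_that("open-close segmentation finds the phantom cross-section and filters shapes", {
  gp <- glom_phantom(radius_um = 40, voxel = 2, noise = 0.03, seed = 6)
  zc <- round(gp$truth$center_um["z"] / 2) + 1
  plane <- gp$volume$channels$protein_2940[zc, , ]
  seg <- segment_glomeruli_openclose(plane, area_range_px = c(100, Inf),
                                     min_circularity = 0.4)
  expect_equal(seg$n_regions, 1L)
  ctr <- round(gp$truth$center_um[c("y", "x")] / 2) + 1
  expect_equal(seg$labels[ctr[1], ctr[2]], 1L)
  # an elongated bar of comparable area is rejected by the circularity filter
  bar <- matrix(0, 80, 80); bar[39:42, 6:75] <- 1
  seg_bar <- segment_glomeruli_openclose(bar, r_open = 0, r_close = 0,
                                         area_range_px = c(10, Inf),
                                         min_circularity = 0.4)
  expect_equal(seg_bar$n_regions, 0L)
  # r_open = r_close = 0 with no filters reduces to plain Otsu components
  two <- matrix(0, 40, 40); two[5:10, 5:10] <- 1; two[25:32, 25:32] <- 1
  seg2 <- segment_glomeruli_openclose(two, r_open = 0, r_close = 0,
                                      area_range_px = c(1, Inf),
                                      min_circularity = 0)
  expect_equal(seg2$n_regions, 2L)
  # blank image -> no regions
  expect_equal(segment_glomeruli_openclose(matrix(0, 16, 16))$n_regions, 0L)
})

test_that("SHG morphological pipeline segments fiber-ringed dark disks", {
  set.seed(11)
  img <- matrix(runif(160 * 160, 0, 0.06), 160, 160)
  yy <- matrix(seq_len(160), 160, 160); xx <- t(yy)
  truth <- list(c(50, 50), c(110, 115))
  disks <- matrix(FALSE, 160, 160)
  for (c in truth) {
    r2 <- (yy - c[1])^2 + (xx - c[2])^2
    disks <- disks | (r2 <= 28^2)
    ring <- r2 > 28^2 & r2 <= 36^2
    img[ring] <- img[ring] + 0.9           # collagen capsule around the disk
  }
  # sparse interstitial fibers elsewhere
  img[abs(yy - xx) < 2 & !disks] <- 0.7
  seg <- segment_glomeruli_shg(img, se_radius_px = 10, area_range_px = c(400, Inf),
                               min_solidity = 0.7)
  expect_gte(seg$n_regions, 2L)
  for (c in truth) {
    lab <- seg$labels[c[1], c[2]]
    expect_gt(lab, 0)
    m <- seg$labels == lab
    d <- (yy - c[1])^2 + (xx - c[2])^2 <= 28^2
    expect_gte(sum(m & d) / sum(m | d), 0.8)
  }
  # mutual exclusion: one id per pixel by construction of a label matrix;
  # the two disks get different ids
  expect_true(seg$labels[truth[[1]][1], truth[[1]][2]] !=
                seg$labels[truth[[2]][1], truth[[2]][2]])
  expect_equal(segment_glomeruli_shg(matrix(0, 32, 32))$n_regions, 0L)
})

test_that("mesangium segmentation intersects the mask with thresholded protein", {
  gp <- glom_phantom(radius_um = 40, mes_fraction = 0.6, voxel = 2, noise = 0.02,
                     seed = 7)
  zc <- round(gp$truth$center_um["z"] / 2) + 1
  plane <- gp$volume$channels$protein_2940[zc, , ]
  gmask <- gp$truth$corpuscle_mask[zc, , ]
  mes <- segment_mesangium(gmask, plane)
  truth2d <- gp$truth$tuft_mask[zc, , ]
  expect_lt(abs(sum(mes) / sum(gmask) - sum(truth2d) / sum(gmask)), 0.02)
  # uniform high protein -> mesangium is the whole mask
  uni <- matrix(0.9, 20, 20); m <- matrix(FALSE, 20, 20); m[5:15, 5:15] <- TRUE
  expect_identical(segment_mesangium(m, uni), m)
  # zero protein -> empty
  expect_false(any(segment_mesangium(m, matrix(0, 20, 20))))
  expect_false(any(segment_mesangium(matrix(FALSE, 20, 20), uni)))
})

test_that("tracking locates the equator, with monotone area decay toward the pole", {
  gp <- glom_phantom(radius_um = 50, mes_fraction = 0.6, voxel = 2, noise = 0,
                     seed = 3)
  rec <- track_glomerulus(gp$volume, glom_seed(gp))
  z_eq <- gp$truth$center_um["z"] / gp$volume$z_spacing_um + 1
  expect_lte(abs(rec$max_plane - z_eq), 1)
  # areas non-increasing from the maximum toward the vanishing plane
  areas <- rec$plane_areas_px
  expect_true(all(diff(areas) <= 0))
  expect_false(rec$clipped)
  expect_equal(rec$thickness_um, 50, tolerance = 4)
  expect_lt(abs(rec$vv_3d - gp$truth$vv_true), 0.02)
  # sphere clipped at the x border is flagged
  gpc <- glom_phantom(radius_um = 40, voxel = 2, pad_px = 5, seed = 5)
  vol <- gpc$volume
  keep <- 1:(dim(vol$channels$protein_2940)[3] - 22)
  vol2 <- multimodal_volume(lapply(vol$channels, function(ch) ch[, , keep]),
                            vol$z_spacing_um, vol$pixel_size_um)
  sd2 <- glom_seed(gpc); sd2[3] <- min(sd2[3], length(keep) - 1)
  rec2 <- track_glomerulus(vol2, sd2)
  expect_true(rec2$clipped)
})

test_that("radius estimation matches the boundary-distance oracle and terminal default", {
  gp <- glom_phantom(radius_um = 100, voxel = 2, seed = 4)
  rec <- track_glomerulus(gp$volume, glom_seed(gp))
  # digitized disk of radius 50 px at 2 um/px -> 100 +- 2 um
  expect_lt(abs(rec$radius_um - 100), 2)
  # rasterized-circle regularity: boundary distance spread below 3% of mean
  m <- rec$max_plane_mask
  boundary <- m & !(EBImage::erode(m * 1, matrix(1, 3, 3)) > 0.5)
  pts <- which(boundary, arr.ind = TRUE)
  dists <- sqrt((pts[, 1] - rec$max_plane_centroid[1])^2 +
                  (pts[, 2] - rec$max_plane_centroid[2])^2)
  expect_lt(stats::sd(dists) / mean(dists), 0.03)
  # max area at the volume's first plane -> 100 um assumed
  gph <- glom_phantom(radius_um = 60, clip = 0.5, voxel = 2, seed = 8)
  rech <- track_glomerulus(gph$volume, c(1, glom_seed(gph)[2], glom_seed(gph)[3]))
  expect_equal(rech$max_plane, 1L)
  expect_equal(rech$radius_um, 100)
})

test_that("hemisphere rule retains and discards by thickness vs radius, boundary inclusive", {
  rec <- structure(list(thickness_um = 90, radius_um = 100), class = "glomerulus_record")
  expect_true(hemisphere_filter(rec))          # boundary case retained
  rec$thickness_um <- 50
  expect_false(hemisphere_filter(rec))
  # clip-fraction phantoms follow their expected flags
  for (clip in c(0, 0.3, 0.5, 0.6)) {
    gp <- glom_phantom(radius_um = 100, clip = clip, voxel = 2, noise = 0,
                       seed = 12)
    rec <- track_glomerulus(gp$volume, glom_seed(gp))
    expect_equal(rec$retained, gp$truth$expected_retained,
                 info = sprintf("clip = %.1f", clip))
  }
})

test_that("Vv estimators agree on degenerate phantoms and are summarized correctly", {
  gp <- glom_phantom(radius_um = 40, mes_fraction = 1, voxel = 2, seed = 2)
  rec <- track_glomerulus(gp$volume, glom_seed(gp))
  for (m in c("3d_hemisphere", "2d_single_plane", "2d_max_plane")) {
    vv <- vv_mes_glom(list(rec), m)
    expect_equal(unname(vv$values), 1, tolerance = 1e-9, info = m)
  }
  gp6 <- glom_phantom(radius_um = 50, mes_fraction = 0.6, voxel = 2, seed = 3)
  rec6 <- track_glomerulus(gp6$volume, glom_seed(gp6))
  vv6 <- vv_mes_glom(list(rec6), "3d_hemisphere")
  expect_lt(abs(unname(vv6$values) - gp6$truth$vv_true), 0.02)
  expect_equal(vv6$summary$n, 1)
  # no retained records is an explicit error naming the filter
  gpd <- glom_phantom(radius_um = 100, clip = 0.6, voxel = 2, seed = 5)
  recd <- track_glomerulus(gpd$volume, glom_seed(gpd))
  expect_error(vv_mes_glom(list(recd), "3d_hemisphere"), "hemisphere")
  # SE = SD / sqrt(n)
  recs <- list(rec, rec6, rec, rec6, rec6)
  s <- vv_mes_glom(recs, "2d_max_plane")$summary
  expect_equal(s$se, s$sd / sqrt(5), tolerance = 1e-12)
})

test_that("polar slices bias the single-plane estimator downward", {
  gp <- glom_phantom(radius_um = 50, mes_fraction = 0.6, voxel = 2, seed = 9)
  ctr <- glom_seed(gp)
  # polar plane: near the top of the sphere, above the tuft
  r_in_px <- 50 * 0.6^(1/3) / 2
  polar_z <- ctr[1] + ceiling(r_in_px) + 2
  rec <- track_glomerulus(gp$volume, ctr, single_plane = polar_z)
  expect_lt(rec$vv_2d_single, gp$truth$vv_true)
  expect_lt(rec$vv_2d_single, 0.2)
})

test_that("3D nuclei counting is exact for non-touching nuclei", {
  gp <- glom_phantom(radius_um = 40, mes_fraction = 0.6, voxel = 2, pad_px = 14,
                     seed = 10, nuclei = c(glomerulus = 6, cortex = 15))
  regions <- array(0L, dim(gp$volume$channels$nuclei))
  regions[gp$truth$tuft_mask] <- 1L
  regions[!gp$truth$corpuscle_mask] <- 2L
  counts <- count_nuclei_3d(gp$volume$channels$nuclei > 0.5, regions)
  expect_equal(unname(counts["1"]), 6L)
  expect_equal(unname(counts["2"]), 15L)
  # empty channel -> zeros
  counts0 <- count_nuclei_3d(array(FALSE, dim(regions)), regions)
  expect_true(all(counts0 == 0L))
  # straddling nucleus counted once, by centroid
  nuc <- array(FALSE, c(5, 5, 5)); nuc[2:4, 2:4, 2:4] <- TRUE
  reg <- array(1L, c(5, 5, 5)); reg[, , 4:5] <- 2L
  c1 <- count_nuclei_3d(nuc, reg)
  expect_equal(sum(c1), 1L)
  expect_equal(unname(c1["1"]), 1L)
})
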