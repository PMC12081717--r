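# Glomerulus detection, z-tracking and mesangial fractional volume
# Vv(Mes/Glom) estimation.
#
# The corpuscle is the outer mask (Bowman's space and parietal epithelium
# included); the mesangium/tuft is recovered by intersecting the corpuscle
# mask with the protein image. Vv(Mes/Glom) is the pixel-count ratio,
# summed over the analyzed planes for the 3D estimator. Glomeruli whose
# measured thickness (max-area plane to vanishing plane) falls below 90% of
# their radius are discarded: such records are either polar caps or
# structures not fully inside the imaging volume.

new_labeled_regions <- function(labels, provenance) {
  ids <- sort(unique(as.integer(labels[labels > 0])))
  # enforce contiguous ids 1..n
  if (length(ids) && !identical(ids, seq_along(ids))) {
    relab <- labels
    for (i in seq_along(ids)) relab[labels == ids[i]] <- i
    labels <- relab
  }
  structure(list(labels = labels, n_regions = length(ids),
                 provenance = provenance),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions:%s> %d region(s)\n", x$provenance, x$n_regions))
  invisible(x)
}

region_shape_filter <- function(labels, area_range = c(50, Inf),
                                min_circularity = 0, min_solidity = 0) {
  ids <- seq_len(max(0L, max(labels)))
  if (length(ids) == 0L) return(labels)
  keep <- logical(length(ids))
  for (i in ids) {
    m <- labels == i
    a <- sum(m)
    if (a < area_range[1] || a > area_range[2]) next
    ok <- TRUE
    if (min_circularity > 0 || min_solidity > 0) {
      if (min_circularity > 0) {
        per <- sum(m & !(EBImage::erode(m * 1, matrix(1, 3, 3)) > 0.5))
        circ <- 4 * pi * a / max(per, 1)^2
        ok <- ok && circ >= min_circularity
      }
      if (ok && min_solidity > 0) {
        pts <- which(m, arr.ind = TRUE)
        h <- grDevices::chull(pts[, 2], pts[, 1])
        hx <- pts[h, 2]; hy <- pts[h, 1]
        hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
        ok <- ok && (a / max(hull_area, 1)) >= min_solidity
      }
    }
    keep[i] <- ok
  }
  out <- labels
  out[!(labels %in% which(keep))] <- 0L
  out
}

#' Rapid glomerulus segmentation by opening and closing
#'
#' Grayscale opening then closing with disk elements smooths texture, Otsu
#' binarization extracts bright structures, and size/circularity filters
#' keep roughly round regions of plausible area. With both radii 0 this
#' reduces to plain Otsu components.
#'
#' @param protein 2-D protein-channel image (e.g. SRS 2940 cm^-1).
#' @param r_open,r_close disk radii (px).
#' @param area_range_px admissible region area `(min, max)` in px.
#' @param min_circularity minimum `4 pi A / P^2` (0 disables).
#' @return A `labeled_regions` (provenance `open_close_pipeline`).
#' @export
segment_glomeruli_openclose <- function(protein, r_open = 2L, r_close = 4L,
                                        area_range_px = c(50, Inf),
                                        min_circularity = 0.4) {
  assert_image(protein)
  if (max(protein) <= 0) return(new_labeled_regions(matrix(0L, nrow(protein), ncol(protein)),
                                                    "open_close_pipeline"))
  x <- protein / max(protein)
  if (r_open > 0) x <- EBImage::opening(x, disc_brush(r_open))
  if (r_close > 0) x <- EBImage::closing(x, disc_brush(r_close))
  thr <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  bw <- x > thr
  bw <- EBImage::fillHull(bw * 1) > 0.5
  labels <- matrix(as.integer(EBImage::bwlabel(bw * 1)), nrow(x), ncol(x))
  labels <- region_shape_filter(labels, area_range_px, min_circularity)
  new_labeled_regions(labels, "open_close_pipeline")
}

#' Morphological glomerulus segmentation from SHG
#'
#' Glomeruli (and tubule lumens) appear as SHG-dark regions surrounded by
#' collagen. The pipeline: disk top-hat background subtraction; median
#' filter; dilation of the fiber signal into a gradient wireframe;
#' inversion; erosion followed by geodesic reconstruction; regional maxima
#' as object seeds; binary opening and closing of the seeds; optional second
#' pass merging missed seeds with the gradient image; finally each object is
#' grown (geodesic dilation) until it reaches the wireframe or another
#' object. A size/solidity filter is applied last.
#'
#' @param shg 2-D non-negative SHG image.
#' @param se_radius_px top-hat disk radius; should be at least twice the
#'   largest visible fiber diameter.
#' @param iterate run the optional second seed-detection pass.
#' @param r_open,r_close disk radii for seed cleanup.
#' @param area_range_px,min_solidity final region filters.
#' @return A `labeled_regions` (provenance `shg_pipeline`).
#' @export
segment_glomeruli_shg <- function(shg, se_radius_px = 10L, iterate = FALSE,
                                  r_open = 2L, r_close = 2L,
                                  area_range_px = c(100, Inf),
                                  min_solidity = 0.7) {
  assert_image(shg)
  ny <- nrow(shg); nx <- ncol(shg)
  if (max(shg) <= 0) return(new_labeled_regions(matrix(0L, ny, nx), "shg_pipeline"))
  x <- shg / max(shg)
  th <- EBImage::whiteTopHat(x, disc_brush(se_radius_px))
  th <- EBImage::medianFilter(clip01(th), 2L)
  fiber_thr <- EBImage::otsu(EBImage::Image(clip01(th)), range = c(0, 1))
  wire <- EBImage::dilate((th > fiber_thr) * 1, disc_brush(2L)) > 0.5  # gradient wireframe
  inv <- 1 - clip01(th / max(th))
  rec <- reconstruct_dilation(EBImage::erode(inv, disc_brush(3L)), inv)
  seeds_bw <- regional_maxima(rec, h = 0.05) & !wire
  if (r_open > 0) seeds_bw <- EBImage::opening(seeds_bw * 1, disc_brush(r_open)) > 0.5
  if (r_close > 0) seeds_bw <- EBImage::closing(seeds_bw * 1, disc_brush(r_close)) > 0.5
  if (iterate) {
    # merge the seeds with the gradient image and re-run the cleanup to
    # recover objects missed by the first reconstruction
    merged <- pmax(seeds_bw * 1, (th > fiber_thr) * 1)
    extra <- regional_maxima(reconstruct_dilation(
      EBImage::erode(1 - merged, disc_brush(3L)), 1 - merged), h = 0.05) & !wire
    seeds_bw <- seeds_bw | (EBImage::opening(extra * 1, disc_brush(r_open)) > 0.5)
  }
  seeds <- EBImage::bwlabel(seeds_bw * 1)
  if (max(seeds) == 0) return(new_labeled_regions(matrix(0L, ny, nx), "shg_pipeline"))
  # grow each seed over non-wireframe territory; propagation stops at the
  # wireframe (excluded from the mask) or where another object wins
  grown <- EBImage::propagate(x, seeds, mask = !wire)
  labels <- matrix(as.integer(grown), ny, nx)
  labels <- region_shape_filter(labels, area_range_px, min_solidity = min_solidity)
  new_labeled_regions(labels, "shg_pipeline")
}

#' Segment the mesangium within a glomerulus mask
#'
#' Intersects the corpuscle mask with the thresholded protein image,
#' removing Bowman's-space background. The threshold is Otsu computed on
#' the within-mask protein values by default, or a fixed value.
#'
#' @param glom_mask logical corpuscle mask.
#' @param protein protein-channel image.
#' @param method `"otsu"` (within-mask) or `"fixed"`.
#' @param fixed_threshold threshold for `method = "fixed"`.
#' @return logical mesangium mask (subset of `glom_mask`).
#' @export
segment_mesangium <- function(glom_mask, protein, method = c("otsu", "fixed"),
                              fixed_threshold = NULL) {
  method <- match.arg(method)
  assert_image(protein)
  assert_same_shape(glom_mask, protein)
  if (!any(glom_mask)) return(glom_mask & FALSE)
  thr <- if (method == "fixed") {
    if (is.null(fixed_threshold)) stopf("fixed method needs fixed_threshold")
    fixed_threshold
  } else otsu_threshold(protein[glom_mask])
  glom_mask & protein >= thr & protein > 0
}

# pick the label under (y, x), falling back to the label with the largest
# overlap with `prev_mask`
pick_label <- function(labels, y, x, prev_mask) {
  yi <- round(y); xi <- round(x)
  if (yi >= 1 && yi <= nrow(labels) && xi >= 1 && xi <= ncol(labels) &&
      labels[yi, xi] > 0) return(labels[yi, xi])
  ov <- labels[prev_mask & labels > 0]
  if (length(ov) == 0L) return(0L)
  as.integer(names(which.max(table(ov))))
}

#' Track one glomerulus through z and build its record
#'
#' Segments the corpuscle on every z-plane of the protein channel, links
#' regions across planes (a region at plane k+1 is the same object if it
#' contains the plane-k centroid; ties resolved by largest overlap), and
#' records per-plane corpuscle and mesangium pixel areas. The analyzed
#' range runs from the maximal-cross-section plane to the vanishing plane
#' (first plane, moving away from the maximum on the longer side, with area
#' below `vanish_frac` of the maximum); glomerulus thickness is the z
#' distance between the two. The mesangium threshold is computed once per
#' object by Otsu over within-corpuscle voxels of all tracked planes, then
#' applied to every plane, so polar planes with no tuft get zero mesangium
#' rather than an Otsu split of noise.
#'
#' @param volume a `multimodal_volume` with a protein channel.
#' @param seed `(z, y, x)` voxel indices (1-based) inside the object, e.g.
#'   a centroid from a 2-D segmentation.
#' @param channel channel name (default `protein_2940`).
#' @param method `"threshold"` (fixed corpuscle threshold, fast) or
#'   `"openclose"` (per-plane [segment_glomeruli_openclose()]).
#' @param corpuscle_threshold intensity threshold separating corpuscle from
#'   surround for `method = "threshold"`.
#' @param mes_threshold optional fixed mesangium threshold; default is the
#'   per-object Otsu described above.
#' @param vanish_frac area fraction of the maximum defining the vanishing
#'   plane (default 0.01).
#' @param single_plane absolute z index used by the 2-D single-plane
#'   estimator (default: the seed plane).
#' @param default_radius_um radius assumed when the max-area plane is the
#'   first or last plane of the volume (default 100).
#' @param ... passed to [segment_glomeruli_openclose()].
#' @return An object of class `glomerulus_record`; see fields in the source
#'   of [vv_mes_glom()]. Key fields: `plane_areas_px`, `mes_areas_px`
#'   (analyzed range), `max_plane`, `vanish_plane`, `thickness_um`,
#'   `radius_um`, `retained`, `clipped`, `vv_3d`, `vv_2d_single`,
#'   `vv_2d_max`, `centroid_um`.
#' @export
track_glomerulus <- function(volume, seed, channel = "protein_2940",
                             method = c("threshold", "openclose"),
                             corpuscle_threshold = 0.2, mes_threshold = NULL,
                             vanish_frac = 0.01, single_plane = NULL,
                             default_radius_um = 100, ...) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "multimodal_volume"))
  if (!channel %in% names(volume$channels)) stopf("channel '%s' absent", channel)
  vol <- volume$channels[[channel]]
  nz <- dim(vol)[1]
  if (nz < 3L) stopf("need >= 3 z-planes")
  z0 <- seed[1]
  if (is.null(single_plane)) single_plane <- z0

  plane_labels <- function(z) {
    img <- vol[z, , ]
    if (method == "threshold") {
      bw <- img > corpuscle_threshold
      bw <- EBImage::fillHull(bw * 1) > 0.5
      matrix(as.integer(EBImage::bwlabel(bw * 1)), nrow(img), ncol(img))
    } else {
      segment_glomeruli_openclose(img, ...)$labels
    }
  }

  masks <- vector("list", nz)
  areas <- numeric(nz)
  cents <- matrix(NA_real_, nz, 2)
  lab0 <- plane_labels(z0)
  l <- lab0[seed[2], seed[3]]
  if (l == 0L) {
    nb <- lab0[max(1, seed[2] - 2):min(nrow(lab0), seed[2] + 2),
               max(1, seed[3] - 2):min(ncol(lab0), seed[3] + 2)]
    nb <- nb[nb > 0]
    if (length(nb) == 0L) stopf("seed voxel is not inside a segmented region")
    l <- as.integer(names(which.max(table(nb))))
  }
  masks[[z0]] <- lab0 == l
  areas[z0] <- sum(masks[[z0]])
  cents[z0, ] <- colMeans(which(masks[[z0]], arr.ind = TRUE))
  for (dir in c(1L, -1L)) {
    cur <- masks[[z0]]; cy <- cents[z0, 1]; cx <- cents[z0, 2]
    z <- z0 + dir
    while (z >= 1L && z <= nz) {
      labz <- plane_labels(z)
      l <- pick_label(labz, cy, cx, cur)
      if (l == 0L) break
      m <- labz == l
      masks[[z]] <- m
      areas[z] <- sum(m)
      cents[z, ] <- colMeans(which(m, arr.ind = TRUE))
      cur <- m; cy <- cents[z, 1]; cx <- cents[z, 2]
      z <- z + dir
    }
  }
  tracked <- which(areas > 0)
  max_plane <- tracked[which.max(areas[tracked])]
  max_area <- areas[max_plane]

  # analyzed side: the longer tracked run from the maximum
  n_up <- sum(tracked > max_plane); n_down <- sum(tracked < max_plane)
  dir <- if (n_up >= n_down) 1L else -1L
  zseq <- seq(max_plane, if (dir == 1L) nz else 1L, by = dir)
  vanish_plane <- NA_integer_
  analyzed <- integer(0)
  for (z in zseq) {
    if (areas[z] < vanish_frac * max_area) { vanish_plane <- z; break }
    analyzed <- c(analyzed, z)
  }
  if (is.na(vanish_plane)) vanish_plane <- zseq[length(zseq)]  # never vanished
  thickness_um <- abs(max_plane - vanish_plane) * volume$z_spacing_um

  # mesangium threshold: per-object Otsu over all analyzed corpuscle voxels
  if (is.null(mes_threshold)) {
    vals <- unlist(lapply(analyzed, function(z) vol[z, , ][masks[[z]]]))
    mes_threshold <- otsu_threshold(vals)
  }
  mes_areas <- vapply(analyzed, function(z)
    sum(masks[[z]] & vol[z, , ] >= mes_threshold), numeric(1))
  plane_areas <- areas[analyzed]

  clipped <- any(vapply(analyzed, function(z) {
    m <- masks[[z]]
    any(m[1, ]) || any(m[nrow(m), ]) || any(m[, 1]) || any(m[, ncol(m)])
  }, logical(1)))

  # centroid in um over analyzed planes, area-weighted
  w <- plane_areas / sum(plane_areas)
  centroid_um <- c(z = sum((analyzed - 1) * w) * volume$z_spacing_um,
                   y = sum(cents[analyzed, 1] * w) * volume$pixel_size_um,
                   x = sum(cents[analyzed, 2] * w) * volume$pixel_size_um)

  rec <- structure(list(
    plane_areas_px = stats::setNames(plane_areas, analyzed),
    mes_areas_px = stats::setNames(mes_areas, analyzed),
    centroid_um = centroid_um,
    max_plane = max_plane, vanish_plane = vanish_plane,
    thickness_um = thickness_um,
    max_plane_mask = masks[[max_plane]],
    max_plane_centroid = cents[max_plane, ],
    mes_threshold = mes_threshold,
    clipped = clipped, n_z = nz,
    pixel_size_um = volume$pixel_size_um,
    z_spacing_um = volume$z_spacing_um,
    single_plane = single_plane,
    default_radius_um = default_radius_um), class = "glomerulus_record")

  rec$radius_um <- estimate_radius(rec)
  rec$retained <- hemisphere_filter(rec)
  rec$vv_3d <- sum(mes_areas) / sum(plane_areas)
  rec$vv_2d_max <- mes_areas[match(max_plane, analyzed)] /
    plane_areas[match(max_plane, analyzed)]
  sp <- match(single_plane, analyzed)
  rec$vv_2d_single <- if (is.na(sp)) {
    if (areas[single_plane] > 0 && !is.null(masks[[single_plane]])) {
      m <- masks[[single_plane]]
      sum(m & vol[single_plane, , ] >= mes_threshold) / sum(m)
    } else NA_real_
  } else mes_areas[sp] / plane_areas[sp]
  rec
}

#' @export
print.glomerulus_record <- function(x, ...) {
  cat(sprintf(paste0("<glomerulus_record> radius %.1f um, thickness %.1f um, ",
                     "%s; Vv 3d=%.3f 2d_max=%.3f 2d_single=%.3f\n"),
              x$radius_um, x$thickness_um,
              if (x$retained) "retained" else "discarded",
              x$vv_3d, x$vv_2d_max, x$vv_2d_single))
  invisible(x)
}

#' Glomerulus radius at the maximal cross-section
#'
#' Mean distance from the corpuscle centroid to the boundary of the mask at
#' the max-area plane, in micrometres. When the largest area occurs at the
#' first or last plane of the volume no true maximum is defined and the
#' radius is assumed to be `default_radius_um` (100 um, about half the
#' diameter of a typical glomerulus).
#'
#' @param record a `glomerulus_record`.
#' @return radius in um.
#' @export
estimate_radius <- function(record) {
  stopifnot(inherits(record, "glomerulus_record"))
  if (record$max_plane == 1L || record$max_plane == record$n_z)
    return(record$default_radius_um)
  m <- record$max_plane_mask
  boundary <- m & !(EBImage::erode(m * 1, matrix(1, 3, 3)) > 0.5)
  pts <- which(boundary, arr.ind = TRUE)
  cyx <- record$max_plane_centroid
  mean(sqrt((pts[, 1] - cyx[1])^2 + (pts[, 2] - cyx[2])^2)) *
    record$pixel_size_um
}

#' Hemisphere inclusion rule
#'
#' A glomerulus is retained iff its thickness (max-area plane to vanishing
#' plane) is at least 90% of its radius; thinner records are polar slices
#' or structures not fully contained in the imaging volume. The boundary is
#' inclusive: exactly 90% is retained.
#'
#' @param record a `glomerulus_record` with radius and thickness set.
#' @return logical.
#' @export
hemisphere_filter <- function(record) {
  stopifnot(inherits(record, "glomerulus_record"))
  record$thickness_um >= 0.9 * record$radius_um
}

#' Mesangial fractional volume over a set of glomeruli
#'
#' Applies one of three estimators to each record and summarizes across
#' glomeruli:
#' * `3d_hemisphere` — sum of mesangium pixels over analyzed planes divided
#'   by sum of corpuscle pixels; only records passing [hemisphere_filter()]
#'   and not clipped at the x/y border are used.
#' * `2d_single_plane` — pixel ratio at each record's stated single plane.
#' * `2d_max_plane` — pixel ratio at the maximal cross-section.
#'
#' @param records list of `glomerulus_record`.
#' @param method estimator name.
#' @return list: `values` per glomerulus, `summary` data.frame
#'   (method, n, mean, sd, se), `used` indices of records used.
#' @export
vv_mes_glom <- function(records,
                        method = c("3d_hemisphere", "2d_single_plane",
                                   "2d_max_plane")) {
  method <- match.arg(method)
  stopifnot(length(records) >= 1L)
  if (method == "3d_hemisphere") {
    used <- which(vapply(records, function(r) r$retained && !r$clipped, logical(1)))
    if (length(used) == 0L)
      stopf("no records pass the hemisphere filter (thickness >= 0.9 radius)")
    vals <- vapply(records[used], function(r) r$vv_3d, numeric(1))
  } else if (method == "2d_single_plane") {
    used <- seq_along(records)
    vals <- vapply(records, function(r) r$vv_2d_single, numeric(1))
    used <- used[!is.na(vals)]; vals <- vals[!is.na(vals)]
  } else {
    used <- seq_along(records)
    vals <- vapply(records, function(r) r$vv_2d_max, numeric(1))
  }
  n <- length(vals)
  list(values = vals,
       summary = data.frame(method = method, n = n, mean = mean(vals),
                            sd = stats::sd(vals),
                            se = stats::sd(vals) / sqrt(n)),
       used = used)
}

# 26-connected 3-D component labeling (flood fill); mask is (z, y, x)
label_components_3d <- function(mask) {
  d <- dim(mask)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  lab <- array(0L, d)
  todo <- mask
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nlab <- 0L
  seedlin <- which(todo)
  for (s in seedlin) {
    if (!todo[s]) next
    nlab <- nlab + 1L
    wave <- s
    todo[s] <- FALSE
    while (length(wave)) {
      lab[wave] <- nlab
      ai <- arrayInd(wave, d)
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
        cbind(ai[, 1] + offs[o, 1], ai[, 2] + offs[o, 2], ai[, 3] + offs[o, 3])))
      ok <- cand[, 1] >= 1 & cand[, 1] <= nz & cand[, 2] >= 1 & cand[, 2] <= ny &
        cand[, 3] >= 1 & cand[, 3] <= nx
      cand <- cand[ok, , drop = FALSE]
      lin <- unique(cand[, 1] + (cand[, 2] - 1) * nz + (cand[, 3] - 1) * nz * ny)
      lin <- lin[todo[lin]]
      todo[lin] <- FALSE
      wave <- lin
    }
  }
  lab
}

#' Count nuclei per region in 3D
#'
#' Labels the nuclei mask into 26-connected components and assigns each
#' nucleus to the region containing its centroid (so a nucleus straddling a
#' boundary is counted exactly once).
#'
#' @param nuclei logical (or 0/1) volume `(z, y, x)`.
#' @param regions integer label volume of the same shape (0 = unassigned;
#'   e.g. 1 = glomerulus, 2 = cortex).
#' @return named integer vector of counts per region id (plus
#'   `"unassigned"` for centroids on label 0, if any).
#' @export
count_nuclei_3d <- function(nuclei, regions) {
  if (!identical(dim(nuclei), dim(regions))) stopf("shapes must match")
  mask <- nuclei > 0.5
  ids <- sort(unique(as.integer(regions[regions > 0])))
  counts <- stats::setNames(integer(length(ids)), as.character(ids))
  if (!any(mask)) return(counts)
  lab <- label_components_3d(mask)
  n <- max(lab)
  unassigned <- 0L
  for (i in seq_len(n)) {
    ai <- arrayInd(which(lab == i), dim(lab))
    ctr <- round(colMeans(ai))
    r <- regions[ctr[1], ctr[2], ctr[3]]
    if (r > 0) counts[as.character(r)] <- counts[as.character(r)] + 1L
    else unassigned <- unassigned + 1L
  }
  if (unassigned > 0) counts <- c(counts, unassigned = unassigned)
  counts
}
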