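test_that("constructors enforce their invariants", {
  expect_error(hyperspectral_stack(array(1, c(4, 4, 3)), c(1, 2)), "spectral planes")
  expect_error(hyperspectral_stack(array(1, c(4, 4, 3)), c(3, 2, 1)), "increasing")
  expect_error(reference_spectrum("x", 1:3, c(0, 0, 0)), "positive maximum")
  expect_error(multimodal_volume(list(a = array(1, c(2, 3, 4)),
                                      b = array(1, c(2, 3, 5))), 1, 1),
               "shape differs")
})

test_that("stack and volume round-trip through TIFF + sidecar", {
  wn <- seq(2700, 3100, length.out = 11)
  st <- hyperspectral_stack(array(runif(5 * 6 * 11), c(5, 6, 11)), wn,
                            pixel_size_um = 0.5)
  path <- file.path(tempdir(), "stack.tif")
  write_stack(st, path)
  back <- read_stack(path)
  expect_equal(back$wavenumbers, st$wavenumbers)
  expect_equal(back$pixel_size_um, 0.5)
  expect_equal(back$data, st$data, tolerance = 1e-6)  # 32-bit float storage

  vol <- multimodal_volume(list(protein_2940 = array(runif(24), c(2, 3, 4)),
                                shg = array(runif(24), c(2, 3, 4))),
                           z_spacing_um = 2, pixel_size_um = 1)
  vpath <- file.path(tempdir(), "vol.tif")
  write_stack(vol, vpath)
  vback <- read_stack(vpath)
  expect_equal(names(vback$channels), c("protein_2940", "shg"))
  expect_equal(vback$channels$shg, vol$channels$shg, tolerance = 1e-6)
})

test_that("page-count mismatch with the sidecar is a format error", {
  wn <- seq(2700, 3100, length.out = 5)
  st <- hyperspectral_stack(array(runif(4 * 4 * 5), c(4, 4, 5)), wn)
  path <- file.path(tempdir(), "bad.tif")
  write_stack(st, path)
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  side$wavenumbers <- side$wavenumbers[1:4]  # 5 pages, 4 listed wavenumbers
  yaml::write_yaml(side, paste0(path, ".yaml"))
  expect_error(read_stack(path), "format error")
  file.remove(paste0(path, ".yaml"))
  expect_error(read_stack(path), "sidecar")
})

test_that("reference spectra round-trip through CSV", {
  r <- tiny_refs()[[1]]
  path <- file.path(tempdir(), "ref.csv")
  write_reference_csv(r, path)
  back <- read_reference_csv(path, name = r$name)
  expect_equal(back$intensities, r$intensities)
  expect_equal(back$wavenumbers, r$wavenumbers)
})

test_that("phasor transform matches a direct per-pixel summation oracle", {
  set.seed(42)
  wn <- seq(2700, 3100, by = 25)
  arr <- array(runif(16 * 16 * length(wn)), c(16, 16, length(wn)))
  st <- hyperspectral_stack(arr, wn)
  ph <- phasor_transform(st, harmonic = 1)
  v0 <- wn[1]; dv <- wn[length(wn)] - v0
  for (px in list(c(1, 1), c(7, 12), c(16, 16))) {
    I <- arr[px[1], px[2], ]
    g <- sum(I * cos(2 * pi * (wn - v0) / dv)) / sum(I)
    s <- sum(I * sin(2 * pi * (wn - v0) / dv)) / sum(I)
    expect_equal(ph$G[px[1], px[2]], g, tolerance = 1e-10)
    expect_equal(ph$S[px[1], px[2]], s, tolerance = 1e-10)
  }
  expect_true(all(ph$G^2 + ph$S^2 <= 1 + 1e-9))
})

test_that("phasor edge cases: flat, delta, and zero spectra", {
  wn <- seq(2700, 3100, by = 4)
  n <- length(wn)
  flat <- phasor_transform(hyperspectral_stack(array(1, c(1, 1, n)), wn))
  expect_lt(abs(flat$G[1, 1]), 1 / n + 1e-12)
  expect_lt(abs(flat$S[1, 1]), 1 / n + 1e-12)
  dta <- array(0, c(1, 1, n)); dta[1, 1, 1] <- 3
  del <- phasor_transform(hyperspectral_stack(dta, wn))
  expect_equal(c(del$G[1, 1], del$S[1, 1]), c(1, 0))
  zarr <- array(0, c(2, 2, n)); zarr[1, 1, ] <- 1
  z <- phasor_transform(hyperspectral_stack(zarr, wn))
  expect_false(z$valid[2, 2])
  expect_true(z$valid[1, 1])
  expect_false(any(is.nan(z$G[z$valid])))
  # distinct references map to distinct phasor points
  refs <- tiny_refs()
  p1 <- phasor_transform(pixel_stack(refs[[1]]$intensities, refs[[1]]$wavenumbers))
  p2 <- phasor_transform(pixel_stack(refs[[2]]$intensities, refs[[2]]$wavenumbers))
  expect_gt((p1$G[1, 1] - p2$G[1, 1])^2 + (p1$S[1, 1] - p2$S[1, 1])^2, 1e-6)
})

test_that("linear unmixing recovers endmembers and matches a grid-search oracle", {
  wn <- c(2850, 2880, 2940)
  E <- cbind(lipid = c(1.0, 0.7, 0.3), protein = c(0.2, 0.5, 1.0))
  # pure lipid pixel
  st <- hyperspectral_stack(array(E[, 1], c(1, 1, 3)), wn)
  um <- linear_unmix(st)
  expect_equal(um$lipid[1, 1], 1, tolerance = 1e-9)
  expect_equal(um$protein[1, 1], 0, tolerance = 1e-9)
  # 50/50 sum
  st2 <- hyperspectral_stack(array(0.5 * E[, 1] + 0.5 * E[, 2], c(1, 1, 3)), wn)
  um2 <- linear_unmix(st2)
  expect_equal(um2$lipid[1, 1], um2$protein[1, 1], tolerance = 1e-9)
  # random non-negative mixtures vs brute-force grid search
  set.seed(7)
  for (i in 1:5) {
    cf <- runif(2, 0, 2)
    b <- as.numeric(E %*% cf) + abs(rnorm(3, 0, 0.05))
    stm <- hyperspectral_stack(array(b, c(1, 1, 3)), wn)
    um3 <- linear_unmix(stm)
    grid <- seq(0, 4, by = 0.002)
    res <- outer(grid, grid, function(a, p)
      (a * E[1, 1] + p * E[1, 2] - b[1])^2 +
        (a * E[2, 1] + p * E[2, 2] - b[2])^2 +
        (a * E[3, 1] + p * E[3, 2] - b[3])^2)
    k <- which(res == min(res), arr.ind = TRUE)[1, ]
    expect_lt(abs(um3$lipid[1, 1] - grid[k[1]]), 2e-3)
    expect_lt(abs(um3$protein[1, 1] - grid[k[2]]), 2e-3)
  }
  expect_error(linear_unmix(hyperspectral_stack(array(1, c(1, 1, 3)),
                                                c(2850, 2880, 2900))),
               "outside")
})

test_that("channel fractions are simplex-normalized per label", {
  a <- array(2, c(2, 4, 4)); b <- array(2, c(2, 4, 4))
  vol <- multimodal_volume(list(ch1 = a, ch2 = b), 1, 1)
  labels <- array(0L, c(2, 4, 4)); labels[1, , ] <- 1L; labels[2, 1:2, ] <- 2L
  cf <- channel_fractions(vol, labels)
  expect_equal(cf$ch1, c(0.5, 0.5))
  # one-hot channel
  b2 <- b; b2[] <- 0
  cf2 <- channel_fractions(list(ch1 = a, ch2 = b2), labels)
  expect_equal(cf2$ch1, c(1, 1))
  # hand-computed means on three labels
  set.seed(1)
  x <- array(runif(32), c(2, 4, 4)); y <- array(runif(32), c(2, 4, 4))
  lab3 <- array(sample(0:3, 32, replace = TRUE), c(2, 4, 4))
  cf3 <- channel_fractions(list(x = x, y = y), lab3)
  for (l in 1:3) {
    mx <- mean(x[lab3 == l]); my <- mean(y[lab3 == l])
    expect_equal(unlist(cf3[cf3$label == l, c("x", "y")], use.names = FALSE),
                 c(mx, my) / (mx + my), tolerance = 1e-12)
  }
  expect_true(all(abs(rowSums(cf3[, c("x", "y")]) - 1) < 1e-9))
})
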