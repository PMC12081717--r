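# SHG collagen analytics: background subtraction, distance-map fiber
# thickness, DFT orientation/anisotropy per spatial bin with
# periodic-plus-smooth decomposition, Voronoi partitioning around
# glomerulus centers, and thickness-versus-distance densities.
#
# Orientation convention (shared with make_fiber_phantom): degrees from the
# +x (column) axis toward +y (row, downward), reported in [0, 180).

#' Flatfield + top-hat background subtraction
#'
#' Divides by a heavy Gaussian blur of the image (normalized to unit mean)
#' to remove slow illumination gradients, then applies a disk top-hat to
#' suppress structures wider than the largest fiber. Output is clipped at 0.
#'
#' @param shg non-negative SHG image.
#' @param disk_radius_px top-hat disk radius; at least the largest fiber
#'   half-width. Radius 0 passes through with a warning.
#' @param flatfield_sigma Gaussian sigma of the flatfield estimate
#'   (default `4 * disk_radius_px`).
#' @return background-subtracted image, min >= 0.
#' @export
background_subtract <- function(shg, disk_radius_px,
                                flatfield_sigma = 4 * disk_radius_px) {
  assert_image(shg)
  if (disk_radius_px <= 0) {
    warnf("disk radius 0: background subtraction skipped")
    return(shg)
  }
  # cap the blur support to the image so the flatfield kernel always fits
  sigma <- min(flatfield_sigma, (min(dim(shg)) - 2) / 7)
  flat <- EBImage::gblur(shg, sigma = sigma)
  flat <- flat / mean(flat)
  corrected <- shg / pmax(flat, 1e-6)
  out <- EBImage::whiteTopHat(corrected, disc_brush(disk_radius_px))
  pmax(out, 0)
}

#' Fiber thickness from the Euclidean distance map
#'
#' Transforms the fiber mask into a Euclidean distance map (pixel value =
#' distance to nearest background pixel). Regional maxima of the map lie on
#' the fiber midline where the distance equals the fiber half-width, so
#' thickness = 2 x distance. Connected plateaus of maxima collapse to one
#' sample at the plateau centroid, avoiding double counting along ridge
#' lines.
#'
#' @param shg_mask logical (or 0/1) fiber mask, e.g. Otsu on the
#'   background-subtracted SHG.
#' @param pixel_size_um pixel size for the um-scaled thickness.
#' @return data.frame `y`, `x` (plateau centroid, px), `thickness_px`,
#'   `thickness_um`; empty for an empty mask.
#' @export
fiber_thickness <- function(shg_mask, pixel_size_um = 1) {
  mask <- shg_mask > 0.5
  empty <- data.frame(y = numeric(0), x = numeric(0),
                      thickness_px = numeric(0), thickness_um = numeric(0))
  if (!any(mask)) return(empty)
  d <- EBImage::distmap(mask * 1, metric = "euclidean")
  d <- matrix(as.numeric(d), nrow(mask), ncol(mask))
  # regional maxima: distance not exceeded anywhere in the 8-neighborhood
  dmax <- EBImage::dilate(d, matrix(1, 3, 3))
  rmax <- mask & (d >= dmax - 1e-9)
  lab <- EBImage::bwlabel(rmax * 1)
  n <- max(lab)
  if (n == 0) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  cy <- as.numeric(tapply(idx[, 1], l, mean))
  cx <- as.numeric(tapply(idx[, 2], l, mean))
  dv <- as.numeric(tapply(d[lab > 0], l, max))
  data.frame(y = cy, x = cx, thickness_px = 2 * dv,
             thickness_um = 2 * dv * pixel_size_um)
}

# Periodic-plus-smooth decomposition (Moisan-type). Returns the periodic
# component, whose DFT is free of the cross artifact caused by boundary
# discontinuities of the torus wrap-around.
periodic_component <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  v <- matrix(0, nr, nc)
  v[1, ] <- u[nr, ] - u[1, ]
  v[nr, ] <- u[1, ] - u[nr, ]  # = -v[1, ]
  v[, 1] <- v[, 1] + (u[, nc] - u[, 1])
  v[, nc] <- v[, nc] + (u[, 1] - u[, nc])
  V <- stats::fft(v)
  qr_ <- 2 * cos(2 * pi * (seq_len(nr) - 1) / nr)
  qc_ <- 2 * cos(2 * pi * (seq_len(nc) - 1) / nc)
  denom <- outer(qr_, qc_, `+`) - 4
  denom[1, 1] <- 1
  S <- V / denom
  S[1, 1] <- 0
  s <- Re(stats::fft(S, inverse = TRUE)) / (nr * nc)
  u - s
}

# Orientation/anisotropy of one bin from the power spectrum inertia tensor.
# Returns c(orientation_deg, anisotropy) with orientation NA for flat bins.
bin_orientation <- function(u, periodic = TRUE) {
  if (stats::sd(u) < 1e-12) return(c(NA_real_, 0))
  u <- u - mean(u)
  p <- if (periodic) periodic_component(u) else u
  P <- Mod(stats::fft(p))^2
  nr <- nrow(u); nc <- ncol(u)
  fy <- ifelse(seq_len(nr) - 1 > nr / 2, seq_len(nr) - 1 - nr, seq_len(nr) - 1) / nr
  fx <- ifelse(seq_len(nc) - 1 > nc / 2, seq_len(nc) - 1 - nc, seq_len(nc) - 1) / nc
  FY <- matrix(fy, nr, nc)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  P[1, 1] <- 0                       # DC excluded
  w <- sum(P)
  if (w <= 0) return(c(NA_real_, 0))
  Ixx <- sum(P * FX^2) / w
  Iyy <- sum(P * FY^2) / w
  Ixy <- sum(P * FX * FY) / w
  tr <- Ixx + Iyy
  dd <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  lam_max <- tr / 2 + dd; lam_min <- tr / 2 - dd
  if (lam_max <= 0) return(c(NA_real_, 0))
  # principal axis of spectral energy; fibers run orthogonal to it
  ang_spec <- 0.5 * atan2(2 * Ixy, Ixx - Iyy) * 180 / pi
  orient <- (ang_spec + 90) %% 180
  c(orient, 1 - lam_min / lam_max)
}

#' Per-bin collagen orientation and anisotropy
#'
#' Tiles the SHG image into square bins (80 um by default), and for each
#' bin computes the dominant fiber orientation and an anisotropy index in
#' [0, 1] from the 2-D DFT power spectrum of the mean-subtracted bin. The
#' periodic component of a periodic-plus-smooth decomposition is
#' transformed instead of the raw bin, removing the axis-aligned cross
#' artifact that boundary discontinuities inject into the DFT. Orientation
#' is the 90-degree-rotated principal axis of the power-spectrum inertia
#' tensor; anisotropy is `1 - lambda_min / lambda_max` of that tensor.
#' Partial edge bins are kept when at least half the bin is inside.
#'
#' @param shg non-negative SHG image.
#' @param bin_um bin side (um), default 80.
#' @param pixel_size_um pixel size (um).
#' @param periodic use the periodic-plus-smooth decomposition (default
#'   TRUE; FALSE gives the naive DFT for comparison).
#' @return data.frame: `bin_y`, `bin_x` (bin indices), `y0`, `x0` (top-left
#'   px), `orientation_deg` (NA for flat bins), `anisotropy`, `mean_shg`,
#'   `flat` (logical degenerate-bin flag).
#' @export
anisotropy_bins <- function(shg, bin_um = 80, pixel_size_um = 1,
                            periodic = TRUE) {
  assert_image(shg)
  b <- max(2L, round(bin_um / pixel_size_um))
  if (b < 16L) warnf("bin side %d px < 16 px: orientation estimates are coarse", b)
  ny <- nrow(shg); nx <- ncol(shg)
  starts <- function(n) {
    s <- seq(1L, n, by = b)
    # drop a trailing partial bin covering less than half the bin side
    if (length(s) > 1L && n - s[length(s)] + 1L < b / 2) s <- s[-length(s)]
    s
  }
  ys <- starts(ny); xs <- starts(nx)
  rows <- list()
  for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
    y0 <- ys[iy]; x0 <- xs[ix]
    u <- shg[y0:min(ny, y0 + b - 1L), x0:min(nx, x0 + b - 1L), drop = FALSE]
    oa <- bin_orientation(u, periodic)
    rows[[length(rows) + 1L]] <-
      data.frame(bin_y = iy, bin_x = ix, y0 = y0, x0 = x0,
                 orientation_deg = oa[1], anisotropy = oa[2],
                 mean_shg = mean(u), flat = is.na(oa[1]))
  }
  out <- do.call(rbind, rows)
  attr(out, "bin_px") <- b
  attr(out, "bin_um") <- b * pixel_size_um
  out
}

#' Voronoi partition of the image around glomerulus centers
#'
#' Assigns every pixel to its nearest seed (Euclidean metric in um); ties
#' go to the lowest seed id.
#'
#' @param glom_centers_um matrix/data.frame with columns `y`, `x` in um.
#' @param shape image shape `c(ny, nx)` in px.
#' @param pixel_size_um pixel size (um).
#' @return list of class `voronoi_partition`: `seeds` (um), `labels`
#'   (integer matrix), `pixel_size_um`.
#' @export
voronoi_partition <- function(glom_centers_um, shape, pixel_size_um = 1) {
  ctr <- as.matrix(glom_centers_um)
  if (nrow(ctr) == 0L) stopf("need at least one glomerulus center")
  ny <- shape[1]; nx <- shape[2]
  yy <- (matrix(seq_len(ny), ny, nx) - 1) * pixel_size_um
  xx <- (matrix(seq_len(nx), ny, nx, byrow = TRUE) - 1) * pixel_size_um
  best <- matrix(Inf, ny, nx)
  labels <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(ctr))) {
    d2 <- (yy - ctr[i, 1])^2 + (xx - ctr[i, 2])^2
    upd <- d2 < best             # strict: ties keep the lower id
    best[upd] <- d2[upd]
    labels[upd] <- i
  }
  structure(list(seeds = ctr, labels = labels, pixel_size_um = pixel_size_um),
            class = "voronoi_partition")
}

#' Fiber thickness versus distance from the nearest glomerulus
#'
#' For each thickness sample, looks up its Voronoi cell and computes the
#' Euclidean distance to that cell's seed (the nearest glomerulus center).
#' Samples falling in an exclusion mask (e.g. highly oriented medullary
#' bins flagged by anisotropy) are dropped. Returns the raw table and a
#' binned 2-D density grid (distance x thickness).
#'
#' @param samples data.frame from [fiber_thickness()].
#' @param partition a `voronoi_partition`.
#' @param exclusion_mask optional logical image; samples on TRUE pixels are
#'   excluded.
#' @param dist_bin_um,thick_bin_um density grid bin widths.
#' @return list: `table` (distance_um, thickness_um, seed), `density`
#'   (matrix of counts), `dist_breaks_um`, `thick_breaks_um`, `n_excluded`.
#' @export
thickness_vs_distance <- function(samples, partition, exclusion_mask = NULL,
                                  dist_bin_um = 50, thick_bin_um = 2) {
  stopifnot(inherits(partition, "voronoi_partition"))
  px <- partition$pixel_size_um
  n0 <- nrow(samples)
  if (n0 == 0L)
    return(list(table = data.frame(distance_um = numeric(0),
                                   thickness_um = numeric(0), seed = integer(0)),
                density = matrix(0, 0, 0), dist_breaks_um = numeric(0),
                thick_breaks_um = numeric(0), n_excluded = 0L))
  yi <- pmin(nrow(partition$labels), pmax(1L, round(samples$y)))
  xi <- pmin(ncol(partition$labels), pmax(1L, round(samples$x)))
  keep <- rep(TRUE, n0)
  if (!is.null(exclusion_mask))
    keep <- !exclusion_mask[cbind(yi, xi)]
  seed_id <- partition$labels[cbind(yi, xi)]
  y_um <- (samples$y - 1) * px; x_um <- (samples$x - 1) * px
  dist_um <- sqrt((y_um - partition$seeds[seed_id, 1])^2 +
                  (x_um - partition$seeds[seed_id, 2])^2)
  tab <- data.frame(distance_um = dist_um[keep],
                    thickness_um = samples$thickness_um[keep],
                    seed = seed_id[keep])
  db <- seq(0, max(tab$distance_um, dist_bin_um) + dist_bin_um, by = dist_bin_um)
  tb <- seq(0, max(tab$thickness_um, thick_bin_um) + thick_bin_um, by = thick_bin_um)
  di <- findInterval(tab$distance_um, db, rightmost.closed = TRUE)
  ti <- findInterval(tab$thickness_um, tb, rightmost.closed = TRUE)
  dens <- matrix(0L, length(db) - 1L, length(tb) - 1L)
  for (i in seq_len(nrow(tab))) dens[di[i], ti[i]] <- dens[di[i], ti[i]] + 1L
  list(table = tab, density = dens, dist_breaks_um = db, thick_breaks_um = tb,
       n_excluded = sum(!keep))
}

#' Flag highly oriented (medullary-like) bins
#'
#' Builds a pixel-level exclusion mask from [anisotropy_bins()] output:
#' bins whose anisotropy exceeds the given quantile across bins are marked.
#'
#' @param bins data.frame from [anisotropy_bins()].
#' @param shape image shape `c(ny, nx)`.
#' @param quantile anisotropy quantile above which a bin is flagged
#'   (default 0.9).
#' @return logical matrix.
#' @export
high_anisotropy_mask <- function(bins, shape, quantile = 0.9) {
  b <- attr(bins, "bin_px")
  thr <- stats::quantile(bins$anisotropy, quantile, names = FALSE)
  m <- matrix(FALSE, shape[1], shape[2])
  sel <- bins$anisotropy > thr
  for (i in which(sel)) {
    y0 <- bins$y0[i]; x0 <- bins$x0[i]
    m[y0:min(shape[1], y0 + b - 1L), x0:min(shape[2], x0 + b - 1L)] <- TRUE
  }
  m
}
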