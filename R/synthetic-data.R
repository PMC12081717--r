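# Synthetic phantoms with voxel-exact ground truth.
#
# Every generator is deterministic given its seed: identical call + seed
# gives bit-identical arrays. Noise is additive Gaussian on intensities,
# clipped at zero.

#' Phantom specification
#'
#' @param kind one of `"spectral_mixture"`, `"glomerulus_volume"`,
#'   `"fiber_field"`, `"redox_map"`.
#' @param shape integer dimensions: `c(y, x)` for images, `c(z, y, x)` for
#'   volumes.
#' @param pixel_size_um lateral pixel size (um).
#' @param z_spacing_um axial spacing (um), volumes only.
#' @param noise_sigma additive Gaussian noise s.d., relative to unit signal.
#' @param seed integer seed; all randomness in a generator flows from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("spectral_mixture", "glomerulus_volume",
                                  "fiber_field", "redox_map"),
                         shape, pixel_size_um = 1, z_spacing_um = 1,
                         noise_sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (any(shape <= 0L)) stopf("shape must be strictly positive")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (pixel_size_um <= 0 || z_spacing_um <= 0) stopf("spacings must be positive")
  structure(list(kind = kind, shape = shape, pixel_size_um = pixel_size_um,
                 z_spacing_um = z_spacing_um, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

add_noise <- function(x, sigma) {
  if (sigma <= 0) return(x)
  pmax(x + stats::rnorm(length(x), 0, sigma), 0) * 1 # clip at 0, keep dim
}

#' Synthetic reference spectrum library
#'
#' Builds `n_subtypes` distinct lipid-subtype stand-ins on a common
#' wavenumber axis. Each spectrum is a mixture of 2-5 Gaussian bands whose
#' centers are drawn from the C-H stretching landmarks
#' (2850, 2880, 2940, 3011 cm^-1) with jitter, max-normalized to 1. Spectra
#' are redrawn until all pairwise cosine similarities are below 0.99.
#'
#' @param n_subtypes number of spectra (>= 2).
#' @param wavenumber_axis strictly increasing grid covering at least
#'   2700-3100 cm^-1.
#' @param seed integer seed.
#' @return list of `reference_spectrum` objects named `subtype_1`, ...
#' @export
make_reference_library <- function(n_subtypes,
                                   wavenumber_axis = seq(2700, 3100, by = 1),
                                   seed = 1L) {
  if (n_subtypes < 2L) stopf("n_subtypes must be >= 2")
  wavenumber_axis <- as.numeric(wavenumber_axis)
  if (any(diff(wavenumber_axis) <= 0)) stopf("invalid axis: must be strictly increasing")
  if (min(wavenumber_axis) > 2700 || max(wavenumber_axis) < 3100)
    stopf("axis must cover [2700, 3100] cm^-1")
  landmarks <- c(2850, 2880, 2940, 3011)
  with_seed(seed, {
    specs <- list()
    cos_ok <- function(a, b) {
      s <- sum(a * b) / sqrt(sum(a^2) * sum(b^2)); s < 0.99
    }
    guard <- 0L
    while (length(specs) < n_subtypes) {
      guard <- guard + 1L
      if (guard > 1000L) stopf("could not draw %d distinct spectra", n_subtypes)
      npk <- sample(2:5, 1)
      centers <- sample(landmarks, npk, replace = TRUE) + stats::rnorm(npk, 0, 6)
      widths <- stats::runif(npk, 12, 35)
      heights <- stats::runif(npk, 0.3, 1)
      y <- rep(0, length(wavenumber_axis))
      for (p in seq_len(npk))
        y <- y + heights[p] * exp(-(wavenumber_axis - centers[p])^2 / (2 * widths[p]^2))
      y <- y / max(y)
      if (all(vapply(specs, function(s) cos_ok(s$intensities, y), logical(1))))
        specs[[length(specs) + 1L]] <-
          reference_spectrum(sprintf("subtype_%d", length(specs) + 1L),
                             wavenumber_axis, y)
    }
    specs
  })
}

#' Spectral mixture phantom
#'
#' Each tissue pixel's spectrum is a non-negative convex mixture of the
#' reference spectra plus optional Gaussian noise; abundance maps are
#' spatially smooth simplex fields (Gaussian-blurred random fields pushed
#' through a softmax). Background pixels (outside a central tissue disk)
#' carry noise only.
#'
#' @param refs list of `reference_spectrum` on a common axis (>= 2).
#' @param spec a `phantom_spec` with 2-D `shape`.
#' @param abundance optional explicit abundance array `(y, x, n_refs)`
#'   overriding the random fields (rows must lie on the simplex where tissue).
#' @param sharpness softmax inverse temperature controlling how dominant the
#'   leading subtype is per pixel (default 3: most pixels > 60% dominant).
#' @return list with `stack` (`hyperspectral_stack`) and `truth` (list:
#'   `abundance_maps` array `(y, x, n_refs)`, `tissue_mask`,
#'   `noiseless` array).
#' @export
make_spectral_mixture_phantom <- function(refs, spec, abundance = NULL,
                                          sharpness = 3) {
  if (length(refs) < 2L) stopf("need >= 2 reference spectra")
  wn <- refs[[1]]$wavenumbers
  for (r in refs)
    if (!isTRUE(all.equal(r$wavenumbers, wn)))
      stopf("axis mismatch between reference spectra")
  ny <- spec$shape[1]; nx <- spec$shape[2]
  K <- length(refs)
  with_seed(spec$seed, {
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    tissue <- ((yy - (ny + 1) / 2)^2 + (xx - (nx + 1) / 2)^2) <=
      (0.45 * min(ny, nx))^2
    if (is.null(abundance)) {
      abundance <- array(0, c(ny, nx, K))
      # brush must fit inside the image: gblur uses a ~6 sigma support
      sig <- max(1, min(min(ny, nx) / 8, (min(ny, nx) - 2) / 7))
      for (k in seq_len(K))
        abundance[, , k] <- EBImage::gblur(matrix(stats::rnorm(ny * nx), ny, nx),
                                           sigma = sig)
      # normalize field scale, then softmax onto the simplex
      for (k in seq_len(K)) {
        f <- abundance[, , k]
        abundance[, , k] <- (f - mean(f)) / stats::sd(f)
      }
      e <- exp(sharpness * abundance)
      tot <- apply(e, c(1, 2), sum)
      for (k in seq_len(K)) abundance[, , k] <- e[, , k] / tot
    } else {
      if (!identical(dim(abundance), c(ny, nx, K)))
        stopf("abundance must be (y, x, n_refs)")
    }
    for (k in seq_len(K)) abundance[, , k][!tissue] <- 0
    R <- vapply(refs, function(r) r$intensities, numeric(length(wn)))  # nv x K
    A <- matrix(abundance, ny * nx, K)
    noiseless <- array(A %*% t(R), c(ny, nx, length(wn)))
    data <- if (spec$noise_sigma > 0)
      array(add_noise(noiseless, spec$noise_sigma), dim(noiseless)) else noiseless
    list(stack = hyperspectral_stack(data, wn, spec$pixel_size_um),
         truth = list(abundance_maps = abundance, tissue_mask = tissue,
                      noiseless = noiseless))
  })
}

#' Spherical glomerulus volume phantom
#'
#' Builds a protein-channel volume holding one renal-corpuscle sphere whose
#' concentric inner sphere (the tuft / mesangium) occupies, voxel-exactly,
#' `mes_fraction` of corpuscle voxels; the shell between them is
#' low-intensity Bowman's space. Voxel membership uses the center-inside
#' rule, and ground truth is reported on the same rule. `clip_fraction` of
#' the sphere diameter is cut off by the z = 0 face of the volume (polar cap
#' removed), emulating glomeruli only partially inside the imaging volume.
#' A nuclei channel holds non-touching small spheres with known counts
#' inside the tuft ("glomerulus") and outside the corpuscle ("cortex").
#'
#' Intensity levels: tuft 1.0, Bowman's space 0.4, surround 0 (+ noise).
#'
#' @param spec `phantom_spec` with 3-D `shape` `(z, y, x)`.
#' @param radius_um corpuscle radius (um); kidney glomeruli are roughly
#'   200 um in diameter, so 100 is the natural default.
#' @param mes_fraction target tuft/corpuscle voxel fraction in (0, 1].
#' @param clip_fraction fraction of the sphere diameter cut off by the
#'   volume boundary, in [0, 1).
#' @param nuclei_counts named integer vector
#'   `c(glomerulus = ..., cortex = ...)`; use 0s to skip nuclei.
#' @param nucleus_radius_um nucleus sphere radius (um).
#' @return list with `volume` (`multimodal_volume`, channels `protein_2940`
#'   and `nuclei`) and `truth` (list: `vv_true`, `voxelization_error`,
#'   `corpuscle_mask`, `tuft_mask`, `center_um` (z,y,x),
#'   `expected_retained`, `expected_thickness_um`,
#'   `nuclei_count_by_region`, `nuclei_centers`).
#' @export
make_glomerulus_volume_phantom <- function(spec, radius_um = 100,
                                           mes_fraction = 0.6,
                                           clip_fraction = 0,
                                           nuclei_counts = c(glomerulus = 0, cortex = 0),
                                           nucleus_radius_um = 4) {
  if (length(spec$shape) != 3L) stopf("glomerulus phantom needs a 3-D shape")
  if (mes_fraction <= 0 || mes_fraction > 1) stopf("mes_fraction must be in (0, 1]")
  if (clip_fraction < 0 || clip_fraction >= 1) stopf("clip_fraction must be in [0, 1)")
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  dz <- spec$z_spacing_um; dxy <- spec$pixel_size_um
  R <- radius_um
  cy <- (ny - 1) / 2 * dxy; cx <- (nx - 1) / 2 * dxy
  cz <- R * (1 - 2 * clip_fraction)           # top cap (z < 0) clipped
  if (cz + R > (nz - 1) * dz) stopf("geometry error: radius too large for shape (z)")
  if (R > cy || R > cx) stopf("geometry error: radius too large for shape (x/y)")

  zc <- (seq_len(nz) - 1) * dz
  yc <- (seq_len(ny) - 1) * dxy
  xc <- (seq_len(nx) - 1) * dxy
  dz2 <- (zc - cz)^2; dy2 <- (yc - cy)^2; dx2 <- (xc - cx)^2
  d2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)   # (z, y, x)
  corpuscle <- d2 <= R^2
  n_corp <- sum(corpuscle)
  if (n_corp == 0L) stopf("geometry error: corpuscle empty")

  # inner radius set by the voxel-distance quantile -> voxel-exact fraction
  if (mes_fraction >= 1) {
    tuft <- corpuscle
  } else {
    dist_corp <- sqrt(d2[corpuscle])
    k <- max(1L, round(mes_fraction * n_corp))
    r_in <- sort(dist_corp, partial = k)[k]
    tuft <- corpuscle & (d2 <= r_in^2)
  }
  vv_true <- sum(tuft) / n_corp

  protein <- array(0, c(nz, ny, nx))
  protein[corpuscle] <- 0.4
  protein[tuft] <- 1.0

  # nuclei: non-touching spheres on a coarse candidate grid
  nuclei <- array(0, c(nz, ny, nx))
  counts <- c(glomerulus = 0L, cortex = 0L)
  centers <- NULL
  r_nuc <- nucleus_radius_um
  want_g <- as.integer(nuclei_counts[["glomerulus"]] %||% 0)
  want_c <- as.integer(nuclei_counts[["cortex"]] %||% 0)
  phantom <- with_seed(spec$seed, {
    if (want_g + want_c > 0) {
      step_um <- 2 * r_nuc + 3 * max(dz, dxy)   # >= 2 empty voxels between nuclei
      gz <- seq(r_nuc, (nz - 1) * dz - r_nuc, by = step_um)
      gy <- seq(r_nuc, (ny - 1) * dxy - r_nuc, by = step_um)
      gx <- seq(r_nuc, (nx - 1) * dxy - r_nuc, by = step_um)
      cand <- as.matrix(expand.grid(z = gz, y = gy, x = gx))
      dc <- sqrt((cand[, 1] - cz)^2 + (cand[, 2] - cy)^2 + (cand[, 3] - cx)^2)
      in_tuft <- dc < (sqrt(max(d2[tuft])) - r_nuc - max(dz, dxy))
      in_cortex <- dc > (R + r_nuc + max(dz, dxy))
      pick <- function(idx, n, what) {
        if (length(idx) < n)
          stopf("geometry error: only %d sites for %d %s nuclei", length(idx), n, what)
        idx[sample(length(idx), n)]
      }
      sel <- c(if (want_g > 0) pick(which(in_tuft), want_g, "glomerular"),
               if (want_c > 0) pick(which(in_cortex), want_c, "cortical"))
      region <- c(rep("glomerulus", want_g), rep("cortex", want_c))
      centers <- cbind(cand[sel, , drop = FALSE])
      for (i in seq_len(nrow(centers))) {
        p <- centers[i, ]
        iz <- which(abs(zc - p[1]) <= r_nuc)
        iy <- which(abs(yc - p[2]) <= r_nuc)
        ix <- which(abs(xc - p[3]) <= r_nuc)
        sub <- outer(outer((zc[iz] - p[1])^2, (yc[iy] - p[2])^2, `+`),
                     (xc[ix] - p[3])^2, `+`) <= r_nuc^2
        nuclei[iz, iy, ix][sub] <- 1.0
      }
      counts <- c(glomerulus = want_g, cortex = want_c)
      centers <- data.frame(z_um = centers[, 1], y_um = centers[, 2],
                            x_um = centers[, 3], region = region)
    }
    if (spec$noise_sigma > 0) {
      protein <- array(add_noise(protein, spec$noise_sigma), dim(protein))
      nuclei <- array(add_noise(nuclei, spec$noise_sigma), dim(nuclei))
    }
    list(protein = protein, nuclei = nuclei, counts = counts, centers = centers)
  })

  # expected hemisphere-rule outcome (see glomerulus module): thickness is
  # measured from the max-area plane to the vanishing pole; a terminal
  # max-area plane forces the 100 um default radius.
  max_terminal <- clip_fraction >= 0.5
  exp_thick <- if (max_terminal) cz + R else R
  radius_used <- if (max_terminal) 100 else R
  truth <- list(vv_true = vv_true,
                voxelization_error = vv_true - mes_fraction,
                corpuscle_mask = corpuscle, tuft_mask = tuft,
                center_um = c(z = cz, y = cy, x = cx), radius_um = R,
                expected_thickness_um = exp_thick,
                expected_retained = exp_thick >= 0.9 * radius_used,
                nuclei_count_by_region = phantom$counts,
                nuclei_centers = phantom$centers)
  vol <- multimodal_volume(list(protein_2940 = phantom$protein,
                                nuclei = phantom$nuclei),
                           z_spacing_um = dz, pixel_size_um = dxy)
  list(volume = vol, truth = truth)
}

#' Collagen fiber phantom
#'
#' Straight ribbons of stated pixel width and orientation on a zero
#' background. Orientation is measured in degrees from the +x (column) axis
#' toward +y (row, downward), in [0, 180). Even widths are centred between
#' pixel rows so the rasterized width is exact; odd widths are centred on a
#' pixel row.
#'
#' @param spec `phantom_spec` with 2-D `shape`.
#' @param widths_px positive fiber widths (px), one per fiber.
#' @param orientations_deg orientations in [0, 180), one per fiber.
#' @param length_frac fiber half-length as a fraction of the image diagonal.
#' @return list with `image` (matrix) and `truth` (data.frame `width_px`,
#'   `orientation_deg`, `center_y`, `center_x`).
#' @export
make_fiber_phantom <- function(spec, widths_px, orientations_deg,
                               length_frac = 0.35) {
  if (length(widths_px) != length(orientations_deg))
    stopf("widths and orientations must have equal length")
  ny <- spec$shape[1]; nx <- spec$shape[2]
  img <- matrix(0, ny, nx)
  n <- length(widths_px)
  if (n == 0L)
    return(list(image = img,
                truth = data.frame(width_px = numeric(0),
                                   orientation_deg = numeric(0),
                                   center_y = numeric(0), center_x = numeric(0))))
  if (any(widths_px < 1)) stopf("fiber widths must be >= 1 px")
  if (any(orientations_deg < 0 | orientations_deg >= 180))
    stopf("orientations must be in [0, 180)")
  with_seed(spec$seed, {
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    # deterministic, well-separated centers on a diagonal layout
    cys <- (seq_len(n) / (n + 1)) * ny
    cxs <- (seq_len(n) / (n + 1)) * nx
    L <- length_frac * sqrt(ny^2 + nx^2)
    truth <- data.frame(width_px = widths_px,
                        orientation_deg = orientations_deg,
                        center_y = cys, center_x = cxs)
    for (i in seq_len(n)) {
      th <- orientations_deg[i] * pi / 180
      ux <- cos(th); uy <- sin(th)          # fiber direction (x right, y down)
      w <- widths_px[i]
      # even widths: center the line between rows so rasterized width is exact
      off <- if (w %% 2 == 0) 0.5 else 0
      dyp <- yy - (cys[i] + off * abs(ux)); dxp <- xx - (cxs[i] + off * abs(uy))
      d_perp <- abs(-uy * dxp + ux * dyp)
      d_par <- abs(ux * dxp + uy * dyp)
      img[d_perp <= (w - 1) / 2 + 1e-9 & d_par <= L] <- 1
    }
    if (spec$noise_sigma > 0)
      img <- matrix(add_noise(img, spec$noise_sigma), ny, nx)
    list(image = img, truth = truth)
  })
}

#' Redox (NADH / FAD) channel-pair phantom
#'
#' Builds two-photon-fluorescence channel stand-ins from a known optical
#' redox ratio map: `FAD = orr_map * total_intensity`,
#' `NADH = (1 - orr_map) * total_intensity`, so `FAD / (NADH + FAD)`
#' recovers the map exactly at zero noise.
#'
#' @param spec `phantom_spec` with 2-D `shape`.
#' @param orr_map matrix of values in [0, 1] matching `spec$shape`; default
#'   is a left-to-right 0 to 1 gradient.
#' @param total_intensity summed channel intensity per pixel (> 0).
#' @return list with `nadh`, `fad` (matrices) and `truth` (list `orr_map`).
#' @export
make_redox_phantom <- function(spec, orr_map = NULL, total_intensity = 1) {
  ny <- spec$shape[1]; nx <- spec$shape[2]
  if (is.null(orr_map))
    orr_map <- matrix(rep(seq(0, 1, length.out = nx), each = ny), ny, nx)
  if (!identical(dim(orr_map), c(ny, nx))) stopf("orr_map shape must match spec")
  if (any(orr_map < 0 | orr_map > 1)) stopf("orr_map values must be in [0, 1]")
  if (total_intensity <= 0) stopf("total_intensity must be positive")
  fad <- orr_map * total_intensity
  nadh <- (1 - orr_map) * total_intensity
  with_seed(spec$seed, {
    if (spec$noise_sigma > 0) {
      fad <- matrix(add_noise(fad, spec$noise_sigma), ny, nx)
      nadh <- matrix(add_noise(nadh, spec$noise_sigma), ny, nx)
    }
    list(nadh = nadh, fad = fad, truth = list(orr_map = orr_map))
  })
}
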