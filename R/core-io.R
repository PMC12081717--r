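# Data model and file I/O for multimodal kidney microscopy.
#
# Conventions: 2-D images are numeric matrices indexed [y, x] with y
# increasing downward; volumes are arrays indexed [z, y, x]. All physical
# distances derive from pixel_size_um (lateral) and z_spacing_um (axial).

#' Hyperspectral SRS stack
#'
#' Container for a per-pixel Raman spectrum image: a `(y, x, wavenumber)`
#' array with a calibrated, strictly increasing wavenumber axis in cm^-1.
#'
#' @param data numeric array `(y, x, n_wavenumbers)`, non-negative, finite.
#' @param wavenumbers strictly increasing numeric vector (cm^-1), one entry
#'   per spectral plane.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param meta optional free-form acquisition metadata (carried, never
#'   interpreted).
#' @return An object of class `hyperspectral_stack`.
#' @export
hyperspectral_stack <- function(data, wavenumbers, pixel_size_um = 1, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a 3-D array (y, x, wavenumber)")
  if (any(!is.finite(data))) stopf("stack data must be finite")
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != dim(data)[3])
    stopf("length(wavenumbers) [%d] != number of spectral planes [%d]",
          length(wavenumbers), dim(data)[3])
  if (any(diff(wavenumbers) <= 0))
    stopf("wavenumber axis must be strictly increasing")
  if (pixel_size_um <= 0) stopf("pixel_size_um must be positive")
  structure(list(data = data, wavenumbers = wavenumbers,
                 pixel_size_um = pixel_size_um, meta = meta),
            class = "hyperspectral_stack")
}

#' @export
print.hyperspectral_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyperspectral_stack> %d x %d px, %d wavenumbers (%.0f-%.0f cm-1), %.3g um/px\n",
              d[1], d[2], d[3], min(x$wavenumbers), max(x$wavenumbers),
              x$pixel_size_um))
  invisible(x)
}

#' Reference spectrum for a lipid subtype
#'
#' @param name subtype name, e.g. `"cholesterol"`, `"TAG"`.
#' @param wavenumbers numeric vector (cm^-1), strictly increasing.
#' @param intensities non-negative numeric vector, same length; maximum must
#'   be positive.
#' @return An object of class `reference_spectrum`.
#' @export
reference_spectrum <- function(name, wavenumbers, intensities) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stopf("wavenumbers and intensities must have equal length")
  if (any(diff(wavenumbers) <= 0)) stopf("wavenumber axis must be strictly increasing")
  if (any(intensities < 0)) stopf("reference intensities must be non-negative")
  if (max(intensities) <= 0) stopf("reference spectrum must have positive maximum")
  structure(list(name = as.character(name), wavenumbers = wavenumbers,
                 intensities = intensities),
            class = "reference_spectrum")
}

#' Registered multimodal volume
#'
#' Channel set acquired on one platform and therefore co-registered. Channel
#' arrays are `(z, y, x)`; recognised names are `lipid_2850`, `sat_2880`,
#' `protein_2940`, `unsat_3011`, `nadh`, `flavin`, `shg`, `nuclei`, but any
#' named channel is carried.
#'
#' @param channels named list of 3-D arrays sharing one shape.
#' @param z_spacing_um axial plane spacing (micrometres).
#' @param pixel_size_um lateral pixel size (micrometres).
#' @return An object of class `multimodal_volume`.
#' @export
multimodal_volume <- function(channels, z_spacing_um, pixel_size_um) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stopf("'channels' must be a named list")
  shp <- NULL
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.array(ch) || length(dim(ch)) != 3L)
      stopf("channel '%s' must be a 3-D array (z, y, x)", nm)
    if (is.null(shp)) shp <- dim(ch)
    if (!identical(dim(ch), shp)) stopf("channel '%s' shape differs", nm)
  }
  if (z_spacing_um <= 0 || pixel_size_um <= 0) stopf("spacings must be positive")
  structure(list(channels = channels, z_spacing_um = z_spacing_um,
                 pixel_size_um = pixel_size_um),
            class = "multimodal_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multimodal_volume> %d z-planes of %d x %d px; channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# ---- TIFF + YAML sidecar round-trip --------------------------------------

#' Write a stack or volume as multi-page TIFF with a YAML sidecar
#'
#' Pixel data go to a 32-bit float multi-page TIFF; axis calibration and the
#' channel/wavenumber listing go to `<path>.yaml`. Volumes are written
#' channel-major (all z-planes of channel 1, then channel 2, ...).
#'
#' @param x a `hyperspectral_stack` or `multimodal_volume`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "hyperspectral_stack")) {
    pages <- lapply(seq_along(x$wavenumbers), function(k) x$data[, , k])
    side <- list(type = "hyperspectral_stack",
                 wavenumbers = as.numeric(x$wavenumbers),
                 pixel_size_um = x$pixel_size_um)
  } else if (inherits(x, "multimodal_volume")) {
    nz <- dim(x$channels[[1]])[1]
    pages <- list()
    for (nm in names(x$channels))
      for (k in seq_len(nz))
        pages[[length(pages) + 1L]] <- x$channels[[nm]][k, , ]
    side <- list(type = "multimodal_volume",
                 channels = names(x$channels), n_z = nz,
                 z_spacing_um = x$z_spacing_um,
                 pixel_size_um = x$pixel_size_um)
  } else stopf("write_stack() handles hyperspectral_stack or multimodal_volume")
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a stack or volume written by [write_stack()]
#'
#' The wavenumber axis / channel listing is taken from the YAML sidecar; a
#' file whose page count disagrees with the sidecar is rejected rather than
#' silently indexed by plane number.
#'
#' @param path TIFF path; `<path>.yaml` must exist (or pass `sidecar`).
#' @param sidecar optional explicit sidecar path.
#' @return A `hyperspectral_stack` or `multimodal_volume`.
#' @export
read_stack <- function(path, sidecar = paste0(path, ".yaml")) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (!file.exists(sidecar))
    stopf("missing axis sidecar '%s': refusing to index planes by number", sidecar)
  side <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  if (identical(side$type, "hyperspectral_stack")) {
    wn <- as.numeric(side$wavenumbers)
    if (length(pages) != length(wn))
      stopf("format error: %d TIFF pages but %d wavenumbers listed",
            length(pages), length(wn))
    d <- dim(pages[[1]])
    arr <- array(0, c(d[1], d[2], length(wn)))
    for (k in seq_along(wn)) arr[, , k] <- pages[[k]]
    hyperspectral_stack(arr, wn, side$pixel_size_um %||% 1)
  } else if (identical(side$type, "multimodal_volume")) {
    chn <- as.character(side$channels)
    nz <- as.integer(side$n_z)
    if (length(pages) != length(chn) * nz)
      stopf("format error: %d TIFF pages but %d channels x %d planes listed",
            length(pages), length(chn), nz)
    d <- dim(pages[[1]])
    channels <- list()
    i <- 0L
    for (nm in chn) {
      a <- array(0, c(nz, d[1], d[2]))
      for (k in seq_len(nz)) { i <- i + 1L; a[k, , ] <- pages[[i]] }
      channels[[nm]] <- a
    }
    multimodal_volume(channels, side$z_spacing_um %||% 1,
                      side$pixel_size_um %||% 1)
  } else stopf("sidecar 'type' must be hyperspectral_stack or multimodal_volume")
}

#' Read / write a reference spectrum as two-column CSV
#'
#' Columns are `wavenumber_cm1` and `intensity`.
#'
#' @param path CSV path.
#' @param name subtype name; defaults to the file stem.
#' @return A `reference_spectrum`.
#' @export
read_reference_csv <- function(path, name = sub("\\.csv$", "", basename(path))) {
  df <- utils::read.csv(path)
  if (!all(c("wavenumber_cm1", "intensity") %in% names(df)))
    stopf("reference CSV needs columns wavenumber_cm1, intensity")
  reference_spectrum(name, df$wavenumber_cm1, df$intensity)
}

#' @rdname read_reference_csv
#' @param ref a `reference_spectrum` to write.
#' @export
write_reference_csv <- function(ref, path) {
  utils::write.csv(data.frame(wavenumber_cm1 = ref$wavenumbers,
                              intensity = ref$intensities),
                   path, row.names = FALSE)
  invisible(path)
}

# ---- Spectral utilities ----------------------------------------------------

#' Spectral phasor transform
#'
#' Maps each pixel spectrum to normalized Fourier coordinates over the
#' spectral window: `G = sum I cos(2 pi n (v - v0)/dv) / sum I` and the
#' matching sine term `S`, with `v0` the window start and `dv` its span.
#' Pixels with zero total intensity are flagged invalid rather than
#' propagating NaN.
#'
#' @param stack a `hyperspectral_stack`.
#' @param harmonic positive integer harmonic `n` (default 1).
#' @param window optional `c(v_min, v_max)` restriction of the axis.
#' @return list with images `G`, `S`, logical `valid`, and `harmonic`.
#' @export
phasor_transform <- function(stack, harmonic = 1L, window = NULL) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  harmonic <- as.integer(harmonic)
  if (harmonic < 1L) stopf("harmonic must be >= 1")
  wn <- stack$wavenumbers
  keep <- if (is.null(window)) rep(TRUE, length(wn)) else
    wn >= window[1] & wn <= window[2]
  if (sum(keep) < 3L) stopf("spectral window too narrow")
  wn <- wn[keep]
  v0 <- wn[1]; dv <- wn[length(wn)] - v0
  phase <- 2 * pi * harmonic * (wn - v0) / dv
  d <- dim(stack$data)
  X <- matrix(stack$data[, , keep, drop = FALSE], d[1] * d[2], sum(keep))
  tot <- rowSums(X)
  valid <- tot > 0
  G <- S <- rep(NA_real_, length(tot))
  G[valid] <- (X[valid, , drop = FALSE] %*% cos(phase)) / tot[valid]
  S[valid] <- (X[valid, , drop = FALSE] %*% sin(phase)) / tot[valid]
  list(G = matrix(G, d[1], d[2]), S = matrix(S, d[1], d[2]),
       valid = matrix(valid, d[1], d[2]), harmonic = harmonic)
}

#' Three-peak linear unmixing into lipid and protein images
#'
#' Solves, per pixel, a non-negative least-squares fit of the SRS
#' intensities at 2850/2880/2940 cm^-1 against two endmember profiles
#' (pure lipid and pure protein three-vectors). With two unknowns the NNLS
#' solution is exact: take the unconstrained fit if feasible, otherwise the
#' best single-endmember fit.
#'
#' @param stack a `hyperspectral_stack` covering the three peaks.
#' @param peaks wavenumbers of the peaks used (cm^-1).
#' @param endmembers 3 x 2 matrix, columns `lipid` and `protein`; defaults
#'   reflect CH2-dominated lipid and CH3-dominated protein band shapes and
#'   should be replaced by measured references when available.
#' @return list of images `lipid`, `protein` (non-negative coefficients).
#' @export
linear_unmix <- function(stack, peaks = c(2850, 2880, 2940),
                         endmembers = cbind(lipid = c(1.0, 0.7, 0.3),
                                            protein = c(0.2, 0.5, 1.0))) {
  stopifnot(inherits(stack, "hyperspectral_stack"))
  wn <- stack$wavenumbers
  if (any(peaks < min(wn) | peaks > max(wn)))
    stopf("requested peaks outside the stack wavenumber axis")
  d <- dim(stack$data)
  npx <- d[1] * d[2]
  B <- matrix(0, npx, length(peaks))
  for (j in seq_along(peaks)) {
    # linear interpolation of the spectral cube at the peak wavenumber
    k <- findInterval(peaks[j], wn)
    if (k == length(wn)) { B[, j] <- as.vector(stack$data[, , k]); next }
    t <- (peaks[j] - wn[k]) / (wn[k + 1] - wn[k])
    B[, j] <- (1 - t) * as.vector(stack$data[, , k]) +
      t * as.vector(stack$data[, , k + 1])
  }
  A <- endmembers
  AtA <- crossprod(A); Atb <- t(B %*% A)   # 2 x npx
  det <- AtA[1, 1] * AtA[2, 2] - AtA[1, 2]^2
  c1 <- (AtA[2, 2] * Atb[1, ] - AtA[1, 2] * Atb[2, ]) / det
  c2 <- (AtA[1, 1] * Atb[2, ] - AtA[1, 2] * Atb[1, ]) / det
  neg <- c1 < 0 | c2 < 0
  if (any(neg)) {
    # exact NNLS for 2 vars: best axis-constrained fit when interior infeasible
    a1 <- pmax(0, Atb[1, neg] / AtA[1, 1])
    a2 <- pmax(0, Atb[2, neg] / AtA[2, 2])
    r1 <- a1^2 * AtA[1, 1] - 2 * a1 * Atb[1, neg]
    r2 <- a2^2 * AtA[2, 2] - 2 * a2 * Atb[2, neg]
    use1 <- r1 <= r2
    c1[neg] <- ifelse(use1, a1, 0)
    c2[neg] <- ifelse(use1, 0, a2)
  }
  list(lipid = matrix(pmax(c1, 0), d[1], d[2]),
       protein = matrix(pmax(c2, 0), d[1], d[2]))
}

#' Per-label simplex-normalized mean channel intensities
#'
#' For each label, the mean intensity of every channel is divided by the sum
#' over channels, so each row sums to 1 — the per-cluster channel
#' contribution display used for multimodal whole-slide clusters.
#'
#' @param volume a `multimodal_volume` (or named list of equally shaped
#'   arrays/matrices).
#' @param labels integer label array matching channel shape (0 = background,
#'   omitted).
#' @return data.frame: `label`, then one column per channel; rows sum to 1.
#' @export
channel_fractions <- function(volume, labels) {
  channels <- if (inherits(volume, "multimodal_volume")) volume$channels else volume
  shp <- dim(channels[[1]])
  if (!identical(dim(labels), shp)) stopf("labels shape must match channels")
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (length(ids) == 0L) stopf("no labeled pixels")
  lab <- as.integer(labels)
  sel <- lab > 0L
  lab <- lab[sel]
  means <- sapply(channels, function(ch) {
    as.numeric(tapply(as.numeric(ch)[sel], lab, mean))
  })
  means <- matrix(means, nrow = length(ids),
                  dimnames = list(NULL, names(channels)))
  tot <- rowSums(means)
  if (any(tot <= 0)) warnf("label(s) with zero total intensity: fractions NaN")
  out <- data.frame(label = ids, means / tot, check.names = FALSE)
  rownames(out) <- NULL
  out
}
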