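# Penalized Reference Matching (PRM) of hyperspectral SRS pixels against
# lipid-subtype reference spectra.
#
# Each pixel spectrum is scored by cosine similarity against the reference
# shifted over a grid of wavenumber offsets; each offset carries a penalty
# weight, and the per-pixel score is the maximum penalized similarity. This
# tolerates small calibration offsets between equipment while down-weighting
# matches that need a large shift.

#' Offset penalty specification
#'
#' Weight `w(delta)` applied to the cosine similarity at reference offset
#' `delta` (cm^-1). `w(0) = 1`, `w` non-increasing in `|delta|`, in (0, 1].
#'
#' @param kind `"gaussian"` (`exp(-delta^2 / (2 scale^2))`), `"linear"`
#'   (`max(min_weight, 1 - |delta|/scale)`) or `"none"` (always 1).
#' @param scale_cm1 penalty scale (cm^-1).
#' @param min_weight floor for the linear kind, keeping weights positive.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(kind = c("gaussian", "linear", "none"),
                         scale_cm1 = 10, min_weight = 1e-3) {
  kind <- match.arg(kind)
  if (scale_cm1 <= 0) stopf("scale_cm1 must be positive")
  structure(list(kind = kind, scale_cm1 = scale_cm1, min_weight = min_weight),
            class = "penalty_spec")
}

#' @rdname penalty_spec
#' @param penalty a `penalty_spec`.
#' @param delta offsets (cm^-1) to evaluate.
#' @return `penalty_weight()`: numeric weights in (0, 1].
#' @export
penalty_weight <- function(penalty, delta) {
  switch(penalty$kind,
         gaussian = exp(-delta^2 / (2 * penalty$scale_cm1^2)),
         linear = pmax(penalty$min_weight, 1 - abs(delta) / penalty$scale_cm1),
         none = rep(1, length(delta)))
}

#' Cosine similarity between two spectra
#'
#' `dot(a, b) / (|a| |b|)`, clipped into [0, 1] (spectra are non-negative,
#' so negative values can only arise from numeric guards). A zero vector
#' scores 0 with a warning rather than NaN.
#'
#' @param a,b numeric vectors of equal length.
#' @return similarity in [0, 1].
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stopf("spectra must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warnf("zero spectrum in cosine similarity: score defined as 0")
    return(0)
  }
  min(1, max(0, sum(a * b) / (na * nb)))
}

#' PRM similarity map for one reference
#'
#' Scores every pixel of a hyperspectral stack against a reference spectrum:
#' `s = max over delta of cos_sim(I(v), r(v - delta)) * w(delta)`. The
#' shifted reference is obtained by linear interpolation on the wavenumber
#' axis (edge values extended); scoring is restricted to the C-H stretching
#' window by default. Zero-intensity pixels are masked with score 0.
#'
#' @param stack a `hyperspectral_stack`.
#' @param ref a `reference_spectrum`.
#' @param offsets_cm1 offset grid (cm^-1); empty grid falls back to 0 only.
#' @param penalty a `penalty_spec`.
#' @param window spectral window `c(min, max)` in cm^-1 applied before
#'   scoring (default 2700-3100, the C-H stretching region).
#' @return An object of class `similarity_map`: `scores` (matrix in [0,1]),
#'   `winning_offset`, logical `mask` of scored pixels, `subtype`,
#'   `offsets_cm1`, `penalty`.
#' @export
prm_score <- function(stack, ref, offsets_cm1 = -10:10,
                      penalty = penalty_spec("gaussian", 10),
                      window = c(2700, 3100)) {
  stopifnot(inherits(stack, "hyperspectral_stack"),
            inherits(ref, "reference_spectrum"),
            inherits(penalty, "penalty_spec"))
  if (length(offsets_cm1) == 0L) offsets_cm1 <- 0
  wn <- stack$wavenumbers
  keep <- wn >= window[1] & wn <= window[2]
  if (sum(keep) < 3L) stopf("stack has < 3 samples in the scoring window")
  wn <- wn[keep]
  span <- max(wn) - min(wn)
  if (any(abs(offsets_cm1) > span)) stopf("offsets exceed the axis span")
  d <- dim(stack$data)
  X <- matrix(stack$data[, , keep, drop = FALSE], d[1] * d[2], sum(keep))
  xn <- sqrt(rowSums(X^2))
  w <- penalty_weight(penalty, offsets_cm1)
  best <- rep(-Inf, nrow(X))
  best_off <- rep(NA_real_, nrow(X))
  for (j in seq_along(offsets_cm1)) {
    # r(v - delta): sample the reference at v - delta, edges extended
    rs <- stats::approx(ref$wavenumbers, ref$intensities,
                        xout = wn - offsets_cm1[j], rule = 2)$y
    rn <- sqrt(sum(rs^2))
    if (rn == 0) next
    s <- (X %*% rs) / (xn * rn) * w[j]
    s[xn == 0] <- -Inf
    upd <- s > best
    best[upd] <- s[upd]
    best_off[upd] <- offsets_cm1[j]
  }
  valid <- xn > 0
  best[!valid] <- 0
  best_off[!valid] <- NA_real_
  structure(list(scores = matrix(pmin(1, pmax(0, best)), d[1], d[2]),
                 winning_offset = matrix(best_off, d[1], d[2]),
                 mask = matrix(valid, d[1], d[2]),
                 subtype = ref$name, offsets_cm1 = offsets_cm1,
                 penalty = penalty),
            class = "similarity_map")
}

#' Simplex normalization across subtype maps
#'
#' Divides each map's per-pixel score by the sum of scores across subtypes,
#' so per-pixel scores sum to 1; pixels with zero total are masked. The
#' normalized intensities are interpreted as relative concentrations.
#'
#' @param maps list of >= 2 `similarity_map` objects of identical shape.
#' @return list of `similarity_map` objects with normalized scores.
#' @export
simplex_normalize <- function(maps) {
  if (length(maps) < 2L) stopf("need >= 2 similarity maps")
  shp <- dim(maps[[1]]$scores)
  for (m in maps) {
    stopifnot(inherits(m, "similarity_map"))
    if (!identical(dim(m$scores), shp)) stopf("similarity maps differ in shape")
  }
  tot <- Reduce(`+`, lapply(maps, function(m) m$scores))
  ok <- tot > 0
  lapply(maps, function(m) {
    s <- m$scores
    s[ok] <- s[ok] / tot[ok]
    s[!ok] <- 0
    m$scores <- s
    m$mask <- m$mask & ok
    m
  })
}

#' Mean spectrum of the top-scoring pixels
#'
#' Selects unmasked pixels whose score is at or above the `(100 - p)`-th
#' percentile (ties included) and returns their mean spectrum with a
#' per-wavenumber standard-deviation band — the "top p% of similarity
#' scores" overlay used to sanity-check a reference match.
#'
#' @param stack the scored `hyperspectral_stack`.
#' @param map its `similarity_map`.
#' @param p percentile in (0, 100]; `p = 100` averages all unmasked pixels.
#' @return list: `mean_spectrum`, `sd_spectrum`, logical `pixel_mask`,
#'   `wavenumbers`, `n_pixels`.
#' @export
top_percentile_spectra <- function(stack, map, p = 1) {
  stopifnot(inherits(stack, "hyperspectral_stack"), inherits(map, "similarity_map"))
  if (p <= 0 || p > 100) stopf("p must be in (0, 100]")
  if (!identical(dim(stack$data)[1:2], dim(map$scores))) stopf("shape mismatch")
  sc <- map$scores[map$mask]
  if (length(sc) == 0L) stopf("no unmasked pixels to select from")
  thr <- stats::quantile(sc, probs = 1 - p / 100, names = FALSE, type = 7)
  sel <- map$mask & map$scores >= thr
  n <- sum(sel)
  if (n < 10L) warnf("only %d pixels selected at p = %g", n, p)
  d <- dim(stack$data)
  X <- matrix(stack$data, d[1] * d[2], d[3])[as.vector(sel), , drop = FALSE]
  list(mean_spectrum = colMeans(X),
       sd_spectrum = apply(X, 2, stats::sd),
       pixel_mask = sel, wavenumbers = stack$wavenumbers, n_pixels = n)
}

#' Ratiometric map of two similarity maps
#'
#' Per-pixel `num / (den + eps)` on unmasked pixels; pixels where both maps
#' are below `eps` are masked. Returns the image, a histogram summary, and
#' the mean ratio (the "mean pixel intensity" line of ratiometric score
#' distributions).
#'
#' @param numerator,denominator `similarity_map` objects of one shape.
#' @param eps denominator guard (default 1e-6).
#' @param breaks histogram breaks (passed to [graphics::hist] semantics via
#'   [base::cut]; default 50 equal bins).
#' @return list: `ratio` (matrix), `valid_mask`, `mean`, `histogram`
#'   (data.frame `mid`, `count`).
#' @export
ratiometric_map <- function(numerator, denominator, eps = 1e-6, breaks = 50L) {
  stopifnot(inherits(numerator, "similarity_map"),
            inherits(denominator, "similarity_map"))
  assert_same_shape(numerator$scores, denominator$scores, "similarity maps")
  valid <- numerator$mask & denominator$mask &
    !(numerator$scores < eps & denominator$scores < eps)
  ratio <- matrix(NA_real_, nrow(numerator$scores), ncol(numerator$scores))
  ratio[valid] <- numerator$scores[valid] / (denominator$scores[valid] + eps)
  v <- ratio[valid]
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  list(ratio = ratio, valid_mask = valid, mean = mean(v),
       histogram = data.frame(mid = h$mids, count = h$counts))
}
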