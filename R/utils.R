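# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("'%s' must be a numeric matrix (y, x)", name)
  if (any(!is.finite(x))) stopf("'%s' contains non-finite values", name)
  invisible(x)
}

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) stopf("%s must share the same shape", what)
  invisible(TRUE)
}

# Trapezoidal integral on possibly non-uniform grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Otsu threshold on a numeric vector (maximizes between-class variance).
# Used where EBImage::otsu is inconvenient (value subsets, arbitrary range).
otsu_threshold <- function(v, levels = 256L) {
  v <- v[is.finite(v)]
  if (length(v) == 0L) return(NA_real_)
  rng <- range(v)
  if (diff(rng) <= .Machine$double.eps) return(rng[1])
  h <- tabulate(pmin(levels, 1L + floor((v - rng[1]) / diff(rng) * levels)),
                nbins = levels)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(levels) - 0.5) / levels * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  denom <- w0 * (1 - w0)
  bcv <- (mu_t * w0 - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(bcv)
  mids[k]
}

# Disc structuring element; radius 0 -> 1x1 identity.
disc_brush <- function(radius) {
  if (radius <= 0) return(matrix(1, 1, 1))
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

# Grayscale geodesic reconstruction by dilation: iterate dilate(marker) ^ mask.
reconstruct_dilation <- function(marker, mask, brush = matrix(1, 3, 3),
                                 max_iter = 10000L) {
  stopifnot(all(marker <= mask + 1e-12))
  cur <- pmin(marker, mask)
  for (i in seq_len(max_iter)) {
    nxt <- pmin(EBImage::dilate(cur, brush), mask)
    if (max(abs(nxt - cur)) < 1e-12) return(nxt)
    cur <- nxt
  }
  cur
}

# Regional maxima of a grayscale image via h-maxima reconstruction.
regional_maxima <- function(x, h = 1e-6) {
  rec <- reconstruct_dilation(x - h, x)
  (x - rec) > h / 2
}

# Per-label pixel counts of an integer label matrix (0 = background).
label_areas <- function(labels) {
  lab <- as.integer(labels)
  lab <- lab[lab > 0L]
  if (length(lab) == 0L) return(integer(0))
  tabulate(lab)
}

# Centroid (y, x) of each label, rows ordered by label id.
label_centroids <- function(labels) {
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (length(ids) == 0L)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x"))))
  idx <- which(labels > 0, arr.ind = TRUE)
  l <- labels[labels > 0]
  cy <- tapply(idx[, 1], l, mean)
  cx <- tapply(idx[, 2], l, mean)
  cbind(y = as.numeric(cy), x = as.numeric(cx))
}

# Deterministic RNG scope: runs expr with a local seed, restores global state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
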