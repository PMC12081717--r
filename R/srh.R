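# Stimulated Raman Histology (SRH): pseudo-coloring of SRS protein / lipid
# channels into H&E- and PAS-like RGB renders.
#
# Color work happens in L*a*b* (D65 white point, sRGB companding) so that
# lightness and chroma edits are perceptually meaningful and device
# independent; nuclei are darkened in L*, background is pushed toward
# white.

#' LUT pair for SRH blending
#'
#' Each LUT linearly interpolates from white (value 0) to an endpoint color
#' (value 1); the two colorized channels are then blended. With the default
#' `multiply` blend this emulates absorbing stains.
#'
#' @param protein_color,lipid_color RGB triplets in [0,1] at full intensity.
#'   Defaults: eosin pink for protein, near-white for lipid (lipid-rich
#'   interstitium stays unstained, as in H&E).
#' @param nuclei_color hematoxylin-like RGB used to recolor nuclei.
#' @param blend_mode `"multiply"`, `"screen"` or `"linear_sum_clipped"`.
#' @return An object of class `lut_pair`.
#' @export
lut_pair <- function(protein_color = c(1.00, 0.55, 0.60),
                     lipid_color = c(1.00, 0.97, 0.95),
                     nuclei_color = c(0.35, 0.25, 0.55),
                     blend_mode = c("multiply", "screen", "linear_sum_clipped")) {
  blend_mode <- match.arg(blend_mode)
  for (col in list(protein_color, lipid_color, nuclei_color))
    if (length(col) != 3L || any(col < 0 | col > 1))
      stopf("LUT endpoint colors must be RGB triplets in [0,1]")
  structure(list(protein_color = protein_color, lipid_color = lipid_color,
                 nuclei_color = nuclei_color, blend_mode = blend_mode),
            class = "lut_pair")
}

# value image in [0,1] -> (y, x, 3) via white -> color interpolation
apply_lut <- function(img, color) {
  out <- array(0, c(dim(img), 3L))
  for (c in 1:3) out[, , c] <- 1 - img * (1 - color[c])
  out
}

blend_rgb <- function(a, b, mode) {
  switch(mode,
         multiply = a * b,
         screen = 1 - (1 - a) * (1 - b),
         # subtractive: absorbances (1 - a) and (1 - b) add, result clipped
         linear_sum_clipped = pmin(1, pmax(0, a + b - 1)))
}

# percentile stretch to [0,1]; constant images map to 0
stretch01 <- function(img, probs = c(0.01, 0.99)) {
  q <- stats::quantile(img, probs, names = FALSE)
  if (q[2] - q[1] <= .Machine$double.eps) return(img * 0)
  clip01((img - q[1]) / (q[2] - q[1]))
}

rgb_to_lab <- function(rgb) {
  d <- dim(rgb)
  m <- matrix(rgb, d[1] * d[2], 3)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, c(d[1], d[2], 3))
}

lab_to_rgb <- function(lab) {
  d <- dim(lab)
  m <- matrix(lab, d[1] * d[2], 3)
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  array(clip01(rgb), c(d[1], d[2], 3))
}

#' Segment nuclei from the lipid-to-protein ratio
#'
#' Nuclei carry the highest lipid:protein SRS ratio, so the ratio image is
#' thresholded at an upper percentile, then de-speckled (components below
#' `min_area` removed), morphologically closed, and hole-filled.
#'
#' @param lipid,protein non-negative images of one shape.
#' @param percentile upper-percentile threshold on the ratio (default 98:
#'   top 2% of pixels are candidate nuclei). Selection is strict (`>`), so a
#'   constant ratio field yields an empty, degenerate-flagged mask.
#' @param min_area minimum component area in px (de-speckle).
#' @param r_close disk radius for closing.
#' @param eps ratio denominator guard.
#' @return logical nuclei mask, with attribute `degenerate` when no pixel
#'   exceeded the threshold.
#' @export
segment_nuclei <- function(lipid, protein, percentile = 98, min_area = 9L,
                           r_close = 2L, eps = NULL) {
  assert_image(lipid); assert_image(protein)
  assert_same_shape(lipid, protein)
  if (is.null(eps)) eps <- 1e-6 * max(protein, 1e-12)
  ratio <- lipid / (protein + eps)
  thr <- stats::quantile(ratio, percentile / 100, names = FALSE)
  mask <- ratio > thr
  degenerate <- !any(mask)
  if (!degenerate) {
    lab <- EBImage::bwlabel(mask * 1)
    areas <- label_areas(lab)
    keep <- which(areas >= min_area)
    mask <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
    if (any(mask) && r_close > 0)
      mask <- EBImage::closing(mask * 1, disc_brush(r_close)) > 0.5
    if (any(mask))
      mask <- EBImage::fillHull(mask * 1) > 0.5
  }
  if (!any(mask)) warnf("nuclei segmentation returned an empty mask")
  attr(mask, "degenerate") <- degenerate
  mask
}

#' Render an H&E-style SRH image
#'
#' Percentile-stretches the protein and lipid channels, colorizes each with
#' its LUT, blends them in RGB, then edits in L*a*b*: nuclei get their L*
#' decreased by `delta_L_nuclei` and b* decreased by `delta_b` (and are
#' tinted toward the hematoxylin endpoint); background pixels get their L*
#' raised toward white and b* slightly decreased.
#'
#' @param protein,lipid non-negative images of one shape.
#' @param nuclei_mask optional logical mask (from [segment_nuclei()]).
#' @param luts a `lut_pair`.
#' @param stretch percentile pair for the channel stretch.
#' @param delta_L_nuclei L* decrease inside nuclei (of 100).
#' @param delta_b b* decrease inside nuclei and background.
#' @param background_quantile tissue floor: pixels whose stretched
#'   protein + lipid falls below this value count as background.
#' @return An object of class `srh_image`: `rgb` (y, x, 3) in [0,1],
#'   `style`, `nuclei_mask`, `background_mask`.
#' @export
render_he <- function(protein, lipid, nuclei_mask = NULL, luts = lut_pair(),
                      stretch = c(0.01, 0.99), delta_L_nuclei = 25,
                      delta_b = 10, background_quantile = 0.05) {
  assert_image(protein); assert_image(lipid)
  assert_same_shape(protein, lipid)
  stopifnot(inherits(luts, "lut_pair"))
  p <- stretch01(protein, stretch)
  l <- stretch01(lipid, stretch)
  if (is.null(nuclei_mask)) nuclei_mask <- matrix(FALSE, nrow(p), ncol(p))
  rgb <- blend_rgb(apply_lut(p, luts$protein_color),
                   apply_lut(l, luts$lipid_color), luts$blend_mode)
  background <- (p + l) < background_quantile & !nuclei_mask
  # tint nuclei toward the hematoxylin endpoint before the Lab edits
  if (any(nuclei_mask)) {
    for (c in 1:3) {
      ch <- rgb[, , c]
      ch[nuclei_mask] <- 0.5 * ch[nuclei_mask] + 0.5 * luts$nuclei_color[c]
      rgb[, , c] <- ch
    }
  }
  lab <- rgb_to_lab(rgb)
  L <- lab[, , 1]; a <- lab[, , 2]; b <- lab[, , 3]
  L[nuclei_mask] <- pmax(0, L[nuclei_mask] - delta_L_nuclei)
  b[nuclei_mask] <- b[nuclei_mask] - delta_b
  L[background] <- L[background] + 0.8 * (98 - L[background])
  b[background] <- b[background] - 0.2 * delta_b
  lab[, , 1] <- L; lab[, , 2] <- a; lab[, , 3] <- b
  structure(list(rgb = lab_to_rgb(lab), style = "HE",
                 nuclei_mask = nuclei_mask, background_mask = background),
            class = "srh_image")
}

#' Render a PAS-style SRH image
#'
#' Starts from the H&E render, then drives chroma with a PAS-intensity
#' field `p = log(1 + k * protein_norm) / log(1 + k)`: a* increases and b*
#' decreases proportionally to `p`, turning protein-dense structures
#' (basement membranes, mesangial matrix) magenta-red. PAS chroma tracks
#' the a*-b* difference logarithmically in protein signal. `k = 0` is the
#' identity with the H&E render.
#'
#' @inheritParams render_he
#' @param k logarithmic gain of the PAS field (>= 0).
#' @param a_gain,b_gain chroma shifts at `p = 1`.
#' @return An `srh_image` with `style = "PAS"`.
#' @export
render_pas <- function(protein, lipid, nuclei_mask = NULL, luts = lut_pair(),
                       k = 4, a_gain = 18, b_gain = 12,
                       stretch = c(0.01, 0.99), delta_L_nuclei = 25,
                       delta_b = 10, background_quantile = 0.05) {
  if (k < 0) stopf("k must be >= 0")
  base <- render_he(protein, lipid, nuclei_mask, luts, stretch,
                    delta_L_nuclei, delta_b, background_quantile)
  if (k == 0) { base$style <- "PAS"; return(base) }
  pn <- stretch01(protein, stretch)
  p <- log1p(k * pn) / log1p(k)
  lab <- rgb_to_lab(base$rgb)
  lab[, , 2] <- lab[, , 2] + a_gain * p
  lab[, , 3] <- lab[, , 3] - b_gain * p
  base$rgb <- lab_to_rgb(lab)
  base$style <- "PAS"
  base
}

#' Per-channel histogram specification
#'
#' Monotone histogram matching of each RGB channel of `rgb` to the
#' corresponding channel of `reference_rgb`, at 8-bit quantization. A
#' constant channel passes through with a warning. The level mapping is
#' monotone, so per-channel pixel rank order is preserved.
#'
#' @param rgb,reference_rgb (y, x, 3) arrays in [0,1].
#' @param levels quantization levels (default 256).
#' @return matched (y, x, 3) array in [0,1].
#' @export
histogram_specification <- function(rgb, reference_rgb, levels = 256L) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stopf("rgb must be (y, x, 3)")
  if (any(rgb < 0 | rgb > 1) || any(reference_rgb < 0 | reference_rgb > 1))
    stopf("RGB values must be in [0, 1]")
  out <- rgb
  for (c in 1:3) {
    x <- rgb[, , c]; r <- reference_rgb[, , c]
    if (max(x) - min(x) <= .Machine$double.eps) {
      warnf("channel %d constant: passthrough", c)
      next
    }
    qx <- pmin(levels - 1L, floor(x * levels))      # 0 .. levels-1
    qr <- pmin(levels - 1L, floor(r * levels))
    cdf_x <- cumsum(tabulate(qx + 1L, levels)) / length(qx)
    cdf_r <- cumsum(tabulate(qr + 1L, levels)) / length(qr)
    # smallest reference level whose CDF reaches the input level's CDF
    map <- findInterval(cdf_x, cdf_r, left.open = TRUE)   # 0-based level
    map <- pmin(map, levels - 1L)
    out[, , c] <- matrix(map[qx + 1L] / (levels - 1L), nrow(x), ncol(x))
  }
  out
}
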