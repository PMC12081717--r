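# Shared fixtures, built in code at test time.

# sinusoidal grating: fibers run along `ang_deg` (degrees from +x toward +y,
# image convention), intensity varies along the normal
make_grating <- function(n, ang_deg, period = 8, phase = 0) {
  th <- ang_deg * pi / 180
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  0.5 + 0.5 * cos(2 * pi / period * (-sin(th) * xx + cos(th) * yy) + phase)
}

# small two-reference library on the standard C-H axis
tiny_refs <- function(n = 2, seed = 1) {
  make_reference_library(n, seq(2700, 3100, by = 2), seed = seed)
}

# single-pixel stack from a spectrum vector
pixel_stack <- function(spectrum, wn) {
  hyperspectral_stack(array(spectrum, c(1, 1, length(wn))), wn)
}

# small glomerulus phantom: radius um / voxel um chosen per test
glom_phantom <- function(radius_um = 50, mes_fraction = 0.6, clip = 0,
                         voxel = 2, noise = 0, seed = 3, pad_px = 5,
                         nuclei = c(glomerulus = 0, cortex = 0)) {
  Rpx <- radius_um / voxel
  nxy <- 2L * ceiling(Rpx) + 2L * pad_px
  nz <- ceiling((radius_um * (1 - 2 * clip) + radius_um) / voxel) + pad_px
  make_glomerulus_volume_phantom(
    phantom_spec("glomerulus_volume", c(nz, nxy, nxy), pixel_size_um = voxel,
                 z_spacing_um = voxel, noise_sigma = noise, seed = seed),
    radius_um = radius_um, mes_fraction = mes_fraction, clip_fraction = clip,
    nuclei_counts = nuclei)
}

# seed voxel (1-based z,y,x) at the phantom center
glom_seed <- function(gp) {
  v <- round(gp$truth$center_um /
               c(gp$volume$z_spacing_um, gp$volume$pixel_size_um,
                 gp$volume$pixel_size_um)) + 1L
  # center may sit above the volume when clipped: seed at the first plane
  pmax(v, c(1L, 1L, 1L))
}
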