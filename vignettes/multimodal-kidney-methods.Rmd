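---
title: "Methods: label-free multimodal kidney image analysis with mmkidney"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free multimodal kidney image analysis with mmkidney}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmkidney)
```

# Scope and data model

`mmkidney` analyzes co-registered label-free kidney microscopy: stimulated
Raman scattering (SRS) channels at the C-H stretching landmarks
(2850 cm^-1^ lipid CH~2~, 2880 cm^-1^ saturated-lipid Fermi band,
2940 cm^-1^ protein CH~3~, 3011 cm^-1^ unsaturated =C-H), two-photon
autofluorescence of NADH and flavins, and second-harmonic generation (SHG)
from fibrillar collagen. Images are numeric matrices indexed `[y, x]` (y
down); volumes are `[z, y, x]` arrays; hyperspectral stacks are
`(y, x, wavenumber)` with a strictly increasing cm^-1^ axis. All physical
quantities derive from `pixel_size_um` and `z_spacing_um`. TIFF files carry
the pixels; a YAML sidecar carries the axis and channel listing, and a file
whose page count disagrees with its sidecar is rejected rather than
silently indexed by plane number.

Because no patient pixel data are available, every stage is validated on
synthetic phantoms with voxel-exact ground truth. The generators are
first-class, tested code; all of their randomness flows from one integer
seed and identical calls are bit-identical.

# Penalized reference matching (PRM)

Each pixel spectrum $I(\nu)$ is scored against a lipid-subtype reference
$r(\nu)$ by

$$s = \max_{\delta \in \Delta} \; \cos\!\big(I(\nu),\, r(\nu - \delta)\big)\; w(\delta),$$

where $\Delta$ is an offset grid (default $-10 \ldots 10$ cm^-1^, step 1)
and $w$ a penalty with $w(0) = 1$, non-increasing in $|\delta|$. The offset
tolerance absorbs small wavenumber calibration differences between
instruments; the penalty keeps a large shift from masquerading as a match.
The penalty form is not fixed by the underlying method description, so a
Gaussian $w(\delta) = \exp(-\delta^2 / 2\sigma^2)$ with $\sigma$ = 10
cm^-1^ is the default, with linear and none alternatives. Aggregation over
offsets is `max`, not mean, so a well-aligned match is never diluted.
Scoring is restricted to the C-H stretching window (2700–3100 cm^-1^), the
shifted reference is linearly interpolated with edge extension, and no
baseline is subtracted by default (SRS background is low). Cosine scoring
makes `prm_score` invariant to positive scaling of pixel and reference;
with `offsets = 0` and `penalty = "none"` it reduces exactly to the cosine
map.

Per-pixel scores across subtypes are simplex-normalized (each divided by
the subtype sum) and read as relative, not absolute, concentrations.
Percentile selection for mean-spectrum overlays includes tied scores, and
the selection is per-subtype.

On zero-noise mixture phantoms the subtype argmax is evaluated on tissue
pixels whose dominant true abundance is at least 0.6: below that the pixel
is a near-tie mixture for which no single subtype label is well defined.
With the default generator (softmax sharpness 3, about 85% of tissue
pixels dominant) the conditioned accuracy is 1.00 at zero noise and
>0.99 at 5% relative noise; unconditioned accuracy is 0.95–0.97.

# Ratiometric biomarkers

The normalized optical redox ratio is ORR = FAD/(NADH + FAD) and lipid
saturation is unsat/(sat + unsat) from the 3011 and 2880 cm^-1^ SRS bands.
The denominator is the plain channel sum; pixels whose sum falls below
`eps` (default $10^{-6} \times$ the summed-channel maximum) are masked
invalid rather than clamped, which keeps the [0, 1] range and the
complement symmetry ORR(a, b) + ORR(b, a) = 1 exact on valid pixels. Both
ratios are invariant to common positive scaling of the two channels.

Axial profiles (e.g. along the cortical–medullary axis) project valid
pixels onto a user-supplied direction, average in 10 µm bins by default,
drop empty bins, and rescale to unit trapezoidal area, making profiles
comparable across samples regardless of global intensity. Group comparisons
use a Welch two-sided t-test on per-region (per-glomerulus) means, not
per-pixel values, so `n` is the number of anatomical structures; for
groups with zero variance the degenerate result t = 0, p = 1 is returned
explicitly because `stats::t.test` refuses constant data.

# Stimulated Raman histology (SRH)

Nuclei carry the highest lipid-to-protein SRS ratio and are segmented by
thresholding that ratio at an upper percentile (default 98, strict
inequality so a constant ratio yields an empty, flagged mask), despeckling
below `min_area`, closing, and hole-filling. Rendering percentile-stretches
(1–99%) the protein and lipid channels, colorizes each with a LUT that
interpolates from white to an endpoint color (eosin pink for protein,
near-white for lipid), and blends multiplicatively — the standard
absorbing-stain composition; screen and clipped-sum blends are exposed.
Color edits happen in L\*a\*b\* (D65, sRGB companding): nuclei L\* is
lowered by 25 and b\* by 10 and the pixels are tinted toward a hematoxylin
purple; background is pushed toward white. No published color values exist
for these renders, so all endpoints and deltas are configuration surface;
the invariant asserted by the tests is semantic — mean nuclear L\* strictly
below tissue L\*, RGB always finite in [0, 1].

The PAS-style render starts from the H&E result and drives chroma with
$p = \log(1 + k\,\text{protein}) / \log(1 + k)$ (default $k = 4$),
increasing a\* and decreasing b\* proportionally to $p$, so the a\*–b\*
difference grows logarithmically with protein signal; $k = 0$ is the
identity with H&E. Histogram specification matches each RGB channel to a
reference image's channel CDF at 8-bit quantization with a monotone level
map, so pixel rank order is preserved and self-matching is idempotent to
one gray level.

# Glomerulus stereology

The corpuscle (tuft plus Bowman's space and parietal epithelium) is the
outer segmentation mask; the mesangium/tuft is the corpuscle intersected
with thresholded protein. Two 2-D detectors are provided: a rapid
opening–closing + Otsu + size/circularity pipeline on protein images, and
the full SHG morphological pipeline (top-hat, median filter, dilated
gradient wireframe, inversion, erosion + geodesic reconstruction,
regional-maxima seeds, opening/closing, optional second pass, and
constrained growth of each seed until it meets the wireframe or a
neighbor, implemented with `EBImage::propagate`), followed by
area/solidity filters.

Tracking links a region through z when the previous plane's centroid falls
inside the next plane's region (ties by largest overlap). The analyzed
range runs from the maximal cross-sectional-area plane to the vanishing
plane, defined as the first plane with area below 1% of the maximum —
"vanishing point" is otherwise undefined; for a complete sphere both
directions vanish, and the longer tracked side is analyzed so thickness
equals the radius. Glomerulus thickness is the z distance between those
planes; the radius is the mean centroid-to-boundary distance at the
max-area plane, or 100 µm (half a typical glomerular diameter) when the
largest area occurs at the volume's first or last plane and no maximum is
defined. Records with thickness below 90% of radius are discarded
(boundary inclusive: exactly 90% is retained); records touching the x/y
image border are flagged clipped and excluded from the 3-D estimator.

One numerical choice matters for honest polar planes: the mesangium
threshold used during tracking is an Otsu computed once per object over
within-corpuscle voxels pooled across analyzed planes. A per-plane Otsu
would split Bowman's-space noise in half on planes with no tuft and invent
mesangium where there is none; the 2-D `segment_mesangium()` keeps the
per-plane within-mask Otsu for single-image use.

Vv(Mes/Glom) estimators: `3d_hemisphere` sums mesangium and corpuscle
pixels over the analyzed planes and divides; `2d_max_plane` and
`2d_single_plane` are single-plane pixel ratios. On concentric-sphere
phantoms the single-plane ratio decreases with distance from the equator,
so random-plane sampling biases the 2-D estimator downward and inflates
its SD relative to the 3-D estimator — the Monte-Carlo in
`estimator_report()` reproduces exactly this ordering. Nuclei are counted
in 3-D with 26-connectivity (8 in 2-D throughout), each nucleus assigned
once, to the region containing its centroid.

# Collagen analytics

Background subtraction divides by a unit-mean heavy Gaussian blur
(flatfield) and applies a disk top-hat whose radius should be at least the
largest fiber half-width. Fiber thickness comes from the Euclidean
distance map of the fiber mask: regional maxima sit on the midline at the
half-width, so thickness is twice the distance there; connected plateaus
collapse to one sample at their centroid to avoid double counting ridge
lines. Even pixel widths are recovered exactly; odd widths read up to +1
px high because the midline pixel center sits half a pixel from the true
axis — a documented discretization bias.

Orientation and anisotropy are computed per square bin (80 µm default)
from the 2-D DFT power spectrum of the mean-subtracted bin. The bin is
first split by a periodic-plus-smooth decomposition (the smooth field is
the Laplace solution of the boundary wrap-around discrepancies, solved in
Fourier space) and only the periodic component is transformed, removing
the axis-aligned cross artifact that crop boundaries inject. The dominant
fiber orientation is the principal axis of the power-spectrum inertia
tensor rotated by 90°, reported in [0, 180) degrees from +x toward +y
(down); anisotropy is $1 - \lambda_{\min}/\lambda_{\max}$ of that tensor,
in [0, 1], with flat bins flagged and assigned 0. Gratings are recovered
within ±0.4°, isotropic noise scores below 0.1, and the statistic is
invariant to global intensity scaling.

A caveat worth stating: for a bare sinusoid whose frequency is not an
integer number of cycles per bin, spectral leakage concentrates
symmetrically around the peak and is not a smooth-boundary effect, so the
decomposition leaves it in place (axis-energy ratio near 1). The ≥10×
axis-energy suppression is demonstrated on the configuration the
decomposition targets — a cropped grating riding on a smooth illumination
gradient — where the measured reduction is over three orders of magnitude.

Voronoi partitioning assigns each pixel to the nearest glomerulus center
(ties to the lowest seed id); thickness-versus-distance tables measure
each thickness sample's distance to its cell's seed, optionally dropping
samples inside an exclusion mask such as `high_anisotropy_mask()` output
(bins above the 0.9 anisotropy quantile by default), which discounts
highly oriented medullary collagen.

# Synthetic phantoms: what they emulate, and what they do not

* `make_reference_library()` — distinct stand-ins for lipid subtype
  references (TAG, ceramide, cholesterol, cholesteryl ester): 2–5 Gaussian
  bands centered near the C-H landmarks with jitter, max-normalized,
  pairwise cosine < 0.99.
* `make_spectral_mixture_phantom()` — per-pixel convex mixtures of the
  references with spatially smooth simplex abundance fields
  (Gaussian-blurred Gaussian noise through a softmax, sharpness 3) inside
  a tissue disk; additive Gaussian noise clipped at zero.
* `make_glomerulus_volume_phantom()` — a corpuscle sphere (tuft 1.0,
  Bowman 0.4, surround 0) whose concentric tuft occupies a voxel-exact
  fraction of corpuscle voxels (inner radius set by the voxel-distance
  quantile; membership by the center-inside rule, and ground truth uses
  the same rule so estimator tests are voxelization-consistent).
  `clip_fraction` removes that fraction of the sphere diameter at the
  z = 0 face, emulating structures only partly inside the imaging volume.
  Nuclei are non-touching 4 µm spheres on a jittered grid with exact
  per-region counts.
* `make_fiber_phantom()` — straight ribbons of stated width and
  orientation; even widths are centered between pixel rows so the
  rasterized width is exact.
* `make_redox_phantom()` — NADH/FAD pair from a known ORR map, exactly
  invertible at zero noise.

The noise model everywhere is additive Gaussian on intensities, clipped at
zero — the simplest model that exposes the SNR behavior of cosine scoring;
shot noise is out of scope. Channel noise characteristics of real SRS/TPF
data are not published for this pipeline, so the default σ = 0.02
(relative to unit signal) is a choice, with 0.05 used where a 5% condition
is part of the test itself. The phantoms deliberately omit anatomical
realism: no capillary networks, no optical point-spread function, no
depth-dependent attenuation, no spatial texture inside compartments.
Passing tests therefore demonstrate correctness of the estimators and
transforms under known geometry and noise — not segmentation robustness on
real tissue, where texture, vignetting and touching structures dominate
the difficulty.

# Problem sizes and numerical choices

The validation suite uses radius-100 µm spheres at 2 µm voxels (107³
volumes) for Vv recovery and the n = 50 random-slice Monte-Carlo; unit
tests use 40–60 µm radii. 64×64 bins are used for orientation checks and
64×64×201 stacks for PRM. Degenerate inputs are defined, not exceptional:
zero spectra score 0 with a warning; all-zero phasor pixels are masked
invalid; empty masks yield empty outputs; constant histogram channels pass
through with a warning; an empty offset grid falls back to δ = 0. Ties are
broken deterministically (percentile selection includes ties, Voronoi ties
take the lowest id, z-linking ties take the largest overlap).

# Known limitations

Registration across modalities is assumed (single-platform acquisition);
stitching and vignetting correction are out of scope. Absolute
concentrations are not estimated — simplex-normalized PRM scores are
relative. The SHG morphological detector's size/shape bounds are
configuration values, not learned; deep-learning glomerulus classification
and GAN-based stain standardization are explicitly out of scope. SHG sees
only fibrillar collagen types 1–3, and thickness measurements inherit the
distance-map discretization bias noted above.
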