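# mmkidney

Label-free multimodal kidney microscopy image analysis in R.

Kidney biopsies are conventionally read from stained sections, which
limits multiplexing and consumes scarce tissue. A label-free alternative
images the same section with stimulated Raman scattering (SRS) at the C-H
stretching bands (2850 cm⁻¹ lipid, 2880 cm⁻¹ saturated lipid, 2940 cm⁻¹
protein, 3011 cm⁻¹ unsaturated lipid), two-photon autofluorescence of NADH
and flavins, and second-harmonic generation (SHG) from fibrillar collagen.
`mmkidney` implements the analysis side of such a platform:

- **PRM** (penalized reference matching): every hyperspectral pixel is
  scored against lipid-subtype reference spectra by
  `s = max_δ cos(I(ν), r(ν−δ)) · w(δ)` over a wavenumber offset grid with
  a penalty `w` (Gaussian by default), then simplex-normalized across
  subtypes — offset tolerance absorbs calibration drift between
  instruments, and normalized scores read as relative concentrations.
- **Ratiometric biomarkers**: the normalized optical redox ratio
  ORR = FAD/(NADH+FAD) and lipid saturation = unsat/(sat+unsat), with
  masked (never clamped) denominators, AUC-normalized axial intensity
  profiles, and per-glomerulus Welch t-tests.
- **SRH** (stimulated Raman histology): H&E- and PAS-style pseudo-staining
  of the unmixed protein/lipid channels via white-to-stain LUTs,
  multiplicative blending, and L\*a\*b\* edits (nuclei darkened, background
  whitened; PAS chroma grows logarithmically with protein signal), plus
  nuclei segmentation from the lipid:protein ratio and per-channel
  histogram specification.
- **Glomerulus stereology**: 2-D corpuscle detection (opening–closing or
  the full SHG morphological pipeline), z-tracking, the hemisphere
  inclusion rule (records with thickness < 90% of radius are discarded;
  radius falls back to 100 µm when the max-area plane is terminal), and
  the mesangial fractional volume Vv(Mes/Glom) by three estimators
  (3-D hemisphere, 2-D single plane, 2-D max plane) with 3-D nuclei
  counting.
- **Collagen analytics**: flatfield + top-hat background subtraction,
  distance-map fiber thickness (thickness = 2 × regional maxima of the
  Euclidean distance map), per-bin DFT orientation/anisotropy with a
  periodic-plus-smooth decomposition that removes crop-boundary cross
  artifacts, Voronoi partitioning around glomerulus centers, and
  thickness-versus-distance densities.
- **Synthetic phantoms** with voxel-exact ground truth for every stage
  (spectral mixtures, corpuscle spheres with known tuft fraction and clip
  geometry, fiber fields, redox maps), so the whole pipeline is testable
  without patient data.

See `vignettes/multimodal-kidney-methods.Rmd` for the models, parameter
defaults, numerical choices and limitations.

## Worked example

```r
library(mmkidney)

## lipid subtyping on a spectral-mixture phantom
refs <- make_reference_library(3, seed = 1)
mix  <- make_spectral_mixture_phantom(
  refs, phantom_spec("spectral_mixture", c(64, 64), noise_sigma = 0.05, seed = 1))
maps <- simplex_normalize(lapply(refs, function(r) prm_score(mix$stack, r)))
arg   <- apply(vapply(maps, function(m) m$scores, maps[[1]]$scores), c(1, 2), which.max)
truth <- apply(mix$truth$abundance_maps, c(1, 2), which.max)
dom   <- apply(mix$truth$abundance_maps, c(1, 2), max)
sel   <- mix$truth$tissue_mask & dom >= 0.6
mean((arg == truth)[sel])
#> [1] 0.9871619

## 3-D mesangial fractional volume on a 100 um corpuscle phantom, 2 um voxels
gp <- make_glomerulus_volume_phantom(
  phantom_spec("glomerulus_volume", c(107, 107, 107), pixel_size_um = 2,
               z_spacing_um = 2, noise_sigma = 0.02, seed = 1),
  radius_um = 100, mes_fraction = 0.6)
rec <- track_glomerulus(gp$volume, round(gp$truth$center_um / 2) + 1)
rec
#> <glomerulus_record> radius 98.7 um, thickness 100.0 um, retained; Vv 3d=0.601 2d_max=0.712 2d_single=0.712
gp$truth$vv_true
#> [1] 0.5991936

## estimator comparison under random slicing planes
estimator_report(10, vv_true = 0.6, seed = 1, radius_um = 60)$table
#>            method  n  mean       sd       se
#> 1   3d_hemisphere 10 0.605 8.91e-06 2.82e-06
#> 2 2d_single_plane 10 0.505 2.63e-01 8.33e-02
#> 3    2d_max_plane 10 0.718 0.00e+00 0.00e+00
```

Reading the numbers: the 3-D hemisphere estimator recovers the voxel-exact
tuft fraction (0.601 vs 0.599); the single-plane estimator is both more
variable (SD 0.26 vs ~10⁻⁵) and biased low under random slicing, because
planes far from the equator see a tuft-poor cross-section — the reason 2-D
measurements understate mesangial expansion. The 2-D max-plane ratio
overshoots the volumetric fraction on a concentric-tuft geometry (0.712 at
the equator), and the hemisphere rule retains this record since its
thickness (100 µm) exceeds 90% of its radius.

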