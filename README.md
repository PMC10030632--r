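# cortmag

Surface-based retinotopy analysis in R: population receptive field (pRF)
modeling, cortical magnification, and polar-angle asymmetries in V1
surface area.

## The problem

Primary visual cortex (V1) does not sample the visual field uniformly.
Beyond the familiar decline of areal cortical magnification with
eccentricity — well described by the Horton–Hoyt law
`M(E) = (17.3 / (E + 0.75))² mm²/deg²` — adult V1 devotes more surface
area to the horizontal than to the vertical meridian (the
horizontal–vertical anisotropy, HVA) and more to the lower than to the
upper vertical meridian (the vertical-meridian asymmetry, VMA). These
cortical asymmetries parallel visual performance and can differ between
groups (for example, a VMA present in adults but absent in children).
Quantifying them requires a chain of delicate steps: fitting a pRF model
to BOLD time series on the cortical surface, delineating V1 from
polar-angle reversals, and measuring the surface area of wedge-shaped
regions of interest centered on the meridians.

`cortmag` implements that chain as tested, reusable components for
researchers working with surface-based retinotopy:

- **Stimulus**: the sweeping-bar contrast-aperture movie
  (`make_bar_aperture()`), written/read as NIfTI + JSON.
- **pRF model**: 2D-Gaussian pRF × aperture forward model with a
  five-parameter two-gamma HRF, and a four-stage coarse-to-fine fit
  (`fit_prf()`; grid search on decimated data, continuous refinement,
  HRF search averaged across vertices, final refit).
- **Motion QC**: framewise displacement with arc-length rotation
  conversion at a 50 mm head radius (`framewise_displacement()`,
  `count_exceedances()`).
- **Map delineation**: automated polar-angle reversal detection
  (`detect_reversals()`) and r²-weighted circular smoothing of angle
  maps (`clean_angles()`).
- **Cortical magnification**: the adaptive 20%-of-vertices annulus
  estimator (`areal_cmag()`) and the Horton–Hoyt reference
  (`horton_hoyt_areal()`, `fraction_within()`).
- **Wedge-ROIs**: geodesic distance maps, log-spaced eccentricity bands,
  iso-angle boundary estimation, and meridian-wedge surface areas
  (`wedge_roi()`, `meridian_surface_areas()`), plus the centers-only
  alternative (`centers_only_area()`).
- **Asymmetry statistics**: HVA/VMA indices, bootstrapped linear fits of
  area against wedge width, and pooled-variance group comparisons with
  Cohen's d (`hva_index()`, `vma_index()`, `bootstrap_linear_fit()`,
  `group_ttest()`).
- **Synthetic cortex**: a generator of triangulated hemisphere meshes
  whose areal magnification follows the Horton–Hoyt law times a
  configurable angular gain, so any HVA/VMA magnitude can be injected
  with analytically known ground truth (`build_hemisphere()`,
  `simulate_bold()`, `simulate_motion()`), and a two-group simulation
  pipeline (`run_pipeline()`).

The asymmetry indices are mean-normalized percent differences:

    HVA = (horizontal − vertical) / mean(horizontal, vertical) × 100
    VMA = (lower − upper) / mean(lower, upper) × 100

computed by default from ±25° wedges spanning 1–7° of eccentricity.

## Worked example

Build a synthetic subject with an adult-like asymmetry profile (HVA 80,
VMA 52) and recover the indices with the wedge-ROI analysis:

```r
library(cortmag)

cfg     <- ground_truth_config(hva_amp = 80, vma_amp = 52)
subject <- build_subject(cfg)
areas   <- meridian_surface_areas(subject, widths = c(15, 25, 35, 45, 55))
asymmetry_indices(areas, width = 25)
#> # A tibble: 1 × 7
#>   half_width horizontal vertical lower_vertical upper_vertical   hva   vma
#>        <dbl>      <dbl>    <dbl>          <dbl>          <dbl> <dbl> <dbl>
#> 1         25       833.     384.           242.           142.  73.7  51.9
```

The recovered HVA (73.7) and VMA (51.9) sit close to the injected 80 and
52; the HVA reads a few points low because border vertices of the
vertical wedges carry a share of adjacent-area triangles (see the
methods vignette). Cortical magnification on the same mesh tracks the
generating law — at 3° the estimate is 21.5 mm²/deg² against the
Horton–Hoyt value of 21.3:

```r
v1 <- subset(subject$left$retinotopy, visual_area == "V1")$vertex
areal_cmag(subject$left$mesh, subject$left$retinotopy, v1,
           r_grid = c(2, 3, 5, 7))
#> # A tibble: 4 × 5
#>       r delta_r n_vertices area_mm2     m
#> 1     2   0.652        702     324. 39.5
#> 2     3   0.800        702     324. 21.5
#> 3     5   1.11         702     324.  9.27
#> 4     7   1.48         702     297.  4.55
```

A full two-group study (10 adult-like vs 10 child-like subjects,
measurement noise, map cleaning, wedge analysis, group t-tests) runs in
under a minute: `run_pipeline(pipeline_config(seed = 1))`.

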