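---
title: "Models and methods behind cortmag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cortmag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cortmag` quantifies how primary visual cortex samples the visual field:
population receptive field (pRF) model fitting, areal cortical
magnification as a function of eccentricity, and the surface area of
wedge-shaped regions centered on the polar-angle meridians, summarized
as horizontal–vertical (HVA) and vertical-meridian (VMA) asymmetry
indices. This vignette describes the models, the parameters that matter,
the synthetic ground-truth generator used to validate every stage, and
the numerical choices made where the methods leave latitude.

## The pRF forward model

A vertex's population receptive field is a circular 2D Gaussian with
center $(x, y)$ and standard deviation $\sigma$, all in degrees of
visual angle. The predicted BOLD response to a binary contrast-aperture
movie $A(t)$ is linear:

$$ r(t) = \sum_{\text{pixels}} G_{x,y,\sigma} \cdot A(t), \qquad
   \hat{b}(t) = (r * h)(t), $$

where $h$ is a hemodynamic response function modeled as a difference of
two gamma densities with five parameters: response delay, undershoot
delay, two dispersions, and an undershoot-to-response amplitude ratio.
Defaults are the conventional double-gamma first-pass values
$(6, 16, 1, 1, 1/6)$ (seconds for the first four); the exact
five-parameter convention is a package choice, since several
parameterizations circulate. Amplitude and baseline are not model
parameters: they are profiled out by least squares at every objective
evaluation, with the amplitude constrained non-negative.

Fitting is a four-stage coarse-to-fine procedure:

1. **Grid search** on data temporally decimated by two (adjacent-pair
   averaging, a boxcar anti-alias — the decimation filter is otherwise
   unspecified in common practice). The grid places $x, y$ on an
   $11 \times 11$ lattice spanning $\pm 1.25$ field radii (centers may
   lie slightly beyond the aperture) and $\sigma$ on 10 log-spaced
   values in $[0.1°, 6°]$.
2. **Continuous refinement** per vertex by Nelder–Mead over
   $(x, y, \log\sigma)$ at full temporal resolution, with box penalties
   ($|x|, |y| \le 1.5$ radii, $\sigma \in [0.05°, 3\,$radii$]$). The
   result is never allowed to be worse than its starting point, which
   guarantees stage-to-stage monotonicity of the objective.
3. **HRF search** with pRF parameters fixed: the five HRF parameters
   are fit by Nelder–Mead minimizing the normalized residual sum of
   squares averaged across the best-fitting vertices (up to 50 vertices
   with stage-2 $R^2 \ge 0.2$).
4. **Final pRF refit** with the fitted HRF held fixed.

Variance explained is $1 - \mathrm{RSS}/\mathrm{TSS}$ about the data
mean, clamped to $[0, 1]$; zero-variance data are flagged degenerate
with $R^2 = 0$.

## The stimulus

The aperture is a bar of width 3° and length 14° sweeping across a
circular field of radius 7° at 0.30°/s, updated twice per second, eight
sweeps: four cardinal sweeps across the full diameter, then four
diagonal sweeps that stop at the field center with the second half
replaced by blanks. Sweep order (L→R, bottom→top, R→L, top→bottom, then
the four diagonals 45° apart) is a canonical package choice; downstream
measures are insensitive to it. Each sweep is padded to a whole number
of TRs, so with the default geometry the movie spans 192 volumes of
2 s. A fixed volume count can be requested (`n_volumes`), implemented
by truncation or blank-padding at the end; it is not the default
because truncating to, say, 96 volumes would drop half of the sweeps.
The default sampling grid is $101 \times 101$ pixels, at which bar–disc
overlap integrals are accurate to well under 1% on test frames;
`grid_resolution = 51` is used in some tests for speed at negligible
accuracy cost.

## The synthetic cortex

Every quantitative claim in the package is validated by parameter
recovery on synthetic hemispheres with analytically known ground truth.
The construction maps the visual field $(E, \theta)$ to flat cortical
coordinates $(u, v)$:

$$ u(E) = k\left[\ln(E + e_0) + \frac{e_0}{E + e_0}\right], \qquad
   \frac{dv}{d\theta_\text{rad}} = k \, g(\theta), $$

with $k = 17.3$ mm and $e_0 = 0.75°$ by default. The Jacobian of this
map is exactly $g(\theta)\,(k/(E+e_0))^2$ mm²/deg² — the Horton–Hoyt
areal law times an angular gain $g$. The gain profile is a sum of
raised-cosine lobes of 45° half-width centered on the four meridians,
with amplitudes solved in closed form so that (i) the full-circle
integral is 360 (total area preserved) and (ii) the ±25° wedge
integrals reproduce any requested HVA and VMA index exactly. The 45°
lobe half-width is a modeling choice: wide enough that the enlarged
meridian representations are smooth, narrow enough that neighboring
lobes do not overlap a ±25° wedge. V1 occupies a full hemifield;
dorsal and ventral V2 and V3 quarterfields adjoin it at the polar-angle
reversals, mirror-mapped and scaled to 0.97 and 0.79 of V1's area
(matching the relative map sizes typically reported). Pial and white
vertex areas are 1.2× and 0.85× midgray by default.

pRF size follows $\sigma = 0.5° + 0.2 E$, a typical V1 size law at 3 T.
Simulated variance explained is Beta(6, 4)-distributed (median ≈ 0.61,
the regime of good retinotopy data); BOLD noise for fitting tests is
calibrated as $\mathrm{sd}(\text{signal})\sqrt{(1-R^2)/R^2}$ so the
fitted median $R^2$ lands near 0.6.

Numerical details of the mesh that matter for validation:

- Vertices form a rows-by-columns grid (rows uniform in field
  elevation, columns uniform in $u$), with rows laid about twice as
  densely as columns because wedge boundaries are resolved along the
  angular direction. The default density is 10,000 vertices per
  hemisphere (about 115 V1 rows at 1.6°); the group pipeline uses
  4,000 for speed.
- Alternate rows are staggered by half a column spacing so vertex
  eccentricities are quasi-continuous, as on a native surface; the
  stagger is anchored at the horizontal-meridian row to keep the
  dorsal and ventral halves exact mirrors.
- The triangulation's diagonal orientation flips at the horizontal
  meridian row, making the edge graph — and hence edge-graph geodesic
  distances — mirror-symmetric between the dorsal and ventral halves.
- Per-vertex area is one third of the summed incident-triangle areas.
  A consequence worth knowing: vertices on the V1/V2 border carry a
  share of V2-side triangles, which inflates wedges that terminate at
  the map border (the vertical-meridian wedges) by a few percent and
  biases the recovered HVA a few points low (about 74 recovered for an
  injected 80). The same bookkeeping applies to real surface data, so
  this is retained rather than corrected; the recovery tolerance of
  ±8 index points accommodates it.

What the generator does **not** emulate: cortical folding (meshes are
flat), BOLD nonlinearities, spatially correlated noise, draining-vein
artifacts, and the irregular vertex spacing of real reconstructions.
Passing recovery tests therefore demonstrates correctness of the
algorithms under the stated noise models, not robustness to every
artifact of real fMRI surfaces.

## Map cleaning and delineation

Polar-angle maps are cleaned by an anchored, $r^2$-weighted circular
smoother standing in for template-based map cleaning: each vertex's
angle is repeatedly replaced by the circular mean of its own raw angle
(weight $r^2$) and its neighbors' current angles (weights
$\lambda r^2$, $\lambda = 1$), iterated until the largest update falls
below 0.1°. On a noiseless map the interior is an exact fixed point;
reversal apices attenuate by a few degrees (the unavoidable cost of
smoothing an extremum) without moving, and because a circular mean of
angles on one side of a meridian stays on that side, cleaning does not
push interior angles across reversals. With 10° vertex noise the
cleaned map sits within ~2.6° RMS of ground truth.

V1/V2/V3 boundaries are detected as local extrema of field elevation on
the vertex graph: elevation reaches ±90° at the V1/V2 borders and
returns through 0° at the V2/V3 borders. A 1° slack absorbs ties along
the ridge; vertices on or next to the open mesh edge are excluded
(truncated neighborhoods make spurious extrema); and candidates are
grouped within two mesh edges, discarding groups smaller than three —
reversals are curvilinear ridges, not isolated points. Detection is
exact on noiseless maps and reliable when residual noise is below the
row-to-row elevation contrast; at noise well above that contrast
isolated false positives can survive in the far periphery of the
higher-order maps.

## Cortical magnification

At each sample eccentricity $r$ (1–7°, excluding the fovea where pRF
position estimates are noisy), the annulus half-width $\Delta r$ is the
smallest value such that 20% of the ROI's vertices — counted equally,
not area-weighted, and read as 20% of the ROI rather than of the whole
hemisphere, since only ROI vertices have in-map eccentricities — fall
within $r \pm \Delta r$. Their summed surface area is divided by the
annulus visual-field area times the hemifield fraction the map
represents (0.5 for one hemisphere; combining hemispheres averages the
curves). Two numerical details: $\Delta r$ is the k-th order statistic
of the absolute deviations with the annulus edge placed halfway to the
next-further vertex, so the ring covers the included vertices' surface
cells without overreach; and annuli reaching below 0° are clipped with
a warning.

## Wedge-ROIs

For each meridian and hemisphere: a line-ROI is traced automatically as
the per-eccentricity-bin vertex whose cleaned angle is closest to the
meridian (log-spaced bins, matching the cortex's roughly uniform
sampling of log eccentricity; tracing replaces the manual line-drawing
used with real data and is validated against the constructed
boundaries). Geodesic distances from the line are multi-source
shortest paths on the mesh edge graph with Euclidean weights — the
edge-graph approximation, which on flat grids inflates distances by a
bounded factor (≤ 8% on an unstaggered grid; both the boundary
estimate and the inclusion rule use the same metric, so the bias
cancels). The 1–7° window is split into 7 log-spaced bands; in each
band and on each side of the meridian, the boundary distance of the
±`half_width` iso-angle line is the mean distance of vertices whose
cleaned angle lies within ±8° of the target and whose $R^2 \ge 0.10$.
Bands with no qualifying vertices are interpolated linearly in log
eccentricity from their neighbors (the treatment of missing bands is
otherwise unspecified); vertices just across the meridian on a side
with no map territory inherit the opposite side's boundary. The wedge
is the union over bands of ROI vertices closer to the meridian than
their band's boundary (with a 10⁻⁹ mm slack so knife-edge ties resolve
consistently), and its surface area is the sum of per-vertex areas at
the chosen depth with **no** $R^2$ filtering. Vertical-meridian wedges
of the two hemispheres are summed; the two horizontal wedges are
summed into one horizontal measure.

The centers-only alternative simply sums vertex areas whose fitted pRF
centers fall in the angular range (after $R^2 \ge 0.10$ thresholding);
it needs no smoothing or continuity assumptions and agrees with the
wedge method within ~15 index points on asymmetric meshes.

## Statistics

HVA and VMA are mean-normalized percent differences, by default from
the ±25° wedges. Bootstrap procedures use the percentile method
(bands are percentile-style; BCa is not attempted): group-mean percent
differences use 1,000 resamples, and the area-vs-width linear fits use
10,000 resamples of subjects with a 68% pointwise band. Group
comparisons use the pooled-variance two-tailed t-test with
$df = n_a + n_b - 2$ and Cohen's $d$ as the mean difference over the
pooled SD. The two-group pipeline (`run_pipeline()`) jitters each
subject's map scale lognormally (CV 0.1, giving a realistic ~20% CV of
map area), adds 10° angle noise, cleans, and recovers the injected
dissociation: groups built with (HVA, VMA) = (80, 52) versus (80, 0)
yield a significant VMA difference and no HVA difference at
$n = 10$ per group.

## Problem sizes and runtimes

Defaults were chosen so a full validation cycle is interactive: the
default stimulus is 192 TRs at 101×101 pixels; fitting-accuracy tests
use 200 vertices at 51×51; synthetic hemispheres are 10,000 vertices
(4,000 in the 20-subject group pipeline, which completes in well under
a minute); Monte Carlo checks use 10,000 replicates. All randomness is
seeded, and the pipeline manifest records the seed and content hashes
so identical configurations reproduce bit-identical results.

## Known limitations

- Flat synthetic meshes validate the algorithms, not their behavior on
  folded, irregularly sampled reconstructions.
- The HVA recovered from wedge areas is biased a few points low by
  border-vertex area bookkeeping (see above).
- The map cleaner is a local smoother; it does not enforce field-sign
  consistency or template topology as model-based cleaning does.
- Geodesics are edge-graph approximations, not exact polyhedral
  geodesics.
- Only V1 wedges are measured; V2/V3 quarterfields make fine polar
  angle binning there unreliable and are used only for delineation and
  map-level summaries.
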