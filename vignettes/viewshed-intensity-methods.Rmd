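---
title: "Methods: viewshed-intensity mapping of cultural ecosystem services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viewshed-intensity mapping of cultural ecosystem services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Georeferenced photographs volunteered on social media mark places people
visit and value. A photograph, however, documents more than its capture
point: the photographer experienced the whole surrounding visible
landscape. `cesviews` operationalises that idea. For every photo location
it computes a *viewshed* — the set of raster cells visible along
unobstructed sight lines within a maximum range — on a high-resolution
digital surface model (DSM), overlays all viewsheds into a
*viewshed-intensity* surface (a per-cell count of overlapping viewsheds),
and models that count against landscape covariates with a
negative-binomial regression. Cells that many photographers could see get
high counts; the regression asks which landscape features (ocean, beach,
parks, trails, proximity to attractions, ...) explain them, as a spatial
proxy for cultural ecosystem services (CES).

# Pipeline stages and their models

## DSM construction

The surface model is built from a LiDAR-style point cloud by *max-Z
binning*: each cell of a square grid (default 6.096 m) takes the maximum
elevation of the points falling in it, after *discarding* (not clamping)
returns above a noise cap (default 300 m) — high returns are atmospheric
or sensor noise, so deletion, not truncation, is the right treatment.
Cell membership uses half-open intervals `[x0, x0 + cellsize)` with the
origin at the lower-left corner; internally row 1 is the southernmost row
and file writers handle north-up ordering. Cells with no surviving return
are nodata; the default policy leaves them (`fill_nodata(policy =
"nearest")` is available, and the viewshed engine tells you when an
observer lands on a void). Slope is Horn's 3x3 finite-difference kernel
with edge replication at the borders; consequently border cells see half
the one-sided gradient, and a cell is nodata whenever its 3x3 window (or
the cell itself) touches nodata.

## Sight-line semantics

Viewshed algorithms differ in details that GIS backends rarely document,
so the package fixes one normative semantics and tests everything against
it:

* the observer's eye sits `eye_height` (default 1.6 m, a standing adult)
  above the *surface* model at the observer cell — on canopy or rooftops
  if that is what the DSM records at that cell;
* the segment between observer and target cell centres is sampled every
  half cell; samples falling inside the observer or target cell are
  excluded; terrain under a sample is the value of the cell containing it
  (nearest-cell lookup);
* the target is visible iff no sample's elevation tangent
  `(z_s - z_o) / d_s` exceeds the target's tangent `(z_t - z_o) / d_t`.
  Tangent comparison is monotone-equivalent to comparing elevation angles
  and avoids trigonometry. Ties pass: grazing rays count as visible;
* distances are centre-to-centre in projected metres; `max_range`
  (default 3000 m) is inclusive; Earth curvature and refraction are
  ignored at a 3 km range;
* nodata cells neither occlude a sight line nor are themselves visible;
* multiple photos in one cell produce identical masks but are counted
  separately in the overlay (active users are deliberately not
  deduplicated).

Two implementations exist: `viewshed()`, a compiled scan, and
`viewshed_naive()`, a plain-R per-target loop. Both are transliterations
of the same expressions, and the build disables floating-point
contraction in the compiled unit so the two agree *bit-exactly*; the test
suite asserts identical masks on 100 seeded random terrains. A
dense-sampling oracle (samples every cellsize/8) is also tested: it is a
*different* function of the terrain — denser sampling visits
corner-clipped cells — and measurement shows it flips decisions only on
grazing rays (tangent margins below 0.005), so the test demands exact
agreement away from grazing incidence and ≥95% agreement overall.

## Intensity, composition, validation

`accumulate()` sums the boolean masks; by construction the total count
equals the summed visible-cell counts of all viewsheds, and the pipeline
asserts this conservation identity on every run. Land-cover composition
within each viewshed is tallied on an NLCD-style categorical raster,
nearest-neighbour-resampled to the DSM grid (categorical data forbid
averaging).

Content validation compares, per land-cover class, a photo's manually
assigned labels with the classes visible in its viewshed, as a 2x2
presence/absence table per class (per-class binary kappa rather than one
multi-category kappa, since each photo can show several classes).
`kappa_2x2()` implements Cohen's chance-corrected agreement
`(p_o - p_e) / (1 - p_e)`. Degenerate tables (chance agreement 1) return
1 when observed agreement is perfect and error otherwise. The default
presence rule is "any visible cell of the class" (fraction strictly
positive); a positive `min_fraction` is compared inclusively. The
relevance filter (photos whose content is unrelated to landscape
appreciation) applies to validation and reporting only, never to the
intensity overlay.

## The intensity model

Counts are overdispersed — most cells are seen by few viewsheds, hotspot
cells by thousands — so the response is modelled as NB2:
mean `mu = exp(X beta)`, variance `mu + alpha mu^2`, with `alpha > 0` the
dispersion (`alpha -> 0` recovers Poisson). `fit_nb()`:

* profiles `alpha` on a log-spaced grid `10^-3 ... 10^2` (31 points),
  maximising the likelihood over `beta` at each candidate by Fisher-scoring
  IRLS (working weights `mu / (1 + alpha mu)`), with step halving so the
  deviance never increases across accepted iterations; convergence when
  the deviance change drops below `1e-8`, at most 100 iterations, linear
  predictors clipped at ±30 with a warning;
* refines the AIC-minimising candidate by golden-section search on
  `log(alpha)` to relative tolerance `1e-4`, keeping the better of the
  grid and refined optimum so the selected AIC is never above any grid
  candidate (asserted);
* reports standard errors from the observed information at the optimum
  (`w_i = mu(1 + alpha y) / (1 + alpha mu)^2`), Wald p-values, and
  `IRR = exp(beta)`.

AIC uses `2(k + 2) - 2 logL` — `k+1` regression coefficients plus the
dispersion. The covariate table is a seeded uniform sample of cells
(default 1%, `round(fraction * n_cells)` rows) carrying the full schema:
class indicators (forest, agriculture, fresh water, ocean, woody and
emergent wetland, urban, park, trail buffer), natural-log distances with
a one-cell offset (`ln(d + cellsize)`) to the coastline, lake/river
shoreline, coastal attractions and historical attractions (km), Horn
slope, and population density. The trail buffer defaults to 100 m (the
source material states both 50 m and 100 m in different places; the
buffer is a configuration knob). Natural logs are used throughout — the
base is a reparameterisation absorbed by the coefficients, but epsilon
handling must be explicit because cells can sit exactly on a feature.

Reporting compares the fit with an intercept-only null fitted by the
same alpha-selection procedure: McFadden `1 - lnL1/lnL0`, Nagelkerke
`[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`, and standardised estimates
`beta_j * SD(x_j) / SD(y)` — the linear-model convention applied to a
count GLM, so it is an approximate effect-size ranking, not a formal
elasticity. Wald p-values are uncorrected for multiplicity, matching the
reporting convention emulated here. Diagnostics: `vif()` (`1/(1 - R2)`,
infinite for exact collinearity, flagged above 10) and `morans_i()`
(row-standardised k-nearest-neighbour weights, default k = 8, seeded
permutation p-value, two-sided around the expectation `-1/(n-1)`; a
custom weights matrix — e.g. rook contiguity — may be supplied).

One reporting caveat: in the emulated analysis the published coefficient
for lakes/rivers is negative (−2.8201, `exp(beta) = 0.059`), yet its
narrated effect is "increased ... by 16.8" — numerically the *reciprocal*.
The package always reports `exp(beta)` as computed and leaves such
narrative inversions to the analyst.

# The synthetic landscape

No public photo database or statewide LiDAR accompanies the method (the
original photo platform is defunct), so the package generates fully
synthetic inputs with known ground truth; the generator is first-class,
tested code, and its defaults define the study conditions used by the
acceptance checks.

The default scene is a 200 x 200 grid of 6.096 m cells (~1.2 x 1.2 km):
an eastern ocean strip behind a straight coastline, a beach (barren)
band, a gently rising coastal plain (2 m at the shore, +6 m per km
inland), Gaussian hills, a lake, zoned land cover (forest with a 10 m
canopy, agriculture, urban, grass background), a park with a small
lookout knoll, trails, attraction and historical-attraction points, and
a population surface peaked over the urban zone. Zones are painted from
analytic geometry (fractions of the extent, so the scene scales), and a
contradictory overlap of land-cover zones is an error, not a silent
overwrite.

Two generator choices deserve explanation:

* **The woody wetland is a −5 m basin.** In a *surface* model, raised
  canopy is itself highly visible from afar — a "wetland forest" modelled
  as a raised block would attract views rather than repel them. What
  makes a landscape element invisible is dead ground: the wetland sits in
  a depression behind the plain's inland rise, so shore-level observers'
  sight lines graze the intervening terrain and pass above it. This
  realises a genuinely negative visibility effect by physics rather than
  by construction of the response.
* **Placement weights are the ground truth of the photo process, not of
  the intensity model.** Photos are placed with probability proportional
  to `exp(x . beta_true)` on the true covariate stack (defaults: ocean
  +1.5, woody wetland −1.0, park +0.6, log-distance-to-coast −0.7, all
  else 0). The fitted model sees viewshed *counts*, which are a smoothed,
  visibility-mediated transform of placement intensity, so the closure
  check asks for *sign* recovery of all strong effects (|beta*| ≥ 0.3),
  not numerical equality.

The point cloud samples the analytic surface on a jittered dense lattice
(4 returns per cell, 5 cm vertical noise, and a 5 x 10^-4 rate of
high-noise returns at 400–600 m that exercise the z-cap), so binning
reconstructs the surface within jitter. Labels for the content-validation
chain are derived from each photo's true viewshed composition and flipped
symmetrically with probability `label_noise` (default 0.2; 0 yields
perfect agreement and kappa 1 for every class by construction);
non-relevant photos are injected at rate 0.132 with empty label sets.
Counts for direct regression tests come from `rnbinom(size = 1/alpha,
mu)`, which *is* the gamma–Poisson mixture in closed form; moment tests
verify mean `mu` and variance `mu + alpha mu^2`. Everything is a pure
function of the spec and its seed; equal seeds give identical bytes.

# Problem sizes and numerical choices

The shipped checks run at desk scale, chosen to exercise every code path
with comfortable statistical power: viewshed parity on 100 seeded 64 x 64
terrains; NB recovery at n = 5000 with beta = (1.0, 0.5, −0.3), alpha =
0.5 (recovery within 3 SEs, alpha in [0.4, 0.6]); the full closure on the
default 200 x 200 scene with 2000 photos and a 12.5% cell sample (n =
5000 rows, matching the recovery size); the noiseless/shuffled agreement
chain with 1000 photos. The Poisson-limit check accepts a fitted alpha up
to 0.05: with finite samples the dispersion MLE sits slightly above the
grid floor whenever the sample variance chances above the mean.

Tie-breaking and degenerate-input rules are explicit throughout: grazing
sight lines are visible; nearest-cell nodata filling breaks ties toward
the smaller row then column; kappa's degenerate chance-agreement case
returns 1 only for perfect tables; `vif` reports exact collinearity as
infinite rather than erroring; `fit_nb` refuses rank-deficient designs
and IRLS failure carries its deviance trace.

# What passing tests do and do not show

The generator emulates the *structure* of the real inputs — co-registered
rasters and vectors, zoned land cover, overdispersed counts, noisy labels
— not their texture: real LiDAR has variable return density, voids and
classification noise; real land cover errs at 30 m resolution; real photo
placement is driven by access and social dynamics far beyond a loglinear
model. Passing the closure shows the pipeline's stages compose correctly
and that strong, physically realised effects survive the
placement-to-visibility transform; it does not validate the loglinear
placement model against human behaviour.

Two further limitations are inherent and visible in the diagnostics.
First, viewshed intensity is spatially smooth by construction, so model
residuals on the synthetic scene are positively autocorrelated (Moran's I
around 0.5) — the independence SEs understate between-sample variability,
which is why the seed-stability check asks for the bulk of coefficients
within combined SEs and sign stability of significant effects rather than
strict 3-SE agreement; spatially explicit error models are out of scope.
Second, classes that are visible from essentially everywhere (open water
on a coastal scene) have degenerate agreement margins: percent agreement
stays meaningful but kappa collapses toward 0 under any label noise, an
honest property of chance correction, not a bug.
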