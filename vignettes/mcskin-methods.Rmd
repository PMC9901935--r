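---
title: "Quantifying Merkel-cell innervation, turnover, and patterning in zebrafish skin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Merkel-cell innervation, turnover, and patterning in zebrafish skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcskin)
```

Zebrafish Merkel cells (MCs) are small *atoh1a*-expressing mechanosensory
cells dispersed through the epidermis above scales. Quantitative work on
this system rests on a handful of image-derived measurements — is a cell
contacted by an axon, how many cells per unit skin area, which cells
survive from one imaging session to the next, where do cells sit on their
scale — and a statistics layer that turns those measurements into
developmental claims (a density breakpoint at the onset of squamation, a
genotype effect that emerges with growth). `mcskin` implements that whole
measurement chain in R, together with synthetic-data generators whose
ground truth is known exactly, so every stage can be validated without any
microscope data.

## Innervation scoring

Each detected nucleus is summarised by its intensity-weighted 3D centroid
and its *maximum nuclear diameter* (the maximum 3D Feret diameter of the
thresholded blob). The scoring volume is a sphere centred on the centroid
whose diameter is 10% larger than the nuclear diameter — radius
$r = 1.1\,d/2$ — and a cell is innervated if at least one foreground voxel
of the axon mask has its centre within $r$ of the centroid:

$$\text{innervated}_i \iff \min_{v \in \text{axon mask}} \lVert c_v - x_i \rVert_2 \le 0.55\, d_i,$$

with all distances in physical µm so anisotropic stacks (z-step ≠ lateral
pixel size) are handled correctly. Two readings of "10% larger" exist
(enlarge the diameter, or the radius); the factor is exposed as
`enlargement` (default 1.1 on the diameter, the literal reading). The
sphere test uses voxel centres with no partial-voxel geometry — the
behaviour of a raster macro — which makes the scorer exactly testable
against an exhaustive per-voxel scan (`oracle` tests do exactly this).

Aggregate frequencies are reported as $100\,k/n$ with a 95% Wilson score
interval (Clopper–Pearson via `ci_method` if preferred). Wilson is the
default because observed frequencies sit near 100%, where the Wald
interval degenerates and Wilson keeps good coverage.

```{r}
sm <- innervation_summary(rep(c(TRUE, FALSE), c(284, 27)), label = "zn-12")
round(c(freq = sm$frequency_pct, sm$ci_pct), 1)
```

## Image measurements

The density and recombination measurements mirror the standard ImageJ
workflow and are bit-level reproducible:

* `max_project()` — maximum intensity projection over z.
* `convert_8bit()` — linear display-range rescale to 0–255 with
  round-half-to-even; banker's rounding makes the result
  platform-independent.
* `global_threshold()` — automatic Huang or Otsu threshold on a 256-level
  histogram. Huang minimises the Shannon entropy of fuzzy memberships
  $\mu_t(g) = (1 + |g - m_{\text{class}}|/C)^{-1}$ with $C$ the dynamic
  range; Otsu maximises between-class variance. Both scan all 256
  candidate levels; ties break to the lowest level. The foreground is
  *strictly above* the returned level.
* `analyze_particles()` — 8-connected components (ImageJ's default) with
  physical area filters, centroids and maximum Feret diameters in µm.
* `percent_area()` — 100 × foreground / total pixels, used on the
  Huang-thresholded lineage-reporter projection as the local recombination
  efficiency.

Where the original workflow names a method only for the recombination
measurement (Huang), the density masks default to Otsu; both are
overridable. Connected components in 3D use 26-connectivity. Pixel
index $i$ maps to physical coordinate $(i - 0.5)\times$ pixel size (pixel
centres), so centroids are unbiased.

`detect_cells_3d()` reimplements nucleus identification as 3D blob
detection: automatic threshold, 26-connected labelling, a minimum-volume
filter (default 10 µm³, far below a real ~5–8 µm nucleus), and per-blob
summaries. Whether the original macro measured nuclear diameter in 2D or
3D is not documented; we use the 3D Feret diameter plus one lateral pixel
of caliper extent, which recovers an 8 µm test sphere within one pixel.

## Photoconversion pulse-chase

Photoconvertible nls-Eos distinguishes cells present at the pulse
(converted channel high) from cells added later. `classify_photoconverted()`
thresholds the intensity fraction converted/(converted+native), by default
at the Otsu split of the observed ratio distribution, so no manual cutoff
is needed; cells dark in both channels are reported as unclassifiable, not
silently dropped. `turnover_stats()` then computes, from per-timepoint
counts,

* remaining% $= 100\,C(t)/C(0)$ and total% $= 100\,T(t)/T(0)$,
* per-interval loss $1 - C(t_{k+1})/C(t_k)$ and additions
  $N(t_{k+1}) - N(t_k)$,
* a half-life from the log-linear decay fit through the origin:
  $\hat\lambda = -\sum_k t_k \log r_k / \sum_k t_k^2$ over timepoints with
  $t_k > 0$, $t_{1/2} = \ln 2/\hat\lambda$.

The origin constraint encodes $r(0) = 1$ exactly, which a free-intercept
fit would not. A constant series has no decay; the half-life is reported
as undefined (`NA` with `half_life_finite = FALSE`) rather than infinite.
A 15%-per-7-day loss gives $t_{1/2} = 7\ln 2 / (-\ln 0.85) \approx 29.9$
days — about a month. The module works on counts; an optional
nearest-neighbour matcher (5 µm gate) builds per-cell fate tables, but no
reported statistic needs cell identity.

## Cohort statistics

`segmented_fit()` estimates a continuous one-breakpoint linear model
$y = b_0 + s_1 x + (s_2 - s_1)(x - \psi)_+$ by the iterative working-model
update (fit $y \sim x + (x-\psi)_+ + V$ with gap indicator $V$, update
$\psi \leftarrow \psi + \hat\gamma/\hat\beta$), with three robustness
ingredients that matter in practice:

1. step halving — an update is accepted only if the profile RSS improves,
   making each run a descent;
2. multi-start at the interior deciles *and* at every inter-observation
   midpoint, because the profile RSS is piecewise smooth with kinks at the
   observed $x$ and every basin contains a midpoint (capped at the 60 most
   promising midpoints for large n);
3. direct evaluation of the kink candidates themselves, since the global
   minimum can sit exactly on an observed $x$, where the iteration has no
   fixed point.

The winner is the lowest-RSS candidate (exact ties: lowest $\psi$); on 200
default simulated cohorts it equals a 2000-point dense grid search within
0.005 mm. If no slope change is identifiable (e.g. the data are a single
line) the fit falls back to OLS with `identifiable = FALSE`. Per-segment
R² and F are computed by separate OLS fits on each side of $\hat\psi$; the
convention behind published per-segment statistics is ambiguous, and the
full segmented-model summaries are available from the returned object if
the other convention is wanted.

`johnson_neyman()` fits $y = b_0 + b_1\,SL + b_2\,G + b_3\,SL\!\times\!G$
and reports where the genotype contrast $\Delta(SL) = b_2 + b_3 SL$ is
significant: the boundaries are the real roots of
$\Delta(SL)^2 = t^2_{\alpha/2,\,n-4}\,\mathrm{Var}(\Delta(SL))$, a
quadratic in SL, intersected with the observed SL range; sub-intervals are
classified by testing at their midpoints, so degenerate cases
("everywhere", "nowhere") come out correctly even when the quadratic is
ill-conditioned.

ANOVA + Tukey HSD (`aov`/`TukeyHSD`, Tukey–Kramer SE for unbalanced
groups), Mann–Whitney and Wilcoxon signed-rank (`wilcox.test`; exact
distributions for small samples, tie-corrected normal approximation
otherwise) are delegated to base R and cross-checked against enumeration
oracles in the test suite. Degenerate paired tests (all differences zero)
return p = 1 with a warning. Boxplot summaries follow the
median/quartile-hinge/1.5 IQR whisker convention.

## Spatial mapping

`align_scales()` translates each traced scale so the midpoint of the
dorsal-most and ventral-most vertices of its annotated posterior margin
lands at the origin — translation only, so shapes and pairwise distances
are untouched. Coordinates are µm with x anterior→posterior and y
ventral→dorsal. `position_density()` is a Gaussian KDE (via
`MASS::kde2d`) with Scott's-rule bandwidths ($\hat\sigma n^{-1/6}$ per
axis) and grid limits padded by four bandwidths; the trapezoidal grid
integral is returned and stays within 1% of 1. `segment_histogram()` bins
positions inside a rectangle along a chosen axis with half-open bins
$[lo, hi)$ throughout: a point on an interior edge counts right, a point
on the far edge is excluded.

## The synthetic-data generators

The generators define the study conditions the tests run under:

* **Skin stacks** (`generate_skin_stack`): a 500 × 500 px lateral field at
  0.518 µm/px — the pixel size implied by a 500 px region of interest
  covering 67,055 µm², the only calibration derivable from the imaging
  description — with a 1 µm z-step over 30 µm (a conventional confocal
  sampling; no z calibration is documented). Nuclei are anisotropic
  Gaussian blobs truncated at 2σ with σ = diameter/4, diameters uniform on
  5–8 µm; axons are persistent 3D random walks rasterised as 1-voxel
  tubes with varicosity beads. Innervation is enforced *constructively*:
  every truth-innervated cell receives a branch ending inside its scoring
  sphere, every axon voxel is carved out of non-innervated spheres, and
  (with `allow_overlap = FALSE`) centroids are placed so scoring spheres
  are pairwise disjoint — making the truth flags exact by construction,
  which the tests verify on every generated stack. Noise is additive
  Gaussian plus optional Poisson shot noise, both switchable to zero.
* **Pulse-chase series** (`generate_photoconversion_series`): binomial
  survival per 7-day interval (default loss 0.15, the published weekly
  rate) plus Poisson additions (default λ = 9 on n₀ = 60, which keeps the
  total roughly constant, as observed); two-channel intensities with class
  means 0.8 (converted) vs 0.05 (new) and sd 0.05, so the classifier stage
  is nontrivial.
* **Cohorts** (`generate_cohort`): SL uniform over 6–16 mm, bilinear mean
  with breakpoint 8.27 mm, near-flat slope 0.05 below and 1.5 cells per
  10⁴ µm² per mm above, n = 52 fish — the published developmental design.
  The default residual σ = 0.4 cells/10⁴ µm² deserves a note: real
  densities are count-derived and strongly heteroscedastic, nearly
  noise-free below the breakpoint, which is what pins the breakpoint in
  real data. A homoscedastic σ large enough to reproduce the published
  above-breakpoint scatter (σ ≈ 2.3) leaves the breakpoint localisable
  only to ±2 mm at n = 52; the homoscedastic emulation therefore uses the
  low-SL scatter, at which the estimator's median breakpoint error is
  0.17 mm. This is a deliberate simplification, and recovery claims should
  be read as conditional on it.
  The two-genotype fixture (n = 17/genotype, SL 7–19 mm, genotype effect
  +2.1, interaction −0.3, σ = 2.5) was calibrated once so that the
  expected single significance boundary sits near 12.5 mm SL, the
  published geometry: no difference at squamation onset, a clear deficit
  in adults. Single-cohort boundaries at this design scatter with sd
  ≈ 2.4 mm, so replicate medians are the meaningful summary.
* **Scale fields** (`generate_scale_field`): rounded polygons with
  anterior lobes and an annotated posterior-margin arc; points sampled by
  rejection under a configurable intensity, so ray/interray contrasts can
  be dialled in and checked against multinomial expectations.
* **Mosaic recombination fields** (`generate_mosaic_field`): a
  keratinocyte-sized checkerboard with each patch labelled at the target
  coverage; with zero noise the Huang %Area recovers coverage exactly.

What the generators do *not* emulate: optical PSFs, spectral
bleed-through, motion, photoconversion photochemistry, fish-to-fish
clustering of scales (cohort rows are independent), or heteroscedastic
density noise (above). Passing tests demonstrate the measurement chain is
correct on data obeying the stated models, not that segmentation would
survive arbitrary real-world image quality.

## Problem sizes and numerical conventions

The shipped test-suite and acceptance-script sizes are the package's
validation conditions: 20 random ≤64³ stacks for the exact innervation
oracle; 100 seeds × 200 cells for frequency recovery; 50 random histograms
and 50 random masks for the threshold and particle oracles; 100 simulated
series for loss/half-life recovery; 200 cohorts for grid-search
equivalence; 50 interaction datasets against a 10⁴-point grid scan; 2000
null simulations for rank-test calibration. Breakpoint iterations stop at
|Δψ| < 10⁻⁶ (≤100 iterations); thresholds and histograms operate on 256
levels; 8-bit conversion rounds half to even; all half-open interval
conventions are as stated above. Deterministic generators save and restore
the caller's RNG state, and the pipeline derives per-stage seeds as
`seed × 100 + stage offset`, so adding a stage never perturbs another
stage's stream.

## Limitations

Printed statistics that depend on the study's per-figure source data
(exact regression R²/F values, the regional ANOVA F, the exact 12.5 mm
boundary) can only be checked in distribution against the emulated
designs, not recomputed, because those spreadsheets are not bundled here.
The breakpoint-recovery tolerance holds at the default noise model, not
under arbitrary scatter. The innervation scorer inherits the raster
macro's convention (voxel centres, no sub-voxel geometry): its calls can
differ from a continuous-geometry reading by up to half a voxel diagonal
near the sphere surface.
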