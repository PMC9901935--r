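# mcskin

Image quantification and statistics for zebrafish Merkel-cell biology.

Zebrafish Merkel cells (MCs) are small *atoh1a*+ mechanosensory cells
dispersed in the epidermis above scales. Studying them quantitatively means
answering four kinds of questions from confocal stacks and per-fish tables:

1. **Innervation** — is each cell contacted by a somatosensory axon? A cell
   is scored innervated if any axon-mask voxel centre lies within a sphere
   centred on the nuclear centroid with diameter 1.1 × the maximum nuclear
   diameter; frequencies carry 95% Wilson score intervals.
2. **Density and recombination** — ImageJ-style measurement chain: maximum
   projection, 8-bit conversion, automatic Huang/Otsu thresholding,
   8-connected particle analysis with physical-area filters, %Area, and
   densities in cells per 10⁴ µm² (per-lobe averaging and pooled tiled
   modes included).
3. **Turnover** — photoconversion pulse-chase accounting: classify cells as
   photoconverted vs newly added from two-channel nls-Eos intensities, then
   derive remaining/total percentages, per-interval loss and addition
   rates, and a half-life t½ = ln 2 / λ from a log-linear decay fit through
   the origin. A 15%-per-week loss gives t½ ≈ 29.9 days.
4. **Cohort and spatial statistics** — OLS with CI bands, one-breakpoint
   segmented regression (iterative breakpoint update with step halving,
   midpoint + kink multistart; equals a dense grid-search RSS minimiser),
   the Johnson–Neyman region where two genotype regression lines differ
   (closed-form quadratic boundaries at df = n − 4), one-way ANOVA with
   Tukey HSD, Mann–Whitney / Wilcoxon rank tests, scale alignment at the
   posterior-margin dorsal-ventral midpoint, 2D position KDEs, and
   anterior–posterior position histograms.

Everything runs against synthetic data with exact ground truth: a
confocal-stack generator (Gaussian-blob nuclei, random-walk axons with
varicosities, constructive innervation, controllable noise), pulse-chase
series, bilinear density cohorts with genotype × SL interactions, lobed
scale outlines with point patterns, and mosaic recombination fields. The
package is aimed at imaging labs who want these measurements scripted and
testable rather than embedded in one-off macros.

## Worked example

The `analysis/` directory holds the numbered drivers; running them in order
reproduces the whole chain (`results/` is created as they go):

```sh
Rscript analysis/01_simulate.R            # fixtures with known truth
Rscript analysis/02_innervation.R         # detect + score + summarise
Rscript analysis/03_turnover.R            # pulse-chase accounting
Rscript analysis/04_density_regression.R  # breakpoint, JN, ANOVA, rank tests
Rscript analysis/05_scale_maps.R          # alignment, KDEs, histograms
```

`02_innervation.R` prints, for a simulated 50-cell stack (90% innervation
probability) and for the published per-marker counts:

```
-- 3D nucleus detection on the nuclear channel
   50 nuclei detected (50 simulated)
-- axon mask: Otsu threshold of the axon channel
   threshold 209.3, 1.38% of voxels above
   innervation: 88.0% (44/50), 95% CI [76.2, 94.4]
   ground truth: 88.0%
-- published counts: per-marker frequencies with Wilson CIs
         marker   k   n frequency_pct ci_lower_pct ci_upper_pct
          zn-12 284 311          91.3         87.7         94.0
 p2rx3a_mCherry 196 228          86.0         80.9         89.9
    p2rx3b_EGFP 225 228          98.7         96.2         99.6
    trpa1b_EGFP 217 225          96.4         93.1         98.2
```

All 50 simulated nuclei are recovered and the scored innervation equals the
generated ground truth exactly; the per-marker rows are the published
counts re-summarised with Wilson intervals. `04_density_regression.R` fits
the developmental cohort (n = 52 fish, true breakpoint 8.27 mm SL):

```
segmented_fit: breakpoint = 8.281
  slope below -0.0007242, slope above 1.502 (converged: TRUE, 6 iter)
  segment 1: R² = 0.000, F = 3.45e-05, p = 0.995
  segment 2: R² = 0.981, F = 1.86e+03, p = 1.37e-32
   grid-search cross-check: psi = 8.279 (iterative 8.281)
Johnson-Neyman: genotype difference significant between (boundary at 11.59, 18.49 mm SL)
```

(the fitted breakpoint lands within 0.011 mm of the configured 8.27 mm,
and the genotype difference becomes significant from ~11.6 mm SL; on this
particular cohort the contrast dips back under the 5% threshold at the
very top of the SL range, which single-cohort Johnson–Neyman analyses at
n = 17/genotype routinely do).

The same pipeline is available programmatically:

```r
library(mcskin)
res <- run_pipeline(list(
  stages = c("simulate", "detect", "innervate", "turnover", "stats"),
  seed = 4, out_dir = "results/pipe"))
```

which writes per-stage CSV/JSON outputs plus a run manifest; reruns with
the same config and seed are byte-identical.

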