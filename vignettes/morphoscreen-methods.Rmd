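---
title: "Morphology-to-function screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology-to-function screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`morphoscreen` implements a donor-level screening analysis for cultured
bone-marrow stromal cell (MSC) populations: single-cell morphology and
cytoskeletal texture, aggregated per donor, are related to functional
outcomes — proliferation, osteoblastic and adipocytic differentiation, and
surface-marker expression. Because no public dataset accompanies this kind
of study, the package ships a first-class synthetic-data module that
generates cohorts with *known* latent structure, so every stage — from
pixel-level segmentation to the multivariable selection — can be validated
against planted truth.

This vignette documents the models, the tunable parameters and their
defaults, and the choices made where the design was genuinely open. The
package is a library: the exported functions, `run_pipeline()` and this
document are the interface (no shell tool is shipped; the orchestration
layer is a single R call).

# The synthetic cohort model

## Donor traits and the effect copula

Each donor carries latent morphology traits: mean cell area (um^2), cell
width-to-length ratio, mean nucleus area, nucleus width-to-length ratio,
roundness traits, and a filament-density scalar (`texture_intensity`).
Areas are log-normal and ratios logit-normal — the minimal choices that
respect the support constraints (areas > 0, ratios in (0, 1]). Defaults:

| trait | marginal | default centre / spread |
|---|---|---|
| mean cell area | log-normal | 3000 um^2, sdlog 0.30 |
| cell w/l ratio | logit-normal | 0.45, sd 0.30 (logit scale) |
| mean nucleus area | log-normal | 380 um^2, sdlog 0.25 |
| nucleus w/l ratio | logit-normal | 0.72, sd 0.35 (logit scale) |
| texture intensity | log-normal | 1.0, sdlog 0.30 |

Cell and nucleus area latents share r = 0.6 (large cells carry large
nuclei); nucleus area is additionally capped at 45% of cell area so the
nucleus always fits inside the cell.

Effects are planted through a Gaussian copula. Every trait is a monotone
transform of a standard-normal latent z; an affected outcome is monotone in

$$ v \;=\; \rho\, z_{\text{trait}} + \sqrt{1-\rho^2}\,\varepsilon,
   \qquad \rho = 2 \sin\!\left(\frac{\pi r_s}{6}\right), $$

which yields exactly the target Spearman correlation $r_s$ for the
bivariate-normal latent pair, and rank correlations survive the monotone
marginal transforms. This matters because every downstream statistic is
rank-based. The default cohort (n = 56 donors) plants three effects, all at
the $r_s = -0.5$ scale: nucleus w/l ratio against the osteogenic outcome,
mean cell area against proliferation AUC, and nucleus w/l ratio against the
CD146+ fraction. All other trait-outcome pairs are independent by default;
an optional `osteo_adipo_link` introduces a differentiation trade-off.

## Assay panel

Growth is logistic from 1,000 seeded cells (carrying capacity 2e5), with a
donor growth rate log-normal around 0.238/day (spread 0.42 on the log
scale). These two numbers were chosen once so that the cohort population
doubling time (PDT) centres near 76.5 +/- 34 h, the range reported for
primary MSC cultures. Counts at days 1, 3, 6, 9, 12, 15 come in triplicate
with multiplicative log-normal noise (CV 10% by default); proliferation AUC
and PDT are then *computed from the simulated counts* by the assay module,
not drawn directly. The osteogenic outcome (alizarin red, AU) is linear in
its latent (clipped at 0), the adipogenic outcome (lipid area %) is a
logistic squash — strictly positive, hence log-transformable. CD marker
percentages use the cohort means and SDs of the emulated population (CD146
62 +/- 30, CD271 26 +/- 25, ALP+ 26 +/- 16, CD44/73/90/105 near-saturated)
clipped to [0, 100].

## Rendered fields

`render_field()` draws each cell as an ellipse with a small low-order
radial perturbation (amplitude <= 4%; near-convex "smoothed blobs"),
placed by dart throwing with bounded retries so that bounding circles never
overlap — the emulated cultures are subconfluent, and overlap resolution is
explicitly out of scope. Nuclei are interior ellipses aligned with the cell
axis. Channels: DAPI (nucleus fill with per-nucleus brightness jitter),
actin and tubulin (faint cell body at 0.12 plus oriented filament strokes
whose number scales with `texture_intensity`, blurred at sigma = 1 px). All
channels receive a linear background gradient and Gaussian noise (sd 0.01).
Ground truth records both the requested area and the rasterized pixel
count, plus moment-based axis lengths measured on the true label maps, and
a border flag.

What the generator does *not* emulate: point-spread physics, shot noise,
uneven staining, touching or overlapping cells, debris, and out-of-focus
fields. Passing the imaging tests therefore shows that the segmentation and
feature contracts hold on clean, well-separated objects — not that the
pipeline is robust to confluent or low-quality real microscopy.

# Segmentation

Nuclei: median-background subtraction, global Otsu threshold, hole filling,
and a distance-transform watershed to split touching nuclei; objects under
`min_area` (30 px at ~1 um/px) are discarded as debris. Cells: seeded
region growing (`EBImage::propagate`) on the smoothed cytoskeleton
intensity, constrained to a foreground mask, so each cell inherits its
nucleus id and strictly contains its nucleus. The foreground mask uses a
planar illumination fit (subtracted), then a two-pass threshold: Otsu
locates the foreground, and the final cut sits at half the cell-body level
(40th percentile of foreground intensity — robust against bright filament
pixels). The half-maximum of a blurred step edge recovers the true
boundary, which is why this calibration is essentially unbiased on rendered
fixtures. In the pipeline the cytoskeleton image is the pixelwise *min* of
the actin and tubulin channels: filament strokes are channel-specific while
the cell body is shared, so the min suppresses texture without eroding the
body. Border-touching objects are removed from both maps before analysis.

Pixel size is always a configuration field (um/px), never hard-coded: the
objective/camera combination of a high-content imager determines it and it
varies between installations.

# Morphometry and SER texture

Width and length are the full axes of the second-moment-equivalent ellipse
(rotation invariant, unlike a bounding box); a 1/12-pixel self-variance
term keeps single-pixel objects finite. Roundness is defined as
$4\,\mathrm{area}/(\pi\,\mathrm{length}^2)$ — one of several conventions in
use; it equals 1 for a circle and penalizes elongation and irregularity.

The SER texture family scores eight local patterns — spot, edge, ridge,
saddle, valley, hole, bright, dark — from Gaussian-derivative responses at
a fixed scale (default 1 px). After smoothing at sigma = scale, the
gradient magnitude $g$ and Hessian eigenvalues $\lambda_1 \le \lambda_2$
classify each pixel: both eigenvalues negative and comparable is a bright
blob (spot), both positive a dark blob (hole), $\lambda_1 \ll 0$ with small
$|\lambda_2|$ a bright line (ridge), the reverse a dark line (valley),
mixed signs a saddle; edge is gradient-dominated, and bright/dark compare
intensity with the region mean. Each feature is the mean response over the
object mask divided by the maximum of the corresponding magnitude over the
mask, which makes features dimensionless in [0, 1], *exactly* invariant to
intensity rescaling, zero on constant regions, and bit-identical under
90-degree grid rotations. The reference implementation in commercial
high-content software is proprietary, so acceptance is by orderings and
invariances (lines score ridge above blobs, blobs score spot above lines),
never by equality with a vendor's constants. The literature names nine
patterns but enumerates eight tokens; the pattern list is configurable and
eight are implemented.

DAPI texture is computed over the nucleus mask; actin and tubulin texture
over the cell mask. Donor profiles carry mean, SD and CV of every feature
(CV only where the mean is positive), the cell count, and a flag — not a
silent drop — for donors below the minimum cell count (default 1,000).

# Statistics

**Bivariate screen.** Each pair is cleaned by ROUT at Q = 1% and then
tested with a two-tailed Spearman correlation (exact permutation p for
n <= 9, t-approximation otherwise). ROUT fits a robust straight line by
IRLS with Lorentzian weights, scales residuals by the RSDR (68.27th
percentile of absolute residuals times n/(n-K), K = 2), converts them to
t p-values on n-K df, and applies the Benjamini-Hochberg step from the most
extreme residual inward: the j-th smallest p is compared with Q j / n. On
clean Gaussian data this removes any point in only ~1% of datasets while
removing five 10-sigma contaminants essentially always. The straight line
is the minimal special case of the nonlinear-regression setting ROUT was
designed for, and is the natural model for a correlation scatter. No
multiplicity adjustment is applied across the screen by default — the
screening practice this reproduces reports unadjusted correlations — but
`fdr = TRUE` appends a BH-adjusted column.

**Groups.** Donors are median-split into high-OB (osteogenic outcome above
the cohort median *and* adipogenic below) and high-AD (the reverse); ties
and mixed donors stay unclassified — strict inequalities, since nothing
principled assigns an exact-median donor. Group differences use the
pooled-variance t-test; discrimination uses the rank (Mann-Whitney) AUC
with a DeLong confidence interval at 97.5% (kept as the default level for
comparability with the reporting convention this package mirrors). The
default orientation is *fixed* (scores expected higher in the positive
class), so a null AUC averages 0.5; folding to AUC >= 0.5 ("auto") is
available but biases null summaries upward, which is why it is not the
default.

**Stability selection.** The Lasso path is computed on each of 50
subsamples of size floor(n/2) drawn without replacement; the first q
distinct variables to enter the path are that subsample's selected set, and
a variable's selection probability pi is its relative frequency over
subsamples. The stable set is {pi >= theta} with theta = 0.75, and q is the
largest integer with $q^2 / ((2\theta - 1) p) \le \mathrm{PFER}$, the
stability-selection bound on the expected number of false selections
(PFER = 2 by default). "First q on the path" implements selection of a
predetermined number of explanatory variables; an active-set-at-fixed-
lambda variant would require a lambda-selection rule that the procedure is
designed to avoid. Predictors are re-standardized inside each subsample to
avoid leakage across subsamples. When more than the remaining budget of
variables enters at a single path step, the lowest column index wins and
the event is flagged; this documented tie-break means column-permutation
equivariance of pi holds only up to tie events. The default predictor
matrix is the 34 per-donor feature *means* (10 morphometry + 24 SER);
SD/CV columns are nearly collinear with the means and are left out of the
default design matrix.

**AIC ladder.** For each outcome (osteogenic raw, adipogenic
log-transformed), nested least-squares models are compared by
AIC = n ln(RSS/n) + 2k (constants shared across models dropped; only
differences are meaningful): m0 intercept-only, m1 the top stable variable,
m2 a four-variable set — for the osteogenic outcome nucleus w/l, cell w/l,
nucleus length and tubulin spot texture; for the adipogenic outcome nuclear
hole texture, nucleus w/l, cell w/l and actin spot texture. Under a null,
exact accounting gives the intercept model the lowest AIC in roughly three
quarters of replicates (the 2k penalty corresponds to a chi-square hurdle
of 2 per parameter), which is the level the tests assert.

# Numerical choices and degenerate inputs

* Spearman p-values: exact enumeration below n = 10; beyond that the
  t-approximation, with p clamped to [0, 1] and r = +/-1 mapped to p = 0.
* ROUT declines to act at Q = 0 and warns below n = 10; an all-zero
  residual spread retains every point.
* `lasso_first_q` drops zero-variance columns with a warning; glmnet runs
  with a tight convergence threshold (1e-12) so path entry order is stable.
* Blank images yield empty label maps with warnings, not errors; empty
  masks and constant regions are defined cases for SER (all zero).
* Rank-deficient AIC fits go through R's pivoted least squares with a
  warning.
* The trapezoid integrates the growth curve on the observed days only — no
  extrapolation to day 0; PDT uses natural logs (the formula is
  base-invariant) and refuses non-growing cultures.
* All simulation entry points take explicit integer seeds; one seed
  reproduces a whole pipeline run byte-for-byte, and the run directory is
  immutable once its manifest is written.

# Problem sizes used in the shipped tests

The validation suite exercises cohorts of 56 donors at the feature-table
fast path (hundreds of replicates for the operating characteristics:
ROC-null calibration, PFER control under a global null with p = 40,
ROUT false/true discovery rates, planted-correlation recovery over 200
cohorts, and 100 end-to-end stability-selection runs), and rendered fields
of 100-200 cells for the imaging contracts. These sizes were chosen so the
whole suite documents the method's behaviour at the study's design scale
while remaining routine to run on a laptop.

# Known limitations

* The rendering model is deliberately minimal; segmentation parameters are
  calibrated on it and will need re-tuning for real micrographs
  (`pixel_size`, `min_area`, smoothing sigmas are all exposed).
* SER values are not numerically comparable to any vendor's texture
  features — only their orderings and invariances are specified.
* Stability selection is implemented for continuous outcomes with the
  Lasso only; complementary-pairs variants, elastic net and logistic
  outcomes are out of scope.
* The bivariate screen deliberately reports unadjusted p-values (with an
  optional FDR column), mirroring common screening practice rather than
  endorsing it.
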