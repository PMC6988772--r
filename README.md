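# morphoscreen

High-content morphology screening for cultured bone-marrow stromal cell
(MSC) populations, in R.

Cultured MSCs are heterogeneous: populations from different donors differ
in proliferation capacity and in their propensity to form osteoblasts or
adipocytes, which makes "cell quality" hard to certify before a clinical
protocol. Quantitative imaging offers a way out: single-cell morphology —
cell and nucleus area, width-to-length (w/l) ratio, roundness — and
cytoskeletal/nuclear texture, averaged over at least a thousand cells per
donor, turn out to carry predictive signal for donor-level function. This
package implements that screening analysis end to end, for

* **imaging scientists** who want a tested, open implementation of the
  per-cell morphometry + SER texture feature set and its donor-level
  aggregation, with nuclear/cellular segmentation of multi-channel fields;
* **biostatisticians** who need the donor-level statistics: Spearman
  screening with ROUT outlier removal, median-split group comparison with
  rank AUC and DeLong intervals, and Lasso stability selection with
  per-family error-rate (PFER) control plus an AIC model ladder;
* **method developers** who want a synthetic cohort generator with planted,
  rank-exact effect sizes and rendered ground-truth images against which
  every stage can be validated.

## The core models

**Planted effects.** Donor traits are log-/logit-normal transforms of
standard-normal latents; an outcome affected by a trait is monotone in
`rho * z_trait + sqrt(1 - rho^2) * eps` with `rho = 2 sin(pi r_s / 6)`, so
the pair attains the target Spearman `r_s` exactly and the rank target
survives all marginal transforms. Defaults plant `r_s = -0.5` for nucleus
w/l -> osteogenic outcome, cell area -> proliferation AUC, and nucleus
w/l -> CD146+ fraction, in 56-donor cohorts.

**Assays.** Proliferation is summarized as the trapezoidal area under the
cell-count curve (days 1-15, triplicates) and as the population doubling
time `PDT = 120 h * log(2) / log(N_day6 / N_day1)`; differentiation as
alizarin-red intensity (osteogenic, AU) and Oil-Red-O lipid area
(adipogenic, %); plus ALP activity per viability unit and CD-marker
percentages.

**Selection.** Stability selection runs the Lasso on 50 half-size
subsamples, keeps the first `q` variables to enter each path, and declares
variables with selection probability `pi >= theta = 0.75` stable, with `q`
the largest integer satisfying the PFER bound
`q^2 / ((2 theta - 1) p) <= PFER = 2`.

See `vignettes/morphoscreen-methods.Rmd` for the full model account,
parameter defaults and design rationale.

## Worked example

```r
library(morphoscreen)
cfg <- effect_config(n_donors = 56, seed = 1)     # default planted cohort
run_pipeline(cfg, out_dir = "demo_run")           # simulate -> analyze -> write tables
cat(make_report("demo_run"), sep = "\n")
```

Output (abridged):

```
-- correlation screen (ROUT Q=1%, Spearman two-tailed) --
  nucleus_wl_ratio       vs alizarin_au          r_s = -0.54  p = 1.746e-05  n = 56
  nucleus_wl_ratio       vs lipid_pct            r_s = +0.01  p = 0.9271  n = 56
  nucleus_wl_ratio       vs cd146_pct            r_s = -0.54  p = 1.669e-05  n = 56
  cell_area              vs proliferation_auc    r_s = -0.44  p = 0.002458  n = 46

-- high_OB vs high_AD group comparison --
  nucleus_wl_ratio: t = -2.90, p = 0.00721; ROC AUC = 0.76 (0.55-0.96, 97.5% CI); n = 15 vs 15

-- stability selection (osteo outcome) --
  nucleus_wl_ratio         pi = 1.00  (negative)  [stable]
  cell_roundness           pi = 0.40  (positive)
  AIC ladder: m0 = -54.2, m1 = -77.3, m2 = -73.4
```

Reading it: the three planted effects are recovered at their target
magnitude (`r_s ≈ -0.5`, p < 0.01) while unplanted pairs stay null; donors
with contrasting differentiation potential differ in nucleus shape (high-OB
donors have more elongated nuclei, hence the negative t and AUC above
chance); and the multivariable selection singles out nucleus w/l ratio as
the one stable osteogenesis predictor (`pi = 1.00 >= theta`), with the AIC
drop from m0 to m1 confirming its predictive value and no further gain from
the four-variable model m2. `ROUT Q=1%` means each scatter was cleaned by
robust-regression outlier removal at a 1% maximum false discovery rate
before the Spearman test; `n` counts the donors that survived it.

The same pipeline runs from rendered images (`mode = "images"`):
multi-channel fields are drawn with ground truth, segmented (Otsu +
distance-watershed nuclei, seeded propagation cells, border-cell
exclusion), and per-cell features are extracted and aggregated before the
identical statistics.

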