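# tcrpi

Prognostic survival modeling from bulk expression cohorts that must be
merged across platforms. `tcrpi` builds a **T-cell-related prognostic index
(TCRPI)**: per-sample T-cell infiltration levels are scored by single-sample
gene set enrichment (ssGSEA), reduced to binary **cell-pair features**
`TCP_ab(s) = 1{NES_a(s) > NES_b(s)}` that are invariant to any strictly
increasing per-sample transform of the data, screened by log-rank tests,
and combined by LASSO-penalized plus multivariate Cox regression into

```
TCRPI(s) = Σ_i Coef_i · TCP_i(s)
```

Patients are split into high/low risk at the cutoff of the 5-year
time-dependent ROC curve closest to the ideal corner, and a composite
clinical index (CTCPI) augments the score with Wald-retained clinical
covariates (age, stage, ...). Because every feature is a within-sample
comparison, the fitted model transfers across cohorts without batch
adjustment — the package proves this property to itself on synthetic
multi-cohort data with planted signatures and per-sample platform
distortions.

Audience: statisticians and computational biologists building or auditing
rank-based prognostic signatures for multi-cohort survival data
(e.g. bladder-cancer immuno-oncology cohorts), and anyone needing the
surrounding evaluation battery (Kaplan–Meier/log-rank, Harrell C-index,
restricted mean survival, response AUC) with enumeration-tested
implementations.

## Worked example

Simulate a 4-cohort study (800 samples each, 19 cell types, 8 planted
prognostic pairs, per-sample platform distortions) and run the full
pipeline:

```r
library(tcrpi)
cfg <- run_config(simulation = simulation_config(seed = 11), seed = 11)
report <- run_pipeline(cfg)
report
#> TCRPI pipeline report
#>   pairs: 171 universe -> 171 non-constant -> 83 prognostic -> 38 LASSO -> 12 final
#>   cutoff 2.3420 (training AUC 0.851 at 60 months)
#>         part    n n_high n_low     logrank_p cindex_tcrpi cindex_ctcpi rms_ratio
#>        part1  800    412   388  1.059916e-76    0.7673991    0.7761606  2.516388
#>        part2  800    416   384  4.835323e-57    0.7440872    0.7515101  2.355086
#>        part3  800    380   420  6.354938e-72    0.7603525    0.7660630  2.443537
#>        part4  800    420   380  7.995855e-51    0.7308597    0.7453897  2.220248
#>  meta_entire 3200   1628  1572 1.181698e-248    0.7506062    0.7596664  2.377276
#>   response: AUC 0.778 (n=800)
```

Reading the output: of the 171-pair universe, 83 pairs pass the training
log-rank screen, the LASSO keeps 38 and the multivariate Cox refit 12; the
risk cutoff 2.342 splits every held-out part (`part2`–`part4`, never seen
during fitting) into groups with strongly separated survival (log-rank
p < 1e-50), a TCRPI C-index near 0.75, low/high restricted-mean-survival
ratios above 2 at 10 years, and the composite CTCPI improving concordance
over the TCRPI alone. In the response-labeled cohort, low TCRPI predicts
immunotherapy response with AUC 0.778.

A fitted model is a frozen, serializable object:

```r
write_pair_index_model(report$model, "model.json")
risk <- apply_index(read_pair_index_model("model.json"),
                    new_cohort, gene_sets)   # high/low per new sample
```

Real data enter through `run_config(mode = "load", paths = list(...))` with
gene × sample TSVs, a GMT of cell-type sets (an illustrative 19-set example
ships in `inst/extdata/tcell_sets_example.gmt`; any user GMT is accepted),
and a clinical CSV (`sample_id, os_months, os_event, age_years, gender,
stage, grade, response`). A thin command-line wrapper lives in
`inst/scripts/tcrpi-pipeline.R` (subcommands `simulate`, `run`, `apply`).

See `vignettes/tcell-pair-index.Rmd` for the model, the design decisions,
and what the synthetic validation does and does not establish.

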