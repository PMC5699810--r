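# copdtriage

Simulation and evaluation of machine-learned triage for chronic
obstructive pulmonary disease (COPD) against a physician-panel consensus
standard.

COPD patients at home must repeatedly decide among four ordinal actions —
**Ok** (no attention needed) < **Plan** (continue treatment, recheck in 1–2
days) < **Doc** (call the doctor) < **ER** (go to the emergency room) — and
whether their symptoms signal an exacerbation. This package reimplements a
consensus-validated triage study as a fully synthetic, seed-reproducible
pipeline for methodologists who want to stress-test that design:

* **Case simulation** — a D-optimal profile design over demographics and
  baseline vitals (`det(XᵀX)` maximized by a Fedorov exchange implemented
  from scratch), completed into 2,501 full cases by a Gaussian copula with
  configurable marginals and correlations, including `unknown` responses.
* **Panel simulation** — parametric raters (linear severity score +
  thresholds + noise) with controllable heterogeneity, including extreme
  over-/under-triager outliers; or ingestion of real label spreadsheets.
* **Consensus** — majority vote with the conservative tie-break (ties go
  to the *higher* category), under three membership scenarios including
  leave-self-out.
* **Models** — grid search + stratified 5-fold CV over nine classifier
  families, out-of-sample selection, and the two bespoke importance
  schemes (gradient-boosting *fraction of samples*; averaged one-vs-rest
  logistic coefficient ranks).
* **Evaluation** — ordinal-safety statistics on the consensus confusion
  matrix: accuracy, emergency one-vs-rest sensitivity/specificity/PPV/NPV,
  upper-triangular proximity `UTP = 1 − LT/n`, errors greater than one
  category, the medical-attention collapse (triage ≥ Doc), and per-rater
  distribution outlier flags.
* **Robustness** — the exhaustive panel-growth analysis: how often the
  consensus changes when a panel of size *s* gains one member, for every
  subset and every size.

## Worked example

A compact end-to-end run (400 cases, 60 validation, 9 raters, GB + LR):

```r
library(copdtriage)
cfg <- experiment_config(
  cohort = cohort_config(n_design = 30, n_total = 400, n_validation = 60,
                         n_candidates = 300, seed = 2026),
  n_raters = 9, n_train_raters = 6, families = c("gb", "lr"), seed = 2026)
rep <- run_pipeline(cfg)

rep$selection$triage
#>  family cv_accuracy validation_accuracy
#>      gb    61.54375            66.66667
#>      lr    59.75657            55.00000

m <- rep$metrics$triage
sprintf("triage ACC %.1f%%  UTP %.1f  EG1 %.1f  ER sens %.1f%%",
        m$ACC, m$UTP, m$EG1, m$TPR)
#> "triage ACC 68.3%  UTP 88.3  EG1 3.3  ER sens 100.0%"

rep$confusion$triage
#>          predicted
#> consensus  1  2 3 4
#>         1 13  0 1 0
#>         2  1 13 7 1
#>         3  0  6 6 3
#>         4  0  0 0 9

round(rep$convergence, 2)
#>  panel_size_from panel_size_to mean_change max_change min_change
#>                5             6        6.51      16.00       0.33
#>                6             7        5.55      15.42       0.00
#>                7             8        3.54       8.33       0.00
#>                8             9        2.67       6.67       0.00
#>                9            10        2.33       3.33       0.00
```

Reading the output: the gradient-boosted model best matches the 9-rater
consensus out of sample (66.7% at this small size); against the consensus
that includes its own vote it reaches 68.3% accuracy while *never* missing
a consensus-ER case (ER sensitivity 100%), under-triaging 11.7% of cases
(UTP 88.3). The convergence table says that a 9-member panel changes its
majority on only 2.3% of cases on average when a 10th member is added —
the panel-size robustness curve. At full scale (2,501 cases) the
distributions tighten; noise-free known panels are recovered at ≥ 95%
validation accuracy (see the acceptance script).

Individual stages are exported directly: `generate_cohort()`,
`encode_features()`, `default_panel()` / `simulate_panel()`,
`consensus_labels()`, `train_and_tune()` / `select_top_models()`,
`triage_metrics()` / `medical_attention_metrics()` / `safety_summary()`,
`convergence_curve()`, and CSV/spreadsheet readers (`read_cases()`,
`read_labels()` with an S1-style dialect).

## Documentation

The methods vignette (`vignettes/copd-triage-simulation.Rmd`) describes
the simulation model and its assumptions, the parameter defaults and why
they were chosen, what the synthetic panel does and does not emulate, and
the numerical conventions (bin edge handling, tie-breaks, undefined
metrics).
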