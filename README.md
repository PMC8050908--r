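# coxdistnet

Individual survival-time prediction from right-censored tabular clinical
data, for biostatisticians and ML researchers who need a *time* — not
just a risk score — out of a Cox-style model.

A Cox model (classical or DeepSurv-style) predicts a log-risk
`h(x)`; turning that into a survival time classically requires choosing
a parametric distribution by hand and sampling `T = u / exp(h(x))`.
`coxdistnet` replaces the hand-picked draw `u` with a learned,
covariate-dependent estimate: a **hazard network** `ĥ_θ(x)` trained on
the Cox negative log partial likelihood

    L(θ) = − Σ_{i: E_i=1} [ ĥ_θ(x_i) − log Σ_{j: T_j ≥ T_i} exp(ĥ_θ(x_j)) ]

is frozen, and a **distribution-function network** `y_pred(x)` is
trained on the hazard-rescaled squared error

    Loss = (1/n) Σ_i ( y_i − y_pred(x_i) / exp(ĥ_θ(x_i)) )²

so the predicted survival time is `ŷ = y_pred(x) / exp(ĥ_θ(x))`.

The package also provides:

* **Kaplan–Meier curve IoU** — area under the pointwise minimum of the
  predicted-times KM curve and the ground-truth KM curve divided by the
  area under the pointwise maximum (rectangle sums, `dx = 0.1`) — plus
  RMSE and Lin's concordance correlation;
* classical **fixed-distribution baselines** (exponential, Weibull,
  Gompertz) with ML parameter fitting and inverse-transform sampling;
* **1D Grad-CAM** feature attribution with per-feature means and a
  patient×feature heat-map table sorted by predicted survival time;
* a **synthetic censored-cohort simulator** with known linear
  log-hazards and calibrated censoring, and a **5-fold CV experiment
  harness** with grid search;
* a thin CLI (`inst/cli/coxdistnet`) with subcommands
  `simulate`, `train-hazard`, `train-survival`, `predict`, `evaluate`,
  `explain`, `gridsearch`, `run-all`.

Everything runs on plain CSV cohorts (named time and event columns, all
other columns features; categorical columns label-encoded, covariates
rescaled to [0, 1]) — no external clinical downloads required.

## Worked example

```r
library(coxdistnet)

cohort <- simulate_cohort(synthetic_spec(n = 1000, seed = 1))
spec   <- network_spec(learning_rate = 1e-3, epochs = 1500, patience = 100)
report <- run_cv_experiment(cohort$dataset, k = 5, seed = 1,
                            hazard_spec = spec, dist_spec = spec)
report
```

```
evaluation_report: 5-fold CV, seed 1
      method       iou     rmse        ccc
 exponential 0.6672601 7.478998 0.09013217
    gompertz 0.6714680 7.304017 0.09611335
    proposed 0.5309715 5.225685 0.14285453
     weibull 0.6700397 7.317403 0.09474351
```

The integrated model ("proposed") predicts held-out death times with
~30% lower RMSE and ~50% higher concordance than the best
fixed-distribution baseline. Its KM-curve IoU is lower here because on
this simulated cohort the baselines' distributions are ML-fitted in a
world where the true family is available to them, so their random draws
reproduce the marginal time distribution almost exactly — see the
methods vignette (`vignettes/coxdistnet-methods.Rmd`) for the full
analysis, training-schedule notes and all modelling conventions.

Feature attribution on a hazard network trained on the full cohort:

```r
hz <- train_hazard(cohort$dataset, spec)
gradcam_1d(hz, cohort$dataset)
#> attribution_result: per-feature mean importances
#>     x1     x2     x4     x5     x3
#> 0.2525 0.2146 0.2080 0.1784 0.1465
```

The two strong generating effects (true log-hazard coefficients +1 and
-1 on `x1`, `x2`) take the top two ranks; with five features on one
cohort the separation from the null features is real but modest —
the attribution tests in the suite quantify it over repeated seeds.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch — simulates a fresh cohort
under the given seed, runs the 5-fold cross-validated head-to-head of
the integrated model against all three baselines, prints the evaluation
report, and writes the results JSON to `--out`.
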