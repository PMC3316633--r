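# tdprime

Does a subliminally flashed reward cue — a rewarding brand logo shown for
16 ms between masks — bias an unrelated economic decision made moments
later, and its neural encoding? `tdprime` implements the full analysis
pipeline for that question: behavioural modelling of temporal discounting
under subliminal priming, signal-detection tests of prime visibility,
parametric fMRI GLMs, and FIR-based searchlight decoding — all driven by a
synthetic-data generator, so every stage runs and is testable without any
external data.

## The models at the core

Hyperbolic discounting with a logistic choice rule:

    SV  = R / (1 + k·D)                       subjective value of $R at D days
    P(later) = logistic(ω · (SV − 20))        vs. a fixed "$20 today"

and a prime-conditional **premium** `a` on the discount rate:

    SV* = R / (1 + (k + a·I_A)·D)             I_A = 1 on Apple-prime trials

Per-subject maximum likelihood estimates (k, a, ω); nested
likelihood-ratio comparison against the baseline model; group-level
premium inference. Trial-level derived quantities feed the imaging
models: the premium Π = SV* − SV, the prime-by-value interaction
Σ = a·SV*, and a difficulty index Γ = 2·min(P, 1−P) with a median split
into easy/hard decisions.

On the imaging side: univariate GLMs with serially orthogonalized
parametric modulators (SV and Σ; SV and Π) and cluster-FWE group
inference by sign-flip permutation, and a searchlight decoder (radius 3
voxels) over FIR estimates — 6 bins × 1 TR, last two bins analysed —
using a linear SVM (C = 1) with leave-one-run-out cross-validation, at
chance 50% by construction.

## Worked example

Simulate one subject at the study's group-mean parameters on the default
216-trial session, then fit and compare both models:

```r
library(tdprime)

sch     <- build_design(design_config(seed = 1))      # 216 TD + 108 PC trials
subject <- discount_params(k = 0.024, a = 0.06, omega = 0.3)
choices <- simulate_choices(subject, sch, seed = 2)

fit_p <- fit_priming(choices)
print(fit_p)
#> priming model fit: n = 216 trials, logLik = -86.708, AIC = 179.42, BIC = 189.54
#>                    k          a      omega
#> estimate 0.026530563 0.04483044 0.36691003
#> se       0.001627412 0.01614120 0.06899255

compare_models(fit_baseline(choices), fit_p)[c("lr_statistic", "p_value")]
#> $lr_statistic
#> [1] 54.13408
#> $p_value
#> [1] 1.872654e-13
```

The generating premium (0.06) is recovered within its standard error, and
the likelihood-ratio test decisively prefers the priming model on this
subject — with `a > 0`, Apple-primed trials are pushed toward the
immediate reward. A chance-level visibility test behaves as it should:

```r
det <- simulate_visibility(0, 96, "detection", seed = 3)
bootstrap_dprime_ci(det, seed = 4)
#> d' = -0.209 (hit 0.458, fa 0.542), 95% CI [-0.695, 0.266], chance-consistent: TRUE
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write tables and NIfTI maps under `results/`:

| script | what it does |
|---|---|
| `01_design.R` | builds the session (216 TD + 108 PC in 6 runs of 54), calibrates amounts, writes events tables |
| `02_behaviour.R` | 13 synthetic participants → per-subject fits, model comparison table, group premium tests |
| `03_visibility.R` | two visibility tests per subject → d′, bootstrap CIs, conjunction awareness verdicts |
| `04_univariate.R` | planted value/interaction/premium regions → parametric GLMs, cluster-FWE tables, apple-vs-cup null check |
| `05_searchlight.R` | planted prime/outcome/difficulty patterns → FIR searchlight decoding, group accuracy inference |

Each stage is deterministic under one master seed and re-runnable on its
own (`Rscript analysis/02_behaviour.R`).

The methods vignette
(`vignettes/priming-discounting-pipeline.Rmd`) documents the models, the
generator's assumptions and limits, and every numerical choice.

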