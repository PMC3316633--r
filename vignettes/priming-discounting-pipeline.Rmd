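---
title: "Subliminal priming of temporal discounting: models, simulation and inference"
author: "tdprime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subliminal priming of temporal discounting: models, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdprime)
```

# The scientific problem

Intertemporal choices trade a smaller, immediately available reward against
a larger, delayed one. Most people devalue delayed rewards hyperbolically:
the subjective value of a reward $R$ available in $D$ days is

$$SV = \frac{R}{1 + kD},$$

with a per-day discount rate $k$; larger $k$ means steeper devaluation
(more impulsive choice). The question this pipeline addresses is whether an
*incidental*, subliminally presented reward cue — a rewarding brand logo
flashed for 16 ms between masks before each choice — shifts this valuation
and its neural encoding, even though the cue is unrelated to the decision.

`tdprime` implements the complete analysis chain for that question as
reusable, tested R functions: behavioural choice modelling by maximum
likelihood, signal-detection analysis of prime visibility, a full
experimental design generator, a synthetic-data generator for choices and
4-D BOLD volumes with planted ground-truth effects, parametric univariate
GLMs with cluster-level family-wise-error (FWE) inference, and FIR-based
searchlight decoding. Every stage runs on synthetic data, so the whole
pipeline is exercisable — and its statistical behaviour verifiable — with
no external data.

# Behavioural models

**Choice rule.** Choices are modelled as logistic in the value difference:

$$P(\text{later}) = \frac{1}{1 + e^{-\omega(SV - 20)}},$$

where \$20 today is the fixed immediate option and $\omega$ (1/dollar) is
the choice sensitivity — the inverse of the decision noise. We treat
$\omega$ as the logistic slope on the value difference (the conventional
softmax form); descriptions of $1/\omega$ as the "variance" of the logistic
are treated as loose wording, since the variance of a logistic with slope
$\omega$ is $\pi^2/(3\omega^2)$.

**Priming premium.** On trials preceded by the rewarding prime (the "Apple"
condition, indicator $I_A$), the discount rate carries an additive premium
$a$:

$$SV^{*} = \frac{R}{1 + (k + a I_A) D}.$$

The additive form is the only rendering consistent with a "premium on the
discount rate" switched by a 0/1 dummy. A positive $a$ makes the primed
subjective value smaller, biasing choice toward the immediate option.

Three derived trial-level quantities feed the imaging models:

* $\Pi = SV^* - SV$, the value shift attributable to priming (zero on
  neutral-cue trials by construction);
* $\Sigma = a \cdot SV^*$, the premium-by-value interaction, which tests
  the hypothesis that the priming effect grows with subjective value. We
  evaluate $\Sigma$ as written on every discounting trial (on cup trials
  $SV^* = SV$); a `sigma_on_cup = FALSE` switch zeroes it there instead;
* the difficulty index $\Gamma$. Only its boundary behaviour is
  constrained by prior work — bounded by 0 and 1, maximal when the
  subjective value of the delayed option equals the immediate \$20,
  decreasing in the distance $\Delta = SV - 20$ — so we adopt
  $\Gamma(\Delta) = 1 - |2P(\Delta) - 1| = 2\min(P, 1-P)$ with
  $P = \text{logistic}(\omega\Delta)$: it satisfies every stated property
  and uses both fitted parameters. "Hard" trials are those with $\Gamma$
  strictly above the subject's median (ties count as easy).

## Estimation

Both models (baseline $k, \omega$; priming $k, a, \omega$) are fitted per
subject by maximum likelihood over usable discounting trials (missed
responses dropped), with probabilities clipped at $10^{-12}$. The
optimizer is bounded L-BFGS-B on $k \in [10^{-4}, 1]$,
$a \in [-0.5, 0.5]$, $\omega \in [10^{-3}, 10]$, with the effective Apple
rate floored at $10^{-8}$ so the box stays feasible; starts are a
deterministic 12-point grid (including $a = 0$) plus the fitted baseline
optimum, which makes the nesting $\ell_{\text{priming}} \ge
\ell_{\text{baseline}}$ structural rather than hoped-for. When several
starts tie (the likelihood is flat in $a$ for subjects whose primed
choices barely constrain it), the smallest $|a|$ attaining the optimum is
reported — the parsimonious point on the ridge. Standard errors come from
the inverse finite-difference observed information; AIC/BIC use the count
of usable trials. Subjects with fewer than 5% of choices in either
category are rejected as non-identifiable, the operational version of
excluding participants who almost always chose the delayed reward.

Model comparison is the 1-df likelihood-ratio test with AIC/BIC
differences. At group level the premium is tested twice: a two-stage
one-sample t-test on the per-subject $\hat a_j$, and a pooled
fixed-effects fit — common $a$, subject-specific $(k_j, \omega_j)$ —
profiled over $a$ with a likelihood-ratio test of $a = 0$. The pooled fit
approximates a nonlinear mixed-effects model with the premium as the fixed
effect of interest; full random-effects integration is deliberately out of
scope, and only the direction and significance of the group effect should
be compared across implementations.

# Experimental design generator

The default session reproduces the scanning structure: 6 delays (1, 10,
21, 55, 90, 180 days) × 6 amounts per delay × 3 repetitions × 2 primes
= 216 discounting trials, plus 108 perceptual-control trials, packed into
6 runs of 54 trials of 7000 ms (378 s of stimulation per run; 189 volumes
at TR 2000 ms). Within-trial timing is fixed: fixation 2417 ms, pre-mask
84 ms, blank 16 ms, prime (or blank) 16 ms, blank 16 ms, post-mask 400 ms,
response screen 4000 ms; the 51-ms shortfall to the 7000-ms grid is
terminal padding. The modelled trial span starts at mask onset (fixation
end) and covers 4500 ms.

**Amount calibration.** Amounts are placed at fixed choice-probability
octiles $\{1,2,3,5,6,7\}/8$ around the indifference amount
$20(1 + kD)$ under a reference sensitivity (default 0.3), so the expected
fraction of later choices is 0.5 by symmetry — the balance the original
calibration aimed for. Where the printed dollar envelope
$[\$20.10, \$385.16]$ binds (short delays at shallow discounting), the
probability offsets are shrunk proportionally, which preserves the
symmetry of the expected choice probabilities while keeping amounts valid
and distinct (one-cent minimum spacing after rounding).

**Run packing.** Each amount-delay-prime cell appears exactly three times
per session in three distinct runs; assignment is a capacity-constrained
greedy fill per prime condition, so each run holds exactly 18 Apple, 18
cup and 18 control trials; later-option screen side is counterbalanced
50/50 within run. A full sequencing optimizer for design efficiency is
intentionally not reimplemented; constrained uniform shuffling under a
fixed seed replaces it.

# Synthetic data generator

The generator defines the study conditions under which every statistical
property of this package is tested; its defaults are fixed, not tuning
knobs.

**Population.** 13 subjects; $k \sim N(0.024, 0.018^2)$,
$a \sim N(0.06, 0.31^2)$, $\omega \sim N(0.3, 0.1^2)$, rejection-sampled
to $k > 0$, $k + a > 0$, $\omega > 0$. The $k$ and $a$ moments are the
study-scale group moments; $\omega$ moments are our choice of a realistic
sensitivity for dollar-scale value differences (at $\omega = 0.3$ a \$7.3
value difference moves choice probability from 0.5 to 0.9).

**Choices.** Bernoulli draws from the generative priming model;
perceptual-control trials are answered correctly with probability 0.98 (a
nuisance parameter).

**Visibility responses.** An equal-variance Gaussian observer with true
sensitivity $d'$ and unbiased criterion $c = d'/2$; the detection test has
signal on half the trials, the identification test is scored as
Apple-versus-rest with signal on a quarter.

**BOLD volumes.** The default grid is 24 × 24 × 18 voxels at 4 mm — a
desk-scale stand-in for a 64 × 64 × 32 acquisition matrix; run timing
matches the acquisition (6 runs × 189 volumes, TR 2 s). Every voxel
receives baseline 100, the evoked response of all trials (4500-ms events
convolved with a canonical double-gamma kernel, unit-mass normalized so an
event of amplitude $A$ plateaus at $A$), cosine drift, and AR(1) Gaussian
noise ($\rho = 0.3$, sd 1 — i.e. 1% of baseline, with the evoked response
of the same order, a realistic single-trial signal-to-noise ratio). The
evoked response carries voxel-specific haemodynamic gain (uniform
0.5–1.5) and latency (±1 s in 0.5-s steps), emulating the documented
regional variability of the vascular response. Planted effects come in two
kinds:

* *parametric* regions scale trial amplitude with the mean-centred SV,
  $\Sigma$ or $\Pi$ (0.02 signal units per modulator unit by default; a
  per-region `size` multiplier compensates for the very different dynamic
  ranges of the modulators — $\Sigma$ spans roughly 1/15 of SV's dollar
  range);
* *pattern* regions add a fixed spatial pattern per class (prime,
  outcome, or difficulty), zero-sum across region voxels and drawn fresh
  per subject. The zero-sum construction leaves the regional mean signal
  class-independent — decodable multivoxel structure without a univariate
  mean difference — and the subject-specific draw mirrors the
  subject-specificity of fine-grained patterns in real data; it also makes
  the group-level univariate contrast on such regions average to zero
  across subjects.

What the generator does **not** emulate: physiological noise structure,
motion, susceptibility artefacts, spatial autocorrelation of noise,
nonlinear haemodynamic summation, and between-region functional
correlations. Passing recovery tests on this generator therefore
demonstrates the correctness and calibration of the *analysis machinery*,
not the detectability of any effect in real recordings.

# Visibility tests

Hits and false alarms follow the test-specific definitions (detection:
"yes" with image present / absent; identification: "Apple" response with
the Apple logo present / another image present);
$d' = z(\text{hit}) - z(\text{fa})$, undefined — reported as `NA`, never
imputed — when either rate is exactly 0 or 1 (an optional log-linear
correction is available behind a flag). Confidence intervals are
percentile bootstrap over 1000 resamples of the subject's responses,
stratified within signal/noise classes so both classes are present in
every resample. A subject counts as *aware* only when both tests'
intervals exclude zero. Percentile intervals (rather than BCa) are used;
at 200 trials their coverage for a chance observer is within a point or
two of nominal.

# Univariate parametric GLMs

Per subject and run, condition boxcars (Apple, cup, control; 4500-ms
events) are convolved with the canonical kernel; parametric modulators are
mean-centred over their carrying trials and *serially orthogonalized* —
each modulator residualized against the condition columns and all earlier
modulators. In the priming-interaction model the order is SV then
$\Sigma$, so shared variance is credited to SV and the $\Sigma$ column
tests prime-specific value modulation; a `reverse_order` flag swaps them
to test prime-independent SV encoding. In the priming-premium model SV
enters on all discounting trials as a regressor of no interest and $\Pi$
on Apple trials only, orthogonalized to SV; a `correct_only` flag
restricts the premium modulator to trials whose observed choice matches
the fitted model's prediction. Ordinary least squares is run per run with
a 128-s cosine high-pass, and betas are averaged across runs.

Group inference: subject contrast maps are smoothed (8 mm FWHM), a
one-sample t is converted to Z, clusters form at $Z > 1.96$ under
6-connectivity, and the null distribution of the maximum cluster size is
built by sign-flipping subject maps (exchangeable under the null);
clusters larger than the 95th null percentile are significant. Sign-flip
permutation replaces Gaussian-random-field theory at the same nominal
criterion; its family-wise error control is exact by construction under
exchangeability and is verified by simulation in the test suite. The
spatial normalization step of a real pipeline is replaced by the shared
synthetic grid.

# FIR searchlight decoding

For decoding, no haemodynamic shape is assumed: a finite-impulse-response
(FIR) model estimates one parameter per condition and 2000-ms time bin
(6 bins covering 12 s from the volume at stimulus onset; 2 × 6 = 12
condition regressors per run for a two-class labelling), per run, after
the same 128-s high-pass. Runs with fewer than 4 trials of either class
are excluded; subjects with fewer than 3 usable runs are excluded — one
uniform operationalization of the original per-analysis exclusions.

The searchlight visits every voxel; the sphere (radius 3 voxels, 123
offsets; radius 2 available for replication) is truncated at grid edges.
Pattern vectors are the per-run, per-class FIR estimates over sphere
voxels at the analysed bins — the last two, where trial-related signal
arrives after haemodynamic delay. Classification is leave-one-run-out: a
linear soft-margin SVM with fixed regularization $C = 1$ is trained on the
other runs' vectors (one per class per run, balanced by construction;
per-fold training-mean removal, no other scaling) and tested on the
held-out run's two vectors, so chance is exactly 50%. Accuracies average
over folds and analysed bins (bins can instead be concatenated into one
vector via `combine = "concatenate"`). The solver is a maximal-violating-
pair SMO driven to a $10^{-9}$ duality gap with the intercept taken as
the midpoint of the KKT-feasible interval, which makes decisions
path-independent, reproducible, and exactly symmetric under label
exchange; it is cross-checked against libsvm in the test suite. Group
inference reuses the sign-flip cluster machinery on smoothed
accuracy-minus-chance maps. Difficulty decoding is additionally run
within each prime condition separately, with the median split recomputed
within condition.

# Numerical and design choices

* Canonical response kernel: difference of gamma densities with modes at
  6 s and 16 s, peak:undershoot 6, 32-s support, unit peak; unit-mass
  normalized inside the convolution.
* FIR bins are tied to 1 TR; trial onsets are mapped to the volume
  containing the stimulus onset.
* Probabilities clipped at $10^{-12}$ in likelihoods; LR statistics
  negative beyond $10^{-6}$ raise an optimization-failure error rather
  than being silently clamped.
* Degenerate designs fail loudly: all-zero modulator columns are dropped
  with a warning (e.g. $\Sigma$ when $\hat a = 0$); rank-deficient design
  matrices raise an error naming the collinear columns.
* Ties: predicted choice at $P = 0.5$ is "now" (toward the immediate
  option); difficulty ties at the median are easy; an SVM decision of
  exactly zero scores half a correct answer.
* Determinism: every stochastic step takes an explicit seed; a master
  seed fans out to stage seeds through a fixed integer derivation
  (`child_seed`), so stages are independently re-runnable and the whole
  pipeline is byte-reproducible.

# Problem sizes used in the checks

The package's statistical guarantees are verified at these scales, chosen
to characterize the estimators well at desk scale: parameter recovery
over 200 simulated subjects (216 trials each); likelihood-ratio type-I
calibration over 1000 null simulations; bootstrap coverage over 500
chance observers (200 trials, 1000 resamples); decoder chance calibration
over 8 synthetic subjects at the default grid; FWE calibration over
repeated small-grid experiments; the group premium power check over 20
replicate cohorts of 13 subjects.

# Known limitations

* The pooled group-level premium test is a fixed-effects approximation of
  a mixed-effects model; between-subject variance in $a$ inflates its LR
  statistic relative to a random-effects treatment.
* $\hat a$ is right-skewed at the study's trial counts when a subject's
  primed choices are nearly uninformative; the ridge tie-break and the
  spec'd box bounds limit, but do not remove, this skew.
* The univariate/multivariate dissociation planted in the generator is an
  idealisation; in real data, strong per-voxel activation differences
  make patterns trivially decodable, which is why a univariate companion
  check accompanies any within-condition decoding claim.
* Calibrated amounts at very short delays cluster within a dollar of
  \$20.10, so those trials carry little information about $k$; this
  matches the printed envelope and is intentional.
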