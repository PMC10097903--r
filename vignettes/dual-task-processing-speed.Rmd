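---
title: "Simulating and scoring dual-task street-crossing assessments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring dual-task street-crossing assessments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualspeed)
```

## The assessment and its computational model

Cognitive processing speed — how quickly a person can carry out elementary
cognitive operations — is commonly measured with clinician-administered
paper-and-pencil instruments scored on a 0–19 scale. A more ecological
alternative embeds the measurement in an everyday activity performed under
attentional load: the participant crosses a simulated two-lane street while
concurrently answering audio-visual Stroop match/mismatch stimuli. Because
the two tasks compete for a shared, limited attentional capacity, the
behavioral record of the crossing task (how often and how safely the walker
crosses, how they scan the street, how their trajectory and velocity evolve)
and the performance record of the Stroop task (accuracy and response time)
together carry information about the participant's processing speed.

`dualspeed` implements the full computational side of such an assessment:

1. a **session simulator** that generates the raw behavioral record of a
   participant with a known latent trait;
2. **feature extraction** producing the 68 session features used for scoring;
3. **correlation screening** of features against the clinical score;
4. a **score-estimation stack** (LASSO, SVR, XGBoost) evaluated by
   leave-one-subject-out cross-validation (LOSO-CV) with per-fold recursive
   feature elimination (RFE), plus Bland–Altman agreement and paired
   feature-set comparisons.

## Task geometry and schedule

The street is a 6 m two-lane roadway with a 0.5 m safe margin on each side.
Vehicles travel at 30 km/h and the avatar walks at a fixed 1.5 m/s, the
normal human walking speed. A crossing is *safe* when strictly more than
1.5 s elapse between the walker leaving the roadway and the next vehicle
arriving at the crossing point. Each of the three dual-task blocks presents
72 Stroop stimuli for 2 s each, so a block lasts exactly 144 s; the blocks
use the color-matching, word-matching and interference-matching conditions
in turn.

The traffic model treats the roadway as a single conflict zone with one
inter-vehicle gap stream (a *whole-roadway* model). A gap admits a safe
crossing iff it exceeds

$$g^\* = \frac{\text{width}}{v_\text{walk}} + \text{margin}
       = \frac{6}{1.5} + 1.5 = 5.5\ \text{s},$$

and the gap generator is calibrated so that 50% of gaps are crossable: gaps
are drawn from a two-component mixture, sub-threshold
$\mathrm{Unif}(1.5, g^\*)$ versus supra-threshold $g^\* + \mathrm{Exp}(2.5)$,
with mixing weight equal to the designed crossable fraction. Each component
lies strictly on its side of $g^\*$, so the crossable proportion is exact in
expectation. The mixture family itself is a design choice of the package —
only the 50% constraint and the kinematic threshold are fixed by the
assessment design. A per-lane traffic model with signed directions is out of
scope.

## The generative behavior model

Every simulated channel is driven by a latent trait $z$, the standardized
0–19 score of the participant (scores are drawn
$\mathcal{N}(13, 3^2)$, rounded and clipped to $[1, 19]$ — a plausible
healthy-adult distribution; the lower clip keeps the relative-accuracy
metric defined). The channel models, with their defaults:

* **Stroop responses.** Response time per stimulus is
  $\mathcal{N}(\mu_c - 0.12\,z + s, 0.30^2)$ seconds, where $\mu_c$ is 0.85
  (color), 0.90 (word) or 1.10 (interference) — the interference penalty is
  the Stroop effect — and $s \sim \mathcal{N}(0, 0.08^2)$ is a per-session
  jitter representing non-trait individual variability. Draws are floored at
  a 0.2 s motor floor; draws beyond the 2 s stimulus window become timeouts,
  which count as incorrect and carry no response time. Correctness is
  Bernoulli with logit $a_c + 0.8\,z$, $a_c \in \{2.2, 2.0, 1.4\}$.
* **Gap decisions.** While waiting, the walker evaluates each gap onset
  unless an attentional miss occurs, with miss probability
  $\mathrm{logit}^{-1}(-1 - 0.6\,z)$ — under dual-task load, lower-trait
  participants let more gaps pass unexamined. An evaluated gap of duration
  $g$ is accepted with probability
  $\mathrm{logit}^{-1}\!\big(1.5\,e^{0.4 z}(g + \varepsilon - g^\* - 0.25)\big)$,
  $\varepsilon \sim \mathcal{N}(0, 0.5^2)$ s of perceptual noise: higher
  trait sharpens the discrimination between crossable and uncrossable gaps.
* **Crossing execution.** On acceptance the walker starts after a reaction
  delay $\max(0.15, \mathcal{N}(0.7 - 0.15\,z, 0.15^2))$ s, enters the
  roadway, traverses it and the far margin at 1.5 m/s, and resets instantly
  to the start point. The walker waits at the near roadway edge, so roadway
  occupancy starts after the reaction delay and the realized outcome rule is
  exactly the threshold rule above shifted by the delay.
* **Head scanning.** While waiting, yaw oscillates sinusoidally at
  $0.45 + 0.12\,z$ Hz with amplitude $\mathcal{N}(55, 8^2)$ degrees (clipped
  to at least 35° so scans cross the 30° head-turn threshold), plus 3° of
  sensor noise; during crossing the head faces the destination with small
  fluctuations. Pitch is $\mathcal{N}(-5, 3^2)$ degrees throughout.
* **Trajectory.** Lateral position follows a mean-reverting wobble process
  with 0.03 m stationary SD (time constant 2 s), calmer while waiting;
  forward velocity is the commanded walking speed plus 0.03 m/s noise. Both
  kinematic channels and head orientation are sampled at 50 Hz, a typical
  head-mounted-display frame rate.

The coefficients are design constants, not measurements. Their single
contract is qualitative: cohorts generated under the defaults must reproduce
the empirically observed correlation signs — response time negative,
Stroop accuracy, safe crossings, head turns and mean forward velocity
positive — which the test suite checks on a 500-participant fixed-seed
cohort. Two mechanisms deserve comment because the fixed walking speed would
otherwise make their features degenerate: mean forward velocity over a block
equals total distance walked divided by 144 s, so its trait dependence comes
from the attentional gap-miss mechanism (higher-trait participants attempt
more crossings), and crossing-time variation comes from the trait-dependent
reaction delay.

Each random channel draws from its own sub-stream derived from the session
seed, so one channel reproduces bit-for-bit even when another channel's
model changes.

## Feature extraction

Seventeen quantities are computed per block and averaged over the three
blocks, giving $17 \times 4 = 68$ features:

| Group | Features |
|---|---|
| Stroop performance | CNST (correct answers), RTST (mean response time) |
| Crossing counts/times | NSC, NUC, NA (= NSC + NUC), TSC, TSC_MAX, TSC_MIN, TTC |
| Trajectory/velocity | SDX, ETPX, MVX, MVY, SDVX, SDVY |
| Head behavior | FN (attention dispersion), HT (head turns) |

Conventions the package adopts where the definitions leave latitude:

* **TSC** is defined per attempt (start point to destination marker); the
  block-level feature is its mean over completed attempts, with the recorded
  extremes as TSC_MAX/TSC_MIN. Attempts truncated by the block clock are
  excluded from all counts and times.
* **TTC** is averaged over safe attempts only; unsafe attempts have TTC at
  or below the margin by definition and would conflate the classes.
* **RTST** excludes timeouts (they carry no response time); CNST counts them
  as incorrect.
* **ETPX** is the base-2 Shannon entropy of the lateral positions counted
  into fixed 0.1 m bins (edges at multiples of the bin width); the binning
  estimator for $P(x_i)$ is a package choice.
* **Head turns** are counted as excursions of $|yaw|$ beyond 30° with
  hysteresis — the yaw must return below the threshold before the next
  excursion counts — over pre-crossing (waiting) intervals only, summed per
  block.
* **FN** is the printed sum of squared attention-matrix entries
  $\sum_{ij} |a_{ij}|^2$ (no square root); a true Frobenius norm is exposed
  via `compute_fn(A, frobenius = TRUE)` but is off by default. The
  180×360 matrix is populated from head direction at 1° resolution, one
  count per pre-crossing frame.
* **Trajectory and velocity features** are computed over the whole block
  (waiting plus crossing). Restricting to crossing intervals would make MVY
  nearly constant at the fixed walking speed; block-level features capture
  initiation and waiting behavior, which is where the discriminative signal
  lies.
* **Missing slots** (no safe crossing in a block, all stimuli timed out) are
  `NA` in the raw vector and are imputed with the cohort median of the slot
  at table level, with the imputation count recorded in an attribute.

## Screening and score estimation

Features are screened by Pearson correlation with the true score; a feature
passes at $|r| > 0.3$ and $p < 0.05$, both strict, with the p-value from the
t-transform on $n-2$ degrees of freedom. No multiple-testing correction is
applied by default (a Benjamini–Hochberg option exists). The package ships a
published 68-row reference screening table
(`reference_screening()`); screening it flags exactly 28 features. Masked
p-values in that table are recomputed from $r$ with $n = 50$; where the
source prints numeric p-values the recomputation agrees with them.

Score estimation uses three regressors: LASSO (penalty chosen by inner
cross-validation on the training fold), radial-kernel SVR (cost grid
0.1–100, inner CV; the kernel is a package choice), and XGBoost (small
fixed-seed configuration, `max_depth` 3, `eta` 0.1, 150 rounds). Evaluation
is LOSO-CV: one fold per participant, with feature standardization,
hyperparameter selection and (in RFE mode) feature elimination all re-run
strictly inside each training fold — a dedicated test asserts the fold
preprocessing statistics are computed from the training rows only. Inner CV
uses 5 folds, reduced so that each inner fold keeps at least 3 observations;
below that the LASSO falls back to the least-penalized path point. RFE
eliminates the single lowest-weight feature per step (absolute standardized
coefficients for linear kinds, gain importance for trees; ties broken by
stable column order) down to 10 survivors; for LASSO the penalty is chosen
once per RFE call and held fixed during elimination.

Reported metrics are MAE, relative accuracy
$\mathrm{ACC} = 1 - \tfrac1n \sum |y_i - \hat y_i| / y_i$ and the Pearson
correlation CC between predicted and true scores, plus Bland–Altman bias and
$\pm 1.96\,\mathrm{SD}$ limits of agreement. ACC and CC are implemented
exactly as printed in the assessment literature; note their true ranges are
$(-\infty, 1]$ and $[-1, 1]$ respectively, not $[0, 1]$. Selection
frequencies across LOSO folds rank the stability of RFE-selected features;
paired t-tests compare per-subject absolute errors between feature sets
(Stroop-only vs behavior-only vs combined).

## What the synthetic cohorts do and do not show

The simulator is a generative stand-in for human sessions: it reproduces the
geometry, schedule, outcome rules and the qualitative correlation structure,
and it provides ground truth for end-to-end testing (on a 200-participant
cohort, LOSO LASSO recovers the true score with CC well above 0.7 and MAE
far below the predict-the-mean baseline, and combined features beat either
single feature family, mirroring the motivation for the dual-task design).
It does **not** reproduce the effect sizes, feature distributions or
inter-feature dependence of real participants — its channels are
conditionally independent given the trait, whereas real behavior shares
motor and strategic structure; its Stroop signal is deliberately strong. A
passing test suite therefore validates the pipeline's correctness and the
design constants, not clinical performance. Published real-data headline
numbers (e.g. MAE ≈ 0.8 on the 0–19 scale from a 50-participant study) stem
from an undeposited dataset and are treated as non-reproducible references,
not test targets.

Problem sizes used by the test suite — a 500-participant cohort for the
correlation-sign checks, 200 for parameter recovery, 50 for the LOSO/RFE
structure, 10,000 draws for the gap-design check — were chosen so that the
checked properties are statistically stable while a full run stays
comfortably in the minutes range.

## Worked example

```{r example, eval = FALSE}
library(dualspeed)

tbl <- simulate_cohort_features(50, seed = 1)

ct <- build_correlation_table(tbl)
screen_features(ct)$count

ev <- loso_evaluate(tbl, model_spec("lasso", seed = 1), mode = "rfe")
ev
head(selection_frequency(ev$fold_features))
```

The same analysis runs end-to-end on disk via `cmd_simulate()`,
`cmd_extract()` and `cmd_analyze()` with a single `pipeline_config()`.

## Known limitations

* The avatar cannot stop mid-roadway; attempts are committed once started.
  Hesitation is represented only through the pre-crossing reaction delay.
* One gap stream serves the whole roadway; per-lane vehicle mechanics and
  signed directions are not modeled.
* The attention matrix is populated from head direction, not gaze; without
  eye tracking the two are conflated.
* Imputation of undefined slots uses the unconditional cohort median, which
  slightly attenuates correlations for sparse-crossing cohorts.
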