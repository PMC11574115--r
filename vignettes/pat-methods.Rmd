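---
title: "Methods: consistency scoring and classification for the Phase Adjustment Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consistency scoring and classification for the Phase Adjustment Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patkit)
```

## The measurement problem

Cardiac interoceptive accuracy — how well a person perceives their own
heartbeat — is hard to measure without contamination from guessing
strategies. The Phase Adjustment Task (PAT) addresses this by presenting
tones triggered by the participant's actual heartbeats but shifted by a
random starting delay, and asking the participant to turn a dial until the
tones feel synchronous with the heart. Whether a participant's chosen
synchrony point sits early or late in the cardiac cycle is irrelevant (and
varies between people); what carries signal is whether the chosen *phase*
is consistent across trials. `patkit` implements the analysis chain from
raw session records to participant classification and group comparison,
plus a simulator that generates sessions with known ground truth.

## Phase angles and the consistency score

A selected tone delay $d$ (ms) on a trial with reference cardiac cycle
length $T$ (ms) corresponds to the phase angle

$$\theta = 2\pi \, \frac{d \bmod T}{T} \in [0, 2\pi).$$

The reference $T$ is the mean RR interval recorded *during that trial*,
not the resting baseline: the phase of a delayed tone is defined relative
to the concurrent cardiac rhythm, which drifts over a session. Delays
longer than one cycle wrap around.

Cross-trial agreement of the angles $\theta_1,\dots,\theta_n$ is
summarised by the mean resultant length

$$R = \left\lVert \frac{1}{n}\sum_{j=1}^n e^{i\theta_j} \right\rVert
  \in [0, 1],$$

which is 1 when all angles coincide and tends to 0 as they disperse
uniformly. $R$ is invariant to rotation (adding a constant to all angles)
and to trial order — exactly the properties the task's logic requires. Note
that for finitely many *random* angles $R$ is not 0 on average: for $n$
uniform phases $E[R] \approx \sqrt{\pi/(4n)}$, which at the $n = 17$
scored trials is $\approx 0.215$. This "uniform null" is the floor against
which interoceptive performance is judged, and the package's tests verify
the simulator reproduces it. The sample $R$ is also upward-biased for
concentrated data: for a population resultant $\rho$,
$E[R^2] = \rho^2 + (1-\rho^2)/n$, a bias the calibration tests account
for explicitly.

Every scored participant contributes exactly 17 trials (see below), so
scores are comparable across participants without small-sample corrections.

## Quality control

Raw sessions are nested JSON records (one file per participant × task).
The cascade, each threshold a named argument with its conventional default:

1. **Practice removal** — trials flagged `is_practice` are dropped; if no
   flags are present the first 2 trials are dropped positionally (logged
   via a message).
2. **Trial validity** — trials with ≤ 4 heart-rate values are removed
   (lack of engagement with the recording), as are trials whose dial was
   never moved. "Never moved" means an empty delay trajectory; a
   single-entry trajectory equal to a recorded default dial position also
   counts, since it is indistinguishable from an untouched dial.
3. **Participant inclusion** — participants with < 17 valid trials are
   excluded (exclusion is a reported value, not an error); the remainder
   are truncated to their *first 17 valid trials in task order*, so the
   truncation happens after filtering.
4. **Screener gate** — in the screened analysis arm, participants whose
   screener-task consistency is strictly below 0.42 are excluded. The
   screener is an easier, exteroceptive variant (two audible tones to
   align), so a low score there indicates non-adherence rather than poor
   interoception; 0.42 is the point at which the probability of belonging
   to the non-interoceptive component is approximately zero under the
   reference mixture.

Engagement metrics (mean trial duration, mean number of unique dial
positions, number of valid trials) are computed over the 17 retained
trials. All counts reconcile: trials in = practice + invalid + valid.

## Mixture classification

Consistency scores pooled across *both* groups (laboratory + remote) are
modelled as a two-component Gaussian mixture — a non-interoceptive
component near the uniform null and an interoceptive component at higher
consistency — fitted by expectation-maximisation:

- **Initialisation** is deterministic: scores are split at the median and
  each half supplies its component's starting mean and SD, with weights
  ½/½. No random restarts, so a given score vector always yields the same
  fit.
- **Convergence**: |Δ log-likelihood| < 1e-8, at most 1000 iterations; the
  log-likelihood trace is retained and is non-decreasing at every step
  (asserted in the tests, and cross-checked against an independent mixture
  fitter).
- **Numerical floors**: component SDs are floored at 1e-4 to prevent
  variance collapse on small or degenerate samples; a fit ending at the
  floor, or with a component weight below 0.01, is *flagged* degenerate
  rather than silently returned, and membership computation refuses it.
- **Labelling convention**: the lower-mean component is always
  "non-interoceptive".

For a score $x$, z-scores $z_k = (x - \mu_k)/\sigma_k$ are formed against
each component, and membership probabilities are the posterior
responsibilities $p_k \propto w_k\,\phi(z_k)/\sigma_k$ (normalised). The
weighting by $w_k$ is the EM-consistent choice; an unweighted
density-ratio variant is available via `weighted = FALSE` for comparison
with procedures that standardise without weighting. The Bayes factor is
$\mathrm{BF} = p_I/p_N$, computed in log space with the log-BF clamped at
±700 so that extreme scores give finite, strictly positive Bayes factors
rather than floating-point under/overflow.

Classification at threshold $T \in \{3, 10, 30\}$ (moderate / strong /
very strong evidence) uses strict inequalities: BF > T ⇒ interoceptive,
BF < 1/T ⇒ non-interoceptive, otherwise unclassified — a BF exactly at a
threshold is unclassified. Strictness gives two structural guarantees the
tests exercise: label symmetry under BF ↔ 1/BF, and unclassified counts
that never decrease as the threshold rises.

## Heart rate and HRV

From the 2-minute baseline beat timestamps (trial-period beats are never
used), RR intervals are the successive differences, and:

- SDNN: sample SD of RR (n − 1 denominator), ms;
- RMSSD: root mean square of successive RR differences, ms;
- pNN50: percentage of successive differences strictly exceeding 50 ms;
- resting heart rate: 60000 / mean(RR), bpm.

No artefact or ectopic-beat correction is applied; RR intervals outside
[300, 2000] ms raise a warning but are retained, keeping the metrics a
faithful function of the recorded beats.

## Group comparisons

- **Consistency**: pooled-variance (Student's) two-sample t-test, so
  df = n₁ + n₂ − 2; Welch's version is available by flag. The test choice
  is explicit configuration, not an automated normality decision.
- **Engagement, HRV, age**: Mann–Whitney U, reported as U and a
  standardised Z using the tie-corrected variance without continuity
  correction (the convention of mainstream statistical software), with a
  two-sided normal p. Exact enumeration is used in the test suite as the
  oracle at tiny n, not at analysis scale.
- **Classification counts and sex**: plain Pearson chi-square without
  Yates correction; expected counts below 5 warn. In the pipeline's
  classification chi-square, a label column empty in *both* groups is
  dropped before testing (a zero marginal makes X² undefined); the counts
  tables themselves always report all three labels.
- **Age matching**: remote participants aged ≥ 30 are removed, laboratory
  participants aged < 19 are removed, and laboratory ages ≥ 63 are removed
  as outliers. The operation is idempotent.
- **Physiology control**: consistency is regressed on resting heart rate
  and RMSSD by OLS (pooled across groups, with intercept — a single
  pooled regression, so group differences are not absorbed into separate
  intercepts), and the residuals are compared with the pooled t-test.
  Near-collinear covariates (condition number > 1e8) are refused. Note
  that when consistency is an exact linear function of the covariates the
  *residuals* vanish; the t statistic on machine-epsilon residuals is
  scale-invariant noise, which is why the package's tests pin the
  residuals, not t, to zero in that degenerate case.

Consistency-score outliers are retained by default (a sensitivity rerun
without them is a one-line filter on the cohort table).

## The simulator

`simulate_cohort()` generates what the analysis consumes — screener and
PAT sessions per participant plus a ground-truth table — under an explicit
generative model:

- **Beats**: RR intervals are truncated-normal (default mean 800 ms, SD
  50 ms, floor 300 ms), accumulated into timestamps over a 120 s baseline.
  An AR(1) or respiratory-modulated series would be more physiological;
  the truncated normal is deliberate, since the pipeline only requires
  plausible RR variability for the time-domain metrics.
- **Responses**: each interoceptive participant has a preferred phase μ
  (uniform per participant unless fixed) and concentration κ drawn from
  `kappa_range`; response phases are von Mises(μ, κ) via the Best–Fisher
  sampler. Non-interoceptive participants respond uniformly (κ = 0). The
  response-generation process of a real human is of course unknown; the
  von Mises model is this package's assumption, stated as such.
- **Default κ range (1, 4)**: population resultants 0.45–0.86, which after
  17-trial sampling noise produces the overlap between components — and
  hence a band of unclassified participants — seen in human cohorts,
  rather than an unrealistically clean separation.
- **Adherence and the screener**: a fraction `p_nonadherent` (default
  0.05) of participants do not engage and respond uniformly on *both*
  tasks. Adherent participants respond on the screener with concentration
  `screener_kappa` (default 8) *regardless of interoceptive status*,
  because the screener is an exteroceptive tone-matching task. This is
  what makes the screener gate meaningful in simulation: it catches
  non-adherence, not non-interoception. Without this distinction the gate
  would remove exactly the non-interoceptive participants and the screened
  mixture would be degenerate by construction.
- **Task structure**: 2 practice + 20 task trials; trial durations
  log-normal around 20 s; dial trajectories are random walks over delay
  values ending at the selected delay, with ~Poisson(27) positions,
  matching the magnitude of observed engagement metrics; confidence (0–9)
  is drawn independently of accuracy, since it is stored but not analysed.
- **Invalid trials**: with probability `p_invalid_trial` (default 0.05) a
  task trial is injected as invalid — either ≤ 4 heart-rate samples or an
  untouched dial — and *labelled* in the record, so QC precision/recall is
  testable exactly (and is exactly 1 by construction).
- **Ages**: laboratory 18 + Poisson(5), remote 18 + Poisson(13) —
  reproducing the young-laboratory/older-remote imbalance that makes age
  matching a non-trivial step.
- **Determinism**: one integer seed in the config; identical configs give
  byte-identical serialized cohorts.

What the simulator does *not* emulate: PPG waveforms and beat-detection
error, within-session learning or fatigue trends, confidence–accuracy
coupling, and any dependence of interoception on age, sex or physiology.
Passing tests on simulated cohorts therefore validate the pipeline's
*logic and statistics*, not claims about real physiological data.

## Problem sizes used in validation

The packaged tests and the acceptance script run at deliberately modest
scale, chosen to make the Monte-Carlo calibrations stable while keeping a
full run fast: cohorts of 20–200 simulated participants, 2000 replicates
for the uniform-null and von Mises calibrations, 10–20 seeds × 500 scores
for mixture recovery, and 100–1000 random draws for the oracle
equivalences. At these sizes the standard errors of every calibrated
quantity are an order of magnitude below the tolerances being asserted.

## Known limitations

- The consistency statistic is the mean resultant length; if the original
  task's angular-similarity formula differs by a monotone transform,
  absolute score values (though not their ordering) would differ.
- The EM fit, like any, can in principle find a local optimum; the
  deterministic median-split initialisation has proven robust on the
  score distributions this task produces and is cross-checked against an
  independent fitter in the tests, but restart counts are configurable
  territory for unusual data.
- The Mann–Whitney p is a large-sample normal approximation; at very
  small group sizes an exact test would be preferable.
- Sessions with more than 20 task trials (possible through app restarts)
  are parsed and truncated like any others, not specially flagged.
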