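# patkit

Analysis toolkit for the **Phase Adjustment Task (PAT)**, a smartphone-based
measure of cardiac interoceptive accuracy. In the PAT, tones are triggered
by the participant's heartbeats (detected by photoplethysmography) but
presented out of phase with them; the participant turns a virtual dial to
shift the tones in time until they feel synchronous. Because the starting
phase is random on every trial, a participant who truly perceives their
heartbeat selects delays that map to *consistent* phase angles across
trials, while a participant who cannot perceive it selects effectively
random phases. `patkit` implements the full analysis pipeline for such
data, for researchers comparing testing conditions (e.g. supervised
laboratory vs unsupervised remote cohorts) or classifying participants as
interoceptive vs non-interoceptive.

## What it computes

Given nested per-participant session records (JSON: a 2-minute baseline
beat series plus per-trial heart-rate samples, dial trajectories, selected
delays, durations, confidence):

1. **Quality control** — practice-trial removal, the trial filters
   (≤ 4 heart-rate values; untouched dial), the < 17-valid-trials exclusion,
   truncation to each participant's first 17 valid trials, engagement
   metrics, and the screener gate (score < 0.42 ⇒ excluded).
2. **Consistency scoring** — each trial's selected delay *d* with reference
   RR interval *T* maps to a phase angle θ = 2π·((d mod T)/T); the
   session's consistency score is the mean resultant length
   R = ‖n⁻¹ Σ e^{iθ_j}‖ ∈ [0, 1] of its 17 phase angles.
3. **Classification** — a two-component Gaussian mixture fitted to the
   pooled consistency scores by expectation-maximisation; per-participant
   z-scores and membership probabilities against each component; Bayes
   factors BF = p_I/p_N thresholded at 3 / 10 / 30 (strict) to label
   participants interoceptive, non-interoceptive, or unclassified.
4. **Physiology** — time-domain HRV (SDNN, RMSSD, pNN50) and resting heart
   rate from the baseline RR series.
5. **Group comparison** — age matching, pooled-variance t-tests on
   consistency, Mann–Whitney U (tie-corrected normal Z) on engagement and
   HRV, chi-square on classification counts and sex, and the control
   analysis regressing heart rate and RMSSD out of consistency.
6. **Simulation** — a session generator with known ground truth
   (interoceptive status, von Mises concentration κ, preferred phase,
   injected invalid trials), so every stage above is testable without
   human data.

## Worked example

```r
library(patkit)

cfg <- simulation_config(n_participants = 120, seed = 2026)
res <- run_pipeline(cfg, arm = "screened")

res$gmm
#> <pat_gmm> N: w=0.564 mu=0.201 sd=0.092 | I: w=0.436 mu=0.763 sd=0.125 | loglik=18.258 (21 iter)
```

The pooled mixture separates a non-interoceptive component centred near
the uniform-phase expectation for 17 trials (≈ 0.215) from an
interoceptive component at high consistency. The manifest accounts for
every exclusion:

```r
res$manifest$counts[c("n_sessions_in", "n_valid_pat", "n_cohort", "n_age_matched")]
#> $n_sessions_in   240   (120 participants x screener + PAT)
#> $n_valid_pat     119   (sessions passing QC with >= 17 valid trials)
#> $n_cohort        109   (valid on both tasks and screener score >= 0.42)
#> $n_age_matched    79
```

The age-matched laboratory-vs-remote comparison of consistency scores:

```r
subset(res$comparisons, sample == "age_matched" & measure == "consistency")
#>       measure statistic df p_value mean_x mean_y
#>   consistency     0.503 77   0.616  0.436    0.4
```

Both simulated groups are drawn from the same generative model, so the
pooled t-test is (correctly) non-significant: mean consistency 0.44
(laboratory) vs 0.40 (remote), t(77) = 0.50, p = 0.62. Classification
counts at the moderate-evidence threshold (BF > 3):

```r
subset(res$tables, sample == "unmatched" & threshold == 3)
#>      sample threshold      group non_interoceptive unclassified interoceptive  n
#>   unmatched         3 laboratory                30            1            22 53
#>   unmatched         3     remote                30            1            25 56
```

## Vignette

`vignettes/pat-methods.Rmd` documents the statistical model, the
generative assumptions of the simulator, every tunable threshold, and the
numerical choices (EM initialisation and floors, Bayes-factor clamping,
tie handling).
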