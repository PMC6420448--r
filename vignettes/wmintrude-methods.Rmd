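---
title: "Simulating and detecting episodic-context intrusions on working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting episodic-context intrusions on working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Words studied together with a shared picture context become episodically
bound to that context and to each other. When a few of those words must later
be held in working memory over a delay, spontaneous reinstatement of their
encoding context can re-activate other words from the same context. Such
intrusions rarely produce outright errors, but they leave two measurable
signatures: substitution errors during distracted free recall are biased
toward same-context and recent words, and "mismatch" decisions about lure
probes (same-context non-targets) are slowed. With fMRI, per-trial decoding
of context-selective activity during the retention delay predicts that
slowing.

`wmintrude` implements this analysis chain end to end and, because the real
behavioural data are not redistributable, ships a synthetic-data generator
whose latent structure is exactly the structure the analyses are designed to
detect.

## Experiment designs

`build_design()` partitions a vocabulary into context sets. The two canonical
layouts are six scene contexts of 12 words (free-recall experiment) and four
lateralized contexts — face/scene crossed with left/right — of 12 words
(scanned DNMS experiment). `generate_learning_schedule()` emits 4-word
learning trials, all words of a trial from one set, with every word presented
exactly three times. We note one arithmetic inconsistency in the source
design description: six sets of 12 words at three presentations in groups of
four imply 54 learning trials, while the described session reports 48; the
generator enforces the exact-repetition constraint (54 trials), because the
per-word repetition count is what the overlap statistic and the context-
binding manipulation depend on.

`generate_dnms_trials()` builds delayed-nonmatch-to-sample trials with equal
numbers of target, lure and other-context probes. The `overlap` of a trial
counts (learning-trial, target-word) co-presentations between the probe and
the current targets — with three repetitions of 4-word trials it ranges 0-9.
Pair-level counting is the only reading consistent with the reported 0-7
range of the statistic (trial-level counting is bounded by 3). Under uniform
companion sampling the generator's lure-trial overlap mean is about 3.3
(checked by the test suite across 40 designs); the empirical mean reported
for the original schedule (3.62) is not treated as a contract since that
schedule's exact constraints are unknown.

`generate_recall_trials()` intermixes the three delay conditions (18 trials
each by default) under the constraint that consecutive trials never share a
context, which is what makes previous-trial and same-context substitutions
mutually exclusive categories.

## The behavioural generator

All tunables live in `generative_params()`. The latent object shared by every
simulator is the **reinstatement trace**: per trial, period (target
presentation, delay, probe presentation) and context, an intensity in [0,1].
The target-set context receives `baseline + boost` (delay boost scaled by the
subject's `memory_strength`), all others `baseline`, plus Gaussian noise
(SD 0.08), truncated to [0,1]. Defaults: baseline 0.2, boost 0.25.

Reaction times are linear in the trace:

RT = mu + b_subject + beta_probe_type
   + gamma_probe * e(probe context, delay) * 1[mismatch trial]
   - gamma_nonprobe * mean e(non-probe contexts, delay) + eps,

with `mu` = 1000 ms, subject intercept SD 100 ms, residual SD 150 ms,
`gamma_probe` = 35 ms per evidence unit, `gamma_nonprobe` = 20 ms per unit.
Responses slower than 4 s become timeouts (no response, no RT); errors are
injected at rate 1 − accuracy (default accuracy 0.95). Noise is additive
Gaussian on the millisecond scale so that the mixed-model coefficients are
in milliseconds, matching the magnitude of the reported effects; the
z-scoring pipeline still log-transforms.

The probe-type offsets (−12.5, +9.25, −5.8 ms for target/lure/other) were
derived analytically so that the cohort-level mean zRTs approximate the
reported condition means (+0.14 lure, −0.11 target, −0.03 other): a
millisecond offset Δ maps to a zRT offset of roughly Δ / s, where
s ≈ 150 ms is the within-subject RT SD, after accounting for the
gamma-coupling contributions of each condition (the target-set context is
elevated on lure trials; the non-probe average includes the elevated target
context on other-context trials). The packaged checks verify that a default
80-subject cohort lands within ±0.05 of the three printed means, and the
acceptance script recomputes the cohort means from scratch.

Free recall replaces each target word independently with a substitution
error at a per-condition rate (defaults 0.015 / 0.07 / 0.14 for
none/break/full distraction, giving per-subject error totals of roughly
1 / 5 / 10 across 18 trials per condition). The substituted word is drawn
from a mixture over the three candidate pools — previous-trial targets (4
words), same-context non-targets (8), all other learned words (56) — with
default weights (0.45, 0.30, 0.25); on the first trial the previous-target
mass is reassigned proportionally. `null_params()` zeroes every planted
effect, equalizes the condition error rates, and sets the mixture to the
chance proportions (4/68, 8/68, 56/68).

The posttask context-memory test marks each word correct with probability
`pi_mem + (1 − pi_mem)/4`; the default `pi_mem` = 0.216 puts group accuracy
near the 41% observed in scanned cohorts. A subject's effective `pi_mem` is
scaled by the same `memory_strength` that gates the delay-period boost, so
poor context learners neither show delay reinstatement nor score well on the
memory test — the coupling that the memory-split analysis and Model 1 are
designed to expose.

## The BOLD generator and decoder

Synthetic voxels are abstract features: each of the eight localizer stimulus
kinds (face/scene/object/scrambled crossed with side) has a unit-norm pattern
equal to a shared component plus `selectivity` times a class-specific random
component. A localizer run is 24 miniblocks (8 kinds x 3) of 20 s separated
by 12-s interblock intervals; a DNMS run presents targets for 2 s, an 18-s
delay, and a 4-s probe period per trial, with every context's pattern
entering the neural signal in proportion to its trace intensity. Neural time
courses are convolved with a double-gamma haemodynamic kernel peaking at 5 s
(unit sum, so sustained activity plateaus at its amplitude — this keeps
decoded evidence on the scale of the latent trace) and corrupted by AR(1)
(rho 0.3) plus white Gaussian noise.

The default noise level (innovation SDs 0.18) was chosen so that default
localizer decoding sits near the cross-validated accuracy of about 67%
reported for real data, against a 25% chance level; the test suite checks
that default decoding stays within a 0.50-0.85 band. "Low-noise" recovery
studies use SDs of 0.005.

The decoder is four independent L2-regularized binary logistic units (one
per lateralized face/scene class, each against the other labeled TRs),
fitted by penalized Newton iterations on features standardized with
training-set statistics; the intercept is unpenalized and the default ridge
penalty is 1.0 on standardized features. Because the units are independent,
the four probability outputs do not sum to one, so simultaneous evidence for
several contexts is representable. Localizer TRs are labeled by shifting
each miniblock window 5 s forward (matching the kernel peak), and
cross-validation splits the labeled TRs into four temporally contiguous
folds of whole blocks. Object and scrambled-scene blocks are never used for
training.

Trial-period evidence averages the per-TR unit outputs over the shifted
window [onset + 5 s, onset + 11 s) of each period. The raw target and delay
windows overlap (the target period is only 2 s long); contested TRs belong
to the earlier period, and each later window then drops one leading TR as a
guard against signal bleed. With 1-s TRs this leaves 6 target TRs, 1 delay
TR and 5 probe TRs per trial; the rule is parameterized
(`shift_seconds`, `window_seconds`, `gap_trs`) because the source
description of the "1 TR offset" is ambiguous.

## Mixed models

`fit_random_intercept_lm()` fits Gaussian linear models with a per-subject
random intercept by REML (via lme4), reporting Wald 95% intervals. p-values
use a normal approximation to the Wald statistic by default, with a
Satterthwaite option (via lmerTest). Models 1-3 are thin wrappers:

* **Model 1**: `rt ~ target_memory_score * probe_type + (1 | subject)`,
  treatment coding with the other-context probe as reference; the memory
  score is the raw 0-4 count of target words whose context was later
  identified correctly. A trial is "learned" for the median-split analysis
  when more than half of its targets (3 or 4 of 4) were correctly assigned.
* **Model 2**: `rt ~ evidence(target presentation) + evidence(delay) +
  evidence(probe) + (1 | subject)`, per probe type; a non-probe variant
  substitutes the mean non-probe-context evidence and exposes the speeding
  effect of non-misleading reinstatement.
* **Model 3**: `rt ~ evidence(delay) * overlap + (1 | subject)` on lure
  trials, with overlap entered uncentered so the main effects are
  interpretable at zero overlap.

Inaccurate and timeout trials are excluded from all three models.

## Numerical and design choices

* Exclusions: subjects strictly below 2/3 accuracy (the accuracy of a
  constant-"mismatch" responder) are dropped; timeouts are dropped from all
  RT analyses; inaccurate trials are kept for accuracy summaries only.
* zRT: natural log, within-subject standardization with the n−1 SD over
  included trials; subjects with fewer than two included trials or zero
  variance are flagged and excluded from contrasts.
* The bootstrap chance analysis resamples each subject's observed error
  count as uniform draws over the 68 candidate non-target words, B = 10,000
  by default, with the add-one convention p = (1 + #{null ≥ obs}) / (B + 1),
  one-sided for over-representation. Resampling is per subject and then
  group-averaged.
* The learning-schedule sampler uses rejection with a deterministic
  swap-repair fallback, so the exact-repetition quota always holds.
* A single global seed expands into per-module, per-subject streams via
  `module_seed()`; the stride between consecutive global seeds exceeds any
  per-run counter range, so different seeds never share a stream.

## What the synthetic data do and do not show

The generator reproduces the statistical structure the analyses assume:
context-biased substitution pools, log-normal-ish within-subject RTs with a
4-s deadline, a latent reinstatement trace shared verbatim between the RT
and BOLD simulators, and a memory-strength gate common to reinstatement and
the posttask test. It does not emulate semantic similarity between words,
serial-position effects, fatigue or practice drifts, head motion,
physiological noise, or spatial structure in voxels (patterns are abstract
features; the real-data path flattens any masked geometry). Passing tests
therefore certify the pipeline's correctness and calibration under the
assumed structure, not conclusions about new empirical data.

One property deserves emphasis: the decoder's one-vs-rest evidence for the
probe context is an attenuated and contaminated proxy of the latent trace —
its units anti-load on the other contexts' patterns, and the single delay
TR carries substantial measurement noise. Trial-wise regressions of RT on
decoded evidence therefore recover planted couplings with wide confidence
intervals and attenuated point estimates, which is why parameter-recovery
checks are stated as CI coverage rather than point equality, and why
low-noise settings are used for recovery studies. The same attenuation
affects any real MVPA-evidence regression; it is a property of the method,
not of the simulation.

## Problem sizes used by the shipped checks

The packaged verification studies use desk-scale sizes chosen to keep the
full suite fast while leaving each check well powered: 80 subjects x 60
trials for the calibrated cohort means; 50 replicates of 12 subjects x 60
trials at low BOLD noise for Model-2 recovery; 500 replicates of reduced
cohorts (8 subjects) for null calibration; 100 label permutations for the
chance-level decoding check; and 10 paired seeds for the
coupling-monotonicity trend.
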