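---
title: "Methods: caller identity, social networks and playback responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caller identity, social networks and playback responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callnet)
```

`callnet` implements the full computational chain of a playback experiment
probing whether group-living primates track the friendships of third
parties: acoustic analysis of agonistic calls, a permutation test of
caller identity that respects repeated-measures structure, quantification
of the group's social relationships from observational data, rule-based
construction of playback conditions, and regression models of the
behavioural response. This vignette explains each model and the design
choices behind it. Everything runs on synthetic data with known ground
truth; no field recordings are required.

## The caller-identity problem and the pDFA

Agonistic calls ("geckers" — tonal squeaks given in repetitive sequences,
with most energy between 2 and 10 kHz) arrive in *bouts*: bursts of
units produced by one caller during one episode. Units within a bout share
the caller's momentary state and recording conditions, so they are not
independent. An ordinary discriminant analysis scored on units therefore
overstates how distinctive callers are.

The permuted discriminant function analysis (pDFA) implemented in
`pdfa_test()` handles this by building the chance distribution at the
*bout* level:

1. Fit a pooled-covariance linear discriminant (five acoustic features) on
   the observed labels and record the classification accuracy. The
   discriminant assigns a unit with feature vector $x$ to the class
   maximising $x^\top W^{-1}\mu_k - \tfrac12 \mu_k^\top W^{-1}\mu_k +
   \log \pi_k$, with $W$ the pooled within-class covariance and $\pi_k$
   empirical priors.
2. Permute the bout-to-caller assignment uniformly at random
   (`permute_nested()`): all units of a bout move together, and the
   multiset of bouts per caller is preserved, so permuted datasets have
   the same nesting geometry and comparable class sizes.
3. Refit and rescore identically on each of `n_perm` permutations, and
   report $p = (r + 1)/(n_\text{perm} + 1)$ where $r$ counts permuted
   accuracies at or above the observed one. The add-one form can never
   return zero and is a valid permutation p-value. Per-caller p-values are
   computed the same way against the per-class null accuracies.

`pdfa_crossvalidated()` replaces the resubstitution accuracy with a
leave-one-out accuracy, applied identically to every permuted dataset.
The default holds out single units, which matches the classic procedure
but leaks bout-level information (the remaining units of the held-out
unit's bout stay in training); `holdout = "bout"` holds out whole bouts
and is the honest variant when bout effects are large. Both are exposed
because the two answers bracket the truth; the tests demonstrate the
leakage directly with a generator that has bout structure and no caller
signal.

Numerical details: the pooled covariance receives a relative ridge of
`1e-8` on its diagonal only when its Cholesky factorisation fails (small
classes under permutation can degenerate); discriminant-score ties are
broken towards the lowest caller id so results are deterministic.
`check_inclusion()` enforces the eligibility rule that a caller's unit
count must exceed the number of parameters in the analysis. Designs in
which every caller has a single bout are rejected: every permutation would
be a class relabelling with identical accuracy, so the test would be
vacuous.

## Acoustic features and stimulus assembly

Spectrograms use a 512-point FFT, Hamming window and 95% overlap
(`spectrogram()`), giving 86.13 Hz bins at 44.1 kHz. Frames are half-open
`[start, start + 512)` and a trailing partial frame is dropped. From the
mean magnitude spectrum `extract_features()` computes:

* `PF` (peak frequency) — bin of the global maximum;
* `FR` (frequency range) — width of the bins within 20 dB of the peak;
* `DFB1` (first dominant frequency band) — centre of the lowest
  contiguous run of such bins;
* `DFA2` — mean over frames of the frequency at which cumulative
  within-frame energy first reaches 50%;
* `duration` — signal length in ms, exact by construction.

The 20 dB relative band threshold is a design choice (the measures become
amplitude-invariant); it is configurable via `acoustic_config()`. The
definition of `DFA2` as a per-frame spectral median averaged over frames
is one reading of a somewhat ambiguous quantity ("the mean of the
frequencies at which the mean value of the energy distribution is reached
per segment"); it is isolated behind the config so an alternative
definition can be swapped in. Note that for tones falling midway between
FFT bins, spectral scalloping can push one extra bin above the band
threshold, so `FR` for a pure tone is bounded by three bins, not two.

`normalize_features()` optionally log-transforms each feature and then
z-scores it. The `"auto"` rule logs a column when a Shapiro–Wilk test
rejects normality at 0.05 and the log reduces absolute skewness; explicit
per-feature flags are also supported, since which features "needed"
transformation in any particular dataset is not recoverable.

`build_stimulus()` emulates conflict-stimulus assembly: the two callers'
waveforms are summed with synchronous onsets, high-passed at 1 kHz with a
zero-phase Butterworth filter (order 4 each way; well over 20 dB of
attenuation one octave below cut-off), standardised to exactly 4 s, and
peak-normalised to −1 dBFS to avoid clipping.

## Social metrics

**Friendship scores.** `build_association_matrix()` counts, for each
dyad, the proximity scans in which one member was the focal and the other
was recorded within 2 m, pooled symmetrically. The default is a raw count
because sampling effort is balanced by design (160 scans per focal); a
`rate` mode divides by the dyad's combined effort for unbalanced data.
Dyadic covariates are z-scored (`zscore_dyadic()`) before modelling.

**Elo ratings.** `elo_ratings()` processes unidirectional agonistic
events in order with the classic logistic update: expected winner
probability $E = 1/(1 + 10^{(R_l - R_w)/400})$, winner gains
$k(1 - E)$, loser loses the same, with $k = 100$ and start 1000 (the
conventional defaults of the dedicated rating packages). With a common
$k$ the rating sum is conserved exactly, which the tests assert after
every event.

**Centrality.** `eigenvector_centrality()` returns each individual's
component of the dominant eigenvector of the weighted association matrix
(computed through igraph, verified against a dense eigensolver to 1e-8),
max-normalised, and splits the group into `ceil(n/2)` central and
`floor(n/2)` peripheral individuals — reproducing a 10/9 split on 19
adults.

**Matrix correlation.** `mantel_test()` correlates the upper-triangle
dyads of two matrices and permutes individuals (rows and columns jointly)
for a one-tailed null; `stability_split()` applies it to association
matrices built from two adjacent chronological blocks of the scan data, a
split-half check that the observed network is stable rather than random.

**Kinship.** Matriline co-membership is coded 1/0
(`kinship_matrix()`); paternal relatedness is not modelled.

## Playback conditions

`select_condition_dyads()` encodes the six stimulus conditions. "Low
friendship with the subject" is operationalised as below the subject's
median score over eligible females — the source procedure gives no
numeric cut-off, and a subject-relative threshold adapts to gregarious
and peripheral subjects alike. Ties break by id order so the selection is
a pure function of its inputs. Conditions 3–4 (neither caller a friend of
the subject, callers friends of each other) are infeasible for central
subjects — a well-connected individual has no such pair — so the selector
returns infeasible for them by rule, and the trial generator marks those
trials skipped. For conditions 5–6 a "matriarch" must be identified from
the data available to the selector; we define her as the most central
female of her matriline (centrality as the proxy for social importance),
pair her with her most-associated female relative (condition 5) or
most-associated out-matriline female (condition 6).

## Looking-time models

The response is the total time a subject looks towards the concealed
speaker in the 30 s after playback onset. Three planned condition
contrasts are fitted as Gaussian linear models with treatment contrasts
(condition 1, 3 and 5 as reference levels) plus two controls, conflict
intensity and trial presentation order; the dyadic-relationship model
regresses looking time on the callers' friendship (z), relatedness (0/1),
absolute Elo difference (z) and the subject's centrality, with trial
order and a random subject intercept.

All models are fitted by maximum likelihood, not REML, so the
likelihood-ratio test of each full model against its control-only null is
valid across fixed-effect structures. Fixed-effect p-values in the mixed
model use Satterthwaite degrees of freedom. A singular random-intercept
fit falls back to the fixed-effects model with a warning rather than
reporting a degenerate variance. Collinearity is screened with
`vif()` ($1/(1-R^2_j)$) and residual normality with `residual_checks()`
(QQ data, skewness, kurtosis, Shapiro–Wilk). The condition models follow
the source analysis in omitting a random intercept (each subject
contributes one trial per condition within a model); the relationship
model includes it. No multiple-testing correction is applied across the
three planned condition models, mirroring the original analysis; this is
a documented caveat, not an endorsement.

A known limitation: looking time is bounded in $[0, 30]$ s but the
Gaussian models are unbounded, so fitted values can stray outside the
window when means sit near a boundary. A `log(y + 1)` transform is left
to the user; the default follows the untransformed analysis.

## The synthetic-data generator

The generator module plants known structure at the sizes of the
motivating study, and those sizes are the package defaults:

* **Calls** (`gen_call_features()`): 9 callers × 6 bouts × 2–12 units
  (uniform), features built as caller mean + bout effect + unit noise,
  all Gaussian (matching the discriminant's equal-covariance model), with
  per-feature sds (default within 1, bout 0.5). Per-caller bout counts
  are not reported by the source, so a uniform units-per-bout range and
  equal bout counts are free choices. `gen_call_waveforms()` renders
  units as harmonic bursts (fundamental 2–5 kHz, three harmonics with
  6 dB/harmonic decay, Hann envelope, 44.1 kHz 16-bit WAV) whose planted
  fundamentals and durations the extractor must recover.
* **Troop** (`gen_troop_observations()`): 19 adults (10 female, 5
  matrilines), 160 scans per focal, 145 agonistic events. Neighbour
  presence in a scan is Bernoulli with the planted dyadic affinity; the
  default affinity combines matriline community structure (within 0.22,
  between 0.06) with continuous individual gregariousness and
  dyad-specific preference, because a network in which friendship is a
  pure kinship indicator would make the friendship and relatedness
  covariates collinear — real groups, and the study group (all reported
  VIFs < 1.5), are not like that. Agonistic winners follow a Bernoulli
  rank rule: the higher-ranked member of the sampled dyad wins with
  probability `rank_steepness` (default 0.9); this is deliberately
  simpler than a rating-dependent model — one tunable hierarchy-signal
  knob. Grooming is a monotone noisy transform of affinity.
* **Trials** (`gen_trials()`): 16 subjects × 6 conditions; look time =
  condition mean + subject intercept + order slope × order + noise,
  truncated (not censored) to $[0, 30]$ — the scoring window records a
  duration within a fixed 30 s window. Default condition means are the
  study's reported means (9.49, 4.30, 7.93, 5.41, 5.34, 4.39 s);
  between-subject sd 2 s, residual sd 4 s and order slope −0.9 s/trial
  are plausibility choices consistent with the reported standard errors.
  With 16 subjects of whom roughly half are central, the schedule yields
  about 82 conducted trials of 96 — the study's count arises from the
  same skipping rule.

Every generator is a pure function of its spec, including the seed; the
test suite asserts bit-for-bit reproducibility.

What the generator does *not* emulate: realistic gecker spectro-temporal
fine structure (harmonic bursts are enough to validate the extractor, not
to fool a bioacoustician), male callers, observation-effort imbalance,
temporal drift in the social network (except when a test plants a regime
change deliberately), and any dependence of looking time on stimulus
acoustics beyond the planted covariates. Passing tests therefore show the
*estimators* are correct and calibrated on data satisfying their
assumptions — they cannot show that real macaque data satisfy those
assumptions.

## Problem sizes and calibration bounds

Calibration properties are checked with 200 replicate datasets at 999
permutations for the pDFA (a rejection rate in [0.02, 0.09] at
$\alpha = 0.05$), 200 replicates at 499 permutations for the Mantel
test, and 200 replicate model fits for LRT calibration and parameter
recovery (±2 SE coverage ≥ 93%, sign recovery ≥ 95%). These sizes give
binomial standard errors of about 1.5 percentage points on a 5% rate,
small enough to detect meaningful miscalibration while keeping the full
suite comfortably fast on a single CPU. Parameter-recovery checks are run
in the regime the generator module guarantees recoverable — planted
effects at least three times the noise sd — so that the $[0,30]$
truncation stays inert; at the default noise levels truncation shrinks
boundary-adjacent condition means, which is a property of the planted
model rather than an estimator defect.

## Reproducing the headline numbers

`scripts/acceptance.R` re-runs all of the above from scratch against the
installed package and writes one JSON object of named quantities (see the
README). Nothing in the script is precomputed: every number is generated,
fitted and measured at run time from the seed supplied on the command
line.
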