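# callnet

`callnet` implements the computational chain behind playback experiments
on third-party social knowledge in group-living primates — studies that
ask whether a listener who overhears a simulated conflict between two
groupmates responds according to the *relationship between those two
callers* (their friendship, kinship or rank difference), not just their
identities. The package covers every quantitative step of such a study,
for researchers in animal behaviour and bioacoustics:

* **Acoustics** — read WAV call units, compute spectrograms (512-point
  FFT, Hamming window, 95% overlap), extract the five classic call
  parameters (first dominant frequency band DFB1, per-frame spectral
  median DFA2, peak frequency PF, frequency range FR, duration),
  normalise feature tables, and assemble two-caller conflict stimuli
  (synchronous overlay, 1 kHz zero-phase low-cut, exact 4-s
  standardisation).
* **pDFA** — permuted discriminant function analysis of caller identity.
  The observed accuracy of a pooled-covariance linear discriminant is
  compared with a chance distribution built by permuting caller labels at
  the level of *calling bouts*, so the non-independence of call units
  within a bout cannot inflate significance:
  `p = (#{acc_perm >= acc_obs} + 1) / (n_perm + 1)`. A leave-one-out
  variant (unit- or bout-level holdout) is included.
* **Social metrics** — dyadic friendship scores from proximity scans,
  sequential Elo ratings from agonistic events (logistic expectation,
  scale 400, k = 100), maternal-kinship coding from matrilines,
  eigenvector centrality with a central/peripheral split, Mantel
  matrix-correlation tests and split-half network-stability checks, and
  the rule-based selector that picks the caller dyad for each of six
  playback conditions.
* **Playback models** — Gaussian linear models of post-playback looking
  time for the planned condition contrasts, and a linear mixed model of
  the dyadic social covariates with a random subject intercept; all
  fitted by maximum likelihood with likelihood-ratio tests against
  control-only nulls, plus VIF and residual-normality diagnostics.
* **Synthetic data** — generators for every input stream (call features
  nested in bouts, harmonic-burst waveforms with planted spectra,
  proximity scans with planted community structure, rank-driven conflict
  sequences, trial tables with planted condition effects), so the whole
  pipeline is testable end to end with known ground truth.

## Worked example

Simulate a study-sized dataset (9 callers, 6 bouts each, a 19-adult troop
with 160 scans per focal), test caller identity, check that proximity
predicts grooming, and fit the first condition model:

```r
library(callnet)

calls <- gen_call_features(call_sim_spec(n_callers = 9, bouts_per_caller = 6,
                                         between_caller_sd = 1.5, seed = 42))
tab <- check_inclusion(normalize_features(calls, log_rule = "none"))
pdfa_test(tab, n_perm = 999, seed = 1)
#> Permuted discriminant function analysis (plain)
#>   observed accuracy : 84.8%
#>   chance accuracy   : 30.4% [95% CI: 23.8-37.4%], 999 permutations
#>   p-value           : 0.001
```

Call units are assigned to the correct caller 84.8% of the time, while
bout-respecting label permutations score only ~30% (roughly the largest
class share): caller identity is recoverable from the five features far
above chance.

```r
troop <- gen_troop_observations(troop_sim_spec(seed = 42))
assoc <- build_association_matrix(troop$scans, ids = troop$ids)
mantel_test(assoc, troop$grooming, n_perm = 999, seed = 1)
#> Mantel test (one-tailed, 999 permutations): r = 0.951, p = 0.001

trials <- gen_trials(trial_sim_spec(seed = 42), troop)
m1 <- fit_condition_model(trials, 1)
m1$lrt
#> Likelihood ratio test: X2 = 19.883, df = 3, p = 0.00017948
round(m1$fit$terms, 3)
#>                    estimate    se      t     p
#> (Intercept)          16.117 2.296  7.019 0.000
#> condition2           -4.894 1.349 -3.628 0.001
#> condition3           -0.418 1.538 -0.272 0.787
#> condition4           -5.172 1.569 -3.297 0.002
#> trial_order          -1.070 0.356 -3.010 0.004
#> conflict_intensity   -1.461 0.660 -2.212 0.032
```

The generator plants longer looking times for condition 1 (a conflict
between two friends, one of them a friend of the subject) than for the
non-friend conditions 2 and 4; the model recovers exactly that pattern —
negative treatment contrasts for conditions 2 and 4 relative to the
condition-1 reference, no difference for condition 3, and a negative
habituation slope over trial order. `fit_relationship_model(trials)`
fits the corresponding mixed model of the dyadic covariates
(friendship, relatedness, Elo difference, subject centrality).

An end-to-end run that writes all reports (feature tables, pDFA JSON,
network metrics, condition dyads, model tables and a checksummed
manifest) into a directory:

```r
run_pipeline(pipeline_config(out_dir = "runs/demo", seed = 1))
```

See `vignettes/callnet-methods.Rmd` for the statistical background, the
design decisions and the generator's scope.

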