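---
title: "Bootstrap divergence point analysis of visual-world fixation curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap divergence point analysis of visual-world fixation curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazediv)
```

## The problem

In a visual-world experiment, listeners hear spoken sentences while viewing
several objects on screen, and their eye movements are recorded. Because
fixations shift toward objects a listener expects to be mentioned, the time
course of fixation proportions indexes predictive language comprehension.
The scientific question gazediv was built around is *when* looks to one set
of objects begin to reliably exceed looks to another -- the **divergence
point** -- and in particular whether listeners who hear a gender-neutral
sentence subject (*They would like to wear...*) predict egocentrically,
fixating the target whose gender stereotype matches their own gender (a tie
for a male listener, a dress for a female listener) more than the other
target.

The design crosses speaker gender (male, female voice) with referent
stereotype (masculine, feminine) within participants and items: 32
participants (16 male, 16 female) on 4 counterbalanced lists, 56 trials
each -- 28 gendered trials with exactly 7 per speaker x referent cell and
28 gender-neutral filler-analysis trials. Each display shows four objects;
on gendered trials they are one masculine and one feminine target (both
plausible arguments of the verb) and one masculine and one feminine
distractor.

## From gaze events to proportion curves

Fixation events (start/end in trial time, screen coordinates, blink flag)
are time-locked to the onset of the predictive verb and coded binomially
into 50 ms bins spanning 1000 ms before to 1500 ms after verb onset. A bin
is coded 1 for an object when the gaze sat inside that object's 300 x 300 px
interest area for a strict majority of the bin (> 25 ms); blinks and gaze
outside every interest area are coded 0 for all objects but stay in the
data. Ties at exactly half a bin break to 0, which keeps the rule
deterministic and symmetric; the coding is invariant to splitting one
fixation into contiguous sub-events, because occupancy is accumulated
before thresholding.

A **contrast** names two disjoint object sets. `targets_vs_distractors`
compares the two verb-compatible targets against the two distractors;
`compatible_vs_incompatible` compares the participant-compatible target
(stereotype matches the participant's gender) against the other target.
For each participant and bin, the curve value is

$$p_A = \frac{\text{looks to } A}{\text{looks to } A + \text{looks to } B},$$

pooled over that participant's selected trials ("aggregating over items").
Two denominator conventions are defensible: counting only looks to A or B
(so 0.50 is the exact null at every bin) or counting all selected trials
(so bins with no look at either set pull both curves down early in the
trial, when most gaze is elsewhere). gazediv implements both behind the
`denominator` argument and defaults to the A-or-B denominator, because the
one-sample test against 0.50 is only calibrated when 0.50 is the actual
null; the all-trials variant is retained for comparison. Bins where a
participant has no informative look are undefined for that participant and
drop out of that bin's sample size rather than being imputed.

Trial subsets follow the design: `all_gendered`, `gender_match`
(participant and speaker share a gender), `gender_mismatch` (they differ --
the subset that isolates egocentric from voice-driven prediction), and
`neutral`. Match and mismatch partition the gendered trials 14/14 per
participant under the counterbalancing.

## The three-step divergence point procedure

1. **Pointwise tests.** At each bin, a two-sided one-sample *t*-test
   compares the participant means against 0.50 (df = participants - 1).
   The participant is the aggregation unit; items are pooled within
   participant first. Degenerate bins use the conventions t = ±Inf, p = 0
   for zero variance off the null and t = 0, p = 1 exactly on it; bins with
   fewer than two defined participants are untestable and count as
   non-significant.
2. **Run-length onset.** The divergence point is the left edge of the first
   bin that starts a run of at least 10 consecutive bins (500 ms) with
   p < .05 (strict inequality), searched from verb onset to 1500 ms after.
   Requiring a sustained run guards against isolated false positives among
   30 correlated tests.
3. **Stratified bootstrap.** The dataset is resampled 2000 times; each
   resample draws trials with replacement *within participant x image-type
   strata*, every resampled trial carrying its entire time course, and the
   curves, tests and onset are recomputed. The divergence estimate is the
   mean onset over resamples that detected one, with a 95% percentile
   interval (2.5th/97.5th order statistics, so both bounds lie on the 50 ms
   lattice while the mean need not); the fraction of resamples with a
   detected onset is reported as `detection_rate`, and resamples without
   one are excluded from the mean and CI rather than imputed.

Two readings of the stratification are possible: resampling whole trials
within participant x image type, or resampling each (participant, time
point, image type) cell independently. gazediv defaults to whole-trial
resampling because fixations in adjacent bins are strongly correlated --
respecting that autocorrelation is the stated reason for bootstrapping
instead of fitting one model per bin -- and independent per-bin resampling
would destroy it. The literal per-bin variant is available via
`bootstrap_config(literal_bins = TRUE)` for comparison.

Randomness is controlled by a single root seed from which per-resample
sub-seeds are drawn up front, so results are exactly reproducible and
independent of execution order.

## The synthetic experiment

Real data for this paradigm live in external archives; gazediv ships a
generator so that every stage of the pipeline can be validated against a
known ground truth at desk scale. `build_design()` reproduces the design
exactly: lists, gender balance within lists, a Latin-square rotation of the
four gendered-item versions (7 trials per speaker x referent cell for every
participant), and per-trial verb/target timings drawn from truncated
normals matching the published per-speaker stimulus statistics (verb onset
mean 1621 ms (SD 414) for the male speaker and 1532 ms (SD 357) for the
female; offsets, target onsets and durations via positive gaps so that
verb onset < verb offset < target onset < sentence end holds by
construction).

`simulate_gaze()` models each trial's gaze as a Markov chain over five
states -- the four objects plus "none" (blink or elsewhere) -- advanced
once per 50 ms bin. With probability `stay_prob` (default 0.85) the state
persists, giving a geometric dwell time of ~330 ms, near typical fixation
durations; otherwise a fresh state is drawn from the current mixture:
`p_offscreen` (0.10) to "none", and the on-screen mass split between the
target pair and the distractor pair. The target share equals
`baseline_pref` (0.5, uniform across the four objects) before the
configured `true_onset_ms` and ramps linearly to `asymptote_pref` over
`ramp_duration_ms`, reaching `bin_ms / ramp_duration_ms` of the effect at
the onset bin itself, so the first bin at which the mixture departs from
baseline -- the unambiguous ground-truth divergence point -- is
`true_onset_ms` exactly. No extra oculomotor latency is inserted between
the configured onset and the mixture change, for the same reason.
Within the target pair, the participant-compatible target receives share
0.5 + `egocentric_effect` scaled by the same ramp; the default 0 reproduces
the observed null (an egocentric preference present from trial start would
instead make the compatible contrast diverge before the verb, which is not
the hypothesis under test). Because refreshes draw from the mixture, the
mixture is also the chain's stationary distribution, which the test suite
checks against empirical occupancy.

Defaults the design does not pin down were chosen once as field-typical
values: `true_onset_ms = 500` and `asymptote_pref = 0.75` sit where the
reference experiments place the target-pair divergence and its asymptotic
preference; `ramp_duration_ms = 100` makes the preference shift fast
relative to the gaze dynamics so that ground truth stays sharp -- the
observed curves are still smooth because gaze persistence low-passes the
mixture; `p_offscreen = 0.10` matches the usual share of off-object gaze;
`comprehension_error_rate = 0.01` matches the reported 99% accuracy.

What the generator deliberately does *not* emulate: every participant and
item shares the same parameters (no individual preference, speed or
stereotype-strength differences), gaze has no saccade-latency structure
beyond the persistence constant, and the simulator emits binned indicators
directly (a thin adapter, `binned_to_events()`, produces event-level
fixation reports for exercising the readers). Passing tests on these data
therefore validate the *machinery* -- coding, mapping, testing, resampling
-- under known truth; they do not certify behaviour under the participant
and item heterogeneity of real data, which in particular widens real
bootstrap CIs well beyond the simulated ones.

## Numerical and edge-case choices

- Bins are half-open `[start, start + 50)` ms, identified by the left edge;
  all windows must sit on the lattice, enforced at the door.
- Significance is strict (`p < alpha`); ties at exactly alpha are
  measure-zero and break conservatively.
- A dataset in which no resample detects an onset returns an explicit
  no-divergence result (onset `NA`, `detection_rate` 0), not an error.
- If every trial within every stratum is identical, all resamples coincide
  and the CI has width exactly 0 -- a degenerate case the suite pins down.
- Proportions of complementary contrasts sum to 1 wherever defined, and at
  most one object can be fixated per bin (gaze exclusivity), both enforced
  by the table validator.

Problem sizes used in the shipped validation: the simulation studies run
200 null experiments for the false-detection rate and 50 effect experiments
at 500 bootstrap resamples for recovery, with the full 2000-resample
bootstrap exercised on single experiments; these sizes give stable Monte
Carlo estimates while keeping the suite quick to run.

## Known limitations

The run-length onset rule is *conservative by construction*: it fires at
the first bin of ten consecutive significant tests, so the detected onset
trails the latent preference change by however long group significance
takes to build. With the default gaze persistence (stay 0.85, occupancy
time constant ≈ 6.7 bins) and 32 homogeneous participants, the expected
per-bin *t* at the true onset bin is ≈ 1, and the first reliably
significant bin is 1--2 bins later; detected onsets therefore
systematically overshoot the generating onset by ~50--100 ms. The
percentile CI inherits this: it quantifies resampling variability around
the *biased* estimator, not uncertainty about the latent onset, and on
homogeneous simulated data it is narrow enough (~50--100 ms) that it often
excludes the generating onset. Comparisons of divergence points between
conditions estimated with the same criterion are unaffected by the shared
delay; absolute onset times should be read as "detectable by this
criterion from this time", not as the moment prediction began. On real
data, between-participant variability widens the CI substantially, which
is why published intervals for this paradigm span ~300 ms.

The package does not model saccade programming, drift correction or
calibration error; it consumes fixation reports as given. Growth-curve or
GAMM modelling of the curves, cluster-based permutation tests and Bayesian
onset models are out of scope.
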