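---
title: "Cluster-based randomization analysis of anticipatory gaze: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based randomization analysis of anticipatory gaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecluster)
library(data.table)
```

# The problem

In the visual-world paradigm, participants inspect a display while
listening to speech; where they look, millisecond by millisecond, tracks
their interpretation of the unfolding sentence. `gazecluster` implements a
complete analysis pipeline for a 2 x 3 repeated-measures experiment on
gender-stereotype-driven *anticipatory* eye movements: displays show a
female and a male character embodying a female- or male-stereotypical
occupation (visual factor, 2 levels), while a passive-voice sentence
conveys a female-stereotypical, male-stereotypical or neutral action
(verbal factor, 3 levels) whose agent — one of the two characters — is
named only by the sentence-final noun. The question is whether gaze moves
toward the stereotype-consistent character *before* that noun, and whether
individual differences in explicit gender attitudes predict the strength
of that anticipation.

The package covers: Latin-square design construction, a synthetic gaze and
questionnaire generator so the whole pipeline runs without any external
data, fixation-report ingestion and AOI assignment, sample expansion and
100-ms binning time-locked to the critical noun, log-ratio preference
scores, within-subject adjusted confidence intervals, two-stage
cluster-based randomization inference with three permutation null schemes,
Likert scale scoring with Cronbach's alpha, and a cluster-level OLS
regression of gaze preference on attitude scores.

# Design construction

`build_item_set(14, 3, 28)` creates 14 occupations (7 female-, 7
male-stereotypical), 42 items (displays) and 28 fillers.
`latin_square_lists()` rotates every item through the six
(occupation x action) cells by cyclic rotation over six lists, so each
list shows every item once with 7 items per cell, and each item occurs in
every cell exactly once across lists.

The sentence's agent is the character matching the display's occupation
stereotype (the female florist in a female-stereotypical display, the male
soldier in a male-stereotypical one). Two facts motivated this rule, which
the design leaves open in principle: (i) the occupation conditions are
balanced within a list, so each list automatically presents equally many
female- and male-agent trials; and (ii) only an agent aligned with the
occupation factor produces the post-noun referential structure the
analysis is meant to detect — a contrast *between* occupation conditions
after noun onset together with opposite-signed zero-reference clusters in
the two occupation scopes. With agent gender orthogonal to the occupation
factor, referential gaze cancels out of every condition mean and no
post-noun cluster can exist.

**Pseudo-randomization.** Each participant's order must start with a
filler and never contain more than two consecutive experimental trials.
Naive rejection sampling of whole permutations is infeasible here: with 42
experimental and 28 filler trials the acceptance probability is of order
1e-8. `randomize_presentation()` instead draws the filler/experimental
*run pattern* uniformly by dynamic programming (counting, for every
suffix, the number of admissible ways to distribute the remaining
experimental trials into gaps of at most two) and then assigns trial
identities by uniform permutation within type. Every valid pattern carries
exactly `42! * 28!` full orders, so the result is uniform over precisely
the set a rejection sampler would target, at negligible cost. The sampler
reports an explicit error naming the deficit when the filler count cannot
break all runs.

# The synthetic gaze generator

The generator (`generator_params()`, `simulate_trial()`,
`simulate_experiment()`) is a renewal process chosen as the simplest
mechanism consistent with fixation-report granularity:

* **Dwell times** are gamma distributed (default mean 220 ms, shape 4,
  typical of fixation durations in scene viewing).
* At each fixation onset, a gaze target is drawn from a 5-way multinomial
  over {female character, male character, object 1, object 2, elsewhere},
  with probabilities frozen at the onset time.
* **Baseline** probabilities are (0.25, 0.25, 0.175, 0.175, 0.15):
  characters attract somewhat more gaze than objects, with a reserve for
  fixations outside all AOIs.
* **Anticipation** is a logistic-shaped ramp in the log-odds of the
  stereotype-consistent character, zero before the cell's onset and
  approaching an asymptote (default 0.65) afterwards, with slope
  0.015/ms (about 300 ms from onset to near-asymptote). The default
  onsets encode the condition-specific pattern the pipeline is designed to
  detect: -1200 ms (female action, female occupation), -800 ms (female
  action, male occupation), -500 ms (male action, female occupation,
  toward the male character), and none for the male-action/male-occupation
  and neutral cells.
* **Referential effect**: from 200 ms after noun onset (an oculomotor
  delay), the named agent's log-odds ramp toward an asymptote of 0.85.
* **Random variation**: participant and item effects (SD 0.3 each) shift
  the asymptote's log-odds additively, so preference strength varies
  across participants and items while the baseline stays common.
* **Timing**: 3000 ms display preview, 1000 ms of sentence before the
  critical verb, and a verb-to-noun lead time drawn from a truncated
  normal with mean 1719.26 ms and SD 228.75 ms.
* Filler engagement responses are Bernoulli with accuracy 0.91;
  coordinates are drawn inside the assigned AOI rectangle so the
  coordinate-based assignment path is exercised end to end.

Fixation boundaries are reported at 1-ms resolution (shared boundaries are
rounded together, so consecutive fixations abut and never overlap), which
is what makes interval-arithmetic binning exactly equal to the literal
1-ms indicator computation.

What the generator deliberately does *not* model: saccade kinematics,
smooth pursuit, blinks as a separate category (gaps count as "elsewhere"),
spatial error in landing positions, and any coupling between successive
fixations beyond the time-varying choice probabilities. A consequence
worth keeping in mind when reading the calibration results: because gaze
only changes at fixation onsets, measured preference lags the underlying
probability ramp by roughly the mean forward-recurrence time of the dwell
process (~140 ms at the defaults). Detected cluster onsets are therefore
expected to trail the generating onsets by about one 100-ms bin, a
property of any fixation-based measure, not an artifact of the pipeline.
Passing tests show the pipeline recovers what this generator encodes; real
data add failure modes (track loss, drift, calibration error) that only
the reading/validation layer addresses.

With `null_generator_params()` every ramp is disabled and gaze stays at
the baseline multinomial for the whole trial — the configuration used for
type-I-error calibration.

# From fixations to bins

`expand_and_bin()` conceptually assigns every 1-ms sample to the AOI of
the fixation covering it (a sample at t belongs to a fixation iff
t is in [start, end)), then averages 100-ms windows tiling
[-2000, +1000) ms around the critical noun: 30 bins, half-open
`[t, t+100)`, the first starting at -2000. Samples covered by no fixation
count as "elsewhere", never redistributed; `n_valid` records how many
samples of a bin any fixation covered, so a trial with no usable gaze is
flagged (all-elsewhere, `n_valid = 0`) rather than erroring. The
implementation is interval arithmetic, property-tested to equal a literal
indicator-vector oracle exactly on randomized trials;
`bin_experiment()` is a vectorized whole-experiment version tested to
match the per-trial function. AOI rectangles are half-open
`[x0,x1) x [y0,y1)`, so a point on the shared edge of touching rectangles
belongs to exactly one; overlapping rectangles are an error in strict
mode, first-match-wins otherwise.

# Preference scores and time courses

The preference score is the empirical log-ratio
`ln((female + 0.5) / (male + 0.5))` on per-bin sample counts, computed per
participant x trial x bin and averaged upward. Positive values mean
female-character preference; the score is antisymmetric under swapping the
characters, and the additive smoothing of 0.5 (the empirical-logit
convention) keeps it finite at zero counts. Smoothing is applied to the
counts *before* the ratio.

Condition time courses are two-stage means (trials to participant,
participants to condition) with within-subject adjusted 95% CIs: Cousineau
normalization (subtract the participant's mean across conditions, add the
grand mean) followed by a t-based CI scaled by the Morey factor
`sqrt(C/(C-1))`. `condition_timecourse()` uses all C = 6 cells (per-AOI
summaries); `logratio_timecourse()` uses the C = 2 occupation conditions
within each action condition, matching the scope of preference plots. For
C = 2 this yields the paired-difference CI half-width divided by sqrt(2) —
the algebraic consequence of the normalization-plus-correction recipe.

# Cluster-based randomization inference

Stage 1 tests each 100-ms bin within each action-condition scope: the
contrast between the two occupation conditions, and each occupation
condition against a zero reference (`zero_reference()` mirrors every
observation with a zero pseudo-observation, making "no preference" an
explicit label). Maximal runs of consecutive significant bins with a
common t sign form clusters, scored by their summed t.

Stage 2 re-runs the same per-bin analysis on label-scrambled data 2000
times per null scheme, recording the largest absolute summed t per
iteration (0 when no cluster forms): condition-swap permutes occupation
labels among each participant's trial series; the two zero-reference
schemes swap each real series with its zero mirror with probability 1/2.
A cluster's p-value is the add-one estimator
`(1 + #{null >= |sum t|}) / (1 + N)`, significant iff `p < 0.025`
(two-tailed percentile criterion, strict).

Design choices a reader should know:

* **Per-bin statistic.** Two routes are provided. The mixed-model route
  (`method = "lmm"`) fits `logratio ~ contrast + (1|participant) +
  (1|item)` per bin and takes the fixed-effect t, falling back (flagged)
  to the aggregated route on failure. The aggregated route
  (`method = "agg"`, default) collapses to participant means and computes
  the paired or one-sample t. The permutation engine always uses the
  aggregated route: the null distribution calibrates whatever
  cluster-forming statistic is used, so validity does not depend on the
  statistic's finite-sample distribution, and the aggregated t makes
  2000-iteration x 30-bin x 9-scope re-analysis a matter of seconds. The
  two routes coincide when random variance is degenerate (tested); the
  bin-level threshold is |t| > 1.96 (normal approximation), a
  cluster-forming heuristic rather than an inference, since degrees of
  freedom for crossed random intercepts are contested and the permutation
  stage supplies the actual error control.
* **Sign purity.** A sign change splits a cluster; a two-tailed summed-t
  mass is otherwise ill-defined.
* **Exchangeable units.** Labels attach to a whole participant x item
  trial series, never to bins of one trial independently, preserving
  within-trial temporal correlation. Swapping a real series with its
  all-zero mirror is algebraically a sign flip of that series, which is
  how the engine implements it.
* **Contrast orientation.** The default tests the occupation contrast
  within each action condition, the orientation under which the reported
  anticipatory clusters are defined; `contrast_factor = "action"` swaps
  the factor roles (female- vs male-stereotypical action within each
  occupation scope, neutral excluded) for users who want the other
  reading.
* **Iterations with no cluster contribute 0** to the null, which is
  conservative, and the add-one p-estimator cannot return zero.

# Attitude scales and the cluster-level regression

NGRO (29 items, 1-7) and the two ASI subscales (11 items each, 0-5) are
scored as means over answered items, after flipping any reverse-keyed
items (`min + max - x`; none by default, configurable — the published
instruments' reverse-keyed items are external to this implementation).
Respondents answering under 80% of a scale are flagged. Reliability is
Cronbach's alpha with n-1 sample variances; the Likert generator inverts
the alpha formula to a one-factor loading (`r = alpha/(k - alpha(k-1))`,
`lambda = sqrt(r)`) and cuts the latent responses at equal-probability
normal quantiles, which attenuates alpha by a percent or two at seven
response categories — within the +-0.05 recovery tolerance the tests use.

The cluster-level regression takes, per participant, the mean log-ratio
over each pre-noun significant zero-reference cluster (the "clusters of
interest"), restricted to the trials of that cluster's own condition
cell. Clusters expressing a male-character preference (negative summed t)
are multiplied by -1 so all aggregates read "strength of the anticipated
preference". Because the generator's anticipation persists into the noun
region, a significant anticipatory cluster typically continues past 0 ms
and merges with the referential cluster; clusters of interest are
therefore those *beginning* before the noun, and aggregation is truncated
at noun onset so the aggregate reflects the anticipatory portion only.
The OLS model is `value ~ (ngro + asi_bs + asi_hs) * cluster` with
z-standardized scale scores and a treatment-coded cluster factor, refitted
once per reference cluster ("rotation"): coefficients change, fitted
values provably do not (asserted to 1e-10 in tests), and each rotation's
scale main effects read off that cluster's within-cluster slopes. Rows
missing a cluster drop per-row, not listwise.

# Numerical and degenerate-input conventions

* Zero-variance per-bin data give t = 0 (not significant), never NaN.
* Empty scopes and single-level contrasts are errors, not silent zeros.
* `validate_config()` collects *all* violations before erroring.
* Every stage is a pure function of (data, config, seed); the pipeline
  run report reproduces bit-for-bit under identical seeds.
* Half-open conventions everywhere (bins, fixation membership, AOI
  rectangles) prevent double counting at boundaries.

# Problem sizes used in the test suite

The packaged checks run at sizes chosen to give stable Monte-Carlo
behaviour: binning equivalence on 1000 randomized trials; type-I
calibration on 100 null experiments of 24 participants with 200
permutation iterations each (the add-one p with 200 iterations can reach
0.005, well below the 0.025 criterion); onset recovery on 50 experiments
of 24 participants; reliability recovery at n = 500 respondents over 20
replicates; regression calibration on 200 simulations at n = 51. The
full-scale analysis drivers under `analysis/` use 51 participants and
2000 iterations, the sizes a real study of this design would use.

# Known limitations

* The mixed-model per-bin route is provided for fidelity but is not the
  calibrated default; with 2000 iterations it is computationally
  impractical, and singular fits are common on per-bin data.
* The generator's anticipation ramp never turns off, so anticipatory and
  referential clusters merge across the noun boundary; real data may show
  separated clusters, which the clusters-of-interest rule also handles
  (truncation at 0 is then a no-op).
* Reverse-keyed questionnaire items default to none; scoring real NGRO /
  ASI data requires supplying the instrument's reverse-key list.
* Cluster extents are resolved at bin width (100 ms); onset statements
  inherit that granularity plus the oculomotor lag discussed above.
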