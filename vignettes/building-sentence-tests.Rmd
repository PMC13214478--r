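---
title: "Building and validating adaptive sentence-in-noise tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating adaptive sentence-in-noise tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srtkit)
```

srtkit turns a psychoacoustically characterized sentence corpus into a
validated adaptive speech-in-noise test, and supplies a virtual-listener
simulator so the entire construction can be studied without human data.
This vignette explains the underlying models, the tunable parameters and
their defaults, the numerical choices, and what the simulator does and
does not tell you about real listeners.

## The psychometric model

Sentence intelligibility is modeled as a two-parameter logistic in SNR,

$$p(x) = \frac{1}{1 + e^{-4 (s/100)(x - m)}},$$

with $m$ the inflection point in dB SNR ($p(m) = 0.5$ exactly) and $s$
the slope of the percent-correct curve at the inflection point in %/dB
(the factor 4 makes $s$ that derivative directly, so parameters read as
audiologists report them). Guess and lapse rates are fixed at zero: the
model is a plain logistic, which suits open-set sentence material where
chance performance is effectively nil, and mirrors how such corpora are
characterized in practice. `fit_psychometric()` minimizes squared error
between the curve (in percent) and the observed percent correct per
presentation, so the reported fit MSE is in squared percentage points.

Fitting uses damped iterative least squares (Levenberg–Marquardt, via
minpack.lm) with a multi-start grid: five starting midpoints across the
observed SNR range plus a response-weighted midpoint guess, crossed with
slope starts of 5, 15 and 30 %/dB. Multi-start matters because a single
adaptive track supplies at most ~25 points concentrated in a 2–4 dB
window, a regime where single-start Gauss–Newton happily parks in a local
minimum. Degenerate inputs are flagged, not fit: all-correct or all-wrong
response sets carry no information about the midpoint and return a
`converged = FALSE` result; fewer than three distinct SNR levels is an
error. A fit whose midpoint lands more than 15 dB outside the sampled
range or whose slope sits at the box bounds is likewise flagged.

Keyword scoring is assumed conditionally independent: the three keywords
of a sentence are Bernoulli draws sharing the logistic success
probability. Real keywords within a sentence are positively correlated
(masker dips, attention), which the simulator ignores for want of a
defensible correlation model; the practical effect is that simulated
per-sentence scores are slightly less dispersed than real ones.

## Corpus filtering and normalization

`apply_filters()` retains sentences that pass, in order: playback
quality, discomfort fraction strictly below 0.25, mean naturalness at
least 4.5 (of 7), midpoint strictly inside (−9.2, −0.5) dB SNR, slope
strictly inside (0, 33.5) %/dB, and fit MSE below 897 %². Rejections are
attributed to the first failing criterion in that order, so the rejection
report always sums with the retained count to the input count. The
psychometric cutoffs are configuration defaults of the reference corpus
(derived there from 1.5-IQR Tukey fences, `iqr_cutoffs()`, with the lower
slope fence raised to zero and the lower MSE fence dropped); they are
deliberately *not* recomputed from whatever corpus is being filtered. One
direction choice was genuinely open: the MSE rule is stated in the
source material as "greater than 897" even though the surrounding
procedure removes upper outliers; srtkit retains *below* the bound, the
only reading consistent with upper-outlier removal, and exposes
`mse_direction` for the literal reading.

Normalization offsets are $o_i = m_i - \bar m$: a level gain of $o_i$ dB
moves sentence $i$'s effective midpoint onto the reference, so positive
offsets boost hard sentences. `trim_by_offset()` removes sentences whose
midpoint sits more than 3 dB from the corpus mean, capping the gains the
test will ever apply. It is single-pass by default and returns the
pre-trim mean as the normalization reference — trimming a roughly
symmetric distribution barely moves the mean, and iterating (available
via `iterate = TRUE`, tolerance 0.05 dB) changes the reference by a few
hundredths of a dB at most.

## List construction

Lists hold 20 sentences, two per syntactic template; the scarcest
template therefore bounds the list count at
`floor(min(count)/2)` (`max_list_count()`). Each randomized sort pairs
every template's sentences middle-out by offset — innermost pair first,
the final pair coupling the most extreme offsets — then scatters pairs
across lists with one random permutation per template, so offset
extremes are balanced both within and across lists. When a template has
more than `2L` candidates, each iteration subsamples `2L` uniformly at
random, letting the optimizer explore sentence selection as well as
arrangement (the alternative, fixing the selection once, explores less
at no cost savings). After each sort the reference mean midpoint is
recomputed over the selected sentences and all offsets recalculated
before costing, so the exported reference is specific to the winning
selection.

The cost is `SD(mean slope per list) + SD(mean offset per list)` with
equal unit weights despite the unit mismatch (%/dB vs dB) — the
construction deliberately treats a decibel of offset dispersion as
costly as a %/dB of slope dispersion; the weights are exposed for anyone
wanting otherwise. The SD uses the n−1 (sample) denominator, switchable
to n. Ties in cost keep the earliest iteration, making `optimize_lists()`
bit-for-bit reproducible under a seed. One thousand iterations of
best-of-N randomized search is not global optimization, and is not meant
to be: the test suite verifies on an exhaustively enumerable toy corpus
(10 templates × 4 sentences, 2 lists, a 2^10 arrangement space) that the
search does attain the global minimum when given enough iterations.

## The adaptive track

The staircase is 1-up/1-down on sentence-level correctness with a
three-phase step schedule: 5 dB until at least 4 sentences are scored
and one reversal has occurred; 2 dB until at least 4 more are scored and
the phase-2 SE (sample SD of the phase's presented nominal levels over
$\sqrt n$) drops below 1 dB; then 1 dB until the 20 list sentences are
exhausted (phase 3 is not always reached — the track completes
regardless). A 1-up/1-down rule converges on the 50% point of whatever
binary response drives it; with the default majority rule (≥ 2 of 3
keywords) the 50% point of the majority score coincides exactly with the
keyword-level midpoint, because $P(k \ge 2) = 3p^2 - 2p^3 = 0.5$ iff
$p = 0.5$. The source procedure never states the up/down decision rule;
majority is the default here for that fixed-point property, and an
`"all"` mode is provided since all-keywords scoring measurably raises
SRTs. The first sentence starts at 0 dB nominal SNR and, if not repeated
*completely* correctly (all three keywords), replays at +5 dB increments
until it is; replays consume no list sentence and never enter phase
counts or the SRT. Restart heuristics (perseveration, first four
correct) are surfaced as warnings only, since they essentially never
trigger in practice.

Two conventions were open and are fixed as follows. First, the step used
to place a sentence is the step of that sentence's phase: the first
phase-2 sentence sits 2 dB (not 5) from the last phase-1 level, which is
how step-shrinking staircases are conventionally run. Second, reversal
detection starts with the second adjustment, the first having no
direction history; the adjustment after the resolved first sentence is
always downward.

The SRT is the mean of the *nominal* (pre-offset) levels of phase-2 and
phase-3 presentations, the SE the sample SD of those levels over
$\sqrt n$ — presented levels only, no virtual-next-level convention,
since the definition is an average over presented sentences. A track
that never leaves phase 1 has no SRT and errors with a diagnostic.

## The simulator and what it can show

`generate_synthetic_corpus()` draws sentence records from: midpoints
$N(-4.8, 1.5^2)$ dB SNR; slopes $N(13, 4.5^2)$ %/dB (sentence-level,
non-adaptive characterization slopes — shallower than adaptively
measured test slopes); MSE log-normal (meanlog $\log 200$, sdlog 0.6);
naturalness $N(5.8, 0.5^2)$ clamped to 1–7; discomfort Beta(0.6, 12);
quality Bernoulli(0.97). The tails of these distributions supply a few
percent of violators of every retention criterion, so the filter always
has work to do, and the pipeline retains ~85–87% of input — enough that
120 sentences per template clears the 88-per-template floor required for
44 lists in well over 95% of seeds (the suite checks 100 seeds). These
are calibration choices made once; they emulate the *shape* of a real
corpus, not any particular one.

Virtual listeners deviate from the corpus reference by a normal SRT
shift (SD 0.5 dB by default, echoing between-subject spreads in
normal-hearing cohorts) and a common slope multiplier. The between-
subject model is this package's own — the construction procedure it
validates says nothing about listener heterogeneity. Session plans
counterbalance in participant pairs: one permutation of the 44 lists per
pair, halves assigned to the two members, training lists drawn from each
member's complement; 20 participants yield exactly 10 measurements per
list. Per-track RNG streams are hashed from (master seed, participant,
order), so re-running one session reproduces its tracks without
disturbing any other.

Simulation shows that the staircase recovers a listener's effective
midpoint to within a few hundredths of a dB on average (500-track mean
within 0.5 dB, SD ≈ 0.55 dB at an 18.5 %/dB slope), that steeper slopes
tighten the SRT distribution, and that the mixed model recovers injected
learning drifts. What passing simulations do *not* show: anything about
real-listener responses (context effects, fatigue, keyword correlation,
lapses), audio-level issues (calibration, spectra, equalization), or the
linguistic adequacy of the material. The simulator validates the
*machinery*, not the test's ecological validity.

## Validation statistics

`list_equivalence()` and `within_subject_stats()` are test-measurement
summaries (training excluded by contract): per-list means/SDs with
normalized deviations from the grand mean, and per-participant SDs
averaged without weighting. Because a grand average can be taken over
lists, participants, or all measurements — which differ under
missingness — `list_equivalence()` reports all three.

`training_effect()` fits `srt ~ order + (1 | participant)` by REML
(lme4) and tests the order coefficient with a marginal F-test using the
residual degrees-of-freedom convention, $n - 2$ fixed parameters, which
matches how such analyses conventionally report F statistics; the 95% CI
uses the same df. Satterthwaite or Kenward–Roger corrections are
deliberately out of scope. With training included, orders run 1–24;
excluded, the training rows are dropped and the original order codes
kept. On balanced data the fixed estimates equal ordinary least squares
regardless of the variance ratio — the suite asserts this degenerate-
limit oracle to 1e-6 — and the null simulation holds the F-test's
type-I error at its nominal level (checked at 500 replicates, ≤ 0.08
tolerance).

`posthoc_slopes()` refits the logistic per track from the presentation
log. A caveat worth stating plainly: per-track least-squares slope
estimates from short adaptive tracks are *upward-biased*. Sampling
concentrates near the midpoint, per-presentation proportions are coarse
(quarters of three keywords), and the slope's sampling distribution is
strongly right-skewed; at a generating slope of 18.5 %/dB the grand
mean over ~500 simulated tracks runs about 5 %/dB high (median ≈ 21).
This is the familiar slope-overestimation phenomenon of adaptive
procedures, and it is why adaptively refit test slopes exceed
sentence-level characterization slopes. The grand average should be
read as a test-specific operating characteristic, not an unbiased
estimate of the underlying sentence slope; non-convergent fits are
excluded and counted, never imputed.

## Problem sizes and runtime choices

The test suite exercises the study design at its natural scale — 44
lists, 20 participants, 10 scores per list (480 tracks per study) — and
uses reduced scales where replication matters more than size: 200
replicate studies for drift recovery, 500 direct-simulation replicates
for test size, 500 tracks for staircase recovery, 100 seeds for
generator calibration, and a 10 × 4 toy corpus where the optimizer's
search space can be enumerated exhaustively. These sizes keep the whole
suite in the minutes range on a single core while leaving Monte Carlo
error well below every asserted tolerance.

## Known limitations

- No audio: levels are abstractions on the SNR axis; calibration,
  masker spectra and transducer equalization are out of scope.
- The listener model (normal SRT shift, common slope scale, independent
  keywords) is intentionally minimal; power analyses inherit its
  optimism.
- The list optimizer is best-of-N randomized search, appropriate for
  the dispersion cost but making no global-optimality claim at scale.
- Post hoc slope estimates carry the upward bias described above.
- The mixed model's residual-df F-test is anti-conservative relative to
  Satterthwaite for small participant counts; with 20 participants and
  480 observations the difference is immaterial.
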