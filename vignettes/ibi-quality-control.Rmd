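---
title: "Quality control and resting HRV estimation for telemetered inter-beat intervals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control and resting HRV estimation for telemetered inter-beat intervals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibiqc)
```

## The measurement problem

Externally mounted heart-rate belts can stream inter-beat intervals (IBIs,
the time in milliseconds between successive R peaks) from free-ranging
animals — here, the motivating system is radio-telemetered belts on wild
breeding grey seals. Resting heart-rate variability (HRV) statistics
computed from such streams, above all the root mean square of successive
differences (rMSSD), index sympathovagal balance and individual coping
style. But field telemetry is harsh on the signal: muscle noise, poor
electrode contact and interrupted line-of-sight transmission cause beats
to be missed or spuriously generated. Vendor software corrects the obvious
extremes — deleting spurious beats and interpolating across missing ones —
and flags what it corrected. Interpolation across *multi-beat* gaps,
however, leaves two uncorrectable artefact shapes in the exported stream:

* **flats** — two or more consecutive identical IBI values (constant
  interpolation), and
* **stairs** — more than two identical, non-zero successive differences
  (linear interpolation).

Both artefacts destroy genuine beat-to-beat variability and so bias rMSSD
downward. This package implements the full screening pipeline around that
problem: emulating the device correction, detecting flats and stairs,
windowing traces into 5-minute segments matched to behavioural activity,
filtering windows for resting-HRV eligibility, and quantifying the rMSSD
bias that residual flats and stairs impose.

## Data model

An `ibi_trace` is an ordered beat series; beat `k`'s IBI is the interval
*ending* at its R peak, so beat times are the cumulative IBI sum from the
session start and the first beat's time equals its own IBI/1000. This
convention makes "the IBI of beat k" and "the time of beat k" mutually
consistent under every edit the pipeline performs (merges, splits, fills),
and total elapsed time equals the IBI sum — the invariant all correction
operations are tested against. Device-native IBIs are integer milliseconds
(1000 Hz sampling); the generators round accordingly.

Per-beat QC flags are annotations, never edits: `corrected` (value was
replaced/derived by the correction step), `flat`, `stair` (detected
artefact shapes — flagged, not corrected), and `out_of_bounds`
(physiologically implausible). Activity labels (`Inactive`/`Active`,
`Unknown` when no classifier output covers the second) attach per beat
from a per-second classifier series.

## Artefact-correction emulation

The vendor algorithm is proprietary; `correct_artefacts()` implements its
operationally observable behaviour with a running-median detector:

* an IBI is *extreme* when it deviates from the `local_window_beats = 7`
  running median by more than `deviation_threshold = 0.25` of that median
  (a Kubios-style "strong" level), or falls outside hard backstop bounds
  (300/3000 ms) that catch cases where the median itself is corrupted;
* a run of up to `max_merge_span` extreme-*short* IBIs whose sum matches
  the local median is merged into one beat — spurious-beat deletion;
* an extreme-*long* IBI of duration `D` is replaced by
  `m = round(D / median)` beats (round half to even: deterministic and
  scale-free). The fill is constant when the valid anchor IBIs on both
  sides agree — producing a flat — and ramps with a constant integer step
  toward the other anchor when they differ — producing a stair. The
  integer-ms remainder of a fill is absorbed by the last filled beat, so
  total duration is conserved exactly (tests assert conservation within
  1 ms per correction event).

This reproduces the qualitative mechanism that matters downstream:
isolated missing beats between informative neighbours are repaired without
leaving a detectable artefact, while multi-beat gaps necessarily leave
flats (equal anchors) or stairs (differing anchors). No attempt is made to
match any vendor version bit-for-bit; the analysis layer depends only on
which IBIs are flagged.

## Flats, stairs and physiological limits

`detect_flats()` reports every maximal run of two or more equal IBIs;
`detect_stairs()` every maximal run of at least `min_diffs = 3` identical
non-zero successive differences ("more than two", spanning at least four
beats). The stricter and laxer readings of that phrase are both available
via `min_diffs`, and `flag_run_head` controls whether the first beat of a
run is flagged (default yes: run membership is the only symmetric choice,
and per-trace artefact counts are defined as flagged-beat counts). Both
detectors are verified against exhaustive brute-force run enumeration on
all short sequences over a three-value alphabet and on random longer
sequences.

Equality is exact by default (`tolerance_ms = 0`), which is the correct
semantics for integer-ms device data; a chained tolerance is available for
real-valued synthetic series. `apply_physiological_limits()` flags beats
outside 20–200 bpm (IBIs outside 300–3000 ms) — a deliberately wide range
for a large phocid seal on land, where documented resting mean heart
rates span roughly 41–124 bpm.

## Windowing, activity and retention

Traces are segmented into sequential half-open clock windows
`[k·300, (k+1)·300)` s; a beat belongs to the window containing its beat
time, and the trailing partially covered span is discarded. Windows are
clock-based rather than beat-count-based because heart rate varies several
fold across traces. Per window the package reports beat and flag counts,
the percentage of beats flagged flat or stair (union of the two flags),
the percentage corrected, the percentage of known-label beats that are
Active, mean heart rate and rMSSD.

The default retention policy keeps a window when at most 5% of its beats
are flagged flat or stair (boundary inclusive) and no beat is Active.
Resting-HRV estimation requires minimal motor activity, but no published
threshold exists for "minimal"; 0% Active is the conservative default and
is configurable (`max_pct_active`, including `NA` to disable). Windows
whose activity is entirely unknown fail an enabled activity criterion
rather than passing silently. Rejections carry the first failed criterion
in a fixed order (`min_beats`, `flats_stairs`, `artefact`, `activity`), and
filtering is monotone: tightening any threshold never enlarges the
retained set.

## rMSSD

\[
\mathrm{rMSSD} = \sqrt{\tfrac{1}{N-1}\textstyle\sum_{j=1}^{N-1}
\Delta\mathrm{IBI}_j^2}
\]

Out-of-bounds beats are excluded *before* differencing, and the exclusion
splits the difference chain — no difference is taken across an excluded
beat, because bridging a gap manufactures a spurious large difference. The
divisor is the number of differences actually taken. Fewer than two usable
adjacent beats yield `NA` with a warning rather than a fabricated value.

## Agreement statistics

`classification_matrix()` cross-tabulates the device's `corrected` flags
against flat (or stair) flags over all beats of one or many traces,
with the three derived reporting percentages (share of corrected IBIs
flagged, share of non-corrected IBIs flagged, share of flagged IBIs that
were corrected); reporting rounds half-to-even to one decimal, two
decimals below 0.1%.

`match_beats()` pairs two streams on a common clock by greedy
nearest-neighbour matching on beat times (candidates within
`max_offset_s = 0.25` s accepted in order of increasing offset, each beat
used once). The tolerance default is a quarter second because the
motivating field protocol synchronised clocks only to within a second;
it is configurable.

`bland_altman()` returns the bias (mean test-minus-reference difference),
±1.96 SD limits of agreement, and 95% confidence intervals using the
classic approximations — bias CI from `sd/√n` with a t quantile, LoA CIs
from `sd·√(3/n)`. These are the standard textbook formulas; more exact
LoA-CI variants exist but the approximation error is negligible at the
pair counts involved (thousands).

## The synthetic-data generator

No field recordings are distributed, so `generate_clean_trace()` stands in
for them: an AR(1) Gaussian process around a mean IBI, optionally plus a
sinusoidal respiratory-sinus-arrhythmia term, rounded to integer ms and
clipped below at 300 ms. The AR(1) innovation SD is inverted from the
closed form \(\mathrm{rMSSD} = \sqrt{2\sigma_X^2(1-\varphi)}\) so the
process hits a requested rMSSD exactly in expectation (verified at 3000
beats over 20 seeds within 5%). Defaults describe the resting field range:
mean IBI 800 ms (75 bpm) within the observed 480–1500 ms span, target
rMSSD 90 ms within the observed 60–110 ms range, \(\varphi = 0.5\) and RSA
period 10 s as placeholders — the true autocorrelation structure of seal
IBI series is unreported, and \(\varphi\) was fixed mid-range before any
downstream experiment was run.

`corrupt_trace()` applies the three field error processes by editing the
R-peak set, which conserves elapsed time exactly: dropout bursts
(Poisson-arriving, exponentially long) delete every peak in a window,
leaving one long spanning IBI — the mechanism that forces multi-beat
interpolation; missed beats delete single peaks; spurious beats insert a
peak at a uniform fraction in (0.2, 0.8) of an interval, so both halves
are individually detectable as short. A per-beat provenance record
(`genuine`/`merged`/`split`/`gap`) makes every downstream claim testable.

What the generator does *not* emulate: dive bradycardia and other
non-stationarities, ectopic-beat morphology, activity-dependent artefact
rates, or electrode deterioration over deployment. Passing tests therefore
demonstrate correctness of the *pipeline mechanics* on a plausible signal,
not device accuracy on real seals.

`generate_reference_pair()` emulates an independent concurrent measurement
(ECG-derived IBIs): Gaussian timing jitter on every R peak plus an
optional constant bias. Note the variance algebra — jitter SD `s` on both
endpoints of an interval gives paired-difference SD `√2·s`, and
consecutive paired differences are negatively correlated (MA(1)), which
makes the naive bias CI conservative.

## The injection study

`run_injection_study()` quantifies how contamination biases rMSSD on an
error-free base trace (obtained with `select_error_free_trace()`, which
rejection-samples generator output until no flats, stairs or out-of-bounds
beats are detected — integer rounding makes chance length-2 flats common,
and the motivating analysis likewise hand-picked zero-artefact traces).

Per run, *flat* contamination repeats the copy step — a uniformly chosen
IBI overwrites its successor — `floor(n/2)` times, recording after each
step the *detected* flat fraction (contamination is a state of the trace,
not a count of actions: copies merge into longer runs) and the rMSSD.
The copy process is absorbing at the all-equal trace, but reaching
absorption by simulation takes on the order of \(n^2\) steps, so each run
ends by recording the absorbing state directly (all values equal to the
first IBI, which no copy can overwrite): the 100% endpoint with rMSSD
exactly 0.

*Stair* contamination repeatedly replaces the interior of a uniformly
chosen anchor pair (`j − i ≥ 2`) with the real-valued linear ramp between
the anchor values (real-valued so successive differences are exactly
equal; integer rounding would break the very definition being studied).
The recorded proportion is the cumulative fraction of beats replaced —
blocks whose anchors happen to share a value degenerate to flat-shaped
fills but contaminate all the same. Blocks accumulate until 95% of beats
have been replaced (beyond that, coverage stalls waiting for rarely-hit
positions) and the run ends with the maximal block spanning the whole
trace: a single ramp replacing all `n − 2` interior beats, whose rMSSD is
`|IBI_n − IBI_1|/(n − 1)` — under a quarter of a millisecond for the
traces used here, i.e. zero at reporting precision.

Pooled over runs (default 1000, matching the reference study size),
observations are binned by contamination proportion (width 0.01, bin =
upper edge) with means and 2.5/97.5 percentiles. The acceptance-scale
experiments use a ~600-beat, 420 s base trace; the suite checks that
binned means are non-increasing, essentially linear over 0–5%, that
stairs depress rMSSD faster than flats at matched contamination, and that
the endpoint collapses to zero.

## Problem sizes and numerical choices

The shipped experiments use: 3000-beat traces for generator calibration
and end-to-end recovery (three targets 70/90/110 ms, light corruption
fixed at `p_missed = p_spurious = 0.002`, 0.2 dropout bursts/min of mean
2 s); ~600-beat traces with 1000 Monte-Carlo runs for the injection
curves; 2487 synthetic pairs (bias 0.9 ms, difference SD 8 ms) for the
Bland-Altman recovery, whose estimated bias CI covers the injected bias in
at least 93 of 100 replicates. These sizes make every experiment exactly
reproducible from a seed in well under a minute each.

All stochastic entry points take an integer `seed` and restore the
caller's RNG state, so identical seeds give identical traces, corruptions
and curves. Ties in the split count `m = round(D/median)` follow round
half to even. Percentages with zero denominators are reported absent
(`NA`), as is rMSSD with fewer than two usable differences.

## Known limitations

* The correction emulator reproduces a described behaviour, not a vendor
  implementation; absolute artefact rates on real exports will differ.
* The AR(1)+RSA generator has no dive response, behavioural
  non-stationarity or measurement-context covariance; determinant
  modelling of artefact rates (e.g. additive mixed models on the exported
  window table) is deliberately out of scope.
* Bland-Altman CIs use the classic approximations and assume exchangeable
  pairs; repeated-measures variants are not implemented.
* Only rMSSD is computed; frequency-domain HRV and other time-domain
  statistics (SDNN, pNN50) are out of scope.
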