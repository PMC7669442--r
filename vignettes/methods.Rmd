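---
title: "Validating consumer sleep wearables against actigraphy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating consumer sleep wearables against actigraphy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sleepagree` implements a free-living validation pipeline for consumer sleep
wearables — a smart ring that reports per-night summary records and a
smartwatch that reports status-change events — against wrist actigraphy as
the reference method. This vignette explains the underlying models, the
tunable parameters, the synthetic-study generator, and the numerical choices
the package makes where the methodology left them open.

## The measurement problem

Polysomnography is impractical outside the laboratory, so free-living
validation studies use actigraphy as the reference: a wrist accelerometer
whose per-epoch activity counts are scored sleep/wake by a validated
algorithm. The nonstaging parameters compared per night and device are

* **TST** — total sleep time (min),
* **WASO** — wake after sleep onset (min),
* **SE** — sleep efficiency, `100 * TST / TIB` (%),
* **SOL** — sleep onset latency (min),

where **TIB** is the time in bed (length of the detected sleep period).
Agreement is quantified on matched nights by the signed difference
*reference minus device*: a negative bias means the device overestimates.

## Actigraphy scoring

### Cole–Kripke epoch classification

Each 60-s epoch `t` receives the score

```
D(t) = 0.001 * (106 a[t-4] + 54 a[t-3] + 58 a[t-2] + 76 a[t-1]
                + 230 a[t] + 74 a[t+1] + 67 a[t+2])
```

with `a[i]` the activity count divided by 100, and is labelled SLEEP when
`D(t) < 1`. These are the canonical one-minute-epoch coefficients as used by
the ActiLife implementation; the division by 100 rescales modern wrist
counts to the count scale of the device the algorithm was derived on.
Without that rescaling, realistic wake-level counts (hundreds per epoch)
saturate the score and realistic quiet-wake counts can never cross the
threshold. The weights, scale, threshold, and divisor are exposed as an
injectable `ck_weights()` object, so alternative published coefficient sets
can be swapped in. Out-of-range window positions count as zero, which keeps
the output exactly as long as the input. Because the weights are
non-negative, increasing any count can only move epochs from SLEEP towards
WAKE, never the reverse.

A known property of the weighted window matters for interpretation: an
isolated wake epoch (counts ~300, i.e. 3.0 after rescaling) scores
`0.23 * 3.0 = 0.69 < 1` and is absorbed into sleep. Wake bouts of one or two
minutes are therefore structurally invisible at 60-s resolution; bouts of
three minutes and more are detected reliably.

### Nonwear detection and sleep periods

Wear time follows the Troiano validation rule: a nonwear bout is a maximal
run of zero counts of at least 60 min, bridged across interruptions of at
most 2 *consecutive* epochs whose counts stay below 100; a larger count or
a longer interruption terminates the run. The auto-detection of sleep
periods then treats nonwear bouts as candidate sleep time and

1. discards candidates longer than 24 h (true nonwear, e.g. a shelved
   device),
2. discards candidates that are not almost all zeros (5 or more nonzero
   epochs),
3. merges candidates separated by at most 60 min (brief in-bed wake), and
4. extends each period across adjacent contiguously SLEEP-labelled epochs.

Each period is assigned to the noon-to-noon night containing its midpoint;
the noon boundary keeps midnight-spanning sleep in one night and is shared
by every device module so that night matching is well defined. Periods are
then cleaned against the self-report logs: overlaps with logged device
removal, periods fully inside the 10:00–20:00 daytime window (naps), and
periods outside the measurement week are deleted with per-deletion reason
codes. The cleaning is idempotent.

From the retained period, onset is the first run of `onset_run = 5`
consecutive SLEEP epochs; TST and WASO are the SLEEP and WAKE minutes
between onset and the final SLEEP epoch; `SOL = onset - period start`; and
`SOL + TST + WASO + terminal wake = TIB` exactly. Because detected periods
typically begin at the first sustained zero-count run — which is the onset
itself — actigraphy SOL is structurally close to zero. This mirrors the
well-known unreliability of actigraphic onset latency, and the package
flags the value `sol_low_confidence` so reporting can segregate it.

## Wearable ingestion

**Ring.** The ring reports one summary record per night (bedtime start/end,
sleep duration, awake total, onset latency, efficiency) in seconds;
`parse_ring()` converts to minutes, takes SE from the efficiency field, and
rejects records with missing fields, negative values, or
`duration + awake` exceeding the bedtime span.

**Watch.** The watch emits a record on each sleep/wake status change.
Candidate events pair each SLEEP transition with the next WAKE transition;
a trailing unterminated SLEEP transition is an open event. Validation
follows a fixed cascade: (1) valid heart rate in the 30-s PPG windows at
both boundaries validates the event; (2) otherwise boundary movement
magnitude below 0.05 (normalized units, configurable — the watch was worn
but the PPG was unusable) validates it; (3) step records strictly inside
the event contradict sleep, so the event is trimmed to its largest
step-free span, provided at least 30 min remain, and discarded otherwise.
Open events and events with no corroborating signal are discarded; every
candidate ends as VALID, CORRECTED, or DISCARDED, and the accounting is
returned with the results. Nights whose candidates are all discarded are
absent from the analysis — the treatment applied to technically invalid
watch nights in the benchmark study (21 of 181 nights, 11.6%).

Watch nightly parameters: TIB spans the first event start to the last event
end, TST is the summed event durations, `WASO = TIB - TST` (only gaps
between events — whether the device counts intra-event wake internally is
unknown, so it is not assumed), and `SE = 100 * TST / TIB`. The watch does
not report SOL; it is derived as the time from the last positive step
record before sleep start to the sleep start, missing when no prior step
exists in the night frame.

## Agreement statistics

On matched nights (inner join on subject and night), per parameter:

* **Paired t**: `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, two-sided
  p; identical in raw mode and printed-summary mode by construction.
* **Bland–Altman**: bias `mean(d)`, limits `bias ± 1.96 sd(d)` (the 1.96
  multiplier reproduces every printed benchmark limit to ±0.02; an exact-t
  multiplier can be passed instead), bias CI via the t critical value
  (which matches printed CIs more closely than 1.96), and the count of
  differences outside the limits.
* **Satisfactory range**: |d| ≤ 30 min for TST and WASO (boundary
  inclusive) and |d| < 5 percentage points for SE (boundary exclusive),
  reported as a percentage.
* **Pearson correlation** between the paired raw values.
* **Gender subgroup test**: two-sample t on the per-night difference
  scores, Welch model by default. The benchmark prints anomalous subgroup
  degrees of freedom (530 for 266 nights — double the conventional value);
  the package reports conventional df and documents the discrepancy rather
  than imitating it.

No multiple-testing correction is applied, matching the benchmark's
analysis; nights are treated as independent (no mixed-effects modelling of
within-subject correlation) for the same reason. Report tables round
minutes and t statistics to 2 decimals and percentages to 1 decimal.
Bland–Altman plots place the *reference value* on the x-axis — following
the benchmark's figures — which differs from the classic pair-mean
convention; the satisfactory ranges appear as dashed lines.

## The synthetic study generator

Raw recordings of the benchmark study were never deposited, so the
generator stands in for them: it draws a latent truth per subject-night and
renders it through all three observation channels, making every downstream
stage testable end to end.

**Truth model.** Defaults reproduce the benchmark design: 45 subjects (23
women, 22 men), 7 nights each; per-night TST ~ N(419.04, 78.31²), WASO ~
N(43.57, 27.28²), SOL ~ N(0.91, 1.37²), all truncated at zero and rounded
to whole minutes, so `TIB = TST + WASO + SOL` holds exactly. Bedtime is
N(23:00, 45 min) on the clock. WASO is realised as 1–4 uniform-length wake
bouts; bout count and placement are constrained so each bout is 3–45 min
(resolvable by the scoring window, see above) and each sleep segment is at
least 60 min (resolvable by the 60-min nonwear rule). The benchmark reports
only nightly totals, so this microstructure is the generator's own minimal
assumption. Between- and within-subject variance are not separated (the
benchmark gives no decomposition); all nights are independent draws.

**Counts.** Awake epochs (daytime, latency, wake bouts) emit
Poisson(300) counts; sleeping epochs emit Poisson(0.001) — near-silence
with rare isolated movement artifacts. The near-zero sleep rate is forced
by the detection rule the pipeline reproduces: sleep time is recovered from
*nonwear-like* zero runs, and a candidate with 5 or more nonzero epochs is
excluded, so a generator that emitted realistic restlessness would make the
named detection rule inoperable. This is a deliberate caricature: the
generator validates the pipeline's logic, not the biology of movement
during sleep.

**Device error.** Configured per parameter as the device-minus-truth bias
and the SD of the reference-minus-device differences; ring defaults come
from the benchmark's ring difference summaries (TST −15.27 ± 39.68, WASO
+17.41 ± 28.24, SE +1.34 ± 5.91, SOL −11.93 ± 14.92, in
reference-minus-device sign) and watch defaults from its watch summaries.
TST is perturbed additively (Gaussian; at a 419-min scale truncation never
binds). WASO and SOL need care: additive Gaussian noise at these SDs would
put a large probability mass below zero, and clipping would shift the
realised bias by several minutes. Instead, WASO is perturbed
*multiplicatively* — device WASO = truth × f with f gamma-distributed,
calibrated in closed form against the truncated-normal truth moments so the
difference has exactly the configured mean and SD, and capped at 4 (a
device cannot plausibly report several times the true wake; tail
probability ~10⁻³) — and SOL is drawn from a gamma with mean truth + bias
and variance noise². Both are nonnegative by construction. The ring
efficiency field is perturbed additively and clamped to [0, 100] (shift
< 0.1 at the defaults). Multiplicative wake error also reproduces a feature
of real validation data: difference spread grows with the amount of wake.

**Watch streams.** Each valid night becomes an alternating SLEEP/WAKE event
walk carrying the drawn TST/WASO, PPG windows at every boundary (invalid
for a whole night with probability 0.1, exercising the movement fallback),
low boundary movement, and step records whose last pre-sleep step encodes
the drawn SOL. With probability 21/181 the night is corrupted into a lone
unterminated SLEEP event, which the cascade must discard.

**Seeding.** A single root seed yields deterministic per-subject child
seeds (one per rendering stage), so identical configs reproduce studies bit
for bit and subjects are reproducible independently of iteration order.

## What the synthetic data can and cannot show

Passing the pipeline on synthetic data demonstrates that scoring, nonwear
detection, period assembly, the validation cascade, night matching, and the
agreement statistics are implemented correctly and that configured device
biases are recovered within sampling tolerance. It does not demonstrate
validity on real recordings: real counts are autocorrelated and
heteroscedastic, real sleep contains movement that the caricatured
emission model suppresses, real device errors are not stationary across
subjects, and the generator's truth is exactly the construct the reference
method estimates, which sidesteps the reference's own error. Headline
percentages that depend on the full (non-Gaussian) shape of the real
difference distribution — e.g. satisfactory-range coverage — are *not*
expected to match the benchmark's printed values under Gaussian
differences; the package recomputes those printed values from the printed
counts instead.

## Numerical choices and degenerate inputs

* Epoch alignment: all truth times are rounded to whole minutes, so epochs
  align exactly and parameter accounting is exact in integer minutes.
* Zero-variance inputs: a paired t with zero variance reports `t = 0, p = 1`
  when the mean is zero and flags `zero_variance` otherwise; Pearson
  correlation with a constant vector returns `NA` with a flag rather than
  an error.
* Series shorter than the 7-epoch scoring window are an explicit error.
* Ties in step-free-span trimming resolve to the first maximal span.
* A detected night with several periods keeps the longest (naps are
  deleted by the daytime rule anyway).
* Sample sizes in the tests: module tests run 3–8 subjects × 3–5 nights;
  the acceptance battery runs the full 45 × 7 benchmark design once plus a
  10,000-replicate null simulation of the paired t.

## Known limitations

* The actigraphy SOL is structurally ~0 (periods begin at onset); the
  package computes it but flags it low-confidence, and no conclusion about
  device SOL validity should rest on it.
* The count emission model is a caricature (see above); wear-time detection
  parameters are exposed but have only been exercised against that model.
* SE is bounded at 100, so the clamped efficiency field saturates for
  near-perfect nights and the recovered SE bias sits a few tenths of a
  percentage point above the configured value — the same saturation a real
  device exhibits near the boundary.
* Sleep staging, raw PPG waveform processing, heart-rate variability, and
  the proprietary count-filtering of the reference device are out of scope.
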