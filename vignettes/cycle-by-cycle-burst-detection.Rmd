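---
title: "Cycle-by-cycle burst detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycle-by-cycle burst detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclebursts)
```

## Why threshold-free burst detection

Wake EEG under rising sleep pressure shows growing theta (4–8 Hz) and
alpha (8–12 Hz) activity. Whether that growth reflects *larger* oscillations
or *more* oscillations cannot be answered by any detector that uses an
amplitude cutoff: a fixed threshold converts amplitude growth into apparent
quantity growth, and a relative threshold (top-N% of waves) fixes the
detected quantity regardless of how much oscillatory activity is present —
inventing oscillations out of 1/f background in quiet recordings and
missing most of them in oscillation-dominated ones. This package instead
detects bursts purely from waveform **shape and regularity**, so amplitude
metrics and quantity metrics can move independently. The cost, discussed
under *Limitations*, is that single isolated waves are invisible (four
regular cycles are required) and that sufficiently regular stretches of
background noise occasionally pass.

## The detection pipeline

**Filter bank.** Overlapping 4 Hz bands (2–6 … 10–14 Hz) ensure any rhythm
between 2 and 14 Hz sits well inside at least one passband. Each band filter
is a high-pass-then-low-pass cascade of linear-phase equiripple FIRs with
stopband edges 1 Hz outside the passband, 0.04 dB passband ripple
(peak-to-peak) and 40 dB stopband attenuation. "Minimum order" is realised
by searching upward from the Kaiser order estimate until the audited
frequency response meets the specification; an unmeetable specification is
an error, never a silent degradation. At 250 Hz these specs require
cascades of roughly 1 000–1 200 taps; the first and last `n_edge` samples
of a filtered trace carry transients and any cycle touching them is
discarded before run formation.

**Phase handling.** The filters are applied causally and the output shifted
back by the exact integer group delay of the symmetric cascade. This is
equivalent to zero-phase filtering but, unlike forward–backward filtering,
preserves the designed magnitude response exactly (forward–backward would
square it, doubling the dB specs). Zero-crossing times are therefore
unbiased with respect to the broadband signal.

**Cycle parsing.** Zero-crossings are read off the narrowband trace with a
fixed convention: a crossing is the first sample at or past the sign
change, and zero-valued samples inherit the previous sign. Peaks are then
located on the *minimally filtered* signal — 0.5–40 Hz, the preprocessing
band — as the extremum of each half-open crossing span, ties to the first
sample. Coordinates are sample indices with half-open spans throughout, so
overlap arithmetic downstream has no boundary ambiguity. The package
applies the 0.5–40 Hz band-pass itself (frequency-domain raised-cosine
mask, exactly zero-phase) unless told the input is already preprocessed.

**Per-cycle criteria.** A cycle (positive peak → negative peak → positive
peak) passes only if all seven hold:

| criterion | quantity | threshold |
|---|---|---|
| A | trough is a raw local minimum | — |
| B | mean period to neighbouring troughs | inside the band's period range |
| C | min/max ratio of the two adjacent periods | ≥ 0.6 |
| D | min/max ratio of rise vs decay amplitude | ≥ 0.5 |
| E | min/max amplitude ratio against each neighbour cycle | ≥ 0.6 |
| F | fraction of flank samples moving the right way | ≥ 0.6 per flank |
| G | net correctly-signed voltage ÷ total voltage excursion | ≥ 0.6 |

Two readings were genuinely open. *B's "neighbouring peaks"* could mean
negative peaks or all peaks; the implementation uses negative peaks, which
makes B consistent with the burst-frequency definition (reciprocal mean
inter-trough interval) and reproduces the quoted 0.1–0.17 s range for the
6–10 Hz band. *F* could apply per flank or to the flank mean; it is applied
per flank (the stricter reading). Cycles missing a neighbour (first/last of
a channel) fail C and E by definition. Criterion G is computed as the net
correctly-signed voltage change divided by the total absolute change along
each flank, averaged over the two flanks — the literal "how much amplitude
went in the wrong direction".

**Run formation and polarity.** Maximal runs of ≥ 4 passing cycles become
bursts. Detection runs on the signal and its negation, because mu-like
rhythms with sharp troughs on one polarity parse better on the other; both
polarities' bursts enter the same within-channel resolution rather than
being merged specially.

**Within-channel overlap resolution.** Across bands and polarities, the
largest burst (most cycles; ties broken by duration, then earlier start —
"largest" alone is not a total order) is kept intact; overlapping
competitors are trimmed to the cycles whose own spans clear the winner, and
a remnant survives only with ≥ 4 cycles. Trimming is at cycle granularity,
matching the unit in which bursts are defined. The output is pairwise
non-overlapping by construction, and the suite asserts it.

**Cross-channel aggregation.** Greedy, longest-first: the longest unassigned
burst seeds an aggregate and is its *reference*; a candidate from another
channel joins when the overlap covers ≥ 50% of the *candidate's* duration
(the shorter burst — the denominator the overlap rule leaves open; choosing
the candidate is the permissive, trimming-symmetric reading) and the mean
frequencies over the overlapping cycles differ by ≤ 1 Hz
(`freq_overlap_only = FALSE` falls back to whole-burst frequencies).

**Metrics.** Aggregates are assigned to theta [4, 8) or alpha [8, 12) Hz by
reference mean frequency — half-open at 8 Hz as a deterministic tie rule.
Per band: amplitude is the three-level mean (rise/decay within cycle →
cycles within aggregate, pooled across member channels → aggregates within
band; the last level is burst-weighted, not cycle-weighted); quantity is
summed reference cycles per minute (robust to bursts merging into longer
ones, unlike bursts-per-minute); occupancy is the covered fraction. Empty
bands report missing values, never zero.

## Spectral power

Welch PSD with 8 s Hann windows and 75% overlap (0.125 Hz resolution),
constant detrend per segment (the minimal standard choice; the source is
silent), one-sided density normalisation checked against Parseval. Power is
z-scored per participant and frequency bin against the pool of all sessions
× conditions × channels (sample SD — a convention that had to be fixed
once), which removes gain-like between-participant differences. Band
averages drop the outer-edge electrodes (48, 63, 68, 73, 81, 88, 94, 99,
119 of the 123-channel montage) and use bins in [low, high).

## Pupillometry

Eye-closure is read from pupil-model confidence only: below 0.5 is closed,
with 50 ms hysteresis applied in a fixed order — confident interruptions
< 50 ms inside a closure stay closed *first*, then isolated dips < 50 ms
stay open. Closures < 1 s are blinks, ≥ 1 s ocular microsleeps. Diameters
convert px → mm through the iris calibration (measured iris span mapped to
the 12 mm human mean; individual iris differences are deliberately
sacrificed for cross-session comparability). Cleaning interpolates invalid
gaps < 0.5 s linearly, *then* deletes valid islands < 0.5 s — the pass
order matters and is fixed. Traces arriving at the acquisition rate
(~120 Hz, jittery) are resampled to the 50 Hz analysis grid by linear
interpolation (diameter) and previous-value steps (confidence), the method
being unstated upstream.

Oddball responses epoch −0.5 to 2 s around tone onsets: all 40 targets plus
the standard immediately before each target, per-trial baseline subtraction
(−0.5–0 s mean), then the printed exclusion ladder — trials < 2/3 clean;
sessions with < 15 usable trials of either type or any averaged timepoint
pooling < 10 trials; participants with < 6 of 12 usable sessions. Averaged
courses are z-scored within participant across timepoints, tone types and
sessions, and the response is the trapezoidal area of target − standard
over 0.5–2 s (trapezoidal being the default reading of "area under the
curve" on a uniform grid).

## Session statistics

Outcomes are z-scored per participant pooling sessions and conditions, then
compared with classical paired t-tests; effect sizes are Hedges'
*g* = *J*·mean(d)/SD(d) with *J* = 1 − 3/(4·df − 1) — the toolbox the
original analysis cites does not print its formula, so the standard
small-sample correction is adopted and documented. The identity
*g* = *J*·*t*/√n is asserted in the tests.

The wake-maintenance-zone contrast interpolates each participant's values
from S5 (17:30) to S8 (02:40, placed at 26.67 h on a continuous next-day
axis) at 21:30 and subtracts that expectation from mean(S6 20:00, S7
23:00); the interpolation weight is (21.5 − 17.5)/(26.667 − 17.5) ≈ 0.436.
Because 21:30 is the S6/S7 midpoint, the statistic is exactly zero whenever
S6 and S7 lie on the S5–S8 chord — asserted analytically in the suite.
Benjamini–Hochberg FDR (via `p.adjust`) is reserved for channelwise maps;
the session battery is deliberately uncorrected, matching the analysis it
mirrors. `min_detectable_g()` inverts the noncentral-t power function
(`power.t.test`, paired, two-sided) and applies *J*; at α = .05 and power
.80 it returns 0.669 for n = 18 and 0.911 for n = 10.

## The synthetic-data module

The generators define the study conditions the tests run under; they are
first-class, tested code.

**Background.** 1/f noise by spectral shaping of white noise (FFT ×
f^(−exponent/2), inverse FFT): the target exponent is exact and there are
no filter transients. Default exponent 1, SD 10 µV — a typical wake-EEG
broadband level.

**Bursts.** Each burst is an added sinusoid of requested frequency,
peak-to-peak amplitude and cycle count; `asymmetry` warps the fraction of
each period spent on the descending flank, producing controlled violations
of criteria D/F/G and mu-like sharp-trough waveforms. A full Hann envelope
was considered and rejected: its amplitude taper makes neighbouring cycles
fail the detector's own consistency criterion E at zero noise, defeating
exact-recovery validation. Instead the waveform carries one sacrificial
lead-in and lead-out cycle (flat envelope, sine on/off at zero crossings);
the edge cycles deterministically fail the neighbour criteria and shield
the nominal cycles, which the detector recovers exactly on a noise-free
background.

**SNR.** The source material reports no background/burst SNR, so one is
defined for reproducibility: SNR = peak-to-peak amplitude ÷ (2 × background
SD in the burst's band). The validation fixture
(`burst_validation_fixture()`) uses SNR 5 with 20 bursts — theta 6 Hz × 10
cycles alternating with alpha 10 Hz × 12 cycles — present on all three
channels, clear of the filter-edge zones. Detection quality is scored on
the pipeline's output unit, aggregates with ≥ 2-channel support, against
ground truth at ≥ 50% interval overlap. Threshold-free detection
necessarily passes occasional regular noise epochs within a single channel
(~0.17 events/s on a pure exponent-1 background at these thresholds);
genuine bursts extend across channels while noise epochs do not replicate,
so multichannel consensus is the appropriate validation unit — and is
exactly what the aggregation stage exists to provide.

**Oddball sequences.** 160 standards, 40 targets, inter-onset intervals
uniform on 1.8–2.4 s, ≥ 3 standards between consecutive targets; the
surplus standards are distributed randomly over the gap slots. All
invariants are property-tested across seeds.

**Pupil traces.** Constant baseline (default 4 mm) plus optional white
noise and gamma-shaped event dilations (peak at 0.9 s); blinks at a Poisson
rate with uniform 0.1–0.6 s durations, microsleeps as 2 s closures whose
count hits the requested closed-time fraction; all closures snapped to the
sample grid so detection recovers the ground-truth table exactly.

**Study tables.** Per-participant session outcomes follow an increasing
saturating exponential of time awake (asymptote 2, rate 0.15 h⁻¹ — a
build-up that has largely saturated by 24 h) for amplitude-like outcomes
and a linear trend for quantity-like outcomes, minus a dip at S6/S7 (the
WMZ) and plus Gaussian noise (SD 0.5). The printed schedule fixes S5–S8
(17:30, 20:00, 23:00, 02:40+24 h); S1–S4 times (03:00, 07:00, 10:30,
14:00) are the package's own choice of a plausible spread over the 24 h
wake period, and wake onset is 02:30.

What the generators do **not** emulate: volume conduction and realistic
scalp topographies, artifacts (eye movements, muscle), non-stationary 1/f
exponents, pupil light reflexes, and circadian (as opposed to homeostatic)
modulation. Passing tests therefore demonstrate algorithmic correctness
under the stated statistical structure, not end-to-end performance on raw
laboratory recordings, which additionally need artifact rejection upstream.

## Numerical choices and degenerate inputs

* Zero-crossing and peak ties break to the earliest sample; all span
  logic is half-open `[start, end)`.
* Constant or all-positive signals yield empty crossing lists, not errors;
  empty bands report `NA`; a zero-spread paired test is flagged degenerate
  rather than returning infinite *t*.
* Filter designs are cached per (band, rate, spec) — they are
  deterministic — and audited on a 0.05 Hz grid plus the edge frequencies.
* Problem sizes in the shipped tests: 100-replicate oracle comparisons for
  the per-cycle criteria, run formation, trimming, BH-FDR and paired
  tests; a single-seed SNR-5 validation fixture (~70 s × 3 channels);
  200 replicates for WMZ dip recovery and 10 000 for its type-I error;
  1 000 seeds for the oddball invariants. These sizes give Monte-Carlo
  standard errors comfortably inside the asserted tolerances.

## Limitations

* Not suited to single isolated waves (local sleep events): four regular
  cycles are a hard floor.
* Single-channel precision against 1/f noise is bounded by the
  shape-criteria false-alarm rate; use multichannel recordings and the
  aggregation stage when quantity estimates matter.
* Filter-edge zones (~2–5 s per band at 250 Hz) are excluded; very short
  recordings lose a meaningful fraction of their span.
* The px→mm pupil calibration sacrifices individual iris-size differences
  by design; absolute diameters are comparable within, not between,
  participants.
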