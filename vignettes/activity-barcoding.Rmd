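---
title: "Activity barcoding, pattern complexity, and capacity-performance analysis"
author: "pabarcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity barcoding, pattern complexity, and capacity-performance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Clinical assessments of children with cerebral palsy measure *capacity* —
what a child can do at best in a standardized setting, typically summarized
by the GMFM-66 score (0–100, higher = less impaired). What the child
actually does all day in their habitual environment — *performance* — is a
different construct, and the two need not agree. `pabarcode` implements a
multidimensional performance measurement from five synchronized body-worn
IMUs (trunk, both thighs, both shanks; triaxial accelerometer in g and
gyroscope in deg/s at 100 Hz), and the cohort statistics used to relate
performance to capacity.

The pipeline has five stages, each usable on its own:

1. **Detection** — postures from the gravity component of trunk and thigh
   acceleration; walking from shank pitch angular velocity.
2. **Barcoding** — the day becomes a sequence over 22 symbolic states
   combining activity type, bout duration and intensity.
3. **Complexity** — the barcode is scored for variety and temporal
   structure (Hn, SampEn, LZC) and combined with overall activity volume
   (CC, CDS).
4. **Physical activity states (PAS)** — a 6-level clinical reduction with
   time fractions and achiever flags.
5. **Cohort analysis** — Spearman/Holm correlation families, age-partialled
   correlations, and achiever/non-achiever ROC with Youden-optimal GMFM-66
   cut-offs.

A seeded synthetic cohort generator stands in for clinical recordings so
that every stage is testable end to end.

## Detection model and its parameters

**Walking.** Steps are mid-swing positive peaks on the band-passed
(0.5–5 Hz Butterworth, zero-phase) pitch angular velocity of the shanks,
above a threshold of 50 deg/s and separated by a 0.25 s refractory period
(the spacing implied by a ceiling cadence of about 240 steps/min). Left and
right detections within 0.12 s of each other are treated as one step, which
tolerates single-sided dropout. Consecutive steps with gaps of at most
2.0 s form a candidate episode; episodes of fewer than **4 consecutive
steps are discarded** — this hard minimum defines a walking bout. Bout
duration is the first-to-last-step span plus half a mean step period at
each end, and cadence is `n_steps / duration * 60`. The upstream detector
publications do not list working parameters, so all of these are declared
engineering defaults, configurable in `detection_params()` and echoed in
the run metadata.

**Postures.** Each 1 s non-walking epoch is labeled *standing* when both
the trunk and at least one thigh gravity vector lie within 40 degrees of
vertical, otherwise *lying/sitting*. Sitting and lying are deliberately
never distinguished: a vertical trunk over a horizontal thigh (sitting
geometry) and a fully horizontal body map to the same merged class, which
is also the class the barcode uses. The 1 s epoch is the finest resolution
the 100 Hz recordings comfortably support and matches the barcode epoch.

**Intensity.** Static-segment intensity is the mean Euclidean norm of the
per-axis mean-subtracted trunk acceleration over the segment. For a pure
sinusoidal body motion of amplitude *a* this converges to *2a/π*; for a
noise-free static posture it is exactly zero. White sensor noise inflates
the estimate by a small noise-floor term (about `sd * sqrt(8/pi)` for
three-axis Gaussian noise), which matters only for segments whose true
intensity sits within about 0.002 g of a classification edge.

**Axis auto-calibration.** Sensors are mounted with arbitrary orientation,
so the functional axes are recovered from the data: the vertical is the
mean accelerometer direction over *movement* (gait) windows — gait is the
one context in which posture is unambiguously upright, whereas still
windows are useless because a seated thigh is static but horizontal — and
the dominant movement axis (pitch, for the shanks) is the first principal
component of the gyroscope over the same windows, orthogonalized against
the vertical, with sign fixed so swing peaks are positive. The rotation is
orthonormal, so signal magnitudes are preserved sample by sample. A
recording without movement cannot be oriented and is a hard error rather
than a silent guess.

## The 22-state barcode and the 6 PAS

A segment is classified once, using its full duration, and its state is
written into every 1 s epoch it covers (split epochs go to the
majority-overlap segment):

| Mode | Duration (s) | Intensity | States | PAS |
|---|---|---|---|---|
| Lying or sitting | — | body accel: low / moderate | 1–2 | 1 |
| Standing | — | body accel: low / moderate / high / very high | 3–6 | 2 |
| Walking or running | short [0, 60) | cadence: <70 / 70–100 / 100–130 / >130 | 7–10 | 3 |
| | medium [60, 120) | same four bands | 11–14 | 4 |
| | long [120, 360) | same | 15–18 | 5 |
| | very long [360, ∞) | same | 19–22 | 6 |

Two bin conventions are worth making explicit. The printed duration labels
("<60", "61–120", "121–360", ">360") read literally would leave 60–61 and
120–121 unassigned; the implementation uses contiguous half-open bins
[0,60), [60,120), [120,360), [360,∞) so the classifier is total. Cadence
bins are likewise half-open with the upper edge exclusive: [0,70), [70,100),
[100,130), [130,∞) steps/min. Second, the body-acceleration thresholds that
separate the static intensity classes are not published anywhere; the
defaults (lying/sitting split at 0.04 g; standing splits at 0.04, 0.10 and
0.20 g) are actigraphy-scale conventions, configurable in
`barcode_params()` and recorded in output metadata. They affect states 1–6
only; the PAS, which collapse intensity, are insensitive to them except
through the lying-vs-standing posture decision, which does not use them at
all.

PAS time fractions are epoch counts over total epochs, in percent.
`%activity` is time in states 3–22 — everything except lying/sitting, so
standing counts as activity. A subject is an *achiever* of a PAS when the
accumulated epoch count in it is nonzero (an exact integer test; rounding a
printed percentage to zero never demotes an achiever).

## Pattern-complexity metrics

All three metrics are computed on the per-epoch (1 Hz) symbol sequence —
the same object the barcode stripe visualizes — not on the per-event
sequence; the epoch length therefore affects the values and is always
logged.

- **Hn** — Shannon entropy of the state histogram divided by `log(22)`.
  The alphabet is fixed at the 22 design states rather than the states a
  subject happens to visit, so a child who only lies and sits scores near
  zero and values are comparable across subjects.
- **LZC** — the LZ76 exhaustive-history phrase count `c(n)` (number of new
  sub-patterns discovered scanning the sequence once), normalized as
  `c(n) * log_22(n) / n` and clamped to [0, 1]. A constant day parses into
  2 phrases; i.i.d. uniform sequences over the full alphabet approach 1.
  The phrase counter is implemented in C++ (day-long sequences make a pure
  R parse impractical) and is checked exhaustively against a brute-force
  definitional parser for every sequence of length ≤ 12 over a 3-symbol
  alphabet.
- **SampEn** — sample entropy with template length m = 2 and *exact* symbol
  matching, since a similarity tolerance is meaningless for categorical
  symbols: `-log(A/B)` with B the matching m-template pairs and A the
  matching (m+1)-template pairs, self-matches excluded. The unbounded value
  is mapped to [0, 1] by the finite-sample ceiling `log(B)` (the value
  attained when a single template pair survives to length m+1); if no pair
  survives (A = 0) the value is capped at that ceiling, i.e. 1. Constant
  and strictly periodic sequences score exactly 0. This normalization is a
  declared convention — published norms for symbolic SampEn differ between
  sources — so numerical equality with other software is not claimed, and
  the rule is flagged in output metadata.

The composites are `CC = Hn + SampEn + LZC` (range 0–3) and
`CDS = CC * %activity` with `%activity` on the 0–100 scale, which puts
daily CDS values in the single-digit-to-tens range familiar from clinical
tables. Degenerate inputs (empty barcodes, sequences shorter than the
template requirements) are hard errors, never silent zeros.

## Cohort statistics

Descriptives are medians with type-7 (linearly interpolated) quartiles, per
GMFCS level and overall. Normality is screened with a one-sample
Kolmogorov–Smirnov test against a normal with estimated moments; the
screen is advisory only, because the pipeline stays nonparametric
throughout. (Whether estimated moments call for a Lilliefors correction is
left open deliberately; the screen never gates anything.)

The correlation battery tests GMFM-66 against two separately
Holm-corrected families reflecting two constructs: **seven PAS variables**
(PAS 1–5 plus the grouping variables PAS 3–6 and PAS 4–6) and **four
complexity variables** (Hn, SampEn, LZC, CDS). PAS 6 is not in the default
family: in a small cohort almost nobody achieves very long bouts, and any
variable with fewer than two distinct nonzero values is excluded as `N.A.`
without consuming a Holm slot. Spearman p-values use the t approximation
for n ≥ 10 and the exact permutation null below that. Bands on |rho| are
fixed at [0, 0.25) no to little, [0.25, 0.50) fair, [0.50, 0.75) moderate
to good, [0.75, 1] very good to excellent. Variables nominally correlated
with age are re-examined with a rank-scale partial correlation controlling
for age (t reference with n − 3 degrees of freedom).

For each PAS with both classes present, ROC analysis asks how well the
capacity score separates achievers from non-achievers. **Positives are the
non-achievers** and the prediction rule is "non-achiever if score <
threshold". AUC is the rank statistic; because the cohorts of interest are
small (n ≈ 25), its difference from 0.5 is tested with a seeded label
permutation test (default 10,000 permutations) rather than an asymptotic
approximation. Candidate thresholds are the midpoints between adjacent
distinct observed scores; the reported cut-off maximizes the Youden index
(sensitivity + specificity − 1), ties broken toward the lower threshold
(within a 1e-9 tolerance, so floating-point noise cannot flip a tie). The
cut-off, with its sensitivity and specificity, is reported only when the
AUC differs from chance at the chosen alpha (0.05 throughout).

## What the synthetic generator emulates — and what it does not

The generator produces one continuous school-day recording per subject
(default 33,840 s ≈ 9.4 h, no non-wear gaps), a cohort stratified by GMFCS
level (default weights 13:4:8 with capacity centers 88/75/57 and
truncated-normal spread), and a semi-Markov day: log-normal sedentary
(median ≈ 7 min) and standing (median ≈ 1.3 min) segments, Poisson bursts
of walking bouts with log-normal durations truncated below 120 s
(median 25 s), and per-bout cadence normal around a capacity-linked mean
near 100 steps/min. Because baseline bouts never exceed 120 s, walking
bouts longer than 120 s (the doorway to PAS 5) and 360 s (PAS 6) arise
only from explicit achievement draws whose probabilities are logistic in
GMFM-66 — located at 75 and 87 points with a 3-point scale by default — so
the ROC stage has a clean, recoverable ground truth without claiming any
published cut-off as truth. Age is uniform on 7–20 years with a mild
negative effect on bout rate, giving the partial-correlation stage
something real to remove. All randomness flows from one master seed
through per-subject derived streams.

Rendered IMU signals encode posture as a per-segment gravity orientation
(upright segments tilt about 5 degrees from vertical, seated thighs about
82 degrees; 70% of sedentary segments are rendered as sitting with a
vertical trunk, 30% as lying), body motion as a sinusoid whose rectified
mean equals the segment's drawn intensity, and each step as one synthetic
mid-swing pulse at the segment's cadence. The two shank channels carry
redundant copies of the step train — physiologically each shank swings
every other step, but the simplified renderer exposes every step on both
sides and the detector deduplicates near-simultaneous contralateral
events. Sensor noise defaults (0.002 g, 0.5 deg/s per axis) are typical
post-calibration MEMS figures.

The generator does **not** emulate pathological gait kinematics,
spasticity, assistive devices, sensor misplacement drift, non-wear, or
barometric data. Passing round-trip tests therefore shows that the
detection and barcoding chain inverts *this* renderer under realistic
noise — boundary epochs, cadence values near a bin edge, and intensities
near a threshold are the honest failure modes, and they are why round-trip
agreement is asserted at 95%, not 100% — but it cannot certify performance
on clinical recordings, for which no public reference data exist.

## Numerical choices and degenerate inputs

- Epoch assignment uses true majority overlap, not midpoint membership, so
  sub-epoch segments are handled correctly.
- A timeline must tile its day exactly; gaps and overlaps are hard errors
  (`validate_timeline()`), as are walking segments with fewer than 4 steps.
- A detected walking bout truncated by the day boundary below 4 steps is
  relabeled standing rather than kept as an invalid bout.
- Quartiles are type 7; changing the convention changes IQRs on small
  cohorts, so the choice is recorded in run metadata.
- The Spearman permutation null is enumerated exactly below n = 10
  (cached factorial tables), which keeps tiny-cohort p-values honest at
  the cost of memory above n ≈ 9 — hence the t approximation from n = 10.
- `roc_cutoff()` with degenerate labels (one class) is an error; the
  battery wrapper skips such PAS instead of fabricating an AUC.

## Problem sizes used by the shipped checks

The test suite exercises the full chain at reduced, fixed sizes chosen to
keep a complete run on one CPU comfortable while leaving every mechanism
intact: round-trip detection uses ten 30-minute days (the mechanism is
per-segment, so day length only scales segment counts); parameter recovery
uses 50 linked and 50 null cohorts of n = 200 full-length (9.4 h)
timelines analyzed at the PAS level; the complexity bound checks use 1,000
random barcodes of lengths 100–3,000 in the suite and 100–10,000 in the
acceptance script. These sizes are the package's own reproducibility
settings, not statements about the method's limits.

## Known limitations

- The static-intensity thresholds and the SampEn normalization are declared
  conventions; absolute values of states 1–6 occupancy and of SampEn are
  therefore not comparable across software, only within a configuration.
- Calibration requires gait somewhere in the recording; a fully sedentary
  day cannot be oriented and must be processed with pre-calibrated axes.
- Cadence is the only gait intensity measure; no spatial parameters.
- The ROC cut-offs inherit all small-sample caveats of Youden-optimal
  thresholds; the permutation test guards the AUC, not the cut-off's
  sampling variability.
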