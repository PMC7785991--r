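---
title: "Methods: simulation, detection and scoring conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, detection and scoring conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfecg)
```

This vignette records the modeling and algorithmic decisions behind
`zfecg`, in enough detail that every number the package produces can be
traced back to a stated convention.

## The generative model

### Rhythm

Baseline interbeat (P-P) intervals are drawn i.i.d. from a normal
distribution with the configured mean and SD, truncated below at half the
mean. Truncation prevents nonphysically short intervals; it also means
the realized moments differ slightly from the nominal parameters. For a
lower truncation at $a$, with $\alpha = (a-\mu)/\sigma$ and hazard
$\lambda = \phi(\alpha)/(1-\Phi(\alpha))$, the realized mean is
$\mu + \sigma\lambda$ and the realized variance
$\sigma^2(1 + \alpha\lambda - \lambda^2)$. Parameter-recovery tests in
the package compare detector estimates against these analytic moments,
not against the nominal inputs. At the wildtype defaults
(mean 0.52 s, SD 0.074 s) the correction is negligible; at mutant SDs
(0.135–0.148 s) it shifts the realized SD by several percent.

### Sinus-arrest injection

Sinus-arrest episodes arrive as a Poisson process in recording time at
`sa_rate_per_min`. Each onset converts the interval beginning at the
first beat at or after it into a pause drawn uniformly from
`[sa_pause_min_s, sa_pause_max_s]` (defaults 1.43–3.0 s: safely above the
1.3 s definitive cutoff, well below the recording length). After every
injected pause the next interval is also replaced with probability
`p_consecutive`, which produces geometric runs of consecutive episodes.
Modeling the onsets as a process in time (rather than picking interval
indices) keeps the realized episode rate tracking the nominal rate even
though pauses themselves consume recording time. One loss remains by
construction: a pause that begins within roughly one pause-length of the
recording end cannot complete inside the trace, so its interval is
truncated away. Over one-minute recordings at 1.6 episodes/min this
biases realized rates a few percent low — visible only as a small,
quantified offset inside the Monte-Carlo tolerances of the tests.

The `class_ii_config()` preset reaches its ≈1.6 pause intervals/min as
1.2 injected onsets/min extended with `p_consecutive = 0.25`
(expected run length $1/(1-0.25) = 4/3$).

### Morphology

Each beat is a sum of five Gaussian bumps: P, Q, R, S, T. Conventions:

* the R bump SD is set so the complex falls to 10% of the R peak at
  $\pm$`qrs_duration_s`/2 — the same 10%-of-peak rule the QRS delineator
  applies, which is what makes the configured duration recoverable by
  measurement;
* the P bump's full width at half maximum is `qrs_duration_s`/2;
* Q and S are −12% of R, at $\pm 0.28 \times$`qrs_duration_s`, with half
  the R width. Because their tails leak slightly into the R center, the R
  bump is scaled up by the analytic leak factor so the rendered peak
  equals `r_amp_mV` exactly;
* a broad low T bump follows the QRS.

`qrs_suppression` scales the whole Q/R/S triplet; the Class II preset
uses 0.1 with doubled white noise, which drives the QRS below the
detectability criteria of `classify_ecg()`. White noise and sinusoidal
baseline wander are added under a seed derived from the schedule seed, so
rhythm and rendering are independently reproducible.

## Detector design

The fiducial measurements this package automates are conventionally done
by hand on acquisition software; there is no canonical algorithm to
reproduce. All mechanics below are therefore this package's decisions,
tuned once against the simulator's ground truth at default noise and then
frozen. Everything is threshold-relative (multiples of rolling medians or
MADs), making fiducial times invariant under amplitude rescaling.

### QRS

`detect_r_peaks()` band-passes at 5–40 Hz, squares the derivative, and
smooths it into an energy envelope. The threshold is 4× the rolling
median of the envelope, floored at 5% of its 95th percentile. Within a
150 ms window after each qualifying crossing, the **latest** envelope
lobe reaching at least 40% of the window maximum marks the complex: the
QRS always follows the P wave, while a strongly suppressed QRS stays
below the 40% gate so the P lobe wins — and those bogus R-at-P detections
are subsequently discarded by the pairing rule, which is exactly what
routes severe recordings to the P-only pathway. The R time is refined to
the raw-signal maximum within 25 ms, and the refractory period
(0.4× the running median interbeat interval) is enforced on the refined
time. Amplitudes are peak minus a local isoelectric baseline (median of
the raw signal 150–200 ms before the peak).

### P waves

P detection runs on a dedicated signal: a 0.7 Hz high-pass (removing
wander), an 8 ms moving average (damping noise while leaving the ~11 ms
SD P bump essentially intact), re-referenced by subtracting a 0.45 s
rolling median so peak heights compare against the local isoelectric
level. A plain low-pass was rejected here: it attenuates this species'
very narrow P wave and lets QRS-band ringing dominate.

With R anchors, the P is the interior maximum of that signal in
[r − 0.15 s, r − 0.03 s] provided it clears 4× the rolling MAD. Without
anchors (standalone mode), peak picking with the same threshold applies a
0.25 s refractory — deliberately **below** the generator's 0.26–0.27 s
shortest possible interval, because a refractory above it merges genuine
consecutive beats at mutant interval SDs. Accepted P indices are finally
refined on a symmetrically smoothed copy of the raw trace, which removes
the sample-level bias the high-pass introduces and recovers noiseless
intervals to within one sample.

### Delineation, pairing, classification

`delineate_qrs()` walks outward from R until the deviation from the local
baseline stays below 10% of the R height for at least 4 ms; beats whose
search hits the window edge are flagged `NA` and excluded from duration
averages. `assemble_beats()` pairs each P with the first R whose lag lies
in (0.01, 0.2) s; unpaired P waves become QRS-less beats and unpaired R
detections are discarded with a warning. `classify_ecg()` calls a
recording Class II when fewer than half its beats carry a QRS, when no
mean R amplitude exists at all, or when that amplitude fails to clear 3×
the noise floor (MAD of the band-passed trace outside detected beats).

## Metric and scoring conventions

* **Heart rate** is defined as 60 / mean P-P, so
  `hr_bpm * mean_pp_s == 60` holds exactly. Acquisition software may
  count a different beat stream and report a slightly different rate;
  this package always reports the P-derived value.
* **PR interval** is measured P peak → QRS onset. Onset-to-onset
  conventions give values too long to be compatible with a ~33 ms
  wildtype PR at this species' rates.
* **Interval SD** uses the sample (n−1) denominator.
* **Group tables** average per-recording indices, never pooled beats —
  one fish, one value. A consequence worth noting: the ratio of group
  mean amplitudes need not equal the group mean of per-fish ratios.
* **P/R ratio** is mean P amplitude over mean R amplitude (values below 1
  for a healthy trace). The inverse labeling sometimes seen elsewhere is
  not used here.
* **Long-beat flags** use the within-recording mean + 2 SD.
* **Sinus-arrest cutoffs**: the definitive cutoff is derived as a fold
  change (default 2.5×) over the normal mean interval — 0.52 s × 2.5 =
  1.3 s — and a 1.0 s screening list is reported alongside without
  entering prevalence. Each long interval counts as exactly one episode
  regardless of length.
* **Consecutive episodes** are counted as maximal runs of ≥ 2 adjacent
  episode intervals, one run = one incidence (the default); counting the
  member episodes instead is available via `consecutive_unit =
  "episodes"`. The per-minute unit is genuinely ambiguous in common
  usage, hence the switch.
* **Cohort frequencies** are per-fish-then-mean: each fish's per-minute
  rate is computed on its own recording before averaging, so short
  recordings are not over-weighted.
* **Statistics**: the group comparison is the classical pooled-variance
  Student t-test (Welch behind `welch = TRUE`); no multiple-testing
  correction is applied to the index table, deliberately. qPCR relative
  expression uses 2^(−ΔΔCt) with per-sample ΔCt; chamber comparison is
  the plain ventricular/atrial surface-area ratio (e.g. 1.865/0.668 ≈
  2.79 — reported as the ratio itself, never as a rounded "fold"
  narrative).

## Problem sizes

The default cohort (14 wildtype, 9 Class I, 5 Class II, one minute per
fish at 1 kHz) and the three presets' parameter values are this package's
choices for a realistic working scale: a regular ~115 bpm wildtype rhythm
with SD 0.074 s; a Class I mutant at mean 0.539 s, SD 0.103 s, weakened
R (0.063 mV) with prolonged PR (0.050 s) and QRS (0.0721 s); a Class II
mutant at SD 0.148 s with ≈1.6 pause intervals/min and a suppressed QRS.
Acceptance-style checks in `tests/testthat/test-acceptance.R` pin the
desk-scale arithmetic (cutoff construction, rate/interval conversion,
prevalence percentages, genotyping fragment lengths, ΔΔCt) and one
stochastic end-to-end recovery of the Class II episode frequency through
the full pipeline; `scripts/acceptance.R` runs the latter standalone.
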