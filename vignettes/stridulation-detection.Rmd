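---
title: "Detecting scarab larval stridulations with fractal dimension analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting scarab larval stridulations with fractal dimension analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stridfd)
```

## The problem

Root-feeding larvae of *Melolontha melolontha* and *M. hippocastani*
(white grubs) are serious agricultural and forest pests, but they live
invisibly in soil for years. Unlike their incidental moving and feeding
sounds, their *stridulations* — actively produced trains of short tonal
sound bursts — are species-specific, which makes them attractive for
non-invasive, species-level acoustic monitoring with buried sensors.
Manual listening does not scale to continuous recordings, so `stridfd`
implements an automated routine that pinpoints candidate stridulations in
mono 44.1 kHz WAV recordings and summarises per-file stridulation activity
semi-quantitatively.

## The method

**Preprocessing.** Each recording is bandpass filtered to 200–5000 Hz,
DC-centred, and peak-normalised to −1.0 dB. Normalisation is cosmetic for
the detector — every statistic downstream is amplitude-scale-free — but
standardises files for listening and plotting.

**Sections and frames.** The waveform is sliced into contiguous 2-s
sections (*sc*, 88 200 samples; a trailing partial section is dropped, not
padded, because padding would bias the roughness statistics). Each section
is tiled twice with non-overlapping frames (*f*) of nominally 88.2 samples
(2 ms) and 176.4 samples (4 ms). Because 88.2 is not an integer, frame
boundaries are placed at `round(i * 88.2)`; frames are then 88 or 89
samples long, the grid never drifts, and a section holds exactly 1000
(2 ms) or 500 (4 ms) frames.

**Madogram fractal dimension.** For each frame the madogram — the
first-order absolute-increment variogram

$$V(\ell) = \frac{1}{2(n-\ell)} \sum_{t=1}^{n-\ell} |x_{t+\ell} - x_t|$$

is evaluated at lags $\ell \in \{1, 2\}$, and the fractal dimension is
$D = 2 - \hat\beta$ with $\hat\beta$ the OLS slope of $\log V(\ell)$
against $\log \ell$. Smooth, tone-like frames give $D$ near 1; rough,
noise-like frames approach 2. $D$ is exactly invariant under amplitude
scaling, which suits the low and variable signal-to-noise ratios of soil
audio. A frame with any $V(\ell) = 0$ (digital silence) is assigned
$D = 1$ and flagged; we experimented with larger lag sets and found they
only increase the estimator's frame-to-frame variance at these frame
lengths, so `{1, 2}` is the default and remains configurable.

**Fractal distance and SFD.** Within each section, $D$ is standardised
robustly:

$$FD_f = \frac{D_f - \mathrm{median}(D_{sc})}{\mathrm{md}(D_{sc})},$$

where md is the raw median deviation from the median (no normal-consistency
factor — the robust analogue of a z-score denominator is deliberately
unscaled). The 4 ms series (500 points) is linearly interpolated to the
2 ms grid (1000 points; endpoints aligned on the normalised index
$[0, 1]$) and the two series are summed into the *summed fractal distance*
(SFD). Stridulation pulses are far smoother than the ambient noise floor,
so both series dip strongly negative at pulses and the sum separates them
further from background. If md $= 0$ in either series the section is
flagged degenerate and excluded — outlier detection is meaningless without
dispersion.

**Detection.** Three filters turn SFD into events:

1. *Vertical threshold*: frames with SFD strictly below −4.0 are
   candidates. Ties at exactly −4.0 are excluded.
2. *Run-length filter*: maximal runs of adjacent candidates longer than 2
   frames are discarded entirely — movement sounds and interference
   produce wide excursions, stridulation pulses 1–2-frame-wide peaks. Each
   surviving run is collapsed to its first frame, one peak per pulse.
3. *Interval clustering*: intervals (TI, in frames) between consecutive
   peaks are computed within sections only. Maximal groups whose internal
   gaps are all strictly below 10 frames and that contain at least two
   peaks are stridulation events; lone surviving peaks are reported in a
   separate single-peak category rather than as events.

**STRAC.** Per file, stridulation activity is
$\mathrm{STRAC} = \sum_{k=1}^{10} k\,n_k$ with $n_k$ the frequency of
interval value $k$ (inclusive of 10). STRAC is a semi-quantitative
activity proxy, not an event count. By default the TI histogram uses the
intervals between all surviving peaks in a section; a switch restricts it
to intervals inside clustered events (the two differ only in the histogram
tail, which STRAC ignores).

The clustering gap (strict $< 10$) and the STRAC cap (inclusive $\le 10$)
are kept as independent settings on purpose: they encode different
phrasings of the routine and can be varied separately.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `low_hz`, `high_hz` | 200, 5000 | Hz | analysis band |
| `hp_order`, `lp_order` | 4, 2 | — | filter steepness per edge (see below) |
| `peak_db` | −1.0 | dBFS | normalisation target |
| `section_seconds` | 2 | s | robust-statistics window |
| `frame_ms` | 2, 4 | ms | frame durations (88.2 / 176.4 samples) |
| `lags` | 1, 2 | samples | madogram lag set |
| `sfd_threshold` | −4.0 | md units | vertical threshold (strict `<`) |
| `max_run` | 2 | frames | widest surviving excursion |
| `max_gap` | 10 | frames | within-event spacing bound (strict `<`) |
| `strac_k_max` | 10 | frames | largest interval in STRAC (inclusive) |

## The filter design

The two band edges are deliberately asymmetric. The high-pass is a steep
4th-order Butterworth (applied forward–backward): low-frequency rumble
from sensor handling, machinery and mains is by far the strongest
contaminant and must go. The low-pass at 5 kHz is a gentle 2nd-order slope
(24 dB/oct after the double pass), comparable to the default slopes of
common audio editors.

The gentle upper edge is not an accident but a requirement of the
statistic. At lags of 1–2 samples and 44.1 kHz, a frame's madogram
roughness is dominated by the highest frequencies present. A steep
zero-phase low-pass acts as a *roughness equaliser*: every broadband sound
collapses onto practically the same $D \approx 1.045$, the section's md
shrinks to the estimator's own sampling noise (≈ 0.010), and the −4.0
threshold then sits inside the estimation-noise tail of every single
section — detection degenerates to flagging noise everywhere. With a
gentle slope, the residual high-frequency shoulder (5–8 kHz) keeps
broadband background genuinely rougher than tonal stridulation pulses and
preserves real differences in roughness between background states. The
cost is a small out-of-band residual (a few percent of total energy for
broadband input, concentrated just above 5 kHz), which is immaterial to
the detector and to listening.

## The synthetic-data generator

Field recordings are large and not redistributable here, so the package
ships a seeded scene generator used by the entire test suite.

**Stridulations.** The common type is a train of raised-cosine-windowed
tone bursts at 1700 Hz. Pulse duration defaults to 4 ms with a 12 ms gap:
on the 2 ms analysis grid this reproduces the reported signature of real
stridulations — threshold peaks 1–2 frames wide, spaced 2–10 frames
apart. (A pulse much longer than 4 ms would span 3+ frames and be removed
by the routine's own run-length filter; real pulses evidently are not.)
Train length is 150 ms (the *M. hippocastani* preset; the *melolontha*
preset doubles it). The rare type is 4 repeated ~250 ms patterns at
3000 Hz separated by 80 ms. Timing jitters by ±1 ms and pulse amplitude
by ±20% per pulse. Pulse timbre is deliberately simple (one carrier, no
harmonic stack or soil dispersion).

**Incidental sounds.** Movement is a broadband scrape (band-limited noise
under an irregular envelope, hundreds of ms); feeding is a < 20 ms damped
click. Both are rougher than stridulation pulses, which is exactly why
the routine must and does reject them.

**Background noise.** The default `"soil"` background is a pink ambient
bed plus a small wideband sensor hiss plus a high-band (5.5–12 kHz)
crackle component whose amplitude flutters quasi-periodically (≈ 12 Hz
with slowly wandering phase). This emulates a property of real
buried-sensor recordings that turns out to be essential for the published
detection logic: the background's *roughness is heterogeneous in time*.
The flutter gives the per-frame $D$ genuine dispersion (md well above the
estimator's sampling noise) while its smoothness dips are shallow, brief
(wide threshold runs are removed by the run filter) and spaced ~40 frames
apart (they cannot cluster into events). Uniformly rough digital noise —
`"white"` or `"pink"`, both also available — lacks this heterogeneity:
for any i.i.d.-roughness background the md collapses to estimation noise
and the minimum SFD of a 1000-frame section lands near −7 *regardless of
the noise level*, so a −4.0 threshold flags every section. That is a
mathematical property of the robust standardisation, not an artefact of
this generator; it implies the routine's real-world performance depends on
background heterogeneity, and passing tests on `"soil"` scenes should be
read as evidence about recordings with comparably structured noise, not
about arbitrary backgrounds.

**SNR convention.** A scene's `snr_db` (default 20) is the ratio of
stridulation-segment RMS to the in-band (200–5000 Hz) RMS of the noise
floor. Incidentals are injected at 10 dB. Stridulations are placed
uniformly at random without mutual overlap; annotations record every
event's support, kind and seed, and are exact by construction.

## Numerical choices and degenerate inputs

* Frame boundaries by `round()`; with frame sizes 88.2/176.4 no half-way
  ties ever occur.
* Degenerate frames ($V(\ell) = 0$): $D := 1$, flagged. Degenerate
  sections (md $= 0$): SFD $:= 0$, excluded from detection, tallied in
  the report.
* All inequalities at the threshold and the cluster gap are strict; the
  STRAC cap is inclusive. Each is configurable.
* Interpolation aligns endpoints on a normalised index; frame-centre
  alignment would shift everything by less than half a frame and was
  rejected as unneeded complexity.
* Recordings not at 44.1 kHz are refused unless explicitly allowed, in
  which case frame sizes are derived from the 2/4 ms durations.

## Validation problem sizes

The test-suite and acceptance computations run at desk scale: estimator
checks use 200 replicates of 1024-point white-noise and fractional
Brownian motion series ($H \in \{0.2, 0.5, 0.8\}$, exact
Cholesky-embedded simulation); detection calibration uses 50 seeded 20-s
scenes (sensitivity of stridulation-bearing sections and the flag rate of
noise-only sections); STRAC behaviour uses 10 scenes of 60 s per injected
count in $\{0, 4, 8, 16\}$ for monotonicity and 20 five-minute scenes
with 4–40 stridulations for the count–STRAC regression.

## Limitations

* The routine does not count stridulations; STRAC is a rank-preserving
  activity proxy and detected sections are meant to be verified by ear.
* Performance depends on the real background's roughness structure;
  heavily tonal interference or noise as smooth as the stridulation
  carrier will defeat the robust threshold.
* The 3000 Hz rare stridulation type sits closer to the background's
  roughness floor than the 1700 Hz common type; at the default 20 dB SNR
  its pulses are only partially detected. The generator produces it
  faithfully, but the shipped defaults are tuned to the common type, as
  in the original routine.
* The exact filter shape of the original study's audio-editor
  preprocessing is unknown; behaviour near the band edges may differ from
  the original analysis.
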