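---
title: "Localizing and assigning mouse ultrasonic vocalizations with a compact phased array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing and assigning mouse ultrasonic vocalizations with a compact phased array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(usvloc)
```

`usvloc` answers "which mouse emitted this call?" for home-cage recordings
made with a compact square four-microphone array next to an overhead camera.
This vignette explains the model behind each stage, the parameters that
matter, what the simulator does and does not emulate, and the numerical
choices made where the design was open.

## The physical model

Coordinates are metres in the camera frame: origin at the optical centre,
x along image columns, y along image rows, z along the optical axis toward
the cage floor. The defaults encode the recording rig the package targets:

* **Microphone array**: a square of side 8 mm, centred 54 × 9 mm laterally
  and 6.5 mm in front of the optical centre (`mic_array()`).
* **Camera**: 640 × 480 pixels, 70° × 55° field of view, modelled as an
  ideal pinhole (`camera_model()`). The rig specifies only resolution and
  field of view, so focal lengths derive from the FOV and lens distortion is
  taken as zero.
* **Floor depth** `floor_z = 0.25` m: sound sources are assumed to lie on
  the cage floor, so one camera suffices to map pixels to 3-D positions.
* **Speed of sound** `c = 346` m/s (air at ~25 °C, matching typical housing
  temperature). Config-exposed, as the true value depends on temperature.

At 0.25 m depth one pixel spans ≈0.55 mm on the floor and one 5 × 5-pixel
beamforming bin ≈2.7 mm.

## Segmentation

The front end mirrors the established multitaper segmentation approach for
rodent USVs: 512-point FFT, 0.5 ms hop, K = 3 Slepian tapers (computed from
the tridiagonal eigenproblem in `dpss_tapers()`). Averaging tapered
periodograms lowers the variance of the noise floor, which is what makes a
fixed detection threshold workable. Each frame's log-spectrum is then
flattened by cepstral liftering: the lowest 12 cepstral coefficients (an
envelope resolution of ≈16 kHz on the 257-bin spectrum) are removed, and
the grid is referenced to its median floor. The cutoff was chosen once so
that a smooth 25 dB broadband tilt flattens to within ±1 dB across the
30–120 kHz analysis band while 1–2-bin tonal ridges pass through
untouched; the upstream tool's exact value is not published, so the cutoff
is config-exposed. Detection uses local per-frame maxima above
`threshold_sigma` (default 4.5) robust standard deviations of the flattened
grid, keeping only the strongest maximum within a 750 Hz bandwidth.

Peaks become a binary image with 0.5 ms × 750 Hz pixels. Closing (dilate
twice, erode once, 3 × 3 square) connects fragments up to two pixels apart.
Crossing syllables are separated by a Harris-style corner measure on the
closed image: rectangles of 3 pixels (frequency) × 15 pixels (time) are
erased around every corner above `corner_quality` (default 0.25 of the
maximum response), and the erased image's components seed a watershed of
the distance transform of the *pre-cut* foreground (`EBImage::propagate`),
so every original peak keeps exactly one label. Design notes:

* The erase rectangle's long axis runs along time: crossings of
  frequency-modulated contours are extended in time, and a time-elongated
  sliver severs both branches. The orientation is config-swappable.
* The corner quality default was tuned once on a constructed X fixture: it
  fires at crossings of slope ≥ ±1 raster bin per frame (±1.5 MHz/s) but
  not along smooth chirp ridges or straight lines. Shallower crossings
  produce one long junction blob that a 3-pixel-tall erasure cannot sever;
  such near-parallel overlaps are intrinsically ambiguous at this raster.
* Components erased entirely by the cut keep their own label rather than
  vanishing, preserving peak conservation.
* Segments whose time span is ≤ 3 ms are dropped.

Separation is scored by the contamination ratio; on 1,000 simulated
overlapped pairs (random ±20 ms shifts), corner cutting roughly halves the
mean contamination relative to plain connected-component grouping (the
ablation switch `corner_cut = FALSE` is part of the API and test suite).

## Localization

The delay-and-sum beamformer evaluates, for each candidate floor position,
how coherently the four channels add after compensating the expected
per-microphone delays. Normalizing each snapshot to unit energy bounds
`P_norm` in [0, 1/m] with equality exactly when the snapshot phases match
the steering vector, which gives the z-scored spatial spectrum a stable
scale. The spectrum is averaged over a segment's spectrogram peaks only —
the segmentation is what makes beamforming cheap and noise-robust.

Numerical choices:

* Peaks of the z-scored grid are bins equal to their 5 × 5
  maximum-filtered value, using exact float equality; plateaus collapse to
  their centroid bin, ties order by height then row-major position.
* `z ≥ 1.6` retains a peak as a source candidate; a segment with no peak
  `z ≥ 2.3` is unlocalized. A constant grid (zero variance) is unlocalized.
* The 100-pixel margins let sources just outside the image still form
  proper maxima rather than edge artefacts.
* Angular errors are measured from the array centroid; the rig description
  does not fix the reference point, and the centroid is the natural choice
  for a 8 mm aperture.

Spatial aliasing: with an 8 mm aperture, a narrowband call at wavelength λ
produces a near-regular grid of spectrum peaks whose spacing scales like
λ/aperture × depth (≈150–250 mm here) and halves when the frequency
doubles. Frequency-modulated calls average the alias grids of their
component frequencies and keep a single dominant peak; constant-frequency
calls can localize onto an alias, which is why the assignment stage wraps
distances (below) rather than trusting absolute peak positions.

Microphone positions are calibrated by maximizing the summed `P_seg` at the
known snout locations of 20 selected syllables (bounded L-BFGS-B within
±3 mm of the nominal square). The objective depends only on delay
*differences*, so a common translation of the whole array is unobservable
(a gauge freedom); relative geometry is recovered to <0.2 mm from 1 mm
perturbations on clean data.

## Assignment

Candidates are mice whose median-filtered (0.16 s window) snout position
lies within the screening threshold of a spectrum peak; the threshold is
the 99th percentile of snout-peak distances in a single-mouse session, i.e.
the system's own localization + tracking error budget. Zero candidates →
unassigned; one → assigned directly; otherwise the two candidates with the
highest mean beam power are compared peak-by-peak with a two-tailed
Wilcoxon signed-rank test (`stats::wilcox.test`: exact for ≤25 non-zero
differences, normal approximation with continuity correction above,
all-zero differences give p = 1).

The p-value alone is not a precision guarantee: when two snouts are close,
the test confidently prefers whichever snout the tracking jitter happened
to put nearer the beam peak, so the smallest p-values are *enriched* for
confident-but-wrong decisions. The confidence lookup table therefore maps
(p, d′, N_c) to an empirical precision estimated by virtual-mouse
simulation on single-mouse data: N_c − 1 virtual snouts are placed at a
controlled distance from the real mouse (uniform direction, resampled into
the cage), the full decision rule runs, and hits/errors are tallied.
Axes: 20 log-spaced p thresholds (10⁻⁶…1), 5 mm wrapped-distance bins
(0–200 mm), N_c ∈ {2, 3, 4}; precision at a p threshold is cumulative over
trials with observed p below it. Lookups interpolate bilinearly in
(log₁₀ p, d′); cells with fewer than 10 trials are flagged empty, and a
query touching an empty region is resolved conservatively (the lowest
populated neighbour, or unassigned if none). A single combined table is
used rather than per-strain tables. Note that most d′ bins can never
populate: both snouts must sit within the screening threshold of *some*
peak, so d′ is bounded by about twice the threshold except when snouts sit
near different alias peaks — exactly the case the wrapping (d′ = distance
between the snouts' offsets from their nearest peaks) is built to handle.

A segment is assigned only when the tabulated confidence exceeds 0.99. The
realized precision over held-out trials is then consistent with that gate
(≈99–100%), while the *assigned fraction* collapses as inter-mouse distance
shrinks — the method refuses rather than guesses, matching the behaviour
reported for the real system. Segments assigned to one mouse merge with
interleaved unassigned segments across gaps < 30 ms into syllables; an
unassigned segment claimed by two mice's syllables joins only the
nearest-in-time one and the ambiguity is counted. Downstream counting uses
syllables with assignment rate 1.0.

## Squeak (BBV) rejection

Audible broadband squeaks would contaminate assignment, so their time
intervals are excluded. The detector decimates to 38.4 kHz behind an
anti-aliasing low-pass (cascaded Butterworth, 8 poles total, 17 kHz
cutoff — without it a 70 kHz call would fold into the audible band and
trigger falsely, which the tests guard against), forms a 10 ms-window
spectrogram of the channel mean restricted to 2–16 kHz, subtracts
per-frequency then per-time medians (removing steady background and
impulsive broadband noise respectively — a squeak survives both because
its harmonic bands occupy a minority of the band), median-filters 0.5 kHz
along frequency, and thresholds the per-frame maximum at 28 dB above the
flattened floor. The channel-mean input and the dB reference are
config-exposed since the source pipeline leaves both open.

## The simulator and what passing tests mean

`render_scenario()` and `simulate_usv_clips()` render frequency-modulated
syllables (flat, up, down, modulated; 45–80 kHz centre frequencies,
30–80 ms, 5 ms cosine ramps) from point sources on the floor, apply exact
sub-sample delays by frequency-domain phase rotation (integer-sample delays
would quantize the phase surface the beamformer measures), optional
1/distance amplitude scaling, and white Gaussian noise at a stated
peak-signal-to-noise ratio. Validation sessions use 20 dB SNR, 5-pixel
(≈2.7 mm) Gaussian snout-tracking jitter, and sources uniform over a
220 × 150 mm floor area; sessions are rendered as independent short clips,
which keeps memory flat and matches the per-segment nature of every
downstream computation. Problem sizes in the validation suite — 200
syllables for the lookup-table session, 120 for the evaluation session,
2,200 held-out trials, 1,000 overlap pairs — were chosen to give stable
medians and proportions at desk scale.

Deliberately *not* simulated: room reverberation (the real rig suppresses
reflections physically; adding them would degrade localization, so the
synthetic error medians bound the real system's from below), microphone
directivity, mouse body acoustics, and amplitude directivity of real USVs.
Consequently the synthetic localization errors (median ≈0.3°, ≈1 mm) are
far better than the real-recording medians (1.95°, 15.8 mm), and the
acceptance checks treat the latter as upper bounds. Likewise the
assignment precision check validates the *gating logic* — that the
confidence machinery keeps realized precision at or above its 0.99
promise — not the real-world assigned fraction, which depends on tracking
quality and acoustics the simulator idealizes.

## Degenerate inputs and edge rules

* Zero STFT snapshots define `P_norm = 0`; zero-variance spatial spectra
  are unlocalized.
* Missing snout data removes a mouse from candidacy; if no mouse has snout
  data the segment is unassigned with a reason, never guessed.
* Interval intersection for squeak exclusion uses closed intervals.
* Peaks sharing a raster cell map to one pixel but remain distinct points
  in every count.
* All randomness flows through `with_seed()`; rendering the same scenario
  with the same seed is byte-identical, and run logs record seeds and
  parameters.
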