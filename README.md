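# usvloc

Who vocalized? Adult mice converse in ultrasonic vocalizations (USVs,
roughly 30–100 kHz) that carry no visible articulation, so in a group there
is no way to tell by eye which animal emitted a call. `usvloc` implements an
*acoustic camera* analysis for home-cage recordings: a compact square
four-microphone array (8 mm on a side) mounted beside an overhead camera
records four-channel audio at 384 kHz, and the package segments the calls,
localizes each call segment on the cage floor by phased-array beamforming,
and assigns it to an individual mouse with a calibrated statistical
confidence. An acoustic array simulator renders ground-truth recordings so
every stage is testable without hardware.

It is aimed at researchers studying rodent vocal communication and social
behaviour who have (or simulate) synchronized multichannel ultrasound audio,
video-frame timestamps, and per-frame snout coordinates from any video
tracker.

## Method

**Segmentation.** A stable multitaper spectrogram (3 Slepian tapers,
512-point FFT, 0.5 ms hop) is flattened by liftering in the cepstral domain
and per-frame spectral peaks are picked. Peaks are rasterized onto a binary
0.5 ms × 750 Hz image, closed morphologically (dilate ×2, erode ×1, 3×3
square), and syllables that cross in time–frequency are separated by erasing
3 × 15-pixel rectangles at detected corner points and regrouping peaks with a
marker-based watershed. Segments ≤ 3 ms are dropped. Separation quality is
scored by the contamination ratio `(1/N) Σ nᵢ` (minority-source points per
segment over all points).

**Localization.** For a hypothesized floor position `r` with microphone
delays `τⱼ(r) = |r − rⱼ|/c`, the delay-and-sum (Bartlett) steering vector is
`a(r, ω) = [e^{−iωτ₁}, …, e^{−iωτₘ}]ᵀ`, `w = a/(aᴴa)`, and the normalized
spatial spectrum of an STFT snapshot `x(ω, t)` is

    P_norm(r, ω, t) = |wᴴ x(ω, t)|² / ‖x(ω, t)‖²  ∈ [0, 1/m].

A segment's spatial spectrum `P_seg(r)` averages `P_norm` over its
spectrogram peaks `(ωₖ, tₖ)` and is evaluated on 5 × 5-pixel bins over the
camera image plus 100-pixel margins (pixels map to the floor plane through a
pinhole camera model), then z-scored. Local maxima under a 5 × 5 maximum
filter with z ≥ 1.6 are source candidates; a segment with no peak at
z ≥ 2.3 is *unlocalized*. The compact array produces spatially aliased
grids of peaks for narrowband calls; frequency-modulated calls suppress the
aliases by averaging.

**Assignment.** Mice whose tracked snout lies within a screening threshold
(the 99th percentile of single-mouse snout-peak distances) of a spectrum
peak are candidates. With two or more candidates, the per-peak beam powers
at the two best snouts are compared by a two-tailed Wilcoxon signed-rank
test, and the decision confidence is looked up in a precomputed table over
(p, d′, N_c) — signed-rank p, *wrapped* snout distance (each snout expressed
relative to its nearest spectrum peak, neutralizing aliasing), and candidate
count — built in advance by virtual-mouse simulations on single-mouse data.
Segments are assigned only at confidence > 0.99. Assigned and unassigned
segments merge into syllables across gaps < 30 ms, with per-syllable
acoustic features and an assignment rate.

**Squeak rejection.** Audible broadband vocalizations are detected on the
decimated (38.4 kHz) signal in the 2–16 kHz band after median-based
spectrogram flattening (threshold 28 dB); overlapping ultrasound segments
are excluded from assignment.

## Worked example

Simulate a 20-syllable single-mouse session, localize every call, and check
the errors against ground truth:

```r
library(usvloc)
clips <- simulate_usv_clips(20, seed = 42)       # 4-channel clips at 20 dB SNR
sess  <- analyze_clips(clips)                    # segment + beamform + localize
sess
#> <usv_session> 20 localized segments (0 unlocalized)
#>   median error: 0.25 deg / 1.14 mm; screening threshold 6.6 mm
```

Each rendered syllable was recovered and localized; the median direction
error (0.25°, measured from the array centroid) and floor-plane error
(1.1 mm) are far inside the bin size of the spatial spectrum (≈2.7 mm),
and the screening threshold is the session's own 99th-percentile
snout-peak distance, dominated by the simulated 5-pixel tracking jitter.
Building a confidence lookup table from the same session:

```r
lut <- build_session_lut(sess, seed = 7)
lut
#> <conf_lut> 88 trials; p: 20 pts [1.0e-06, 1]; d': 40 bins (0-200 mm); Nc: 2,3,4
#>   empty cells: 2320 / 2400
```

Most distance bins stay empty by construction: two mice can only both be
candidates when their wrapped snout distance is within roughly twice the
screening threshold, so only the small-d′ cells (and alias-wrapped cases)
ever receive trials, and lookups outside the charted region conservatively
return "unassigned".

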