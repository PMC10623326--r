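---
title: "Quantifying bacterial colony growth from laser biospeckle: methods and design"
author: "specklegrow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial colony growth from laser biospeckle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specklegrow)
```

## The measurement problem

When coherent laser light scatters off an agar plate, the camera records a
granular interference pattern — laser speckle. A static surface produces a
static speckle pattern; microscopic motion inside the sample (cell growth,
division, cytoplasmic activity inside a bacterial colony) decorrelates the
pattern from frame to frame. Ordinary reflectance imaging shows *where* a
colony is; the temporal dynamics of its speckle show *whether it is still
growing*. That distinction matters wherever growth state, not presence, is
the question: antimicrobial susceptibility testing, nutrient-limitation
studies, colony aging.

`specklegrow` converts a time-lapse speckle sequence (e.g. frames every
30 s over many hours) into per-tile activity signals, activity envelopes,
colony-level radial summaries, and an automatic growing / non-growing
classification per tile and time window. Because no public reference
recordings exist for this kind of measurement, the package also ships a
fully controlled synthetic biospeckle simulator that provides ground truth
for every processing stage; all tests and the acceptance results are
computed against it.

## The processing model

**Tiles.** The field of view is partitioned into N x N pixel tiles
(default N = 10); edge remainders are dropped so every tile has identical
statistics. All analysis is per tile.

**Normalized cross-correlation.** For each consecutive frame pair and each
tile, the normalized cross-correlation surface is evaluated on integer
displacements $(u, v)$, $|u|,|v| \le$ `maxShift` (default 3 px):

$$
\mathrm{NCC}(u,v) = \frac{\sum_{x,y}\,(a_{x,y}-\bar a)\,(b_{x-u,y-v}-\bar b)}
{\sqrt{\sum_{x,y} (a_{x,y}-\bar a)^2 \; \sum_{x,y} (b_{x-u,y-v}-\bar b)^2}}
$$

Sums run over the overlap of the displaced fragments and $\bar a$, $\bar b$
are the overlap means. Taking the means over the overlap (rather than the
whole fragment) keeps the estimator unbiased at nonzero displacement; the
two conventions coincide at $(u,v) = (0,0)$. Zero-variance (uniform) tiles
yield a zero surface and are flagged rather than erroring. A small search
range is deliberate: at a 30 s cadence biological inter-frame motion is
sub-pixel, and a small range suppresses spurious distant peaks.

**Subpixel peak.** The integer argmax $(\hat u, \hat v)$ (ties resolved
toward the smaller displacement magnitude — the no-motion null — then
row-major order) is refined per axis by the three-point parabola

$$
\hat\delta = \frac{\mathrm{NCC}(\hat u-1)-\mathrm{NCC}(\hat u+1)}
{2\,[\mathrm{NCC}(\hat u-1)-2\,\mathrm{NCC}(\hat u)+\mathrm{NCC}(\hat u+1)]}
$$

If the peak sits on the surface border or the parabola degenerates
(denominator below $10^{-12}$), the refinement is 0 and the sample is
flagged; refinements are clamped to $[-0.5, 0.5]$, since beyond that the
integer peak itself would have moved.

**Time signal.** Per-pair offsets are accumulated into the tile's time
signal with $\mathrm{sig}(0)=0$. Offsets are motion-signed (the negative
of the correlation argmax, i.e. the displacement of the later frame's
content). Two accumulation semantics are provided because the source
formulation is one-dimensional and silent on the point: per-axis signed
sums combined as $\sqrt{\mathrm{sig}_x^2+\mathrm{sig}_y^2}$ (default), and
accumulated magnitudes (monotone non-decreasing).

**Envelope.** The raw signal is a random walk; its useful content is local
dispersion, not level. The envelope is a trailing moving RMS over
`window` frames with two robustness steps: window-mean subtraction
(`centered = TRUE`, default) and truncated-mean style dropping of the
$\lceil \mathrm{trim} \cdot n\rceil$ largest and smallest window values
(default trim 0.1 per tail). Centering is the default on purpose: the
plain RMS of an accumulated signal plateaus at the walk's level and never
vanishes, whereas the centered envelope decays to zero when motion stops —
matching the observed vanishing of activity after growth arrest. The
literal uncentered form is available as `centered = FALSE`. Window
defaults to 120 frames (1 h at 30 s cadence); desk-scale synthetic
sequences in the tests use 21 frames, about a tenth of the sequence
length, the same proportion. Warm-up samples use the partial window (with
per-tail trimming capped so at least one value survives), so the envelope
has the signal's length.

**Colony summaries.** The colony center is found by thresholding the
temporal-max envelope map at a background-referenced level (tiles at or
below the `thresholdQuantile` quantile — default 0.5 — are the background
sample; the threshold is that quantile plus five background MADs), filling
holes so a peripherally active ring detects as its full disk, and keeping
4-connected components of at least 4 tiles; each component's
envelope-weighted centroid is the center. The detection procedure is this
package's own design (a manual center override is supported). Per tile,
the envelope peak and its (earliest) peak time are extracted; tiles are
binned by peak time and, separately, by distance from the center (bins:
one envelope window, one tile width — the native resolutions of the
upstream stages), and each bin reports the **median** peak envelope,
absorbing the tile-to-tile spread from nutrient access, crowding, and
growth asynchrony. The radius-averaged envelope map (mean envelope per
radius bin per frame) and center cross-sections provide the spatiotemporal
views.

**Growth arrest.** Arrest is detected on the colony-aggregate envelope
time course (median envelope over colony tiles, per frame): the first
sample after the global peak that falls below `fraction` (default 0.1) of
the peak *and stays below it* — persistence guards against transient dips.
The peak-time-binned median profile is unsuitable for this purpose by
construction: after growth stops no tile attains a new peak, so that curve
has no support where the decay must be measured; the time course is the
quantity that "vanishes". The detection rule is an operationalization of a
qualitatively reported phenomenon, with the tolerance of one envelope
window (the envelope's own lag).

**Classification.** Each in-colony tile-window (window default 3 h of
frames; 30-frame windows in the desk-scale tests) yields a feature vector:
the envelope segment linearly resampled to L = 32 points plus window mean,
max, last-minus-first slope, and standard deviation. A multilayer
perceptron with one hidden layer of 32 logistic units and a logistic
output is trained on standardized features with inverse-class-frequency
weights (`nnet` under the hood; one hidden layer is that implementation's
design, and proved sufficient — held-out accuracy is checked in the
acceptance suite). Out-of-colony tiles are labeled by the presence mask
alone, never by the network: presence and activity are different kinds of
evidence, so the three-way output (out-of-colony / non-growing / growing)
is a binary activity classifier composed with a mask. Prediction uses the
package's own forward pass from the stored weights, so a model restored
from its JSON serialization predicts bit-identically.

## The synthetic biospeckle model

The simulator generates fully developed speckle as the squared modulus of
a band-limited circular complex Gaussian field (white complex Gaussian
spectrum shaped by a Gaussian envelope), giving the canonical intensity
statistics: exponential intensity distribution, contrast (std/mean) of 1,
spatial correlation length set by `grainSize` (default 2 px). Temporal
activity is an autoregressive field update per frame,
$E' = \rho E + \sqrt{1-\rho^2}\,\xi$, with fresh band-limited innovations
$\xi$, so the frame-to-frame field correlation is exactly $\rho$ per pixel
and ground-truth activity is defined as $1-\rho$.

A colony is a disk growing linearly in radius until an arrest frame
(constant after), with $\rho_\mathrm{body}$ inside, optionally a lower
$\rho_\mathrm{ring}$ in a peripheral annulus (the ring of active growth at
the colony edge), a multiplicative intensity gain for colony brightness,
and the background correlation again after arrest. Camera noise is
additive Gaussian on intensity (default 1% of mean background intensity),
clipped at zero. Everything is bit-reproducible from (scene, seed).

What the simulator does *not* model: optical-bench physics (lens,
polarization, attenuation), biology beyond the radius curve and activity
profile (no growth law links $\rho$ to a growth rate — the literature
gives no quantitative mapping, so $\rho$ is a free parameter), spatially
correlated camera noise, illumination drift, condensation, or plate
movement. Passing tests therefore demonstrate that the pipeline recovers
what the decorrelation model encodes, not that it is robust to every
artifact of a real bench.

## Study conditions used by the tests and acceptance results

Chosen once, desk-scale:

* Activity monotonicity: five 200 x 200 px, 200-frame scenes with a
  uniformly active disk (radius 70 px) at
  $\rho \in \{1.0, 0.99, 0.95, 0.9, 0.8\}$; mean envelope over interior
  tiles must increase strictly with $1-\rho$.
* Subpixel recovery: shifts $\{-0.4,-0.2,0.1,0.3\}$ px applied via the
  Fourier shift theorem, one axis at a time, to 120 x 120 px frames
  (144 tiles each); per-axis RMSE of the recovered shift below 0.05 px.
* Ring recovery: static disk of radius 70 px with a 14 px active annulus;
  the radius profile's maximum must fall in the annulus bins.
* Arrest recovery: arrest at frame 100 of 200; detection within one
  envelope window (21 frames).
* Classifier: six 128 x 128 px, 180-frame colonies with varied radii,
  growth rates, arrest frames and ring activity; train on five, evaluate
  on the held-out sixth (accuracy at least 0.90 over in-colony
  tile-windows; at least 90% of post-arrest windows non-growing).

## Numerical choices and degenerate inputs

* NCC values are clipped only by arithmetic (bounded in $[-1,1]$ up to
  $10^{-9}$); zero-variance overlaps contribute 0.
* Argmax ties: smaller displacement magnitude first (the no-motion null),
  then row-major order.
* An all-zero (degenerate) correlation surface yields a zero offset with
  a flag, not an error: uniform tiles are data, not failures.
* Envelope warm-up uses partial windows; full-window trimming that would
  discard everything is a parameter error.
* A static scene with zero camera noise produces *exactly* zero signals
  and centered envelopes (self-correlation peaks at the origin and the
  symmetric parabola refines to zero); with camera noise the null level
  is small but nonzero, which is the realistic regime.
* Integer TIFF round-trips are lossless at 8/16 bit; floating-point
  fields and sequences round-trip bit-identically through the RDS store.
  Model JSON stores weights as `%.17g` strings, which round-trip doubles
  exactly.

## Known limitations

* The 1-D per-axis parabola jitters on the axis *orthogonal* to a large
  subpixel displacement (the refinement is evaluated on a ridge displaced
  in the other dimension): with 10 x 10 tiles, cross-axis RMSE reaches
  ~0.1 px at 0.4 px diagonal shifts while the shifted axis stays within
  ~0.02 px. For activity quantification this jitter is part of the signal
  dispersion the envelope measures; for metrological displacement use,
  larger tiles or a 2-D peak fit would be needed.
* Colony detection assumes colonies cover less than the background
  quantile fraction of the field (default: half) and are
  envelope-contrasted against it; confluent growth needs a manual mask.
* The classifier is trained and validated on simulated features; applying
  it to real recordings requires retraining on matched data.
* `nnet`'s optimizer is deterministic given a seed but single-threaded;
  very large training sets are better subsampled.
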