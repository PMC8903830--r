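---
title: "Models and methods: calcium ensembles and ripple-spindle coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: calcium ensembles and ripple-spindle coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofire)
```

This vignette describes the statistical procedures the package implements,
the choices made where a procedure is under-determined, and what the
synthetic-data generator does and does not emulate. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The setting

One-photon miniscope imaging of CA1 or ACC during contextual fear
conditioning yields, per session, a set of spatial footprints (2D weight
maps from constrained matrix factorization), raw and denoised fluorescence
traces at 10 Hz, and, downstream, sparse calcium-event times per neuron.
Sessions are 6-min context exposures; during training, three foot-shocks
are delivered (defaults 180, 240 and 300 s — shock times are session
metadata, never hard-coded, since protocols vary). Separately, dual-site
LFP (CA1 and ACC, 1250 Hz after downsampling) is recorded during sleep,
with slow-wave-sleep (SWS) intervals supplied by an external scorer.

## Curation

Four stages, in order; each stage's removals are logged in the
`curation_report`.

**Shape.** Footprints are binarized at 50% of their maximum weight
(configurable). The boundary polygon is traced by marching squares at that
level (`grDevices::contourLines`), giving sub-pixel area A and perimeter P;
the compacity is C = P²/(4πA). The inertia ratio is the ratio of the
principal second moments of area of the binarized pixel set (a 1/12
per-pixel self-moment keeps one-pixel-thin regions non-singular), which is
1 for a disk and (a/b)² for an a:b ellipse. Neurons with inertia ratio > 5
or C > 35 (both strict) are rejected. On *binary* masks the marching-squares
perimeter of a curved boundary is overestimated by a few percent (C ≈ 1.15
for a radius-20 digital disk); on the smooth weight maps extraction actually
produces, the contour interpolates sub-pixel and C is accurate to ~1%.

**Overlap.** Pairs with binarized centroids within 36 px are candidates;
when their overlap ½(|∩|/|N₁| + |∩|/|N₂|) exceeds 0.5, the member with the
lower peak-to-noise ratio is removed. Pairs are processed in
descending-overlap order and removed neurons cannot remove others — a
deterministic, conservative resolution; PNR ties remove the larger neuron
id, logged. The test suite checks this against exhaustive rule application
on small instances.

**Event candidates.** Peaks are found on raw and denoised traces with three
criteria: amplitude ≥ 3 baseline-noise SDs above the trace median, ≥ 15
frames (1.5 s) apart, and width at half prominence ≥ 3 frames (300 ms at
10 Hz). The baseline-noise SD is 1.4826·MAD of the first-differenced trace
divided by √2, floored at 1e-9 — robust to the events themselves and safe
on constant traces. Candidates are denoised-trace peaks; each is annotated
with the nearest raw peak within 1 s. Eight features are extracted — PNR,
width-to-height and prominence on both traces, the raw–denoised Pearson
correlation in ±1 s, and a local PNR whose noise SD comes from ±2 s around
the peak excluding ±0.3 s — standardized, projected on the principal
components retaining 90% of variance, and classified by a Gaussian
quadratic discriminant with per-class covariances shrunk 1% toward their
diagonal (stable on small manual label sets). Training labels can come from
manual annotation or, in the synthetic path, from ground truth: true events
versus injected denoised-only artifacts.

**Low activity.** A neuron is kept iff N_peaks + 2·H_max − 3 > 0, strict.
"Relative height" H_max is defined here as the largest accepted-event
prominence on the denoised trace, divided by the session-wide denoised
dynamic range and clipped to [0, 1] — a bounded definition that keeps the
rule's units coherent; it is a stated choice, not an inferred one.

## Correlated pairs

Each event becomes a ±200 ms run of 1s (±2 frames at 10 Hz) in a binary
raster; overlapping pads merge. Co-activity is the zero-lag Pearson
correlation between rows. The padding already absorbs sub-200-ms lags, so
zero lag is the default; a max-|r|-over-lags option exists. The null is
built by redrawing every neuron's event times uniformly in-session (counts
preserved; a circular-shift option preserves inter-event structure
instead), rebuilding the raster, and pooling all pairwise correlations over
1000 shuffles (configurable); the correlated-pair threshold is the pooled
mean + 2 SD. Zero-variance rows get correlation 0 and are excluded from the
pool. Correlated-pair counts are percentages of possible pairs, optionally
within a subset (e.g. FSR neurons) or across two disjoint groups, and are
normalized to the same-day baseline session's percentage (ratio 1 = at
baseline; a zero baseline flags the ratio undefined rather than infinite).

## Foot-shock-responsive neurons

Counts in 5-s bins are z-scored to the mean and SD of the baseline bins
(0–180 s, before the first shock), with the baseline SD floored at 0.5
events/bin so silent-baseline neurons get large but finite z (flagged). A
neuron is FSR when its windowed z rises above 2 SD during or after any
shock, windows being [shock, shock + 30 s] including the delivery bin. The
default statistic is the *mean* binned z over a window; a per-bin-maximum
variant is available, but with Poisson counts the maximum over ~18 bins has
so heavy a null tail that a large share of non-responders would qualify,
which would make the planted-fraction recovery and the sham control
uninformative — the window mean matches the window-averaged pre/post
quantification and keeps the sham false-positive rate low. The pre/post
response is the mean z over 30 s before vs after each shock, averaged over
shocks (which is why an FSR neuron's average postFS can fall below the 2 SD
classification criterion). The sham control runs the identical computation
on a no-shock baseline session at virtual shock times.

## Registration and A&C overlap

The spatial correlation of two footprints is Pearson over the union of
their binarized supports — restricting to the union keeps the shared
background of zeros from inflating r. Cross-session matches are candidate
pairs with r > 0.85 (the fixed-threshold variant of cell registration),
resolved greedily in descending r into one-to-one matches; multi-session
identities form by transitive linking, and a link that would put two
same-session neurons into one identity is skipped — with descending-r
processing this breaks chains at their weakest link automatically. Greedy
resolution is checked against an exact optimal-assignment oracle on small
instances in the tests.

A&C neurons are registered cells active in both the trained (A) and neutral
(C) context on the same day. Their count is summarized by the Jaccard index
J = |A∩C|/|A∪C| over registered identities. Because larger sessions contain
more A&C neurons by chance, J is z-scored against 1000 surrogate indices
obtained by drawing the two sessions' sizes uniformly without replacement
from the identity pool; z-scores are min–max normalized within an
explicitly declared comparison group (the grouping is user metadata — the
package does not guess it). The per-neuron activity preference of A&C cells
is the bounded contrast (r_C − r_A)/(r_C + r_A) (0 = no preference; a plain
difference mode exists); neurons silent in both contexts are excluded and
counted.

## Context decoding

Each context session is tiled with 5-s bins (half-open; a trailing partial
bin is dropped); entries are mean events per frame per A&C neuron, giving
72 vectors per 360-s context. A linear-kernel SVM (cost 1) is evaluated by
stratified 10-fold cross-validation with per-fold standardization fitted on
training folds only; accuracy is reported both as the mean of fold
accuracies (the primary number) and as pooled-prediction accuracy. Folds
are seeded random splits; a contiguous-block option exists because 5-s bins
are temporally autocorrelated and random folds can be slightly optimistic.
Mice with fewer than 50 A&C neurons are flagged not-includable (the
computation still runs).

The permutation null redraws each neuron's event times uniformly over the
two *concatenated* sessions, preserving its total event count, then
rebuilds features and reruns the CV. This destroys all context information
and centers the null at 50%. The alternative — shuffling each session
separately — fixes every neuron's per-context total, so held-out bins must
exactly compensate the training bins' chance imbalance; that dependence
drives CV accuracy far *below* chance (a property worth knowing when
designing permutation tests on count-preserving shuffles), and it is why
the pooled redraw is the implemented null. Decoder accuracy is related to
behavior through the discrimination ratio
(freeze_A − freeze_C)/(freeze_A + freeze_C) ∈ [−1, 1] and standard Pearson
statistics.

## Ripples, spindles, coupling

Downsampling applies a zero-phase low-pass at 0.4 × the target rate before
decimation. Ripples: the 100–250 Hz band-passed CA1 trace is squared,
smoothed with a 10-ms window, and z-scored over SWS samples only (only SWS
is analyzed, so the normalization uses it alone). Contiguous regions above
3 SD are candidates; candidates separated by less than 20 ms are merged
*before* duration filtering, so two short bursts can form one valid event;
merged events are kept when their peak z exceeds 5 SD and their duration
lies in 50–100 ms. The peak time is the z maximum. Spindles: the 12–15 Hz
band-passed ACC trace's analytic-signal envelope (FFT Hilbert method),
smoothed 50 ms, z-scored over SWS; regions above 2.5 SD lasting 200–2000 ms
are spindles, with the center at the onset/offset midpoint. A ripple is
coupled when its peak lies within ±0.5 s of some spindle center (onset and
center modes exist); the coupled percentage can be swept over window sizes.
Occurrence rates are event counts divided by total SWS seconds.

One numerical consequence to keep in mind: a 3-Hz-wide band-pass rings with
a time constant of roughly 1/(π·BW) ≈ 0.1 s, so a strong oscillatory burst's
above-threshold envelope extent exceeds its nominal length by hundreds of
milliseconds. Duration bounds therefore act on the *measured* extent, and a
very strong sub-200-ms 13 Hz transient can still register as a short
spindle. The 100-ms ripple maximum is unusually strict for the SWR
literature; it is applied exactly as specified but is configurable.

## The synthetic-data generator

The generator produces every input with known ground truth: Poisson event
trains with piecewise-constant rates (context gains; FSR neurons multiply
their rate for 30 s after each shock — the same window the analysis uses);
synchronous assemblies as shared co-event times copied into each member's
train with uniform jitter; raw/denoised trace pairs from a
difference-of-exponentials calcium kernel (rise 0.05 s, decay 0.5 s,
GCaMP6f-like) plus white Gaussian noise, with optional denoised-only
artifact transients emulating deconvolution errors; footprints as Gaussian
radial profiles (σ = radius/2) with controllable elongation and an 8-lobe
sinusoidal boundary roughness, placed with rejection sampling so unrequested
pairs do not collide, and overlap-pair placement solved by bisection on
center distance; multi-session populations drawn from a fixed reservoir
(default 4× the session size) with exact carryover — or independent draws
for the chance condition — and per-session Gaussian centroid jitter; and
dual-site LFP as 1/f background with Gaussian-enveloped bursts (ripple
150 Hz, spindle 13 Hz defaults, mid-band of the detection filters). The
burst envelope is deliberately flat-topped (σ = duration/3) so events hold
their amplitude across their nominal duration, as physiological events do.
Coupled ripples are placed within a configurable offset (default ±0.4 s) of
a spindle center and uncoupled ripples are rejection-sampled away from every
spindle's window, so the injected coupling fraction is exact by
construction.

What it does **not** emulate: movies and motion artifacts, bursty or
refractory spike statistics (events are Poisson given the rate profile),
slow drifts in baseline fluorescence, field-of-view misalignment beyond
translation jitter, non-1/f LFP structure (slow oscillations, theta, EMG),
and behavioral trajectories. Passing tests therefore demonstrate that each
operator recovers what it is defined to recover under these idealized
conditions — correctness of the statistics, not robustness to every failure
mode of real recordings.

## Problem sizes and reproducibility

The test suite and acceptance script run everything at desk scale, chosen
to keep Monte-Carlo error well inside the asserted tolerances: sessions of
25–200 neurons, shuffle nulls of 100–300 draws where the default is 1000
(the defaults remain 1000; the draw count only sets the Monte-Carlo error
of the null moments), 50 replicates for Jaccard calibration, 200 decoder
shuffles for the chance-level check, and 600-s LFP recordings with 40–50
ripples. Every stochastic operation takes an explicit integer seed, derives
any internal seed streams from it, restores the caller's RNG state, and is
bit-reproducible; seeds are recorded in the returned objects.

## Known limitations

* Registration recall under centroid jitter falls steeply: with Gaussian
  footprints the union-support correlation drops below the 0.85 threshold
  at shifts beyond roughly a tenth of the footprint diameter, so the fixed
  threshold assumes well-aligned fields of view (as the probabilistic
  registration it stands in for also does). Precision stays high; recall is
  reported, not hidden.
* Spindle/ripple duration estimates inherit band-pass smearing, as above.
* H_max, the local-PNR window, the shuffle scheme and the min–max grouping
  are stated choices where the underlying procedure is under-specified;
  each is a documented parameter, and alternatives (circular shuffle,
  per-bin FSR criterion, lagged correlation, plain-difference contrasts)
  are exposed as options rather than silently decided.
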