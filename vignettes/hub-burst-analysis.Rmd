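---
title: "Quantifying transcription factor hubs and transcriptional bursting from live embryo imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcription factor hubs and transcriptional bursting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HubKinetics)
```

## The measurement problem

In early *Drosophila* embryos, morphogen transcription factors such as
Dorsal accumulate in sub-nuclear, high-concentration microenvironments
("hubs"). Two-channel volumetric live imaging captures, simultaneously,
a tagged transcription factor (channel 1) and nascent transcription at
a reporter locus made visible by the MS2/MCP system (channel 2: a
single diffraction-limited spot per nucleus). The scientific questions
are quantitative: how dense and bright are hubs relative to the
nucleoplasm, how long do hubs dwell at a locus, and how do hub contact
and intensity relate to the amplitude, duration, output, loading rate
and frequency of transcriptional bursts.

HubKinetics implements that measurement chain end to end: nucleus
segmentation and tracking, hub detection by a morphological
residual-plus-watershed recipe, MS2 spot detection and tracking with
motion-corrected interpolation, interaction-sphere metrics, dwell-time
classification by a three-component Gaussian mixture, derivative-based
burst calling, and the cross-correlation and group statistics that
relate the two channels. Because raw embryo movies are large and not
generally redistributable, the package also ships a first-class
synthetic-data generator producing ground-truthed movies and traces
with the statistical structure the analysis assumes; the test suite
and the acceptance script run entirely on this generator.

## Acquisition geometry and units

Defaults mirror a lattice light-sheet acquisition: one two-channel
volume every 11.56 s, z-planes every 0.3 um (63 planes span 18.9 um),
and a lateral pixel pitch of 0.104 um. The lateral pitch is not a
published constant of the acquisition; 0.104 um is typical for this
instrument class and only its ratio to the 0.5 um interaction sphere
matters for any conclusion the package draws. Every physical quantity
is carried in micrometres and minutes, frame indices are 0-based, and
all morphological footprints are specified in micrometres and converted
per axis to voxels, so the ~3x coarser z sampling is handled
consistently throughout.

## Hub detection

Within each nucleus mask, channel-1 intensities are divided by their
mask mean (`normalizeNucleus()`), making "enrichment 2.0" mean "twice
the nucleoplasmic average" regardless of illumination or expression
level; detection is thereby invariant to rescaling of the raw
intensities. `detectHubs()` then applies: median filter, grayscale
erosion, morphological reconstruction by dilation (seed = eroded,
mask = median-filtered), and subtraction of the reconstruction from the
median-filtered image. The reconstruction recovers the smooth
nucleoplasmic background while erasing features narrower than the
erosion ball, so the residual isolates compact bright structures. The
residual is binarised (Otsu on the in-mask residual by default, fixed
override available), local maxima at a minimum physical separation seed
a marker-controlled watershed on the inverted residual — splitting
closely associated hubs that plain connected components would fuse —
and a voxel-count filter removes fragments.

Kernel sizes are deliberately conservative and all recorded with the
output: median footprint 3x3x1 voxels; erosion ball 0.15 um; maxima
separation 0.3 um; minimum hub size 4 voxels. None of these constants
is canonical — they are sized to the hub scale (~0.2-0.5 um) and are
the first thing to revisit on data with different optics.

## MS2 spot tracking and the interaction sphere

`detectMS2Candidates()` band-passes channel 2 (median filter, then
difference of Gaussians with sigma 0.1/0.3 um) and keeps voxels above
the 99.5th percentile of the filtered in-mask distribution; the
brightest connected component is taken as the locus
(`selectLocusSpot()`, ties broken deterministically by size then
label). Per-nucleus overrides of the sigmas and percentile are
supported and logged, since spot brightness varies strongly between
nuclei. Between bursts the spot is invisible, so `fillTrack()`
interpolates the position in nucleus-relative coordinates
r = (position − centroid) / equivalent radius per axis, and
extrapolates up to 20 frames before first appearance by holding the
first detected r fixed. This transform is exact under rigid nucleus
translation and isotropic size change — the simplest formalisation of
"correcting for the motion and size of the nucleus" — and the tests
assert both exactness properties on constructed fixtures.

Hub presence at the locus is measured inside a 0.5 um-radius sphere
centred on the spot's weighted centroid (`sphereMetrics()`). A voxel
belongs to the sphere when its centre lies within the radius in
physical distance; partial-voxel weighting was rejected for
simplicity and oracle-checkability (the test suite compares against
exhaustive per-voxel enumeration, and the occupied volume converges on
4/3*pi*0.5^3 ~ 0.5236 um^3 as voxels shrink). Contiguous frames with
any hub overlap form interaction runs (`extractRuns()`); the default
gap tolerance is 0, reading "consistently present" strictly, with a
configurable tolerance for sensitivity analysis.

## Dwell-time classification

Run durations pool into a three-component Gaussian mixture
(`fitDwellMixture()`): expectation-maximisation on the raw durations,
initialised from several deterministic partitions under a fixed seed —
k-means on the raw durations, k-means on their logarithms (dwell
components separate multiplicatively, and raw k-means alone tends to
split the widest component rather than resolve the short/mid pair),
and quantile thirds — keeping the highest final likelihood. Variances
are floored at 1e-4 of the sample variance so near-point-masses cannot
collapse the likelihood, components are relabelled in ascending mean
order (short/mid/long), and runs are hard-assigned by maximum
responsibility.
Fitting EM on the raw samples (rather than to the cumulative curve) is
the standard reading of a mixture fit to dwell times and is declared
here as this package's definition. Pooling is per gene and cycle by
default, with grouping under the caller's control. An independent EM
implementation (mclust) serves as a cross-check in the test suite,
never as the fitting path.

## Burst calling and burst-hub statistics

`callBursts()` smooths the MS2 trace with a Gaussian kernel (default
sigma 1.5 frames) and thresholds its discrete time-derivative at
+/- 2 x MAD. A burst begins at an upward threshold crossing while the
background-subtracted intensity is above a small floor; the onset is
refined by intersecting the rising tangent at the derivative peak with
the baseline, which recovers the true onset exactly for linear rises
(the property the trapezoid oracle tests pin down). The baseline is a
20-frame rolling minimum — any smoothing-plus-derivative scheme needs a
baseline rule and none is canonical, so this one is declared and
configurable. A burst ends when the background-subtracted
intensity falls to 5% of its amplitude. Per burst: amplitude (peak
smoothed minus pre-burst baseline), duration, output (trapezoidal
integral of background-subtracted intensity, intensity x minutes), and
loading rate defined as amplitude / (peak time − onset), i.e. the
initial rise slope; frequency divides burst count by the observed
trace span.

`linkBurstsToHubs()` asks whether a hub occupies the interaction
sphere at each burst-start frame — either any hub, or one whose
overlap mean intensity reaches a threshold set to the average ventral
hub intensity (`highIntensityThreshold()`) — and measures the arrival
lead (burst start minus the containing run's first frame) and the
dwell after start (run's last frame minus burst start). First bursts
are flagged and excluded from arrival-lead summaries: a hub "arriving
before" the first burst of a cycle is not well defined when
observation begins mid-interphase.

`crossCorrelate()` z-scores both smoothed traces and evaluates the
normalized cross-correlation over a bounded lag window, dividing each
sum by n − |lag| to correct the finite overlap. The sign convention is
fixed and documented: a positive peak lag means the hub signal follows
the MS2 signal. The estimator is antisymmetric under swapping its
inputs, so any published sign convention can be matched by a single
negation. The lag window should stay below the dominant burst period
on strongly periodic traces, where the bias correction can favour the
period alias.

## The synthetic-data generator

`simulateTraces()` and `simulateEmbryoMovie()` generate, respectively,
frame-grid intensity traces and full two-channel 4D movies, each with
complete ground truth. The burst model is a linear rise at a
configurable loading rate to a plateau, then exponential decay — the
simplest waveform with closed-form amplitude, output and loading rate,
which is exactly what the burst-calling oracles need. Two coupling
modes are mutually exclusive per run so ground truth stays
unambiguous: lag coupling (the hub trace is the smoothed MS2 trace
shifted by an imposed lag) exercises the cross-correlation stage, and
arrival coupling (hub presence switches on a fixed lead before each
non-first burst and off a fixed dwell after the burst start, snapped
to the frame grid) exercises burst-hub linking. Arrival coupling
validates that lead + dwell + one frame fits inside the burst spacing
and drops any trailing burst whose hub window would be truncated by
the end of the trace, so imposed and recoverable values coincide.

At movie level, nuclei are ellipsoids with a rise-and-fall
nucleoplasmic intensity profile and constant-velocity drift; hubs are
isotropic Gaussian blobs in physical units placed uniformly inside the
nucleus, born by a Poisson process and dying with exponential
lifetimes, so the standing hub count per nucleus is Poisson with mean
density x nuclear volume at every frame (the placement test's
expectation); the MS2 spot is a diffraction-limited Gaussian whose
voxel-summed intensity equals the burst-model value. Poisson-Gaussian
camera noise (shot gain, read noise, offset) is applied last. The
trace noise model of the real instrument is not published; the
Gaussian trace noise and Poisson-Gaussian camera model here are
explicit placeholders, fully configurable, and that choice bounds what
passing tests show: the pipeline recovers what this generator imposes
under these noise assumptions, which is a statement about the
analysis, not about any particular embryo. The generator also omits
photorealistic PSFs, mitotic divisions and multi-spot nuclei by
design.

## Nucleus segmentation stand-in

The published pipelines use a learned slice segmenter; training one is
out of scope here, so `segmentNucleiSlice()` is a deliberately simple
intensity segmenter (smoothing, Otsu, hole filling, distance-transform
watershed). Everything downstream — `stitchAndInterpolate()` (IoU >=
0.5 across slices, signed-distance shape interpolation across gaps of
up to 2 slices), `trackNuclei()` (greedy nearest-neighbour by
ascending centroid distance, 2 um per-frame limit appropriate to slow
blastoderm nuclei at ~11.6 s framing) — accepts externally produced
label volumes, so output from a learned segmenter drops in without
code changes. Nucleus swaps within one frame step are inherently
ambiguous for any nearest-neighbour tracker; the greedy rule is
documented and deterministic. Manual nucleus curation in the original
workflow is replaced by explicit, reproducible filters (minimum
nuclear volume; optional per-nucleus parameter overrides; an edits
mechanism for MS2 tracks).

## Numerical choices and degenerate inputs

Zero-variance inputs are defined, not accidental: a uniform field
yields no MS2 candidates (the percentile of a zero-variance
distribution is not a threshold), a zero-variance trace makes the
cross-correlation undefined (returned as missing with a warning), a
zero nuclear mean is a hard error, and identical dwell durations
produce a variance-floored single-effective-component fit flagged as
degenerate. Exact ties are broken deterministically everywhere (spot
selection: volume then label; watershed flooding: FIFO; lag peaks:
smallest absolute lag) so that fixed seed implies bit-identical
output, which the end-to-end determinism test asserts at the level of
emitted CSV bytes.

## Problem sizes

The shipped tests and the acceptance script run on deliberately small
instances chosen to exercise every code path at comfortable runtime:
trace-level cohorts of 20 nuclei with 3-5 bursts each, 2,000-sample
dwell mixtures, 200 noisy traces for burst-recall, 50 planted-blob
nuclei of 56x56x22 voxels, and a 2-nucleus, 3-4 frame, 64-72 voxel
movie for the end-to-end determinism check. All sizes scale up through
the same interfaces.

## Known limitations

Hub identity is not tracked through the nucleoplasm at large — a hub
leaving and re-entering the interaction sphere starts a new run, which
is the strict reading of "consistently present". Intensities are
relative (nucleoplasm-normalized channel 1; arbitrary-unit MS2); no
absolute RNAPII-count calibration is attempted. The burst model is
phenomenological: no two-state promoter inference. The stand-in
nucleus segmenter is adequate for the synthetic movies it is tested
on and is not a substitute for a trained model on real data.
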