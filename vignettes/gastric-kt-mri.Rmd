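---
title: "Dynamic gastric MRI with k-t interpolated reconstruction: models and methods"
author: "gastroKT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic gastric MRI with k-t interpolated reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gastroKT implements a complete desk-scale counterpart of a contrast-enhanced
dynamic MRI protocol for rodent gastric motility: a dynamic stomach phantom,
the time-interleaved undersampled Cartesian acquisition with respiratory
gating, a single-coil k-t convolutional-interpolation reconstruction, and the
image-quality and motility quantification used to validate it. This vignette
explains the models, the tunable parameters, and the numerical choices, in
the order a run executes them.

## Contrast model: saturation recovery

The luminal contrast rests on a gadolinium-doped semi-solid test meal. A
1 mL, 182 mM Gd stock mixed into 25 mL of liquified diet gel yields a 7 mM
meal (`dilutionConcentration(182, 1, 25)`), with a very short longitudinal
relaxation time (T1 about 17 ms at 7 T) against tissue T1 above 800 ms.
Spatially non-selective saturation pulses precede each slice packet; with an
effective recovery time of about 127 ms between saturation and the k-space
centre echo, the recovered magnetization fraction

$$ f(t_\mathrm{rec}, T_1) = 1 - e^{-t_\mathrm{rec}/T_1} $$

is about 0.9994 for the doped meal and 0.147 (under 20%) for tissue
(`saturationRecoveryFraction`). The phantom's intensity model is
deliberately reduced to this recovery fraction: flip-angle steady-state
effects and TE decay are not modelled (TR/TE/FA travel as metadata in
`acquisitionParams`), because the lumen-tissue contrast that the
reconstruction exploits is recovery-dominated. The relative tissue proton
density is not fixed by the physics above, so `tissueProperties` exposes it
(`tissueBase`, default 1).

## The dynamic phantom

`phantomConfig` describes a piecewise-homogeneous lumen inside a cylinder of
suppressed tissue: an antral tube of resting radius 3 mm running in the
slice direction, joined at its dorsal end to a concentric corpus/fundus
ellipsoid. The tube is oriented through-plane so that its cross-sections lie
in the high-resolution image plane (0.5 mm in-plane vs 1.5 mm slices), which
is where the analysis measures them.

The antral contraction is a travelling occlusion wave on the tube radius,

$$ r(z, t) = r_0 \, \bigl(1 - A \, w(z - v t)\bigr), $$

with `w` a periodic raised-cosine bump of unit amplitude (the waveform is a
modelling choice; nothing in the physics fixes it), so the radius occlusion
equals `A` exactly at the wave trough. Defaults are the cohort-scale study
conditions: `A = 0.231`, frequency 5.3 cpm, speed 0.56 mm/s. Unless set
explicitly, the wavelength is derived as `v * 60 / f` (about 6.3 mm) so that
frequency and velocity are honoured simultaneously; an explicit wavelength
wins, and the effective temporal frequency is then `v / lambda`.

Boundary voxels carry their in-plane occupancy fraction (each voxel is
subdivided 4 x 4 by default) rather than a hard 0/1 membership: acquired
MRI magnitudes are band-limited and exhibit partial-volume averaging, and a
binary-edged phantom would put unrealistically heavy energy into the
k-space periphery. Noise, when requested, is additive Gaussian on the image
with the magnitude taken afterwards; Rician statistics are not modelled.
Respiration can displace the whole lumen rigidly through-plane during the
inhalation burst only (`respirationDisplacement`, default 0 mm — the gated
acquisition the package models is designed to avoid exactly this motion,
so the default phantom emulates successful gating).

What the phantom does *not* emulate: gastric emptying and secretion, B0/B1
inhomogeneity, coil sensitivity structure, flowing blood, through-plane
curvature of a real antrum, and Rician noise. Tests passing on the phantom
therefore demonstrate the internal consistency of the pipeline under the
method's own assumptions, not performance on in-vivo data.

```{r phantom}
library(gastroKT)
cfg <- phantomConfig()                    # 64 x 64 x 4, 0.5 x 0.5 x 1.5 mm
ref <- generatePhantom(cfg)               # 60 frames, 2 s apart
```

## Acquisition model: gating, packets, interleaving

The protocol excites 24 slices in 6 packets of 4, all slices of a packet
within one TR, giving a volume time of
`nPackets * linesPerSlicePerFrame * TR` = 6 x 24 x 10.6 ms = 1.526 s
(`volumeAcquisitionTime`). Acquisition is triggered on the falling edge of
the respiration pressure burst (`detectTriggers` on a `simulateRespiration`
trace) and runs to volume completion, ignoring triggers that arrive
meanwhile; with periodic cycles of length `c` the start-to-start interval is
`ceiling(volumeTime / c) * c` (`scheduleVolumes`), at most 3 s for
physiologic cycles of 1-2 s.

Undersampling is Cartesian and time-interleaved (`samplingPattern`,
`buildMask`, `applyMask`): `nACS` central phase-encode lines are always
acquired; peripheral line `j` (0-based) is acquired in frame `t` iff
`j mod R` equals the frame's phase offset, `(t - 1) mod R` by default, so
any `R` consecutive frames jointly cover every line. For even `nACS` the
block is placed so the DC line is the upper-middle ACS line. The per-frame
line budget (`linesPerSlicePerFrame`) is deliberately independent
configuration rather than derived from `nPE`/`nACS`/`R`, so protocol
variants can be timed directly.

## k-t convolutional interpolation

The reconstruction premise is linear predictability in k-t space: the
homogeneous bright lumen acts as a spatial multiplier (playing the role
coil sensitivities play in parallel imaging), hence a shift-invariant
convolution kernel in k-space, and the quasi-periodic narrow-band motion
justifies time-invariant kernels.

For reduction `R` there are `R - 1` missing-line phases; each phase gets
its own kernel shape (two shapes at `R = 3`). A target missing line at
`(ky, t)` draws sources from a temporal window of `R` frames centred on
`t`; in each window frame the sampled lines within `kyHalfWidth` (default
2) of the target contribute, each extended by `2 * kxHalfWidth + 1 = 5`
frequency-encode taps. Restricting `|dky|` like this keeps the stencil's
ky span inside a 12-line autocalibration block for every `R` up to 11 —
taking instead the nearest sampled lines unconditionally would push
sources `R - 1` lines away and leave no valid calibration equations at
high `R`. For `R = 3` the restriction is inactive: the stencil is exactly
the five nearest sampled lattice neighbours.

Calibration (`calibrateKernels`) assembles, for each kernel shape, the
unregularized least-squares system over all autocalibration positions whose
full stencil stays inside the ACS block — pooling frequency-encode
positions, frames, and (by default) slices; per-slice weights are a flag.
Pooling all frames is the stationarity premise made concrete; the kernels
are time-invariant, so any frame whose shifted stencil stays in range
contributes equations. The solve is by SVD; a rank-deficient system yields
the minimum-norm solution and is flagged in the calibration report together
with the equation count, the relative fit residual, and the condition
number. Sampled k-space of a discrete image is periodic, so frequency-encode
taps index circularly; a ky source beyond the array lands on an unsampled
(zero) line whenever `R` does not divide `nPE`, which is the zero-padding
convention stated positively.

Temporal edges: the window is clamped inside the sequence and dedicated
edge kernels are calibrated for each clamped window shape, so the first and
last frames are reconstructed rather than discarded. Interpolation
(`interpolateKspace`) fills only mask-false lines, always from acquired
lines; acquired lines — ACS and peripheral — pass through bit-exactly
(data consistency). `reconstructImages` applies the centred inverse 2D DFT
and takes magnitudes.

```{r recon}
ku  <- applyMask(phantomToKspace(ref), samplingPattern(64L, 12L, 3L))
cal <- calibrateKernels(ku, ktKernelGeometry(3L))
rec <- reconstructImages(interpolateKspace(ku, cal$kernels))
```

## Image quality

`imageQuality` emulates the evaluation protocol: both series are first
normalized to [0, 1]. Normalization is global across the series — one
affine map per series — rather than per frame, so temporal intensity
dynamics are preserved; this is a documented choice where either reading is
possible. RE is the L2 norm of the vectorized difference over the L2 norm
of the reference; PSNR is `10 log10(range^2 / MSE)` with an infinite
sentinel for identical images; SSIM is the standard structural similarity
with a uniform 7 x 7 window and constants `(0.01 R)^2, (0.03 R)^2`,
computed per 2D slice/frame plane over fully interior windows and averaged
(window size and 2D-vs-3D are unstated in the protocol; both are exposed).
`mip` provides per-frame maximum intensity projections across slices.

## Motility quantification

`segmentLumen` thresholds the series (Otsu on the pooled histogram by
default) and keeps the largest 3D-connected component per frame.
`antralAxis` returns the centroid polyline of the antrum: given two
endpoint hints it walks the slices the segment crosses, taking in each the
centroid of the in-plane component containing the interpolated hint point,
capped by the hints; the polyline is arc-length parameterized.
`crossSectionAreas` counts lumen voxels in a slab perpendicular to the
local tangent (default thickness: one slice spacing) and converts counts
to mm^2; when the tangent is near the slice normal only the in-plane
component containing the axis point is counted, so a neighbouring luminal
compartment crossing the same slab cannot contaminate the antral area.

`detectExtrema` collapses plateaus (voxel-quantized areas are flat near
extrema), keeps sign-change extrema whose excursion exceeds 10% of the
series range, and enforces peak/valley alternation by discarding the weaker
of adjacent same-type extrema. `contractionAmplitude` is the mean
peak-normalized peak-to-valley excursion; the extremum values are refined
by a three-point parabola (strict local extrema only), because the 2 s
frame grid rarely samples the true peak or trough and the raw values bias
the amplitude low. The occlusion ratio is defined on areas; since the
phantom modulates radius, recovery tests convert via
`1 - sqrt(1 - a)` (`areaToRadiusOcclusion`).

`contractionFrequency` takes the dominant non-DC bin of the FFT of the
mean-removed series (gated, irregular frame times are linearly resampled
to their median interval first). `propagationVelocity` divides the
section distance by the wave delay, estimated by normalized
cross-correlation: lags are searched on the positive side only (the caller
passes sections in downstream order) and below one contraction period
estimated from the series itself — both restrictions remove the aliases of
a periodic correlation function, under the assumption that the sections lie
within one wavelength of each other. The peak lag is refined by parabolic
interpolation; a peak below 0.3, or a correlation maximal at zero lag,
raises an error rather than returning a direction-violating velocity.
`gastricVolume` is voxel counting in mL, per frame and time-averaged.

```{r motility}
hints <- antralAxisTruth(cfg)[c(1, 9), ]
measureMotility(rec, hints = hints, positions = c(0.75, 2.25, 3.75))
```

## Files, configuration, pipeline

`ImageSeries` round-trips through NIfTI-1 with voxel spacing in the header
and frame times in a JSON sidecar (header-TR fallback with a warning).
Complex k-space uses the package's container: a NIfTI pair holding real and
imaginary parts plus a JSON sidecar with the sampling mask, frame times and
acquisition attributes under a schema version — NIfTI has no native
complex/mask convention, and this split keeps the bulk data in a format any
imaging tool reads while the bookkeeping stays structured text. YAML run
configurations (`readRunConfig`) validate every stage's parameters before
anything executes. `runPipeline` chains simulate, undersample, calibrate,
interpolate, reconstruct, evaluate and motility deterministically under one
seed and writes metrics, motility, calibration report and a manifest;
`sweepReduction` tabulates RE/SSIM/PSNR across reduction factors. A thin
command-line front end over these functions ships in
`inst/cli/gastrokt.R`.

## Problem sizes and numerical choices

The package's reference conditions are a 64 x 64 x 4 grid with 60 frames at
2 s — the effective resolution a 1.5 s volume achieves under 1 s
respiratory cycles — with reconstruction sweeps over R = 2, 3, 11 at
ACS = 12. At this size a full sweep runs in about a minute and the whole
validation suite in a few minutes on one core. Other fixed numerics:
calibration caps the (deterministically thinned) equation count at 2e5 per
kernel; the SVD rank tolerance is 1e-10 relative; Otsu thresholds use a
256-bin histogram; extrema prominence defaults to 10% of range; the
cross-correlation acceptance threshold is 0.3.

## Known limitations

Single-coil, Cartesian, 2D-per-slice only — no parallel imaging, compressed
sensing, non-Cartesian trajectories, or learned reconstructions. The
velocity estimator assumes one coherent wave between sections closer than a
wavelength. The phantom's validation scope is stated above; in particular,
absolute image-quality values on the phantom are not comparable to in-vivo
values, only their ordering and trends are meaningful.
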