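# gastroKT

Dynamic contrast-enhanced MRI of the rodent stomach, end to end and in
silico: **gastroKT** is an R toolkit for researchers developing or
validating accelerated gastric MRI protocols. It reproduces the
computational core of a whole-stomach imaging framework — a
gadolinium-doped test meal imaged with saturation-recovery contrast,
respiration-gated multi-slice acquisition, time-interleaved Cartesian
undersampling with autocalibration (ACS) lines, and single-coil **k-t
convolutional-interpolation reconstruction** — together with the
image-quality and gastric-motility quantification used to validate it.

## The models in brief

**Contrast.** After a saturation pulse, magnetization recovers as
$f = 1 - e^{-t_\mathrm{rec}/T_1}$. With $t_\mathrm{rec} \approx 127$ ms the
doped meal ($T_1 \approx 17$ ms) recovers fully ($f \approx 0.9994$) while
tissue ($T_1 > 800$ ms) stays below 20% ($f \approx 0.147$): the lumen is
bright, everything else dark.

**Acquisition.** Peripheral phase-encode lines are sampled every $R$-th
line with a per-frame offset (`(frame - 1) mod R`), so $R$ consecutive
frames cover all of k-space; 12 central ACS lines are always acquired.
Volumes of 24 slices (6 packets of 4, all slices of a packet within one
TR) take $6 \times 24 \times 10.6\,\mathrm{ms} \approx 1.5$ s and are
triggered in the quiescent phase of respiration, giving an effective
temporal resolution of at most 3 s for cycles of 1–2 s.

**Reconstruction.** A missing line of phase $d \in \{1, \dots, R-1\}$ is
estimated as a linear combination of acquired $(k_y, t)$ lattice
neighbours (within a centred $R$-frame window and $\pm 2$ lines), each with
5 frequency-encode taps. Kernel weights are fitted on the ACS region by
unregularized least squares and applied shift-invariantly — the k-t
analogue of GRAPPA, workable with a single coil because the homogeneous
bright lumen acts as an effective sensitivity profile and the
quasi-periodic motion (~5 cpm) makes the kernels time-invariant.

**Motility.** From segmented dynamic images: cross-sectional area–time
series perpendicular to the antral axis; contraction amplitude as the
occlusion ratio (peak-to-valley over peak), frequency as the dominant FFT
component, propagation velocity as section distance over cross-correlation
delay, and luminal volume by voxel counting.

## Worked example

Simulate the default phantom (64 × 64 × 4 voxels, 60 frames at 2 s;
contraction amplitude 0.231, frequency 5.3 cpm, speed 0.56 mm/s),
undersample at R = 3 with 12 ACS lines, reconstruct, and quantify:

```r
library(gastroKT)
cfg <- runConfig(reduction = 3L, nACS = 12L, seed = 1L)
res <- runPipeline(cfg)

str(res$metrics)
#> List of 3
#>  $ re  : num 0.139
#>  $ ssim: num 0.852
#>  $ psnr: num 30.8

res$motility$recon
#> MotilityMetrics:
#>   amplitude (area occlusion)   0.363
#>   amplitude (radius-equiv.)    0.202
#>   frequency                    5.50 cpm
#>   propagation velocity         0.552 mm/s
#>   time-averaged volume         0.217 mL
```

Reading the numbers: the reconstruction deviates from the fully sampled
reference by a relative error of 0.139 after [0, 1] normalization
(SSIM 0.85, PSNR 30.8 dB). The motility analysis of the *reconstructed*
series recovers the generator's ground truth — radius-equivalent occlusion
0.202 vs 0.231 configured, frequency 5.5 cpm vs 5.3 (one FFT bin of the
2-minute record), velocity 0.552 vs 0.56 mm/s — i.e. the accelerated
acquisition preserves the motility readout. The desk-scale phantom holds
~0.22 mL; a real rat stomach is an order of magnitude larger.

A shell front end with `simulate` / `undersample` / `reconstruct` /
`evaluate` / `motility` / `sweep` subcommands lives in
`inst/cli/gastrokt.R`; configuration is YAML (see `readRunConfig`).

## Package layout

- `R/phantom.R` — saturation-recovery signal model, dynamic stomach
  phantom, respiration trace, forward Fourier model
- `R/sampling.R` — interleaved masks, retrospective undersampling,
  protocol timing, trigger detection and volume scheduling
- `R/recon.R` — k-t kernel geometry, ACS least-squares calibration,
  interpolation, image reconstruction
- `R/quality.R` — RE / SSIM / PSNR / MIP / Pearson correlation
- `R/motility.R` — segmentation, antral axis, area–time series,
  amplitude / frequency / velocity / volume
- `R/io.R`, `R/pipeline.R` — NIfTI and k-space containers, YAML configs,
  deterministic end-to-end pipeline and R-sweep

The methods vignette (`vignettes/gastric-kt-mri.Rmd`) documents the models,
parameter choices, and limitations in detail.
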