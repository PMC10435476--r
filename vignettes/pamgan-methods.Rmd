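---
title: "Enhancing AR-PAM b-scans with paired and unpaired GANs: models, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing AR-PAM b-scans with paired and unpaired GANs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pamgan)
```

## The problem

Photoacoustic microscopy trades resolution against depth. An
optical-resolution (OR-PAM) system focuses the excitation laser tightly and
resolves ~12 um laterally, but loses focus within roughly a millimetre of
tissue. An acoustic-resolution (AR-PAM) system focuses the *ultrasound*
detection instead: it images deeper (to ~1.9 mm with a 50 MHz transducer,
several millimetres with a 5 MHz one) but its lateral resolution is an
order of magnitude coarser (~85 um, 590 um for the deep system). Both
modes share the same ~27 um axial (depth) resolution, which is set by the
transducer bandwidth, not the optics.

`pamgan` implements the strategy of learning a mapping from AR-PAM b-scans
(2D lateral-by-depth cross-sections) to OR-PAM-like b-scans with image-to-
image translation GANs, in two regimes:

* **paired (cGAN)** — a conditional GAN trained on co-registered
  (AR, OR) b-scan patches, where the discriminator judges
  (source, candidate) pairs;
* **unpaired (CycleGAN)** — two generators (AR→OR and OR→AR) and two
  unconditioned discriminators, constrained by cycle-consistency L1 terms,
  for the label-free setting where no co-registered OR scan exists (e.g.
  the deep 5 MHz system).

The paired objective is

$$\mathcal{L}(A,O) = \mathbb{E}[\log D(A,O)] +
  \mathbb{E}[\log(1 - D(A, G(A)))] + \lambda\,\mathbb{E}\lVert O - G(A)\rVert_1 ,$$

optimized as a minimax game; the unpaired scheme runs the adversarial
terms in both directions and replaces the paired L1 by
$\lambda_{cyc}(\lVert F(G(a)) - a\rVert_1 + \lVert G(F(o)) - o\rVert_1)$.

## Networks

The generator is an encoder–residual–decoder network: a 7x7 stem
convolution, `n_downsamples` stride-2 3x3 convolutions, `n_res_blocks`
residual blocks with identity skips at the bottleneck, mirrored
transposed-convolution upsampling, and a 7x7 output convolution. The
full-scale configuration is 9 residual blocks and 64 base filters on
single-channel 256x256 patches; the desk-scale experiments use 2 blocks
and 8 filters on 64x64 patches, which keeps a CPU training run in minutes
while preserving every architectural element. The discriminator is a
Markovian (patch) discriminator: stacked stride-2 4x4 convolutions whose
output is a spatial grid of local decisions; `decision_mode =
"global_scalar"` mean-pools that grid to a single value. Design choices
that are genuinely open for this architecture family, and how we resolved
them:

* **Normalization** — instance norm, the standard choice for batch-size-1
  translation training (batch statistics are meaningless at batch 1).
* **Output activation** — tanh rescaled to [0, 1], matching
  uint8-normalized amplitude patches.
* **Discriminator conditioning** — the paired discriminator sees the
  source and candidate as two channels (the pix2pix convention); cycle
  discriminators see the candidate alone.
* **Patch map vs 1x1 decision** — both are implemented; the default keeps
  the patch map and reduces it by averaging in the loss, which preserves
  the Markovian property while still yielding one number per patch.
* **Downsampling depth** — 2, the convention of this generator family.

All layers, their backward passes and the Adam optimizer are implemented
in the package on top of small C++ convolution kernels; training is
single-sample and fully seeded, so an entire run is a pure function of
(datasets, specs, config).

## Training schedule and loss weights

Defaults follow the reference schedule for these systems: Adam at
learning rate 2e-4, decayed by a factor 0.5 (the default scheduler fires
at epochs 100 and 150 of a 200-epoch run), batch size 1, unsigned-8-bit
patch data, Adam betas (0.5, 0.999). The desk-scale
profile disables the decay entirely: its runs are 12–25 epochs long and
never reach the regime the scheduler is meant for.

Two knobs deserve explanation:

* **L1 weight.** `train_config()` defaults to an L1 weight of 0.01, the
  value reported for the full-scale systems this package models; the
  conventional value in the pix2pix/CycleGAN families is 100, which the
  desk-scale demo profile uses: with 0.01 the adversarial term dominates and the
  generator is free to hallucinate texture, which defeats the L1-anchored
  reconstruction this application relies on. Both profiles are one
  argument away.
* **Adversarial criterion.** The default is binary cross-entropy on
  sigmoid decisions. A
  least-squares variant (`adv_loss = "lsgan"`) is provided and used by
  the desk-scale profile: on sparse, mostly-dark PAM b-scans the BCE
  discriminator quickly becomes confident and its unbounded gradients
  destabilize the generator (we observed the classic collapse where the
  output saturates dark and the L1 recovers above its early-epoch value);
  the bounded least-squares gradients avoid this. This is precisely the
  motivation the LSGAN literature gives for the variant.
* **Cycle weight.** The unpaired profile uses `cycle_weight = 25`,
  stronger than the 10 conventional in the cited family. On sparse
  b-scans a weakly constrained unpaired generator can satisfy the
  distribution game by denoising alone while letting vessel amplitude
  fade (nothing pairs it to the right brightness); a heavier cycle
  penalty makes discarding structure expensive, because the backward
  generator must still reconstruct the input from it.

## The phantom simulator

No public dataset exists for this instrument pairing, so the package
ships a forward simulator that provides ground truth:

* **Geometry** — either straight hair-like cylinders whose depth
  increases linearly along the fast axis (the depth-staircase target used
  for visibility experiments), or a seeded random branching vessel tree
  with smoothly varying direction and diameter. The desk-scale profile
  uses vessels of 18–30 um diameter (2–3 pixels) with enough seeds and
  branching (6 roots, branch probability 0.15) that b-scans contain
  realistic, dense vasculature rather than isolated dots; early sparser
  settings produced b-scans that were ~99% background, which no real
  vascular field of view resembles.
* **PSF** — separable Gaussian: an isotropic lateral 2D Gaussian whose
  FWHM grows linearly beyond the depth of focus, times an axial 1D
  Gaussian; this matches the Gaussian-fit profile analysis used for
  evaluation. Defaults: OR 12 um lateral / 27 um axial, visible to
  1000 um; AR 85 um / 27 um, visible to 1900 um; deep-AR 590 um /
  150 um. Blur is applied slice-by-slice in depth (shift-variant along z
  only), which captures out-of-focus degradation at desk-scale cost.
* **Attenuation** — amplitude decays as `exp(-z / 1500 um)` with a hard
  zero beyond the visibility depth. The decay constant is a free
  simulator parameter (no quantitative decay law is available for these
  systems); every
  evaluation in this package is designed not to depend on its exact
  value, and it is recorded in provenance.
* **Noise** — additive Gaussian noise plus, on OR only, salt-and-pepper
  impulses (density 0.005), where such artifacts are observed in
  practice. The noise asymmetry is anchored to the reported instrument
  behaviour: AR-PAM acquisitions are an order of magnitude noisier than
  OR-PAM ones (in vivo SNR near 15 dB versus near 77 dB), so the demo
  profile uses sigma 0.02 of full scale for AR and 0.005 for OR. An
  AR-to-OR translator therefore has to denoise as well as deblur — which
  is also part of what the full-scale systems' networks learn.
* **Pitches** — 10 um lateral / 20 um depth, a 2x-coarsened version of
  the acquisition grid, chosen so that desk-scale volumes stay small.

What the simulator does *not* model: wave-equation acoustics, speckle,
fluence heterogeneity, motion, or co-registration error. Passing the
recovery experiment on synthetic pairs therefore demonstrates that the
training/enhancement machinery can invert a known dual-PSF forward model
at desk scale — not that it reaches the in vivo figures reported for the
full-scale instruments, which were measured on scanner data that is not
publicly available.

## Evaluation protocol

`snr_db()` and `cnr_db()` implement the printed decibel formulas over
explicit rectangular ROIs (power = mean squared amplitude; CNR is
`10*log10((mu_s - mu_b) / sigma_b)` exactly as printed, not the 20-log
amplitude convention). `ssim()` is the standard windowed
luminance-contrast-structure product (uniform 7-pixel window, K1 = 0.01,
K2 = 0.03, sample covariance), cross-checked in the test suite against an
independent reference implementation. `fit_gaussian()` performs a
Levenberg–Marquardt fit of a four-parameter Gaussian initialized at the
profile's peak with a half-maximum-crossing width estimate (global
moments are polluted by the noise floor of mostly-flat resolution
profiles and can start the optimizer at a degenerate flat solution);
FWHM is `2*sqrt(2*ln 2)*sigma`. Lateral resolution of a structure is measured the standard way: a
lateral profile at the structure's depth, Gaussian-fitted. For the y-invariant calibration tube the profile is
averaged over slow-scan rows first; on maximum-amplitude projections the
OR salt-and-pepper impulses survive the depth maximum and would corrupt
the fit, so tube FWHMs are measured in the b-scan plane.

## The desk-scale recovery experiment

`run_recovery_experiment()` is the package's end-to-end check and the
workhorse of `scripts/acceptance.R`:

1. simulate 8 training + 2 held-out vessel volumes (25 b-scans of
   64x64 each, so 200 training pairs) under the PSF/noise conditions
   above, with AR lateral blur 80 um = 8 px against ~2 px vessels;
2. train the compact model (2 residual blocks, 8 base filters,
   L1-weight-100 / least-squares profile);
3. on the held-out volumes, compare L1-to-OR and SSIM-to-truth of the
   enhanced output against the AR input;
4. scan a held-out calibration tube (20 um, at focus) with both PSFs,
   enhance the AR scan, and Gaussian-fit all three lateral profiles.

Recovery means: enhanced L1-to-OR below the AR baseline, enhanced tube
FWHM closer to the OR value than to the AR value, and enhanced
SSIM-to-truth above the AR input's. The CycleGAN variant runs the same
protocol on shuffled, decoupled pools. Problem sizes (200 pairs, 64x64,
8/2 volumes, 25/12 epochs) are the package's desk-scale study conditions;
they were chosen so a full experiment runs in minutes on one CPU core
(15 epochs paired, 16 unpaired in the shipped profiles).

## Numerical conventions and degenerate inputs

* Depth ties in the maximum-amplitude projection resolve to the
  shallowest sample (deterministic, physically conservative).
* Patch tiling is raster-order with no jitter; edge tiles shift inward so
  every tile contains real data; b-scans smaller than the patch are
  zero-padded bottom/right. Overlap stitching averages contributions
  (or feathers them with a triangular window); with an unmodified patch
  set, stitching is the exact inverse of tiling.
* `to_uint8()` rounds half up, making conversions bit-exact across
  implementations.
* Bandpass filtering is zero-phase (forward–backward Butterworth,
  order 4) so the depth axis never shifts; the envelope is the
  analytic-signal magnitude, taken after filtering (the conventional
  ultrasound chain).
  Default band edges are +/-80% fractional bandwidth around the
  transducer centre (10–90 MHz at 50 MHz; 1–9 MHz for the 5 MHz system).
* All-zero volumes cannot be normalized; constant profiles cannot be
  fitted; mis-shaped inputs, non-co-registered pairs, out-of-band specs
  and unusable ROIs raise classed errors (`pamgan_error_*`).
* Every stochastic stage derives its seed from the global seed plus the
  stage name (FNV-1a hash), so one integer reproduces a whole pipeline
  run bit-for-bit on one platform.

## Known limitations

* The GAN engine is single-threaded CPU code; the full-scale 9-block /
  64-filter / 256x256 configuration builds and runs but is not something
  you would train to 200 epochs in it. The architecture is
  capacity-parameterized precisely so the desk-scale and full-scale
  topologies share one code path.
* Salt-and-pepper noise on OR targets bounds the achievable L1: the
  network learns the *clean* conditional mean, while the L1 is measured
  against noisy targets.
* The simulator's attenuation law is a free parameter; absolute
  SNR-versus-depth numbers from the simulator are not calibrated to any
  instrument.
* CW-SSIM is included as an optional metric with convention-chosen
  parameters and is excluded from acceptance checks.
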