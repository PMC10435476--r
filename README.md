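# pamgan

Deep-learning enhancement of acoustic-resolution photoacoustic microscopy
(AR-PAM) b-scans toward optical-resolution (OR-PAM) quality, in R.

Photoacoustic microscopy images optical absorption (hemoglobin, melanin)
by listening to the ultrasound that pulsed laser light generates in
tissue. The two standard embodiments sit at opposite ends of a trade-off:
OR-PAM focuses the laser to ~12 um lateral resolution but only works
within ~1 mm of the surface, while AR-PAM focuses the acoustic detection
instead, reaching ~1.9 mm (or several mm at 5 MHz) at ~85 um (or 590 um)
lateral resolution. Both share the ~27 um axial resolution of the
transducer. `pamgan` learns the mapping from AR b-scans to OR-like
b-scans with image-to-image translation GANs:

* a **conditional GAN** (paired): generator `G` maps an AR patch to an
  OR-like patch; a Markovian patch discriminator judges (source,
  candidate) pairs; the generator loss adds a weighted L1 distance to the
  co-registered OR target:

  `L(A,O) = E[log D(A,O)] + E[log(1 - D(A,G(A)))] + lambda * E|O - G(A)|_1`

* a **CycleGAN** (unpaired): forward and backward generators with two
  unconditioned discriminators and cycle-consistency L1 terms
  `|F(G(a)) - a| + |G(F(o)) - o|`, for label-free training when no
  co-registered OR scan exists.

The generator is the ResNet-style encoder/decoder (7x7 stem, strided
downsampling, residual blocks with identity skips, transposed-conv
decoder; 9 blocks x 64 filters at full scale) and training follows the
reference schedule (Adam, lr 2e-4 halved by a scheduler, batch 1,
unsigned-8-bit patches). All network layers, their backward passes and
the optimizer are implemented in the package (RcppArmadillo kernels), so
the whole pipeline runs on one CPU with no deep-learning framework.

Because no public dataset exists for this instrument pairing, the package
includes a dual-PSF forward simulator (hair and vessel phantoms, depth-
dependent Gaussian PSFs, attenuation, visibility cutoffs, noise) that
produces intrinsically co-registered AR/OR/truth volumes, plus the full
evaluation suite used for quality comparison: SNR and CNR in dB over
explicit ROIs, SSIM, and lateral/axial Gaussian-fit FWHM profiling.

## Worked example

Desk-scale end-to-end run — simulate co-registered vessel phantoms, train
the compact paired model, enhance held-out AR scans, and measure recovery:

```r
library(pamgan)

res <- run_recovery_experiment(seed = 1, mode = "cgan", epochs = 15)
dplyr::glimpse(res$metrics)
#> Rows: 1
#> Columns: 10
#> $ mode                 <chr> "cgan"
#> $ epochs               <int> 15
#> $ n_train_pairs        <int> 200
#> $ l1_ar                <dbl> 0.01669853
#> $ l1_generated         <dbl> 0.01271045
#> $ ssim_ar_truth        <dbl> 0.4099672
#> $ ssim_generated_truth <dbl> 0.7797905
#> $ fwhm_ar_um           <dbl> 77.64913
#> $ fwhm_or_um           <dbl> 16.03104
#> $ fwhm_generated_um    <dbl> 5.765007
```

Reading the numbers: on two held-out phantom volumes the enhanced output
is closer to the OR scan than the raw AR input in mean absolute error
(`l1_generated < l1_ar`, a 24% reduction) and far more similar to the
noise-free ground truth (`ssim 0.78 vs 0.41` — the AR input is both
blurred and noisy). A held-out 20 um calibration tube that images at
77.6 um FWHM in the AR scan comes out at 5.8 um after enhancement,
against 16.0 um in the OR scan: the generator restores (here slightly
over-sharpens past) OR-like lateral resolution from AR input. Exact
values vary with the seed; the unpaired CycleGAN variant
(`mode = "cyclegan"`, 16 epochs) shows the same qualitative recovery
with smaller margins.

The same pipeline is scriptable from a config file:

```sh
inst/cli/pamgan run --demo --seed 1 --out demo-out --verbose
# or with an explicit YAML configuration:
inst/cli/pamgan run --config inst/extdata/demo-config.yaml
```

which writes TIFF volumes, MAP/depth-map PNGs, the training-history CSV,
a model checkpoint, the SNR/CNR/SSIM/FWHM metrics CSV, and a JSON
provenance record per stage.

Lower-level pieces compose with the pipe:

```r
vol <- make_truth_volume(phantom_spec("hairs"), pitch_spec(), seed = 1) |>
  simulate_scan(psf_ar(), noise_model(0.01, 0), seed = 2, modality = "AR")
map <- max_amplitude_projection(vol)
autoplot(map)                      # en-face MAP
autoplot(map, what = "depth")      # depth-encoded MAP
```

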