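# scanloc

Single-molecule localization microscopy (SMLM) reconstruction for
**confocal line-scan** data — the regime where fluorophores photoswitch
*while* a galvanometric scanner sweeps their point spread function, so the
camera records Airy patterns chopped off at the top or bottom. Gaussian
PSF fitting fails on such data; `scanloc` replaces it with a stack of
compressed sensing and small convolutional fitters trained on a faithful
simulator.

The package is aimed at microscopists and methods developers working with
line-scanned dSTORM/FLIM-style acquisitions, and at anyone who wants a
self-contained, dependency-light reference implementation of

* a **line-by-line raster simulator**: emitters appear with Poisson rate
  λ per scanned line, wait through a Poisson(90 ms) switch-ON countdown,
  stay ON for a Poisson(90 ms) lifetime (the line clock is Δt = 6 ms),
  and are rendered into each line band only while ON. An emitter is
  accepted as ground truth when the scanner captured ≥ 40% of its ON
  lines. Photon counts are drawn from [800, 1500] with 20% per-frame
  jitter; noise is Poisson shot noise plus Gaussian read noise with
  σ ∈ [175, 185] drawn per batch.
* a **trainable orthogonal wavelet filter bank** (shared
  analysis/synthesis taps, Gram–Schmidt-coupled `lp_n = lp − ⟨hp,lp⟩/⟨hp,hp⟩·hp`,
  per-subband bias + ReLU) for denoising and ROI detection;
* a **FISTA compressed-sensing layer** minimizing
  `½‖Ab − y‖² + λ‖b‖₁, b ≥ 0` on a u-fold upsampled emitter lattice, with
  λ predicted per crop by a small CNN (sigmoid × 0.025) and the whole
  solver unrolled on a built-in autodiff tape so gradients reach the λ
  estimator;
* four **fitter architectures** (CS-CNN, CS-Inception, CS-U-Net and a
  Recursive U-Net that replaces the CS matrix iterations with
  weight-shared encode/decode refinement steps,
  `F(N+1) = F(N) + F_update`, image state `BN(x(t) + x(0) + update)`)
  mapping a 9×9×3 crop to the 8-channel feature space
  `(p, Δx, Δy, N, σx, σy, σN, B)`;
* the **Gaussian-mixture localization loss** with count and background
  terms (`L = L_loc + L_count + L_bg`);
* deterministic **post-processing**: pixels above `t_cls` seed a
  cross-shaped filter `F = [[0,1,0],[1,1,1],[0,1,0]]`; a formation whose
  cross sum exceeds `t_re = 0.7` emits its highest-probability pixel,
  above `2·t_re` also the second highest;
* **evaluation**: Jaccard index `TP/(TP+FP+FN)` with optimal (Hungarian)
  matching, RMSE over matched pairs, and Fourier ring correlation between
  half-dataset renderings.

Everything — including the networks — runs on base R linear algebra; no
deep-learning runtime is required.

## Worked example

Simulate a movie, train a small Recursive U-Net on simulated crops, and
reconstruct:

```r
library(scanloc)

cfg <- scan_config(s_im = 16L, lambda_on = 0.4, seed = 42L)
stack <- simulate_stack(cfg, n_frames = 40)
nrow(stack$truth)
#> [1] 437                  # accepted ground-truth emitters

crops <- make_training_crops(2400, scan_config(), seed = 1)
model <- fitter_net("rec_unet", seed = 1)
res <- train_fitter(model, crops[1:2000], crops[2001:2400],
                    steps = 1600, eval_every = 400, lr = 1e-3)
tail(res$log, 1)
#>   step     loss val_loss        JI     RMSE
#> 4 1600 8.274442  23.7078 0.4602941 77.17383

write_stack_tiff(stack, "movie.tif")
tab <- infer_stack("movie.tif", model)
head(tab, 2)
#>   frame   x_px   y_px photons sigma_x sigma_y sigma_N p_score
#> 1     0  9.765  9.776    1706 0.20137  0.3471  0.2415  0.3082
#> 2     0 14.840 12.827    1905 0.09376  0.1542  0.1801  0.4303
write_thunderstorm_csv(tab, "locs.csv")         # nm units, 1-based frames

ev <- evaluate_predictions(tab, stack$truth)    # vs simulator ground truth
```

`x_px`/`y_px` are pixel-unit coordinates (100 nm pixels); `photons` is the
estimated brightness in detector units; `sigma_*` are the per-localization
uncertainty channels; `p_score` is the classifier probability of the
emitting pixel. The training log row shows the detector improving on its
held-out crops (Jaccard 0.46, RMSE 77 nm at a 250 nm match radius after
1600 steps); the demonstration movie above is a dense scene whose
partially scanned emitters remain hard at this training budget, so the
end-to-end scores on it are substantially lower than the per-crop ones.
Confidence and the scores grow steadily with more steps — see the
vignette for how the training scale interacts with the probability map
and the extraction thresholds.

Crop datasets serialize via `write_crops()`/`read_crops()` as one array
container (`<prefix>_pixels.rds`: the `9×9×3×n` noisy and noiseless
arrays plus per-crop σ) and a ground-truth CSV (`<prefix>_truth.csv`:
`crop,x,y,photons`, 0-based crop index, pixel units).

The same operations are available from a shell via the thin dispatcher
`inst/cli/scanloc.R` (`simulate`, `detect`, `train`, `fit`, `cs-fit`,
`evaluate`, `render`).

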