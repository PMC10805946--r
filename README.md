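# interpgaze

Trait-interpolated gaze-behavior sensor data via a semi-supervised
InfoGAN, in R.

## The problem

Head and eye movements recorded by glasses-type wearables (3-axis
accelerometer, 3-axis gyrometer, 3-channel electrooculography, 50 Hz) carry
a saccade–fixation rhythm that personality traits modulate — but each
individual also imprints attributes (sensor gains, offsets, noise,
idiosyncratic rhythms) that swamp between-individual comparisons when only
a dozen participants are available.  `interpgaze` disentangles the two: a
semi-supervised information-maximizing adversarial network (ss-InfoGAN)
learns a generator `G(c_BF', c_P', c_T', z)` over standardized 9 × 512
sensor windows, where `c_BF'` are five continuous Big-Five codes, `c_P'` a
one-hot person-identity code, `c_T'` a time code and `z` noise.  Sweeping
the openness code at **fixed** identity codes produces *interpolated* data —
the same virtual individual at every trait level — from which trait effects
can be read by simple averaging, e.g. as the lag of the peak of the mean
movement-amplitude autocorrelation (in 50 Hz samples):

```
r_k = sum_t (x_t - x̄)(x_{t+k} - x̄) / sum_t (x_t - x̄)^2 ,   k = 0..150
```

with `x_t = |ΔACC_X| + |ΔACC_Y| + |GYRO_X| + |GYRO_Y| + |EOG_H| + |EOG_V|`.

The package implements, as first-class tested code:

* a ground-truthed **simulator** (`sim_config()`, `simulate_dataset()`):
  gamma-renewal saccade–fixation streams whose log mean fixation duration
  is `log μ0(task) + β(task)·openness`, rendered per channel with
  per-individual attribute confounds orthogonal to all traits;
* **preprocessing** (`make_windowed_dataset()`): smoothing, 512/128
  windowing, per (channel, participant, task) standardization, and the
  three label families;
* the **model and training loop** (`init_model()`, `fit()`): 1-D
  transposed-convolution generator and convolutional discriminator with
  batch/spectral normalization, translation-consistency augmentation, Adam
  (0.005/0.001, β1 = 0.5, β2 = 0.9), hand-derived exact backprop (compiled
  im2col/col2im kernels under `src/`);
* the three **disentanglement tests** (`real_data_test()` with
  leave-one-out cross-validation, `generated_data_test()`,
  `real_and_generated_test()`);
* the **interpolation analysis** (`sweep_generate()`, `profile_by_level()`,
  `peak_lag()`, `trend_test()`);
* a staged **pipeline CLI** (`run_stage()`, `inst/cli/interpgaze.R`) with
  YAML configs and hash-checked artifacts.

## Worked example

A miniature end-to-end run (about a minute on one CPU):

```r
library(interpgaze)

cfg <- sim_config(n_participants = 6, tasks = "data_entry",
                  duration_s = 240,
                  fixation_mean_base = c(data_entry = 1.6),
                  trait_slope = c(data_entry = -0.3), seed = 5)
sim <- simulate_dataset(cfg, seed = 5)
ds  <- make_windowed_dataset(sim$recordings, sim$population)
ds
#> <windowed_dataset> 540 windows of 9x512; 6 participants; tasks: data_entry

model <- init_model(arch_config("desk"), length(ds$roster), seed = 11)
res   <- fit(ds, model, train_config(epochs = 30, batch_size = 64, seed = 3))
tail(res$log[, c("epoch", "p_real_real", "p_real_fake")], 1)
#>    epoch p_real_real p_real_fake
#> 30    30   0.6754325   0.3261753
```

The adversarial probabilities settle with real above generated, both away
from 0/1 — the stable-band signature of established adversarial training.
Now ask the discriminator's code head how well the generator's openness
code can be recovered from its own generated windows (the generated data
test), per virtual individual:

```r
gt <- generated_data_test(res$model, n_cases = 50, seed = 21)
round(c(mean_r = gt$mean_r, sd_r = gt$sd_r), 2)
#> mean_r   sd_r
#>   0.64   0.10
```

A mean within-individual correlation of 0.64 between the openness code fed
to the generator and the code estimated back from the generated windows
means trait variation is encoded in the synthetic sensor data at fixed
identity — the disentanglement the method exists to deliver.  The full
evaluation (held-out-participant trait estimation, transfer to an
independent estimator, and the sweep's period-versus-openness trend) runs in
`tests/testthat/test-acceptance.R`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic world does and does not emulate, numerical conventions, and known
limitations.
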