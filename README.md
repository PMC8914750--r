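# gripforce

Grip strength estimation from forearm muscle deformation (force myography)
at multiple wrist angles, with a fully synthetic sensor bench so every stage
of the pipeline is testable without hardware.

## The problem

Force myography infers hand grip force from the mechanical deformation of
the forearm surface instead of from electrical (EMG) activity, which is
sensitive to sweat, hair and electrode placement. The sensing model here is
a wearable band with twelve photoresistor channels (sponge compression
changes light transmission, hence the divider voltage) that read muscle
deformation, and three Hall sensors that read the field of a wrist-mounted
magnet to encode the wrist angle. Grip force depends on the wrist posture,
so the estimator is *angle-conditioned*: a classifier recognizes the wrist
angle from the Hall channels and selects that angle's muscle-model
parameters.

## The model

Each deformation channel is treated as a Voigt viscoelastic element (spring
and damper in parallel), linearized to

    F = a · X + b · Ẋ + c

where `X` is the 12-channel deformation signal, `Ẋ` its time derivative,
`a` (12 elastic coefficients), `b` (12 viscosity coefficients) and `c` (one
offset) are fitted per wrist angle by linear least squares, minimizing
`Q = Σᵢ (Fᵢ − F(Xᵢ))²` over the 25 free parameters. Wrist angle
(−90°, 0°, 90°) is recognized by a time-series 1-D CNN over 200 ms windows
in which the three Hall channels are stitched into one vector, min-max
normalized, and convolved along time (two conv–ReLU–maxpool stages, a dense
softmax head, seeded SGD with momentum, and disturbance augmentation so
windows with spikes or a 100-sample data loss are still classified).
Evaluation uses RMSE between measured and estimated force, per angle and
averaged.

The synthetic bench generates everything the pipeline consumes: a
saturating photoresistor response, a cosine-geometry Hall field, 10-bit 0–5
V ADC quantization (LSB 4.88 mV), grip ramps from 0 toward the 35 N
grip-meter range, configurable noise (with the −90° angle noisier, where
gripping is awkward), and seeded reproducibility down to byte-identical
CSVs.

## Worked example

```r
library(gripforce)

cfg <- synth_config()                         # default synthetic subject
trial <- generate_grip_trial(0, cfg, seed = 1)
head(trial[, c("t", "p01", "p02", "h1", "h2", "h3", "force")], 3)
#>       t       p01       p02       h1       h2       h3     force
#> 1 0.000 0.4638672 0.5224609 3.128252 3.548504 3.297525 1.5127078
#> 2 0.001 0.5273438 0.5273438 3.051728 3.527459 3.272676 2.1763803
#> 3 0.002 0.5029297 0.4882812 3.302551 3.543809 3.181456 0.6286668

fit_trials(trial, cfg, angle = 0)             # least-squares Voigt fit
#> <voigt_fit> angle 0 deg: n = 4000, Q = 3820 N^2

res <- reproduce_experiment(seed = 42)        # the whole experiment
res
#> <eval_summary>
#>   RMSE per angle (N): -90: 1.674, 0: 1.010, 90: 0.999
#>   RMSE mean +/- sd: 1.228 +/- 0.346 N
#>   measured~estimated r: 0.9938
#>   wrist-angle accuracy: 100.00%
#>   force~deformation r (mean over angles): 0.9940
```

Reading the output: each 4 s trial ramps the grip from rest toward 35 N;
`Q` is the residual sum of squares of the fit against the noisy force
measurement (≈1 N² per sample at the default 1 N force noise).
`reproduce_experiment()` trains the wrist-angle CNN on stitched Hall
windows (here classifying every held-out window correctly), fits per-angle
Voigt parameters on training trials, and estimates force on held-out trials
with classifier-gated parameter selection. The −90° angle carries the
largest RMSE because the synthetic subject is configured noisier there;
estimated force stays within about 1.2 N RMSE of the measurement on
average, and grip force correlates with mean deformation at r ≈ 0.99.

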