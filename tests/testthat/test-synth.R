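# Sensor-physics generator: response curves, ADC, Hall field, trials,
# corruption, CSV determinism.

test_that("photoresistor curve anchors at v_dark, saturates at v_sat, and is strictly monotone", {
  cfg <- synth_config()
  expect_identical(photoresistor_response(0, cfg), cfg$photo_curve$v_dark)
  # saturation limit of the exponential form
  expect_equal(photoresistor_response(1e6, cfg), cfg$photo_curve$v_sat,
               tolerance = 1e-12)
  v <- photoresistor_response(0:15, cfg)
  expect_true(all(diff(v) > 0))
  expect_error(photoresistor_response(-1, cfg), "finite and >= 0")
  expect_error(photoresistor_response(NaN, cfg), "finite and >= 0")
})

test_that("ADC LSB is 4.88 mV at 10 bit / 5 V and quantization obeys the half-LSB bound", {
  cfg <- synth_config()
  expect_equal(round(1000 * adc_lsb(cfg), 2), 4.88)
  expect_identical(quantize_adc(0, cfg), 0)
  expect_identical(quantize_adc(6.0, cfg), 5.0)  # clamped to full scale
  v <- seq(0, 5, length.out = 2001)
  q <- quantize_adc(v, cfg)
  expect_true(all(abs(q - v) <= adc_lsb(cfg) / 2 + 1e-15))
  expect_true(all(q >= 0 & q <= 5))
  expect_error(quantize_adc(Inf, cfg), "finite")
})

test_that("hall response peaks at the placement phase, is even for zero phase, and separates the three angles", {
  cfg <- synth_config()
  hg <- cfg$hall_geometry
  for (i in 1:3) {
    expect_equal(hall_response(hg$phase[i], i, cfg),
                 hg$baseline + hg$amplitude[i])
  }
  cfg0 <- synth_config(hall_geometry = list(baseline = 2, amplitude = c(1, 1, 1),
                                            phase = c(0, 0, 0)))
  for (th in c(10, 45, 120)) {
    expect_equal(hall_response(th, 1, cfg0), hall_response(-th, 1, cfg0))
  }
  # the three 3-vectors at -90, 0, 90 are pairwise distinct
  vecs <- sapply(c(-90, 0, 90), function(th) {
    sapply(1:3, function(i) hall_response(th, i, cfg))
  })
  d <- as.matrix(dist(t(vecs)))
  expect_true(all(d[upper.tri(d)] > 0.1))
  expect_error(hall_response(0, 4, cfg), "sensor_index")
  expect_error(hall_response(200, 1, cfg), "theta")
})

test_that("grip trials keep force within the grip-meter range and track mean deformation", {
  cfg <- synth_config()
  for (ang in c(-90, 0, 90)) {
    tr <- generate_grip_trial(ang, cfg, seed = 11 + ang)
    expect_true(all(tr$force >= 0 & tr$force <= 35))
    expect_true(all(as.matrix(tr[, sprintf("p%02d", 1:12)]) >= 0))
    expect_true(all(as.matrix(tr[, sprintf("p%02d", 1:12)]) <= 5))
    expect_gte(force_deformation_correlation(tr), 0.96)
  }
  expect_error(generate_grip_trial(45, cfg), "one of -90, 0, 90")
})

test_that("a zero-noise trial satisfies the Voigt model exactly before quantization", {
  cfg0 <- synth_config(noise = list(photo_sd = 0, hall_sd = 0, force_sd = 0),
                       trial_duration = 1)
  tr <- generate_grip_trial(0, cfg0, seed = 5, quantize = FALSE)
  X <- attr(tr, "latent_voltage")
  D <- attr(tr, "latent_deriv")
  p <- cfg0$true_params[["0"]]
  resid <- tr$force - (X %*% p$a + D %*% p$b + p$c)
  expect_lt(max(abs(resid)), 1e-9)
  # emitted photo channels equal the latent voltages when noise and ADC are off
  expect_equal(as.matrix(tr[, sprintf("p%02d", 1:12)]), X,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("trial generation is reproducible and the CSV round-trips byte-identically", {
  cfg <- synth_config()
  t1 <- generate_grip_trial(90, cfg, seed = 123)
  t2 <- generate_grip_trial(90, cfg, seed = 123)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_sensor_csv(t1, f1); write_sensor_csv(t2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_sensor_csv(f1)
  expect_equal(back$force, t1$force, tolerance = 1e-12)
  unlink(c(f1, f2))
})

test_that("window corruption alters exactly the contracted samples and never the label", {
  w <- structure(list(values = runif(600) + 1, label = 0, t_start = 0, W = 200L),
                 class = "hall_window")
  d <- corrupt_window(w, "dropout", seed = 4)
  expect_identical(sum(d$values != w$values), 100L)
  expect_identical(d$label, w$label)
  expect_length(d$values, 600L)
  # a zeroed run is contiguous
  changed <- which(d$values == 0)
  expect_identical(changed, changed[1]:(changed[1] + 99L))

  s0 <- corrupt_window(w, "spikes", k = 0, seed = 4)
  expect_identical(s0$values, w$values)
  s5 <- corrupt_window(w, "spikes", k = 5, seed = 4)
  expect_identical(sum(s5$values != w$values), 5L)
  expect_identical(s5$label, w$label)

  short <- structure(list(values = runif(60), label = 0, t_start = 0, W = 20L),
                     class = "hall_window")
  expect_error(corrupt_window(short, "dropout"), ">= 100 samples")
})

test_that("config validation enforces the generator invariants and YAML round-trips", {
  expect_error(synth_config(sampling_rate = 0), "sampling_rate")
  expect_error(synth_config(max_force = -1), "max_force")
  expect_error(synth_config(adc = list(bits = 0, v_ref = 5)), "bits")
  expect_error(synth_config(noise = list(photo_sd = -0.1, hall_sd = 0, force_sd = 0)),
               "noise")
  bad_bank <- default_param_bank()[c("0", "90")]
  expect_error(synth_config(true_params = bad_bank), "angle keys")

  cfg <- synth_config(seed = 77L)
  f <- tempfile(fileext = ".yaml")
  write_synth_config(cfg, f)
  back <- read_synth_config(f)
  expect_equal(back$seed, 77L)
  expect_equal(back$true_params[["-90"]]$a, cfg$true_params[["-90"]]$a)
  expect_equal(back$noise$angle_scale[["-90"]], 1.75)
  unlink(f)
})
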