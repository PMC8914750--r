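# Voigt model: derivatives, prediction, least-squares fitting, gated
# end-to-end estimation.

test_that("derivative estimation is exact on constants and ramps and accurate on sinusoids", {
  expect_equal(estimate_derivative(rep(4, 10), dt = 0.01), rep(0, 10))
  ramp <- 3.5 * (0:20)
  expect_equal(estimate_derivative(ramp, dt = 1), rep(3.5, 21))
  t_s <- seq(0, 1, by = 1e-3)
  d <- estimate_derivative(sin(2 * pi * t_s), dt = 1e-3)
  analytic <- 2 * pi * cos(2 * pi * t_s)
  interior <- 2:(length(t_s) - 1)
  expect_lt(max(abs(d[interior] - analytic[interior])), 1e-3)
  expect_error(estimate_derivative(1:10, dt = 0), "> 0")
  expect_error(estimate_derivative(1:2, dt = 1), "3 time points")
})

test_that("predict_force evaluates the linear Voigt form", {
  p <- voigt_params(a = rep(0, 12), b = rep(0, 12), c = 7, angle = 0)
  expect_equal(predict_force(p, rep(0, 12), rep(0, 12)), 7)
  a <- rep(0, 12); a[3] <- 1
  p2 <- voigt_params(a = a, b = rep(0, 12), c = 0, angle = 0)
  x <- rep(0, 12); x[3] <- 2
  expect_equal(predict_force(p2, x, rep(0, 12)), 2)
  # affine combination of states maps to the same combination of forces (c = 0)
  set.seed(4)
  p3 <- voigt_params(a = rnorm(12), b = rnorm(12), c = 0, angle = 90)
  s1 <- rnorm(12); s2 <- rnorm(12); d1 <- rnorm(12); d2 <- rnorm(12)
  for (al in c(0.2, 0.5, 0.9)) {
    expect_equal(predict_force(p3, al * s1 + (1 - al) * s2, al * d1 + (1 - al) * d2),
                 al * predict_force(p3, s1, d1) + (1 - al) * predict_force(p3, s2, d2))
  }
  expect_error(predict_force(p3, rep(Inf, 12), rep(0, 12)), "finite")
})

test_that("zero-noise fitting recovers the generator truth and matches the pseudo-inverse oracle", {
  cfg0 <- synth_config(noise = list(photo_sd = 0, hall_sd = 0, force_sd = 0),
                       trial_duration = 1)
  for (ang in c(-90, 0, 90)) {
    tr <- generate_grip_trial(ang, cfg0, seed = 21, quantize = FALSE)
    X <- attr(tr, "latent_voltage")
    D <- attr(tr, "latent_deriv")
    ft <- fit_voigt_params(X, D, tr$force, ang)
    truth <- cfg0$true_params[[as.character(ang)]]
    expect_lt(max(abs(ft$params$a - truth$a)), 1e-6)
    expect_lt(max(abs(ft$params$b - truth$b)), 1e-6)
    expect_lt(abs(ft$params$c - truth$c), 1e-6)
    expect_lt(ft$Q, 1e-12)
    expect_false(ft$condition_warning)
    expect_equal(ft$n, 1000L)
    # independent oracle: Moore-Penrose pseudo-inverse on the same design
    A <- cbind(X, D, 1)
    beta <- MASS::ginv(A) %*% tr$force
    expect_equal(c(ft$params$a, ft$params$b, ft$params$c), as.numeric(beta),
                 tolerance = 1e-8)
  }
})

test_that("degenerate and duplicated designs behave as least squares dictates", {
  # constant deformation, constant force: intercept absorbs it exactly
  X <- matrix(1, 40, 12); D <- matrix(0, 40, 12)
  ft <- fit_voigt_params(X, D, rep(8, 40), 0)
  expect_equal(ft$Q, 0, tolerance = 1e-18)
  expect_true(ft$condition_warning)  # rank-deficient design
  expect_equal(predict_force(ft$params, rep(1, 12), rep(0, 12)), 8,
               tolerance = 1e-9)
  # duplicating rows leaves the minimizer unchanged
  cfg0 <- synth_config(noise = list(photo_sd = 0, hall_sd = 0, force_sd = 0.5),
                       trial_duration = 1)
  tr <- generate_grip_trial(0, cfg0, seed = 9, quantize = FALSE)
  Xl <- attr(tr, "latent_voltage"); Dl <- attr(tr, "latent_deriv")
  f1 <- fit_voigt_params(Xl, Dl, tr$force, 0)
  f2 <- fit_voigt_params(rbind(Xl, Xl), rbind(Dl, Dl), c(tr$force, tr$force), 0)
  expect_equal(f1$params$a, f2$params$a, tolerance = 1e-8)
  expect_equal(f1$params$c, f2$params$c, tolerance = 1e-8)
  expect_error(fit_voigt_params(Xl[1:10, ], Dl[1:10, ], tr$force[1:10], 0),
               "under-determined")
})

test_that("fitted Q never exceeds Q at the generator truth, and refitting predictions is idempotent", {
  cfg <- synth_config(trial_duration = 1)
  for (s in 1:3) {
    tr <- generate_grip_trial(0, cfg, seed = 30 + s)
    ft <- fit_trials(tr, cfg, 0)
    X <- gripforce:::maf_matrix(as.matrix(tr[, sprintf("p%02d", 1:12)]))
    D <- estimate_derivative(X, 1 / cfg$sampling_rate)
    truth <- cfg$true_params[["0"]]
    Q_true <- sum((tr$force - predict_force(truth, X, D))^2)
    expect_lte(ft$Q, Q_true)
    # refit on the model's own predictions: same parameters, zero residual
    refit <- fit_voigt_params(X, D, predict_force(ft$params, X, D), 0)
    expect_equal(refit$params$a, ft$params$a, tolerance = 1e-6)
    expect_equal(refit$params$b, ft$params$b, tolerance = 1e-6)
    expect_lt(refit$Q, 1e-10)
  }
})

test_that("parameter recovery error shrinks as force noise shrinks", {
  base <- synth_config(trial_duration = 1)
  mae <- sapply(c(0, 0.5, 1.0), function(sdf) {
    cfgn <- synth_config(noise = list(photo_sd = 0, hall_sd = 0, force_sd = sdf),
                         trial_duration = 1)
    errs <- sapply(1:20, function(s) {
      tr <- generate_grip_trial(0, cfgn, seed = 400 + s, quantize = FALSE)
      ft <- fit_voigt_params(attr(tr, "latent_voltage"), attr(tr, "latent_deriv"),
                             tr$force, 0)
      truth <- cfgn$true_params[["0"]]
      mean(abs(c(ft$params$a - truth$a, ft$params$b - truth$b)))
    })
    mean(errs)
  })
  expect_true(all(diff(mae) > 0))  # monotone in the noise level
})

test_that("end-to-end gated estimation is near-exact on a clean stream and total on noisy ones", {
  cfg0 <- synth_config(noise = list(photo_sd = 0, hall_sd = 0, force_sd = 0))
  bank <- lapply(cfg0$true_params, identity)
  tr <- generate_grip_trial(0, cfg0, seed = 77)
  trace <- estimate_grip(tr, fixture_model, bank, cfg0)
  expect_true(all(is.finite(trace$Fp)))
  expect_equal(nrow(trace), nrow(tr))
  # ADC quantization is the only error source on a clean stream
  expect_lt(max(abs(trace$Fp - attr(tr, "force_true"))), 0.1)
  expect_true(all(trace$angle_pred == 0))

  # angle schedule -90 -> 0 -> 90: exactly one parameter switch per transition
  cfg <- synth_config()
  streams <- lapply(c(-90, 0, 90), function(a) {
    generate_angle_stream(a, 4, cfg, seed = 600 + a)
  })
  sched <- do.call(rbind, streams)
  sched$t <- (seq_len(nrow(sched)) - 1) / cfg$sampling_rate
  trace2 <- estimate_grip(sched, fixture_model, bank, cfg)
  switches <- sum(diff(trace2$angle_pred) != 0)
  expect_equal(switches, 2L)
  expect_equal(unique(trace2$angle_pred), c(-90, 0, 90))
})

test_that("parameter banks round-trip through JSON", {
  bank <- default_param_bank()
  f <- tempfile(fileext = ".json")
  write_param_bank(bank, f)
  back <- read_param_bank(f)
  expect_equal(back[["90"]]$a, bank[["90"]]$a)
  expect_equal(back[["-90"]]$c, bank[["-90"]]$c)
  unlink(f)
})
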