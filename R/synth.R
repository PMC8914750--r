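# Synthetic sensor physics: photoresistor curve, ADC, Hall field, grip trials.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive k named sub-seeds from one top-level seed (kept < 2^31).
split_seed <- function(seed, names) {
  with_rng_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(names))
    names(s) <- names
    s
  })
}

#' Photoresistor voltage response to sponge deformation
#'
#' Saturating exponential model of the sensing element: compressing the
#' light-permeable sponge raises its density, more light reaches the
#' photoresistor, and the divider voltage rises from the dark level toward a
#' saturation level,
#' `v = v_dark + (v_sat - v_dark) * (1 - exp(-d / d_scale))`.
#' The curve is strictly increasing and deterministic; measurement noise and
#' ADC quantization are applied separately by the generator.
#'
#' @param d Deformation in mm, in the characterized range 0-15 mm.
#' @param cfg A [synth_config] supplying `photo_curve`.
#' @return Voltage(s) in V, same length as `d`.
#' @examples
#' cfg <- synth_config()
#' photoresistor_response(0, cfg)   # dark voltage
#' photoresistor_response(10, cfg)
#' @export
photoresistor_response <- function(d, cfg) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0)) {
    stop("deformation `d` must be finite and >= 0", call. = FALSE)
  }
  pc <- cfg$photo_curve
  pc$v_dark + (pc$v_sat - pc$v_dark) * (1 - exp(-d / pc$d_scale))
}

#' ADC least-significant-bit step
#'
#' Full scale divided by the code count: `v_ref / 2^bits`. For the default
#' 10-bit, 5 V converter this is 4.88 mV.
#'
#' @param cfg A [synth_config].
#' @return LSB in volts.
#' @export
adc_lsb <- function(cfg) {
  cfg$adc$v_ref / 2^cfg$adc$bits
}

#' Quantize a voltage through the simulated ADC
#'
#' Clamps to `[0, v_ref]` and rounds to the nearest LSB multiple, so the
#' quantization error never exceeds half an LSB.
#'
#' @param v Voltage(s), finite.
#' @param cfg A [synth_config].
#' @return Quantized voltage(s) in `[0, v_ref]`.
#' @examples
#' quantize_adc(2.5001, synth_config())
#' @export
quantize_adc <- function(v, cfg) {
  if (!is.numeric(v) || any(!is.finite(v))) {
    stop("`v` must be finite", call. = FALSE)
  }
  lsb <- adc_lsb(cfg)
  v <- pmin(pmax(v, 0), cfg$adc$v_ref)
  round(v / lsb) * lsb
}

#' Hall-sensor field at a given wrist angle
#'
#' Cosine dipole approximation: sensor i, mounted with an angular placement
#' offset `phase[i]`, reads `baseline + amplitude[i] * cos(theta - phase[i])`
#' when the wrist-mounted magnet sits at angle `theta`. The three placement
#' phases make the 3-vector of readings distinct at -90, 0 and 90 degrees,
#' which is all the classifier needs.
#'
#' @param theta Wrist angle(s) in degrees, in `[-180, 180]`.
#' @param sensor_index Which Hall sensor, 1..3.
#' @param cfg A [synth_config] supplying `hall_geometry`.
#' @return Field value(s) (arbitrary units on the ADC voltage scale).
#' @examples
#' cfg <- synth_config()
#' sapply(1:3, function(i) hall_response(0, i, cfg))
#' @export
hall_response <- function(theta, sensor_index, cfg) {
  if (any(!is.finite(theta)) || any(theta < -180) || any(theta > 180)) {
    stop("`theta` must be finite and within [-180, 180] degrees", call. = FALSE)
  }
  if (length(sensor_index) != 1L || !(sensor_index %in% 1:3)) {
    stop("`sensor_index` must be 1, 2 or 3", call. = FALSE)
  }
  hg <- cfg$hall_geometry
  hg$baseline + hg$amplitude[sensor_index] *
    cos((theta - hg$phase[sensor_index]) * pi / 180)
}

# Smoothstep ramp 0 -> 1 with zero slope at both ends.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# Latent 12-channel deformation field for one ramp trial (mm). Each channel
# ramps to its own peak with small smooth sinusoidal perturbations; the
# per-channel frequencies/phases differ so the 25-column design matrix built
# from any trial has full rank.
latent_deformation <- function(t_s, duration) {
  n <- length(t_s)
  env <- smoothstep(t_s / duration)
  j <- seq_len(12)
  d_peak <- 8.5 + 1.2 * sin(j * 0.7)
  d <- matrix(0, n, 12)
  for (k in j) {
    # per-channel envelope shape + three incommensurate sinusoids keep the
    # 12 channels (and their derivatives) linearly well separated
    p_env <- stats::runif(1, 0.6, 1.6)
    f <- stats::runif(3, c(0.3, 0.9, 1.8), c(0.8, 1.6, 2.6))
    ph <- stats::runif(3, 0, 2 * pi)
    amp <- c(0.55, 0.35, 0.20) * stats::runif(3, 0.7, 1.3)
    peak <- d_peak[k] * stats::runif(1, 0.90, 1.05)
    ripple <- amp[1] * sin(2 * pi * f[1] * t_s + ph[1]) +
      amp[2] * sin(2 * pi * f[2] * t_s + ph[2]) +
      amp[3] * sin(2 * pi * f[3] * t_s + ph[3])
    d[, k] <- pmax(peak * env^p_env + ripple * env, 0)
  }
  d
}

#' Generate one synthetic grip-ramp trial
#'
#' Simulates a subject slowly squeezing the grip meter from rest toward its
#' 35 N range at a fixed wrist angle. Twelve smooth latent deformation
#' channels are mapped through [photoresistor_response()] to clean voltages
#' `X`; the ground-truth grip force is computed from the angle's Voigt
#' parameters as `F = a.X + b.Xdot + c` (with `Xdot` from the same
#' central-difference estimator the fitting routine uses, so a zero-noise
#' trial satisfies the model exactly) and clipped to the grip-meter range.
#' Emitted photoresistor channels receive Gaussian noise (scaled per angle by
#' `noise$angle_scale`) and, by default, ADC quantization; Hall channels are
#' the angle's [hall_response()] plus noise; the emitted force is the true
#' force plus measurement noise, clipped to `[0, max_force]`.
#'
#' @param angle Wrist angle: -90, 0 or 90.
#' @param cfg A [synth_config].
#' @param seed Integer seed; the trial is reproducible given `(cfg, seed)`.
#' @param quantize Apply ADC quantization to the photoresistor channels
#'   (default `TRUE`). Disable to inspect the pre-ADC signal path.
#' @param duration Trial length in seconds; defaults to `cfg$trial_duration`.
#' @return A data frame of class `grip_trial` with columns `t`, `p01..p12`,
#'   `h1..h3`, `force`, `angle`, plus attributes `latent_voltage`,
#'   `latent_deriv` (clean pre-noise voltage matrix and its derivative),
#'   `force_true` (pre-noise force) and `angle`.
#' @examples
#' tr <- generate_grip_trial(0, synth_config(trial_duration = 1), seed = 7)
#' range(tr$force)
#' @export
generate_grip_trial <- function(angle, cfg, seed = cfg$seed,
                                quantize = TRUE, duration = cfg$trial_duration) {
  assert_angle(angle)
  stopifnot(inherits(cfg, "synth_config"))
  n <- as.integer(round(duration * cfg$sampling_rate))
  if (n < 3L) stop("trial too short for derivative estimation", call. = FALSE)
  dt <- 1 / cfg$sampling_rate
  t_s <- (seq_len(n) - 1L) * dt
  key <- angle_key(angle)
  pars <- cfg$true_params[[key]]

  with_rng_seed(seed, {
    d <- latent_deformation(t_s, duration)
    v_clean <- photoresistor_response(d, cfg)
    dim(v_clean) <- dim(d)
    v_dot <- estimate_derivative(v_clean, dt)
    f_true <- as.numeric(v_clean %*% pars$a + v_dot %*% pars$b + pars$c)
    f_true <- pmin(pmax(f_true, 0), cfg$max_force)

    sd_photo <- cfg$noise$photo_sd * cfg$noise$angle_scale[[key]]
    v_emit <- v_clean
    if (sd_photo > 0) {
      v_emit <- v_emit + matrix(stats::rnorm(n * 12, sd = sd_photo), n, 12)
    }
    if (quantize) v_emit <- quantize_adc(v_emit, cfg)

    hall <- vapply(1:3, function(i) {
      h <- rep(hall_response(angle, i, cfg), n)
      if (cfg$noise$hall_sd > 0) h <- h + stats::rnorm(n, sd = cfg$noise$hall_sd)
      h
    }, numeric(n))

    sd_force <- cfg$noise$force_sd * cfg$noise$angle_scale[[key]]
    f_emit <- f_true
    if (sd_force > 0) f_emit <- f_emit + stats::rnorm(n, sd = sd_force)
    f_emit <- pmin(pmax(f_emit, 0), cfg$max_force)

    out <- data.frame(t = t_s, v_emit, hall, force = f_emit, angle = angle)
    names(out) <- c("t", sprintf("p%02d", 1:12), paste0("h", 1:3), "force", "angle")
    structure(out,
              latent_voltage = v_clean,
              latent_deriv = v_dot,
              force_true = f_true,
              angle = angle,
              class = c("grip_trial", "data.frame"))
  })
}

#' Generate a resting-hand stream at a fixed wrist angle
#'
#' Convenience generator for classifier data: the hand is relaxed (latent
#' deformation zero, photoresistor channels at dark voltage plus noise) while
#' the wrist holds one angle, so the Hall channels carry the class signal.
#'
#' @param angle Wrist angle: -90, 0 or 90.
#' @param n_windows Number of full stitching windows the stream must cover.
#' @param cfg A [synth_config].
#' @param seed Integer seed.
#' @return A `grip_trial`-shaped data frame (force column `NA`).
#' @export
generate_angle_stream <- function(angle, n_windows, cfg, seed = cfg$seed) {
  assert_angle(angle)
  n <- as.integer(n_windows) * window_samples(cfg)
  dt <- 1 / cfg$sampling_rate
  t_s <- (seq_len(n) - 1L) * dt
  key <- angle_key(angle)
  with_rng_seed(seed, {
    sd_photo <- cfg$noise$photo_sd * cfg$noise$angle_scale[[key]]
    v <- matrix(cfg$photo_curve$v_dark, n, 12)
    if (sd_photo > 0) v <- v + matrix(stats::rnorm(n * 12, sd = sd_photo), n, 12)
    v <- quantize_adc(v, cfg)
    hall <- vapply(1:3, function(i) {
      rep(hall_response(angle, i, cfg), n) +
        if (cfg$noise$hall_sd > 0) stats::rnorm(n, sd = cfg$noise$hall_sd) else 0
    }, numeric(n))
    out <- data.frame(t = t_s, v, hall, force = NA_real_, angle = angle)
    names(out) <- c("t", sprintf("p%02d", 1:12), paste0("h", 1:3), "force", "angle")
    structure(out, angle = angle, class = c("grip_trial", "data.frame"))
  })
}

#' Corrupt a stitched Hall window
#'
#' Injects the disturbance scenarios the classifier must shrug off:
#' `"spikes"` replaces `k` randomly chosen samples with the full-scale value;
#' `"dropout"` zeroes a contiguous run of exactly 100 samples (data loss in
#' one time window). The label and length are never altered.
#'
#' @param window A single `hall_window` (see [stitch_windows()]).
#' @param mode `"spikes"` or `"dropout"`.
#' @param k Number of spike samples (spikes mode). Default 5.
#' @param seed Integer seed for the corruption positions.
#' @param full_scale Value used for spikes; 1 for normalized windows.
#' @param dropout_len Length of the zeroed run. Default 100 samples.
#' @return The corrupted `hall_window`.
#' @export
corrupt_window <- function(window, mode = c("spikes", "dropout"), k = 5L,
                           seed = 1L, full_scale = 1, dropout_len = 100L) {
  stopifnot(inherits(window, "hall_window"))
  mode <- match.arg(mode)
  len <- length(window$values)
  with_rng_seed(seed, {
    if (mode == "spikes") {
      k <- as.integer(k)
      if (k < 0L || k > len) stop("`k` must be within 0..window length", call. = FALSE)
      if (k > 0L) {
        idx <- sample.int(len, k)
        window$values[idx] <- full_scale
      }
    } else {
      dropout_len <- as.integer(dropout_len)
      if (len < dropout_len) {
        stop(sprintf("dropout needs a window of >= %d samples", dropout_len),
             call. = FALSE)
      }
      start <- sample.int(len - dropout_len + 1L, 1L)
      window$values[start:(start + dropout_len - 1L)] <- 0
    }
  })
  window
}

#' Read or write a sensor stream as CSV
#'
#' One row per sample with columns `t`, `p01..p12`, `h1..h3`, `force`,
#' `angle`; the header is mandatory and missing force/angle are written as
#' empty fields. Identical configuration and seed produce byte-identical
#' files.
#'
#' @param records A `grip_trial` / sensor-record data frame.
#' @param path File path.
#' @return `write_sensor_csv()` returns `path` invisibly;
#'   `read_sensor_csv()` returns the data frame.
#' @export
write_sensor_csv <- function(records, path) {
  cols <- c("t", sprintf("p%02d", 1:12), paste0("h", 1:3), "force", "angle")
  stopifnot(all(cols %in% names(records)))
  utils::write.csv(as.data.frame(records)[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  out <- utils::read.csv(path, header = TRUE)
  structure(out, class = c("grip_trial", "data.frame"))
}
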