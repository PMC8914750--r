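#' Synthetic sensor-session configuration
#'
#' Collects every setting of the synthetic generator: the ground-truth Voigt
#' parameter bank, the photoresistor response curve, the Hall field geometry,
#' noise levels, ADC quantization, sampling rate and the windowing constant.
#' Defaults describe the simulated acquisition system: a 0-5 V, 10-bit ADC
#' (LSB 4.88 mV), a 35 N grip-meter range, ramp trials of 4 s, 1000
#' samples/s so a 200 ms window holds 200 samples per channel, photoresistor
#' noise of 0.02 V, Hall noise of 0.08 (field units) and force-measurement
#' noise of 1.0 N. The subject's noise at the -90 degree wrist angle is
#' inflated 1.75x (applied to both the deformation channels and the force
#' production), encoding the observation that exerting force with the wrist
#' fully pronated is awkward, so both the muscle signal and the produced
#' force are less repeatable there than at 0 or 90 degrees.
#'
#' @param sampling_rate Samples per second (> 0). Default 1000.
#' @param trial_duration Grip-trial length in seconds. Default 4.
#' @param max_force Grip-meter full scale (N). Default 35.
#' @param true_params Ground-truth parameter bank; see [default_param_bank()].
#' @param photo_curve List `v_dark`, `v_sat` (V) and `d_scale` (mm): the
#'   saturating deformation-to-voltage curve, see [photoresistor_response()].
#' @param hall_geometry List `baseline`, `amplitude` (length 3) and `phase`
#'   (length 3, degrees): the cosine dipole approximation of the three Hall
#'   sensors, see [hall_response()].
#' @param noise List `photo_sd` (V), `hall_sd`, `force_sd` (N) and
#'   `angle_scale`, a named per-angle multiplier applied to the subject's
#'   photoresistor and force-production noise.
#' @param adc List `bits` (>= 1) and `v_ref` (V).
#' @param window_s Stitching window length in seconds. Default 0.2.
#' @param seed Integer seed recorded with the configuration.
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config()
#' adc_lsb(cfg) * 1000  # LSB in mV
#' @export
synth_config <- function(sampling_rate = 1000,
                         trial_duration = 4,
                         max_force = 35,
                         true_params = default_param_bank(),
                         photo_curve = list(v_dark = 0.5, v_sat = 4.5, d_scale = 5),
                         hall_geometry = list(baseline = 2.5,
                                              amplitude = c(1, 1, 1),
                                              phase = c(-45, 0, 45)),
                         noise = list(photo_sd = 0.02, hall_sd = 0.08,
                                      force_sd = 1.0,
                                      angle_scale = c("-90" = 1.75, "0" = 1, "90" = 1)),
                         adc = list(bits = 10L, v_ref = 5),
                         window_s = 0.2,
                         seed = 1L) {
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1L)
  if (!is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be > 0", call. = FALSE)
  }
  if (!is.finite(trial_duration) || trial_duration <= 0) {
    stop("`trial_duration` must be > 0", call. = FALSE)
  }
  if (!is.finite(max_force) || max_force <= 0) {
    stop("`max_force` must be > 0", call. = FALSE)
  }
  assert_param_bank(true_params)
  stopifnot(all(c("v_dark", "v_sat", "d_scale") %in% names(photo_curve)))
  if (photo_curve$v_sat <= photo_curve$v_dark || photo_curve$d_scale <= 0) {
    stop("photo_curve requires v_sat > v_dark and d_scale > 0", call. = FALSE)
  }
  stopifnot(all(c("baseline", "amplitude", "phase") %in% names(hall_geometry)),
            length(hall_geometry$amplitude) == 3L,
            length(hall_geometry$phase) == 3L)
  stopifnot(all(c("photo_sd", "hall_sd", "force_sd") %in% names(noise)))
  if (any(unlist(noise[c("photo_sd", "hall_sd", "force_sd")]) < 0)) {
    stop("all noise sds must be >= 0", call. = FALSE)
  }
  if (is.null(noise$angle_scale)) {
    noise$angle_scale <- c("-90" = 1, "0" = 1, "90" = 1)
  }
  if (!setequal(names(noise$angle_scale), angle_key(ANGLE_CLASSES))) {
    stop("noise$angle_scale must be named by the angles -90, 0, 90", call. = FALSE)
  }
  adc$bits <- as.integer(adc$bits)
  if (adc$bits < 1L || adc$v_ref <= 0) {
    stop("adc requires bits >= 1 and v_ref > 0", call. = FALSE)
  }
  if (window_s <= 0) stop("`window_s` must be > 0", call. = FALSE)

  structure(list(sampling_rate = sampling_rate,
                 trial_duration = trial_duration,
                 max_force = max_force,
                 true_params = true_params,
                 photo_curve = photo_curve,
                 hall_geometry = hall_geometry,
                 noise = noise,
                 adc = adc,
                 window_s = window_s,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  sampling: %g Hz, trial %g s, window %g s\n",
              x$sampling_rate, x$trial_duration, x$window_s))
  cat(sprintf("  force range: 0-%g N; ADC: %d bit / %g V (LSB %.4g mV)\n",
              x$max_force, x$adc$bits, x$adc$v_ref, 1000 * adc_lsb(x)))
  cat(sprintf("  noise sd: photo %g V, hall %g, force %g N; -90 deg noise scale %gx\n",
              x$noise$photo_sd, x$noise$hall_sd, x$noise$force_sd,
              x$noise$angle_scale[["-90"]]))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Samples per stitching window
#' @param cfg A [synth_config].
#' @return Integer number of samples per channel in one window.
#' @export
window_samples <- function(cfg) {
  as.integer(round(cfg$window_s * cfg$sampling_rate))
}

#' Read or write a generator configuration as YAML
#'
#' The YAML mirrors the `synth_config` fields; the parameter bank is stored
#' inline as per-angle `a`, `b`, `c` entries. The seed is always written.
#'
#' @param cfg A [synth_config].
#' @param path File path.
#' @return `write_synth_config()` returns `path` invisibly;
#'   `read_synth_config()` returns a [synth_config].
#' @export
write_synth_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synth_config"))
  out <- unclass(cfg)
  out$true_params <- lapply(cfg$true_params, function(p) {
    list(angle = as.integer(p$angle), a = p$a, b = p$b, c = p$c)
  })
  out$noise$angle_scale <- as.list(cfg$noise$angle_scale)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bank <- lapply(raw$true_params, function(p) {
    voigt_params(a = unlist(p$a), b = unlist(p$b), c = p$c, angle = p$angle)
  })
  names(bank) <- angle_key(vapply(bank, `[[`, numeric(1), "angle"))
  synth_config(sampling_rate = raw$sampling_rate,
               trial_duration = raw$trial_duration,
               max_force = raw$max_force,
               true_params = bank,
               photo_curve = raw$photo_curve,
               hall_geometry = list(baseline = raw$hall_geometry$baseline,
                                    amplitude = unlist(raw$hall_geometry$amplitude),
                                    phase = unlist(raw$hall_geometry$phase)),
               noise = list(photo_sd = raw$noise$photo_sd,
                            hall_sd = raw$noise$hall_sd,
                            force_sd = raw$noise$force_sd,
                            angle_scale = unlist(raw$noise$angle_scale)),
               adc = raw$adc,
               window_s = raw$window_s,
               seed = raw$seed)
}
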