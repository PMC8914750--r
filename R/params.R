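#' Voigt grip-model parameters for one wrist angle
#'
#' The grip strength-forearm muscle model treats each deformation channel as
#' a Voigt element (spring and damper in parallel), linearized to
#' \deqn{F = \sum_j a_j X_j + \sum_j b_j \dot X_j + c}
#' with twelve elastic coefficients `a` (N per deformation unit), twelve
#' viscosity coefficients `b` (N s per deformation unit) and a scalar offset
#' `c` (N). One parameter set belongs to one wrist angle; the pipeline keeps
#' a bank of three sets and switches between them as the classified angle
#' changes.
#'
#' @param a Numeric vector of 12 elastic coefficients.
#' @param b Numeric vector of 12 viscosity coefficients.
#' @param c Scalar offset (N).
#' @param angle Wrist angle this set belongs to: -90, 0 or 90.
#' @return An object of class `voigt_params`.
#' @examples
#' p <- voigt_params(a = rep(1, 12), b = rep(0.1, 12), c = -2, angle = 0)
#' p$c
#' @export
voigt_params <- function(a, b, c, angle) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  c <- as.numeric(c)
  assert_angle(angle)
  if (length(a) != 12L || length(b) != 12L) {
    stop("`a` and `b` must each have length 12", call. = FALSE)
  }
  if (length(c) != 1L) stop("`c` must be a scalar", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)) || !is.finite(c)) {
    stop("all Voigt parameters must be finite", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, angle = angle), class = "voigt_params")
}

#' @export
print.voigt_params <- function(x, ...) {
  cat(sprintf("<voigt_params> angle %d deg\n", as.integer(x$angle)))
  cat("  a:", paste(sprintf("%.3f", x$a), collapse = " "), "\n")
  cat("  b:", paste(sprintf("%.3f", x$b), collapse = " "), "\n")
  cat(sprintf("  c: %.3f N\n", x$c))
  invisible(x)
}

#' Default ground-truth parameter bank for the synthetic subject
#'
#' Fixed (non-random) per-angle Voigt parameter sets used as the generator's
#' ground truth. Elastic coefficients average about 0.85 N/V so that a full
#' deformation ramp across twelve channels sums to a grip force just under
#' the 35 N grip-meter range; viscosity coefficients are two orders of
#' magnitude smaller, as expected for slow volitional ramps; the offset
#' cancels the resting (dark-voltage) elastic term so the relaxed hand reads
#' 0 N. Channel-to-channel and angle-to-angle variation is deterministic so
#' that the three parameter sets are distinct and every design matrix built
#' from a ramp trial has full column rank.
#'
#' @param v_dark Dark voltage of the photoresistor curve (V); the offset `c`
#'   is chosen so the resting force is zero at this voltage.
#' @return Named list with entries `"-90"`, `"0"`, `"90"`, each a
#'   [voigt_params] object.
#' @examples
#' bank <- default_param_bank()
#' names(bank)
#' @export
default_param_bank <- function(v_dark = 0.5) {
  j <- seq_len(12)
  bank <- lapply(ANGLE_CLASSES, function(angle) {
    shift <- (angle / 90) * 0.6          # distinct per-angle channel weighting
    a <- 0.85 * (1 + 0.15 * sin(j * 0.9 + shift))
    b <- 0.020 * (1 + 0.20 * cos(j * 1.3 + shift))
    voigt_params(a = a, b = b, c = -v_dark * sum(a), angle = angle)
  })
  names(bank) <- angle_key(ANGLE_CLASSES)
  bank
}

assert_param_bank <- function(bank) {
  need <- angle_key(ANGLE_CLASSES)
  if (!is.list(bank) || !setequal(names(bank), need)) {
    stop("`true_params` must be a named list with exactly the angle keys -90, 0, 90",
         call. = FALSE)
  }
  ok <- vapply(bank, inherits, logical(1), what = "voigt_params")
  if (!all(ok)) stop("all parameter bank entries must be `voigt_params`", call. = FALSE)
  invisible(bank)
}

#' Read or write a Voigt parameter bank as JSON
#'
#' The bank is serialized as an array of objects
#' `{"angle": -90|0|90, "a": [..12], "b": [..12], "c": x}`.
#'
#' @param bank Named list of [voigt_params] (names `"-90"`, `"0"`, `"90"`).
#' @param path File path.
#' @return `write_param_bank()` returns `path` invisibly;
#'   `read_param_bank()` returns the bank.
#' @export
write_param_bank <- function(bank, path) {
  assert_param_bank(bank)
  entries <- lapply(bank, function(p) {
    list(angle = as.integer(p$angle), a = p$a, b = p$b, c = p$c)
  })
  jsonlite::write_json(unname(entries), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_param_bank
#' @export
read_param_bank <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = TRUE)
  bank <- lapply(seq_len(nrow(entries)), function(i) {
    voigt_params(a = entries$a[[i]], b = entries$b[[i]],
                 c = entries$c[[i]], angle = entries$angle[[i]])
  })
  names(bank) <- angle_key(vapply(bank, `[[`, numeric(1), "angle"))
  assert_param_bank(bank[angle_key(ANGLE_CLASSES)])
}
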