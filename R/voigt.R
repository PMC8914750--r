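# Angle-conditioned Voigt grip model: derivative estimation, prediction,
# least-squares fitting and classifier-gated end-to-end force estimation.

#' Estimate time derivatives of deformation channels
#'
#' Central finite differences at interior samples, one-sided differences at
#' the two ends, so the output aligns sample-for-sample with the input.
#' Exact for linear signals.
#'
#' @param x Numeric vector or matrix (one channel per column), >= 3 samples.
#' @param dt Uniform sampling interval in seconds (> 0).
#' @return Derivative series, same shape as `x` (units of `x` per second).
#' @examples
#' estimate_derivative(c(0, 1, 2, 3), dt = 1)
#' @export
estimate_derivative <- function(x, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single value > 0", call. = FALSE)
  }
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1L) else x
  n <- nrow(xm)
  if (n < 3L) stop("need at least 3 time points", call. = FALSE)
  d <- xm
  d[2:(n - 1L), ] <- (xm[3:n, , drop = FALSE] - xm[1:(n - 2L), , drop = FALSE]) / (2 * dt)
  d[1L, ] <- (xm[2L, ] - xm[1L, ]) / dt
  d[n, ] <- (xm[n, ] - xm[n - 1L, ]) / dt
  if (vec) as.vector(d) else d
}

#' Predict grip force from a deformation state
#'
#' Evaluates the linearized Voigt model `F = a.X + b.Xdot + c` for one or
#' more deformation states.
#'
#' @param params A [voigt_params] set.
#' @param X 12 deformation values, or a matrix with 12 columns (one state
#'   per row).
#' @param Xdot Matching time-derivatives.
#' @return Predicted force(s) in N.
#' @examples
#' p <- voigt_params(rep(1, 12), rep(0, 12), c = 0, angle = 0)
#' predict_force(p, X = rep(0.5, 12), Xdot = rep(0, 12))
#' @export
predict_force <- function(params, X, Xdot) {
  stopifnot(inherits(params, "voigt_params"))
  Xm <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  Dm <- if (is.null(dim(Xdot))) matrix(Xdot, nrow = 1L) else as.matrix(Xdot)
  if (ncol(Xm) != 12L || ncol(Dm) != 12L || nrow(Xm) != nrow(Dm)) {
    stop("X and Xdot must both have 12 channels and matching rows", call. = FALSE)
  }
  if (any(!is.finite(Xm)) || any(!is.finite(Dm))) {
    stop("X and Xdot must be finite", call. = FALSE)
  }
  f <- as.numeric(Xm %*% params$a + Dm %*% params$b + params$c)
  if (length(f) == 1L) f[[1L]] else f
}

#' Fit Voigt parameters by linear least squares
#'
#' Minimizes the residual sum of squares `Q = sum_i (F_i - F(X_i))^2` over
#' the 25 free parameters (12 elastic, 12 viscous, 1 offset) on the design
#' matrix `[X | Xdot | 1]`. The solver is a rank-revealing SVD least squares:
#' when the design is rank deficient, or its condition number exceeds 1e8, a
#' condition warning is flagged and the minimum-norm solution is returned.
#'
#' @param X Matrix of deformation states, `n x 12` with `n >= 25`.
#' @param Xdot Matching derivative matrix (already estimated).
#' @param force Measured forces, length `n` (N).
#' @param angle Wrist angle the parameters belong to.
#' @return A `voigt_fit` list: `params` ([voigt_params]), `Q` (residual sum
#'   of squares, N^2), `n`, `condition_warning`, `condition_number`.
#' @export
fit_voigt_params <- function(X, Xdot, force, angle) {
  assert_angle(angle)
  X <- as.matrix(X)
  Xdot <- as.matrix(Xdot)
  n <- nrow(X)
  if (ncol(X) != 12L || ncol(Xdot) != 12L) stop("need 12 channels", call. = FALSE)
  if (nrow(Xdot) != n || length(force) != n) stop("row counts differ", call. = FALSE)
  if (n < 25L) {
    stop("under-determined: need at least 25 samples for 25 parameters", call. = FALSE)
  }
  if (any(!is.finite(X)) || any(!is.finite(Xdot)) || any(!is.finite(force))) {
    stop("inputs must be finite", call. = FALSE)
  }
  A <- cbind(X, Xdot, 1)
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * sv$d[1L]
  rank <- sum(sv$d > tol)
  kappa <- if (rank < ncol(A)) Inf else sv$d[1L] / sv$d[ncol(A)]
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  beta <- sv$v %*% (dinv * crossprod(sv$u, force))
  resid <- force - A %*% beta
  fit <- list(params = voigt_params(a = beta[1:12], b = beta[13:24],
                                    c = beta[25], angle = angle),
              Q = sum(resid^2),
              n = n,
              condition_warning = kappa > 1e8,
              condition_number = kappa)
  class(fit) <- "voigt_fit"
  fit
}

#' @export
print.voigt_fit <- function(x, ...) {
  cat(sprintf("<voigt_fit> angle %d deg: n = %d, Q = %.4g N^2%s\n",
              as.integer(x$params$angle), x$n, x$Q,
              if (x$condition_warning) " [condition warning]" else ""))
  invisible(x)
}

#' Fit a Voigt parameter set from raw grip trials
#'
#' Applies the standard signal path — causal moving-average filter (window
#' 6) on the 12 photoresistor channels, central-difference derivative — to
#' one or more trials recorded at a single wrist angle, stacks them, and
#' fits the 25-parameter model against the measured force.
#'
#' @param trials A `grip_trial` or list of them, all at the same angle.
#' @param cfg A [synth_config] (supplies the sampling interval).
#' @param angle The wrist angle of the trials.
#' @param maf_w Moving-average window, default 6 samples.
#' @return A `voigt_fit` (see [fit_voigt_params()]).
#' @export
fit_trials <- function(trials, cfg, angle, maf_w = 6L) {
  if (inherits(trials, "data.frame")) trials <- list(trials)
  dt <- 1 / cfg$sampling_rate
  Xs <- list(); Ds <- list(); Fs <- list()
  for (tr in trials) {
    X <- maf_matrix(as.matrix(tr[, sprintf("p%02d", 1:12)]), w = maf_w)
    Xs[[length(Xs) + 1L]] <- X
    Ds[[length(Ds) + 1L]] <- estimate_derivative(X, dt)
    Fs[[length(Fs) + 1L]] <- tr$force
  }
  fit_voigt_params(do.call(rbind, Xs), do.call(rbind, Ds), unlist(Fs), angle)
}

#' Classifier-gated grip-force estimation on a sensor stream
#'
#' The end-to-end estimator: the stream's Hall channels are stitched into
#' 200 ms windows and each window's wrist angle is classified by the trained
#' CNN; the 12 photoresistor channels are moving-average filtered and
#' differentiated; each sample's force is then predicted with the Voigt
#' parameter set of its window's classified angle (the parameter set is held
#' constant within a window; samples after the last full window reuse the
#' last window's angle so every sample gets an estimate).
#'
#' @param stream A sensor-record data frame (`t`, `p01..p12`, `h1..h3`,
#'   optionally `force`).
#' @param model A trained [train_angle_cnn()] model.
#' @param params_bank Named list of [voigt_params] covering all three angles
#'   (fitted, e.g., by [fit_trials()]).
#' @param cfg A [synth_config].
#' @param maf_w Moving-average window, default 6 samples.
#' @return A `grip_trace` data frame: `t`, `Fm` (measured force or `NA`),
#'   `Fp` (estimated force), `angle_pred` (per-sample gated angle).
#' @export
estimate_grip <- function(stream, model, params_bank, cfg, maf_w = 6L) {
  stopifnot(inherits(model, "angle_cnn"))
  assert_param_bank(params_bank)
  n <- NROW(stream)
  W <- window_samples(cfg)
  if (n < W) stop("stream shorter than one window", call. = FALSE)
  dt <- 1 / cfg$sampling_rate

  windows <- stitch_windows(stream, cfg)
  win_angle <- predict_window_set(model, windows)$class

  X <- maf_matrix(as.matrix(stream[, sprintf("p%02d", 1:12)]), w = maf_w)
  Xdot <- estimate_derivative(X, dt)

  win_of_sample <- pmin((seq_len(n) - 1L) %/% W + 1L, length(win_angle))
  angle_pred <- win_angle[win_of_sample]
  Fp <- numeric(n)
  for (key in angle_key(ANGLE_CLASSES)) {
    idx <- which(angle_pred == as.numeric(key))
    if (length(idx)) {
      p <- params_bank[[key]]
      Fp[idx] <- as.numeric(X[idx, , drop = FALSE] %*% p$a +
                              Xdot[idx, , drop = FALSE] %*% p$b + p$c)
    }
  }
  Fm <- if ("force" %in% names(stream)) stream$force else rep(NA_real_, n)
  structure(data.frame(t = stream$t, Fm = Fm, Fp = Fp, angle_pred = angle_pred),
            class = c("grip_trace", "data.frame"))
}

#' Read or write a grip trace as CSV
#'
#' Columns `t`, `F_measured`, `F_estimated`, `angle_predicted`.
#'
#' @param trace A `grip_trace` data frame.
#' @param path File path.
#' @return `write_grip_trace()` returns `path` invisibly;
#'   `read_grip_trace()` returns the trace.
#' @export
write_grip_trace <- function(trace, path) {
  df <- data.frame(t = trace$t, F_measured = trace$Fm,
                   F_estimated = trace$Fp, angle_predicted = trace$angle_pred)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_grip_trace
#' @export
read_grip_trace <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  structure(data.frame(t = df$t, Fm = df$F_measured, Fp = df$F_estimated,
                       angle_pred = df$angle_predicted),
            class = c("grip_trace", "data.frame"))
}
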