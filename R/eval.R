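# Evaluation metrics and experiment summaries.

#' Root-mean-square error between measured and estimated force
#'
#' `RMSE = sqrt(mean((Fp - Fm)^2))`; symmetric in its arguments and zero
#' exactly when the two series coincide.
#'
#' @param Fm Measured force series (N).
#' @param Fp Estimated force series (N), same length.
#' @return RMSE in N.
#' @examples
#' rmse(c(0, 0), c(3, 4))
#' @export
rmse <- function(Fm, Fp) {
  if (length(Fm) != length(Fp)) stop("length mismatch", call. = FALSE)
  if (length(Fm) == 0L) stop("empty input", call. = FALSE)
  sqrt(mean((Fp - Fm)^2))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] that enforces the preconditions the
#' pipeline relies on: equal lengths of at least 3 and non-constant inputs
#' (a constant series has no defined correlation).
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Correlation between grip force and mean muscle deformation
#'
#' For one trial, the product-moment correlation between the force series
#' and the per-sample mean of the 12 moving-average-filtered deformation
#' channels — the calibration statistic of the force-myography premise that
#' grip force tracks forearm deformation.
#'
#' @param trial A `grip_trial` data frame.
#' @param maf_w Moving-average window, default 6 samples.
#' @return Correlation coefficient.
#' @export
force_deformation_correlation <- function(trial, maf_w = 6L) {
  X <- maf_matrix(as.matrix(trial[, sprintf("p%02d", 1:12)]), w = maf_w)
  pearson_correlation(trial$force, rowMeans(X))
}

#' Summarize an angle-conditioned grip-estimation experiment
#'
#' Computes the RMSE of every trace, aggregates per angle and overall
#' (mean and sd across angle x trial RMSEs), the overall measured-estimated
#' correlation on the concatenated traces, and attaches the wrist-angle
#' confusion matrix.
#'
#' @param traces Named list (names `"-90"`, `"0"`, `"90"`), each a list of
#'   `grip_trace` objects for that angle; at least one trace per angle.
#' @param confusion A 3x3 confusion matrix from [evaluate_classifier()].
#' @return An `eval_summary` list: `rmse_per_angle`, `rmse_mean`, `rmse_sd`,
#'   `pearson_r`, `confusion`, `accuracy`, `n_samples`.
#' @export
summarize_experiment <- function(traces, confusion) {
  need <- angle_key(ANGLE_CLASSES)
  if (!is.list(traces) || !all(need %in% names(traces))) {
    stop("`traces` must contain entries for all three angles", call. = FALSE)
  }
  per_trace <- lapply(need, function(key) {
    trs <- traces[[key]]
    if (inherits(trs, "data.frame")) trs <- list(trs)
    if (length(trs) == 0L) stop("missing traces for angle ", key, call. = FALSE)
    vapply(trs, function(tr) rmse(tr$Fm, tr$Fp), numeric(1))
  })
  names(per_trace) <- need
  rmse_per_angle <- vapply(per_trace, mean, numeric(1))
  all_rmse <- unlist(per_trace)
  fm <- unlist(lapply(need, function(key) {
    trs <- traces[[key]]; if (inherits(trs, "data.frame")) trs <- list(trs)
    lapply(trs, `[[`, "Fm")
  }))
  fp <- unlist(lapply(need, function(key) {
    trs <- traces[[key]]; if (inherits(trs, "data.frame")) trs <- list(trs)
    lapply(trs, `[[`, "Fp")
  }))
  structure(list(rmse_per_angle = rmse_per_angle,
                 rmse_mean = mean(all_rmse),
                 rmse_sd = stats::sd(all_rmse),
                 pearson_r = pearson_correlation(fm, fp),
                 confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 n_samples = length(fm)),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat("<eval_summary>\n")
  cat(sprintf("  RMSE per angle (N): %s\n",
              paste(sprintf("%s: %.3f", names(x$rmse_per_angle),
                            x$rmse_per_angle), collapse = ", ")))
  cat(sprintf("  RMSE mean +/- sd: %.3f +/- %.3f N\n", x$rmse_mean, x$rmse_sd))
  cat(sprintf("  measured~estimated r: %.4f\n", x$pearson_r))
  cat(sprintf("  wrist-angle accuracy: %.2f%%\n", 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation summary as JSON
#'
#' @param summary An `eval_summary`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_eval_summary <- function(summary, path) {
  out <- list(rmse_per_angle = as.list(summary$rmse_per_angle),
              rmse_mean = summary$rmse_mean,
              rmse_sd = summary$rmse_sd,
              pearson_r = summary$pearson_r,
              accuracy = summary$accuracy,
              confusion = unname(apply(summary$confusion, 1L, as.list, simplify = FALSE)),
              n_samples = summary$n_samples)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
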