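# Stream preprocessing: moving-average filter, min-max normalization,
# 200 ms window stitching and stratified splitting.

#' Causal moving-average filter
#'
#' Element i of the output is the mean of the last `min(i, w)` input samples
#' (a growing warm-up window at the start), so the output has the same length
#' as the input and never uses future samples. Constant series are fixed
#' points and the filter is linear.
#'
#' @param series Numeric vector (non-empty, finite).
#' @param w Window length, default 6 samples.
#' @return Filtered vector, same length as `series`.
#' @examples
#' moving_average_filter(1:12, w = 6)
#' @export
moving_average_filter <- function(series, w = 6L) {
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("`w` must be >= 1", call. = FALSE)
  if (length(series) == 0L) stop("`series` must be non-empty", call. = FALSE)
  n <- length(series)
  cs <- cumsum(series)
  i <- seq_len(n)
  lag <- cs - c(rep(0, min(w, n)), cs[seq_len(max(n - w, 0))])
  lag / pmin(i, w)
}

# Column-wise MAF for a multichannel matrix.
maf_matrix <- function(x, w = 6L) {
  apply(x, 2L, moving_average_filter, w = w)
}

#' Min-max normalize a vector to [0, 1]
#'
#' `M = (m - m_min) / (m_max - m_min)` applied over the whole vector (one
#' "row" of data): the minimum maps to 0 and the maximum to 1. A constant
#' vector (degenerate `m_max = m_min`) maps to all zeros.
#'
#' @param row Non-empty numeric vector with finite entries.
#' @return Normalized vector in `[0, 1]`.
#' @examples
#' minmax_normalize(c(0, 5, 10))
#' @export
minmax_normalize <- function(row) {
  if (length(row) == 0L) stop("`row` must be non-empty", call. = FALSE)
  if (!is.numeric(row) || any(!is.finite(row))) {
    stop("`row` must be finite numeric", call. = FALSE)
  }
  lo <- min(row)
  hi <- max(row)
  if (hi == lo) return(rep(0, length(row)))
  (row - lo) / (hi - lo)
}

#' Stitch a sensor stream into labeled Hall windows
#'
#' Cuts the stream into consecutive non-overlapping windows of `window_s`
#' seconds (the trailing partial window is discarded) and, for each window,
#' concatenates the three Hall channels in sensor order into one vector
#' `[h1 samples | h2 samples | h3 samples]` of length `3 * W`. Each stitched
#' vector is then min-max normalized. By default normalization spans the
#' whole stitched row, so the between-channel field levels that encode the
#' wrist angle survive; `normalize = "channel"` rescales each channel block
#' independently and `"none"` skips rescaling. The window label is the
#' stream's angle label (majority vote when a window straddles an angle
#' transition; exact ties are discarded).
#'
#' @param stream A sensor-record data frame with columns `h1..h3`, `t` and
#'   optionally `angle`.
#' @param cfg A [synth_config] (supplies `window_s` and the sampling rate).
#' @param normalize `"row"` (default), `"channel"`, or `"none"`.
#' @return An object of class `hall_windows`: list with `values` (matrix,
#'   one window per row, `3 * W` columns), `label` (numeric angle or `NA`),
#'   `t_start` (s) and `W` (samples per channel).
#' @examples
#' cfg <- synth_config()
#' ws <- stitch_windows(generate_angle_stream(0, 4, cfg, seed = 1), cfg)
#' dim(ws$values)
#' @export
stitch_windows <- function(stream, cfg, normalize = c("row", "channel", "none")) {
  normalize <- match.arg(normalize)
  if (NROW(stream) == 0L) stop("`stream` is empty", call. = FALSE)
  W <- window_samples(cfg)
  n_win <- NROW(stream) %/% W
  if (n_win < 1L) stop("stream shorter than one full window", call. = FALSE)

  h <- as.matrix(stream[, paste0("h", 1:3)])
  has_label <- "angle" %in% names(stream)
  values <- matrix(NA_real_, n_win, 3L * W)
  label <- rep(NA_real_, n_win)
  t_start <- numeric(n_win)
  keep <- rep(TRUE, n_win)

  for (i in seq_len(n_win)) {
    rows <- ((i - 1L) * W + 1L):(i * W)
    vec <- c(h[rows, 1L], h[rows, 2L], h[rows, 3L])
    vec <- switch(normalize,
                  row = minmax_normalize(vec),
                  channel = c(minmax_normalize(vec[1:W]),
                              minmax_normalize(vec[(W + 1):(2 * W)]),
                              minmax_normalize(vec[(2 * W + 1):(3 * W)])),
                  none = vec)
    values[i, ] <- vec
    t_start[i] <- stream$t[rows[1L]]
    if (has_label) {
      lab <- stream$angle[rows]
      lab <- lab[!is.na(lab)]
      if (length(lab)) {
        tab <- table(lab)
        top <- tab[tab == max(tab)]
        if (length(top) > 1L) keep[i] <- FALSE else label[i] <- as.numeric(names(top))
      }
    }
  }
  structure(list(values = values[keep, , drop = FALSE],
                 label = label[keep],
                 t_start = t_start[keep],
                 W = W),
            class = "hall_windows")
}

#' @export
print.hall_windows <- function(x, ...) {
  cat(sprintf("<hall_windows> %d windows x %d values (W = %d per channel)\n",
              nrow(x$values), ncol(x$values), x$W))
  if (any(!is.na(x$label))) print(table(label = x$label, useNA = "no"))
  invisible(x)
}

#' Number of windows in a `hall_windows` set
#' @param x A `hall_windows` object.
#' @return Integer count.
#' @export
n_windows <- function(x) {
  stopifnot(inherits(x, "hall_windows"))
  nrow(x$values)
}

#' Extract one window from a `hall_windows` set
#' @param x A `hall_windows` object.
#' @param i Window index.
#' @return A single `hall_window`: list with `values`, `label`, `t_start`, `W`.
#' @export
get_window <- function(x, i) {
  stopifnot(inherits(x, "hall_windows"), i >= 1L, i <= nrow(x$values))
  structure(list(values = x$values[i, ], label = x$label[i],
                 t_start = x$t_start[i], W = x$W),
            class = "hall_window")
}

#' Combine several `hall_windows` sets
#' @param ... `hall_windows` objects with matching window length.
#' @return A single `hall_windows` object.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "hall_windows")))
  W <- unique(vapply(sets, `[[`, integer(1), "W"))
  if (length(W) != 1L) stop("window lengths differ", call. = FALSE)
  structure(list(values = do.call(rbind, lapply(sets, `[[`, "values")),
                 label = unlist(lapply(sets, `[[`, "label")),
                 t_start = unlist(lapply(sets, `[[`, "t_start")),
                 W = W),
            class = "hall_windows")
}

# Subset a hall_windows set by window index.
subset_windows <- function(x, idx) {
  structure(list(values = x$values[idx, , drop = FALSE],
                 label = x$label[idx],
                 t_start = x$t_start[idx],
                 W = x$W),
            class = "hall_windows")
}

#' Stratified train/test split of labeled windows
#'
#' Splits the window set into disjoint train and test subsets whose union is
#' the input, stratified by angle label so each class contributes the same
#' train fraction (4:1 by default), reproducibly for a given seed.
#'
#' @param windows A labeled `hall_windows` set.
#' @param ratio Train fraction, default 0.8 (a 4:1 split).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, both `hall_windows`.
#' @export
split_dataset <- function(windows, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(windows, "hall_windows"))
  if (any(is.na(windows$label))) stop("all windows must be labeled", call. = FALSE)
  if (n_windows(windows) < 5L) stop("need at least 5 windows to split", call. = FALSE)
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)", call. = FALSE)
  counts <- table(windows$label)
  if (any(counts < 2L)) {
    stop("every label needs >= 2 windows for a stratified split", call. = FALSE)
  }
  train_idx <- with_rng_seed(seed, {
    unlist(lapply(names(counts), function(lv) {
      idx <- which(windows$label == as.numeric(lv))
      n_tr <- round(length(idx) * ratio)
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # both sides non-empty
      sample(idx, n_tr)
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_windows(windows)), train_idx)
  list(train = subset_windows(windows, train_idx),
       test = subset_windows(windows, test_idx))
}

#' Read or write stitched windows as CSV
#'
#' One window per row: `t_start`, `label`, then `v_1..v_3W`.
#'
#' @param windows A `hall_windows` object.
#' @param path File path.
#' @return `write_windows_csv()` returns `path` invisibly;
#'   `read_windows_csv()` returns a `hall_windows` object.
#' @export
write_windows_csv <- function(windows, path) {
  stopifnot(inherits(windows, "hall_windows"))
  df <- data.frame(t_start = windows$t_start, label = windows$label,
                   windows$values)
  names(df) <- c("t_start", "label", paste0("v_", seq_len(ncol(windows$values))))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_windows_csv
#' @export
read_windows_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(values) <- NULL
  if (ncol(values) %% 3L != 0L) stop("window length not divisible by 3", call. = FALSE)
  structure(list(values = values, label = df$label, t_start = df$t_start,
                 W = ncol(values) %/% 3L),
            class = "hall_windows")
}
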