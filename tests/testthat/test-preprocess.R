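# Filtering, normalization, stitching and splitting.

test_that("moving average filter: warm-up edge, windowed-mean oracle, fixed points, linearity", {
  expect_equal(moving_average_filter(rep(5, 7)), rep(5, 7))
  expect_equal(moving_average_filter(3), 3)
  # direct windowed-mean oracle over a ramp
  x <- 1:12
  oracle <- sapply(seq_along(x), function(i) mean(x[max(1, i - 5):i]))
  got <- moving_average_filter(x, w = 6)
  expect_equal(got, oracle)
  expect_equal(got[7], mean(2:7))  # = 4.5
  # linearity under a fixed window
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(moving_average_filter(2 * a - 3 * b, 6),
               2 * moving_average_filter(a, 6) - 3 * moving_average_filter(b, 6))
  expect_error(moving_average_filter(1:5, w = 0), ">= 1")
  expect_error(moving_average_filter(numeric(0)), "non-empty")
})

test_that("min-max normalization hits its endpoints and handles the degenerate row", {
  expect_equal(minmax_normalize(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(1, 3, 2)), c(0, 1, 0.5))
  expect_equal(minmax_normalize(c(2, 2, 2)), c(0, 0, 0))
  set.seed(3)
  for (i in 1:20) {
    r <- minmax_normalize(rnorm(30))
    expect_true(all(r >= 0 & r <= 1))
    expect_equal(min(r), 0)
    expect_equal(max(r), 1)
  }
  # idempotent on rows already spanning [0, 1]
  v <- c(0, 0.25, 0.7, 1)
  expect_equal(minmax_normalize(v), v)
  expect_error(minmax_normalize(c(1, NA)), "finite")
  expect_error(minmax_normalize(numeric(0)), "non-empty")
})

test_that("stitching yields floor(duration / window) windows of length 3W in sensor order", {
  cfg <- synth_config()
  stream <- generate_angle_stream(0, 5, cfg, seed = 1)
  ws <- stitch_windows(stream, cfg)
  expect_equal(n_windows(ws), 5L)          # 1.0 s at 1000 Hz, 200 ms windows
  expect_equal(ncol(ws$values), 600L)      # 3 channels x 200 samples
  expect_true(all(ws$values >= 0 & ws$values <= 1))
  expect_equal(ws$label, rep(0, 5))

  # trailing partial window discarded, count independent of content
  stream2 <- rbind(stream, stream[1:150, ])
  ws2 <- stitch_windows(stream2, cfg)
  expect_equal(n_windows(ws2), 5L)

  # concatenation order: first W entries are h1 in time order (un-normalized)
  raw <- stitch_windows(stream, cfg, normalize = "none")
  expect_equal(raw$values[1, 1:200], stream$h1[1:200])
  expect_equal(raw$values[1, 201:400], stream$h2[1:200])
  expect_equal(raw$values[1, 401:600], stream$h3[1:200])

  # all-equal constant channels normalize to all-zero windows
  stream3 <- stream
  stream3$h1 <- 2; stream3$h2 <- 2; stream3$h3 <- 2
  expect_true(all(stitch_windows(stream3, cfg)$values == 0))

  expect_error(stitch_windows(stream[0, ], cfg), "empty")
  expect_error(stitch_windows(stream[1:50, ], cfg), "shorter than one full window")
})

test_that("row normalization preserves the between-channel levels that encode the angle", {
  cfg <- synth_config()
  ws <- lapply(c(-90, 0, 90), function(a) {
    stitch_windows(generate_angle_stream(a, 2, cfg, seed = 50 + a), cfg)
  })
  ch_means <- t(sapply(ws, function(w) {
    c(mean(w$values[1, 1:200]), mean(w$values[1, 201:400]),
      mean(w$values[1, 401:600]))
  }))
  d <- as.matrix(dist(ch_means))
  expect_true(all(d[upper.tri(d)] > 0.2))
})

test_that("mixed-label windows take the majority label and exact ties are dropped", {
  cfg <- synth_config(window_s = 0.01)  # W = 10 for a compact transition test
  stream <- generate_angle_stream(0, 3, cfg, seed = 2)
  stream$angle <- c(rep(-90, 7), rep(0, 13), rep(90, 5), rep(0, 5))
  ws <- stitch_windows(stream, cfg)
  expect_equal(n_windows(ws), 2L)          # third window is a 5/5 tie, dropped
  expect_equal(ws$label, c(-90, 0))
})

test_that("the stratified 4:1 split partitions the windows with per-label balance", {
  sp <- fixture_split
  n <- n_windows(fixture_windows)
  expect_equal(n_windows(sp$train) + n_windows(sp$test), n)
  expect_equal(n_windows(sp$train) / n, 0.8, tolerance = 0.02)
  # disjoint and exhaustive: recombine and compare the value matrices
  all_vals <- rbind(sp$train$values, sp$test$values)
  expect_equal(dim(all_vals), dim(fixture_windows$values))
  # per-label train proportion within one window of 80%
  for (lv in c(-90, 0, 90)) {
    n_lab <- sum(fixture_windows$label == lv)
    n_tr <- sum(sp$train$label == lv)
    expect_lte(abs(n_tr - 0.8 * n_lab), 1)
  }
  # reproducible per seed
  sp2 <- split_dataset(fixture_windows, ratio = 0.8, seed = 99)
  expect_identical(sp$train$values, sp2$train$values)
  expect_error(split_dataset(fixture_windows, ratio = 1.2), "ratio")
})

test_that("window CSV round-trips values, labels and start times", {
  ws <- stitch_windows(generate_angle_stream(90, 3, fixture_cfg, seed = 8),
                       fixture_cfg)
  f <- tempfile(fileext = ".csv")
  write_windows_csv(ws, f)
  back <- read_windows_csv(f)
  expect_equal(back$values, ws$values, tolerance = 1e-12)
  expect_equal(back$label, ws$label)
  expect_equal(back$W, ws$W)
  unlink(f)
})
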