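# Time-series 1-D CNN for wrist-angle classification.
#
# The stitched 200 ms Hall window (one vector of 3*W values) is reshaped to
# 3 channels x W time steps, so convolution runs along time with the three
# sensors as input channels. Architecture, loss and optimizer are implemented
# directly with matrix operations: im2col convolution, ReLU, max pooling,
# one dense softmax layer, cross-entropy loss, minibatch SGD with momentum.
# All randomness (init, shuffling) flows from one seed on one thread, so
# training is bit-reproducible.

#' Configuration of the wrist-angle CNN
#'
#' Defaults: two 1-D convolution layers (8 then 16 filters, kernel 5, ReLU),
#' each followed by max pooling of size 2, then one dense softmax layer over
#' the three angle classes; cross-entropy loss, minibatch SGD with momentum
#' 0.9, learning rate 1e-3, batch size 32, 30 epochs, fixed seed.
#'
#' @param conv_layers List of layers, each `list(filters =, kernel_size =)`;
#'   kernel sizes must be odd.
#' @param pool_size Max-pooling width (and stride) after each conv layer.
#' @param epochs Training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param learning_rate SGD learning rate.
#' @param momentum SGD momentum coefficient.
#' @param augment_prob Fraction of training windows that receive a random
#'   disturbance (a zeroed dropout run or full-scale spikes) each epoch, so
#'   the network learns to classify disturbed windows too. Set 0 to disable.
#' @param augment_dropout Length of the zeroed run used in augmentation.
#' @param augment_spikes Number of full-scale spike samples in augmentation.
#' @param rng_seed Integer seed for initialization, shuffling and
#'   augmentation.
#' @return An object of class `angle_cnn_config`.
#' @export
angle_cnn_config <- function(conv_layers = list(list(filters = 8L, kernel_size = 5L),
                                                list(filters = 16L, kernel_size = 5L)),
                             pool_size = 2L,
                             epochs = 30L,
                             batch_size = 32L,
                             learning_rate = 1e-3,
                             momentum = 0.9,
                             augment_prob = 0.5,
                             augment_dropout = 100L,
                             augment_spikes = 5L,
                             rng_seed = 1L) {
  for (ly in conv_layers) {
    stopifnot(is.list(ly), all(c("filters", "kernel_size") %in% names(ly)))
    if (ly$kernel_size %% 2L == 0L) stop("kernel sizes must be odd", call. = FALSE)
  }
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  if (augment_prob < 0 || augment_prob > 1) {
    stop("`augment_prob` must be in [0, 1]", call. = FALSE)
  }
  structure(list(conv_layers = conv_layers, pool_size = as.integer(pool_size),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 augment_prob = augment_prob,
                 augment_dropout = as.integer(augment_dropout),
                 augment_spikes = as.integer(augment_spikes),
                 rng_seed = as.integer(rng_seed), classes = ANGLE_CLASSES),
            class = "angle_cnn_config")
}

# ---- array plumbing ---------------------------------------------------------

# Stitched rows (B, 3W) -> input array (B, 3 channels, W time steps).
windows_to_array <- function(values, W) {
  B <- nrow(values)
  x <- array(0, dim = c(B, 3L, W))
  for (ch in 1:3) x[, ch, ] <- values[, ((ch - 1L) * W + 1L):(ch * W)]
  x
}

# im2col: (B, C, L) -> (B*Lo, C*k) patch matrix, Lo = L - k + 1.
im2col <- function(x, k) {
  d <- dim(x)
  B <- d[1L]; C <- d[2L]; L <- d[3L]
  Lo <- L - k + 1L
  t_idx <- as.vector(outer(seq_len(Lo), 0:(k - 1L), `+`))  # (Lo*k)
  xp <- x[, , t_idx, drop = FALSE]                          # (B, C, Lo*k)
  dim(xp) <- c(B, C, Lo, k)
  xp <- aperm(xp, c(1L, 3L, 2L, 4L))                        # (B, Lo, C, k)
  dim(xp) <- c(B * Lo, C * k)
  xp
}

conv_forward <- function(x, Wmat, bias, k) {
  d <- dim(x)
  B <- d[1L]; Lo <- d[3L] - k + 1L
  xp <- im2col(x, k)
  y <- xp %*% Wmat
  y <- sweep(y, 2L, bias, `+`)
  dim(y) <- c(B, Lo, ncol(Wmat))
  list(out = aperm(y, c(1L, 3L, 2L)), xp = xp)               # (B, F, Lo)
}

conv_backward <- function(dy, cache, Wmat, k, in_dim) {
  B <- in_dim[1L]; C <- in_dim[2L]; L <- in_dim[3L]
  Lo <- L - k + 1L
  dym <- aperm(dy, c(1L, 3L, 2L))                            # (B, Lo, F)
  dim(dym) <- c(B * Lo, dim(dy)[2L])
  dW <- crossprod(cache$xp, dym)
  db <- colSums(dym)
  dxp <- dym %*% t(Wmat)                                     # (B*Lo, C*k)
  dim(dxp) <- c(B, Lo, C, k)
  dxp <- aperm(dxp, c(1L, 3L, 2L, 4L))                       # (B, C, Lo, k)
  dx <- array(0, dim = in_dim)
  for (j in seq_len(k)) {
    dx[, , j:(j + Lo - 1L)] <- dx[, , j:(j + Lo - 1L)] + dxp[, , , j]
  }
  list(dx = dx, dW = dW, db = db)
}

pool_forward <- function(x, p) {
  d <- dim(x)
  Lp <- d[3L] %/% p
  xt <- x[, , seq_len(Lp * p), drop = FALSE]
  dim(xt) <- c(d[1L], d[2L], p, Lp)
  out <- xt[, , 1L, ]
  dim(out) <- c(d[1L], d[2L], Lp)
  argm <- array(1L, dim = c(d[1L], d[2L], Lp))
  if (p > 1L) for (j in 2:p) {
    slice <- xt[, , j, ]
    dim(slice) <- c(d[1L], d[2L], Lp)
    better <- slice > out
    out[better] <- slice[better]
    argm[better] <- j
  }
  list(out = out, argm = argm, in_dim = d)
}

pool_backward <- function(dy, cache, p) {
  d <- cache$in_dim
  Lp <- dim(dy)[3L]
  dxt <- array(0, dim = c(d[1L], d[2L], p, Lp))
  for (j in seq_len(p)) {
    mask <- cache$argm == j
    contrib <- array(0, dim = dim(dy))
    contrib[mask] <- dy[mask]
    dxt[, , j, ] <- contrib
  }
  dx <- array(0, dim = d)
  dim(dxt) <- c(d[1L], d[2L], p * Lp)
  dx[, , seq_len(p * Lp)] <- dxt
  dx
}

# Disturbance augmentation on a training batch: with probability
# augment_prob a window gets either a contiguous zeroed run (sample loss) or
# full-scale spikes, positioned in the flat stitched vector. Runs under the
# training RNG, so it is seeded with everything else.
augment_batch <- function(xb, cfg) {
  d <- dim(xb)
  len <- d[2L] * d[3L]
  for (i in seq_len(d[1L])) {
    if (stats::runif(1) >= cfg$augment_prob) next
    flat <- as.vector(aperm(xb[i, , , drop = FALSE], c(3L, 2L, 1L)))  # channel blocks
    if (stats::runif(1) < 0.5 && len >= cfg$augment_dropout) {
      s <- sample.int(len - cfg$augment_dropout + 1L, 1L)
      flat[s:(s + cfg$augment_dropout - 1L)] <- 0
    } else {
      flat[sample.int(len, min(cfg$augment_spikes, len))] <- 1
    }
    xb[i, , ] <- t(matrix(flat, d[3L], d[2L]))
  }
  xb
}

# ---- network ----------------------------------------------------------------

init_network <- function(cfg, W_in) {
  C <- 3L
  L <- W_in
  layers <- list()
  for (ly in cfg$conv_layers) {
    k <- as.integer(ly$kernel_size)
    f <- as.integer(ly$filters)
    if (L - k + 1L < cfg$pool_size) stop("window too short for this architecture", call. = FALSE)
    layers[[length(layers) + 1L]] <- list(
      W = matrix(stats::rnorm(C * k * f, sd = sqrt(2 / (C * k))), C * k, f),
      b = rep(0, f), k = k, filters = f)
    L <- (L - k + 1L) %/% cfg$pool_size
    C <- f
  }
  D <- C * L
  dense <- list(W = matrix(stats::rnorm(D * 3L, sd = sqrt(2 / D)), D, 3L),
                b = rep(0, 3))
  list(conv = layers, dense = dense, out_dim = c(C, L))
}

forward_pass <- function(net, x, cfg, keep_cache = FALSE) {
  caches <- list()
  for (i in seq_along(net$conv)) {
    ly <- net$conv[[i]]
    in_dim <- dim(x)
    cv <- conv_forward(x, ly$W, ly$b, ly$k)
    a <- cv$out
    relu_mask <- a > 0
    a[!relu_mask] <- 0
    pl <- pool_forward(a, cfg$pool_size)
    if (keep_cache) {
      caches[[i]] <- list(conv = cv, relu = relu_mask, pool = pl, in_dim = in_dim)
    }
    x <- pl$out
  }
  B <- dim(x)[1L]
  flat <- matrix(x, B, prod(dim(x)[2:3]))
  logits <- sweep(flat %*% net$dense$W, 2L, net$dense$b, `+`)
  list(logits = logits, flat = flat, caches = caches)
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

backward_pass <- function(net, fw, y_idx, cfg) {
  B <- nrow(fw$logits)
  probs <- softmax_probs(fw$logits)
  dlogits <- probs
  dlogits[cbind(seq_len(B), y_idx)] <- dlogits[cbind(seq_len(B), y_idx)] - 1
  dlogits <- dlogits / B
  grads <- list(dense = list(W = crossprod(fw$flat, dlogits),
                             b = colSums(dlogits)),
                conv = vector("list", length(net$conv)))
  dflat <- dlogits %*% t(net$dense$W)
  dx <- array(dflat, dim = c(B, net$out_dim[1L], net$out_dim[2L]))
  for (i in rev(seq_along(net$conv))) {
    cache <- fw$caches[[i]]
    dx <- pool_backward(dx, cache$pool, cfg$pool_size)
    dx[!cache$relu] <- 0
    cb <- conv_backward(dx, cache$conv, net$conv[[i]]$W, net$conv[[i]]$k,
                        cache$in_dim)
    grads$conv[[i]] <- list(W = cb$dW, b = cb$db)
    dx <- cb$dx
  }
  grads
}

#' Train the wrist-angle CNN
#'
#' Trains the time-series CNN on labeled stitched windows with seeded
#' minibatch SGD + momentum and cross-entropy loss. Training is
#' deterministic for a given `(train, cfg)` on one thread. The per-epoch
#' training accuracy is kept in the returned model's `history`.
#'
#' @param train A labeled `hall_windows` set (all windows the same length).
#' @param cfg An [angle_cnn_config()].
#' @param verbose Print per-epoch training accuracy. Default `FALSE`.
#' @return An object of class `angle_cnn`.
#' @export
train_angle_cnn <- function(train, cfg = angle_cnn_config(), verbose = FALSE) {
  stopifnot(inherits(train, "hall_windows"), inherits(cfg, "angle_cnn_config"))
  if (n_windows(train) == 0L) stop("training set is empty", call. = FALSE)
  if (any(is.na(train$label))) stop("all training windows must be labeled", call. = FALSE)
  if (ncol(train$values) != 3L * train$W) stop("inconsistent window lengths", call. = FALSE)
  y_idx <- match(train$label, ANGLE_CLASSES)
  if (any(is.na(y_idx))) stop("labels must be -90, 0 or 90", call. = FALSE)

  X <- windows_to_array(train$values, train$W)
  B_all <- dim(X)[1L]

  with_rng_seed(cfg$rng_seed, {
    net <- init_network(cfg, train$W)
    vel <- list(dense = list(W = net$dense$W * 0, b = net$dense$b * 0),
                conv = lapply(net$conv, function(ly) list(W = ly$W * 0, b = ly$b * 0)))
    history <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(B_all)
      for (start in seq(1L, B_all, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, B_all)]
        xb <- X[idx, , , drop = FALSE]
        if (cfg$augment_prob > 0) xb <- augment_batch(xb, cfg)
        fw <- forward_pass(net, xb, cfg, keep_cache = TRUE)
        grads <- backward_pass(net, fw, y_idx[idx], cfg)
        # momentum SGD update
        vel$dense$W <- cfg$momentum * vel$dense$W - cfg$learning_rate * grads$dense$W
        vel$dense$b <- cfg$momentum * vel$dense$b - cfg$learning_rate * grads$dense$b
        net$dense$W <- net$dense$W + vel$dense$W
        net$dense$b <- net$dense$b + vel$dense$b
        for (i in seq_along(net$conv)) {
          vel$conv[[i]]$W <- cfg$momentum * vel$conv[[i]]$W - cfg$learning_rate * grads$conv[[i]]$W
          vel$conv[[i]]$b <- cfg$momentum * vel$conv[[i]]$b - cfg$learning_rate * grads$conv[[i]]$b
          net$conv[[i]]$W <- net$conv[[i]]$W + vel$conv[[i]]$W
          net$conv[[i]]$b <- net$conv[[i]]$b + vel$conv[[i]]$b
        }
      }
      pred <- max.col(forward_pass(net, X, cfg)$logits, ties.method = "first")
      history[ep] <- mean(pred == y_idx)
      if (verbose) message(sprintf("epoch %d: train accuracy %.4f", ep, history[ep]))
    }
    structure(list(net = net, cfg = cfg, W = train$W, classes = ANGLE_CLASSES,
                   history = history),
              class = "angle_cnn")
  })
}

#' @export
print.angle_cnn <- function(x, ...) {
  arch <- paste(vapply(x$cfg$conv_layers, function(ly) {
    sprintf("conv(%d,k%d)-pool%d", ly$filters, ly$kernel_size, x$cfg$pool_size)
  }, character(1)), collapse = " -> ")
  cat(sprintf("<angle_cnn> %s -> dense(3) softmax; input 3 x %d\n", arch, x$W))
  cat(sprintf("  final training accuracy: %.4f (%d epochs)\n",
              utils::tail(x$history, 1L), x$cfg$epochs))
  invisible(x)
}

# Forward a hall_windows set: returns list(class numeric, prob matrix).
predict_window_set <- function(model, windows) {
  stopifnot(inherits(model, "angle_cnn"), inherits(windows, "hall_windows"))
  if (windows$W != model$W) stop("window length does not match the trained model", call. = FALSE)
  X <- windows_to_array(windows$values, windows$W)
  logits <- forward_pass(model$net, X, model$cfg)$logits
  prob <- softmax_probs(logits)
  colnames(prob) <- angle_key(model$classes)
  cls <- model$classes[max.col(prob, ties.method = "first")]
  list(class = cls, prob = prob)
}

#' Predict the wrist angle of stitched Hall windows
#'
#' Runs the trained network forward and returns the predicted class(es) with
#' softmax class probabilities (non-negative, summing to one).
#'
#' @param model A trained [train_angle_cnn()] model.
#' @param window A single `hall_window` (from [get_window()]) or a
#'   `hall_windows` set.
#' @return For a single window, a list with `angle` (one of -90, 0, 90) and
#'   `prob` (named length-3 vector); for a set, a list with `class` (vector)
#'   and `prob` (matrix, one row per window).
#' @export
predict_angle <- function(model, window) {
  if (inherits(window, "hall_window")) {
    ws <- structure(list(values = matrix(window$values, nrow = 1L),
                         label = window$label, t_start = window$t_start,
                         W = window$W),
                    class = "hall_windows")
    res <- predict_window_set(model, ws)
    return(list(angle = res$class[1L], prob = res$prob[1L, ]))
  }
  predict_window_set(model, window)
}

#' Confusion matrix of angle predictions
#'
#' Rows are true classes, columns predicted, in the fixed order -90, 0, 90.
#'
#' @param true Numeric vector of true angle labels.
#' @param pred Numeric vector of predicted angles.
#' @return A 3x3 integer matrix with angle dimnames.
#' @export
confusion_matrix <- function(true, pred) {
  stopifnot(length(true) == length(pred))
  ft <- factor(true, levels = ANGLE_CLASSES)
  fp <- factor(pred, levels = ANGLE_CLASSES)
  if (any(is.na(ft)) || any(is.na(fp))) stop("labels must be -90, 0 or 90", call. = FALSE)
  m <- table(true = ft, predicted = fp)
  matrix(as.integer(m), 3L, 3L,
         dimnames = list(true = angle_key(ANGLE_CLASSES),
                         predicted = angle_key(ANGLE_CLASSES)))
}

#' Evaluate the classifier on labeled test windows
#'
#' @param model A trained [train_angle_cnn()] model.
#' @param test A labeled `hall_windows` set.
#' @return List with `confusion` (3x3 matrix, rows = true class) and
#'   `accuracy` (trace over total).
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(test, "hall_windows"))
  if (n_windows(test) == 0L) stop("test set is empty", call. = FALSE)
  if (any(is.na(test$label))) stop("all test windows must be labeled", call. = FALSE)
  pred <- predict_window_set(model, test)$class
  cm <- confusion_matrix(test$label, pred)
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm))
}

#' Save or load a trained angle CNN
#'
#' The model (configuration + weights) is serialized to a single file.
#'
#' @param model An `angle_cnn` model.
#' @param path File path.
#' @return `save_angle_cnn()` returns `path` invisibly; `load_angle_cnn()`
#'   returns the model.
#' @export
save_angle_cnn <- function(model, path) {
  stopifnot(inherits(model, "angle_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_angle_cnn
#' @export
load_angle_cnn <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "angle_cnn"))
  model
}
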