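#' stepperNet architecture description
#'
#' Fixed architecture of the stride/non-stride classifier: the 100 x 6
#' feature image is convolved with three 10 x 6 kernels (step 1, valid
#' support, so each feature map has height 100 - 10 + 1 = 91), rectified,
#' max-pooled with a 3 x 1 kernel at stride 3 (remainder truncated, 30 per
#' map), concatenated (90), joined with the 19-element score vector (109),
#' passed through two fully connected ReLU layers of 30 and 15 neurons, and
#' projected to 2 logits normalized by softmax. The stride probability is the
#' second softmax component.
#'
#' @param input_rows,input_cols Feature-image size (100 x 6).
#' @param n_kernels Number of convolution kernels (3).
#' @param kernel_rows,kernel_cols Kernel size (10 x 6).
#' @param pool Max-pool length and stride (3).
#' @param fc_sizes Fully connected layer widths, `c(30, 15)`.
#' @param score_len Length of the appended score vector (19).
#' @param n_outputs Number of classes (2).
#' @return A list of class `network_config` including the derived sizes
#'   `conv_h` (91), `pooled_h` (30), `concat_len` (90) and `joined_len`
#'   (109).
#' @export
network_config <- function(input_rows = 100L, input_cols = 6L,
                           n_kernels = 3L, kernel_rows = 10L,
                           kernel_cols = 6L, pool = 3L,
                           fc_sizes = c(30L, 15L), score_len = 19L,
                           n_outputs = 2L) {
  conv_h <- input_rows - kernel_rows + 1L
  pooled_h <- conv_h %/% pool
  cfg <- list(input_rows = input_rows, input_cols = input_cols,
              n_kernels = n_kernels, kernel_rows = kernel_rows,
              kernel_cols = kernel_cols, pool = pool,
              fc_sizes = as.integer(fc_sizes), score_len = score_len,
              n_outputs = n_outputs,
              conv_h = conv_h, pooled_h = pooled_h,
              concat_len = n_kernels * pooled_h,
              joined_len = n_kernels * pooled_h + score_len)
  if (conv_h < 1 || pooled_h < 1) stop("kernel larger than input", call. = FALSE)
  structure(cfg, class = "network_config")
}

#' Training settings for stepperNet
#'
#' Defaults follow the published recipe: plain stochastic gradient descent
#' (one example at a time) with momentum for 7 epochs at learning rate 0.015
#' and momentum 0.75; training is repeated from `n_restarts` random
#' initializations and the restart with the highest held-out accuracy wins.
#'
#' @param epochs Number of passes over the training split (default 7).
#' @param learning_rate SGD learning rate (default 0.015).
#' @param momentum Momentum coefficient in \[0, 1) (default 0.75).
#' @param n_restarts Random restarts (default 10).
#' @param seed RNG seed making the whole run reproducible.
#' @param train_fraction Fraction of examples used for gradient updates; the
#'   rest is the held-out split scoring each restart (default 0.87,
#'   mirroring a 3493/521 style split).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 7L, learning_rate = 0.015,
                         momentum = 0.75, n_restarts = 10L, seed = 1L,
                         train_fraction = 0.87) {
  stopifnot(epochs >= 1, learning_rate > 0, momentum >= 0, momentum < 1,
            n_restarts >= 1, train_fraction > 0, train_fraction < 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), train_fraction = train_fraction),
            class = "train_config")
}

# im2row: unroll the valid 10x6 windows of M into a conv_h x (kr*kc) matrix
# so convolution is a single matrix product
conv_patches <- function(M, cfg) {
  kr <- cfg$kernel_rows
  idx <- outer(seq_len(cfg$conv_h), 0:(kr - 1L), `+`)  # conv_h x kr row ids
  P <- matrix(0, cfg$conv_h, kr * cfg$kernel_cols)
  for (cc in seq_len(cfg$kernel_cols)) {
    P[, ((cc - 1L) * kr + 1L):(cc * kr)] <- matrix(M[idx, cc], cfg$conv_h, kr)
  }
  P
}

init_params <- function(cfg) {
  he <- function(nr, nc, fan_in) {
    matrix(stats::runif(nr * nc, -1, 1) * sqrt(6 / fan_in), nr, nc)
  }
  kdim <- cfg$kernel_rows * cfg$kernel_cols
  list(
    K = he(kdim, cfg$n_kernels, kdim),         # kernels, one per column
    bK = rep(0, cfg$n_kernels),
    W1 = he(cfg$fc_sizes[1], cfg$joined_len, cfg$joined_len),
    b1 = rep(0, cfg$fc_sizes[1]),
    W2 = he(cfg$fc_sizes[2], cfg$fc_sizes[1], cfg$fc_sizes[1]),
    b2 = rep(0, cfg$fc_sizes[2]),
    W3 = he(cfg$n_outputs, cfg$fc_sizes[2], cfg$fc_sizes[2]),
    b3 = rep(0, cfg$n_outputs)
  )
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# full forward pass keeping intermediates for backprop / inspection.
# P is the precomputed patch matrix of the feature image (conv_patches).
forward_pass <- function(params, P, score, cfg) {
  Z <- P %*% params$K + matrix(params$bK, nrow(P), cfg$n_kernels, byrow = TRUE)
  A <- pmax(Z, 0)
  keep <- cfg$pooled_h * cfg$pool
  pooled <- matrix(0, cfg$pooled_h, cfg$n_kernels)
  argmax <- matrix(0L, cfg$pooled_h, cfg$n_kernels)
  for (k in seq_len(cfg$n_kernels)) {
    blocks <- matrix(A[seq_len(keep), k], nrow = cfg$pool)
    w <- max.col(t(blocks), ties.method = "first")
    argmax[, k] <- (seq_len(cfg$pooled_h) - 1L) * cfg$pool + w
    pooled[, k] <- blocks[cbind(w, seq_len(cfg$pooled_h))]
  }
  h0 <- c(as.numeric(pooled), score)
  s1 <- as.numeric(params$W1 %*% h0) + params$b1
  h1 <- pmax(s1, 0)
  s2 <- as.numeric(params$W2 %*% h1) + params$b2
  h2 <- pmax(s2, 0)
  logits <- as.numeric(params$W3 %*% h2) + params$b3
  prob <- softmax(logits)
  list(Z = Z, A = A, argmax = argmax, pooled = pooled, h0 = h0,
       s1 = s1, h1 = h1, s2 = s2, h2 = h2, logits = logits, prob = prob)
}

#' stepperNet forward pass
#'
#' Computes the stride probability of a feature set. With
#' `details = TRUE` the intermediate tensors are returned as well, which is
#' useful for inspecting the architecture (feature-map height 91, pooled and
#' concatenated length 90, joined length 109).
#'
#' @param params Network parameters from [stepper_train()] or
#'   `gaitseg:::init_params`.
#' @param features A `feature_set` (see [build_feature_set()]).
#' @param cfg A [network_config()].
#' @param details If `TRUE`, return intermediates instead of just the
#'   probability.
#' @return The stride probability in \[0, 1\], or a list of intermediates.
#' @export
stepper_forward <- function(params, features, cfg = network_config(),
                            details = FALSE) {
  stopifnot(inherits(features, "feature_set"))
  M <- features$M
  if (nrow(M) != cfg$input_rows || ncol(M) != cfg$input_cols) {
    stop("feature image must be ", cfg$input_rows, " x ", cfg$input_cols,
         call. = FALSE)
  }
  if (length(features$c) != cfg$score_len) {
    stop("score vector must have length ", cfg$score_len, call. = FALSE)
  }
  fw <- forward_pass(params, conv_patches(M, cfg), features$c, cfg)
  if (details) {
    c(fw, list(conv_h = nrow(fw$Z), concat_len = length(as.numeric(fw$pooled)),
               joined_len = length(fw$h0), prob_stride = fw$prob[2]))
  } else {
    fw$prob[2]
  }
}

# cross-entropy loss and analytic gradient for one example.
# y is 1 for stride, 0 for non-stride (stride = second softmax component).
loss_grad <- function(params, P, score, y, cfg) {
  fw <- forward_pass(params, P, score, cfg)
  target <- if (y == 1) c(0, 1) else c(1, 0)
  loss <- -sum(target * log(pmax(fw$prob, 1e-300)))
  dlog <- fw$prob - target
  gW3 <- dlog %o% fw$h2
  gb3 <- dlog
  dh2 <- as.numeric(t(params$W3) %*% dlog) * (fw$s2 > 0)
  gW2 <- dh2 %o% fw$h1
  gb2 <- dh2
  dh1 <- as.numeric(t(params$W2) %*% dh2) * (fw$s1 > 0)
  gW1 <- dh1 %o% fw$h0
  gb1 <- dh1
  dh0 <- as.numeric(t(params$W1) %*% dh1)
  npool <- cfg$pooled_h * cfg$n_kernels
  dpool <- matrix(dh0[seq_len(npool)], cfg$pooled_h, cfg$n_kernels)
  dA <- matrix(0, cfg$conv_h, cfg$n_kernels)
  for (k in seq_len(cfg$n_kernels)) {
    dA[fw$argmax[, k], k] <- dA[fw$argmax[, k], k] + dpool[, k]
  }
  dZ <- dA * (fw$Z > 0)
  gK <- crossprod(P, dZ)
  gbK <- colSums(dZ)
  list(loss = loss,
       grads = list(K = gK, bK = gbK, W1 = gW1, b1 = gb1,
                    W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3),
       prob = fw$prob[2])
}

#' Train stepperNet with SGD, momentum and random restarts
#'
#' Stochastic gradient descent on the mean cross-entropy, one example per
#' update, with classical momentum. Training is repeated from
#' `tc$n_restarts` random initializations; each restart is scored by its
#' accuracy on the held-out split and the best restart's parameters are
#' returned. The whole procedure is reproducible given `tc$seed`.
#'
#' @param features List of `feature_set` objects.
#' @param labels Logical (or 0/1) vector: `TRUE`/1 for stride.
#' @param tc A [train_config()].
#' @param cfg A [network_config()].
#' @return List of class `stepper_net`: `params`, `cfg`, `epoch_loss`
#'   (per-epoch mean training loss of the winning restart), `val_accuracy`,
#'   `restart_accuracy` (held-out accuracy of every restart) and the indices
#'   of the held-out split.
#' @export
stepper_train <- function(features, labels, tc = train_config(),
                          cfg = network_config()) {
  labels <- as.integer(as.logical(labels))
  n <- length(features)
  if (n < 2) stop("need at least 2 examples", call. = FALSE)
  if (length(labels) != n) stop("labels must match features", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  patches <- lapply(features, function(f) conv_patches(f$M, cfg))
  scores <- lapply(features, `[[`, "c")

  set.seed(tc$seed)
  n_train <- max(1L, min(n - 1L, round(tc$train_fraction * n)))
  perm <- sample.int(n)
  train_idx <- perm[seq_len(n_train)]
  val_idx <- perm[(n_train + 1L):n]
  # guarantee both classes in the training split
  if (length(unique(labels[train_idx])) < 2) {
    swap_in <- val_idx[labels[val_idx] != labels[train_idx][1]][1]
    train_idx[1] <- swap_in
    val_idx <- setdiff(perm, train_idx)
  }

  best <- NULL
  best_acc <- -1
  restart_acc <- numeric(tc$n_restarts)
  for (rs in seq_len(tc$n_restarts)) {
    params <- init_params(cfg)
    vel <- lapply(params, function(p) p * 0)
    epoch_loss <- numeric(tc$epochs)
    for (ep in seq_len(tc$epochs)) {
      ord <- train_idx[sample.int(length(train_idx))]
      tot <- 0
      for (i in ord) {
        lg <- loss_grad(params, patches[[i]], scores[[i]], labels[i], cfg)
        tot <- tot + lg$loss
        for (nm in names(params)) {
          vel[[nm]] <- tc$momentum * vel[[nm]] -
            tc$learning_rate * lg$grads[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
      }
      epoch_loss[ep] <- tot / length(ord)
    }
    pred <- vapply(val_idx, function(i) {
      forward_pass(params, patches[[i]], scores[[i]], cfg)$prob[2]
    }, numeric(1))
    acc <- mean((pred > 0.5) == (labels[val_idx] == 1))
    restart_acc[rs] <- acc
    if (acc > best_acc) {
      best_acc <- acc
      best <- list(params = params, epoch_loss = epoch_loss)
    }
  }
  structure(list(params = best$params, cfg = cfg,
                 epoch_loss = best$epoch_loss, val_accuracy = best_acc,
                 restart_accuracy = restart_acc,
                 train_idx = train_idx, val_idx = val_idx),
            class = "stepper_net")
}

#' @export
print.stepper_net <- function(x, ...) {
  cat(sprintf(
    "<stepper_net> held-out accuracy %.3f over %d restart(s); final loss %.4g\n",
    x$val_accuracy, length(x$restart_accuracy),
    x$epoch_loss[length(x$epoch_loss)]))
  invisible(x)
}

#' Decide stride vs non-stride from a probability
#'
#' A region of motion is accepted as a walking stride when its stride
#' probability exceeds 0.5; a probability of exactly 0.5 (ties) is rejected.
#'
#' @param prob Numeric vector of probabilities in \[0, 1\].
#' @return Character vector, `"stride"` or `"non-stride"`.
#' @export
classify_stride <- function(prob) {
  if (any(is.na(prob)) || any(prob < 0 | prob > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  ifelse(prob > 0.5, "stride", "non-stride")
}

#' Save / load a trained stepperNet as portable JSON
#'
#' The container stores the architecture description plus every weight array
#' as base64-encoded little-endian float64, so models round-trip bitwise
#' across platforms without binary file formats.
#'
#' @param model A `stepper_net` (or a bare list with `params` and `cfg`).
#' @param path File path.
#' @return `load_stepper_net` returns a `stepper_net`.
#' @export
save_stepper_net <- function(model, path) {
  p <- model$params
  enc <- function(x) {
    list(dim = if (is.matrix(x)) dim(x) else length(x),
         data = jsonlite::base64_enc(
           writeBin(as.numeric(x), raw(), size = 8, endian = "little")))
  }
  payload <- list(
    format = "gaitseg-steppernet-1",
    config = unclass(model$cfg),
    params = lapply(p, enc)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_stepper_net
#' @export
load_stepper_net <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "gaitseg-steppernet-1")) {
    stop("not a gaitseg stepperNet model file: ", path, call. = FALSE)
  }
  cfg <- do.call(network_config, payload$config[c(
    "input_rows", "input_cols", "n_kernels", "kernel_rows", "kernel_cols",
    "pool", "fc_sizes", "score_len", "n_outputs")])
  dec <- function(x) {
    v <- readBin(jsonlite::base64_dec(x$data), "double",
                 n = prod(x$dim), size = 8, endian = "little")
    if (length(x$dim) == 2) matrix(v, x$dim[1], x$dim[2]) else v
  }
  params <- lapply(payload$params, dec)
  structure(list(params = params, cfg = cfg, epoch_loss = numeric(0),
                 val_accuracy = NA_real_, restart_accuracy = numeric(0)),
            class = "stepper_net")
}
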