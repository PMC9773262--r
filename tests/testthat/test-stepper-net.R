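test_that("every intermediate tensor has the architecture's derived shape", {
  cfg <- network_config()
  expect_equal(cfg$conv_h, 91)
  expect_equal(cfg$pooled_h, 30)
  expect_equal(cfg$concat_len, 90)
  expect_equal(cfg$joined_len, 109)
  set.seed(30)
  params <- gaitseg:::init_params(cfg)
  corpus <- tiny_corpus(n = 4, seed = 30)
  fw <- stepper_forward(params, corpus$features[[1]], cfg, details = TRUE)
  expect_equal(dim(fw$Z), c(91, 3))
  expect_equal(dim(fw$pooled), c(30, 3))
  expect_equal(fw$concat_len, 90)
  expect_equal(fw$joined_len, 109)
  expect_length(fw$h1, 30)
  expect_length(fw$h2, 15)
  expect_length(fw$logits, 2)
  expect_equal(sum(fw$prob), 1)
})

test_that("all-zero parameters give probability exactly 0.5", {
  cfg <- network_config()
  set.seed(31)
  params <- gaitseg:::init_params(cfg)
  zero <- lapply(params, function(p) p * 0)
  f <- tiny_corpus(n = 2, seed = 31)$features[[1]]
  expect_equal(stepper_forward(zero, f, cfg), 0.5)
})

test_that("a shrunk network matches a hand-computed forward pass", {
  # 4x2 image, one 2x2 kernel -> conv height 3, pool 3 -> 1; score length 1
  cfg <- network_config(input_rows = 4L, input_cols = 2L, n_kernels = 1L,
                        kernel_rows = 2L, kernel_cols = 2L, pool = 3L,
                        fc_sizes = c(2L, 2L), score_len = 1L)
  expect_equal(cfg$conv_h, 3)
  expect_equal(cfg$joined_len, 2)
  M <- matrix(c(1, 0, 1, 0,
                0, 1, 0, 1), 4, 2)
  f <- structure(list(M = M, c = 2), class = "feature_set")
  params <- list(
    K = matrix(c(1, -1, 2, 1), 4, 1),  # column-major: rows of col 1, col 2
    bK = 0.5,
    W1 = matrix(c(1, 0, 0, 1), 2, 2), b1 = c(0, -1),
    W2 = matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE), b2 = c(0, 0),
    W3 = matrix(c(1, 0, 0, 1), 2, 2), b3 = c(0, 0)
  )
  # windows (rows i..i+1 of both columns): patch_i = (M[i,1], M[i+1,1],
  # M[i,2], M[i+1,2]); conv_i = patch . (1,-1,2,1) + 0.5
  # i=1: (1,0,0,1) -> 1 - 0 + 0 + 1 + 0.5 = 2.5
  # i=2: (0,1,1,0) -> 0 - 1 + 2 + 0 + 0.5 = 1.5
  # i=3: (1,0,0,1) -> 2.5
  # pool over 3 -> max = 2.5; h0 = (2.5, 2)
  # fc1: relu((2.5, 2) + (0,-1)) = (2.5, 1)
  # fc2: relu((2.5+1, 2.5-1)) = (3.5, 1.5)
  # logits = (3.5, 1.5); p_stride = exp(1.5)/(exp(3.5)+exp(1.5))
  expect_equal(stepper_forward(params, f, cfg),
               exp(1.5) / (exp(3.5) + exp(1.5)))
})

test_that("analytic gradients match central finite differences", {
  cfg <- network_config(input_rows = 12L, input_cols = 3L, n_kernels = 2L,
                        kernel_rows = 4L, kernel_cols = 3L, pool = 3L,
                        fc_sizes = c(5L, 4L), score_len = 3L)
  set.seed(32)
  params <- gaitseg:::init_params(cfg)
  M <- matrix(runif(12 * 3), 12, 3)
  score <- rnorm(3)
  P <- gaitseg:::conv_patches(M, cfg)
  y <- 1
  base <- gaitseg:::loss_grad(params, P, score, y, cfg)
  eps <- 1e-6
  for (nm in names(params)) {
    g <- base$grads[[nm]]
    num <- params[[nm]] * 0
    for (i in seq_along(params[[nm]])) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      lu <- gaitseg:::loss_grad(up, P, score, y, cfg)$loss
      ld <- gaitseg:::loss_grad(dn, P, score, y, cfg)$loss
      num[i] <- (lu - ld) / (2 * eps)
    }
    denom <- pmax(abs(num), 1)
    expect_lt(max(abs(g - num) / denom), 1e-5)
  }
})

test_that("training separates a linearly separable toy set perfectly", {
  # synthetic feature sets whose score vector carries the label
  set.seed(33)
  make_f <- function(label) {
    M <- matrix(runif(600), 100, 6)
    sc <- rnorm(19, mean = 0, sd = 0.3)
    sc[2] <- if (label) 3 else -3
    structure(list(M = M, c = sc), class = "feature_set")
  }
  labels <- rep(c(TRUE, FALSE), 30)
  feats <- lapply(labels, make_f)
  model <- stepper_train(feats, labels,
                         train_config(seed = 33, n_restarts = 2))
  expect_equal(model$val_accuracy, 1)
  expect_length(model$epoch_loss, 7)
})

test_that("training is bitwise reproducible under a fixed seed", {
  corpus <- tiny_corpus(n = 24, seed = 34)
  tc <- train_config(seed = 7, n_restarts = 2, epochs = 2)
  m1 <- stepper_train(corpus$features, corpus$labels, tc)
  m2 <- stepper_train(corpus$features, corpus$labels, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$epoch_loss, m2$epoch_loss)
})

test_that("best-of-k restart accuracy is monotone non-decreasing in k", {
  corpus <- tiny_corpus(n = 30, seed = 35)
  model <- stepper_train(corpus$features, corpus$labels,
                         train_config(seed = 9, n_restarts = 5, epochs = 2))
  best_of_k <- cummax(model$restart_accuracy)
  expect_true(all(diff(best_of_k) >= 0))
  expect_equal(model$val_accuracy, max(model$restart_accuracy))
})

test_that("the 0.5 decision rule rejects ties", {
  expect_equal(classify_stride(c(0.9, 0.1, 0.5, 0.500001)),
               c("stride", "non-stride", "non-stride", "stride"))
  expect_error(classify_stride(1.2), "\\[0, 1\\]")
  expect_error(stepper_train(tiny_corpus(4, seed = 1)$features,
                             c(TRUE, TRUE, TRUE, TRUE)), "both classes")
})

test_that("model JSON serialization round trips exactly", {
  corpus <- tiny_corpus(n = 16, seed = 36)
  model <- stepper_train(corpus$features, corpus$labels,
                         train_config(seed = 3, n_restarts = 1, epochs = 1))
  f <- withr::local_tempfile(fileext = ".json")
  save_stepper_net(model, f)
  back <- load_stepper_net(f)
  expect_equal(back$params, model$params, tolerance = 0)
  p1 <- stepper_forward(model$params, corpus$features[[1]], model$cfg)
  p2 <- stepper_forward(back$params, corpus$features[[1]], back$cfg)
  expect_identical(p1, p2)
})
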