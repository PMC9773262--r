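test_that("build_template averages resampled strides", {
  s1 <- simulate_stride(seed = 20)$R
  tpl <- build_template(list(s1))
  expect_equal(dim(tpl$T), c(100, 6))
  expect_equal(tpl$T, apply(s1, 2, fourier_resample, n = 100),
               ignore_attr = TRUE)

  # opposite strides cancel
  tpl0 <- build_template(list(s1, -s1))
  expect_lt(max(abs(tpl0$T)), 1e-12)

  # columnwise mean against a loop oracle
  strides <- replicate(15, simulate_stride()$R, simplify = FALSE)
  tpl <- build_template(strides)
  acc <- matrix(0, 100, 6)
  for (s in strides) {
    for (j in 1:6) acc[, j] <- acc[, j] + fourier_resample(s[, j], 100)
  }
  expect_equal(unname(tpl$T), acc / 15)
  expect_equal(tpl$n_strides, 15)
  expect_error(build_template(list()), "at least one")
})

test_that("DTW distance agrees with exhaustive path enumeration", {
  set.seed(21)
  # random integer pairs of lengths 2..6
  for (rep in 1:60) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    x <- sample(0:3, n, replace = TRUE)
    y <- sample(0:3, m, replace = TRUE)
    al <- dtw_align(x, y)
    expect_equal(al$cost, brute_dtw_cost(x, y))
  }
  # exhaustive over all {0,1,2}-valued pairs of length 3 x 3
  grid <- expand.grid(rep(list(0:2), 3))
  for (i in seq_len(nrow(grid))) {
    x <- as.numeric(grid[i, ])
    y <- as.numeric(grid[(i %% nrow(grid)) + 1, ])
    expect_equal(dtw_align(x, y)$cost, brute_dtw_cost(x, y))
  }
})

test_that("DTW identity and time-stretch invariance", {
  x <- c(0, 1, 2, 1, 0.5, 0)
  al <- dtw_align(x, x)
  expect_equal(al$distance, 0)
  expect_equal(al$warped, x)
  # doubling every sample is a monotone re-parametrization: distance 0
  x2 <- rep(x, each = 2)
  expect_equal(dtw_align(x2, x)$distance, 0)
  expect_equal(dtw_align(x, x2)$distance, 0)
  # warped query has the reference length
  expect_length(dtw_align(c(1, 5, 2, 8, 1), x)$warped, length(x))
  expect_error(dtw_align(c(1, NA, 2), x), "finite")
})

test_that("p-value rescaling follows 0.1*log(p) with an epsilon clamp", {
  expect_equal(rescale_p(1), 0)
  expect_equal(rescale_p(exp(-10)), -1)
  expect_equal(rescale_p(0), 0.1 * log(.Machine$double.eps))
  expect_true(is.finite(rescale_p(0)))
  expect_error(rescale_p(1.2), "probability")
  expect_error(rescale_p(-0.1), "probability")
})

test_that("feature sets have the documented layout and self-match behaviour", {
  s <- simulate_stride(stride_params(noise_sd = 0), seed = 22)
  tpl <- build_template(list(s$R))
  f <- build_feature_set(s$rom, tpl)
  expect_length(f$c, 19)
  expect_true(all(f$M >= 0 & f$M <= 1))
  expect_equal(dim(f$M), c(100, 6))
  expect_true(all(f$r >= -1 & f$r <= 1))
  expect_true(all(f$d >= 0))
  # c layout: duration then (1/d, r, phat) per channel
  expect_equal(f$c[1], s$rom$duration)
  expect_equal(f$c[2], 1 / max(f$d[1], 1e-6))
  expect_equal(f$c[3], f$r[1])

  # a ROM already on the template grid: d ~ 0, capped 1/d, r = 1
  rom100 <- structure(list(R = tpl$T, t = (0:99) / 100, duration = 0.99,
                           start = 1L, end = 100L), class = "rom")
  f0 <- build_feature_set(rom100, tpl)
  expect_equal(f0$d, rep(0, 6))
  expect_equal(f0$c[seq(2, 17, by = 3)], rep(1e6, 6))
  expect_equal(f0$r, rep(1, 6), tolerance = 1e-12)
})

test_that("the feature image is invariant to positive affine channel rescaling", {
  s <- simulate_stride(seed = 23)
  tpl <- build_template(list(simulate_stride(seed = 24)$R))
  f1 <- build_feature_set(s$rom, tpl)
  rom2 <- s$rom
  rom2$R <- sweep(sweep(s$rom$R, 2, c(2, 3, 0.5, 10, 1.5, 4), `*`),
                  2, c(-1, 5, 0.3, 100, 0, -9), `+`)
  f2 <- build_feature_set(rom2, tpl)
  expect_equal(f1$M, f2$M, tolerance = 1e-9)
})

test_that("degenerate constant channels fall back to r = 0, p = 1", {
  s <- simulate_stride(seed = 25)
  rom <- s$rom
  rom$R[, 2] <- 0  # kill ay
  tpl <- build_template(list(simulate_stride(seed = 26)$R))
  w <- capture_warnings(f <- build_feature_set(rom, tpl))
  expect_match(w, "constant", all = FALSE)
  expect_equal(f$r[2], 0)
  expect_equal(f$p[2], 1)
})

test_that("stride features sit closer to the template than non-stride features", {
  set.seed(27)
  tpl <- build_template(replicate(30, simulate_stride()$R, simplify = FALSE))
  d_stride <- replicate(50, {
    mean(build_feature_set(simulate_stride()$rom, tpl)$d)
  })
  kinds <- c("stomp", "jump", "wiggle")
  d_non <- replicate(50, {
    rom <- simulate_nonstride(sample(kinds, 1))
    mean(suppressWarnings(build_feature_set(rom, tpl)$d))
  })
  expect_lt(mean(d_stride), mean(d_non))
})

test_that("template CSV round trips", {
  tpl <- build_template(replicate(3, simulate_stride()$R, simplify = FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_template(tpl, f)
  back <- read_template(f)
  expect_equal(back$T, tpl$T, tolerance = 1e-9)
  expect_error(read_template(system.file("DESCRIPTION", package = "gaitseg")),
               "template CSV")
})
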