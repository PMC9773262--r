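test_that("finite_difference matches its definition and conventions", {
  expect_equal(finite_difference(c(5, 5, 5), c(0, 0.01, 0.02)), c(0, 0, 0))
  expect_equal(finite_difference(c(0, 1, 3), c(0, 0.01, 0.02)), c(0, 100, 200))

  set.seed(1)
  x <- rnorm(50)
  t <- cumsum(runif(50, 0.005, 0.02))
  out <- finite_difference(x, t)
  # loop-based oracle
  exp <- numeric(50)
  for (k in 2:50) exp[k] <- (x[k] - x[k - 1]) / (t[k] - t[k - 1])
  expect_equal(out, exp)

  # derivative of a cumulative sum at uniform dt recovers increments / dt
  inc <- rnorm(30)
  tu <- (0:29) / 100
  d <- finite_difference(cumsum(inc), tu)
  expect_equal(d[-1], inc[-1] / 0.01)

  expect_error(finite_difference(1:3, c(0, 0.2, 0.1)), "increasing")
  expect_error(finite_difference(1:3, c(0, 0.1)), "length")
})

test_that("gyro_magnitude is the per-sample Euclidean norm and is symmetric", {
  expect_equal(gyro_magnitude(0, 0, 0), 0)
  expect_equal(gyro_magnitude(3, 4, 0), 5)
  set.seed(2)
  a <- rnorm(40); b <- rnorm(40); c <- rnorm(40)
  w <- gyro_magnitude(a, b, c)
  expect_equal(w, sapply(1:40, function(k) sqrt(a[k]^2 + b[k]^2 + c[k]^2)))
  expect_true(all(w >= 0))
  # invariance under axis permutation and sign flips
  expect_equal(gyro_magnitude(-c, a, -b), w)
  expect_error(gyro_magnitude(1:3, 1:3, 1:2), "length")
})

test_that("minmax_normalize rescales to [0,1] and is affine-invariant", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  s <- c(0, 0.25, 1, 0.5)
  expect_equal(minmax_normalize(s), s)
  set.seed(3)
  x <- rnorm(25)
  expect_equal(minmax_normalize(3.7 * x + 11), minmax_normalize(x))
  expect_warning(out <- minmax_normalize(rep(2, 5)), "constant")
  expect_equal(out, rep(0, 5))
})

test_that("fourier_resample is exact for band-limited signals", {
  expect_equal(fourier_resample(rep(3.2, 57), 100), rep(3.2, 100))

  x <- sin(2 * pi * (0:79) / 80)
  y <- fourier_resample(x, 100)
  expect_length(y, 100)
  expect_lt(max(abs(y - sin(2 * pi * (0:99) / 100))), 1e-6)

  # round trip there and back for a band-limited input
  z <- 0.5 + sin(2 * pi * 3 * (0:63) / 64) + 0.2 * cos(2 * pi * 5 * (0:63) / 64)
  expect_lt(max(abs(fourier_resample(fourier_resample(z, 100), 64) - z)), 1e-6)

  # odd/even length combinations stay real and exact in length
  for (m in c(9, 10, 33)) {
    for (n in c(7, 50, 101)) {
      expect_length(fourier_resample(rnorm(m), n), n)
    }
  }
  expect_error(fourier_resample(1:10, 1), "n must be")
})

test_that("imu_recording validates channel shape and time axis", {
  t <- (0:9) / 100
  expect_silent(rec <- imu_recording(t, 1:10, 1:10, 1:10, 1:10, 1:10, 1:10))
  expect_equal(rec$m, 10)
  expect_error(imu_recording(t, 1:9, 1:10, 1:10, 1:10, 1:10, 1:10), "length")
  tbad <- t; tbad[5] <- tbad[4]
  expect_error(imu_recording(tbad, 1:10, 1:10, 1:10, 1:10, 1:10, 1:10),
               "increasing")
  expect_error(imu_recording(t * 10, 1:10, 1:10, 1:10, 1:10, 1:10, 1:10),
               "sampling interval")
})

test_that("recording CSV round trip is faithful and schema errors are caught", {
  set.seed(4)
  t <- (0:49) / 100
  rec <- imu_recording(t, rnorm(50), rnorm(50), rnorm(50, 9.81),
                       rnorm(50), rnorm(50), rnorm(50))
  f <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, f)
  rec2 <- read_recording(f)
  for (ch in c("t", "ax", "ay", "az", "gx", "gy", "gz")) {
    expect_lt(max(abs(rec[[ch]] - rec2[[ch]])), 1e-9)
  }

  # missing column
  df <- utils::read.csv(f)
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df[-3], f2, row.names = FALSE)
  expect_error(read_recording(f2), "missing column")

  # shuffled rows -> unsorted time axis, named row
  utils::write.csv(df[c(2, 1, 3:50), ], f2, row.names = FALSE)
  expect_error(read_recording(f2), "unsorted time axis at data row 2")

  # non-numeric cell
  df2 <- df; df2$ax <- as.character(df2$ax); df2$ax[7] <- "oops"
  utils::write.csv(df2, f2, row.names = FALSE)
  expect_error(read_recording(f2), "ax")
})

test_that("annotation CSV round trips and rejects unknown enumerations", {
  ann <- data.frame(event = c("HO", "TO", "HS", "FF"), side = "left",
                    t = c(0.1, 0.25, 0.6, 0.85), source = "gold")
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(back$event, ann$event)
  expect_equal(back$t, ann$t)

  bad <- ann; bad$event[2] <- "XX"
  write_annotations(bad, f)
  expect_error(read_annotations(f), "unknown event type 'XX' at data row 2")
})

test_that("derived_signals carries derivatives, magnitude and its sd", {
  s <- simulate_stride(stride_params(noise_sd = 0), seed = 5)
  rec <- imu_recording(s$t, s$R[, "ax"], s$R[, "ay"], s$R[, "az"],
                       s$R[, "gx"], s$R[, "gy"], s$R[, "gz"])
  d <- derived_signals(rec)
  expect_equal(d$dax[1], 0)
  expect_length(d$wa, rec$m)
  expect_true(all(d$wa >= 0))
  expect_equal(d$sigma_wa, sqrt(mean((d$wa - mean(d$wa))^2)))
})
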