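#' Construct a six-axis IMU recording
#'
#' Bundles the seven channels of a foot-worn inertial measurement unit into a
#' validated container: a time axis plus three acceleration and three angular
#' rate channels. All downstream functions in the package (segmentation,
#' feature extraction, event detection) consume this object.
#'
#' @param t Numeric vector of strictly increasing timestamps in seconds.
#' @param ax,ay,az Acceleration channels in m/s^2. `x` points heel-to-toe,
#'   `z` is normal to the sole pointing up, `y` completes the right-handed
#'   frame.
#' @param gx,gy,gz Angular rate channels in deg/s about the same axes.
#' @param fs Nominal sampling rate in Hz (default 100). The median sampling
#'   interval must be within 10% of `1/fs`.
#'
#' @return An object of class `imu_recording`: a list with elements `t`,
#'   `ax`, `ay`, `az`, `gx`, `gy`, `gz`, `m` (sample count) and `fs`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' rec <- imu_recording(t, sin(t), cos(t), 9.81 + 0 * t, 0 * t, 0 * t, 0 * t)
#' rec$m
imu_recording <- function(t, ax, ay, az, gx, gy, gz, fs = 100) {
  chans <- list(t = t, ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
  m <- length(t)
  if (m < 2) stop("an IMU recording needs at least 2 samples", call. = FALSE)
  lens <- vapply(chans, length, integer(1))
  if (any(lens != m)) {
    stop("all channels must share the recording length ", m, "; got lengths ",
         paste(lens, collapse = ", "), call. = FALSE)
  }
  bad <- vapply(chans, function(x) !is.numeric(x) || anyNA(x), logical(1))
  if (any(bad)) {
    stop("non-numeric or missing values in channel(s): ",
         paste(names(chans)[bad], collapse = ", "), call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing (first violation at row ",
         which(diff(t) <= 0)[1] + 1L, ")", call. = FALSE)
  }
  med_dt <- stats::median(diff(t))
  if (abs(med_dt - 1 / fs) > 0.1 / fs) {
    stop(sprintf(
      "median sampling interval %.4g s is not within 10%% of 1/fs = %.4g s",
      med_dt, 1 / fs), call. = FALSE)
  }
  structure(c(chans, list(m = m, fs = fs)), class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples, %.2f s at %g Hz nominal\n",
              x$m, x$t[x$m] - x$t[1], x$fs))
  invisible(x)
}

#' First-order time derivative of a sampled signal
#'
#' Backward difference against the (possibly non-uniform) time axis. By
#' convention the first sample of the derivative is 0, so the output has the
#' same length as the input.
#'
#' @param signal Numeric vector.
#' @param t Numeric vector of strictly increasing timestamps, same length.
#' @return Numeric vector: `out[k] = (signal[k] - signal[k-1]) / (t[k] -
#'   t[k-1])` for `k >= 2`, and `out[1] = 0`.
#' @export
#' @examples
#' finite_difference(c(0, 1, 3), c(0, 0.01, 0.02))
finite_difference <- function(signal, t) {
  if (length(signal) != length(t)) {
    stop("signal and t must have the same length", call. = FALSE)
  }
  if (length(t) < 2) stop("need at least 2 samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  c(0, diff(signal) / dt)
}

#' Angular-rate magnitude
#'
#' Euclidean norm of the three gyroscope channels at every sample; the
#' activity signal used both for region-of-motion segmentation and for the
#' heel-off / flat-foot threshold rule.
#'
#' @param gx,gy,gz Numeric vectors of equal length (deg/s).
#' @return Non-negative numeric vector of the same length.
#' @export
gyro_magnitude <- function(gx, gy, gz) {
  if (length(gx) != length(gy) || length(gy) != length(gz)) {
    stop("gyroscope channels must have equal lengths", call. = FALSE)
  }
  sqrt(gx^2 + gy^2 + gz^2)
}

#' Min-max normalization to [0, 1]
#'
#' Rescales a signal so its minimum maps to 0 and its maximum to 1. A
#' constant signal has no range to rescale; it is returned as all zeros with
#' a warning so downstream features stay finite.
#'
#' @param signal Numeric vector, length >= 1.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(signal) {
  if (length(signal) < 1) stop("empty signal", call. = FALSE)
  rng <- range(signal)
  if (rng[1] == rng[2]) {
    warning("constant signal: min-max normalization returns all zeros")
    return(rep(0, length(signal)))
  }
  (signal - rng[1]) / (rng[2] - rng[1])
}

#' Band-limited (Fourier) resampling
#'
#' Resamples a signal to exactly `n` points by zero-padding or truncating its
#' discrete Fourier spectrum, i.e. the interpolation is exact for signals
#' band-limited below the output Nyquist frequency. Conjugate symmetry of the
#' constructed spectrum guarantees a real output for real input (the Nyquist
#' bin is split/folded when either length is even).
#'
#' @param signal Numeric vector, length >= 2.
#' @param n Target length (integer >= 2), default 100.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' fourier_resample(sin(2 * pi * (0:79) / 80), 100)
fourier_resample <- function(signal, n = 100L) {
  m <- length(signal)
  if (m < 2) stop("signal must have length >= 2", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2) stop("target length n must be >= 2", call. = FALSE)
  if (anyNA(signal)) stop("signal contains missing values", call. = FALSE)
  if (n == m) return(signal)
  X <- stats::fft(signal)
  Y <- rep(0 + 0i, n)
  N <- min(m, n)
  nyq <- N %/% 2 + 1L                 # non-negative frequency bins kept
  Y[1:nyq] <- X[1:nyq]
  k <- N - nyq                        # negative frequency bins kept
  if (k > 0) Y[(n - k + 1L):n] <- X[(m - k + 1L):m]
  if (N %% 2 == 0) {
    h <- N %/% 2
    if (n < m) {
      # fold the source's symmetric bin into the output Nyquist bin
      Y[h + 1L] <- Y[h + 1L] + X[m - h + 1L]
    } else {
      # split the source Nyquist bin symmetrically
      Y[h + 1L] <- Y[h + 1L] / 2
      Y[n - h + 1L] <- Y[h + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / m
}

#' Derived signals of a recording
#'
#' Computes, for each of the six inertial channels, its time derivative
#' (first sample 0 by convention), plus the angular-rate magnitude and its
#' standard deviation over the supplied window.
#'
#' @param rec An [imu_recording].
#' @return A list with elements `dax`, `day`, `daz`, `dgx`, `dgy`, `dgz`
#'   (derivatives), `wa` (angular-rate magnitude) and `sigma_wa` (its
#'   population standard deviation).
#' @export
derived_signals <- function(rec) {
  stopifnot(inherits(rec, "imu_recording"))
  d <- lapply(rec[c("ax", "ay", "az", "gx", "gy", "gz")],
              finite_difference, t = rec$t)
  names(d) <- paste0("d", names(d))
  wa <- gyro_magnitude(rec$gx, rec$gy, rec$gz)
  c(d, list(wa = wa, sigma_wa = sqrt(mean((wa - mean(wa))^2))))
}

imu_header <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
event_levels <- c("HO", "TO", "HS", "FF")
side_levels <- c("left", "right")

#' Read / write an IMU recording as CSV
#'
#' The on-disk schema is a UTF-8 CSV with header `t,ax,ay,az,gx,gy,gz`
#' ('.' decimal separator): `t` in seconds, acceleration in m/s^2, angular
#' rate in deg/s. Values survive a write/read round trip to better than
#' 1e-9.
#'
#' @param path File path.
#' @param fs Nominal sampling rate passed to [imu_recording()].
#' @return `read_recording` returns an [imu_recording];
#'   `write_recording` invisibly returns `path`.
#' @export
read_recording <- function(path, fs = 100) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(imu_header, names(df))
  if (length(missing_cols) > 0) {
    stop("recording CSV '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in imu_header) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop("non-numeric value in column '", col, "' at data row ",
           ifelse(is.na(bad), 1L, bad), " of ", path, call. = FALSE)
    }
  }
  if (anyNA(df[imu_header])) {
    bad <- which(!stats::complete.cases(df[imu_header]))[1]
    stop("missing value at data row ", bad, " of ", path, call. = FALSE)
  }
  if (any(diff(df$t) <= 0)) {
    stop("unsorted time axis at data row ", which(diff(df$t) <= 0)[1] + 1L,
         " of ", path, call. = FALSE)
  }
  imu_recording(df$t, df$ax, df$ay, df$az, df$gx, df$gy, df$gz, fs = fs)
}

#' @rdname read_recording
#' @param rec An [imu_recording] to write.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- as.data.frame(rec[imu_header])
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write gait-event annotations as CSV
#'
#' Schema: header `event,side,t,source` with `event` one of HO, TO, HS, FF;
#' `side` left or right; `t` in seconds on the recording clock; `source`
#' identifying the origin (e.g. `gold`, a labeler id, or `detector`).
#'
#' @param path File path.
#' @return `read_annotations` returns a `data.frame` with columns `event`,
#'   `side`, `t`, `source`; `write_annotations` invisibly returns `path`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event", "side", "t", "source")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation CSV '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!df$event %in% event_levels)
  if (length(bad) > 0) {
    stop("unknown event type '", df$event[bad[1]], "' at data row ", bad[1],
         " of ", path, call. = FALSE)
  }
  bad <- which(!df$side %in% side_levels)
  if (length(bad) > 0) {
    stop("unknown side '", df$side[bad[1]], "' at data row ", bad[1],
         " of ", path, call. = FALSE)
  }
  if (!is.numeric(df$t) || anyNA(df$t)) {
    stop("non-numeric timestamp in annotation CSV ", path, call. = FALSE)
  }
  df[need]
}

#' @rdname read_annotations
#' @param ann Annotation `data.frame` (columns `event`, `side`, `t`,
#'   `source`).
#' @export
write_annotations <- function(ann, path) {
  need <- c("event", "side", "t", "source")
  stopifnot(all(need %in% names(ann)))
  utils::write.csv(ann[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
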