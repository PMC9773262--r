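#' Region-of-motion segmentation settings
#'
#' Parameters of the motion detector that cuts a long recording into regions
#' of motion (ROMs), the candidate strides. The activity signal is the
#' angular-rate magnitude, low-pass filtered with a zero-phase Butterworth
#' filter; a sample is active when the filtered activity exceeds a dynamic
#' threshold
#' `tau = max(threshold_floor, threshold_fraction * rolling 95th percentile)`
#' computed over a centered 5 s window. Active runs closer than `merge_gap`
#' are merged, padded by `margin` on both sides and finally gated to
#' `[min_duration, max_duration]`.
#'
#' @param lowpass_cutoff Low-pass cutoff in Hz (default 10; walking energy
#'   sits below 10 Hz).
#' @param lowpass_order Butterworth order (default 4), applied forward and
#'   backward so the effective response is zero-phase.
#' @param threshold_fraction Fraction of the rolling 95th percentile used as
#'   threshold (default 0.2).
#' @param threshold_floor Absolute threshold floor in deg/s (default 30),
#'   rejecting gyroscope noise at rest.
#' @param min_duration,max_duration Admissible ROM duration in seconds
#'   (defaults 0.2 and 3.0, wide enough for slow pathological strides).
#' @param merge_gap Maximum inactive gap (s) bridged between active runs
#'   (default 0.1).
#' @param margin Padding (s) added on each side of a region (default 0.05).
#' @return A list of class `rom_config`.
#' @export
rom_config <- function(lowpass_cutoff = 10, lowpass_order = 4,
                       threshold_fraction = 0.2, threshold_floor = 30,
                       min_duration = 0.2, max_duration = 3.0,
                       merge_gap = 0.1, margin = 0.05) {
  cfg <- list(lowpass_cutoff = lowpass_cutoff, lowpass_order = lowpass_order,
              threshold_fraction = threshold_fraction,
              threshold_floor = threshold_floor,
              min_duration = min_duration, max_duration = max_duration,
              merge_gap = merge_gap, margin = margin)
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1)))) {
    stop("all rom_config values must be positive scalars", call. = FALSE)
  }
  if (min_duration >= max_duration) {
    stop("min_duration must be smaller than max_duration", call. = FALSE)
  }
  structure(cfg, class = "rom_config")
}

#' Extract a region of motion from a recording
#'
#' @param rec An [imu_recording].
#' @param start,end Sample indices (1-based, inclusive).
#' @return An object of class `rom`: list with `start`, `end`, `t` (time
#'   axis), `R` (n x 6 matrix of raw channels ax, ay, az, gx, gy, gz) and
#'   `duration` in seconds.
#' @export
rom_slice <- function(rec, start, end) {
  stopifnot(inherits(rec, "imu_recording"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1 || end > rec$m || end - start + 1L < 2L) {
    stop("invalid ROM bounds [", start, ", ", end, "]", call. = FALSE)
  }
  idx <- start:end
  R <- cbind(ax = rec$ax[idx], ay = rec$ay[idx], az = rec$az[idx],
             gx = rec$gx[idx], gy = rec$gy[idx], gz = rec$gz[idx])
  structure(list(start = start, end = end, t = rec$t[idx], R = R,
                 duration = rec$t[end] - rec$t[start]),
            class = "rom")
}

#' @export
print.rom <- function(x, ...) {
  cat(sprintf("<rom> samples [%d, %d], %.3f s\n", x$start, x$end, x$duration))
  invisible(x)
}

# rolling 95th percentile on a coarse grid, linearly interpolated back to
# every sample; window centered, in samples
rolling_q95 <- function(x, window, step = max(1L, window %/% 10L)) {
  m <- length(x)
  half <- window %/% 2L
  at <- unique(c(seq(1L, m, by = step), m))
  q <- vapply(at, function(i) {
    lo <- max(1L, i - half); hi <- min(m, i + half)
    stats::quantile(x[lo:hi], 0.95, names = FALSE, type = 7)
  }, numeric(1))
  if (length(at) == 1) return(rep(q, m))
  stats::approx(at, q, xout = seq_len(m), rule = 2)$y
}

#' Segment a recording into regions of motion
#'
#' Detects contiguous stretches of sustained foot motion (candidate strides)
#' as described under [rom_config()]. The result is deterministic for a fixed
#' recording and configuration; the returned regions are disjoint and sorted
#' in time.
#'
#' @param rec An [imu_recording].
#' @param cfg A [rom_config()].
#' @return A list of `rom` objects (possibly empty).
#' @export
#' @examples
#' sim <- simulate_recording(n_strides = 3, n_nonstride = 0, seed = 1)
#' length(segment_roms(sim$recording, rom_config()))
segment_roms <- function(rec, cfg = rom_config()) {
  stopifnot(inherits(rec, "imu_recording"), inherits(cfg, "rom_config"))
  wa <- gyro_magnitude(rec$gx, rec$gy, rec$gz)
  fs <- rec$fs
  nyq <- fs / 2
  if (cfg$lowpass_cutoff < nyq) {
    bf <- signal::butter(cfg$lowpass_order, cfg$lowpass_cutoff / nyq,
                         type = "low")
    act <- as.numeric(signal::filtfilt(bf, wa))
  } else {
    act <- wa
  }
  win <- max(3L, as.integer(round(5 * fs)))
  tau <- pmax(cfg$threshold_floor,
              cfg$threshold_fraction * rolling_q95(act, win))
  active <- act > tau
  if (!any(active)) return(list())

  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])

  # merge runs separated by a short inactive gap
  if (nrow(regions) > 1) {
    merged <- regions[1, , drop = FALSE]
    for (i in 2:nrow(regions)) {
      gap <- rec$t[regions[i, 1]] - rec$t[merged[nrow(merged), 2]]
      if (gap < cfg$merge_gap) {
        merged[nrow(merged), 2] <- regions[i, 2]
      } else {
        merged <- rbind(merged, regions[i, ])
      }
    }
    regions <- merged
  }

  # pad by margin, clamp, and keep neighbours disjoint (split mid-gap)
  pad <- as.integer(round(cfg$margin * fs))
  regions[, 1] <- pmax(1L, regions[, 1] - pad)
  regions[, 2] <- pmin(rec$m, regions[, 2] + pad)
  if (nrow(regions) > 1) {
    for (i in 2:nrow(regions)) {
      if (regions[i, 1] <= regions[i - 1, 2]) {
        mid <- (regions[i, 1] + regions[i - 1, 2]) %/% 2L
        regions[i - 1, 2] <- mid
        regions[i, 1] <- mid + 1L
      }
    }
  }

  out <- list()
  for (i in seq_len(nrow(regions))) {
    s <- regions[i, 1]; e <- regions[i, 2]
    if (e - s + 1L < 2L) next
    dur <- rec$t[e] - rec$t[s]
    if (dur >= cfg$min_duration && dur <= cfg$max_duration) {
      out[[length(out) + 1L]] <- rom_slice(rec, s, e)
    }
  }
  out
}

#' Tabulate ROMs
#'
#' @param roms List of `rom` objects as returned by [segment_roms()].
#' @return `data.frame` with columns `rom_id`, `start_idx`, `end_idx`,
#'   `t_start`, `t_end`, `duration`.
#' @export
rom_table <- function(roms) {
  data.frame(
    rom_id = seq_along(roms),
    start_idx = vapply(roms, `[[`, integer(1), "start"),
    end_idx = vapply(roms, `[[`, integer(1), "end"),
    t_start = vapply(roms, function(r) r$t[1], numeric(1)),
    t_end = vapply(roms, function(r) r$t[length(r$t)], numeric(1)),
    duration = vapply(roms, `[[`, numeric(1), "duration")
  )
}
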