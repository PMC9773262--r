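#' Parameters of a simulated stride
#'
#' Waveform parameters for one synthetic stride of a foot-worn IMU. The
#' shapes are sums of Gaussian bumps plus a rate plateau between heel off and
#' flat foot, chosen so that the event-defining signatures of real strides
#' are present by construction: sustained angular rate between HO and FF, a
#' sharp vertical-acceleration impulse at HS (so the derivative of `az` peaks
#' there), and a forward/vertical acceleration crossing at TO.
#'
#' @param duration Stride duration in seconds; `NA` (default) draws it from
#'   N(1.1, 0.1^2), truncated below at 0.7 s.
#' @param swing_fraction Fraction of the stride spent in swing (TO to HS),
#'   default 0.38.
#' @param peak_swing_rate Peak sagittal angular rate in deg/s (default 350).
#' @param plateau_rate Sustained rate magnitude between HO and FF in deg/s
#'   (default 120); this keeps the whole moving phase above the HO/FF
#'   detection threshold.
#' @param hs_impulse Heel-strike acceleration impulse in m/s^2 (default 15).
#' @param pushoff_amp Amplitude of the `ax - az` push-off transition in m/s^2
#'   (default 6).
#' @param noise_sd Additive Gaussian sensor noise, as a fraction of each
#'   channel's range (default 0.02).
#' @param fs Sampling rate in Hz (default 100).
#' @return List of class `stride_params`.
#' @export
stride_params <- function(duration = NA, swing_fraction = 0.38,
                          peak_swing_rate = 350, plateau_rate = 120,
                          hs_impulse = 15, pushoff_amp = 6,
                          noise_sd = 0.02, fs = 100) {
  stopifnot(swing_fraction > 0, swing_fraction < 1, peak_swing_rate > 0,
            plateau_rate > 0, hs_impulse > 0, pushoff_amp > 0,
            noise_sd >= 0, fs > 0)
  if (!is.na(duration) && duration <= 0.3) {
    stop("stride duration must exceed 0.3 s", call. = FALSE)
  }
  structure(list(duration = duration, swing_fraction = swing_fraction,
                 peak_swing_rate = peak_swing_rate,
                 plateau_rate = plateau_rate, hs_impulse = hs_impulse,
                 pushoff_amp = pushoff_amp, noise_sd = noise_sd, fs = fs),
            class = "stride_params")
}

#' Annotation-noise parameters of a simulated labeler
#'
#' @param jitter_sd Gaussian timing jitter in ms (default 10).
#' @param p_miss Probability of dropping each label (default 0.01).
#' @param spurious_rate Expected spurious labels per true label (default
#'   0.01).
#' @param grid Snapping grid in ms (default 10, one sample at 100 Hz).
#' @return List of class `labeler_noise`.
#' @export
labeler_noise <- function(jitter_sd = 10, p_miss = 0.01,
                          spurious_rate = 0.01, grid = 10) {
  stopifnot(jitter_sd >= 0, p_miss >= 0, p_miss <= 1,
            spurious_rate >= 0, spurious_rate <= 1, grid > 0)
  structure(list(jitter_sd = jitter_sd, p_miss = p_miss,
                 spurious_rate = spurious_rate, grid = grid),
            class = "labeler_noise")
}

#' Labeling-protocol constants
#'
#' The arithmetic of the multi-labeler study design: `N_s` strides per side,
#' `N_v` treadmill speeds, `N_h` participants and `N_e` event types give
#' `N_L = 2 * N_s * N_v * N_h * N_e` labels per labeler, and `N` labelers
#' give `N_E = N * N_L` labels in total.
#'
#' @param N_s Strides per side (default 50).
#' @param N_v Walking speeds (default 3).
#' @param N_h Walking participants (default 4).
#' @param N_e Event types (default 4).
#' @param N Labelers (default 5).
#' @return List with the inputs plus the derived `N_L` and `N_E`.
#' @export
#' @examples
#' protocol_constants()$N_L  # 4800
protocol_constants <- function(N_s = 50L, N_v = 3L, N_h = 4L, N_e = 4L,
                               N = 5L) {
  N_L <- 2L * N_s * N_v * N_h * N_e
  list(N_s = N_s, N_v = N_v, N_h = N_h, N_e = N_e, N = N,
       N_L = N_L, N_E = N * N_L)
}

gauss_bump <- function(t, center, width) exp(-0.5 * ((t - center) / width)^2)

# deterministic stride waveform on time axis t (seconds from 0) with event
# indices k (named ho/to/hs/ff); returns an n x 6 matrix without noise
stride_waveform <- function(t, k, p) {
  n <- length(t)
  t_ho <- t[k["ho"]]; t_to <- t[k["to"]]; t_hs <- t[k["hs"]]; t_ff <- t[k["ff"]]
  mid_swing <- (t_to + t_hs) / 2
  w_swing <- (t_hs - t_to) / 4
  gy <- p$peak_swing_rate * gauss_bump(t, mid_swing, w_swing) -
    0.35 * p$peak_swing_rate * gauss_bump(t, t_ho + 0.05, 0.02) -
    0.40 * p$peak_swing_rate * gauss_bump(t, t_hs + 0.03, 0.02)
  plateau <- p$plateau_rate * (t >= t_ho & t <= t_ff)
  gx <- 0.20 * gy
  gz <- 0.30 * gy + plateau
  # vertical acceleration: gravity + slow body oscillation + HS impulse
  az_base <- 9.81 + 0.5 * sin(2 * pi * (t - t[1]) / max(t[n] - t[1], 0.1))
  spike <- numeric(n)
  decay_idx <- k["hs"]:min(n, k["hs"] + 6L)
  spike[decay_idx] <- p$hs_impulse * exp(-(seq_along(decay_idx) - 1) / 2)
  az <- az_base + spike
  # forward acceleration: crosses az halfway between samples k_to - 1, k_to
  t_cross <- t_to - 0.5 / p$fs
  ax <- az_base + p$pushoff_amp * tanh((t - t_cross) / 0.03)
  ay <- 0.8 * sin(2 * pi * 1.3 * (t - t[1])) * gauss_bump(t, mid_swing,
                                                          2 * w_swing)
  cbind(ax = ax, ay = ay, az = az, gx = gx, gy = gy, gz = gz)
}

add_channel_noise <- function(X, noise_sd) {
  if (noise_sd <= 0) return(X)
  for (j in seq_len(ncol(X))) {
    rng <- diff(range(X[, j]))
    if (rng == 0) rng <- 1
    X[, j] <- X[, j] + stats::rnorm(nrow(X), 0, noise_sd * rng)
  }
  X
}

#' Simulate one stride segment with gold events
#'
#' Generates a 6-channel IMU segment whose gait-event signatures are placed
#' by construction: HO at 10% of the segment, TO at 22%, HS at
#' `TO + swing_fraction`, FF at 88%. With `noise_sd = 0` the rule-based
#' detectors recover all four events to within one sample.
#'
#' @param p A [stride_params()].
#' @param seed Optional integer seed for reproducibility.
#' @return List with `rom` (a `rom`-like segment starting at t = 0), `R`
#'   (the n x 6 signal matrix), `t`, `events` (gold `gait_events`),
#'   `event_idx` (named indices) and `params`.
#' @export
#' @examples
#' s <- simulate_stride(stride_params(noise_sd = 0), seed = 1)
#' s$events
simulate_stride <- function(p = stride_params(), seed = NULL) {
  stopifnot(inherits(p, "stride_params"))
  if (!is.null(seed)) set.seed(seed)
  dur <- if (is.na(p$duration)) max(0.7, stats::rnorm(1, 1.1, 0.1)) else
    p$duration
  n <- max(30L, as.integer(round(dur * p$fs)))
  t <- (0:(n - 1)) / p$fs
  k <- c(ho = as.integer(round(0.10 * n)),
         to = as.integer(round(0.22 * n)))
  k["hs"] <- k["to"] + as.integer(round(p$swing_fraction * n))
  k["ff"] <- as.integer(round(0.88 * n))
  k <- pmax(k, 2L)
  if (any(diff(k) <= 0) || k["ff"] >= n) {
    stop("infeasible stride parameters: events out of order", call. = FALSE)
  }
  X <- add_channel_noise(stride_waveform(t, k, p), p$noise_sd)
  rom <- structure(list(start = 1L, end = n, t = t, R = X,
                        duration = t[n] - t[1]),
                   class = "rom")
  events <- structure(list(ho = t[k["ho"]], to = t[k["to"]],
                           hs = t[k["hs"]], ff = t[k["ff"]],
                           indices = k, valid = TRUE, reason = NULL),
                      class = "gait_events")
  list(rom = rom, R = X, t = t, events = events, event_idx = k, params = p)
}

# non-stride motion archetypes: each returns an n x 6 matrix on time axis t.
# They produce enough angular rate to form a ROM but lack the stride's
# event grammar and template shape.
nonstride_segment <- function(t, kind, fs) {
  n <- length(t)
  tt <- t - t[1]
  env <- sin(pi * seq(0, 1, length.out = n))^2  # Hann-like envelope
  base_az <- 9.81
  if (kind == "stomp") {
    spikes <- numeric(n)
    at <- unique(pmax(2L, round(n * c(0.3, 0.7))))
    for (a in at) {
      j <- a:min(n, a + 4L)
      spikes[j] <- spikes[j] + 20 * exp(-(seq_along(j) - 1))
    }
    gy <- 180 * sin(2 * pi * 6 * tt) * env
    cbind(ax = base_az + 2 * sin(2 * pi * 5 * tt) * env,
          ay = 1.5 * sin(2 * pi * 4 * tt) * env,
          az = base_az + spikes,
          gx = 0.6 * gy, gy = gy, gz = 0.4 * gy)
  } else if (kind == "jump") {
    lob <- gauss_bump(tt, max(tt) / 2, max(tt) / 6)
    cbind(ax = base_az - 4 * lob,
          ay = 0.5 * lob,
          az = base_az + 25 * lob - 10 * gauss_bump(tt, max(tt) * 0.8,
                                                    max(tt) / 10),
          gx = 90 * lob, gy = 260 * lob, gz = 120 * lob)
  } else {  # "wiggle": band-limited random motion
    smooth <- function(amp) {
      x <- stats::rnorm(n)
      x <- stats::filter(x, rep(1 / 7, 7), sides = 2)
      x[is.na(x)] <- 0
      amp * as.numeric(x) * env
    }
    cbind(ax = base_az + smooth(4), ay = smooth(3), az = base_az + smooth(5),
          gx = smooth(120), gy = smooth(200), gz = smooth(140))
  }
}

#' Simulate a long recording of strides, non-strides and rest
#'
#' Interleaves stride segments, non-stride motion bursts (stomping, jumping
#' and band-limited random motion) and quiet rest gaps into one continuous
#' recording with a consistent 100 Hz time axis and full gold annotation.
#' Segment order is randomized.
#'
#' @param n_strides,n_nonstride Numbers of stride and non-stride segments.
#' @param p A [stride_params()] shared by all strides (durations are redrawn
#'   per stride when `duration` is `NA`).
#' @param gap_mean,gap_sd Rest-gap duration statistics in seconds.
#' @param seed Optional integer seed.
#' @return List with `recording` (an [imu_recording]), `segments` (a
#'   `data.frame` with `start_idx`, `end_idx`, `label` stride/non-stride and
#'   `kind`), `events` (list of gold `gait_events` on the recording clock,
#'   one per stride) and `event_table` (annotation `data.frame`,
#'   source `gold`).
#' @export
simulate_recording <- function(n_strides, n_nonstride, p = stride_params(),
                               gap_mean = 0.8, gap_sd = 0.15, seed = NULL) {
  stopifnot(n_strides >= 0, n_nonstride >= 0)
  if (!is.null(seed)) set.seed(seed)
  fs <- p$fs
  kinds <- c(rep("stride", n_strides),
             rep(c("stomp", "jump", "wiggle"), length.out = n_nonstride))
  kinds <- if (length(kinds)) sample(kinds) else character(0)

  rest <- function(dur) {
    n <- max(2L, as.integer(round(dur * fs)))
    cbind(ax = stats::rnorm(n, 0, 0.02), ay = stats::rnorm(n, 0, 0.02),
          az = stats::rnorm(n, 9.81, 0.02), gx = stats::rnorm(n, 0, 0.5),
          gy = stats::rnorm(n, 0, 0.5), gz = stats::rnorm(n, 0, 0.5))
  }

  blocks <- list(rest(max(1, stats::rnorm(1, gap_mean, gap_sd))))
  seg_rows <- list()
  events <- list()
  offset <- nrow(blocks[[1]])
  for (kind in kinds) {
    if (kind == "stride") {
      s <- simulate_stride(p)
      X <- s$R
      ev <- s$events
      ev_abs <- ev
      shift <- offset / fs
      for (nm in c("ho", "to", "hs", "ff")) ev_abs[[nm]] <- ev[[nm]] + shift
      ev_abs$indices <- ev$indices + offset
      events[[length(events) + 1L]] <- ev_abs
    } else {
      dur <- max(0.45, stats::rnorm(1, 0.7, 0.12))
      n <- as.integer(round(dur * fs))
      X <- add_channel_noise(nonstride_segment((0:(n - 1)) / fs, kind, fs),
                             p$noise_sd)
    }
    seg_rows[[length(seg_rows) + 1L]] <- data.frame(
      start_idx = offset + 1L, end_idx = offset + nrow(X),
      label = if (kind == "stride") "stride" else "non-stride", kind = kind)
    blocks[[length(blocks) + 1L]] <- X
    offset <- offset + nrow(X)
    gap <- rest(max(0.3, stats::rnorm(1, gap_mean, gap_sd)))
    blocks[[length(blocks) + 1L]] <- gap
    offset <- offset + nrow(gap)
  }
  X <- do.call(rbind, blocks)
  t <- (seq_len(nrow(X)) - 1) / fs
  rec <- imu_recording(t, X[, "ax"], X[, "ay"], X[, "az"],
                       X[, "gx"], X[, "gy"], X[, "gz"], fs = fs)
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(start_idx = integer(0), end_idx = integer(0),
               label = character(0), kind = character(0))
  ev_tab <- do.call(rbind, c(list(
    data.frame(event = character(0), side = character(0), t = numeric(0),
               source = character(0))),
    lapply(events, function(e) data.frame(
      event = c("HO", "TO", "HS", "FF"), side = "left",
      t = c(e$ho, e$to, e$hs, e$ff), source = "gold"))))
  list(recording = rec, segments = segments, events = events,
       event_table = ev_tab)
}

#' Simulate noisy annotations from several labelers
#'
#' Each labeler reproduces the gold event times with i.i.d. Gaussian timing
#' jitter snapped to an annotation grid, misses each label independently with
#' probability `p_miss`, and inserts spurious labels (uniform over the
#' spanned interval) at rate `spurious_rate` per true label.
#'
#' @param gold Strictly increasing vector of gold event times (seconds).
#' @param noise A [labeler_noise()].
#' @param n_labelers Number of labelers (>= 2).
#' @param seed Optional integer seed.
#' @return List of numeric vectors (sorted, in seconds), one per labeler.
#' @export
simulate_labelers <- function(gold, noise = labeler_noise(), n_labelers = 5,
                              seed = NULL) {
  stopifnot(inherits(noise, "labeler_noise"), n_labelers >= 2,
            length(gold) >= 1, !is.unsorted(gold, strictly = TRUE))
  if (!is.null(seed)) set.seed(seed)
  span <- range(gold)
  lapply(seq_len(n_labelers), function(s) {
    x <- gold + stats::rnorm(length(gold), 0, noise$jitter_sd / 1000)
    x <- round(x * 1000 / noise$grid) * noise$grid / 1000
    x <- x[stats::runif(length(x)) >= noise$p_miss]
    n_spur <- stats::rpois(1, noise$spurious_rate * length(gold))
    if (n_spur > 0) {
      x <- c(x, stats::runif(n_spur, span[1], span[2]))
    }
    x <- sort(x)
    # enforce strict increase on the snapping grid
    while (any(diff(x) <= 0)) x <- x[c(TRUE, diff(x) > 0)]
    x
  })
}

#' Simulate one non-stride motion segment
#'
#' Generates a standalone burst of non-walking foot motion. Three archetypes
#' are available: `"stomp"` (sharp repeated vertical impacts with fast rate
#' oscillation), `"jump"` (one large smooth lobe in rate and vertical
#' acceleration) and `"wiggle"` (band-limited random motion). The variety
#' mimics the heterogeneity of real non-stride movement, which is what makes
#' the non-stride class the harder one for the classifier.
#'
#' @param kind `"stomp"`, `"jump"` or `"wiggle"`.
#' @param duration Segment duration in seconds; `NA` (default) draws from
#'   N(0.7, 0.12^2) truncated below at 0.45 s.
#' @param p A [stride_params()] (used for `fs` and `noise_sd`).
#' @param seed Optional integer seed.
#' @return A `rom`-like segment starting at t = 0.
#' @export
simulate_nonstride <- function(kind = c("stomp", "jump", "wiggle"),
                               duration = NA, p = stride_params(),
                               seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  dur <- if (is.na(duration)) max(0.45, stats::rnorm(1, 0.7, 0.12)) else
    duration
  n <- max(20L, as.integer(round(dur * p$fs)))
  t <- (0:(n - 1)) / p$fs
  X <- add_channel_noise(nonstride_segment(t, kind, p$fs), p$noise_sd)
  structure(list(start = 1L, end = n, t = t, R = X, duration = t[n] - t[1]),
            class = "rom")
}

#' Build a labeled synthetic feature corpus
#'
#' Convenience factory for classifier experiments: simulates a balanced set
#' of stride and non-stride segments, builds a stride template from an
#' independent set of simulated strides, and extracts the feature set of
#' every segment.
#'
#' @param n_examples Total number of examples (split as evenly as possible
#'   between the classes, order shuffled).
#' @param p A [stride_params()].
#' @param n_template Number of strides averaged into the template (default
#'   448).
#' @param seed Optional integer seed.
#' @return List with `features` (list of `feature_set`), `labels` (logical,
#'   `TRUE` = stride) and `template`.
#' @export
synthetic_feature_corpus <- function(n_examples, p = stride_params(),
                                     n_template = 448L, seed = NULL) {
  stopifnot(n_examples >= 2)
  if (!is.null(seed)) set.seed(seed)
  tpl_strides <- replicate(n_template, simulate_stride(p)$R, simplify = FALSE)
  template <- build_template(tpl_strides)
  n_stride <- ceiling(n_examples / 2)
  labels <- sample(rep(c(TRUE, FALSE), c(n_stride, n_examples - n_stride)))
  kinds <- c("stomp", "jump", "wiggle")
  features <- lapply(labels, function(is_stride) {
    rom <- if (is_stride) simulate_stride(p)$rom else
      simulate_nonstride(sample(kinds, 1), p = p)
    suppressWarnings(build_feature_set(rom, template))
  })
  list(features = features, labels = labels, template = template)
}
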