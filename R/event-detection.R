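# local maxima of a vector: strictly above the previous sample, at least as
# high as the next (so the first sample of a plateau counts); endpoints are
# not peaks
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

# topographic prominence of the peak at index `at`: height above the higher
# of the two key saddles, i.e. the minima between the peak and the nearest
# taller sample on each side (or the signal end)
peak_prominence <- function(x, at) {
  h <- x[at]
  left <- x[seq_len(at - 1)]
  taller <- which(left > h)
  lmin <- min(left[seq.int(if (length(taller)) max(taller) else 1L,
                           at - 1L)])
  right <- x[(at + 1L):length(x)]
  taller <- which(right > h)
  rmin <- min(right[seq.int(1L, if (length(taller)) min(taller) else
                              length(right))])
  h - max(lmin, rmin)
}

#' Detect heel off and flat foot in a stride region
#'
#' The foot is moving between heel off (HO) and flat foot (FF), so both are
#' read off the angular-rate magnitude `wa`: HO is the first and FF the last
#' sample where `wa[k] / sigma_wa > 0.5`, with `sigma_wa` the (population)
#' standard deviation of `wa` over the region.
#'
#' @param rom A `rom` with at least 10 samples.
#' @return List with `ho` and `ff` (sample indices within the ROM) and
#'   `valid`; when no sample exceeds the threshold, `valid` is `FALSE` with a
#'   `reason`.
#' @export
detect_ho_ff <- function(rom) {
  R <- rom$R
  if (nrow(R) < 10) stop("ROM must have at least 10 samples", call. = FALSE)
  wa <- gyro_magnitude(R[, "gx"], R[, "gy"], R[, "gz"])
  sigma <- sqrt(mean((wa - mean(wa))^2))
  above <- which(wa > 0.5 * sigma)
  if (sigma == 0 || length(above) < 2 || above[1] == above[length(above)]) {
    return(list(ho = NA_integer_, ff = NA_integer_, valid = FALSE,
                reason = "no motion above the rate-magnitude threshold"))
  }
  list(ho = above[1], ff = above[length(above)], valid = TRUE, reason = NULL)
}

#' Detect heel strike after heel off
#'
#' Heel strike (HS) shows as an impulse in the vertical acceleration, so it
#' is located at the most prominent local maximum of the time derivative of
#' `az` strictly after the HO index. Prominence is topographic (height above
#' the higher of the two flanking key saddles); ties go to the earliest
#' index.
#'
#' @param rom A `rom`.
#' @param ho_idx Heel-off sample index within the ROM.
#' @return List with `hs` (sample index) and `valid`/`reason`.
#' @export
detect_hs <- function(rom, ho_idx) {
  daz <- finite_difference(rom$R[, "az"], rom$t)
  peaks <- local_maxima(daz)
  peaks <- peaks[peaks > ho_idx]
  if (length(peaks) == 0) {
    return(list(hs = NA_integer_, valid = FALSE,
                reason = "no local maximum of d(az)/dt after heel off"))
  }
  prom <- vapply(peaks, function(i) peak_prominence(daz, i), numeric(1))
  list(hs = peaks[which.max(prom)], valid = TRUE, reason = NULL)
}

#' Detect toe off between heel off and heel strike
#'
#' Toe off (TO) is where the forward and vertical accelerations coincide,
#' `ax[k] = az[k]`. On sampled data this is read as the first zero crossing
#' of `ax - az` inside the window `(ho_idx, hs_idx)`; the later sample of the
#' crossing pair is returned, and an exact zero counts as the event sample.
#'
#' @param rom A `rom`.
#' @param ho_idx,hs_idx Window bounds (HO and HS sample indices).
#' @return List with `to` (sample index) and `valid`/`reason`.
#' @export
detect_to <- function(rom, ho_idx, hs_idx) {
  if (is.na(ho_idx) || is.na(hs_idx) || ho_idx >= hs_idx) {
    return(list(to = NA_integer_, valid = FALSE,
                reason = "invalid toe-off search window"))
  }
  d <- rom$R[, "ax"] - rom$R[, "az"]
  for (k in (ho_idx + 1L):hs_idx) {
    if (d[k] == 0 || sign(d[k]) * sign(d[k - 1L]) < 0) {
      return(list(to = k, valid = TRUE, reason = NULL))
    }
  }
  list(to = NA_integer_, valid = FALSE,
       reason = "no ax/az crossing between heel off and heel strike")
}

#' Detect all four gait events in a stride region
#'
#' Composes [detect_ho_ff()], [detect_hs()] and [detect_to()] and enforces
#' the stride-phase ordering HO < TO < HS < FF. Timestamps are emitted on the
#' ROM's own time axis; a failure in any sub-detector (or an ordering
#' violation) marks the stride invalid with a reason code instead of raising
#' an error, so one bad stride never aborts a batch.
#'
#' @param rom A `rom` that has been classified as a stride.
#' @return Object of class `gait_events`: list with timestamps `ho`, `to`,
#'   `hs`, `ff` (seconds), `indices` (named integer vector within the ROM),
#'   `valid` and `reason`.
#' @export
#' @examples
#' s <- simulate_stride(stride_params(noise_sd = 0), seed = 2)
#' ev <- detect_events(s$rom)
#' ev$valid
detect_events <- function(rom) {
  invalid <- function(reason) {
    structure(list(ho = NA_real_, to = NA_real_, hs = NA_real_, ff = NA_real_,
                   indices = c(ho = NA_integer_, to = NA_integer_,
                               hs = NA_integer_, ff = NA_integer_),
                   valid = FALSE, reason = reason),
              class = "gait_events")
  }
  hf <- detect_ho_ff(rom)
  if (!hf$valid) return(invalid(hf$reason))
  hs <- detect_hs(rom, hf$ho)
  if (!hs$valid) return(invalid(hs$reason))
  to <- detect_to(rom, hf$ho, hs$hs)
  if (!to$valid) return(invalid(to$reason))
  idx <- c(ho = hf$ho, to = to$to, hs = hs$hs, ff = hf$ff)
  if (any(diff(idx) <= 0)) {
    return(invalid("event ordering HO < TO < HS < FF violated"))
  }
  structure(list(ho = rom$t[idx["ho"]], to = rom$t[idx["to"]],
                 hs = rom$t[idx["hs"]], ff = rom$t[idx["ff"]],
                 indices = idx, valid = TRUE, reason = NULL),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<gait_events> HO %.3f  TO %.3f  HS %.3f  FF %.3f s\n",
                x$ho, x$to, x$hs, x$ff))
  } else {
    cat("<gait_events> invalid:", x$reason, "\n")
  }
  invisible(x)
}
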