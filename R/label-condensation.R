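#' Needleman-Wunsch alignment of two event-timestamp sequences
#'
#' Globally aligns two strictly increasing label sequences by dynamic
#' programming, run as a cost minimization: matching `x_i` with `y_j` costs
#' `|x_i - y_j|`, and every gap (a label of one sequence left unmatched)
#' costs the mean inter-label interval of the *first* sequence,
#' `mean(delta x)` with `delta x_i = x_i - x_(i-1)` and `x_0 = 0`. Traceback
#' ties prefer a match over a gap in `x` over a gap in `y`, making the
#' alignment deterministic.
#'
#' @param x,y Numeric vectors of strictly increasing timestamps (non-empty).
#' @return List of class `nwa_alignment`: `pairs` (2-column matrix of matched
#'   index pairs, increasing in both columns), `gaps_x` and `gaps_y` (indices
#'   left unmatched in each sequence), `cost` (total alignment cost) and
#'   `gap_penalty`.
#' @export
#' @examples
#' nwa_align(c(1, 2, 3), c(1, 2.1, 3))$cost
nwa_align <- function(x, y) {
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("label sequences must be non-empty", call. = FALSE)
  if (any(diff(x) <= 0) || any(diff(y) <= 0)) {
    stop("label sequences must be strictly increasing", call. = FALSE)
  }
  g <- mean(diff(c(0, x)))            # = x[m] / m
  F <- matrix(0, m + 1, n + 1)
  F[, 1] <- g * (0:m)
  F[1, ] <- g * (0:n)
  for (i in 1:m) {
    for (j in 1:n) {
      F[i + 1, j + 1] <- min(F[i, j] + abs(x[i] - y[j]),
                             F[i, j + 1] + g,
                             F[i + 1, j] + g)
    }
  }
  # traceback, tie order: match, gap in x (unmatched x_i), gap in y
  i <- m; j <- n
  pairs <- matrix(integer(0), 0, 2)
  gaps_x <- integer(0); gaps_y <- integer(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        isTRUE(all.equal(F[i + 1, j + 1], F[i, j] + abs(x[i] - y[j])))) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1; j <- j - 1
    } else if (i > 0 &&
               isTRUE(all.equal(F[i + 1, j + 1], F[i, j + 1] + g))) {
      gaps_x <- c(i, gaps_x)
      i <- i - 1
    } else {
      gaps_y <- c(j, gaps_y)
      j <- j - 1
    }
  }
  colnames(pairs) <- c("i", "j")
  structure(list(pairs = pairs, gaps_x = gaps_x, gaps_y = gaps_y,
                 cost = F[m + 1, n + 1], gap_penalty = g),
            class = "nwa_alignment")
}

#' Condense labels from several annotators into a matched matrix
#'
#' Runs [nwa_align()] over every unordered pair of labelers (the
#' lower-indexed labeler is always the first argument, fixing the asymmetric
#' gap penalty) and, after each round, discards every label that was gapped
#' in at least one pairwise alignment. Rounds repeat until no label is
#' removed; at that point all sequences have equal length and positional
#' correspondence, and the matched label matrix `L` (rows = events, columns =
#' labelers), its row means `lbar` (the consensus labels), the error matrix
#' `D[, i] = lbar - L[, i]` and the limit of agreement are assembled.
#'
#' @param seqs List of at least two strictly increasing numeric vectors
#'   (label timestamps; any single time unit).
#' @return Object of class `label_matrix`: `L`, `lbar`, `D`, `loa` (95th
#'   percentile of `|D|`, linear interpolation), `M` (matched labels per
#'   labeler), `N` (labelers), `n_removed`, and `rounds`.
#' @export
condense_labels <- function(seqs) {
  N <- length(seqs)
  if (N < 2) stop("need at least two labelers", call. = FALSE)
  total_in <- sum(lengths(seqs))
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    drop <- lapply(seqs, function(s) logical(length(s)))
    for (a in 1:(N - 1)) {
      for (b in (a + 1):N) {
        al <- nwa_align(seqs[[a]], seqs[[b]])
        drop[[a]][al$gaps_x] <- TRUE
        drop[[b]][al$gaps_y] <- TRUE
      }
    }
    n_drop <- sum(vapply(drop, sum, numeric(1)))
    if (n_drop == 0) break
    seqs <- Map(function(s, d) s[!d], seqs, drop)
    if (any(lengths(seqs) == 0)) {
      stop("label condensation emptied a labeler's sequence", call. = FALSE)
    }
  }
  M <- unique(lengths(seqs))
  if (length(M) != 1) {
    stop("condensation converged with unequal sequence lengths; ",
         "input sequences are inconsistent", call. = FALSE)
  }
  L <- do.call(cbind, seqs)
  res <- compute_loa(L)
  structure(c(res, list(M = M, N = N, n_removed = total_in - M * N,
                        rounds = rounds)),
            class = "label_matrix")
}

#' Limit of agreement of a matched label matrix
#'
#' Given the matrix `L` of matched labels (one row per event instance, one
#' column per labeler), computes the consensus labels `lbar` (row means), the
#' error matrix `D[, i] = lbar - L[, i]`, and the limit of agreement: the
#' 95th percentile (linear-interpolation quantile) of the absolute entries of
#' `D`.
#'
#' @param L Numeric matrix, `M x N` with `N >= 2`.
#' @return List with `L`, `lbar`, `D` and `loa` (same time unit as `L`).
#' @export
#' @examples
#' compute_loa(cbind(c(0, 100), c(10, 110)))$loa
compute_loa <- function(L) {
  L <- as.matrix(L)
  if (nrow(L) < 1 || ncol(L) < 2) {
    stop("L must have at least 1 row and 2 columns", call. = FALSE)
  }
  lbar <- rowMeans(L)
  D <- lbar - L
  list(L = L, lbar = lbar, D = D,
       loa = stats::quantile(abs(D), 0.95, names = FALSE, type = 7))
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf(
    "<label_matrix> %d matched labels x %d labelers, %d removed (%.2f%%), LOA %.3g\n",
    x$M, x$N, x$n_removed,
    100 * x$n_removed / (x$M * x$N + x$n_removed), x$loa))
  invisible(x)
}

#' Error metrics of detected event times against reference times
#'
#' Pairs the two timestamp sequences with [nwa_align()] (reference first, so
#' the gap penalty is its mean inter-label interval) and summarises the
#' matched errors `e = truth - detected` with the mean error, its standard
#' deviation, the mean absolute error, the root mean squared error and the
#' 95th-percentile absolute error (limit of agreement). Inputs are in
#' seconds; metrics are reported in milliseconds.
#'
#' @param detected,truth Strictly increasing timestamp vectors in seconds.
#' @return List of class `error_metrics` with `mean`, `std`, `mae`, `rmse`,
#'   `loa95` (all ms) and `n_samples`.
#' @export
error_metrics <- function(detected, truth) {
  if (length(detected) == 0 || length(truth) == 0) {
    stop("detected and truth must be non-empty", call. = FALSE)
  }
  al <- nwa_align(truth, detected)
  if (nrow(al$pairs) == 0) {
    stop("no events could be matched between detected and truth", call. = FALSE)
  }
  e <- (truth[al$pairs[, 1]] - detected[al$pairs[, 2]]) * 1000
  structure(list(mean = mean(e),
                 std = stats::sd(e),
                 mae = mean(abs(e)),
                 rmse = sqrt(mean(e^2)),
                 loa95 = stats::quantile(abs(e), 0.95, names = FALSE, type = 7),
                 n_samples = length(e)),
            class = "error_metrics")
}

#' @export
print.error_metrics <- function(x, ...) {
  cat(sprintf(
    "<error_metrics> mean %.1f  std %.1f  MAE %.1f  RMSE %.1f  LOA %.1f ms (n = %d)\n",
    x$mean, x$std, x$mae, x$rmse, x$loa95, x$n_samples))
  invisible(x)
}
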