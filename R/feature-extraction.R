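#' Build a stride template from example strides
#'
#' Averages a collection of stride segments into a 100 x 6 reference matrix
#' `T`: each channel of each stride is band-limited resampled to 100 points
#' first, then the strides are averaged columnwise. The template acts as the
#' reference that candidate regions are compared against via dynamic time
#' warping and correlation.
#'
#' @param strides A list of n x 6 numeric matrices (columns ax, ay, az, gx,
#'   gy, gz) or `rom` objects.
#' @return Object of class `stride_template`: list with `T` (100 x 6 matrix)
#'   and `n_strides`.
#' @export
#' @examples
#' s <- simulate_stride(seed = 1)
#' tpl <- build_template(list(s$R, s$R))
#' dim(tpl$T)
build_template <- function(strides) {
  if (length(strides) < 1) stop("need at least one stride", call. = FALSE)
  mats <- lapply(strides, function(s) {
    if (inherits(s, "rom")) s <- s$R
    s <- as.matrix(s)
    if (ncol(s) != 6 || nrow(s) < 2) {
      stop("each stride must be an n x 6 matrix with n >= 2", call. = FALSE)
    }
    apply(s, 2, fourier_resample, n = 100L)
  })
  acc <- Reduce(`+`, mats) / length(mats)
  colnames(acc) <- c("ax", "ay", "az", "gx", "gy", "gz")
  structure(list(T = acc, n_strides = length(strides)),
            class = "stride_template")
}

#' Read / write a stride template as CSV
#'
#' On-disk schema: 100 rows x 6 columns with header `ax,ay,az,gx,gy,gz`.
#'
#' @param path File path.
#' @return `read_template` returns a `stride_template`.
#' @export
read_template <- function(path) {
  df <- utils::read.csv(path)
  need <- c("ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df)) || nrow(df) != 100) {
    stop("template CSV must have 100 rows and columns ax,ay,az,gx,gy,gz",
         call. = FALSE)
  }
  TT <- as.matrix(df[need])
  if (anyNA(TT)) stop("template contains missing values", call. = FALSE)
  structure(list(T = TT, n_strides = NA_integer_), class = "stride_template")
}

#' @rdname read_template
#' @param template A `stride_template` to write.
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "stride_template"))
  utils::write.csv(as.data.frame(template$T), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Dynamic time warping against a reference
#'
#' Aligns a query sequence onto a reference with the classic unconstrained
#' step set \{(1,1), (1,0), (0,1)\}, absolute-difference local cost and
#' anchored endpoints. The accumulated cost is normalized by the path length
#' (the number of cells on the optimal path). The query is also projected
#' onto the reference grid: where several query samples map to one reference
#' index their mean is taken, so the warped query always has the reference's
#' length (needed for a well-defined correlation afterwards).
#'
#' @param query Numeric vector, length >= 2, finite.
#' @param reference Numeric vector, length >= 2, finite.
#' @return List with `warped` (query aligned to the reference grid),
#'   `distance` (normalized DTW distance), `cost` (unnormalized accumulated
#'   cost) and `path` (2-column matrix of aligned index pairs).
#' @export
#' @examples
#' dtw_align(c(0, 1, 2, 1, 0), c(0, 1, 1, 2, 1, 0))$distance
dtw_align <- function(query, reference) {
  if (length(query) < 2 || length(reference) < 2) {
    stop("both sequences must have length >= 2", call. = FALSE)
  }
  if (anyNA(query) || anyNA(reference) ||
      any(!is.finite(query)) || any(!is.finite(reference))) {
    stop("sequences must be finite with no missing values", call. = FALSE)
  }
  res <- .dtw_core(as.numeric(query), as.numeric(reference))
  path_len <- length(res$i)
  warped <- vapply(split(query[res$i], res$j), mean, numeric(1))
  # split() orders by reference index, which is already 1..m contiguous
  list(warped = as.numeric(warped),
       distance = res$cost / path_len,
       cost = res$cost,
       path = cbind(query = res$i, reference = res$j))
}

#' Rescale a correlation p-value
#'
#' Maps a p-value to `0.1 * log(p)` (natural log). The p-value is clamped
#' below at machine epsilon before taking the log so the feature stays
#' finite.
#'
#' @param p Probability in \[0, 1\].
#' @return Non-positive finite scalar.
#' @export
rescale_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("p must be a probability in [0, 1]", call. = FALSE)
  }
  0.1 * log(max(p, .Machine$double.eps))
}

#' Extract classifier features from a region of motion
#'
#' Builds the feature set `F = {M, c}` of a candidate stride: `M` is the
#' 100 x 6 image obtained by min-max normalizing each raw channel and
#' band-limited resampling it to 100 samples; `c` is the 19-element score
#' vector `(dt, 1/d_1, r_1, p^_1, ..., 1/d_6, r_6, p^_6)` where, per channel,
#' `d_i` is the normalized DTW distance of the raw channel against the
#' template column, `r_i` and `p_i` are the Pearson correlation (and its
#' two-sided p-value, t distribution with 98 degrees of freedom) between the
#' warped channel and the template column, and `p^_i = 0.1 log(p_i)`. `d_i`
#' is floored at 1e-6 before inversion so a perfect match yields a large but
#' finite feature. A constant (degenerate) channel gets `r_i = 0`, `p_i = 1`
#' with a warning.
#'
#' @param rom A `rom` (or any list with elements `R`, an n x 6 matrix, and
#'   `duration`).
#' @param template A `stride_template`.
#' @return Object of class `feature_set`: list with `M` (100 x 6, entries in
#'   \[0, 1\]), `c` (length 19), and the per-channel vectors `d`, `r`, `p`.
#' @export
build_feature_set <- function(rom, template) {
  stopifnot(inherits(template, "stride_template"))
  R <- rom$R
  if (is.null(R) || ncol(R) != 6 || nrow(R) < 2) {
    stop("rom must carry an n x 6 signal block with n >= 2", call. = FALSE)
  }
  M <- apply(R, 2, function(ch) fourier_resample(minmax_normalize(ch), 100L))
  M <- pmin(pmax(M, 0), 1)  # Fourier ringing can leave [0,1] marginally
  d <- r <- p <- numeric(6)
  for (i in 1:6) {
    al <- dtw_align(R[, i], template$T[, i])
    d[i] <- al$distance
    if (stats::sd(al$warped) == 0 || stats::sd(template$T[, i]) == 0) {
      warning("degenerate constant channel ", i,
              ": correlation set to 0, p-value to 1")
      r[i] <- 0; p[i] <- 1
    } else {
      ct <- stats::cor.test(al$warped, template$T[, i])
      r[i] <- unname(ct$estimate); p[i] <- ct$p.value
    }
  }
  inv_d <- 1 / pmax(d, 1e-6)
  phat <- vapply(p, rescale_p, numeric(1))
  score <- c(rom$duration, rbind(inv_d, r, phat))
  stopifnot(length(score) == 19L)
  structure(list(M = M, c = score, d = d, r = r, p = p),
            class = "feature_set")
}
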