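# Independent brute-force oracles used to pin down the dynamic programs and
# metrics. These deliberately share no code with the package: plain
# enumeration and loops only.

# Minimum-cost DTW by exhaustive path enumeration. A path is a sequence of
# cells from (1,1) to (n,m) moving by (1,0), (0,1) or (1,1); its cost is the
# sum of |x_i - y_j| over every visited cell.
brute_dtw <- function(x, y) {
  n <- length(x); m <- length(y)
  best <- Inf
  lens <- integer(0)   # node counts of all cost-optimal paths
  recurse <- function(i, j, acc, steps) {
    acc <- acc + abs(x[i] - y[j])
    if (acc > best) return(invisible())
    if (i == n && j == m) {
      if (acc < best) {
        best <<- acc
        lens <<- steps
      } else {
        lens <<- unique(c(lens, steps))
      }
      return(invisible())
    }
    if (i < n) recurse(i + 1, j, acc, steps + 1L)
    if (j < m) recurse(i, j + 1, acc, steps + 1L)
    if (i < n && j < m) recurse(i + 1, j + 1, acc, steps + 1L)
  }
  recurse(1, 1, 0, 1L)
  list(cost = best, lengths = lens)
}

brute_dtw_cost <- function(x, y) brute_dtw(x, y)$cost

# Minimum-cost global alignment by exhaustive enumeration: every label is
# either matched (cost |x_i - y_j|, order preserved) or gapped (cost g, the
# mean inter-label interval of x with x_0 = 0).
brute_nwa_cost <- function(x, y) {
  g <- mean(diff(c(0, x)))
  recurse <- function(i, j) {
    if (i > length(x) && j > length(y)) return(0)
    if (i > length(x)) return((length(y) - j + 1) * g)
    if (j > length(y)) return((length(x) - i + 1) * g)
    min(abs(x[i] - y[j]) + recurse(i + 1, j + 1),
        g + recurse(i + 1, j),
        g + recurse(i, j + 1))
  }
  recurse(1, 1)
}

# Loop-based error metrics on a vector of errors in ms.
brute_metrics <- function(e) {
  s <- 0; sa <- 0; sq <- 0
  for (v in e) {
    s <- s + v; sa <- sa + abs(v); sq <- sq + v^2
  }
  n <- length(e)
  list(mean = s / n, mae = sa / n, rmse = sqrt(sq / n))
}

# Topographic prominence by a full scan: walk out from the peak to the
# nearest strictly taller sample on each side; the prominence is the peak
# height minus the higher of the two interval minima.
brute_prominence <- function(x, at) {
  h <- x[at]
  lmin <- h
  for (i in seq(at - 1, 1)) {
    if (x[i] > h) break
    if (x[i] < lmin) lmin <- x[i]
  }
  rmin <- h
  for (i in seq(at + 1, length(x))) {
    if (x[i] > h) break
    if (x[i] < rmin) rmin <- x[i]
  }
  h - max(lmin, rmin)
}

# a small deterministic feature corpus shared by classifier tests
tiny_corpus <- function(n = 60, seed = 42) {
  synthetic_feature_corpus(n, seed = seed, n_template = 30)
}
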