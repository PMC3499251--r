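# Shared numeric helpers.  All genomic coordinates in this package are
# 0-based half-open; R vector indexing is 1-based, so boundary conversions
# happen exactly once, inside the slice/extract helpers.

#' Centered running mean with partial windows at the edges
#'
#' `smoothed[i]` is the mean of `x[max(1, i-half) : min(n, i+half)]`; the
#' divisor shrinks near the vector ends so no positions are lost.
#'
#' @param x numeric vector.
#' @param half half-width of the window in positions (full width `2*half+1`).
#' @return numeric vector the same length as `x`.
#' @export
running_mean <- function(x, half) {
  n <- length(x)
  if (half <= 0L || n == 0L) return(as.numeric(x))
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered running sum over a fixed window, zero-padded beyond the ends.
running_sum <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  cs[hi + 1L] - cs[lo]
}

# Cross-correlation cc[o] = sum_i x[o + i - 1] * w[i], o = 1..(n - m + 1).
# FFT-based via stats::convolve; numerically ~1e-10 relative, which is fine
# for likelihood surfaces (exact-arithmetic checks use direct sums).
cross_correlate <- function(x, w) {
  n <- length(x); m <- length(w)
  if (m > n) stop("weight vector longer than signal")
  if (as.double(n) * m < 2e5) {
    # direct evaluation for small problems (exact, no FFT round-off)
    vapply(seq_len(n - m + 1L),
           function(o) sum(x[o:(o + m - 1L)] * w), numeric(1))
  } else {
    # pad to a 2-3-5-smooth length: mixed-radix FFT stays O(N log N)
    N <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
    X <- fft(c(x, numeric(N - n)))
    Wf <- fft(c(rev(w), numeric(N - m)))
    conv <- Re(fft(X * Wf, inverse = TRUE)) / N
    conv[m:n]
  }
}

# all 4^k DNA k-mers in lexicographic order
all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reorder for lexicographic
  sort(apply(as.matrix(grid), 1L, paste0, collapse = ""))
}

# reverse complement of a character vector of DNA strings
revcomp <- function(s) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# argmax with the package-wide tie-break: among maximal entries choose the
# one closest to `center` (index units), then the leftmost.
argmax_tiebreak <- function(x, center) {
  mx <- max(x)
  cand <- which(x == mx)
  if (length(cand) == 1L) return(cand)
  d <- abs(cand - center)
  cand <- cand[d == min(d)]
  cand[1L]
}

# sample lengths from a truncated normal by vectorized rejection
rtruncnorm_int <- function(n, mean, sd, lower, upper) {
  out <- integer(0)
  while (length(out) < n) {
    draw <- as.integer(round(rnorm(2L * (n - length(out)) + 16L, mean, sd)))
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
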