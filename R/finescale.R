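# Rotational-positioning diagnostics: dinucleotide and DNase nick profiles
# across 147-bp nucleosome cores, the midpoint-phasing cross-correlogram,
# and the spectral helpers used to quantify 10-bp periodicity.

#' Dinucleotide frequency profile across 147-bp fragments
#'
#' Counts each of the 16 dinucleotides at every offset along the fragment
#' (146 dinucleotide starts for a 147-bp fragment), on the forward genomic
#' strand of the fragment interval.  Offsets are dyad-relative: the dyad is
#' offset 0 and dinucleotide starts run -73..+72.  Positions containing
#' ambiguous bases are skipped.
#'
#' @param fragments a [fragment_set()]; every fragment must be exactly
#'   147 bp.
#' @param genome named character vector of chromosome sequences.
#' @param expected optional `dinuc_profile` (typically from bias-matched
#'   simulated fragments); when supplied a log2 observed/expected matrix is
#'   attached.
#' @param eps floor for the log-ratio.
#' @return object of class `dinuc_profile`: list with `counts` (16 x 146),
#'   `freq` (per-offset frequencies summing to 1), `offsets`, and `log2`
#'   when `expected` was given.
#' @export
dinucleotide_profile <- function(fragments, genome, expected = NULL,
                                 eps = 1e-6) {
  len <- fragment_lengths(fragments)
  if (any(len != 147L)) stop("all fragments must be exactly 147 bp")
  dinucs <- sort(as.vector(outer(c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T"), paste0)))
  seqs <- character(nrow(fragments))
  for (ch in unique(fragments$chrom)) {
    sel <- fragments$chrom == ch
    seqs[sel] <- substring(genome[[ch]], fragments$start[sel] + 1L,
                           fragments$end[sel])
  }
  counts <- matrix(0, nrow = 16L, ncol = 146L,
                   dimnames = list(dinucs, NULL))
  for (j in seq_len(146L)) {
    d <- substr(seqs, j, j + 1L)
    tab <- table(factor(d, levels = dinucs))
    counts[, j] <- as.numeric(tab)
  }
  colsum <- colSums(counts)
  freq <- sweep(counts, 2L, pmax(colsum, 1), "/")
  out <- list(counts = counts, freq = freq,
              offsets = seq_len(146L) - 74L)  # dinucleotide start vs dyad
  if (!is.null(expected))
    out$log2 <- normalize_by_expected(freq, expected$freq, eps)
  class(out) <- "dinuc_profile"
  out
}

#' @export
print.dinuc_profile <- function(x, ...) {
  cat(sprintf("<dinuc_profile> 16 x %d, %0.0f fragments\n",
              ncol(x$counts), max(colSums(x$counts))))
  invisible(x)
}

#' Stranded DNase nick profile around fragment dyads
#'
#' Mean nick count per fragment, by strand, as a function of the offset
#' from each fragment midpoint.  The window extends `window` bp either side
#' of the dyad (beyond the 147-bp core into the linkers).  When a
#' `dnase_bias` table is supplied, an expected-rate track is computed from
#' the genome sequence and the profile of expected rates is accumulated the
#' same way; the result then carries a bias-normalised log2 version.
#'
#' @param fragments a [fragment_set()] of 147-bp fragments.
#' @param nicks data.frame with `chrom`, `pos`, `strand`, or a list
#'   `list(plus = track, minus = track)` of per-strand [midpoint_track()]s.
#' @param genome genome sequences (needed only when `dnase_bias` is given).
#' @param dnase_bias optional `dnase_bias` table.
#' @param window half-width of the profile in bp (default 200).
#' @param eps floor for the log-ratio.
#' @return object of class `stranded_cut_profile`: `offsets`, `plus`,
#'   `minus` (mean counts per fragment), and `plus_log2`/`minus_log2` when
#'   bias-normalised.
#' @export
dnase_cut_profile <- function(fragments, nicks, genome = NULL,
                              dnase_bias = NULL, window = 200, eps = 1e-6) {
  stopifnot(window >= 147)
  mids <- fragment_midpoints(fragments)
  offs <- (-window):window
  plus <- numeric(length(offs)); minus <- plus
  eplus <- plus; eminus <- plus
  nick_tr <- .nicks_as_tracks(nicks)
  use_bias <- !is.null(dnase_bias)
  if (use_bias && is.null(genome))
    stop("bias normalisation requires the genome")
  for (ch in unique(fragments$chrom)) {
    m <- mids[fragments$chrom == ch]
    for (side in c("plus", "minus")) {
      v <- nick_tr[[side]]$counts[[ch]]
      if (is.null(v)) next
      prof <- .accumulate_offsets(v, m, window)
      if (side == "plus") plus <- plus + prof else minus <- minus + prof
    }
    if (use_bias) {
      ev <- .expected_nick_track(genome, ch, dnase_bias)
      eplus <- eplus + .accumulate_offsets(ev$plus, m, window)
      eminus <- eminus + .accumulate_offsets(ev$minus, m, window)
    }
  }
  nfrag <- length(mids)
  if (sum(plus) + sum(minus) == 0) stop("no nicks in any fragment window")
  out <- list(offsets = offs, plus = plus / nfrag, minus = minus / nfrag)
  if (use_bias) {
    out$plus_log2 <- normalize_by_expected(plus, eplus, eps)
    out$minus_log2 <- normalize_by_expected(minus, eminus, eps)
  }
  class(out) <- "stranded_cut_profile"
  out
}

# sum v[m + o] over anchor positions m (0-based), for o in -window..window
.accumulate_offsets <- function(v, anchors, window) {
  n <- length(v)
  out <- numeric(2L * window + 1L)
  # pad so every anchor window is in range, then accumulate by shifting
  pad <- c(numeric(window), v, numeric(window))
  idx <- anchors + 1L + window  # index of offset 0 in padded vector
  keep <- anchors >= 0L & anchors < n
  idx <- idx[keep]
  if (!length(idx)) return(out)
  for (o in -window:window)
    out[o + window + 1L] <- sum(pad[idx + o])
  out
}

.nicks_as_tracks <- function(nicks) {
  if (is.list(nicks) && !is.data.frame(nicks) &&
      all(c("plus", "minus") %in% names(nicks)))
    return(nicks)
  stopifnot(is.data.frame(nicks))
  sl <- tapply(nicks$pos, nicks$chrom, max)
  sl <- stats::setNames(as.integer(sl + 10L), names(sl))
  mk <- function(strand) {
    counts <- lapply(stats::setNames(names(sl), names(sl)), function(ch) {
      p <- nicks$pos[nicks$chrom == ch & nicks$strand == strand]
      tabulate(p + 1L, nbins = sl[[ch]])
    })
    midpoint_track(counts)
  }
  list(plus = mk("+"), minus = mk("-"))
}

# per-base expected nick rate for one chromosome, both strands
.expected_nick_track <- function(genome, chrom, dnase_bias) {
  s <- genome[[chrom]]
  n <- nchar(s)
  pos <- seq_len(n)
  # plus-strand context at 0-based p: 1-based p-2 .. p+3
  rate <- dnase_bias$rate
  ctx_p <- substring(s, pos - 3L, pos + 2L)
  ctx_m <- revcomp_fast(substring(s, pos - 2L, pos + 3L))
  rp <- unname(rate[ctx_p]); rp[is.na(rp)] <- 0
  rm_ <- unname(rate[ctx_m]); rm_[is.na(rm_)] <- 0
  list(plus = rp, minus = rm_)
}

# vectorised reverse complement for equal-length 6-mers (or any fixed k)
revcomp_fast <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  k <- nchar(comp[1L])
  out <- comp
  for (j in seq_len(k)) {
    substr(out, j, j) <- substr(comp, k - j + 1L, k - j + 1L)
  }
  out
}

#' Midpoint phasing cross-correlogram
#'
#' Distribution of test-set midpoints around ascertainment-set midpoints:
#' for every ascertained midpoint (weighted by its count) the test counts
#' at offsets `-max_offset..max_offset` are accumulated.  The two tracks
#' must come from disjoint library sets (ascertainment-bias guard).  When
#' an `expected` track from simulated fragments is supplied, the same
#' statistic is computed against it and a ratio profile is attached.
#'
#' @param ascertain,test [midpoint_track()]s built from disjoint libraries.
#' @param expected optional [midpoint_track()] of simulated midpoints.
#' @param max_offset maximum offset in bp (default 100).
#' @return object of class `phasing_histogram`: `offsets`, `counts`, and
#'   `normalized` (observed/expected ratio, rescaled to mean 1) when
#'   `expected` was given.
#' @export
midpoint_phasing <- function(ascertain, test, expected = NULL,
                             max_offset = 100) {
  if (length(intersect(ascertain$libraries, test$libraries)) > 0)
    stop("ascertain and test tracks share libraries; ",
         "phasing requires disjoint library sets")
  counts <- .phasing_xcorr(ascertain, test, max_offset)
  out <- list(offsets = (-max_offset):max_offset, counts = counts)
  if (!is.null(expected)) {
    e <- .phasing_xcorr(ascertain, expected, max_offset)
    r <- (counts / sum(counts)) / pmax(e / sum(e), 1e-12)
    out$normalized <- r
  }
  class(out) <- "phasing_histogram"
  out
}

.phasing_xcorr <- function(a, b, max_offset) {
  out <- numeric(2L * max_offset + 1L)
  for (ch in names(a$counts)) {
    va <- a$counts[[ch]]
    vb <- b$counts[[ch]]
    if (is.null(vb)) next
    n <- max(length(va), length(vb))
    length(va) <- n; length(vb) <- n
    va[is.na(va)] <- 0; vb[is.na(vb)] <- 0
    anchors <- which(va > 0) - 1L
    w <- va[anchors + 1L]
    pad <- c(numeric(max_offset), vb, numeric(max_offset))
    idx <- anchors + 1L + max_offset
    for (o in -max_offset:max_offset)
      out[o + max_offset + 1L] <- out[o + max_offset + 1L] +
        sum(w * pad[idx + o])
  }
  out
}

#' Dominant periodicity of a profile
#'
#' Mean-centred Fourier analysis.  The best period is located on a
#' zero-padded spectrum (default 4096 points, giving sub-bp period
#' resolution) within the requested band; the power fraction is the share
#' of total non-DC power (unpadded periodogram) that falls inside the band.
#' A pure in-band tone therefore has power fraction near 1, and white noise
#' near the band's bandwidth share.
#'
#' @param profile numeric vector (length at least 3x the upper band edge).
#' @param period_band `c(lo, hi)` period band in bp (default 8-12).
#' @param pad zero-padded FFT length for period refinement.
#' @return list with `best_period` (bp; NA for a constant vector) and
#'   `power_fraction` in `[0, 1]`.
#' @export
periodicity_power <- function(profile, period_band = c(8, 12), pad = 4096) {
  stopifnot(all(is.finite(profile)), length(period_band) == 2L)
  lo <- period_band[1L]; hi <- period_band[2L]
  n <- length(profile)
  if (n < 3 * hi) stop("profile too short for the requested band")
  x <- profile - mean(profile)
  if (all(x == 0)) return(list(best_period = NA_real_, power_fraction = 0))
  # unpadded periodogram for the band power share
  p <- Mod(fft(x))^2
  nf <- floor(n / 2)
  f <- (1:nf) / n
  pw <- p[2:(nf + 1L)]
  inband <- f >= 1 / hi & f <= 1 / lo
  power_fraction <- sum(pw[inband]) / sum(pw)
  # zero-padded spectrum for sub-bp period location
  N <- max(pad, 2^ceiling(log2(n)))
  xp <- c(x, numeric(N - n))
  pp <- Mod(fft(xp))^2
  fN <- (1:floor(N / 2)) / N
  ppw <- pp[2:(floor(N / 2) + 1L)]
  sel <- fN >= 1 / hi & fN <= 1 / lo
  best_period <- 1 / fN[sel][which.max(ppw[sel])]
  list(best_period = best_period, power_fraction = power_fraction)
}

#' Relative spectral amplitude of a periodicity band
#'
#' The amplitude of the best-fitting sinusoid with period inside the band,
#' expressed relative to the profile mean (`2 |X(f*)| / (n * mean)`), so
#' it is invariant to uniform count scaling and grows with the
#' peak-to-trough contrast of a phased profile.  Unlike the power
#' *fraction*, it is insensitive to how much power sits in harmonics and
#' is therefore the right comparator for phasing strength.
#'
#' @param profile numeric vector of non-negative values.
#' @param period_band `c(lo, hi)` period band in bp.
#' @param pad zero-padded FFT length.
#' @return relative amplitude (0 for a flat or empty profile).
#' @export
phasing_amplitude <- function(profile, period_band, pad = 8192) {
  n <- length(profile)
  mu <- mean(profile)
  if (mu <= 0) return(0)
  x <- profile - mu
  N <- max(pad, 2^ceiling(log2(n)))
  sp <- Mod(fft(c(x, numeric(N - n))))
  fN <- (1:floor(N / 2)) / N
  sel <- fN >= 1 / period_band[2L] & fN <= 1 / period_band[1L]
  if (!any(sel)) return(0)
  2 * max(sp[2:(floor(N / 2) + 1L)][sel]) / (n * mu)
}

#' Phase lag between two periodic profiles
#'
#' Estimates the lag (in bp) between two profiles sharing a dominant
#' periodicity, from the phase of the cross-spectrum at the dominant
#' in-band frequency of their sum.  Positive lag means the second profile
#' is shifted downstream of the first.
#'
#' @param a,b numeric vectors of equal length.
#' @param period_band period band searched for the common tone.
#' @param pad zero-padded FFT length.
#' @return list with `lag` (bp) and `period` (bp).
#' @export
estimate_strand_lag <- function(a, b, period_band = c(8, 12), pad = 4096) {
  stopifnot(length(a) == length(b))
  per <- periodicity_power(a + b, period_band, pad)$best_period
  omega <- 2 * pi / per
  t <- seq_along(a) - 1
  za <- sum((a - mean(a)) * exp(-1i * omega * t))
  zb <- sum((b - mean(b)) * exp(-1i * omega * t))
  # b(t) = a(t - lag)  =>  Arg(zb conj(za)) = -omega * lag
  dphi <- Arg(zb * Conj(za))
  lag <- -dphi / omega
  # fold into (-period/2, period/2]
  lag <- lag - per * round(lag / per)
  list(lag = lag, period = per)
}
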