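# Translational positioning: region sampling, the positioning score,
# empirical-null calibration (pi0 / q-values), score classes, per-bp score
# tracks with nucleosome peak calling, and nucleosome repeat length
# estimation from aggregate midpoint plots.

#' Sample mappable regions avoiding a blacklist
#'
#' Uniformly samples fixed-length windows whose mappable base fraction
#' meets `min_mappable` and which do not intersect any blacklist interval.
#'
#' @param seqlengths named integer vector of chromosome lengths.
#' @param n number of regions requested.
#' @param length region length in bp (default 200).
#' @param mappability named list of logical vectors, or NULL.
#' @param blacklist data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), or NULL.
#' @param min_mappable minimum mappable fraction (default 0.8).
#' @param seed integer seed.
#' @param max_tries proposal cap as a multiple of `n`.
#' @return data.frame of regions (`chrom`, `start`, `end`); fewer than `n`
#'   rows (with a warning) if eligible windows are scarce.
#' @export
sample_regions <- function(seqlengths, n, length = 200, mappability = NULL,
                           blacklist = NULL, min_mappable = 0.8, seed,
                           max_tries = 50L) {
  set.seed(seed)
  chrom_p <- seqlengths / sum(as.numeric(seqlengths))
  out <- vector("list", max_tries)
  got <- 0L
  for (b in seq_len(max_tries)) {
    m <- max(2L * (n - got), 200L)
    ch <- sample(names(seqlengths), m, replace = TRUE, prob = chrom_p)
    start <- floor(runif(m) * (seqlengths[ch] - length))
    start <- as.integer(pmax(start, 0L))
    end <- start + as.integer(length)
    ok <- end <= seqlengths[ch]
    if (!is.null(mappability)) {
      for (c2 in unique(ch)) {
        i <- which(ch == c2 & ok)
        if (!length(i)) next
        mm <- mappability[[c2]]
        cs <- cumsum(c(0L, mm))
        frac <- (cs[end[i] + 1L] - cs[start[i] + 1L]) / length
        ok[i] <- frac >= min_mappable
      }
    }
    if (!is.null(blacklist) && nrow(blacklist)) {
      for (c2 in unique(ch)) {
        i <- which(ch == c2 & ok)
        if (!length(i)) next
        bl <- blacklist[blacklist$chrom == c2, , drop = FALSE]
        if (!nrow(bl)) next
        hit <- vapply(i, function(j)
          any(start[j] < bl$end & end[j] > bl$start), logical(1))
        ok[i] <- !hit
      }
    }
    if (any(ok))
      out[[b]] <- data.frame(chrom = ch[ok], start = start[ok],
                             end = end[ok], stringsAsFactors = FALSE)
    got <- got + sum(ok)
    if (got >= n) break
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer())
  if (nrow(df) < n)
    warning(sprintf("only %d of %d requested regions were eligible",
                    nrow(df), n))
  df[seq_len(min(n, nrow(df))), , drop = FALSE]
}

#' Positioning score of a region
#'
#' The site score `S(i)` is the fraction of midpoints in a `window`-bp
#' window centred on `i` that lie within `near` bp of `i`; the region
#' score is the maximum `S(i)` over sites in the region, with ties broken
#' towards the site closest to the region midpoint, then leftmost.
#' Windows extend beyond the region boundary when data are available
#' there.  Regions with fewer than `min_midpoints` midpoints are marked
#' invalid.
#'
#' @param track a [midpoint_track()].
#' @param region one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param window full window width in bp (odd; default 201).
#' @param near half-width of the numerator window (default 15).
#' @param min_midpoints minimum midpoints in the region for a valid score
#'   (default 50).
#' @return one-row data.frame: `chrom`, `start`, `end`, `score`,
#'   `argmax_site` (0-based position), `n_midpoints`, `valid`.
#' @export
positioning_score <- function(track, region, window = 201, near = 15,
                              min_midpoints = 50) {
  stopifnot(window %% 2 == 1, near < (window - 1) / 2)
  half <- (window - 1L) / 2L
  start <- region$start; end <- region$end; chrom <- region$chrom
  width <- end - start
  x <- track_slice(track, chrom, start - half, end + half)
  s <- .site_scores(x, half, near)[(half + 1L):(half + width)]
  n_mid <- sum(track_slice(track, chrom, start, end))
  if (all(is.na(s))) {
    return(data.frame(chrom = chrom, start = start, end = end,
                      score = NA_real_, argmax_site = NA_integer_,
                      n_midpoints = n_mid, valid = FALSE,
                      stringsAsFactors = FALSE))
  }
  s2 <- ifelse(is.na(s), -Inf, s)
  best <- argmax_tiebreak(s2, center = width %/% 2 + 1L)
  data.frame(chrom = chrom, start = start, end = end,
             score = s[best], argmax_site = start + best - 1L,
             n_midpoints = n_mid,
             valid = n_mid >= min_midpoints,
             stringsAsFactors = FALSE)
}

# per-site S(i) for a padded count vector; NA where the denominator is 0
.site_scores <- function(x, half, near) {
  num <- running_sum(x, near)
  den <- running_sum(x, half)
  ifelse(den > 0, num / den, NA_real_)
}

#' Positioning scores for many regions
#'
#' Vectorised wrapper around [positioning_score()].
#'
#' @inheritParams positioning_score
#' @param regions data.frame of regions.
#' @return data.frame with one row per region.
#' @export
score_regions <- function(track, regions, window = 201, near = 15,
                          min_midpoints = 50) {
  rows <- lapply(seq_len(nrow(regions)), function(i)
    positioning_score(track, regions[i, ], window, near, min_midpoints))
  do.call(rbind, rows)
}

#' Per-base positioning score track
#'
#' `S(i)` at every position of `[start, end)` (0-based), using data beyond
#' the interval where available.
#'
#' @inheritParams positioning_score
#' @param chrom,start,end interval to score.
#' @param stride compute every `stride`-th site (default 1).
#' @param min_midpoints sites whose full window holds fewer midpoints than
#'   this are returned as NA (default 0: all sites scored).
#' @return numeric vector (NA where no midpoints fall in the window or
#'   support is below `min_midpoints`).
#' @export
positioning_score_track <- function(track, chrom, start, end, window = 201,
                                    near = 15, stride = 1L,
                                    min_midpoints = 0) {
  half <- (window - 1L) / 2L
  x <- track_slice(track, chrom, start - half, end + half)
  keep_rng <- (half + 1L):(half + end - start)
  s <- .site_scores(x, half, near)[keep_rng]
  if (min_midpoints > 0) {
    den <- running_sum(x, half)[keep_rng]
    s[den < min_midpoints] <- NA_real_
  }
  if (stride > 1L) {
    keep <- seq(1L, length(s), by = stride)
    out <- rep(NA_real_, length(s))
    out[keep] <- s[keep]
    return(out)
  }
  s
}

#' Empirical-null calibration of positioning scores
#'
#' Each observed score gets an empirical p-value: the fraction of null
#' scores strictly exceeding it, floored at `1/(N+1)` to avoid zeros.  The
#' null proportion is estimated as `pi0 = #{p > lambda} / (m (1-lambda))`
#' (clamped to `[0, 1]`); the fraction of regions with better-than-chance
#' positioning is `1 - pi0`.  q-values use the standard monotone step-up
#' construction with the pi0 estimate.
#'
#' @param observed numeric vector of observed region scores.
#' @param null_scores numeric vector of scores from the empirical null
#'   (bias-matched simulated midpoints).
#' @param lambda pi0 tuning parameter in (0, 1) (default 0.5).
#' @return list with `p_values`, `q_values`, `pi0`, `fraction_positioned`.
#' @export
null_calibration <- function(observed, null_scores, lambda = 0.5) {
  stopifnot(length(null_scores) > 0, lambda > 0, lambda < 1)
  N <- length(null_scores)
  if (N < 100)
    warning("fewer than 100 null scores; p-value resolution is unstable")
  m <- length(observed)
  ns <- sort(null_scores)
  # #{null > obs} = N - #{null <= obs}
  p <- (N - findInterval(observed, ns)) / N
  p <- pmax(p, 1 / (N + 1))
  pi0 <- sum(p > lambda) / (m * (1 - lambda))
  pi0 <- min(max(pi0, 0), 1)
  # q-values: monotone step-up over sorted p
  o <- order(p)
  ranked <- pi0 * m * p[o] / seq_len(m)
  qv <- rev(cummin(rev(ranked)))
  q <- numeric(m); q[o] <- pmin(qv, 1)
  list(p_values = p, q_values = q, pi0 = pi0,
       fraction_positioned = 1 - pi0)
}

#' Classify positioning scores into strength bands
#'
#' Default bands: weak (0.3, 0.5], moderate (0.5, 0.7], strong (0.7, 1],
#' and the sub-0.3 remainder.
#'
#' @param scores numeric vector in `[0, 1]` (NAs dropped).
#' @param edges increasing band edges (default `c(0.3, 0.5, 0.7, 1)`).
#' @return named numeric vector of fractions: `below`, `weak`, `moderate`,
#'   `strong`.
#' @export
classify_scores <- function(scores, edges = c(0.3, 0.5, 0.7, 1)) {
  scores <- scores[!is.na(scores)]
  stopifnot(all(scores >= 0 & scores <= 1), length(edges) == 4L)
  m <- length(scores)
  if (m == 0L) return(c(below = NA, weak = NA, moderate = NA, strong = NA))
  weak <- sum(scores > edges[1] & scores <= edges[2]) / m
  moderate <- sum(scores > edges[2] & scores <= edges[3]) / m
  strong <- sum(scores > edges[3] & scores <= edges[4]) / m
  c(below = 1 - weak - moderate - strong, weak = weak,
    moderate = moderate, strong = strong)
}

#' Call nucleosome peaks from a per-bp score track
#'
#' Contiguous runs of sites with score above `enter` form peak regions;
#' the peak is the maximum-score site in the run (ties broken towards the
#' run midpoint, then leftmost) and peaks whose score is below `keep` are
#' discarded.
#'
#' @param scores numeric per-bp score vector (NA treated as below
#'   threshold).
#' @param start 0-based genomic position of `scores[1]`.
#' @param chrom chromosome label carried into the output.
#' @param enter run-forming threshold (default 0.4, strict).
#' @param keep minimum peak score retained (default 0.5).
#' @return data.frame: `chrom`, `peak` (0-based), `score`, `region_start`,
#'   `region_end`.
#' @export
call_nucleosome_peaks <- function(scores, start = 0L, chrom = "chr1",
                                  enter = 0.4, keep = 0.5) {
  above <- !is.na(scores) & scores > enter
  if (!any(above))
    return(data.frame(chrom = character(), peak = integer(),
                      score = numeric(), region_start = integer(),
                      region_end = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  runs <- which(r$values)
  rows <- lapply(runs, function(k) {
    i0 <- begins[k]; i1 <- ends[k]
    seg <- scores[i0:i1]
    best <- argmax_tiebreak(seg, center = (i1 - i0 + 1L) %/% 2L + 1L)
    pk_score <- seg[best]
    if (pk_score < keep) return(NULL)
    data.frame(chrom = chrom, peak = start + i0 + best - 2L,
               score = pk_score, region_start = start + i0 - 1L,
               region_end = start + i1, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(chrom = character(), peak = integer(),
                      score = numeric(), region_start = integer(),
                      region_end = integer()))
  do.call(rbind, rows)
}

#' Estimate the nucleosome repeat length from an aggregate midpoint plot
#'
#' Midpoint counts are aggregated by offset from a set of anchor peaks,
#' smoothed with a centred sliding mean, and local maxima (strictly
#' dominant over `min_sep` bp either side) are located.  Peak offsets are
#' regressed on their signed peak index; the repeat length is the slope of
#' the least-squares line.
#'
#' @param track a [midpoint_track()].
#' @param anchors data.frame with `chrom` and `peak` (0-based positions),
#'   e.g. from [call_nucleosome_peaks()].
#' @param span aggregate half-width in bp (default 1000; should cover at
#'   least 3 repeat lengths).
#' @param smooth sliding-window width in bp for the aggregate (default 10;
#'   applied as a centred window of half-width `floor(smooth/2)`).
#' @param min_sep strict-dominance half-width for local maxima (default 30).
#' @return object of class `nrl_estimate`: `repeat_length`, `intercept`,
#'   `peak_offsets`, `residual_sd`, `aggregate`.
#' @export
estimate_nrl <- function(track, anchors, span = 1000, smooth = 10,
                         min_sep = 30) {
  stopifnot(nrow(anchors) >= 1)
  agg <- numeric(2L * span + 1L)
  for (ch in unique(anchors$chrom)) {
    v <- track$counts[[ch]]
    if (is.null(v)) next
    a <- anchors$peak[anchors$chrom == ch]
    pad <- c(numeric(span), v, numeric(span))
    idx <- a + 1L
    for (o in -span:span)
      agg[o + span + 1L] <- agg[o + span + 1L] + sum(pad[idx + o + span])
  }
  sm <- running_mean(agg, floor(smooth / 2))
  peaks <- .local_maxima(sm, min_sep)
  offsets <- peaks - span - 1L
  if (length(offsets) < 3)
    stop("fewer than 3 aggregate peaks detected; cannot estimate NRL")
  # signed index from the aggregate's dominant period (robust to spurious
  # local maxima); off-lattice stragglers (> spacing/4 from their nearest
  # lattice position) are dropped, and duplicate indices keep the closest
  spacing <- tryCatch(
    periodicity_power(sm, c(120, 280), pad = 8192)$best_period,
    error = function(e) NA_real_)
  if (!is.finite(spacing))
    spacing <- stats::median(diff(sort(offsets)))
  for (pass in 1:2) {
    idx <- round(offsets / spacing)
    dev <- abs(offsets - idx * spacing)
    ok <- dev <= spacing / 4
    o <- order(idx, dev)
    ok[o][duplicated(idx[o])] <- FALSE
    if (sum(ok) < 3)
      stop("fewer than 3 lattice-consistent aggregate peaks")
    offsets <- offsets[ok]
    idx <- idx[ok]
    fit <- lm(offsets ~ idx)
    spacing <- unname(coef(fit)[2L])
  }
  out <- list(repeat_length = unname(coef(fit)[2L]),
              intercept = unname(coef(fit)[1L]),
              peak_offsets = offsets,
              residual_sd = sqrt(mean(stats::residuals(fit)^2)),
              aggregate = sm)
  class(out) <- "nrl_estimate"
  out
}

#' @export
print.nrl_estimate <- function(x, ...) {
  cat(sprintf("<nrl_estimate> repeat length %.2f bp from %d aggregate peaks (residual SD %.2f bp)\n",
              x$repeat_length, length(x$peak_offsets), x$residual_sd))
  invisible(x)
}

# indices of local maxima dominating +-min_sep positions; plateaus of
# equal values resolve to their centre
.local_maxima <- function(x, min_sep) {
  n <- length(x)
  cand <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - min_sep); hi <- min(n, i + min_sep)
    cand[i] <- x[i] > 0 && x[i] == max(x[lo:hi])
  }
  if (!any(cand)) return(integer(0))
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  runs <- which(r$values)
  vapply(runs, function(k) begins[k] + (ends[k] - begins[k]) %/% 2L,
         integer(1))
}
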