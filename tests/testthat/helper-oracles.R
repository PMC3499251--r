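# Independent brute-force oracles used across the suite.  These are
# deliberately naive (double loops, direct tabulation) so they share no
# code with the implementation paths they check.

# brute-force positioning score over a region: pad the track, loop sites
brute_region_score <- function(counts, region_start, region_end,
                               window = 201, near = 15) {
  half <- (window - 1) / 2
  n <- length(counts)
  at <- function(j) if (j >= 1 && j <= n) counts[j] else 0
  best <- -Inf; best_site <- NA
  width <- region_end - region_start
  center <- width %/% 2 + 1
  for (i in seq_len(width)) {
    g <- region_start + i          # 1-based index in counts
    num <- 0; den <- 0
    for (j in (g - half):(g + half)) {
      v <- at(j)
      den <- den + v
      if (abs(j - g) <= near) num <- num + v
    }
    if (den == 0) next
    s <- num / den
    if (s > best + 1e-15 ||
        (abs(s - best) <= 1e-15 &&
         (abs(i - center) < abs(best_site - center) ||
          (abs(i - center) == abs(best_site - center) && i < best_site)))) {
      best <- s; best_site <- i
    }
  }
  list(score = if (is.finite(best)) best else NA_real_,
       site = best_site)
}

# literal term-by-term multinomial LLR
brute_llr <- function(counts, probs) {
  k <- length(probs)
  total <- 0
  for (i in seq_len(k)) total <- total + counts[i] * log(probs[i] / (1 / k))
  total
}

# brute-force centred running mean with partial edge windows
brute_running_mean <- function(x, half) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# brute-force sensitive region: smooth, find peak near mid, expand run
brute_sensitive_region <- function(v, mid, smooth = 101, search = 200) {
  sm <- brute_running_mean(v, (smooth - 1) %/% 2)
  lo <- max(1, mid - search); hi <- min(length(sm), mid + search)
  best <- -Inf; peak <- NA
  for (i in lo:hi) {
    if (sm[i] > best ||
        (sm[i] == best && (abs(i - mid) < abs(peak - mid) ||
                           (abs(i - mid) == abs(peak - mid) && i < peak)))) {
      best <- sm[i]; peak <- i
    }
  }
  if (best == 0) return(NULL)
  s <- peak; while (s > 1 && sm[s - 1] > best / 2) s <- s - 1
  e <- peak; while (e < length(sm) && sm[e + 1] > best / 2) e <- e + 1
  list(peak = as.integer(peak), value = best,
       region = as.integer(c(s, e)))
}

# build a one-chromosome midpoint track from a raw count vector
track_from_counts <- function(counts, chrom = "chr1", libs = "lib1") {
  midpoint_track(stats::setNames(list(counts), chrom), libs)
}

# quick fragment_set builder
frags <- function(start, end, chrom = "chr1", lib = "lib1", ...) {
  fragment_set(data.frame(chrom = chrom, start = start, end = end,
                          library_id = lib, ...))
}
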