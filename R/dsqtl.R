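# Genotype-stratified aggregation of DNase I nicks and MNase midpoints at
# DNase I sensitivity QTLs (dsQTLs).  Each cell line is labelled
# homozygous sensitive / heterozygous / homozygous insensitive from the
# genotype of the associated SNP; nucleosome organisation is compared
# across the three classes after centring every region on its DNase I
# sensitive-region midpoint.

#' Define the DNase I sensitive region around a dsQTL
#'
#' Smooths the combined (sensitive + heterozygous) nick track with a
#' centred sliding mean, locates the peak as the maximum smoothed value
#' within `search` bp of the dsQTL midpoint (ties broken towards the
#' midpoint, then leftmost), and defines the sensitive region as the
#' maximal contiguous run around the peak where the smoothed value
#' exceeds half the peak value.
#'
#' @param nick_vec numeric nick-count vector (one region's track).
#' @param dsqtl_mid 1-based index of the dsQTL midpoint within `nick_vec`.
#' @param smooth sliding-window width (default 101; centred, partial at
#'   the vector ends).
#' @param search half-width of the peak search window (default 200).
#' @return object of class `sensitive_region`: `peak` (1-based index),
#'   `peak_value`, `region` (`c(start, end)`, 1-based inclusive),
#'   `smoothed`, `valid`.
#' @export
define_sensitive_region <- function(nick_vec, dsqtl_mid, smooth = 101,
                                    search = 200) {
  half <- (smooth - 1L) %/% 2L
  sm <- running_mean(nick_vec, half)
  lo <- max(1L, dsqtl_mid - search)
  hi <- min(length(sm), dsqtl_mid + search)
  win <- sm[lo:hi]
  if (all(win == 0))
    return(structure(list(peak = NA_integer_, peak_value = 0,
                          region = c(NA_integer_, NA_integer_),
                          smoothed = sm, valid = FALSE),
                     class = "sensitive_region"))
  peak <- as.integer(lo - 1L + argmax_tiebreak(win,
                                               center = dsqtl_mid - lo + 1L))
  pv <- sm[peak]
  above <- sm > pv / 2
  s <- peak; while (s > 1L && above[s - 1L]) s <- s - 1L
  e <- peak; while (e < length(sm) && above[e + 1L]) e <- e + 1L
  structure(list(peak = peak, peak_value = pv, region = c(s, e),
                 smoothed = sm, valid = TRUE),
            class = "sensitive_region")
}

#' @export
print.sensitive_region <- function(x, ...) {
  cat(sprintf("<sensitive_region> peak %s (value %.3g), region [%s, %s]\n",
              x$peak, x$peak_value, x$region[1], x$region[2]))
  invisible(x)
}

#' Filter dsQTLs on region geometry and genotype consistency
#'
#' Three filters, applied in order: (1) discard dsQTLs where either edge
#' of the sensitive region lies more than `max_edge_dist` bp from the
#' dsQTL midpoint; (2) discard both members of any pair of dsQTLs whose
#' sensitive regions overlap (regions are compared in genomic
#' coordinates); (3) discard dsQTLs whose per-genotype mean smoothed
#' values over the sensitive region are inconsistent: heterozygote mean
#' above the homozygous-sensitive mean, or homozygous-insensitive mean
#' above either.
#'
#' @param dsqtls data.frame with one row per candidate: `id`, `chrom`,
#'   `region_start`, `region_end` (genomic, 0-based half-open),
#'   `edge_dist` (max distance of a region edge from the dsQTL midpoint),
#'   `mean_sens`, `mean_het`, `mean_insens`.
#' @param max_edge_dist rule-1 threshold in bp (default 100).
#' @return list with `kept` (filtered data.frame), `discarded` (named
#'   counts per rule), `rule` (per-input rule label or "kept").
#' @export
filter_dsqtls <- function(dsqtls, max_edge_dist = 100) {
  n <- nrow(dsqtls)
  rule <- rep("kept", n)
  # rule 1: region edge too far from the dsQTL midpoint
  r1 <- dsqtls$edge_dist > max_edge_dist
  rule[r1] <- "edge_distance"
  # rule 2: overlapping sensitive regions among survivors (both removed)
  alive <- which(!r1)
  if (length(alive) > 1L) {
    for (ch in unique(dsqtls$chrom[alive])) {
      i <- alive[dsqtls$chrom[alive] == ch]
      if (length(i) < 2L) next
      s <- dsqtls$region_start[i]; e <- dsqtls$region_end[i]
      hit <- vapply(seq_along(i), function(a)
        any(s[a] < e[-a] & e[a] > s[-a]), logical(1))
      rule[i[hit]] <- "overlap"
    }
  }
  # rule 3: genotype means inconsistent with the dsQTL direction
  alive <- which(rule == "kept")
  bad <- dsqtls$mean_het[alive] > dsqtls$mean_sens[alive] |
    dsqtls$mean_insens[alive] > dsqtls$mean_het[alive] |
    dsqtls$mean_insens[alive] > dsqtls$mean_sens[alive]
  rule[alive[bad]] <- "inconsistent"
  kept <- dsqtls[rule == "kept", , drop = FALSE]
  discarded <- c(edge_distance = sum(rule == "edge_distance"),
                 overlap = sum(rule == "overlap"),
                 inconsistent = sum(rule == "inconsistent"))
  list(kept = kept, discarded = discarded, rule = rule)
}

#' Aggregate MNase midpoints and DNase nicks by dsQTL genotype class
#'
#' For each genotype class (2 = homozygous sensitive, 1 = heterozygous,
#' 0 = homozygous insensitive), sums per-sample track slices centred on
#' each retained dsQTL's sensitive-region midpoint; each sample's
#' contribution is scaled by its total sequenced-read count
#' (counts per billion).
#'
#' @param dsqtls data.frame with `chrom` and `center` (0-based genomic
#'   position of the sensitive-region midpoint).
#' @param genotypes matrix of allele dosages (rows = dsQTLs, columns =
#'   samples): 2/1/0 copies of the sensitive allele.
#' @param mid_tracks named list (by sample) of [midpoint_track()]s.
#' @param nick_tracks named list (by sample) of
#'   `list(plus = , minus = )` [midpoint_track()]s, or NULL.
#' @param flank half-width of the aggregated window (default 1000).
#' @param read_totals named numeric vector of per-sample total sequenced
#'   reads; defaults to each sample's midpoint-track total.
#' @return object of class `genotype_aggregate`: `offsets`, `midpoints`
#'   (3 x width matrix, rows "sens", "het", "insens"), `nicks` (same
#'   shape, or NULL), `n_pairs` per class.
#' @export
aggregate_by_genotype <- function(dsqtls, genotypes, mid_tracks,
                                  nick_tracks = NULL, flank = 1000,
                                  read_totals = NULL) {
  samples <- colnames(genotypes)
  stopifnot(!is.null(samples), nrow(genotypes) == nrow(dsqtls))
  missing <- setdiff(samples, names(mid_tracks))
  if (length(missing)) {
    warning("samples without midpoint tracks excluded: ",
            paste(missing, collapse = ","))
    samples <- setdiff(samples, missing)
  }
  if (is.null(read_totals))
    read_totals <- vapply(mid_tracks[samples], function(t) t$total,
                          numeric(1))
  width <- 2L * flank + 1L
  classes <- c(sens = 2, het = 1, insens = 0)
  mids <- matrix(0, 3L, width, dimnames = list(names(classes), NULL))
  nicks <- if (!is.null(nick_tracks))
    matrix(0, 3L, width, dimnames = list(names(classes), NULL)) else NULL
  n_pairs <- stats::setNames(integer(3L), names(classes))
  for (si in seq_along(samples)) {
    sm <- samples[si]
    scale <- 1e9 / read_totals[[sm]]
    for (qi in seq_len(nrow(dsqtls))) {
      g <- genotypes[qi, sm]
      cls <- names(classes)[match(g, classes)]
      if (is.na(cls)) next
      ch <- dsqtls$chrom[qi]; c0 <- dsqtls$center[qi]
      mids[cls, ] <- mids[cls, ] +
        scale * track_slice(mid_tracks[[sm]], ch, c0 - flank, c0 + flank + 1L)
      if (!is.null(nicks)) {
        nt <- nick_tracks[[sm]]
        nicks[cls, ] <- nicks[cls, ] +
          scale * (track_slice(nt$plus, ch, c0 - flank, c0 + flank + 1L) +
                   track_slice(nt$minus, ch, c0 - flank, c0 + flank + 1L))
      }
      n_pairs[cls] <- n_pairs[cls] + 1L
    }
  }
  out <- list(offsets = (-flank):flank, midpoints = mids, nicks = nicks,
              n_pairs = n_pairs)
  class(out) <- "genotype_aggregate"
  out
}

#' @export
print.genotype_aggregate <- function(x, ...) {
  cat(sprintf("<genotype_aggregate> (dsQTL, sample) pairs: sens %d, het %d, insens %d\n",
              x$n_pairs["sens"], x$n_pairs["het"], x$n_pairs["insens"]))
  invisible(x)
}

#' Subset dsQTLs to narrow regions with large genotype effects
#'
#' Retains dsQTLs whose sensitive-region width is strictly below the
#' cohort median and whose genotype effect (absolute difference between
#' the homozygous-sensitive and homozygous-insensitive means) is strictly
#' above the cohort median.
#'
#' @param dsqtls data.frame with `region_start`, `region_end`,
#'   `mean_sens`, `mean_insens`.
#' @return the retained subset (possibly empty; warns on degenerate
#'   cohorts of size < 2).
#' @export
subset_by_effect <- function(dsqtls) {
  if (nrow(dsqtls) < 2L) {
    warning("cohort too small for median subsetting")
    return(dsqtls[integer(0), , drop = FALSE])
  }
  width <- dsqtls$region_end - dsqtls$region_start
  effect <- abs(dsqtls$mean_sens - dsqtls$mean_insens)
  keep <- width < stats::median(width) & effect > stats::median(effect)
  dsqtls[keep, , drop = FALSE]
}
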