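# MNase end-composition bias and DNase I nick bias, plus the bias-matched
# fragment simulator used as the empirical null throughout the package.
#
# MNase cutting leaves a strong compositional signature in the first and
# last four bases of each fragment; DNase I nicking is biased by the
# hexamer spanning positions -3..+3 around the nick.  Both are learned as
# simple k-mer tables and removed either by normalisation (observed over
# expected) or by simulating fragments whose end composition matches the
# data.

#' Learn MNase end 4-mer bias from observed fragments
#'
#' Tabulates the 4-mer formed by the first four and (separately) the last
#' four bases of each fragment, adds a pseudocount to every 4-mer, and
#' normalises each end to a probability distribution.  Fragments whose end
#' 4-mers contain ambiguous bases are skipped and counted.
#'
#' @param fragments a [fragment_set()].
#' @param genome named character vector of chromosome sequences.
#' @param pseudocount added to every 4-mer count before normalising.
#' @return object of class `kmer_bias`: list with elements `left`, `right`
#'   (named probability vectors over the 256 4-mers), `pseudocount`,
#'   `n_skipped`.
#' @export
learn_end_kmer_bias <- function(fragments, genome, pseudocount = 1) {
  km <- all_kmers(4L)
  left <- stats::setNames(numeric(256L), km)
  right <- left
  skipped <- 0L
  for (ch in unique(fragments$chrom)) {
    if (is.null(genome[[ch]])) stop("genome lacks chromosome ", ch)
    sel <- fragments$chrom == ch
    s <- fragments$start[sel]; e <- fragments$end[sel]
    lk <- substring(genome[[ch]], s + 1L, s + 4L)
    rk <- substring(genome[[ch]], e - 3L, e)
    ok <- lk %in% km & rk %in% km
    skipped <- skipped + sum(!ok)
    lt <- table(factor(lk[ok], levels = km))
    rt <- table(factor(rk[ok], levels = km))
    left <- left + as.numeric(lt)
    right <- right + as.numeric(rt)
  }
  left <- left + pseudocount
  right <- right + pseudocount
  out <- list(left = left / sum(left), right = right / sum(right),
              pseudocount = pseudocount, n_skipped = skipped)
  class(out) <- "kmer_bias"
  out
}

#' @export
print.kmer_bias <- function(x, ...) {
  cat(sprintf("<kmer_bias> 4-mer end tables (pseudocount %g); top left-end: %s\n",
              x$pseudocount,
              paste(names(sort(x$left, decreasing = TRUE))[1:3],
                    collapse = ",")))
  invisible(x)
}

#' Simulate fragments matched to a size distribution and end-bias table
#'
#' Proposes fragments uniformly over mappable genome positions with lengths
#' drawn from `size_dist`, then rejection-samples them so that the end
#' 4-mer frequencies match the `bias` tables.  The acceptance weight of a
#' proposal is the ratio (target left-end frequency x target right-end
#' frequency) / (proposal frequency product), normalised by the empirical
#' maximum weight so that acceptance is exact (left and right ends are
#' weighted independently).  Proposal end frequencies are taken from the
#' genome-wide forward-strand 4-mer distribution, which is the marginal end
#' composition of a uniformly placed fragment.
#'
#' @param genome named character vector of chromosome sequences.
#' @param size_dist a [size_distribution()].
#' @param bias a `kmer_bias` table, or NULL for unbiased (uniform
#'   acceptance) sampling.
#' @param n number of fragments requested.
#' @param mappability named list of logical vectors (TRUE = mappable), or
#'   NULL.  Proposals whose end positions fall in unmappable bases are
#'   rejected.
#' @param seed integer seed; the output is reproducible given the seed.
#' @param max_batches safety cap on proposal rounds.
#' @param library_id library id stamped on the simulated fragments.
#' @return a [fragment_set()] with attributes `seed` and `acceptance_rate`.
#' @export
simulate_fragments <- function(genome, size_dist, bias = NULL, n,
                               mappability = NULL, seed,
                               max_batches = 200L, library_id = "sim") {
  stopifnot(n > 0)
  set.seed(seed)
  km <- all_kmers(4L)
  if (!is.null(bias)) {
    prop <- genome_kmer_freq(genome, 4L)
    wl <- bias$left / prop
    wr <- bias$right / prop
  }
  sl <- seq_lengths(genome)
  chrom_p <- sl / sum(sl)
  lens <- size_dist$length
  lp <- size_dist$count / sum(size_dist$count)

  acc <- vector("list", max_batches)
  n_acc <- 0L; n_prop <- 0L; batch <- 0L
  wmax <- NA_real_
  while (n_acc < n && batch < max_batches) {
    batch <- batch + 1L
    m <- max(2L * (n - n_acc), 2000L)
    ch <- names(sl)[sample.int(length(sl), m, replace = TRUE,
                               prob = chrom_p)]
    L <- lens[sample.int(length(lens), m, replace = TRUE, prob = lp)]
    start <- floor(runif(m) * (sl[ch] - L))
    start <- pmax(as.integer(start), 0L)
    end <- start + L
    ok <- end <= sl[ch]
    # mappability: both end positions must be mappable
    if (!is.null(mappability)) {
      for (c2 in unique(ch)) {
        i <- which(ch == c2 & ok)
        if (!length(i)) next
        mm <- mappability[[c2]]
        ok[i] <- ok[i] & mm[start[i] + 1L] & mm[end[i]]
      }
    }
    n_prop <- n_prop + m
    if (!is.null(bias)) {
      lk <- rep(NA_character_, m); rk <- lk
      for (c2 in unique(ch)) {
        i <- which(ch == c2 & ok)
        if (!length(i)) next
        lk[i] <- substring(genome[[c2]], start[i] + 1L, start[i] + 4L)
        rk[i] <- substring(genome[[c2]], end[i] - 3L, end[i])
      }
      ok <- ok & lk %in% km & rk %in% km
      w <- rep(0, m)
      w[ok] <- wl[lk[ok]] * wr[rk[ok]]
      if (is.na(wmax)) wmax <- max(w)  # empirical cap from first batch
      wmax <- max(wmax, w)
      keep <- ok & runif(m) * wmax < w
    } else {
      keep <- ok
    }
    if (any(keep)) {
      acc[[batch]] <- data.frame(chrom = ch[keep], start = start[keep],
                                 end = end[keep],
                                 stringsAsFactors = FALSE)
      n_acc <- n_acc + sum(keep)
    }
  }
  df <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer())
  if (nrow(df) < n)
    warning(sprintf("requested %d fragments, accepted %d", n, nrow(df)))
  n_acc_total <- nrow(df)
  df <- df[seq_len(min(n, nrow(df))), , drop = FALSE]
  df$library_id <- library_id
  fs <- fragment_set(df)
  attr(fs, "seed") <- seed
  attr(fs, "acceptance_rate") <- n_acc_total / n_prop
  fs
}

#' Learn DNase I nick bias as a 6-mer rate table
#'
#' For each hexamer spanning positions -3..+3 around a nick, the expected
#' nick rate is (number of nicks with that context) / (number of genomic
#' occurrences of the hexamer).  Minus-strand nick contexts are read out as
#' the reverse complement; genomic occurrences are counted strand-
#' symmetrically (forward occurrences of the hexamer plus forward
#' occurrences of its reverse complement).
#'
#' @param nicks data.frame with columns `chrom`, `pos` (0-based nick site)
#'   and `strand` (`"+"`/`"-"`).
#' @param genome named character vector of chromosome sequences.
#' @return object of class `dnase_bias`: list with `rate` (named vector
#'   over hexamers with at least one genomic occurrence), `nick_count`,
#'   `genome_count`, `n_excluded` (hexamers with nicks but no genomic
#'   occurrence — impossible unless nicks disagree with the genome).
#' @export
learn_dnase_bias <- function(nicks, genome) {
  km <- all_kmers(6L)
  ctx <- character(nrow(nicks))
  for (ch in unique(nicks$chrom)) {
    sel <- which(nicks$chrom == ch)
    p <- nicks$pos[sel]
    plus <- nicks$strand[sel] != "-"
    # plus strand: bases p-3 .. p+2 (0-based); minus: revcomp of p-2 .. p+3
    ctx[sel[plus]] <- substring(genome[[ch]], p[plus] - 2L, p[plus] + 3L)
    if (any(!plus))
      ctx[sel[!plus]] <- revcomp(substring(genome[[ch]], p[!plus] - 1L,
                                           p[!plus] + 4L))
  }
  ok <- ctx %in% km
  nick_count <- as.numeric(table(factor(ctx[ok], levels = km)))
  names(nick_count) <- km
  fwd <- genome_kmer_counts(genome, 6L)
  genome_count <- fwd + fwd[revcomp(km)]
  names(genome_count) <- km
  defined <- genome_count > 0
  excluded <- sum(nick_count[!defined] > 0)
  rate <- nick_count[defined] / genome_count[defined]
  out <- list(rate = rate, nick_count = nick_count,
              genome_count = genome_count, n_excluded = excluded,
              n_nicks_used = sum(nick_count[defined]))
  class(out) <- "dnase_bias"
  out
}

#' @export
print.dnase_bias <- function(x, ...) {
  cat(sprintf("<dnase_bias> %d hexamers with defined rates; %0.0f nicks used\n",
              length(x$rate), x$n_nicks_used))
  invisible(x)
}

#' Log2 ratio of observed to expected profiles
#'
#' Elementwise `log2(observed / expected)` with both sides floored at a
#' small epsilon before division (so zero expectations do not produce
#' infinities).
#'
#' @param observed,expected numeric vectors or matrices of equal dimension.
#' @param eps floor applied to both sides before the ratio.
#' @return numeric object of the same shape; attribute `eps` records the
#'   floor used.
#' @export
normalize_by_expected <- function(observed, expected, eps = 1e-6) {
  if (length(observed) != length(expected))
    stop("observed and expected have different lengths")
  out <- log2(pmax(observed, eps) / pmax(expected, eps))
  if (!is.null(dim(observed))) dim(out) <- dim(observed)
  attr(out, "eps") <- eps
  out
}
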