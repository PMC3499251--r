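# The multinomial nucleosome-array template model.
#
# Midpoint counts in a window of k positions are modelled as multinomial
# with placement probabilities lambda (the "template"); the null is the
# uniform template lambda_0 = 1/k.  The log-likelihood ratio is
#     LLR = sum_i x_i * ln(lambda_i / (1/k))      (natural log)
# which is linear in the counts.  Templates are learned by iterative
# alignment of training windows, scanned across the genome, calibrated by
# permutation FDR, and composed into flanking-array models around
# protein-binding barriers with a nucleosome-free region (NFR) of
# estimated width.

#' Construct a nucleosome-array template
#'
#' @param probs non-negative vector over template positions; floored at
#'   `floor` and renormalised to sum to 1.
#' @param symmetric logical; if TRUE the template is averaged with its
#'   mirror image.
#' @param floor minimum per-position probability before renormalisation.
#' @return object of class `array_template`: `probs`, `k`, `symmetric`,
#'   `floor`.
#' @export
array_template <- function(probs, symmetric = FALSE, floor = 1e-6) {
  stopifnot(all(probs >= 0), length(probs) >= 2)
  p <- probs / sum(probs)
  p <- pmax(p, floor)
  p <- p / sum(p)
  if (symmetric) {
    p <- (p + rev(p)) / 2
    p <- p / sum(p)
  }
  out <- list(probs = p, k = length(p), symmetric = symmetric,
              floor = floor)
  class(out) <- "array_template"
  out
}

#' @export
print.array_template <- function(x, ...) {
  cat(sprintf("<array_template> k = %d bp, %s%s\n", x$k,
              if (x$symmetric) "symmetric" else "asymmetric",
              if (!is.null(x$provenance))
                sprintf(", trained (%d iterations, %d regions)",
                        x$provenance$iterations, x$provenance$n_regions)
              else ""))
  invisible(x)
}

#' Default five-nucleosome array template
#'
#' A symmetric sum of Gaussian bumps at the given spacing over a
#' `k`-bp span: a generic phased-array shape used to initialise training
#' when no empirically derived pattern is available.
#'
#' @param k template width in bp (default 879, spanning 5 nucleosomes).
#' @param n_nuc number of nucleosome bumps (default 5).
#' @param nrl bump spacing in bp (default 186).
#' @param sd bump standard deviation in bp (default 20).
#' @param floor probability floor.
#' @return an [array_template()].
#' @export
default_array_template <- function(k = 879, n_nuc = 5, nrl = 186,
                                   sd = 20, floor = 1e-6) {
  mid <- (k + 1) / 2
  centers <- mid + (seq_len(n_nuc) - (n_nuc + 1) / 2) * nrl
  x <- seq_len(k)
  p <- rowSums(vapply(centers, function(c0) exp(-(x - c0)^2 / (2 * sd^2)),
                      numeric(k)))
  array_template(p, symmetric = TRUE, floor = floor)
}

#' Array log-likelihood ratio for a count vector
#'
#' `LLR = sum_i x_i ln(lambda_i k)` in nats: the multinomial
#' log-likelihood of the counts under the template minus that under the
#' uniform null.  Exactly linear in the counts.
#'
#' @param counts non-negative count vector of length `template$k`.
#' @param template an [array_template()].
#' @return log-likelihood ratio (nats).
#' @export
array_llr <- function(counts, template) {
  if (any(counts < 0)) stop("negative counts")
  if (length(counts) != template$k)
    stop("counts length does not match template width")
  sum(counts * log(template$probs * template$k))
}

#' Train an array template by iterative alignment
#'
#' Each iteration aligns every training window at the offset maximising
#' the multinomial likelihood under the current template, accumulates the
#' aligned midpoint counts, smooths them with a centred sliding mean,
#' floors and renormalises, and (if `symmetric`) averages with the mirror
#' image.  Stops when the L1 change drops below `tol` or after `max_iter`
#' iterations.  Deterministic given the input order.
#'
#' @param regions list of numeric count vectors, each wider than the
#'   template.
#' @param init an [array_template()] initial value (e.g.
#'   [default_array_template()]).
#' @param max_iter maximum iterations (default 30).
#' @param tol L1 convergence tolerance (default 1e-3).
#' @param smooth smoothing window width in bp (default 5, centred).
#' @return an [array_template()] with a `provenance` element (iterations,
#'   converged, n_regions).
#' @export
train_template <- function(regions, init, max_iter = 30, tol = 1e-3,
                           smooth = 5) {
  stopifnot(length(regions) > 0)
  k <- init$k
  lambda <- init$probs
  if (any(vapply(regions, length, integer(1)) < k))
    stop("every training region must be at least as wide as the template")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # uniform-referenced weights: counts outside the template contribute 0,
    # so placements that shift mass off the template are compared fairly
    w <- log(lambda * k)
    acc <- numeric(k)
    for (x in regions) {
      cc <- cross_correlate(x, w)
      o <- which.max(cc)   # ties: leftmost (deterministic)
      acc <- acc + x[o:(o + k - 1L)]
    }
    new <- running_mean(acc, floor(smooth / 2))
    new <- pmax(new / sum(new), init$floor)
    new <- new / sum(new)
    if (init$symmetric) {
      new <- (new + rev(new)) / 2
      new <- new / sum(new)
    }
    delta <- sum(abs(new - lambda))
    lambda <- new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("template training did not converge in ", max_iter,
            " iterations")
  out <- array_template(lambda, symmetric = init$symmetric,
                        floor = init$floor)
  out$provenance <- list(iterations = it, converged = converged,
                         n_regions = length(regions))
  out
}

#' Slide a template over a window and return the best LLR
#'
#' The template midpoint is slid from `slide[1]` to `slide[2]` bp relative
#' to the window midpoint in `step`-bp increments.  At each offset the
#' window positions not covered by the template carry the same probability
#' per site as the uniform null, so they contribute zero to the LLR and
#' all data in the window enter the likelihood.  Template positions
#' overhanging the window edge are matched against zero counts.
#'
#' @param x numeric count vector for the window (default design: 1 kb).
#' @param template an [array_template()].
#' @param slide `c(lo, hi)` template-midpoint offsets in bp relative to
#'   the window midpoint (default `c(-100, 200)`).
#' @param step slide increment in bp (default 1).
#' @return list of class `llr_result`: `llr` (max over offsets),
#'   `best_offset` (bp re window midpoint), `n_midpoints`, `zero` flag.
#' @export
test_region <- function(x, template, slide = c(-100, 200), step = 1) {
  W <- length(x)
  k <- template$k
  stopifnot(k <= W + 2 * max(abs(slide)))
  n_mid <- sum(x)
  if (n_mid == 0)
    return(structure(list(llr = 0, best_offset = NA_integer_,
                          n_midpoints = 0, zero = TRUE),
                     class = "llr_result"))
  w <- log(template$probs * k)
  wmid <- (W + 1L) %/% 2L       # window midpoint, 1-based
  tmid <- (k + 1L) %/% 2L       # template midpoint index
  offs <- seq(slide[1L], slide[2L], by = step)
  starts <- wmid + offs - tmid + 1L   # template start, 1-based in x
  pad <- max(0L, 1L - min(starts), max(starts) + k - 1L - W)
  xp <- c(numeric(pad), x, numeric(pad))
  cc <- cross_correlate(xp, w)
  llr <- cc[starts + pad]
  best <- which.max(llr)
  structure(list(llr = llr[best], best_offset = offs[best],
                 n_midpoints = n_mid, zero = FALSE),
            class = "llr_result")
}

#' @export
print.llr_result <- function(x, ...) {
  cat(sprintf("<llr_result> LLR = %.2f nats at offset %s bp (%0.0f midpoints)\n",
              x$llr, x$best_offset, x$n_midpoints))
  invisible(x)
}

#' Scan a genome for strongly positioned nucleosome arrays
#'
#' Slides the template across each chromosome in `step`-bp increments,
#' computes the LLR of each k-bp window against the uniform null, drops
#' windows below `llr_min`, with fewer than `min_midpoints` midpoints, or
#' with insufficient mappability, and merges surviving overlapping windows
#' into maximal intervals annotated with their maximum LLR.
#'
#' @param track a [midpoint_track()].
#' @param template an [array_template()].
#' @param step stride in bp (default 5).
#' @param llr_min minimum window LLR retained (default 50).
#' @param min_midpoints minimum midpoints per window (default `template$k`).
#' @param mappability optional named list of logical vectors.
#' @param min_mappable minimum mappable fraction per window (default 0.8).
#' @return data.frame of merged intervals: `chrom`, `start`, `end`
#'   (0-based half-open), `llr` (maximum over member windows).
#' @export
scan_genome <- function(track, template, step = 5, llr_min = 50,
                        min_midpoints = NULL, mappability = NULL,
                        min_mappable = 0.8) {
  k <- template$k
  if (is.null(min_midpoints)) min_midpoints <- k
  w <- log(template$probs * k)
  out <- list()
  for (ch in sort(names(track$counts))) {
    v <- track$counts[[ch]]
    n <- length(v)
    if (n < k) next
    cc <- cross_correlate(v, w)
    starts <- seq(1L, n - k + 1L, by = step)
    llr <- cc[starts]
    cs <- cumsum(c(0, v))
    nmid <- cs[starts + k] - cs[starts]
    keep <- llr >= llr_min & nmid >= min_midpoints
    if (!is.null(mappability)) {
      mm <- cumsum(c(0L, mappability[[ch]]))
      frac <- (mm[starts + k] - mm[starts]) / k
      keep <- keep & frac >= min_mappable
    }
    if (!any(keep)) next
    s <- starts[keep]; l <- llr[keep]
    ir <- IRanges::IRanges(start = s, width = k)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    mx <- tapply(l[S4Vectors::queryHits(ov)], S4Vectors::subjectHits(ov),
                 max)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      llr = as.numeric(mx),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), llr = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single-nucleosome template
#'
#' A 147-bp Gaussian bump used to locate individual positioned nucleosomes
#' for the `drop_top` and `keep_two` permutation schemes.
#'
#' @param width footprint width (default 147).
#' @param sd bump standard deviation in bp (default 20).
#' @param floor probability floor.
#' @return an [array_template()].
#' @export
single_nucleosome_template <- function(width = 147, sd = 20, floor = 1e-6) {
  x <- seq_len(width)
  array_template(exp(-(x - (width + 1) / 2)^2 / (2 * sd^2)),
                 symmetric = TRUE, floor = floor)
}

# best placements of the single-nucleosome template in x (greedy,
# non-overlapping); returns 1-based start indices
.call_single_nucleosomes <- function(x, single, n_calls) {
  k <- single$k
  w <- log(single$probs * k)
  cc <- cross_correlate(x, w)
  starts <- integer(0)
  masked <- cc
  for (j in seq_len(n_calls)) {
    if (all(!is.finite(masked))) break
    o <- which.max(masked)
    starts <- c(starts, o)
    lo <- max(1L, o - k + 1L); hi <- min(length(masked), o + k - 1L)
    masked[lo:hi] <- -Inf
  }
  starts
}

#' Permutation FDR for array LLRs
#'
#' Computes observed LLRs (via [test_region()]) for a set of windows and
#' compares them with LLRs from permuted versions of the same windows.
#' Schemes: `"full"` shuffles the counts across all window positions;
#' `"drop_top"` locates the best single-nucleosome match, zeroes its
#' footprint in both the observed and permuted data, then computes the
#' LLR; `"keep_two"` excludes two randomly chosen called-nucleosome
#' footprints from the shuffle (their counts stay in place).
#' `FDR(t) = #{perm LLR >= t} / (n_perm * #{obs LLR >= t})`, clamped to
#' `[0, 1]` and made monotone non-increasing in `t`.
#'
#' @param regions list of numeric count vectors (equal widths).
#' @param template an [array_template()].
#' @param scheme `"full"`, `"drop_top"` or `"keep_two"`.
#' @param n_perm permutations per region (default 1).
#' @param seed integer seed for the shuffles.
#' @param slide,step passed to [test_region()].
#' @param single single-nucleosome template for the footprint schemes.
#' @return object of class `permutation_fdr`: `table` (threshold, n_obs,
#'   n_perm_ge, fdr), `obs_llr`, `perm_llr`, `scheme`.
#' @export
permutation_fdr <- function(regions, template,
                            scheme = c("full", "drop_top", "keep_two"),
                            n_perm = 1, seed,
                            slide = c(-100, 200), step = 1,
                            single = single_nucleosome_template()) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1)
  set.seed(seed)
  kf <- single$k
  obs <- vapply(regions, function(x)
    test_region(.drop_top_prep(x, scheme, single), template, slide,
                step)$llr, numeric(1))
  perm <- numeric(0)
  for (b in seq_len(n_perm)) {
    pb <- vapply(regions, function(x) {
      px <- .permute_region(x, scheme, single)
      test_region(.drop_top_prep(px, scheme, single), template, slide,
                  step)$llr
    }, numeric(1))
    perm <- c(perm, pb)
  }
  tab <- .fdr_table(obs, perm, n_perm)
  out <- list(table = tab, obs_llr = obs, perm_llr = perm, scheme = scheme,
              n_perm = n_perm)
  class(out) <- "permutation_fdr"
  out
}

#' @export
print.permutation_fdr <- function(x, ...) {
  cat(sprintf("<permutation_fdr> scheme %s, %d regions, %d permutation(s)\n",
              x$scheme, length(x$obs_llr), x$n_perm))
  invisible(x)
}

# zero the footprint of the best single-nucleosome match (drop_top scheme)
.drop_top_prep <- function(x, scheme, single) {
  if (scheme != "drop_top") return(x)
  kf <- single$k
  o <- .call_single_nucleosomes(x, single, 1L)
  if (length(o)) x[o:(min(length(x), o + kf - 1L))] <- 0
  x
}

# one shuffled copy of a region's count vector under the given scheme;
# total counts are always conserved
.permute_region <- function(x, scheme, single) {
  if (scheme == "keep_two") {
    kf <- single$k
    calls <- .call_single_nucleosomes(x, single, 5L)
    pick <- calls[sample.int(length(calls), min(2L, length(calls)))]
    protect <- unique(unlist(lapply(pick, function(o)
      o:min(length(x), o + kf - 1L))))
    free <- setdiff(seq_along(x), protect)
    x[free] <- x[sample(free)]
    x
  } else {
    x[sample.int(length(x))]
  }
}

# FDR(t) = #{perm >= t} / (n_perm * #{obs >= t}), clamped to [0, 1] and
# made monotone non-increasing in t (descending-threshold running max)
.fdr_table <- function(obs, perm, n_perm) {
  thresholds <- sort(unique(obs), decreasing = TRUE)
  n_obs_ge <- vapply(thresholds, function(t) sum(obs >= t), numeric(1))
  n_perm_ge <- vapply(thresholds, function(t) sum(perm >= t), numeric(1))
  raw <- ifelse(n_obs_ge > 0,
                pmin((n_perm_ge / n_perm) / n_obs_ge, 1), NA_real_)
  fdr <- cummax(ifelse(is.na(raw), -Inf, raw))
  fdr[is.na(raw)] <- NA_real_
  tab <- data.frame(threshold = thresholds, n_obs = n_obs_ge,
                    n_perm_ge = n_perm_ge, fdr = fdr)
  tab <- tab[order(tab$threshold), ]
  rownames(tab) <- NULL
  tab
}

#' LLR threshold attaining a requested FDR
#'
#' @param fit a [permutation_fdr()] result.
#' @param level target FDR (e.g. 0.01).
#' @return the smallest threshold whose (monotone) FDR is at or below
#'   `level`, or NA if none attains it.
#' @export
threshold_at_fdr <- function(fit, level) {
  tab <- fit$table
  ok <- !is.na(tab$fdr) & tab$fdr <= level
  if (!any(ok)) return(NA_real_)
  min(tab$threshold[ok])
}

#' Flanking-array half templates
#'
#' Direct construction of the 1-kb upstream/downstream array templates
#' used around binding-site barriers: Gaussian nucleosome bumps whose
#' innermost bump centre sits `edge_offset` bp from the inner (NFR-facing)
#' end, with successive bumps every `nrl` bp outward.  The downstream
#' template is the mirror image of the upstream one.
#'
#' @param nrl nucleosome repeat length in bp (default 190).
#' @param length template length in bp (default 1000).
#' @param sd bump standard deviation (default 20).
#' @param edge_offset distance from the NFR edge to the first dyad
#'   (default 74, half a nucleosome footprint).
#' @param floor probability floor.
#' @return list with `up` and `down` [array_template()]s.
#' @export
flanking_templates <- function(nrl = 190, length = 1000, sd = 20,
                               edge_offset = 74, floor = 1e-6) {
  x <- seq_len(length)
  centers <- seq(length - edge_offset, 1, by = -nrl)
  p <- rowSums(vapply(centers, function(c0)
    exp(-(x - c0)^2 / (2 * sd^2)), numeric(length)))
  up <- array_template(p, symmetric = FALSE, floor = floor)
  down <- array_template(rev(up$probs), symmetric = FALSE, floor = floor)
  list(up = up, down = down)
}

#' Derive half templates from a trained master template
#'
#' Splits the master template at its centre, mirrors the outward-decaying
#' half so the strongest nucleosome abuts the inner end, and extends it to
#' `length` bp by tiling the terminal `nrl`-bp period.
#'
#' @param template trained master [array_template()].
#' @param nrl repeat period used for the extension.
#' @param length output half-template length (default 1000).
#' @return list with `up` and `down` [array_template()]s.
#' @export
derive_half_templates <- function(template, nrl, length = 1000) {
  k <- template$k
  right <- template$probs[((k + 1L) %/% 2L):k]
  up <- rev(right)                     # strongest bump at the right end
  while (base::length(up) < length) {
    block <- up[seq_len(min(nrl, base::length(up)))]
    up <- c(block, up)
  }
  up <- up[(base::length(up) - length + 1L):base::length(up)]
  upt <- array_template(up, symmetric = FALSE, floor = template$floor)
  list(up = upt,
       down = array_template(rev(upt$probs), symmetric = FALSE,
                             floor = template$floor))
}

#' Fit flanking arrays and a nucleosome-free region around a summit
#'
#' Composes `[upstream template | uniform NFR | downstream template]` for
#' each candidate NFR width, assigning the NFR sites the region-mean
#' midpoint rate (i.e. the uniform per-site probability of the spanned
#' region) and splitting the remaining mass equally between the two
#' halves.  The composite may also slide around the summit.  Returns the
#' maximum-likelihood NFR width, its LLR against the uniform null over the
#' same span, and the NFR edge positions used for alignment.
#'
#' @param x numeric count vector containing the 2 kb (+ max NFR) window.
#' @param summit 1-based index of the binding-site summit within `x`.
#' @param halves list with `up`/`down` templates (see
#'   [flanking_templates()]).
#' @param max_nfr maximum NFR width in bp (default 200).
#' @param nfr_step NFR width grid step (default 5).
#' @param slide maximum composite shift either side of the summit
#'   (default 50).
#' @param slide_step shift grid step (default 5).
#' @return object of class `flanking_fit`: `nfr_width`, `llr`, `offset`,
#'   `edge_up`, `edge_down` (1-based indices in `x`), `nfr_rate`
#'   (midpoints per bp in the fitted NFR), `flat` (TRUE when the
#'   likelihood is flat within 1 nat across widths).
#' @export
fit_flanking_arrays <- function(x, summit, halves, max_nfr = 200,
                                nfr_step = 5, slide = 50, slide_step = 5) {
  lu <- halves$up$k; ld <- halves$down$k
  widths <- seq(0, max_nfr, by = nfr_step)
  offs <- seq(-slide, slide, by = slide_step)
  best <- list(llr = -Inf)
  per_width_best <- numeric(length(widths))
  for (wi in seq_along(widths)) {
    wdt <- widths[wi]
    L <- lu + wdt + ld
    q <- c(halves$up$probs * (1 - wdt / L) / 2,
           rep(1 / L, wdt),
           halves$down$probs * (1 - wdt / L) / 2)
    lw <- log(q * L)
    wbest <- -Inf
    for (s in offs) {
      a <- summit + s - (lu + wdt %/% 2L)  # composite start - 1 (0-based)
      seg <- .pad_slice(x, a + 1L, a + L)
      llr <- sum(seg * lw)
      if (llr > wbest) wbest <- llr
      if (llr > best$llr) {
        best <- list(llr = llr, width = wdt, offset = s,
                     edge_up = a + lu + 1L, edge_down = a + lu + wdt,
                     n = sum(seg))
      }
    }
    per_width_best[wi] <- wbest
  }
  flat <- diff(range(per_width_best)) < 1
  out <- list(nfr_width = best$width, llr = best$llr,
              offset = best$offset, edge_up = best$edge_up,
              edge_down = best$edge_down,
              nfr_rate = if (best$width > 0)
                sum(.pad_slice(x, best$edge_up, best$edge_down)) /
                  best$width else 0,
              flat = flat)
  class(out) <- "flanking_fit"
  out
}

#' @export
print.flanking_fit <- function(x, ...) {
  cat(sprintf("<flanking_fit> NFR width %d bp, LLR %.1f nats%s\n",
              x$nfr_width, x$llr,
              if (x$flat) " (flat likelihood: width unidentifiable)" else ""))
  invisible(x)
}

# 1-based slice with zero padding outside the vector
.pad_slice <- function(x, from, to) {
  idx <- from:to
  out <- numeric(length(idx))
  ok <- idx >= 1L & idx <= length(x)
  out[ok] <- x[idx[ok]]
  out
}

#' Occupancy-stratified aggregation of aligned flanking profiles
#'
#' Ranks peaks within each factor, pools same-quantile peaks across
#' factors into `n_bins` bins, and aggregates their midpoint profiles
#' aligned on the NFR edges (upstream segments right-aligned on the
#' upstream edge, downstream segments left-aligned on the downstream edge,
#' the variable-width centre padded with NA).  Aligned columns supported
#' by fewer than `min_support` of the bin's peaks are masked.
#'
#' @param profiles list of per-peak numeric count vectors.
#' @param fits list of [fit_flanking_arrays()] results (same order).
#' @param occupancy numeric vector of per-peak occupancies (e.g. ChIP-seq
#'   read depth).
#' @param factor character vector of factor labels per peak.
#' @param n_bins number of occupancy bins (default 5, quintiles).
#' @param flank_out flanking length kept outside each NFR edge
#'   (default 800).
#' @param min_support minimum fraction of peaks supporting a column
#'   (default 0.5).
#' @return object of class `stratified_aggregate`: `aggregate` (n_bins x
#'   width matrix, NA where masked), `support`, `bin` (per-peak bin),
#'   `excluded_factors`.
#' @export
stratify_and_aggregate <- function(profiles, fits, occupancy, factor,
                                   n_bins = 5, flank_out = 800,
                                   min_support = 0.5) {
  stopifnot(length(profiles) == length(fits),
            length(occupancy) == length(profiles),
            length(factor) == length(profiles))
  bin <- rep(NA_integer_, length(profiles))
  excluded <- character(0)
  for (f in unique(factor)) {
    i <- which(factor == f)
    if (length(i) < n_bins) {
      excluded <- c(excluded, f)
      warning("factor ", f, " has fewer peaks than bins; excluded")
      next
    }
    r <- rank(occupancy[i], ties.method = "first")
    bin[i] <- ceiling(r / length(i) * n_bins)
  }
  widths <- vapply(fits, function(f) f$edge_down - f$edge_up + 1L,
                   integer(1))
  cmax <- max(widths, 1L)
  width_out <- flank_out + cmax + flank_out
  agg <- matrix(NA_real_, n_bins, width_out)
  support <- matrix(0, n_bins, width_out)
  sums <- matrix(0, n_bins, width_out)
  npk <- integer(n_bins)
  for (j in seq_along(profiles)) {
    if (is.na(bin[j])) next
    ft <- fits[[j]]
    up <- .pad_slice(profiles[[j]], ft$edge_up - flank_out, ft$edge_up - 1L)
    ctr <- if (ft$edge_down >= ft$edge_up)
      .pad_slice(profiles[[j]], ft$edge_up, ft$edge_down) else numeric(0)
    dn <- .pad_slice(profiles[[j]], ft$edge_down + 1L,
                     ft$edge_down + flank_out)
    row <- rep(NA_real_, width_out)
    row[seq_len(flank_out)] <- up
    if (length(ctr))
      row[flank_out + seq_along(ctr)] <- ctr
    row[(flank_out + cmax + 1L):width_out] <- dn
    b <- bin[j]
    got <- !is.na(row)
    sums[b, got] <- sums[b, got] + row[got]
    support[b, ] <- support[b, ] + got
    npk[b] <- npk[b] + 1L
  }
  for (b in seq_len(n_bins)) {
    if (npk[b] == 0L) next
    ok <- support[b, ] >= min_support * npk[b]
    agg[b, ok] <- sums[b, ok] / support[b, ok]
  }
  out <- list(aggregate = agg, support = support, bin = bin,
              n_per_bin = npk, flank_out = flank_out,
              excluded_factors = excluded)
  class(out) <- "stratified_aggregate"
  out
}
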