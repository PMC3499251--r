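# Fragment ingestion, quality/size filtering and dyad midpoint tracks.
#
# A fragment is one MNase digestion product, recovered either from a
# properly-paired read pair (fragment = the interval between the outermost
# mapped bases) or from a single-end read (fragment position inferred from
# the 5' end plus a fixed offset).  Coordinates are 0-based half-open.

#' Construct a fragment set
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `library_id`, `mapq`, `strand`, `is_single`.
#' @return a `fragment_set`: a data.frame with normalised columns.
#' @export
fragment_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (is.null(df$library_id)) df$library_id <- rep("lib1", nrow(df))
  df$library_id <- as.character(df$library_id)
  if (is.null(df$strand)) df$strand <- rep("+", nrow(df))
  if (is.null(df$is_single)) df$is_single <- rep(FALSE, nrow(df))
  if (nrow(df) && any(df$end <= df$start))
    stop("fragment with end <= start")
  if (nrow(df) && any(!nzchar(df$library_id)))
    stop("empty library_id")
  class(df) <- c("fragment_set", "data.frame")
  df
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %d fragments, %d libraries\n",
              nrow(x), length(unique(x$library_id))))
  if (nrow(x)) {
    len <- x$end - x$start
    cat(sprintf("  length: min %d, median %g, max %d\n",
                min(len), stats::median(len), max(len)))
  }
  invisible(x)
}

fragment_lengths <- function(fragments) fragments$end - fragments$start

#' Load aligned MNase-seq fragments
#'
#' Reads fragments from a BED file (6 columns: chrom, start, end, name used
#' as library id, score used as mapping quality, strand), an in-memory
#' data.frame with the same fields, or an indexed BAM file of paired-end
#' alignments (requires Rsamtools).  Pairs are resolved to one fragment per
#' properly-paired read pair; a pair is kept only if both mates meet the
#' mapping-quality threshold.  Pairs whose mates map to different
#' chromosomes are skipped and counted in the `skipped` attribute.
#'
#' @param x path to a BED/BAM file, or a data.frame.
#' @param min_mapq minimum mapping quality; records (and their mates) below
#'   it are discarded.  Default 10.
#' @param library_id library identifier assigned when the input carries none.
#' @return a [fragment_set()] with attribute `skipped` (named counts of
#'   discarded records) and attribute `size_distribution`.
#' @export
load_fragments <- function(x, min_mapq = 10, library_id = "lib1") {
  skipped <- c(low_mapq = 0L, cross_chrom = 0L)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("cannot read input: ", x)
    if (grepl("\\.bam$", x, ignore.case = TRUE)) {
      df <- .load_bam_pairs(x, min_mapq)
      skipped <- attr(df, "skipped")
    } else if (file.size(x) == 0) {
      df <- data.frame(chrom = character(), start = integer(),
                       end = integer(), library_id = character())
    } else {
      df <- read.table(x, header = FALSE, sep = "\t",
                       stringsAsFactors = FALSE)
      names(df)[seq_len(min(6L, ncol(df)))] <-
        c("chrom", "start", "end", "library_id", "mapq", "strand")[
          seq_len(min(6L, ncol(df)))]
      if (ncol(df) < 4L) df$library_id <- library_id
      if (!is.null(df$mapq) && is.numeric(df$mapq)) {
        keep <- df$mapq >= min_mapq
        skipped["low_mapq"] <- sum(!keep)
        df <- df[keep, , drop = FALSE]
      }
    }
  } else if (is.data.frame(x)) {
    df <- x
    if (!is.null(df$mapq)) {
      keep <- df$mapq >= min_mapq
      skipped["low_mapq"] <- sum(!keep)
      df <- df[keep, , drop = FALSE]
    }
    if (is.null(df$library_id)) df$library_id <- library_id
  } else {
    stop("unsupported input type")
  }
  if (nrow(df) == 0L) {
    df <- data.frame(chrom = character(), start = integer(),
                     end = integer(), library_id = character())
  }
  fs <- fragment_set(df)
  attr(fs, "skipped") <- skipped
  attr(fs, "size_distribution") <- size_distribution(fs)
  fs
}

.load_bam_pairs <- function(path, min_mapq) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                  isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    what = c("qname", "rname", "pos", "mapq", "isize", "mrnm"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  cross <- sum(!is.na(b$mrnm) & as.character(b$mrnm) != as.character(b$rname))
  # minimum mapq over each pair, keyed by read name
  mq <- tapply(b$mapq, b$qname, min, na.rm = TRUE)
  keep_name <- names(mq)[mq >= min_mapq]
  sel <- b$qname %in% keep_name & b$isize > 0 &
    as.character(b$mrnm) == as.character(b$rname)
  low <- sum(b$isize > 0) - sum(sel)
  df <- data.frame(chrom = as.character(b$rname)[sel],
                   start = b$pos[sel] - 1L,
                   end = b$pos[sel] - 1L + b$isize[sel],
                   library_id = basename(path),
                   stringsAsFactors = FALSE)
  attr(df, "skipped") <- c(low_mapq = low, cross_chrom = cross)
  df
}

#' Fragment size distribution
#'
#' @param fragments a [fragment_set()].
#' @return object of class `size_distribution`: a histogram of fragment
#'   length to count.
#' @export
size_distribution <- function(fragments) {
  len <- fragment_lengths(fragments)
  tab <- table(len)
  out <- list(length = as.integer(names(tab)), count = as.integer(tab),
              n = length(len))
  class(out) <- "size_distribution"
  out
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> n = %d, support [%s, %s]\n", x$n,
              if (length(x$length)) min(x$length) else NA,
              if (length(x$length)) max(x$length) else NA))
  invisible(x)
}

#' Central interval of a size distribution
#'
#' Bounds enclosing the central `mass` fraction of fragment lengths
#' (empirical type-1 quantiles at `(1-mass)/2` and `(1+mass)/2`).
#'
#' @param dist a [size_distribution()].
#' @param mass fraction of probability mass, in (0, 1).
#' @return integer vector `c(low, high)`.
#' @export
central_interval <- function(dist, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  lengths <- rep(dist$length, dist$count)
  as.integer(quantile(lengths, c((1 - mass) / 2, (1 + mass) / 2),
                      type = 1, names = FALSE))
}

#' Filter fragments by size
#'
#' Retains fragments with `low <= length <= high`.  In `"central"` mode the
#' bounds are computed as the central `mass` interval of the input's own
#' size distribution (the defaults reproduce a central-95% filter).
#'
#' @param fragments a [fragment_set()].
#' @param low,high explicit inclusive bounds in bp (mode `"explicit"`).
#' @param mode `"explicit"` or `"central"`.
#' @param mass central probability mass for `"central"` mode.
#' @return filtered `fragment_set`; attribute `bounds` records the bounds
#'   actually applied.
#' @export
size_filter <- function(fragments, low = 126, high = 184,
                        mode = c("explicit", "central"), mass = 0.95) {
  mode <- match.arg(mode)
  if (mode == "central") {
    b <- central_interval(size_distribution(fragments), mass)
    low <- b[1L]; high <- b[2L]
  }
  stopifnot(low <= high)
  len <- fragment_lengths(fragments)
  keep <- len >= low & len <= high
  out <- fragments[keep, , drop = FALSE]
  class(out) <- c("fragment_set", "data.frame")
  if (nrow(fragments) > 0L && nrow(out) == 0L)
    warning("size_filter removed every fragment")
  attr(out, "bounds") <- c(low = low, high = high)
  out
}

#' Remove duplicate fragments within each library
#'
#' A duplicate is a fragment with identical (library, chrom, start, end) to
#' one already seen; identical coordinates in different libraries are kept
#' (amplification duplicates arise within a library).
#'
#' @param fragments a [fragment_set()].
#' @return deduplicated `fragment_set` with attribute `n_removed`.
#' @export
remove_duplicates <- function(fragments) {
  key <- paste(fragments$library_id, fragments$chrom,
               fragments$start, fragments$end, sep = "\r")
  dup <- duplicated(key)
  out <- fragments[!dup, , drop = FALSE]
  class(out) <- c("fragment_set", "data.frame")
  attr(out, "n_removed") <- sum(dup)
  out
}

#' Construct a midpoint track
#'
#' @param counts named list of per-chromosome non-negative count vectors.
#' @param libraries character vector of contributing library ids.
#' @return object of class `midpoint_track`.
#' @export
midpoint_track <- function(counts, libraries = character()) {
  stopifnot(is.list(counts), !is.null(names(counts)))
  counts <- lapply(counts, as.numeric)
  if (any(unlist(lapply(counts, function(v) any(v < 0)))))
    stop("negative counts in midpoint track")
  out <- list(counts = counts,
              total = sum(unlist(lapply(counts, sum))),
              libraries = unique(libraries),
              seqlengths = vapply(counts, length, integer(1)))
  class(out) <- "midpoint_track"
  out
}

#' @export
print.midpoint_track <- function(x, ...) {
  cat(sprintf("<midpoint_track> %d chromosome(s), %.0f midpoints, libraries: %s\n",
              length(x$counts), x$total,
              paste(x$libraries, collapse = ",")))
  invisible(x)
}

#' Slice a midpoint track
#'
#' Counts over the 0-based half-open interval `[start, end)`; positions
#' beyond the chromosome are returned as zero.
#'
#' @param track a [midpoint_track()].
#' @param chrom chromosome name.
#' @param start,end interval bounds.
#' @return numeric vector of length `end - start`.
#' @export
track_slice <- function(track, chrom, start, end) {
  v <- track$counts[[chrom]]
  if (is.null(v)) return(numeric(end - start))
  idx <- (start + 1L):end
  ok <- idx >= 1L & idx <= length(v)
  out <- numeric(end - start)
  out[ok] <- v[idx[ok]]
  out
}

# elementwise sum of two midpoint tracks over the union of chromosomes
track_add <- function(a, b) {
  chroms <- union(names(a$counts), names(b$counts))
  counts <- lapply(stats::setNames(chroms, chroms), function(ch) {
    va <- a$counts[[ch]] %||% numeric(0)
    vb <- b$counts[[ch]] %||% numeric(0)
    n <- max(length(va), length(vb))
    length(va) <- n; length(vb) <- n
    va[is.na(va)] <- 0; vb[is.na(vb)] <- 0
    va + vb
  })
  midpoint_track(counts, c(a$libraries, b$libraries))
}

#' Infer dyad midpoints and accumulate a per-base track
#'
#' For paired fragments the dyad is the fragment midpoint,
#' `start + floor((length - 1) / 2)` (the left of the two central bases for
#' even lengths; deterministic and strand-independent).  For single-end
#' records the dyad is `single_end_offset` bp downstream of the 5' end on
#' the read's strand (minus strand: 5' end is the last aligned base).
#'
#' @param fragments a [fragment_set()].
#' @param seqlengths named integer vector of chromosome lengths.
#' @param mode `"paired"` or `"single_end"`.
#' @param single_end_offset dyad offset from the 5' end for single-end
#'   records (default 75, half a median-sized fragment).
#' @return a [midpoint_track()]; attribute `n_dropped` counts dyads falling
#'   outside their chromosome.
#' @export
compute_midpoints <- function(fragments, seqlengths,
                              mode = c("paired", "single_end"),
                              single_end_offset = 75) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    len <- fragment_lengths(fragments)
    mid <- fragments$start + (len - 1L) %/% 2L
  } else {
    plus <- fragments$strand != "-"
    mid <- ifelse(plus,
                  fragments$start + single_end_offset,
                  fragments$end - 1L - single_end_offset)
  }
  counts <- lapply(stats::setNames(names(seqlengths), names(seqlengths)),
                   function(ch) numeric(seqlengths[[ch]]))
  dropped <- 0L
  for (ch in unique(fragments$chrom)) {
    if (is.null(counts[[ch]])) { dropped <- dropped +
      sum(fragments$chrom == ch); next }
    m <- mid[fragments$chrom == ch]
    ok <- m >= 0L & m < seqlengths[[ch]]
    dropped <- dropped + sum(!ok)
    tab <- tabulate(m[ok] + 1L, nbins = seqlengths[[ch]])
    counts[[ch]] <- counts[[ch]] + tab
  }
  tr <- midpoint_track(counts, unique(fragments$library_id))
  attr(tr, "n_dropped") <- dropped
  tr
}

#' Midpoint positions of fragments (paired rule)
#' @param fragments a [fragment_set()].
#' @return integer vector of dyad positions (0-based).
#' @export
fragment_midpoints <- function(fragments) {
  fragments$start + (fragment_lengths(fragments) - 1L) %/% 2L
}
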