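# Plain-text track and table export.  All genomic files are 0-based
# half-open (BED / bedGraph); tables are TSV with '#' header comments
# recording units.

#' Write fragments as 6-column BED
#' @param fragments a [fragment_set()].
#' @param path output file.
#' @export
write_fragments_bed <- function(fragments, path) {
  # score column carries mapping quality; 255 = not recorded
  df <- data.frame(fragments$chrom, fragments$start, fragments$end,
                   fragments$library_id, 255L, fragments$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read fragments from a BED file
#' @param path BED file (chrom, start, end, name, score, strand).
#' @return a [fragment_set()].
#' @export
read_fragments_bed <- function(path) {
  load_fragments(path, min_mapq = -Inf)
}

#' Write a midpoint track as bedGraph
#'
#' Runs of equal counts are collapsed; zero runs are omitted.
#'
#' @param track a [midpoint_track()].
#' @param path output file.
#' @export
write_track_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$counts)) {
    v <- track$counts[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    df <- data.frame(ch, starts[keep], ends[keep], r$values[keep])
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Write a TSV with unit-recording header comments
#' @param df data.frame.
#' @param path output file.
#' @param comments character vector written as leading `#` lines.
#' @export
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE))
  invisible(path)
}

#' Write stranded nicks as BED
#' @param nicks data.frame with `chrom`, `pos`, `strand`.
#' @param path output file.
#' @export
write_nicks_bed <- function(nicks, path) {
  df <- data.frame(nicks$chrom, nicks$pos, nicks$pos + 1L, ".", 0L,
                   nicks$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
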