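# Genome sequences are carried internally as a named character vector
# (one element per chromosome).  FASTA input/output goes through Biostrings.

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of upper-case chromosome sequences.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(dss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome)
  names(dss) <- names(genome)
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome named character vector of sequences.
#' @return named integer vector.
#' @export
seq_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

# Extract sequence for a 0-based half-open interval (no bounds padding).
extract_seq <- function(genome, chrom, start, end) {
  substring(genome[[chrom]], start + 1L, end)
}

# Mappability masks are named lists of logical vectors (TRUE = mappable),
# or NULL meaning everything is mappable.
mask_slice <- function(mask, chrom, start, end) {
  if (is.null(mask)) return(rep(TRUE, end - start))
  m <- mask[[chrom]]
  idx <- (start + 1L):end
  ok <- idx >= 1L & idx <= length(m)
  out <- rep(FALSE, end - start)
  out[ok] <- m[idx[ok]]
  out
}

# genome-wide k-mer frequencies on the forward strand (pseudocounted)
genome_kmer_freq <- function(genome, k, pseudocount = 1) {
  km <- all_kmers(k)
  counts <- stats::setNames(numeric(length(km)), km)
  for (chrom in names(genome)) {
    oc <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString(genome[[chrom]]), width = k)
    counts[names(oc)] <- counts[names(oc)] + oc
  }
  counts <- counts + pseudocount
  counts / sum(counts)
}

# forward-strand occurrence counts of each k-mer (no pseudocount)
genome_kmer_counts <- function(genome, k) {
  km <- all_kmers(k)
  counts <- stats::setNames(numeric(length(km)), km)
  for (chrom in names(genome)) {
    oc <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAString(genome[[chrom]]), width = k)
    counts[names(oc)] <- counts[names(oc)] + oc
  }
  counts
}
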