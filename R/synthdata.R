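# Synthetic data with known ground truth: genomes (optionally containing
# tandem "container" repeats), planted nucleosome arrays and binding-site
# barriers, MNase fragment sets, stranded DNase nick tracks and genotype
# cohorts.  The generator realises the statistical structure the analyses
# assume -- truncated-normal fragment sizes, a major dyad position with
# 10-bp lattice minor positions, regularly spaced arrays, barrier-phased
# flanking arrays with genotype-dosage-scaled strength, and rotationally
# modulated DNase nicking -- and emits a truth catalogue for
# parameter-recovery tests.

#' Build a synthetic-data configuration
#'
#' Defaults emulate the measured fragment process: sizes ~
#' Normal(152, 11.5) truncated to 126-184 bp, arrays with repeat length
#' 190 bp and positioning strength 0.6, a 10-bp translational lattice with
#' decay 0.25, DNase nicking with 10.2-bp rotational period and a 2.5-bp
#' strand phase shift.
#'
#' @param genome_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param base_comp named base probabilities (A, C, G, T).
#' @param n_fragments total fragments to emit (across samples).
#' @param frag_size list with `mean`, `sd`, `min`, `max`.
#' @param arrays data.frame with `start`, `end` (0-based half-open),
#'   `nrl`, `strength`, or NULL.
#' @param barriers data.frame with `pos`, `nfr_width`, `strength`,
#'   `genotype_linked` (logical), or NULL.
#' @param n_flank nucleosomes planted on each side of a barrier.
#' @param lattice_decay geometric decay of the 10-bp minor positions.
#' @param fuzz_width half-width of the residual uniform dyad scatter.
#' @param background_frac fraction of fragments placed uniformly over
#'   mappable positions; NULL = the non-array fraction of the genome.
#' @param repeats list with `start`, `n_copies`, `unit_length`,
#'   `core_length`, `mutation_rate`, or NULL: plants a tandem array of
#'   GC-rich cores separated by AT-rich spacers (a container-element
#'   block).
#' @param unmappable data.frame with `start`, `end` of unmappable blocks,
#'   or NULL.
#' @param end_bias a `kmer_bias` table used to thin fragments by end
#'   composition, or NULL.
#' @param dnase list with `rate` (nicks per bp per strand), `period`,
#'   `phase_shift`, `amp` (rotational modulation depth), `linker_enrich`,
#'   `nfr_gain` (hypersensitivity boost at an active barrier NFR).
#' @param n_samples number of cell lines / libraries.
#' @param seed integer seed (mandatory; all outputs are reproducible from
#'   the config).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(genome_length = 1e6, chrom = "chr1",
                         base_comp = c(A = 0.295, C = 0.205,
                                       G = 0.205, T = 0.295),
                         n_fragments = 1e5,
                         frag_size = list(mean = 152, sd = 11.5,
                                          min = 126, max = 184),
                         arrays = NULL, barriers = NULL, n_flank = 5,
                         lattice_decay = 0.25, fuzz_width = 73,
                         background_frac = NULL, repeats = NULL,
                         unmappable = NULL, end_bias = NULL,
                         dnase = list(rate = 0.01, period = 10.2,
                                      phase_shift = 2.5, amp = 0.8,
                                      linker_enrich = 3, nfr_gain = 10),
                         n_samples = 1, seed) {
  if (missing(seed)) stop("synth_config requires a seed")
  if (!is.null(arrays)) {
    stopifnot(all(arrays$strength >= 0 & arrays$strength <= 1),
              all(arrays$nrl > 0))
    lat <- 1 + 2 * lattice_decay + 2 * lattice_decay^2
    if (any(arrays$strength * lat > 1 + 1e-9))
      stop("positioning strength incompatible with lattice decay: ",
           "strength * (1 + 2d + 2d^2) must not exceed 1")
  }
  if (!is.null(barriers)) {
    lat <- 1 + 2 * lattice_decay + 2 * lattice_decay^2
    stopifnot(all(barriers$strength >= 0))
    if (any(barriers$strength * lat > 1 + 1e-9))
      stop("barrier strength incompatible with lattice decay: ",
           "strength * (1 + 2d + 2d^2) must not exceed 1")
  }
  cfg <- list(genome_length = as.integer(genome_length), chrom = chrom,
              base_comp = base_comp, n_fragments = as.integer(n_fragments),
              frag_size = frag_size, arrays = arrays, barriers = barriers,
              n_flank = n_flank, lattice_decay = lattice_decay,
              fuzz_width = fuzz_width, background_frac = background_frac,
              repeats = repeats, unmappable = unmappable,
              end_bias = end_bias, dnase = dnase,
              n_samples = as.integer(n_samples),
              sample_ids = paste0("s", seq_len(n_samples)),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic genome, mappability mask and truth skeleton
#'
#' The sequence is i.i.d. under `base_comp`, with an optional planted
#' tandem-repeat block (GC-rich core + AT-rich spacer per copy, lightly
#' mutated so copies are degenerate).  The truth skeleton carries the
#' planted dyad catalogue: array nucleosomes at `start + nrl/2 + j*nrl`
#' within each array interval, and `n_flank` barrier-phased nucleosomes on
#' each side of every barrier (first dyad 74 bp outside the NFR edge).
#'
#' @param config a [synth_config()].
#' @return list with `genome` (named character), `mappability` (named
#'   list of logical vectors), `truth` (list: `dyads` data.frame with
#'   columns chrom, pos, kind, source, strength, nrl; `arrays`;
#'   `barriers`; `genotypes` dosage matrix for genotype-linked barriers).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  L <- config$genome_length
  bases <- names(config$base_comp)
  seqv <- sample(bases, L, replace = TRUE, prob = config$base_comp)
  if (!is.null(config$repeats)) {
    rp <- config$repeats
    core <- rp$core_length %||% 147L
    unit_len <- rp$unit_length %||% 188L
    mut <- rp$mutation_rate %||% 0.05
    spacer <- unit_len - core
    unit <- c(sample(bases, core, replace = TRUE,
                     prob = c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)),
              sample(bases, spacer, replace = TRUE,
                     prob = c(A = 0.4, C = 0.1, G = 0.1, T = 0.4)))
    block <- rep(unit, rp$n_copies)
    flip <- runif(length(block)) < mut
    block[flip] <- sample(bases, sum(flip), replace = TRUE)
    if (rp$start + length(block) > L)
      stop("repeat block exceeds the genome")
    seqv[(rp$start + 1L):(rp$start + length(block))] <- block
  }
  genome <- stats::setNames(paste(seqv, collapse = ""), config$chrom)
  mask <- rep(TRUE, L)
  if (!is.null(config$unmappable))
    for (i in seq_len(nrow(config$unmappable)))
      mask[(config$unmappable$start[i] + 1L):config$unmappable$end[i]] <- FALSE
  mappability <- stats::setNames(list(mask), config$chrom)
  truth <- .truth_skeleton(config)
  list(genome = genome, mappability = mappability, truth = truth)
}

.truth_skeleton <- function(config) {
  dy <- list()
  if (!is.null(config$arrays)) {
    for (i in seq_len(nrow(config$arrays))) {
      a <- config$arrays[i, ]
      pos <- seq(a$start + round(a$nrl / 2), a$end - round(a$nrl / 2),
                 by = a$nrl)
      dy[[length(dy) + 1L]] <- data.frame(
        chrom = config$chrom, pos = as.integer(pos), kind = "array",
        source = i, strength = a$strength, nrl = a$nrl,
        stringsAsFactors = FALSE)
    }
  }
  genotypes <- NULL
  if (!is.null(config$barriers)) {
    nb <- nrow(config$barriers)
    for (i in seq_len(nb)) {
      b <- config$barriers[i, ]
      nrl <- b$nrl %||% 190
      half <- round(b$nfr_width / 2)
      offs <- half + 74 + (seq_len(config$n_flank) - 1L) * nrl
      pos <- c(b$pos - rev(offs), b$pos + offs)
      dy[[length(dy) + 1L]] <- data.frame(
        chrom = config$chrom, pos = as.integer(pos), kind = "barrier",
        source = i, strength = b$strength, nrl = nrl,
        stringsAsFactors = FALSE)
    }
    linked <- which(config$barriers$genotype_linked %||% rep(FALSE, nb))
    if (length(linked)) {
      # dosages cycle 2/1/0 across samples, rotated per barrier so each
      # barrier sees every class when n_samples >= 3
      genotypes <- matrix(0L, nb, config$n_samples,
                          dimnames = list(NULL, config$sample_ids))
      for (i in linked)
        genotypes[i, ] <- rep(c(2L, 1L, 0L),
                              length.out = config$n_samples +
                                (i - 1L))[i:(i + config$n_samples - 1L)]
    }
  }
  dyads <- if (length(dy)) do.call(rbind, dy) else
    data.frame(chrom = character(), pos = integer(), kind = character(),
               source = integer(), strength = numeric(), nrl = numeric())
  dyads <- dyads[dyads$pos - 73 >= 0 &
                 dyads$pos + 73 < config$genome_length, , drop = FALSE]
  rownames(dyads) <- NULL
  linked <- if (!is.null(config$barriers))
    (config$barriers$genotype_linked %||%
       rep(FALSE, nrow(config$barriers))) else logical(0)
  list(dyads = dyads, arrays = config$arrays, barriers = config$barriers,
       genotypes = genotypes, linked = linked)
}

# dyad offsets and probabilities for one nucleosome: major + 10-bp lattice
# + uniform fuzz
.dyad_offset_sample <- function(n, strength, decay, fuzz_width) {
  d <- decay
  pk <- strength * c(1, d, d, d^2, d^2)
  offs <- c(0L, -10L, 10L, -20L, 20L)
  p_fuzz <- max(0, 1 - sum(pk))
  comp <- sample.int(6L, n, replace = TRUE, prob = c(pk, p_fuzz))
  out <- integer(n)
  lattice <- comp <= 5L
  out[lattice] <- offs[comp[lattice]]
  nf <- sum(!lattice)
  if (nf) out[!lattice] <- sample.int(2L * fuzz_width + 1L, nf,
                                      replace = TRUE) - fuzz_width - 1L
  out
}

#' Generate synthetic MNase fragments
#'
#' Fragments are allocated between planted nucleosomes and a uniform
#' background.  Each nucleosomal fragment draws its dyad from the
#' major/lattice/fuzz mixture of its nucleosome, then a truncated-normal
#' length, and the fragment is centred on the dyad (so its midpoint
#' recovers the dyad exactly).  Barrier nucleosomes that are
#' genotype-linked scale their positioning strength by the sample's
#' allele dosage (2/1/0 -> full/half/none), and samples with dosage 0
#' receive no barrier phasing at all (their dyads scatter uniformly over
#' one repeat length).  Fragments are split across `n_samples` libraries.
#'
#' @param config a [synth_config()].
#' @param world output of [generate_genome()] (for the mask and truth).
#' @return list with `fragments` (a [fragment_set()] with per-sample
#'   `library_id`) and `truth` (the input truth plus per-nucleosome
#'   fragment counts).
#' @export
generate_fragments <- function(config, world) {
  set.seed(config$seed + 1L)
  truth <- world$truth
  L <- config$genome_length
  fs <- config$frag_size
  dyads <- truth$dyads
  n_nuc <- nrow(dyads)
  bg_frac <- config$background_frac
  if (is.null(bg_frac)) {
    covered <- if (n_nuc) min(1, sum(n_nuc * 190) / L) else 0
    bg_frac <- 1 - covered
  }
  n_total <- config$n_fragments
  n_bg <- rbinom(1L, n_total, bg_frac)
  n_pos <- n_total - n_bg
  samp <- sample(config$sample_ids, n_total, replace = TRUE)
  out_pos <- NULL
  nuc_counts <- integer(n_nuc)
  if (n_pos > 0 && n_nuc > 0) {
    pick <- sample.int(n_nuc, n_pos, replace = TRUE)
    nuc_counts <- tabulate(pick, nbins = n_nuc)
    strength <- dyads$strength[pick]
    sample_of <- samp[seq_len(n_pos)]
    # genotype scaling for linked barrier nucleosomes
    if (!is.null(truth$genotypes)) {
      is_b <- dyads$kind[pick] == "barrier" &
        truth$linked[dyads$source[pick]]
      if (any(is_b)) {
        dos <- truth$genotypes[cbind(dyads$source[pick[is_b]],
                                     match(sample_of[is_b],
                                           colnames(truth$genotypes)))]
        strength[is_b] <- strength[is_b] * dos / 2
      }
    }
    offset <- integer(n_pos)
    for (s in unique(strength)) {
      i <- which(strength == s)
      offset[i] <- .dyad_offset_sample(length(i), s, config$lattice_decay,
                                       config$fuzz_width)
    }
    # dosage-0 barrier nucleosomes: scatter over one repeat length
    zero <- strength == 0 & dyads$kind[pick] == "barrier"
    if (any(zero)) {
      hw <- as.integer(round(dyads$nrl[pick][zero] / 2))
      offset[zero] <- as.integer(floor(runif(sum(zero)) * (2 * hw + 1))) - hw
    }
    dy <- dyads$pos[pick] + offset
    len <- rtruncnorm_int(n_pos, fs$mean, fs$sd, fs$min, fs$max)
    start <- dy - (len - 1L) %/% 2L
    end <- start + len
    keep <- start >= 0L & end <= L
    out_pos <- data.frame(chrom = config$chrom, start = start[keep],
                          end = end[keep],
                          library_id = sample_of[keep],
                          stringsAsFactors = FALSE)
  }
  out_bg <- NULL
  if (n_bg > 0) {
    len <- rtruncnorm_int(n_bg, fs$mean, fs$sd, fs$min, fs$max)
    start <- as.integer(floor(runif(n_bg) * (L - len)))
    end <- start + len
    mask <- world$mappability[[config$chrom]]
    keep <- mask[start + 1L] & mask[end]
    out_bg <- data.frame(chrom = config$chrom, start = start[keep],
                         end = end[keep],
                         library_id = samp[n_pos + seq_len(n_bg)][keep],
                         stringsAsFactors = FALSE)
  }
  df <- rbind(out_pos, out_bg)
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer(),
                                    library_id = character())
  if (!is.null(config$end_bias)) {
    w <- .end_bias_weight(df, world$genome, config$end_bias)
    keep <- runif(nrow(df)) * max(w) < w
    df <- df[keep, , drop = FALSE]
  }
  truth$nucleosome_counts <- nuc_counts
  list(fragments = fragment_set(df), truth = truth)
}

.end_bias_weight <- function(df, genome, bias) {
  km <- all_kmers(4L)
  w <- numeric(nrow(df))
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    lk <- substring(genome[[ch]], df$start[i] + 1L, df$start[i] + 4L)
    rk <- substring(genome[[ch]], df$end[i] - 3L, df$end[i])
    wl <- bias$left[lk]; wr <- bias$right[rk]
    wl[is.na(wl)] <- 0; wr[is.na(wr)] <- 0
    w[i] <- wl * wr
  }
  w
}

#' Generate stranded DNase nick tracks, dsQTL and summit tables
#'
#' Per-sample nick counts are Poisson draws from an intensity that is
#' `rate * linker_enrich` in linker DNA, rotationally modulated inside
#' nucleosome footprints (`rate * (1 + amp cos(2 pi (offset - shift) /
#' period))`, with the minus strand shifted downstream by `phase_shift`
#' bp), and boosted at active barrier NFRs in proportion to allele dosage
#' (`rate * linker_enrich * (1 + nfr_gain * dosage / 2)`).
#'
#' @param config a [synth_config()].
#' @param world output of [generate_genome()].
#' @return list with `nicks` (named per-sample list of
#'   `list(plus, minus)` [midpoint_track()]s), `dsqtls` (data.frame id,
#'   chrom, pos, snp_pos plus one dosage column per sample), `summits`
#'   (data.frame chrom, pos), `truth`.
#' @export
generate_dnase_and_genotypes <- function(config, world) {
  set.seed(config$seed + 2L)
  truth <- world$truth
  L <- config$genome_length
  dn <- config$dnase
  dyads <- truth$dyads
  base_plus <- rep(dn$rate * dn$linker_enrich, L)
  base_minus <- base_plus
  if (nrow(dyads)) {
    shared <- dyads$kind == "array"
    mod <- .rotational_intensity(dyads[shared, , drop = FALSE], L, dn)
    base_plus[mod$idx] <- mod$plus
    base_minus[mod$idx] <- mod$minus
  }
  nicks <- list()
  for (si in seq_len(config$n_samples)) {
    sm <- config$sample_ids[si]
    ip <- base_plus; im <- base_minus
    if (!is.null(config$barriers) && nrow(config$barriers)) {
      for (bi in seq_len(nrow(config$barriers))) {
        b <- config$barriers[bi, ]
        dos <- if (!is.null(truth$genotypes) &&
                   isTRUE(config$barriers$genotype_linked[bi]))
          truth$genotypes[bi, sm] else 2L
        half <- round(b$nfr_width / 2)
        idx <- max(1L, b$pos - half + 1L):min(L, b$pos + half)
        boost <- dn$rate * dn$linker_enrich * (1 + dn$nfr_gain * dos / 2)
        ip[idx] <- boost; im[idx] <- boost
        # barrier flanking footprints: rotational modulation scaled by dosage
        bd <- dyads[dyads$kind == "barrier" & dyads$source == bi, ,
                    drop = FALSE]
        if (nrow(bd) && dos > 0) {
          m2 <- .rotational_intensity(bd, L, dn, depth = dos / 2)
          ip[m2$idx] <- m2$plus; im[m2$idx] <- m2$minus
        }
      }
    }
    counts_p <- rpois(L, ip)
    counts_m <- rpois(L, im)
    nicks[[sm]] <- list(
      plus = midpoint_track(stats::setNames(list(counts_p), config$chrom),
                            sm),
      minus = midpoint_track(stats::setNames(list(counts_m), config$chrom),
                             sm))
  }
  dsqtls <- NULL; summits <- NULL
  if (!is.null(config$barriers) && nrow(config$barriers)) {
    summits <- data.frame(chrom = config$chrom, pos = config$barriers$pos)
    linked <- which(config$barriers$genotype_linked %||%
                    rep(FALSE, nrow(config$barriers)))
    if (length(linked)) {
      dsqtls <- data.frame(id = paste0("dsq", linked),
                           chrom = config$chrom,
                           pos = config$barriers$pos[linked],
                           snp_pos = config$barriers$pos[linked])
      dsqtls <- cbind(dsqtls, truth$genotypes[linked, , drop = FALSE])
    }
  }
  list(nicks = nicks, dsqtls = dsqtls, summits = summits, truth = truth)
}

# rotational nick intensity within the footprints of a set of dyads;
# returns modified indices and per-strand intensities
.rotational_intensity <- function(dyads, L, dn, depth = 1) {
  offs <- -73:73
  idx_all <- outer(dyads$pos, offs, "+") + 1L
  off_all <- matrix(rep(offs, each = nrow(dyads)), nrow(dyads))
  ok <- idx_all >= 1L & idx_all <= L
  idx <- as.vector(idx_all[ok]); off <- as.vector(off_all[ok])
  plus <- dn$rate * (1 + depth * dn$amp * cos(2 * pi * off / dn$period))
  minus <- dn$rate * (1 + depth * dn$amp *
                        cos(2 * pi * (off - dn$phase_shift) / dn$period))
  # collapse duplicate indices (overlapping footprints): keep last write
  list(idx = idx, plus = plus, minus = minus)
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_genome()], [generate_fragments()] and
#' [generate_dnase_and_genotypes()] under one configuration.
#'
#' @param config a [synth_config()].
#' @return list: `genome`, `mappability`, `truth`, `fragments`, `nicks`,
#'   `dsqtls`, `summits`, `config`.
#' @export
generate_dataset <- function(config) {
  world <- generate_genome(config)
  fr <- generate_fragments(config, world)
  world$truth <- fr$truth
  dg <- generate_dnase_and_genotypes(config, world)
  list(genome = world$genome, mappability = world$mappability,
       truth = dg$truth, fragments = fr$fragments, nicks = dg$nicks,
       dsqtls = dg$dsqtls, summits = dg$summits, config = config)
}
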