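# Multinomial array-template model: LLR statistic, template training,
# window testing, genome scanning, permutation FDR, flanking fits.

test_that("array LLR matches term-by-term evaluation and is linear in counts", {
  tmpl <- array_template(c(0.4, 0.3, 0.2, 0.1), floor = 1e-12)
  x <- c(4, 3, 2, 1)
  manual <- 4 * log(0.4 * 4) + 3 * log(0.3 * 4) + 2 * log(0.2 * 4) +
    1 * log(0.1 * 4)
  expect_equal(array_llr(x, tmpl), manual, tolerance = 1e-12)
  expect_equal(array_llr(x, tmpl), 1.0644, tolerance = 1e-4)
  expect_equal(array_llr(c(10, 0, 0, 0), tmpl), 10 * log(1.6),
               tolerance = 1e-12)

  unif <- array_template(rep(1, 100), floor = 1e-9)
  set.seed(61)
  expect_equal(array_llr(rpois(100, 3), unif), 0, tolerance = 1e-10)

  for (i in 1:100) {
    k <- sample(5:50, 1)
    tm <- array_template(runif(k) + 0.01, floor = 1e-9)
    xx <- rpois(k, 4)
    expect_equal(array_llr(xx, tm), brute_llr(xx, tm$probs),
                 tolerance = 1e-10)
    cc <- runif(1, 0.5, 5)
    expect_equal(array_llr(cc * xx, tm), cc * array_llr(xx, tm),
                 tolerance = 1e-10)
  }
  expect_error(array_llr(c(-1, 1, 1, 1), tmpl), "negative")
})

test_that("templates are normalised, floored and optionally symmetric", {
  set.seed(62)
  for (i in 1:20) {
    p <- runif(200)
    p[sample(200, 5)] <- 0
    tm <- array_template(p, symmetric = i %% 2 == 0)
    expect_lt(abs(sum(tm$probs) - 1), 1e-12)
    expect_true(all(tm$probs >= tm$floor / 2))
    if (tm$symmetric) expect_equal(tm$probs, rev(tm$probs))
  }
})

test_that("training recovers a known template and forces symmetry on mirrored input", {
  truth <- default_array_template(k = 400, n_nuc = 3, nrl = 120, sd = 15)
  set.seed(63)
  regions <- lapply(1:120, function(i) {
    o <- sample(0:100, 1)
    tabulate(o + sample.int(400, 1500, replace = TRUE,
                            prob = truth$probs), nbins = 500)
  })
  init <- default_array_template(k = 400, n_nuc = 3, nrl = 115, sd = 25)
  fit <- train_template(regions, init, max_iter = 40, tol = 1e-4)
  expect_lt(sum(abs(fit$probs - truth$probs)), 0.05)
  expect_true(fit$provenance$converged)

  mirrored <- c(regions[1:30], lapply(regions[1:30], rev))
  fit2 <- train_template(mirrored, init, max_iter = 15, tol = 1e-3)
  expect_identical(fit2$probs, rev(fit2$probs))
})

test_that("trained template spacing matches the generating repeat length", {
  truth <- default_array_template(k = 879, n_nuc = 5, nrl = 190, sd = 18)
  set.seed(64)
  regions <- lapply(1:150, function(i) {
    o <- sample(0:121, 1)
    tabulate(o + sample.int(879, 1500, replace = TRUE,
                            prob = truth$probs), nbins = 1000)
  })
  fit <- train_template(regions, default_array_template(k = 879, nrl = 186),
                        max_iter = 40, tol = 1e-4)
  # autocovariance of the learned template peaks at the repeat length
  p <- fit$probs - mean(fit$probs)
  ac <- vapply(150:230, function(l)
    sum(p[1:(879 - l)] * p[(l + 1):879]), numeric(1))
  expect_equal((150:230)[which.max(ac)], 190, tolerance = 2)
})

test_that("test_region is translation-equivariant and recovers planted offsets", {
  tmpl <- default_array_template(k = 400, n_nuc = 3, nrl = 120, sd = 15)
  set.seed(65)
  # zero tail so shifting within the window loses no counts
  x <- tabulate(sample.int(920, 800, replace = TRUE), nbins = 1000)
  r1 <- test_region(x, tmpl, slide = c(-100, 120))
  x_sh <- c(numeric(37), x)[1:1000]
  r2 <- test_region(x_sh, tmpl, slide = c(-100, 120) + 37)
  expect_equal(r2$llr, r1$llr, tolerance = 1e-8)
  expect_equal(r2$best_offset, r1$best_offset + 37)

  # counts drawn from the template at a known offset
  true_off <- 40
  probs <- tmpl$probs
  start <- 500 + true_off - 200  # template midpoint at wmid + true_off
  y <- tabulate(start - 1 + sample.int(400, 3000, replace = TRUE,
                                       prob = probs), nbins = 1000)
  r4 <- test_region(y, tmpl, slide = c(-100, 200))
  expect_lte(abs(r4$best_offset - true_off), 2)

  z <- test_region(numeric(1000), tmpl)
  expect_equal(z$llr, 0)
  expect_true(z$zero)
})

test_that("uniform windows do not produce large LLR maxima", {
  tmpl <- default_array_template(k = 879, nrl = 190)
  set.seed(66)
  llrs <- vapply(1:200, function(i) {
    x <- tabulate(sample.int(1000, 900, replace = TRUE), nbins = 1000)
    test_region(x, tmpl)$llr
  }, numeric(1))
  expect_lt(median(llrs), 5)
})

test_that("genome scan finds a planted array and merges overlapping windows", {
  arr <- data.frame(start = 20000, end = 30000, nrl = 190, strength = 0.6)
  cfg <- synth_config(genome_length = 50000, n_fragments = 50000,
                      arrays = arr, lattice_decay = 0.2,
                      background_frac = 0.6, seed = 67)
  ds <- generate_dataset(cfg)
  tr <- compute_midpoints(ds$fragments, seq_lengths(ds$genome))
  tmpl <- default_array_template(nrl = 190)
  hits <- scan_genome(tr, tmpl, step = 5, llr_min = 50,
                      min_midpoints = 300)
  expect_equal(nrow(hits), 1L)
  ov <- min(hits$end, 30000) - max(hits$start, 20000)
  expect_gte(ov / 10000, 0.8)
  # merged intervals are disjoint by construction
  if (nrow(hits) > 1)
    expect_true(all(hits$start[-1] >= head(hits$end, -1)))

  # matched-density uniform genome: nothing survives
  cfg0 <- synth_config(genome_length = 50000, n_fragments = 50000,
                       background_frac = 1, seed = 68)
  ds0 <- generate_dataset(cfg0)
  tr0 <- compute_midpoints(ds0$fragments, seq_lengths(ds0$genome))
  hits0 <- scan_genome(tr0, tmpl, step = 5, llr_min = 50,
                       min_midpoints = 300)
  expect_equal(nrow(hits0), 0L)
})

test_that("FDR table arithmetic and permutation count conservation", {
  tab <- nucarray:::.fdr_table(obs = c(60, 40, 10, 5),
                               perm = c(12, 8, 6, 3), n_perm = 1)
  expect_equal(tab$fdr[tab$threshold == 10], 1 / 3)
  # monotone non-increasing in threshold
  expect_true(all(diff(tab$fdr) <= 1e-12))

  set.seed(69)
  single <- single_nucleosome_template()
  for (scheme in c("full", "keep_two")) {
    for (i in 1:20) {
      x <- tabulate(sample.int(500, 300, replace = TRUE), nbins = 500)
      px <- nucarray:::.permute_region(x, scheme, single)
      expect_equal(sum(px), sum(x))
      expect_equal(sort(px), sort(x))
    }
  }
})

test_that("flanking fit recovers the degenerate zero-width NFR and flags flat fits", {
  ht <- flanking_templates(nrl = 190)
  bar <- data.frame(pos = 4000, nfr_width = 0, strength = 0.6,
                    genotype_linked = FALSE, nrl = 190)
  cfg <- synth_config(genome_length = 8000, n_fragments = 20000,
                      barriers = bar, background_frac = 0.1,
                      lattice_decay = 0.2, seed = 70)
  ds <- generate_dataset(cfg)
  tr <- compute_midpoints(ds$fragments, seq_lengths(ds$genome))
  x <- track_slice(tr, "chr1", 4000 - 1600, 4000 + 1600)
  ft <- fit_flanking_arrays(x, summit = 1601, ht)
  expect_lte(ft$nfr_width, 10)

  flat <- fit_flanking_arrays(rep(2, 2300), summit = 1150, ht)
  expect_true(flat$flat)
})

test_that("occupancy stratification is rank-based and pools factors fairly", {
  ht <- flanking_templates(nrl = 190, length = 300, edge_offset = 74)
  mkfit <- function() {
    f <- list(edge_up = 500L, edge_down = 560L)
    class(f) <- "flanking_fit"
    f
  }
  profiles <- replicate(20, rpois(1100, 2), simplify = FALSE)
  fits <- replicate(20, mkfit(), simplify = FALSE)
  # one factor, occupancies 1..10 -> bins of size 2 in rank order
  s1 <- stratify_and_aggregate(profiles[1:10], fits[1:10], occupancy = 1:10,
                               factor = rep("F1", 10), n_bins = 5,
                               flank_out = 200)
  expect_equal(as.numeric(table(s1$bin)), rep(2, 5))
  expect_equal(s1$bin, rep(1:5, each = 2))
  # two factors with disjoint scales -> equal counts from each per bin
  occ <- c(1:10, 1001:1010)
  fac <- rep(c("F1", "F2"), each = 10)
  s2 <- stratify_and_aggregate(profiles, fits, occ, fac, n_bins = 5,
                               flank_out = 200)
  for (b in 1:5)
    expect_equal(sum(s2$bin == b & fac == "F1"),
                 sum(s2$bin == b & fac == "F2"))
  # small factor excluded with a warning
  expect_warning(
    s3 <- stratify_and_aggregate(profiles[1:12], fits[1:12],
                                 occupancy = c(1:10, 1, 2),
                                 factor = c(rep("F1", 10), "F2", "F2"),
                                 n_bins = 5, flank_out = 200),
    "excluded")
  expect_true(all(is.na(s3$bin[11:12])))
})
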