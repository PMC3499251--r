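# End-composition bias learning, the bias-matched simulator, DNase nick
# bias, and observed/expected normalisation.

test_that("end 4-mer tables match a hand count on a toy genome", {
  genome <- c(chr1 = "ACGTACGTTTAACCGGATCGATCGTTTTAAAACCCCGGGGACGTACGTAAATTTCCCGGG")
  set.seed(3)
  start <- sample(0:40, 10, replace = TRUE)
  fs <- frags(start, start + 20L)
  tab <- learn_end_kmer_bias(fs, genome, pseudocount = 1)
  # independent tabulation with substr + table
  km <- sort(apply(expand.grid(b1 = c("A","C","G","T"), b2 = c("A","C","G","T"),
                               b3 = c("A","C","G","T"), b4 = c("A","C","G","T"),
                               stringsAsFactors = FALSE)[, 4:1], 1,
                   paste0, collapse = ""))
  lk <- vapply(start, function(s) substr(genome[[1]], s + 1, s + 4), "")
  rk <- vapply(start, function(s) substr(genome[[1]], s + 17, s + 20), "")
  exp_left <- (table(factor(lk, levels = km)) + 1)
  exp_left <- as.numeric(exp_left / sum(exp_left))
  exp_right <- (table(factor(rk, levels = km)) + 1)
  exp_right <- as.numeric(exp_right / sum(exp_right))
  expect_equal(unname(tab$left), exp_left, tolerance = 1e-12)
  expect_equal(unname(tab$right), exp_right, tolerance = 1e-12)
  expect_equal(sum(tab$left), 1)
  expect_equal(sum(tab$right), 1)
})

test_that("a single shared start 4-mer dominates the left table", {
  genome <- c(chr1 = paste0(strrep("ACGT", 100)))
  starts <- seq(0, 80, by = 4)   # every fragment starts with ACGT
  fs <- frags(starts, starts + 20L)
  tab <- learn_end_kmer_bias(fs, genome)
  expect_equal(names(which.max(tab$left)), "ACGT")
  # with pseudocount 1 over 256 cells: (n + 1) / (n + 256)
  n <- length(starts)
  expect_equal(max(tab$left), (n + 1) / (n + 256))
})

test_that("the simulator is reproducible and accepts everything under a null bias", {
  set.seed(9)
  genome <- c(chr1 = paste(sample(c("A","C","G","T"), 20000, replace = TRUE),
                           collapse = ""))
  sdist <- structure(list(length = 140:160, count = rep(1L, 21), n = 21),
                     class = "size_distribution")
  a <- simulate_fragments(genome, sdist, n = 2000, seed = 42)
  b <- simulate_fragments(genome, sdist, n = 2000, seed = 42)
  expect_identical(a$start, b$start)
  expect_identical(a$end, b$end)
  expect_gte(attr(a, "acceptance_rate"), 0.95)

  # uniform bias table: acceptance weight is constant, rate stays ~1
  km <- nucarray:::all_kmers(4)
  prop <- nucarray:::genome_kmer_freq(genome, 4)
  unif_bias <- structure(list(left = prop, right = prop, pseudocount = 1),
                         class = "kmer_bias")
  u <- simulate_fragments(genome, sdist, bias = unif_bias, n = 2000,
                          seed = 43)
  expect_gte(attr(u, "acceptance_rate"), 0.90)
})

test_that("rejection sampling recovers a 2:1 AAAA-biased left-end target", {
  set.seed(10)
  genome <- c(chr1 = paste(sample(c("A","C","G","T"), 3e5, replace = TRUE),
                           collapse = ""))
  prop <- nucarray:::genome_kmer_freq(genome, 4)
  tgt <- prop
  tgt["AAAA"] <- 2 * tgt["AAAA"]
  tgt <- tgt / sum(tgt)
  bias <- structure(list(left = tgt, right = prop, pseudocount = 1),
                    class = "kmer_bias")
  sdist <- structure(list(length = 147L, count = 1L, n = 1L),
                     class = "size_distribution")
  sim <- simulate_fragments(genome, sdist, bias = bias, n = 1e5, seed = 77)
  emp <- learn_end_kmer_bias(sim, genome, pseudocount = 0)
  expect_lt(abs(emp$left[["AAAA"]] - tgt[["AAAA"]]), 0.01)
})

test_that("simulated fragments respect the mappability mask", {
  set.seed(12)
  genome <- c(chr1 = paste(sample(c("A","C","G","T"), 10000, replace = TRUE),
                           collapse = ""))
  mask <- rep(TRUE, 10000); mask[3000:4000] <- FALSE
  sdist <- structure(list(length = 147L, count = 1L, n = 1L),
                     class = "size_distribution")
  sim <- simulate_fragments(genome, sdist, n = 3000, seed = 5,
                            mappability = list(chr1 = mask))
  expect_true(all(mask[sim$start + 1]))
  expect_true(all(mask[sim$end]))
})

test_that("DNase 6-mer rates equal a hand-computed table and conserve nicks", {
  set.seed(14)
  genome <- c(chr1 = paste(sample(c("A","C","G","T"), 200, replace = TRUE),
                           collapse = ""))
  nicks <- data.frame(chrom = "chr1",
                      pos = sample(10:190, 20, replace = TRUE),
                      strand = sample(c("+", "-"), 20, replace = TRUE))
  tab <- learn_dnase_bias(nicks, genome)
  # independent context read-out
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  ctx <- vapply(seq_len(20), function(i) {
    p <- nicks$pos[i]
    if (nicks$strand[i] == "+") substr(genome[[1]], p - 2, p + 3)
    else rc(substr(genome[[1]], p - 1, p + 4))
  }, "")
  for (k in unique(ctx)) {
    occ_f <- length(gregexpr(k, genome[[1]], fixed = TRUE)[[1]])
    occ_f <- sum(gregexpr(paste0("(?=", k, ")"), genome[[1]],
                          perl = TRUE)[[1]] > 0)
    occ_r <- sum(gregexpr(paste0("(?=", rc(k), ")"), genome[[1]],
                          perl = TRUE)[[1]] > 0)
    expect_equal(tab$rate[[k]], sum(ctx == k) / (occ_f + occ_r))
  }
  # conservation: sum(rate * occurrences) equals the nicks used
  used <- sum(tab$rate * tab$genome_count[names(tab$rate)])
  expect_equal(used, tab$n_nicks_used)
})

test_that("log2 observed/expected normalisation", {
  x <- c(1, 2, 3)
  expect_equal(as.numeric(normalize_by_expected(x, x)), c(0, 0, 0))
  expect_equal(as.numeric(normalize_by_expected(2 * x, x)), c(1, 1, 1))
  expect_equal(as.numeric(normalize_by_expected(c(1, 4), c(2, 2))),
               c(-1, 1))
  expect_error(normalize_by_expected(1:3, 1:4), "length")
})

test_that("simulated sizes match the sampled distribution (chi-square GOF)", {
  set.seed(16)
  genome <- c(chr1 = paste(sample(c("A","C","G","T"), 50000, replace = TRUE),
                           collapse = ""))
  lens <- 126:184
  wt <- dnorm(lens, 152, 11.5)
  sdist <- structure(list(length = lens,
                          count = as.integer(round(wt * 1e5)),
                          n = sum(round(wt * 1e5))),
                     class = "size_distribution")
  sim <- simulate_fragments(genome, sdist, n = 2e4, seed = 6)
  obs <- table(factor(sim$end - sim$start, levels = lens))
  p <- sdist$count / sum(sdist$count)
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = p))
  expect_gt(gof$p.value, 0.01)
})
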