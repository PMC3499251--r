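# Fragment ingestion, size filtering, dyad midpoints, deduplication.

test_that("load_fragments applies the mapping-quality filter and handles empty input", {
  df <- data.frame(chrom = "chr1", start = c(1000, 5000), end = c(1152, 5147),
                   library_id = "A", mapq = c(30, 5))
  fs <- load_fragments(df, min_mapq = 10)
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$start, 1000L)
  expect_equal(fs$end, 1152L)
  expect_equal(attr(fs, "skipped")[["low_mapq"]], 1L)

  empty_bed <- withr::local_tempfile(fileext = ".bed")
  file.create(empty_bed)
  fs0 <- load_fragments(empty_bed)
  expect_s3_class(fs0, "fragment_set")
  expect_equal(nrow(fs0), 0L)
})

test_that("load_fragments round-trips a BED file", {
  bed <- withr::local_tempfile(fileext = ".bed")
  fs <- frags(c(100L, 300L), c(247L, 452L), lib = c("A", "B"))
  write_fragments_bed(fs, bed)
  back <- load_fragments(bed)
  expect_equal(back$start, fs$start)
  expect_equal(back$end, fs$end)
  expect_equal(back$library_id, fs$library_id)
})

test_that("size_filter keeps the closed interval and is idempotent", {
  fs <- frags(rep(0L, 4), c(125L, 126L, 184L, 185L))
  kept <- size_filter(fs, 126, 184)
  expect_equal(sort(kept$end - kept$start), c(126L, 184L))
  expect_equal(attr(kept, "bounds"), c(low = 126, high = 184))

  # scoring subset bounds
  fs2 <- frags(rep(0L, 4), c(141L, 142L, 152L, 153L))
  kept2 <- size_filter(fs2, 142, 152)
  expect_equal(sort(kept2$end - kept2$start), c(142L, 152L))

  # identity on already-conforming input, and idempotence
  fs3 <- frags(rep(0L, 5), rep(147L, 5))
  expect_equal(nrow(size_filter(fs3, 126, 184)), 5L)
  once <- size_filter(fs, 126, 184)
  twice <- size_filter(once, 126, 184)
  expect_equal(twice$end, once$end)

  expect_warning(size_filter(frags(0L, 300L), 126, 184), "every fragment")
})

test_that("central-mass bounds converge to the quantile oracle on truncated-normal sizes", {
  set.seed(401)
  len <- integer(0)
  while (length(len) < 1e5) {
    d <- round(rnorm(2e5, 152, 11.5))
    len <- c(len, d[d >= 100 & d <= 200])
  }
  len <- len[seq_len(1e5)]
  fs <- frags(rep(0L, length(len)), len)
  kept <- size_filter(fs, mode = "central", mass = 0.95)
  b <- attr(kept, "bounds")
  oracle <- quantile(len, c(0.025, 0.975), type = 1, names = FALSE)
  expect_lte(abs(b[["low"]] - oracle[1]), 2)
  expect_lte(abs(b[["high"]] - oracle[2]), 2)
  # theoretical central interval of Normal(152, 11.5): about [130, 175]
  expect_lte(abs(b[["low"]] - 129.5), 2)
  expect_lte(abs(b[["high"]] - 174.5), 2)
})

test_that("paired midpoints follow the left-of-centre rule and conserve totals", {
  fs <- frags(c(1000L, 1000L), c(1147L, 1152L))
  expect_equal(fragment_midpoints(fs), c(1073L, 1075L))

  # brute-force centre enumeration oracle for assorted lengths
  set.seed(11)
  for (i in 1:50) {
    s <- sample(0:5000, 1); L <- sample(120:200, 1)
    covered <- s:(s + L - 1)
    oracle_mid <- covered[floor((L + 1) / 2)]
    f1 <- frags(s, s + L)
    m <- fragment_midpoints(f1)
    expect_identical(m, oracle_mid)
    expect_true(m >= s && m < s + L)
  }

  tr <- compute_midpoints(fs, c(chr1 = 5000L))
  expect_equal(tr$total, 2)
  expect_equal(which(tr$counts$chr1 > 0) - 1L, c(1073L, 1075L))
})

test_that("single-end midpoints are strand-aware", {
  fs <- fragment_set(data.frame(
    chrom = "chr1", start = c(2000L, 3000L), end = c(2025L, 3025L),
    library_id = "A", strand = c("+", "-")))
  tr <- compute_midpoints(fs, c(chr1 = 5000L), mode = "single_end",
                          single_end_offset = 75)
  pos <- which(tr$counts$chr1 > 0) - 1L
  expect_true(2075L %in% pos)            # 5' + 75 on the plus strand
  expect_true((3025L - 1L - 75L) %in% pos)  # 5' is the last aligned base
})

test_that("midpoints outside the chromosome are dropped and counted", {
  fs <- frags(c(10L, 4990L), c(157L, 5137L))
  tr <- compute_midpoints(fs, c(chr1 = 5000L))
  expect_equal(tr$total, 1)
  expect_equal(attr(tr, "n_dropped"), 1L)
})

test_that("deduplication is per-library", {
  fs <- fragment_set(data.frame(
    chrom = "chr1",
    start = c(10L, 10L, 10L, 50L, 50L),
    end = c(157L, 157L, 157L, 197L, 197L),
    library_id = c("A", "A", "B", "A", "A")))
  dd <- remove_duplicates(fs)
  # duplicates within A collapse; the identical interval in B survives
  expect_equal(nrow(dd), 3L)
  expect_equal(attr(dd, "n_removed"), 2L)
  expect_equal(sum(dd$library_id == "B"), 1L)

  # exhaustive grouping oracle on random data
  set.seed(21)
  df <- data.frame(chrom = "chr1",
                   start = sample(0:20, 100, replace = TRUE),
                   library_id = sample(c("A", "B"), 100, replace = TRUE))
  df$end <- df$start + sample(146:148, 100, replace = TRUE)
  got <- nrow(remove_duplicates(fragment_set(df)))
  oracle <- nrow(unique(df[, c("library_id", "chrom", "start", "end")]))
  expect_equal(got, oracle)
})

test_that("midpoint computation commutes with chromosome partitioning", {
  set.seed(31)
  df <- data.frame(chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
                   start = sample(0:3000, 200, replace = TRUE))
  df$end <- df$start + sample(130:170, 200, replace = TRUE)
  df$library_id <- "A"
  sl <- c(chr1 = 4000L, chr2 = 4000L)
  whole <- compute_midpoints(fragment_set(df), sl)
  parts <- lapply(c("chr1", "chr2"), function(ch)
    compute_midpoints(fragment_set(df[df$chrom == ch, ]), sl[ch]))
  for (i in 1:2) {
    ch <- c("chr1", "chr2")[i]
    expect_equal(whole$counts[[ch]], parts[[i]]$counts[[ch]])
  }
  expect_equal(whole$total, sum(vapply(parts, function(p) p$total, 1)))
})
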