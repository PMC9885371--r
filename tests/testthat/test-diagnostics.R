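test_that("GHF records normalize hits per 100 kb", {
  ann <- data.frame(symbol = c("a", "b", "c", "d", "e"), chrom = "c",
                    start = c(10, 5e4, 1e5, 15e4, 2e5),
                    end = c(20, 6e4, 1.1e5, 16e4, 2.1e5))
  trk1 <- data.frame(chrom = "c", start = 0, end = 1e5, n_samples = 1)
  r1 <- ghf_records(trk1, ann)
  expect_equal(r1$n_genes_hit, 2L)            # genes a, b
  expect_equal(r1$ghf, 2)
  expect_equal(r1$bin_index, 1)

  trk2 <- data.frame(chrom = "c", start = 0, end = 2.5e5, n_samples = 3)
  r2 <- ghf_records(trk2, ann)
  expect_equal(r2$n_genes_hit, 5L)
  expect_equal(r2$ghf, 5 / 2.5)

  trk0 <- data.frame(chrom = "c", start = 3e5, end = 4e5, n_samples = 2)
  r0 <- ghf_records(trk0, ann)
  expect_equal(r0$ghf, 0)                     # zero-hit segments retained
})

test_that("GHF is position-invariant and inversely scales with length", {
  ann <- data.frame(symbol = c("a", "b"), chrom = "c",
                    start = c(1e5, 6e5), end = c(1.2e5, 6.2e5))
  here <- data.frame(chrom = "c", start = 0.9e5, end = 1.9e5, n_samples = 1)
  there <- data.frame(chrom = "c", start = 5.9e5, end = 6.9e5, n_samples = 1)
  expect_equal(ghf_records(here, ann)$ghf, ghf_records(there, ann)$ghf)
  double_len <- data.frame(chrom = "c", start = 0.9e5, end = 2.9e5,
                           n_samples = 1)
  expect_equal(ghf_records(double_len, ann)$ghf,
               ghf_records(here, ann)$ghf / 2)
})

test_that("ghf_summary weights by sample count and matches a rank oracle", {
  set.seed(7)
  n <- 100
  len <- round(runif(n, 1e4, 2e6))
  rec <- data.frame(chrom = "c", start = 0, end = len, length = len,
                    n_samples = sample.int(5L, n, replace = TRUE),
                    n_genes_hit = rpois(n, 2e5 / len) + 0L)
  rec$ghf <- rec$n_genes_hit / (rec$length / 1e5)
  rec$bin_index <- floor(rec$length / 1e5)
  s <- ghf_summary(rec)
  # oracle: Pearson on midranks over the sample-expanded records
  idx <- rep(seq_len(n), rec$n_samples)
  oracle <- cor(rank(rec$length[idx]), rank(rec$ghf[idx]))
  expect_equal(s$spearman, oracle, tolerance = 1e-12)
  expect_true(all(s$bins$q25 <= s$bins$median))
  expect_true(all(s$bins$median <= s$bins$q75))
  expect_identical(sum(s$bins$n_events),
                   sum(rec$n_samples[rec$length < 5e6]))
})

test_that("ghf_summary handles monotone decay, ties and degenerate input", {
  rec <- data.frame(chrom = "c", start = 0, end = 1,
                    length = c(1e5, 2e5, 3e5), n_samples = 1,
                    n_genes_hit = c(9L, 4L, 1L))
  rec$ghf <- rec$n_genes_hit / (rec$length / 1e5)
  rec$bin_index <- floor(rec$length / 1e5)
  expect_equal(ghf_summary(rec)$spearman, -1)
  flat <- transform(rec, ghf = 2)
  expect_equal(ghf_summary(flat)$spearman, 0)
  expect_error(ghf_summary(rec[1, ]), "two distinct segment lengths")
})

test_that("breakpoint enrichment p equals the hypergeometric tail", {
  ann <- data.frame(symbol = c("drv", "oth"), chrom = "c",
                    start = c(100, 3000), end = c(300, 3200))
  sizes <- c(c = 10000)
  # every breakpoint inside the driver gene
  coh <- data.frame(sample = c("s1", "s2"), chrom = "c",
                    start = c(120, 150), end = c(200, 250))
  res <- breakpoint_gene_enrichment(coh, ann, "drv", sizes)
  expect_equal(res$p_value,
               hyper_tail(res$table[1, 1], res$table[1, 2],
                          res$table[2, 1], res$table[2, 2]),
               tolerance = 1e-12)
  expect_equal(res$table[1, 1], 4)            # all 4 breakpoints in footprint
  expect_lt(res$p_value, 1e-5)
  expect_identical(res$mode, "gene-level")

  # zero breakpoints in drivers: one-sided p = 1
  coh2 <- data.frame(sample = "s1", chrom = "c", start = 5000, end = 6000)
  res2 <- breakpoint_gene_enrichment(coh2, ann, "drv", sizes)
  expect_equal(res2$p_value, 1)

  expect_error(breakpoint_gene_enrichment(coh, ann, "absent", sizes),
               "no driver symbols")
  expect_error(breakpoint_gene_enrichment(coh[0, ], ann, "drv", sizes),
               "no breakpoints")
})

test_that("proportional breakpoint placement shows no driver enrichment", {
  set.seed(3)
  sizes <- c(c = 1e6)
  ann <- data.frame(symbol = sprintf("g%02d", 1:20), chrom = "c",
                    start = seq(0, by = 5e4, length.out = 20))
  ann$end <- ann$start + 4e4
  drivers <- ann$symbol[1:5]
  ps <- replicate(60, {
    start <- sample.int(1e6 - 1000L, 40L) - 1L
    coh <- data.frame(sample = sprintf("s%d", 1:40), chrom = "c",
                      start = start, end = start + sample.int(900L, 40L))
    breakpoint_gene_enrichment(coh, ann, drivers, sizes)$p_value
  })
  # under proportional placement p is not concentrated near 0
  expect_gt(median(ps), 0.2)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("length-corrected enrichment detects a planted driver rate excess", {
  sizes <- c(c = 5e6)
  set.seed(11)
  ann <- data.frame(symbol = sprintf("g%03d", 1:100), chrom = "c",
                    start = seq(0, by = 5e4, length.out = 100))
  ann$end <- ann$start + 4e4
  drivers <- ann$symbol[1:15]
  for (s in 1:5) {
    set.seed(100 + s)
    # ~10x per-bp breakpoint rate inside driver genes
    n_drv <- 800L; n_bg <- 300L
    drv_gene <- sample.int(15L, n_drv, replace = TRUE)
    drv_pos <- ann$start[drv_gene] + sample.int(4e4, n_drv, replace = TRUE) - 1L
    bg_pos <- sample.int(5e6 - 600L, n_bg) - 1L
    start <- c(drv_pos, bg_pos)
    coh <- data.frame(sample = sprintf("s%d", seq_along(start)), chrom = "c",
                      start = start, end = start + 500L)
    res <- breakpoint_length_corrected_enrichment(coh, ann, drivers)
    expect_lt(res$p_value, 0.001)
    expect_identical(res$mode, "length-corrected")
  }
})

test_that("equal breakpoint rates everywhere give no length-corrected signal", {
  ann <- data.frame(symbol = c("a", "b", "c", "d"), chrom = "c",
                    start = c(0, 100, 200, 300), end = c(50, 150, 250, 350))
  coh <- data.frame(sample = sprintf("s%d", 1:4), chrom = "c",
                    start = c(10, 110, 210, 310), end = c(20, 120, 220, 320))
  res <- breakpoint_length_corrected_enrichment(coh, ann, c("a", "b"))
  expect_gte(res$p_value, 0.5)
})
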