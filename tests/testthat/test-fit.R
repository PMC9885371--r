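small_fit <- function(seed = 4, n_perm = 60) {
  sim <- generate_cohort(simulation_config(n_samples = 20, n_genes = 40,
                                           chrom_sizes = c(chr1 = 3e6),
                                           seed = seed))
  list(sim = sim,
       fit = cndscan(sim$cohort, sim$annotation, sim$config$chrom_sizes,
                     n_permutations = n_perm, seed = seed))
}

test_that("cndscan returns a coherent fitted object", {
  sf <- small_fit()
  fit <- sf$fit
  expect_s3_class(fit, "cndscan")
  expect_identical(nrow(fit$results), 40L)
  expect_s3_class(fit$track, "cnd_track")
  expect_identical(attr(fit$results, "n_permutations"), 60L)
  # fit equals the composed pipeline run by hand
  trk <- build_collective_track(normalize_cohort(sf$sim$cohort), fit$sizes)
  tab <- significance_table(sf$sim$annotation, trk, fit$sizes,
                            permutation_config(60, seed = 4))
  expect_equal(fit$results, tab)
})

test_that("S3 methods print, summarize, extract and simulate", {
  sf <- small_fit()
  expect_output(print(sf$fit), "collective segments")
  s <- summary(sf$fit)
  expect_s3_class(s, "summary.cndscan")
  expect_output(print(s), "Top genes")
  cf <- coef(sf$fit)
  expect_identical(names(cf), sf$sim$annotation$symbol)
  expect_equal(unname(cf), sf$fit$results$score)
  nd <- simulate(sf$fit, nsim = 25, seed = 9)
  expect_identical(dim(nd), c(40L, 25L))
  expect_identical(significant_genes(sf$fit),
                   sf$fit$results$symbol[sf$fit$results$significant])
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(sf$fit))
})

test_that("cmd_simulate then cmd_score runs end to end, deterministically", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "run")
  suppressMessages(cmd_simulate(prefix, n_samples = 20, n_genes = 40,
                                chrom_sizes = c(chr1 = 3e6), seed = 5))
  for (f in c("_segments.tsv", "_truth.json", "_genes.bed", "_chrom.sizes"))
    expect_true(file.exists(paste0(prefix, f)))
  out1 <- file.path(dir, "res1.tsv"); out2 <- file.path(dir, "res2.tsv")
  suppressMessages(cmd_score(paste0(prefix, "_segments.tsv"),
                             paste0(prefix, "_genes.bed"),
                             paste0(prefix, "_chrom.sizes"), out1,
                             permutations = 50, seed = 7,
                             dialect = segment_dialect("pgxseg")))
  suppressMessages(cmd_score(paste0(prefix, "_segments.tsv"),
                             paste0(prefix, "_genes.bed"),
                             paste0(prefix, "_chrom.sizes"), out2,
                             permutations = 50, seed = 7,
                             dialect = segment_dialect("pgxseg")))
  expect_identical(readLines(out1), readLines(out2))   # byte-identical
  res <- read_results(out1)
  expect_identical(nrow(res), 40L)
  manifest <- jsonlite::read_json(paste0(out1, ".manifest.json"))
  expect_identical(manifest$command, "score")
  expect_identical(manifest$counts$genes, 40L)
  expect_length(manifest$inputs, 3L)
})

test_that("cmd_diagnose writes GHF tables and both enrichment modes", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "run")
  sim <- suppressMessages(cmd_simulate(prefix, n_samples = 20, n_genes = 40,
                                       chrom_sizes = c(chr1 = 3e6),
                                       seed = 6))
  drivers <- file.path(dir, "drivers.gmt")
  writeLines(paste(c("planted", "desc", sim$truth$planted_genes),
                   collapse = "\t"), drivers)
  out <- suppressMessages(cmd_diagnose(paste0(prefix, "_segments.tsv"),
                                       paste0(prefix, "_genes.bed"),
                                       paste0(prefix, "_chrom.sizes"),
                                       drivers, file.path(dir, "diag"),
                                       dialect = segment_dialect("pgxseg")))
  ghf <- read.delim(file.path(dir, "diag_ghf.tsv"))
  expect_gt(nrow(ghf), 0)
  bins <- readLines(file.path(dir, "diag_ghf_bins.tsv"))
  expect_match(bins[1], "weighted_spearman")
  enr <- read.delim(file.path(dir, "diag_breakpoint_enrichment.tsv"),
                    comment.char = "#")
  expect_identical(enr$mode, c("gene-level", "length-corrected"))
  expect_true(all(enr$p_value >= 0 & enr$p_value <= 1))
})

test_that("cmd_enrich and cmd_embed cover their error and success paths", {
  dir <- withr::local_tempdir()
  sf <- small_fit()
  res_path <- file.path(dir, "res.tsv")
  write_results(sf$fit$results, res_path)
  sets <- file.path(dir, "sets.gmt")
  writeLines(c(paste(c("S1", "d", sf$sim$annotation$symbol[1:5]),
                     collapse = "\t"),
               paste(c("S2", "d", sf$sim$annotation$symbol[6:10]),
                     collapse = "\t")), sets)
  out <- file.path(dir, "enr.tsv")
  tab <- suppressMessages(cmd_enrich(res_path, sets, out))
  expect_identical(tab$set, c("S1", "S2"))
  expect_true(file.exists(out))

  expect_error(suppressMessages(
    cmd_embed(c(res_path, res_path), out = file.path(dir, "e.tsv"))),
    "at least 3")
})

test_that("the installed CLI script simulates and rejects bad invocations", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "cndscan", package = "cndscan")
  skip_if(cli == "", "CLI script not installed")
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  ok <- system2(rscript, c(cli, "simulate", "--out",
                           file.path(dir, "sim"), "--seed", "3",
                           "--samples", "10", "--genes", "20"),
                stdout = FALSE, stderr = FALSE)
  expect_identical(ok, 0L)
  expect_true(file.exists(file.path(dir, "sim_segments.tsv")))
  bad <- system2(rscript, c(cli, "frobnicate"), stdout = FALSE,
                 stderr = FALSE)
  expect_identical(bad, 3L)
  missing <- system2(rscript, c(cli, "score"), stdout = FALSE,
                     stderr = FALSE)
  expect_identical(missing, 3L)
})
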