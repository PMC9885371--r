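# Shared fixtures and independent oracles. Oracles are deliberately naive
# (per-bp counting, double loops, brute-force tail sums) and never share
# code with the implementation paths they check.

# random cohort on a single short chromosome
rand_cohort <- function(n_samples = 5L, chrom_len = 5000L, max_segs = 4L,
                        chrom = "chr1") {
  rows <- lapply(seq_len(n_samples), function(i) {
    k <- sample.int(max_segs + 1L, 1L) - 1L
    if (k == 0L) return(NULL)
    start <- sample.int(chrom_len - 1L, k, replace = TRUE) - 1L
    len <- sample.int(200L, k, replace = TRUE)
    data.frame(sample = sprintf("s%02d", i), chrom = chrom,
               start = start, end = pmin(start + len, chrom_len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(sample = "s01", chrom = chrom, start = 0, end = 1,
                      stringsAsFactors = FALSE)
  out
}

# oracle: per-bp deleted-sample count, one bp at a time
perbp_coverage <- function(cohort, chrom_len, chrom = "chr1") {
  cov <- integer(chrom_len)
  for (sid in unique(cohort$sample)) {
    seen <- logical(chrom_len)
    d <- cohort[cohort$sample == sid & cohort$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(d)))
      seen[seq.int(d$start[i] + 1L, d$end[i])] <- TRUE
    cov <- cov + seen
  }
  cov
}

# coverage implied by a collective track, expanded bp by bp
track_coverage <- function(track, chrom_len, chrom = "chr1") {
  cov <- integer(chrom_len)
  d <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d)))
    cov[seq.int(d$start[i] + 1L, d$end[i])] <- d$n_samples[i]
  cov
}

# oracle: double-loop gene scoring straight from the definition
naive_scores <- function(annotation, track) {
  vapply(seq_len(nrow(annotation)), function(g) {
    lg <- annotation$end[g] - annotation$start[g]
    s <- 0
    for (i in seq_len(nrow(track))) {
      if (track$chrom[i] != annotation$chrom[g]) next
      ov <- min(track$end[i], annotation$end[g]) -
        max(track$start[i], annotation$start[g])
      if (ov >= 1)
        s <- s + track$n_samples[i] / ((track$end[i] - track$start[i]) + lg)
    }
    s
  }, numeric(1))
}

# oracle: Benjamini-Yekutieli step-up from the closed form
by_stepup <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- p[o] * m * cm / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(adj))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# oracle: brute-force hypergeometric upper tail P(X >= a) for the 2x2
# [[a, b], [c, d]] with margins fixed
hyper_tail <- function(a, b, c, d) {
  K <- a + b; n <- a + c; N <- a + b + c + d
  xs <- a:min(K, n)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# small deterministic cohort used across io/track tests
toy_cohort <- function() {
  data.frame(sample = c("A", "A", "B"), chrom = "chr1",
             start = c(0, 100, 100), end = c(300, 400, 400),
             stringsAsFactors = FALSE)
}

# two planted profile clusters: group A has small p on one gene block,
# group B on a disjoint block, noise elsewhere
planted_profiles <- function(n_per_group = 5L, n_genes = 200L) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  mk <- function(id, block) {
    p <- runif(n_genes, 0.2, 1)
    p[block] <- runif(length(block), 0.001, 0.01)
    significance_profile(data.frame(symbol = genes, empirical_p = p), id)
  }
  c(lapply(seq_len(n_per_group), function(i) mk(sprintf("A%d", i), 1:20)),
    lapply(seq_len(n_per_group), function(i) mk(sprintf("B%d", i), 101:120)))
}

# vectorized brute-force scorer for large oracle instances: per gene, the
# definition applied over every track row at once
naive_scores_vec <- function(annotation, track) {
  vapply(seq_len(nrow(annotation)), function(g) {
    lg <- annotation$end[g] - annotation$start[g]
    ov <- pmin(track$end, annotation$end[g]) -
      pmax(track$start, annotation$start[g])
    sel <- track$chrom == annotation$chrom[g] & ov >= 1
    sum(track$n_samples[sel] / ((track$end[sel] - track$start[sel]) + lg))
  }, numeric(1))
}
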