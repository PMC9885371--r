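# Internal: one-sided ("greater") Fisher exact p for a 2x2 table
# [[a, b], [c, d]] with fixed margins, i.e. the hypergeometric upper tail
# P(X >= a | N = a+b+c+d, K = a+b, n = a+c). Identical to
# fisher.test(alternative = "greater")$p.value, but remains fast when the
# margins are bp-scale (fisher.test's conditional-MLE odds ratio loops over
# the full support). The odds ratio reported is the sample cross-product
# ratio, not the conditional MLE.
.fisher_greater <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

.enrichment_result <- function(a, b, c, d, mode,
                               labels = c("in", "out")) {
  tab <- matrix(as.numeric(c(a, b, c, d)), 2L, 2L, byrow = TRUE,
                dimnames = list(group = labels,
                                count = c("hit", "not_hit")))
  structure(list(table = tab,
                 odds_ratio = (a * d) / (b * c),
                 p_value = .fisher_greater(a, b, c, d),
                 mode = mode),
            class = "cnd_enrichment")
}

#' @export
print.cnd_enrichment <- function(x, ...) {
  cat(sprintf("One-sided enrichment test (mode: %s)\n", x$mode))
  print(x$table)
  cat(sprintf("odds ratio %.4g, one-sided Fisher p = %.4g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Gene-hit-frequency records of a collective track
#'
#' For each collective segment: the number of genes it overlaps by at least
#' 1 bp, normalized by segment length in units of 100 kb ("gene hit
#' frequency", genes per 100 kb). Each of the S_i samples carrying the
#' segment contributes one deletion event, so the record carries weight
#' S_i; summaries and the decay correlation expand records by this weight.
#' Zero-hit segments are retained (ghf = 0).
#'
#' @param track a `cnd_track`.
#' @param annotation gene annotation (`symbol`, `chrom`, `start`, `end`).
#' @return data frame `chrom`, `start`, `end`, `length`, `n_samples`,
#'   `n_genes_hit`, `ghf`, `bin_index` (`floor(length / 1e5)`), one row per
#'   collective segment.
#' @export
ghf_records <- function(track, annotation) {
  gidx <- .gene_index(annotation)
  hits <- integer(nrow(track))
  segs <- split(seq_len(nrow(track)), as.character(track$chrom))
  for (chrom in names(segs)) {
    si <- segs[[chrom]]
    gx <- gidx[[chrom]]
    if (is.null(gx)) next
    sstart <- as.numeric(track$start[si]); send <- as.numeric(track$end[si])
    lo <- findInterval(sstart - gx$maxlen, gx$gstart) + 1L
    hi <- findInterval(send - 0.5, gx$gstart)
    ncand <- pmax(0L, hi - lo + 1L)
    if (sum(ncand) == 0L) next
    j <- rep.int(seq_along(si), ncand)
    g <- sequence(ncand, from = lo)
    keep <- gx$gend[g] > sstart[j]
    hits[si] <- tabulate(j[keep], nbins = length(si))
  }
  len <- as.numeric(track$end - track$start)
  data.frame(chrom = as.character(track$chrom),
             start = as.numeric(track$start), end = as.numeric(track$end),
             length = len, n_samples = track$n_samples,
             n_genes_hit = hits, ghf = hits / (len / 1e5),
             bin_index = floor(len / 1e5), stringsAsFactors = FALSE)
}

#' Binned summary and decay correlation of gene-hit frequency
#'
#' Expands each record by its sample weight (one deletion event per
#' carrying sample), bins segment lengths into `[k*bin_width,
#' (k+1)*bin_width)` windows up to `max_size`, and reports per-bin
#' quartiles of GHF together with the sample-weighted Spearman correlation
#' between segment length and GHF over all expanded records (a negative
#' value is the signature of short segments targeting gene-rich regions).
#'
#' @param records output of [ghf_records()].
#' @param bin_width bin width in bp (default 100 kb).
#' @param max_size largest segment length summarized in the bin table
#'   (default 5 Mb); the correlation uses all records.
#' @return list with `bins` (data frame `bin_index`, `bin_start`,
#'   `bin_end`, `n_events`, `q25`, `median`, `q75`) and `spearman`.
#' @export
ghf_summary <- function(records, bin_width = 1e5, max_size = 5e6) {
  if (nrow(records) == 0L || length(unique(records$length)) < 2L)
    stop("GHF decay needs at least two distinct segment lengths",
         call. = FALSE)
  w <- rep.int(seq_len(nrow(records)), records$n_samples)
  len <- records$length[w]
  ghf <- records$ghf[w]
  bin <- floor(len / bin_width)
  inrange <- len < max_size
  bins <- lapply(split(ghf[inrange], bin[inrange]), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(n = length(v), q25 = q[1L], median = q[2L], q75 = q[3L])
  })
  bi <- as.integer(names(bins))
  bins <- do.call(rbind, bins)
  bintab <- data.frame(bin_index = bi, bin_start = bi * bin_width,
                       bin_end = (bi + 1) * bin_width,
                       n_events = as.integer(bins[, "n"]),
                       q25 = bins[, "q25"], median = bins[, "median"],
                       q75 = bins[, "q75"], stringsAsFactors = FALSE)
  bintab <- bintab[order(bintab$bin_index), , drop = FALSE]
  rownames(bintab) <- NULL
  rho <- if (stats::sd(ghf) == 0) 0 else
    stats::cor(len, ghf, method = "spearman")
  list(bins = bintab, spearman = rho)
}

# Internal: merged (union) footprint of a set of gene intervals, and bp sum.
.footprint <- function(genes) {
  merged <- normalize_segments(genes[, c("chrom", "start", "end")])
  list(intervals = merged, bp = sum(merged$end - merged$start))
}

# Internal: count breakpoints falling in a set of disjoint sorted intervals
# (half-open containment: start <= p < end), multiplicity preserved.
.count_in_footprint <- function(bps, intervals) {
  total <- 0L
  for (chrom in unique(bps$chrom)) {
    iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
    if (nrow(iv) == 0L) next
    p <- bps$pos[bps$chrom == chrom]
    idx <- findInterval(p, iv$start)           # last interval with start <= p
    inside <- idx >= 1L & p < iv$end[pmax(idx, 1L)]
    total <- total + sum(inside)
  }
  total
}

#' Breakpoint over-representation in a driver gene set (gene-level)
#'
#' Tests whether segment breakpoints fall inside the genomic footprint of a
#' curated driver gene set more often than the footprint's share of the
#' genome predicts. The 2x2 table classifies every bp of the genome as
#' driver-footprint vs rest, and as carrying an observed breakpoint vs not;
#' the test is a one-sided (greater) Fisher exact test. Breakpoint-in-gene
#' membership uses half-open containment (`start <= p < end`). The exact
#' construction of the contingency table is this package's own; it is
#' recorded in the result's `mode` and swappable.
#'
#' @param cohort normalized cohort segment table.
#' @param annotation gene annotation.
#' @param driver_set character vector of driver gene symbols.
#' @param sizes chromosome sizes (defines total genome bp).
#' @return a `cnd_enrichment` with the 2x2 table, sample odds ratio,
#'   one-sided p, and mode `"gene-level"`.
#' @export
breakpoint_gene_enrichment <- function(cohort, annotation, driver_set,
                                       sizes) {
  sizes <- chrom_sizes(sizes)
  drivers <- annotation[annotation$symbol %in% driver_set, , drop = FALSE]
  if (nrow(drivers) == 0L)
    stop("no driver symbols found in the annotation", call. = FALSE)
  bps <- segment_breakpoints(cohort)
  if (nrow(bps) == 0L) stop("cohort has no breakpoints", call. = FALSE)
  fp <- .footprint(drivers)
  genome_bp <- sum(sizes)
  a <- .count_in_footprint(bps, fp$intervals)
  c_ <- nrow(bps) - a
  b <- max(0, fp$bp - a)
  d <- max(0, (genome_bp - fp$bp) - c_)
  .enrichment_result(a, b, c_, d, mode = "gene-level",
                     labels = c("driver_footprint", "rest_of_genome"))
}

#' Breakpoint over-representation in drivers, corrected for gene length
#'
#' Length-corrected variant: each gene's breakpoint count is divided by its
#' length, genes are dichotomized at the genome-wide median rate
#' (strictly above vs not), and the 2x2 crosses driver membership with
#' above-median rate, tested one-sided (greater). This is a concrete,
#' explicitly labeled construction for "length-corrected"; see `mode`.
#'
#' @inheritParams breakpoint_gene_enrichment
#' @return a `cnd_enrichment` with mode `"length-corrected"`.
#' @export
breakpoint_length_corrected_enrichment <- function(cohort, annotation,
                                                   driver_set) {
  drivers_in <- annotation$symbol %in% driver_set
  if (!any(drivers_in))
    stop("no driver symbols found in the annotation", call. = FALSE)
  bps <- segment_breakpoints(cohort)
  if (nrow(bps) == 0L) stop("cohort has no breakpoints", call. = FALSE)
  counts <- numeric(nrow(annotation))
  for (chrom in unique(bps$chrom)) {
    gi <- which(annotation$chrom == chrom)
    if (!length(gi)) next
    p <- bps$pos[bps$chrom == chrom]
    counts[gi] <- vapply(gi, function(i)
      sum(p >= annotation$start[i] & p < annotation$end[i]), numeric(1))
  }
  rate <- counts / (annotation$end - annotation$start)
  above <- rate > stats::median(rate)
  a <- sum(above & drivers_in); b <- sum(!above & drivers_in)
  c_ <- sum(above & !drivers_in); d <- sum(!above & !drivers_in)
  .enrichment_result(a, b, c_, d, mode = "length-corrected",
                     labels = c("driver", "non_driver"))
}
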