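#' Configuration for synthetic cohort generation
#'
#' Defines the simulated study conditions: a cohort of tumor samples each
#' carrying background deletions with a broad length distribution, plus
#' focal recurrent deletions concentrated on a small set of planted target
#' genes (the known truth for recovery testing).
#'
#' @param n_samples cohort size (default 100).
#' @param chrom_sizes named vector of chromosome lengths (default one 10 Mb
#'   chromosome).
#' @param n_genes number of non-overlapping genes placed uniformly
#'   (default 200).
#' @param gene_length_range gene lengths are log-uniform on this range in
#'   bp (default 5-200 kb).
#' @param background_rate expected background deletions per sample per
#'   chromosome (Poisson mean, default 2).
#' @param background_length_range background deletion lengths, uniform on
#'   this range in bp (default 50 kb - 1 Mb).
#' @param n_planted number of planted target genes (default 5).
#' @param penetrance fraction of samples carrying a focal deletion per
#'   planted gene (default 0.3).
#' @param focal_extension focal deletion length is uniform on
#'   `[gene length, gene length + focal_extension]` (default 100 kb), so
#'   collective segments around planted genes are short and recurrent.
#' @param seed integer seed; generation is fully reproducible given it.
#' @return a `cnd_sim_config` list.
#' @export
simulation_config <- function(n_samples = 100L,
                              chrom_sizes = c(chr1 = 1e7),
                              n_genes = 200L,
                              gene_length_range = c(5e3, 2e5),
                              background_rate = 2,
                              background_length_range = c(5e4, 1e6),
                              n_planted = 5L,
                              penetrance = 0.3,
                              focal_extension = 1e5,
                              seed = NULL) {
  chrom_sizes <- chrom_sizes(chrom_sizes)
  stopifnot(n_samples >= 1, n_genes >= 1, n_planted >= 0,
            n_planted <= n_genes, background_rate >= 0,
            focal_extension >= 0,
            length(gene_length_range) == 2L,
            gene_length_range[1L] >= 1,
            gene_length_range[2L] >= gene_length_range[1L],
            length(background_length_range) == 2L,
            background_length_range[1L] >= 1,
            background_length_range[2L] >= background_length_range[1L])
  if (penetrance <= 0 || penetrance > 1)
    stop("penetrance must lie in (0, 1]", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 chrom_sizes = chrom_sizes,
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.numeric(gene_length_range),
                 background_rate = background_rate,
                 background_length_range = as.numeric(background_length_range),
                 n_planted = as.integer(n_planted),
                 penetrance = penetrance,
                 focal_extension = focal_extension,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cnd_sim_config")
}

#' Generate a synthetic non-overlapping gene annotation
#'
#' Genes are assigned to chromosomes proportionally to length, lengths drawn
#' log-uniform on the configured range, and placements made uniform among
#' non-overlapping arrangements: the length vector is redrawn (bounded
#' retries) until the total footprint fits the chromosome, and the leftover
#' slack is split into gaps by uniform order statistics.
#'
#' @param config a [simulation_config()]. Its `seed` (when set) makes the
#'   annotation reproducible.
#' @return data frame `symbol`, `chrom`, `start`, `end`, sorted, pairwise
#'   disjoint within chromosomes.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "cnd_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sizes <- config$chrom_sizes
  share <- as.numeric(sizes) / sum(sizes)
  per_chrom <- diff(round(cumsum(c(0, share)) * config$n_genes))
  lr <- log(config$gene_length_range)
  out <- list()
  gnum <- 0L
  for (k in seq_along(sizes)) {
    n <- per_chrom[k]
    if (n == 0L) next
    chromlen <- as.numeric(sizes[k])
    lens <- NULL
    for (try in seq_len(100L)) {
      cand <- round(exp(stats::runif(n, lr[1L], lr[2L])))
      if (sum(cand) <= chromlen) { lens <- cand; break }
    }
    if (is.null(lens))
      stop(sprintf(
        "cannot place %d genes on a %.0f bp chromosome: footprint does not fit after 100 retries",
        n, chromlen), call. = FALSE)
    slack <- chromlen - sum(lens)
    gaps <- diff(c(0, sort(stats::runif(n, 0, slack))))
    starts <- round(cumsum(gaps) + cumsum(c(0, lens[-n])))
    out[[k]] <- data.frame(
      symbol = sprintf("G%04d", gnum + seq_len(n)),
      chrom = names(sizes)[k],
      start = as.numeric(starts), end = as.numeric(starts + lens),
      stringsAsFactors = FALSE)
    gnum <- gnum + n
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Generate a synthetic deletion cohort with planted target genes
#'
#' Draws, per sample and chromosome, a Poisson number of background
#' deletions with uniform lengths and uniform starts, then plants focal
#' recurrent deletions: for each planted gene, each sample independently
#' carries (with probability `penetrance`) a deletion whose length is
#' uniform on `[L_g, L_g + focal_extension]`, positioned uniformly among
#' all placements overlapping the gene by at least 1 bp (clamped to the
#' chromosome). Whole and partial deletions of the target both occur, so
#' segment breakpoints fall inside the gene — the disruption signature the
#' model scores. Truth is recorded before per-sample normalization, so
#' merged background+focal events remain attributable.
#'
#' @param config a [simulation_config()].
#' @return list with `cohort` (normalized segment table), `annotation`,
#'   `truth` (list: `planted_genes`, `segments` with an `origin` column of
#'   `"background"`/`"planted"` and the targeted `gene`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cnd_sim_config"))
  annotation <- generate_annotation(config)   # re-seeds when config$seed set
  sizes <- config$chrom_sizes
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  segs <- list()
  # background deletions
  for (k in seq_along(sizes)) {
    chromlen <- as.numeric(sizes[k])
    counts <- stats::rpois(config$n_samples, config$background_rate)
    tot <- sum(counts)
    if (tot == 0L) next
    len <- pmin(round(stats::runif(tot, config$background_length_range[1L],
                                   config$background_length_range[2L])),
                chromlen)
    start <- .runif_int(chromlen - len)
    segs[[length(segs) + 1L]] <- data.frame(
      sample = rep(samples, counts), chrom = names(sizes)[k],
      start = as.numeric(start), end = as.numeric(start + len),
      origin = "background", gene = NA_character_,
      stringsAsFactors = FALSE)
  }
  # planted focal deletions covering the target genes
  planted <- if (config$n_planted > 0L)
    sort(sample(annotation$symbol, config$n_planted)) else character(0)
  for (g in planted) {
    gi <- annotation[annotation$symbol == g, ]
    chromlen <- as.numeric(sizes[[gi$chrom]])
    carrier <- stats::runif(config$n_samples) < config$penetrance
    n <- sum(carrier)
    if (n == 0L) next
    lg <- gi$end - gi$start
    len <- pmin(lg + round(stats::runif(n, 0, config$focal_extension)),
                chromlen)
    # overlap-anywhere placement: start in [gs - len + 1, ge - 1]
    lo <- pmax(0, gi$start - len + 1)
    hi <- pmin(gi$end - 1, chromlen - len)
    hi <- pmax(hi, lo)                       # degenerate room: forced placement
    start <- lo + .runif_int(hi - lo)
    segs[[length(segs) + 1L]] <- data.frame(
      sample = samples[carrier], chrom = gi$chrom,
      start = as.numeric(start), end = as.numeric(start + len),
      origin = "planted", gene = g, stringsAsFactors = FALSE)
  }
  truth_segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0),
               origin = character(0), gene = character(0),
               stringsAsFactors = FALSE)
  rownames(truth_segments) <- NULL
  cohort <- normalize_cohort(truth_segments[, c("sample", "chrom", "start",
                                                "end")], sizes)
  list(cohort = cohort, annotation = annotation,
       truth = list(planted_genes = planted, segments = truth_segments),
       config = config)
}

#' Write a synthetic cohort to disk
#'
#' Emits the cohort as a pgxseg-style tab-delimited segment file (columns
#' `biosample_id`, `reference_name`, `start`, `end`, `variant_type` with
#' `DEL` state, 0-based half-open) plus a JSON truth file with the planted
#' genes, per-segment provenance and generation parameters.
#'
#' @param sim output of [generate_cohort()].
#' @param segments_path path for the segment TSV.
#' @param truth_path path for the truth JSON.
#' @return invisible list of the two paths.
#' @export
write_cohort <- function(sim, segments_path, truth_path) {
  seg <- data.frame(biosample_id = sim$cohort$sample,
                    reference_name = sim$cohort$chrom,
                    start = format(sim$cohort$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(sim$cohort$end, scientific = FALSE,
                                 trim = TRUE),
                    variant_type = "DEL", stringsAsFactors = FALSE)
  utils::write.table(seg, segments_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- sim$config
  cfg$chrom_sizes <- as.list(cfg$chrom_sizes)
  jsonlite::write_json(
    list(planted_genes = sim$truth$planted_genes,
         segments = sim$truth$segments,
         config = unclass(cfg)),
    truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(segments = segments_path, truth = truth_path))
}
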