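#' Permutation settings for the shuffling null
#'
#' @param n_permutations number of within-chromosome shuffles (default 1000).
#'   The smallest attainable empirical p-value is
#'   `1/(n_permutations + 1)`, so FDR resolution depends on this choice.
#' @param seed integer seed for reproducible shuffles, or `NULL`.
#' @param alpha significance level applied to the adjusted p-values
#'   (default 0.05).
#' @return a `cnd_perm_config` list.
#' @export
permutation_config <- function(n_permutations = 1000L, seed = NULL,
                               alpha = 0.05) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L)
    stop("n_permutations must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (n_permutations < 20L)
    warning(sprintf(
      "with %d permutation(s) the smallest attainable p-value is %.3g; FDR calls will have little resolution",
      n_permutations, 1 / (n_permutations + 1)), call. = FALSE)
  structure(list(n_permutations = n_permutations,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 alpha = alpha),
            class = "cnd_perm_config")
}

# Internal: uniform draw on {0, ..., m} elementwise (m may vary).
.runif_int <- function(m) {
  pmin(floor(stats::runif(length(m)) * (m + 1)), m)
}

#' Shuffle collective segments within their chromosomes
#'
#' Each collective segment is independently re-placed at a start drawn
#' uniformly from `{0, ..., chrom_length - L_i}` on its own chromosome;
#' length and sample count ride along unchanged. Overlaps among shuffled
#' segments are permitted (rejection sampling would bias placement on
#' crowded chromosomes). The original track is not modified.
#'
#' @param track a `cnd_track` (or compatible data frame).
#' @param sizes chromosome sizes ([chrom_sizes()]).
#' @return a data frame with the same columns as `track`, re-placed.
#' @export
shuffle_track <- function(track, sizes) {
  sizes <- chrom_sizes(sizes)
  unknown <- setdiff(unique(as.character(track$chrom)), names(sizes))
  if (length(unknown))
    stop("track chromosome(s) absent from sizes table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  len <- track$end - track$start
  room <- sizes[as.character(track$chrom)] - len
  if (any(room < 0))
    stop("collective segment longer than its chromosome", call. = FALSE)
  start <- .runif_int(room)
  out <- track
  out$start <- as.numeric(start)
  out$end <- as.numeric(start + len)
  rownames(out) <- NULL
  out
}

# Internal: run `n_permutations` shuffles of `track`, computing the full
# gene score vector per shuffle and handing it to `accumulate(scores, b)`.
# One runif(nrow(track)) draw per permutation, in track row order, so every
# consumer sees the identical placement law and RNG stream.
.for_each_null <- function(annotation, track, sizes, n_permutations,
                           accumulate) {
  sizes <- chrom_sizes(sizes)
  gidx <- .gene_index(annotation)
  len <- as.numeric(track$end - track$start)
  room <- as.numeric(sizes[as.character(track$chrom)] - len)
  if (any(room < 0))
    stop("collective segment longer than its chromosome", call. = FALSE)
  chrom <- as.character(track$chrom)
  seg_by_chrom <- split(seq_len(nrow(track)), chrom)
  S <- track$n_samples
  ng <- nrow(annotation)
  for (b in seq_len(n_permutations)) {
    sstart <- .runif_int(room)
    scores <- numeric(ng)
    for (cn in names(gidx)) {
      gx <- gidx[[cn]]
      si <- seg_by_chrom[[cn]]
      if (is.null(si)) next
      res <- .chrom_scores(gx, sstart[si], sstart[si] + len[si], S[si])
      scores[gx$orig] <- res$score
    }
    accumulate(scores, b)
  }
  invisible(NULL)
}

#' Per-gene null score distributions under within-chromosome shuffling
#'
#' For each permutation, every collective segment is re-placed uniformly
#' within its chromosome ([shuffle_track()] law) and the gene score of every
#' annotated gene is recomputed with the same scoring rule as the observed
#' data. Genes on chromosomes without any collective segment have an
#' all-zero null.
#'
#' @inheritParams score_all_genes
#' @param sizes chromosome sizes.
#' @param config a [permutation_config()].
#' @return numeric matrix, genes (annotation order; rownames = symbols) by
#'   permutations.
#' @export
null_distributions <- function(annotation, track, sizes,
                               config = permutation_config()) {
  stopifnot(inherits(config, "cnd_perm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  null <- matrix(0, nrow(annotation), config$n_permutations,
                 dimnames = list(as.character(annotation$symbol), NULL))
  .for_each_null(annotation, track, sizes, config$n_permutations,
                 function(scores, b) null[, b] <<- scores)
  null
}

#' Add-one empirical p-value of an observed score
#'
#' `p = (1 + #(null >= observed)) / (1 + n_permutations)`: ties count as
#' exceedances and the add-one numerator/denominator guarantee a valid,
#' never-zero p-value (its floor is `1/(n_permutations + 1)`).
#'
#' @param observed observed score (scalar).
#' @param null numeric vector of null scores.
#' @param n_permutations expected length of `null` (defaults to
#'   `length(null)`).
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, null,
                             n_permutations = length(null)) {
  if (length(null) != n_permutations)
    stop("null vector length does not match n_permutations", call. = FALSE)
  (1 + sum(null >= observed)) / (1 + n_permutations)
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up FDR adjustment valid under arbitrary dependence:
#' `q_(i) = min(1, min_{j >= i} p_(j) * m * c(m) / j)` with
#' `c(m) = sum_{k=1..m} 1/k`, computed on the ascending order statistics and
#' mapped back to input order. Delegates to [stats::p.adjust()]
#' (`method = "BY"`) after validating the input.
#'
#' @param pvals numeric vector of p-values in `(0, 1]`.
#' @return adjusted p-values in `(0, 1]`, same order as input; monotone
#'   non-decreasing in the input p-values.
#' @examples
#' adjust_benjamini_yekutieli(c(0.01, 0.02, 0.03))  # all 0.055
#' @export
adjust_benjamini_yekutieli <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BY")
}

#' Per-gene significance of deletion scores
#'
#' Composes the full testing stage: observed scores ([score_all_genes()]),
#' the shuffling null, add-one empirical p-values, and genome-wide
#' Benjamini-Yekutieli adjustment across all scored genes (one analysis is
#' one family). A gene is flagged significant when its adjusted p-value is
#' below `config$alpha`. Null scores are streamed (exceedance counts only),
#' so memory stays flat in the number of permutations.
#'
#' @inheritParams null_distributions
#' @return data frame, one row per gene in annotation order: `symbol`,
#'   `chrom`, `start`, `end`, `score`, `n_segments`, `n_null` (null scores
#'   >= observed), `empirical_p`, `adjusted_p`, `significant`. Attributes
#'   `n_permutations`, `alpha`, `seed` record the configuration.
#' @export
significance_table <- function(annotation, track, sizes,
                               config = permutation_config()) {
  stopifnot(inherits(config, "cnd_perm_config"))
  observed <- score_all_genes(annotation, track)
  if (!is.null(config$seed)) set.seed(config$seed)
  exceed <- integer(nrow(annotation))
  .for_each_null(annotation, track, sizes, config$n_permutations,
                 function(scores, b) exceed <<- exceed + (scores >= observed$score))
  empirical_p <- (1 + exceed) / (1 + config$n_permutations)
  adjusted_p <- adjust_benjamini_yekutieli(empirical_p)
  out <- data.frame(symbol = observed$symbol,
                    chrom = as.character(annotation$chrom),
                    start = as.numeric(annotation$start),
                    end = as.numeric(annotation$end),
                    score = observed$score,
                    n_segments = observed$n_segments,
                    n_null = exceed,
                    empirical_p = empirical_p,
                    adjusted_p = adjusted_p,
                    significant = adjusted_p < config$alpha,
                    stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- config$n_permutations
  attr(out, "alpha") <- config$alpha
  attr(out, "seed") <- config$seed
  out
}
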