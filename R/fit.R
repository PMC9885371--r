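#' Fit the segmental-breakpoint deletion model to a cohort
#'
#' End-to-end analysis: per-sample normalization of the deletion segments,
#' construction of the breakpoint-partitioned collective track, gene scoring
#' (`sum_i S_i / (L_i + L_g)` over overlapping collective segments), a
#' within-chromosome shuffling null, add-one empirical p-values and
#' genome-wide Benjamini-Yekutieli FDR control.
#'
#' @param segments cohort deletion segments: data frame `sample`, `chrom`,
#'   `start`, `end` (0-based half-open; see [read_segments()] for file
#'   ingest).
#' @param annotation gene annotation: data frame `symbol`, `chrom`, `start`,
#'   `end` ([read_gene_annotation()]).
#' @param sizes chromosome sizes ([chrom_sizes()], [read_chrom_sizes()]).
#' @param n_permutations,alpha,seed see [permutation_config()].
#' @return an object of class `cndscan`: a list with `results` (the
#'   [significance_table()]), `track`, `annotation`, `sizes`, `config` and
#'   `call`.
#' @examples
#' sim <- generate_cohort(simulation_config(n_samples = 20, n_genes = 40,
#'                                          chrom_sizes = c(chr1 = 2e6),
#'                                          seed = 1))
#' fit <- cndscan(sim$cohort, sim$annotation, sim$config$chrom_sizes,
#'                n_permutations = 50, seed = 1)
#' fit
#' @export
cndscan <- function(segments, annotation, sizes, n_permutations = 1000L,
                    alpha = 0.05, seed = NULL) {
  sizes <- chrom_sizes(sizes)
  cohort <- normalize_cohort(segments, sizes)
  .check_intervals(annotation, sizes, what = "gene")
  track <- build_collective_track(cohort, sizes)
  config <- permutation_config(n_permutations = n_permutations, seed = seed,
                               alpha = alpha)
  results <- significance_table(annotation, track, sizes, config)
  structure(list(results = results, track = track, annotation = annotation,
                 sizes = sizes, config = config, call = match.call()),
            class = "cndscan")
}

#' @export
print.cndscan <- function(x, ...) {
  cat("Segmental-breakpoint CND significance model\n\n")
  cat(sprintf("  samples: %d   input segments: %d   collective segments: %d\n",
              attr(x$track, "n_samples_total"),
              attr(x$track, "n_input_segments"), nrow(x$track)))
  cat(sprintf("  genes scored: %d   permutations: %d   alpha: %g (BY-adjusted)\n",
              nrow(x$results), x$config$n_permutations, x$config$alpha))
  cat(sprintf("  significant genes: %d\n", sum(x$results$significant)))
  invisible(x)
}

#' @export
summary.cndscan <- function(object, n = 10L, ...) {
  r <- object$results
  ord <- order(r$empirical_p, -r$score)
  structure(list(n_samples = attr(object$track, "n_samples_total"),
                 n_segments = attr(object$track, "n_input_segments"),
                 n_collective = nrow(object$track),
                 n_genes = nrow(r),
                 n_permutations = object$config$n_permutations,
                 alpha = object$config$alpha,
                 n_significant = sum(r$significant),
                 top = utils::head(r[ord, , drop = FALSE], n)),
            class = "summary.cndscan")
}

#' @export
print.summary.cndscan <- function(x, ...) {
  cat("Segmental-breakpoint CND significance model\n\n")
  cat(sprintf("Cohort: %d samples, %d deletion segments -> %d collective segments\n",
              x$n_samples, x$n_segments, x$n_collective))
  cat(sprintf("Test:   %d genes, %d permutations, BY alpha %g -> %d significant\n\n",
              x$n_genes, x$n_permutations, x$alpha, x$n_significant))
  cat("Top genes by empirical p-value:\n")
  top <- x$top
  top$score <- signif(top$score, 4)
  top$empirical_p <- signif(top$empirical_p, 4)
  top$adjusted_p <- signif(top$adjusted_p, 4)
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cndscan <- function(object, ...) {
  stats::setNames(object$results$score, object$results$symbol)
}

#' Plot method: per-gene significance along the genome
#'
#' Draws -log10 empirical p-values by gene midpoint position, one panel per
#' chromosome laid out side by side, significant genes highlighted.
#'
#' @param x a `cndscan` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cndscan <- function(x, ...) {
  r <- x$results
  chroms <- names(x$sizes)[names(x$sizes) %in% unique(r$chrom)]
  offset <- stats::setNames(cumsum(c(0, as.numeric(x$sizes[chroms])))[seq_along(chroms)],
                            chroms)
  pos <- offset[r$chrom] + (r$start + r$end) / 2
  y <- -log10(r$empirical_p)
  graphics::plot(pos, y, pch = 16, cex = 0.6,
                 col = ifelse(r$significant, "firebrick", "grey40"),
                 xlab = "genomic position (concatenated chromosomes)",
                 ylab = expression(-log[10] ~ "empirical p"), ...)
  graphics::abline(v = offset[-1], lty = 3, col = "grey70")
  invisible(x)
}

#' Simulate from the fitted null
#'
#' Draws `nsim` within-chromosome shuffles of the fitted collective track
#' and returns the per-gene null score matrix, i.e. samples from the
#' distribution the observed scores are tested against.
#'
#' @param object a `cndscan` fit.
#' @param nsim number of shuffles.
#' @param seed optional seed.
#' @param ... unused.
#' @return genes-by-`nsim` matrix of null scores.
#' @export
simulate.cndscan <- function(object, nsim = 1, seed = NULL, ...) {
  null_distributions(object$annotation, object$track, object$sizes,
                     permutation_config(n_permutations = nsim, seed = seed,
                                        alpha = object$config$alpha))
}

#' Significant genes of a fit
#'
#' @param object a `cndscan` fit.
#' @return character vector of gene symbols with BY-adjusted p below alpha.
#' @export
significant_genes <- function(object) {
  stopifnot(inherits(object, "cndscan"))
  object$results$symbol[object$results$significant]
}
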