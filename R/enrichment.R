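#' Gene-set enrichment of significant genes
#'
#' One-sided (greater) Fisher exact test on the 2x2 table crossing
#' significant vs non-significant genes with in-set vs not-in-set
#' membership. The universe is the set of genes scored in the analysis (the
#' annotation), not the gene-set collection; set membership is intersected
#' with the universe first.
#'
#' @param sig character vector of significant gene symbols (must be a
#'   subset of `universe`).
#' @param universe character vector of all scored gene symbols.
#' @param gene_set character vector of gene symbols in the set.
#' @param name optional set name carried into the output.
#' @return one-row data frame: `set`, `n_sig_in_set`, `n_sig_not_in_set`,
#'   `n_nonsig_in_set`, `n_nonsig_not_in_set`, `odds_ratio`, `p_value`.
#' @export
set_enrichment <- function(sig, universe, gene_set, name = NA_character_) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  sig <- unique(as.character(sig))
  if (length(setdiff(sig, universe)))
    stop("significant genes must be a subset of the universe", call. = FALSE)
  inset <- universe %in% gene_set
  issig <- universe %in% sig
  a <- sum(issig & inset); b <- sum(issig & !inset)
  c_ <- sum(!issig & inset); d <- sum(!issig & !inset)
  data.frame(set = name, n_sig_in_set = a, n_sig_not_in_set = b,
             n_nonsig_in_set = c_, n_nonsig_not_in_set = d,
             odds_ratio = (a * d) / (b * c_),
             p_value = .fisher_greater(a, b, c_, d),
             stringsAsFactors = FALSE)
}

#' Enrichment of significant genes across a gene-set collection
#'
#' @inheritParams set_enrichment
#' @param gene_sets named list of symbol vectors ([read_gene_sets()]).
#' @return data frame with one [set_enrichment()] row per set.
#' @export
enrich_gene_sets <- function(sig, universe, gene_sets) {
  if (!length(gene_sets)) stop("no gene sets supplied", call. = FALSE)
  out <- do.call(rbind, lapply(names(gene_sets), function(nm)
    set_enrichment(sig, universe, gene_sets[[nm]], name = nm)))
  rownames(out) <- NULL
  out
}

# Internal: pathway p-value matrix (analyses x shared pathways) from a
# named list of enrich_gene_sets() tables.
.pathway_pmat <- function(analyses) {
  if (length(analyses) < 2L)
    stop("at least two analyses are required", call. = FALSE)
  if (is.null(names(analyses)) || any(names(analyses) == ""))
    stop("analyses must be a named list", call. = FALSE)
  shared <- Reduce(intersect, lapply(analyses, function(a) a$set))
  if (!length(shared))
    stop("analyses share no pathway", call. = FALSE)
  m <- vapply(analyses, function(a) a$p_value[match(shared, a$set)],
              numeric(length(shared)))
  m <- t(matrix(m, nrow = length(shared),
                dimnames = list(shared, names(analyses))))
  m
}

#' Standardized pathway significance matrix across analyses
#'
#' Builds the analyses-by-pathways matrix of `log10` one-sided Fisher
#' p-values and min-max standardizes each pathway column to `[0, 1]`, with
#' 0 at the lowest p (strongest enrichment). Columns constant across
#' analyses are set to 0 by convention.
#'
#' @param analyses named list of [enrich_gene_sets()] tables, one per
#'   analysis; pathways are matched by set name (intersection).
#' @return numeric matrix, analyses x pathways, values in `[0, 1]`.
#' @export
pathway_matrix <- function(analyses) {
  lp <- log10(.pathway_pmat(analyses))
  out <- apply(lp, 2L, function(v) {
    rng <- range(v)
    if (rng[1L] == rng[2L]) rep(0, length(v))
    else (v - rng[1L]) / (rng[2L] - rng[1L])
  })
  out <- matrix(out, nrow = nrow(lp), dimnames = dimnames(lp))
  out
}

#' Raw canonical-pathway significance matrix
#'
#' As [pathway_matrix()] but keeps the original one-sided Fisher p-values
#' unstandardized, the form used to compare a small canonical pathway panel
#' across analyses (clustering is then restricted to the pathway axis).
#'
#' @inheritParams pathway_matrix
#' @return numeric matrix, analyses x pathways, raw p-values.
#' @export
canonical_pathway_matrix <- function(analyses) {
  .pathway_pmat(analyses)
}

#' Hierarchical clustering of a significance matrix
#'
#' Agglomerative clustering with Euclidean distance and average linkage
#' (UPGMA), run on the rows, the columns, or both. `hclust` merges are
#' deterministic (lowest-index merge on ties).
#'
#' @param m numeric matrix with row and column names.
#' @param axis `"both"`, `"rows"` or `"cols"`.
#' @return list with `rows` and `cols` (each an [stats::hclust] or `NULL`)
#'   plus `row_order`/`col_order` label vectors.
#' @export
hierarchical_cluster <- function(m, axis = c("both", "rows", "cols")) {
  axis <- match.arg(axis)
  if (any(!is.finite(m)))
    stop("matrix contains non-finite values", call. = FALSE)
  cl <- function(x) {
    if (nrow(x) < 2L)
      stop("need at least two observations to cluster", call. = FALSE)
    stats::hclust(stats::dist(x, method = "euclidean"), method = "average")
  }
  rows <- if (axis %in% c("both", "rows")) cl(m) else NULL
  cols <- if (axis %in% c("both", "cols")) cl(t(m)) else NULL
  list(rows = rows, cols = cols,
       row_order = if (!is.null(rows)) rownames(m)[rows$order] else rownames(m),
       col_order = if (!is.null(cols)) colnames(m)[cols$order] else colnames(m))
}

#' Export a dendrogram in Newick format
#'
#' @param hc an [stats::hclust] object.
#' @param path output file, or `NULL` to return the Newick string.
#' @return the Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export", call. = FALSE)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Genome-wide significance profile of an analysis
#'
#' @param results a [significance_table()] (or `cndscan` fit).
#' @param id analysis identifier.
#' @return a `cnd_profile`: list with `id`, `symbols`, `p` (per-gene
#'   empirical p-values, in `(0, 1]`).
#' @export
significance_profile <- function(results, id) {
  if (inherits(results, "cndscan")) results <- results$results
  structure(list(id = as.character(id),
                 symbols = as.character(results$symbol),
                 p = as.numeric(results$empirical_p)),
            class = "cnd_profile")
}

#' Two-dimensional UMAP embedding of significance profiles
#'
#' Embeds per-analysis genome-wide empirical p-value vectors in 2-D with
#' UMAP, for cohort-similarity maps. Gene lists are intersected and
#' reordered so all profiles align; raw empirical p-values are embedded by
#' default (`transform = "log10"` offers -log10 as an alternative).
#'
#' @param profiles list of [significance_profile()] objects (at least 3).
#' @param n_neighbors UMAP neighborhood size (capped at
#'   `length(profiles) - 1`).
#' @param min_dist UMAP minimum embedding distance.
#' @param seed integer seed; the embedding is deterministic given it.
#' @param transform `"none"` (raw p) or `"log10"` (-log10 p).
#' @return data frame `id`, `x`, `y`; attribute `parameters` records the
#'   settings used.
#' @export
embed_profiles <- function(profiles, n_neighbors = 15L, min_dist = 0.1,
                           seed = NULL, transform = c("none", "log10")) {
  transform <- match.arg(transform)
  if (length(profiles) < 3L)
    stop("at least 3 profiles are required for embedding", call. = FALSE)
  if (!all(vapply(profiles, inherits, logical(1), "cnd_profile")))
    stop("profiles must be cnd_profile objects", call. = FALSE)
  if (!requireNamespace("uwot", quietly = TRUE))
    stop("the 'uwot' package is required for UMAP embedding", call. = FALSE)
  shared <- Reduce(intersect, lapply(profiles, `[[`, "symbols"))
  if (length(shared) < 2L)
    stop("profiles share fewer than 2 genes", call. = FALSE)
  x <- t(vapply(profiles, function(p) p$p[match(shared, p$symbols)],
                numeric(length(shared))))
  if (transform == "log10") x <- -log10(x)
  nn <- max(2L, min(as.integer(n_neighbors), nrow(x) - 1L))
  if (!is.null(seed)) set.seed(seed)
  # spectral initialization needs more points than the embedding rank;
  # fall back to (seeded) random placement for very small profile sets
  init <- if (nrow(x) < 8L) "random" else "spectral"
  coords <- uwot::umap(x, n_neighbors = nn, min_dist = min_dist,
                       init = init, n_threads = 1, n_sgd_threads = 0)
  out <- data.frame(id = vapply(profiles, `[[`, character(1), "id"),
                    x = coords[, 1L], y = coords[, 2L],
                    stringsAsFactors = FALSE)
  attr(out, "parameters") <- list(n_neighbors = nn, min_dist = min_dist,
                                  seed = seed, transform = transform,
                                  n_genes = length(shared))
  out
}
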