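#' Collapse a cohort's deletions into the collective segment track
#'
#' Every distinct segment boundary (start or end of any sample's deletion)
#' partitions its chromosome into atoms; each atom covered by at least one
#' sample becomes a collective segment carrying the number of covering
#' samples `n_samples` (the S_i of the gene score) and its length
#' `end - start` (L_i). Zero-coverage gaps are excluded. Atoms are never
#' merged across breakpoints, even when adjacent atoms have equal S_i: the
#' partition is defined purely by distinct breakpoints, because each atom is
#' a separate term of the gene score.
#'
#' The input must be normalized per sample ([normalize_cohort()]): within a
#' sample, segments are disjoint, so per-bp coverage equals the number of
#' deleted samples.
#'
#' @param cohort normalized cohort segment table (`sample`, `chrom`, `start`,
#'   `end`).
#' @param sizes optional chromosome sizes for strict validation.
#' @return a `cnd_track`: data frame `chrom`, `start`, `end`, `n_samples`,
#'   sorted by (chrom, start), with attributes `n_samples_total` (samples in
#'   the cohort table) and `n_input_segments`.
#' @export
build_collective_track <- function(cohort, sizes = NULL) {
  if (!"sample" %in% names(cohort))
    stop("cohort table lacks a 'sample' column", call. = FALSE)
  if (nrow(cohort) == 0L)
    stop("cannot build a collective track from an empty cohort", call. = FALSE)
  .check_intervals(cohort, sizes, what = "segment")
  out <- lapply(split(cohort, as.character(cohort$chrom)), function(d) {
    bp <- sort(unique(c(d$start, d$end)))
    atom_start <- bp[-length(bp)]
    atom_end <- bp[-1L]
    # coverage sweep: +1 at each segment start, -1 at each end
    delta <- rowsum(c(rep(1, nrow(d)), rep(-1, nrow(d))), c(d$start, d$end))
    cov <- cumsum(delta[match(atom_start, as.numeric(rownames(delta))), 1L])
    keep <- cov >= 1L
    data.frame(chrom = d$chrom[1L], start = atom_start[keep],
               end = atom_end[keep], n_samples = as.integer(cov[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  structure(out,
            n_samples_total = length(unique(as.character(cohort$sample))),
            n_input_segments = nrow(cohort),
            class = c("cnd_track", "data.frame"))
}

#' Segment breakpoints of a cohort
#'
#' Each sample segment contributes its start and its end; multiplicity across
#' samples is preserved (two samples sharing a boundary yield two
#' breakpoints).
#'
#' @inheritParams build_collective_track
#' @return data frame `chrom`, `pos` with one row per breakpoint occurrence,
#'   sorted by (chrom, pos).
#' @export
segment_breakpoints <- function(cohort) {
  .check_intervals(cohort, what = "segment")
  out <- data.frame(chrom = rep(as.character(cohort$chrom), 2L),
                    pos = c(cohort$start, cohort$end),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a collective track as BED
#'
#' One line per collective segment; the BED name column carries the covering
#' sample count, for inspection with standard genome-arithmetic tools.
#'
#' @param track a `cnd_track` from [build_collective_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  stopifnot(inherits(track, "cnd_track"))
  lines <- sprintf("%s\t%s\t%s\t%d", track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   track$n_samples)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.cnd_track <- function(x, ...) {
  cat(sprintf(
    "Collective CND track: %d segments on %d chromosome(s), %d sample(s)\n",
    nrow(x), length(unique(x$chrom)), attr(x, "n_samples_total")))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more segments\n", nrow(x) - 10L))
  invisible(x)
}
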