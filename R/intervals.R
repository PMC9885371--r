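#' @title Genomic interval conventions
#'
#' @description
#' All coordinates in cndscan are 0-based, half-open: an interval covers the
#' bases `start, start+1, ..., end-1`, and its length is `end - start`.
#' Readers convert on ingest (see [read_segments()]). Chromosome names are
#' taken verbatim from input; no "chr"-prefix rewriting is performed.
#'
#' Cohort deletion segments are held as a plain data frame with columns
#' `sample`, `chrom`, `start`, `end` (one row per deletion segment); gene
#' annotation as a data frame with columns `symbol`, `chrom`, `start`, `end`;
#' chromosome sizes as a named numeric vector of lengths in bp.
#'
#' @name cndscan-coordinates
NULL

#' Validate a chromosome sizes table
#'
#' @param sizes named numeric vector mapping chromosome name to length in bp.
#' @return the validated vector, invisibly usable downstream.
#' @export
chrom_sizes <- function(sizes) {
  if (is.data.frame(sizes)) {
    if (ncol(sizes) < 2L)
      stop("chromosome sizes need two columns: name, length", call. = FALSE)
    sizes <- stats::setNames(as.numeric(sizes[[2L]]), as.character(sizes[[1L]]))
  }
  if (is.null(names(sizes)) || any(names(sizes) == ""))
    stop("chromosome sizes must be named", call. = FALSE)
  if (anyDuplicated(names(sizes)))
    stop("duplicate chromosome names in sizes table", call. = FALSE)
  sizes <- stats::setNames(as.numeric(sizes), names(sizes))
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all chromosome lengths must be positive and finite", call. = FALSE)
  sizes
}

# Internal: validate an interval data frame (any extra columns pass through).
# `sizes` optional; when given, strict chromosome membership + bounds checks.
.check_intervals <- function(x, sizes = NULL, what = "interval") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
    stop(sprintf("%s coordinates must be finite numbers", what), call. = FALSE)
  if (any(x$start < 0))
    stop(sprintf("%s start positions must be >= 0", what), call. = FALSE)
  if (any(x$end <= x$start))
    stop(sprintf("%s intervals must satisfy end > start (0-based half-open)",
                 what), call. = FALSE)
  if (!is.null(sizes)) {
    sizes <- chrom_sizes(sizes)
    unknown <- setdiff(unique(as.character(x$chrom)), names(sizes))
    if (length(unknown))
      stop(sprintf("%s on chromosome(s) absent from sizes table: %s", what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    if (any(x$end > sizes[as.character(x$chrom)]))
      stop(sprintf("%s extends beyond chromosome end", what), call. = FALSE)
  }
  invisible(x)
}

#' Overlap length of two genomic intervals
#'
#' Returns the number of shared bases of two 0-based half-open intervals, or 0
#' when they lie on different chromosomes. Book-ended intervals
#' (`a$end == b$start`) share no base and return 0.
#'
#' @param a,b lists or one-row data frames with `chrom`, `start`, `end`.
#' @return integer overlap length in bp (>= 0).
#' @examples
#' interval_overlap(list(chrom = "chr1", start = 0, end = 100),
#'                  list(chrom = "chr1", start = 50, end = 150))  # 50
#' @export
interval_overlap <- function(a, b) {
  if (as.character(a$chrom) != as.character(b$chrom)) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Normalize one sample's deletion segments
#'
#' Sorts segments per chromosome and merges overlapping or book-ended
#' (`end == next start`) intervals, so that within one sample and chromosome
#' the stored segments are pairwise disjoint and sorted. A deletion split by
#' the caller at an internal point is one event for sample-counting purposes;
#' merging book-ended pieces prevents double-counting a sample in the
#' collective track. Idempotent; total covered bp is preserved.
#'
#' @param segments data frame with columns `chrom`, `start`, `end` (extra
#'   columns are dropped).
#' @param sizes optional chromosome sizes for strict validation.
#' @return data frame `chrom`, `start`, `end`, sorted by (chrom, start).
#' @export
normalize_segments <- function(segments, sizes = NULL) {
  .check_intervals(segments, sizes, what = "segment")
  segments <- data.frame(chrom = as.character(segments$chrom),
                         start = as.numeric(segments$start),
                         end = as.numeric(segments$end),
                         stringsAsFactors = FALSE)
  if (nrow(segments) <= 1L) {
    return(segments[order(segments$chrom, segments$start), , drop = FALSE])
  }
  out <- lapply(split(segments, segments$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    ns <- d$start[1L]; ne <- d$end[1L]
    starts <- numeric(0); ends <- numeric(0)
    if (nrow(d) > 1L) {
      for (i in 2L:nrow(d)) {
        if (d$start[i] <= ne) {          # overlap or book-ended: extend
          ne <- max(ne, d$end[i])
        } else {
          starts <- c(starts, ns); ends <- c(ends, ne)
          ns <- d$start[i]; ne <- d$end[i]
        }
      }
    }
    starts <- c(starts, ns); ends <- c(ends, ne)
    data.frame(chrom = d$chrom[1L], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Normalize every sample of a cohort segment table
#'
#' Applies [normalize_segments()] within each sample of a cohort table.
#'
#' @param cohort data frame with columns `sample`, `chrom`, `start`, `end`.
#' @param sizes optional chromosome sizes for strict validation.
#' @return data frame with the same columns, normalized per sample and sorted
#'   by (sample, chrom, start). Samples with zero segments disappear from the
#'   table; callers that must retain them track sample ids separately.
#' @export
normalize_cohort <- function(cohort, sizes = NULL) {
  if (!"sample" %in% names(cohort))
    stop("cohort table lacks a 'sample' column", call. = FALSE)
  .check_intervals(cohort, sizes, what = "segment")
  if (nrow(cohort) == 0L) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE))
  }
  parts <- split(cohort, as.character(cohort$sample))
  out <- lapply(names(parts), function(sid) {
    seg <- normalize_segments(parts[[sid]])
    if (nrow(seg) == 0L) return(NULL)
    cbind(data.frame(sample = sid, stringsAsFactors = FALSE), seg)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample, out$chrom, out$start), , drop = FALSE]
}
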