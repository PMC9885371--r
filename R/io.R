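#' Segment-table dialect
#'
#' Describes how to read a tab-delimited cohort segment table: which columns
#' hold the sample id, chromosome and coordinates, how deletion rows are
#' recognized, and whether coordinates are 1-based inclusive. The deletion
#' filter accepts either a categorical state column matched against
#' `deletion_states`, or a numeric `value_column` compared against an
#' explicit `value_threshold` (`value < threshold`). No default numeric
#' threshold is assumed: deletion calling cutoffs are platform-dependent
#' and must be set by the user.
#'
#' @param preset `"generic"` (columns `sample`, `chrom`, `start`, `end`,
#'   `state`) or `"pgxseg"` (columns `biosample_id`, `reference_name`,
#'   `start`, `end`, `variant_type`).
#' @param sample,chrom,start,end,state column names; override the preset.
#' @param deletion_states state values accepted as deletions.
#' @param value_column,value_threshold alternative numeric filter: keep rows
#'   with `value_column < value_threshold`. Both must be given together.
#' @param one_based `TRUE` when input coordinates are 1-based inclusive;
#'   they are converted to 0-based half-open on ingest.
#' @return a `cnd_dialect` list.
#' @export
segment_dialect <- function(preset = c("generic", "pgxseg"),
                            sample = NULL, chrom = NULL, start = NULL,
                            end = NULL, state = NULL,
                            deletion_states = c("DEL", "HOMODEL", "HLDEL",
                                                "-1", "-2"),
                            value_column = NULL, value_threshold = NULL,
                            one_based = FALSE) {
  preset <- match.arg(preset)
  cols <- switch(preset,
    generic = list(sample = "sample", chrom = "chrom", start = "start",
                   end = "end", state = "state"),
    pgxseg = list(sample = "biosample_id", chrom = "reference_name",
                  start = "start", end = "end", state = "variant_type"))
  if (!is.null(sample)) cols$sample <- sample
  if (!is.null(chrom)) cols$chrom <- chrom
  if (!is.null(start)) cols$start <- start
  if (!is.null(end)) cols$end <- end
  if (!is.null(state)) cols$state <- state
  if (xor(is.null(value_column), is.null(value_threshold)))
    stop("value_column and value_threshold must be given together",
         call. = FALSE)
  if (!is.logical(one_based) || length(one_based) != 1L || is.na(one_based))
    stop("one_based must be TRUE or FALSE", call. = FALSE)
  structure(list(columns = cols,
                 deletion_states = as.character(deletion_states),
                 value_column = value_column,
                 value_threshold = value_threshold,
                 one_based = one_based),
            class = "cnd_dialect")
}

#' Read a cohort deletion-segment table
#'
#' Reads a tab-delimited segment table under a [segment_dialect()]: keeps
#' only rows passing the deletion filter, converts coordinates to 0-based
#' half-open, rejects malformed rows (non-numeric coordinates, or
#' `end <= start` after conversion) with a warning naming their line
#' numbers, and normalizes each sample ([normalize_cohort()]). Row counts
#' reconcile as `rows_in = rows_kept + rows_filtered + rows_malformed` and
#' are stored as attributes and reported via [message()].
#'
#' @param path tab-delimited file with a header line.
#' @param dialect a [segment_dialect()].
#' @param sizes optional chromosome sizes; when given, unknown chromosomes
#'   or out-of-bounds segments are an error (strict mode).
#' @return normalized cohort segment table (`sample`, `chrom`, `start`,
#'   `end`) with attributes `rows_in`, `rows_kept`, `rows_filtered`,
#'   `rows_malformed`.
#' @export
read_segments <- function(path, dialect = segment_dialect(), sizes = NULL) {
  stopifnot(inherits(dialect, "cnd_dialect"))
  if (!file.exists(path))
    stop(sprintf("segment file not found: %s", path), call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- unlist(dialect$columns[c("sample", "chrom", "start", "end")])
  filt_col <- if (!is.null(dialect$value_column)) dialect$value_column else
    dialect$columns$state
  miss <- setdiff(c(need, filt_col), names(raw))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  rows_in <- nrow(raw)
  if (rows_in == 0L) {
    out <- data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "rows_in") <- 0L; attr(out, "rows_kept") <- 0L
    attr(out, "rows_filtered") <- 0L; attr(out, "rows_malformed") <- 0L
    return(out)
  }
  line_no <- seq_len(rows_in) + 1L          # header is line 1
  # deletion filter
  if (!is.null(dialect$value_column)) {
    val <- suppressWarnings(as.numeric(raw[[dialect$value_column]]))
    keep <- !is.na(val) & val < dialect$value_threshold
  } else {
    keep <- raw[[dialect$columns$state]] %in% dialect$deletion_states
  }
  rows_filtered <- sum(!keep)
  kept <- raw[keep, , drop = FALSE]
  kept_lines <- line_no[keep]
  start <- suppressWarnings(as.numeric(kept[[dialect$columns$start]]))
  end <- suppressWarnings(as.numeric(kept[[dialect$columns$end]]))
  if (dialect$one_based) start <- start - 1  # [s,e] 1-based -> [s-1,e) 0-based
  bad <- is.na(start) | is.na(end) | start < 0 | end <= start
  if (any(bad))
    warning(sprintf("%s: dropped %d malformed row(s) at line(s) %s", path,
                    sum(bad), paste(utils::head(kept_lines[bad], 20L),
                                    collapse = ", ")), call. = FALSE)
  rows_malformed <- sum(bad)
  cohort <- data.frame(sample = as.character(kept[[dialect$columns$sample]][!bad]),
                       chrom = as.character(kept[[dialect$columns$chrom]][!bad]),
                       start = start[!bad], end = end[!bad],
                       stringsAsFactors = FALSE)
  out <- normalize_cohort(cohort, sizes)
  message(sprintf(
    "%s: %d rows in, %d kept as deletions, %d filtered, %d malformed",
    basename(path), rows_in, nrow(cohort), rows_filtered, rows_malformed))
  attr(out, "rows_in") <- rows_in
  attr(out, "rows_kept") <- nrow(cohort)
  attr(out, "rows_filtered") <- rows_filtered
  attr(out, "rows_malformed") <- rows_malformed
  out
}

#' Read gene annotation from BED4 or minimal GFF3
#'
#' BED4: `chrom start end name`, already 0-based half-open. GFF3: feature
#' lines with type `gene`; 1-based inclusive coordinates are converted; the
#' symbol comes from the `gene_name`, `Name` or `ID` attribute (first
#' found). Duplicate symbols are an error in strict mode; otherwise the
#' records are merged into a single span `min(start)`-`max(end)` (same
#' chromosome required).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param strict error on duplicate symbols instead of merging.
#' @return data frame `symbol`, `chrom`, `start`, `end`, sorted by
#'   (chrom, start).
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3"),
                                 strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("annotation file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "bed"
  }
  if (format == "bed") {
    d <- utils::read.delim(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(d) < 4L)
      stop("BED annotation needs 4 columns: chrom start end name",
           call. = FALSE)
    genes <- data.frame(symbol = as.character(d[[4L]]),
                        chrom = as.character(d[[1L]]),
                        start = as.numeric(d[[2L]]),
                        end = as.numeric(d[[3L]]),
                        stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, length, integer(1)) >= 9L]
    f <- f[vapply(f, `[[`, character(1), 3L) == "gene"]
    if (!length(f)) stop("no gene features in GFF3 file", call. = FALSE)
    attr_field <- vapply(f, `[[`, character(1), 9L)
    sym <- vapply(attr_field, function(a) {
      for (key in c("gene_name", "Name", "ID")) {
        m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]+)"), a))[[1L]]
        if (length(m) == 2L) return(m[2L])
      }
      NA_character_
    }, character(1), USE.NAMES = FALSE)
    if (anyNA(sym))
      stop("GFF3 gene feature without gene_name/Name/ID attribute",
           call. = FALSE)
    genes <- data.frame(symbol = sym,
                        chrom = vapply(f, `[[`, character(1), 1L),
                        start = as.numeric(vapply(f, `[[`, character(1), 4L)) - 1,
                        end = as.numeric(vapply(f, `[[`, character(1), 5L)),
                        stringsAsFactors = FALSE)
  }
  if (nrow(genes) == 0L) stop("annotation contains zero genes", call. = FALSE)
  if (anyDuplicated(genes$symbol)) {
    if (strict)
      stop("duplicate gene symbol(s) in annotation: ",
           paste(unique(genes$symbol[duplicated(genes$symbol)]),
                 collapse = ", "), call. = FALSE)
    genes <- do.call(rbind, lapply(split(genes, genes$symbol), function(d) {
      if (length(unique(d$chrom)) > 1L)
        stop(sprintf("gene %s appears on multiple chromosomes", d$symbol[1L]),
             call. = FALSE)
      data.frame(symbol = d$symbol[1L], chrom = d$chrom[1L],
                 start = min(d$start), end = max(d$end),
                 stringsAsFactors = FALSE)
    }))
  }
  .check_intervals(genes, what = "gene")
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Read gene sets (GMT or plain symbol list)
#'
#' GMT lines are `name<TAB>description<TAB>symbol...`; a file without tabs
#' is read as a single one-symbol-per-line set named after the file. Blank
#' lines are ignored, symbols deduplicated within a set, and empty sets
#' dropped with a warning.
#'
#' @param path input file.
#' @return named list of character symbol vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path))
    stop(sprintf("gene-set file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("gene-set file is empty", call. = FALSE)
    return(stats::setNames(list(), character(0)))
  }
  if (any(grepl("\t", lines, fixed = TRUE))) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(f, function(x)
      unique(x[-(1:2)][nzchar(x[-(1:2)])]))
    names(sets) <- vapply(f, `[[`, character(1), 1L)
  } else {
    nm <- sub("\\.[^.]*$", "", basename(path))
    sets <- stats::setNames(list(unique(trimws(lines))), nm)
  }
  empty <- vapply(sets, length, integer(1)) == 0L
  if (any(empty))
    warning(sprintf("dropped %d empty gene set(s): %s", sum(empty),
                    paste(names(sets)[empty], collapse = ", ")),
            call. = FALSE)
  sets[!empty]
}

#' Read a chromosome sizes table
#'
#' Two tab-delimited columns, chromosome name and length in bp (UCSC
#' `chrom.sizes` style, no header).
#'
#' @param path input file.
#' @return named numeric vector ([chrom_sizes()]).
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path))
    stop(sprintf("chromosome sizes file not found: %s", path), call. = FALSE)
  d <- utils::read.delim(path, header = FALSE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  chrom_sizes(stats::setNames(as.numeric(d[[2L]]), as.character(d[[1L]])))
}

#' Write a gene significance table
#'
#' Tab-delimited, deterministic row order (chrom, start, symbol), numeric
#' columns at 12 significant digits so values round-trip losslessly through
#' [read_results()]. Optional metadata is written as leading `# key: value`
#' comment lines.
#'
#' @param results a [significance_table()] data frame.
#' @param path output file.
#' @param metadata optional named list written as `#` header lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, metadata = NULL) {
  need <- c("symbol", "chrom", "start", "end", "score", "n_null",
            "empirical_p", "adjusted_p", "significant")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("results table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  r <- results[order(results$chrom, results$start, results$symbol),
               need, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(sprintf("# %s: %s", names(metadata),
                       vapply(metadata, function(v)
                         paste(format(v, scientific = FALSE, trim = TRUE),
                               collapse = ","), character(1))), con)
  writeLines(paste(need, collapse = "\t"), con)
  if (nrow(r))
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s\t%d\t%s\t%s\t%s",
                       r$symbol, r$chrom,
                       format(r$start, scientific = FALSE, trim = TRUE),
                       format(r$end, scientific = FALSE, trim = TRUE),
                       sprintf("%.12g", r$score), as.integer(r$n_null),
                       sprintf("%.12g", r$empirical_p),
                       sprintf("%.12g", r$adjusted_p),
                       ifelse(r$significant, "TRUE", "FALSE")), con)
  invisible(path)
}

#' Read back a gene significance table
#'
#' @param path file written by [write_results()].
#' @return data frame with the table's columns; `#` metadata lines skipped.
#' @export
read_results <- function(path) {
  if (!file.exists(path))
    stop(sprintf("results file not found: %s", path), call. = FALSE)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  d$significant <- as.logical(d$significant)
  d
}
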