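#' Barcode count table
#'
#' The central currency between pipeline stages: a named integer vector of
#' read counts per barcode sequence, together with bookkeeping on how many
#' raw reads went in and how many yielded a barcode.
#'
#' @param counts Named non-negative numeric vector; names are barcode
#'   sequences (A/C/G/T), values read counts.
#' @param sample_id Optional sample label.
#' @param total_reads_in Number of raw reads the table was derived from.
#'   Defaults to `sum(counts)` (i.e. a table not derived from raw reads).
#' @param reads_extracted Number of reads that yielded a barcode. Defaults
#'   to `sum(counts)` and must equal it.
#'
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, sample_id = NA_character_,
                        total_reads_in = NULL, reads_extracted = NULL) {
  if (length(counts) > 0L) {
    if (is.null(names(counts)) || anyNA(names(counts)) || any(names(counts) == ""))
      stop("'counts' must be named by barcode sequence")
    if (anyDuplicated(names(counts)))
      stop("duplicate barcode sequences in 'counts'")
    if (any(counts < 0)) stop("counts must be non-negative")
    bad <- grepl("[^ACGT]", names(counts))
    if (any(bad))
      stop("invalid nucleotide characters in barcode(s): ",
           paste(utils::head(names(counts)[bad], 3L), collapse = ", "))
  }
  n_ext <- sum(counts)
  if (is.null(reads_extracted)) reads_extracted <- n_ext
  if (is.null(total_reads_in)) total_reads_in <- reads_extracted
  if (reads_extracted != n_ext)
    stop("reads_extracted must equal sum(counts)")
  if (reads_extracted > total_reads_in)
    stop("reads_extracted cannot exceed total_reads_in")
  structure(
    list(counts = counts, sample_id = sample_id,
         total_reads_in = as.numeric(total_reads_in),
         reads_extracted = as.numeric(reads_extracted)),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d barcodes, %s reads", length(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!is.na(x$sample_id)) cat(sprintf(" [%s]", x$sample_id))
  cat("\n")
  if (x$total_reads_in > x$reads_extracted)
    cat(sprintf("  extracted %s / %s raw reads\n",
                format(x$reads_extracted, big.mark = ","),
                format(x$total_reads_in, big.mark = ",")))
  invisible(x)
}

#' Read a barcode count table from TSV/CSV
#'
#' Expects two columns (barcode, count); a header line is detected and
#' skipped. Duplicate barcodes are summed with a warning.
#'
#' @param path File path (plain or gzipped).
#' @param sample_id Optional sample label; defaults to the file name.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- basename(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(count_table(integer(0), sample_id = sample_id))
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad_ncol <- which(lengths(parts) < 2L)
  if (length(bad_ncol))
    stop("line ", bad_ncol[[1]], ": expected 2 columns (barcode, count)")
  first <- trimws(parts[[1]])
  start <- 1L
  if (grepl("[^ACGT]", first[[1]]) || is.na(suppressWarnings(as.numeric(first[[2]]))))
    start <- 2L  # header
  if (start > length(parts))
    return(count_table(integer(0), sample_id = sample_id))
  bc <- vapply(parts[start:length(parts)], function(p) trimws(p[[1]]), "")
  cnt_chr <- vapply(parts[start:length(parts)], function(p) trimws(p[[2]]), "")
  cnt <- suppressWarnings(as.numeric(cnt_chr))
  line_no <- seq(start, length(parts))
  if (anyNA(cnt) || any(cnt != floor(cnt)))
    stop("line ", line_no[which(is.na(cnt) | cnt != floor(cnt))[1]],
         ": count is not a non-negative integer")
  if (any(cnt < 0))
    stop("line ", line_no[which(cnt < 0)[1]], ": negative count")
  bad <- grepl("[^ACGT]", bc)
  if (any(bad))
    stop("line ", line_no[which(bad)[1]], ": invalid nucleotide in barcode '",
         bc[which(bad)[1]], "'")
  if (anyDuplicated(bc)) {
    warning("duplicate barcodes summed in ", basename(path))
    agg <- tapply(cnt, bc, sum)
    cnt <- as.numeric(agg)
    bc <- names(agg)
  }
  names(cnt) <- bc
  count_table(cnt, sample_id = sample_id)
}

#' Write a count table as two-column TSV (barcode, count)
#'
#' @param x A [count_table()] or named count vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  cnt <- if (inherits(x, "count_table")) x$counts else x
  cnt <- sort(cnt, decreasing = TRUE)
  utils::write.table(
    data.frame(barcode = names(cnt), count = unname(cnt)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a structured JSON report
#'
#' Every report carries a schema version, the package version, the seed used
#' (if any) and md5 checksums of declared input files, so each artifact is
#' reproducible from its recorded configuration.
#'
#' @param result A serializable list of results.
#' @param path Output JSON path.
#' @param seed Seed used for any randomness, or `NULL`.
#' @param inputs Character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, seed = NULL, inputs = character()) {
  checks <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  payload <- list(
    schema_version = "1.0",
    tool = "clonotrace",
    tool_version = as.character(utils::packageVersion("clonotrace")),
    seed = seed,
    input_md5 = checks,
    result = result)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
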