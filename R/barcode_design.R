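#' Barcode layout specification
#'
#' A cellular barcode combines a randomized region (default 15 nt, giving
#' 4^15 ~ 1.07e9 possible labels) with a block of fixed metadata positions
#' (default 10 nt) that encode cell-line provenance. The metadata block sits
#' adjacent to the randomized region, not interleaved with it.
#'
#' @param random_length Length of the randomized region in nucleotides.
#' @param meta_length Length of the fixed metadata block in nucleotides.
#' @return An object of class `barcode_spec`.
#' @export
barcode_spec <- function(random_length = 15L, meta_length = 10L) {
  random_length <- as.integer(random_length)
  meta_length <- as.integer(meta_length)
  if (random_length < 1L) stop("random_length must be >= 1")
  if (meta_length < 0L) stop("meta_length must be >= 0")
  structure(list(random_length = random_length, meta_length = meta_length,
                 alphabet = c("A", "C", "G", "T")),
            class = "barcode_spec")
}

#' Cell-line metadata tag
#'
#' Holds the provenance fields encoded into the fixed metadata positions:
#' campaign year, cell line development (CLD) campaign index within that
#' year, host cell line identifier and expressed molecule identifier.
#'
#' @param year Calendar year of the campaign.
#' @param cld_number CLD campaign index within the year (0-based).
#' @param host_id Host cell line identifier (0-based).
#' @param molecule_id Expressed molecule identifier (0-based).
#' @return An object of class `metadata_tag`.
#' @export
metadata_tag <- function(year, cld_number = 0L, host_id = 0L, molecule_id = 0L) {
  structure(list(year = as.integer(year), cld_number = as.integer(cld_number),
                 host_id = as.integer(host_id), molecule_id = as.integer(molecule_id)),
            class = "metadata_tag")
}

#' Default metadata codebook
#'
#' Fixed-width positional base-4 code over the alphabet A=0, C=1, G=2, T=3.
#' Field widths: year 2 nt (stored as offset from `base_year`, capacity 16),
#' cld_number 3 nt (capacity 64), host_id 2 nt (capacity 16), molecule_id
#' 3 nt (capacity 64); 10 nt in total. The codebook is a plain list so users
#' can substitute their own layout (see [read_codebook()]).
#'
#' @param base_year Year encoded as 0.
#' @return A codebook list with `fields` (name, width, offset) and `alphabet`.
#' @export
default_codebook <- function(base_year = 2020L) {
  list(
    alphabet = c("A", "C", "G", "T"),
    fields = list(
      year        = list(width = 2L, offset = as.integer(base_year)),
      cld_number  = list(width = 3L, offset = 0L),
      host_id     = list(width = 2L, offset = 0L),
      molecule_id = list(width = 3L, offset = 0L)))
}

#' @rdname default_codebook
#' @param path JSON file with `alphabet` and `fields` entries.
#' @export
read_codebook <- function(path) {
  cb <- jsonlite::read_json(path, simplifyVector = TRUE)
  cb$alphabet <- as.character(cb$alphabet)
  cb$fields <- lapply(cb$fields, function(f)
    list(width = as.integer(f$width), offset = as.integer(f$offset)))
  cb
}

#' @rdname default_codebook
#' @param codebook A codebook list.
#' @export
write_codebook <- function(codebook, path) {
  jsonlite::write_json(codebook, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

int_to_base4 <- function(x, width, alphabet) {
  digits <- integer(width)
  for (i in seq_len(width)) {
    digits[width - i + 1L] <- x %% 4L
    x <- x %/% 4L
  }
  paste(alphabet[digits + 1L], collapse = "")
}

base4_to_int <- function(code, alphabet) {
  d <- match(strsplit(code, "")[[1]], alphabet) - 1L
  if (anyNA(d)) stop("letter outside codebook alphabet in '", code, "'")
  sum(d * 4L^rev(seq_along(d) - 1L))
}

#' Encode a metadata tag into the fixed barcode positions
#'
#' @param tag A [metadata_tag()].
#' @param spec A [barcode_spec()]; the codebook widths must sum to
#'   `spec$meta_length`.
#' @param codebook Codebook layout, see [default_codebook()].
#' @return Nucleotide string of length `spec$meta_length`.
#' @export
encode_metadata <- function(tag, spec = barcode_spec(),
                            codebook = default_codebook()) {
  widths <- vapply(codebook$fields, `[[`, 1L, "width")
  if (sum(widths) != spec$meta_length)
    stop("codebook widths (", sum(widths), ") do not fill meta_length (",
         spec$meta_length, ")")
  parts <- character(length(codebook$fields))
  for (i in seq_along(codebook$fields)) {
    fname <- names(codebook$fields)[i]
    f <- codebook$fields[[i]]
    val <- tag[[fname]] - f$offset
    cap <- 4L^f$width
    if (is.null(tag[[fname]]) || is.na(val) || val < 0L || val >= cap)
      stop("field '", fname, "' out of codebook capacity [",
           f$offset, ", ", f$offset + cap - 1L, "]")
    parts[i] <- int_to_base4(val, f$width, codebook$alphabet)
  }
  paste(parts, collapse = "")
}

#' Decode fixed barcode positions back into a metadata tag
#'
#' Exact inverse of [encode_metadata()]; the all-A code decodes to the
#' codebook origin (all offsets).
#'
#' @param code Nucleotide string of length `spec$meta_length`.
#' @inheritParams encode_metadata
#' @return A [metadata_tag()].
#' @export
decode_metadata <- function(code, spec = barcode_spec(),
                            codebook = default_codebook()) {
  if (nchar(code) != spec$meta_length)
    stop("code length ", nchar(code), " != meta_length ", spec$meta_length)
  widths <- vapply(codebook$fields, `[[`, 1L, "width")
  if (sum(widths) != spec$meta_length)
    stop("codebook widths do not fill meta_length")
  vals <- list()
  pos <- 1L
  for (i in seq_along(codebook$fields)) {
    f <- codebook$fields[[i]]
    sub <- substr(code, pos, pos + f$width - 1L)
    vals[[names(codebook$fields)[i]]] <- base4_to_int(sub, codebook$alphabet) + f$offset
    pos <- pos + f$width
  }
  do.call(metadata_tag, vals)
}

#' Barcode library
#'
#' A multiset of barcode sequences with abundances: either a plasmid library
#' or a cell pool. All sequences must share one length.
#'
#' @param entries Named non-negative numeric vector (sequence -> abundance).
#' @param spec A [barcode_spec()]; total length must match the sequences.
#' @return An object of class `barcode_library`.
#' @export
barcode_library <- function(entries, spec = NULL) {
  if (length(entries)) {
    if (is.null(names(entries))) stop("'entries' must be named by sequence")
    len <- unique(nchar(names(entries)))
    if (length(len) != 1L) stop("all barcode sequences must have one length")
    if (any(entries < 0)) stop("abundances must be >= 0")
    if (sum(entries) <= 0) stop("total abundance must be > 0")
    if (is.null(spec)) spec <- barcode_spec(random_length = len, meta_length = 0L)
    if (spec$random_length + spec$meta_length != len)
      stop("sequence length ", len, " does not match spec total length")
  } else if (is.null(spec)) spec <- barcode_spec()
  structure(list(entries = entries, spec = spec), class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("barcode_library: %d variants, total abundance %s\n",
              length(x$entries), format(sum(x$entries), big.mark = ",")))
  invisible(x)
}

#' Read/write a barcode library as two-column TSV (sequence, count)
#' @param path File path.
#' @param spec Optional [barcode_spec()] to validate against.
#' @return A [barcode_library()].
#' @export
read_barcode_library <- function(path, spec = NULL) {
  ct <- read_count_table(path)
  barcode_library(ct$counts, spec = spec)
}

#' @rdname read_barcode_library
#' @param lib A [barcode_library()].
#' @export
write_barcode_library <- function(lib, path) {
  write_count_table(lib$entries, path)
}

gini_coefficient <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L || sum(x) == 0) return(NA_real_)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}

#' Positional composition and abundance dispersion of a library
#'
#' Computes the abundance-weighted per-position nucleotide frequency matrix
#' (rows sum to 1) and summary statistics of abundance dispersion (CV and
#' Gini coefficient). A well-made library shows near-uniform composition at
#' the randomized positions and low dispersion.
#'
#' @param lib A [barcode_library()].
#' @return List with `position_freq` (positions x 4 matrix), `abundance_cv`,
#'   `abundance_gini`, `n_variants`, `total_abundance`.
#' @export
library_uniformity <- function(lib) {
  if (!length(lib$entries)) stop("empty library")
  seqs <- names(lib$entries)
  ab <- as.numeric(lib$entries)
  len <- nchar(seqs[[1]])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  freq <- matrix(0, nrow = len, ncol = 4L,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  tot <- sum(ab)
  for (b in c("A", "C", "G", "T"))
    freq[, b] <- colSums((m == b) * ab) / tot
  mu <- mean(ab)
  cv <- if (mu > 0) stats::sd(ab) / mu else NA_real_
  list(position_freq = freq,
       abundance_cv = cv,
       abundance_gini = gini_coefficient(ab),
       n_variants = length(seqs),
       total_abundance = tot)
}
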