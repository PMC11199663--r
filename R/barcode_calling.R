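#' Error-clustering parameters
#'
#' @param max_distance Maximum Levenshtein distance for absorbing a
#'   low-count barcode into a higher-count neighbor (default 1).
#' @param merge_ratio Minimum parent:child count ratio required for
#'   absorption (default 5).
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(max_distance = 1L, merge_ratio = 5) {
  if (max_distance < 0L) stop("max_distance must be >= 0")
  if (merge_ratio < 1) stop("merge_ratio must be >= 1")
  structure(list(max_distance = as.integer(max_distance),
                 merge_ratio = merge_ratio),
            class = "clustering_params")
}

# Candidate neighbor index for Levenshtein distance <= 1 on a set of
# sequences: two sequences are at distance <= 1 only if they share a
# "deletion fingerprint" (the sequence itself or the sequence with one
# position deleted). Sharing is necessary, not sufficient, so candidates
# are verified with an exact distance computation.
deletion_fingerprints <- function(seqs) {
  n <- length(seqs)
  lens <- nchar(seqs)
  fps <- vector("list", n)
  for (i in seq_len(n)) {
    s <- seqs[i]
    L <- lens[i]
    dels <- vapply(seq_len(L), function(p)
      paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, L)), "")
    fps[[i]] <- c(s, unique(dels))
  }
  ids <- rep(seq_len(n), lengths(fps))
  split(ids, unlist(fps, use.names = FALSE))
}

neighbor_candidates_d1 <- function(seqs) {
  buckets <- deletion_fingerprints(seqs)
  n <- length(seqs)
  nb <- vector("list", n)
  for (b in buckets) {
    if (length(b) < 2L) next
    for (i in b) nb[[i]] <- c(nb[[i]], b)
  }
  lapply(seq_len(n), function(i) setdiff(unique(nb[[i]]), i))
}

greedy_absorb <- function(seqs, counts, params, neighbors_of) {
  # neighbors_of(i): indices at Levenshtein distance <= max_distance from i
  n <- length(seqs)
  active <- rep(TRUE, n)
  parent_count <- counts
  # smallest count first; ties broken lexicographically by sequence
  ord <- order(counts, seqs, method = "radix")
  for (i in ord) {
    nb <- neighbors_of(i)
    nb <- nb[active[nb]]
    if (!length(nb)) next
    eligible <- nb[parent_count[nb] >= params$merge_ratio * parent_count[i]]
    if (!length(eligible)) next
    # highest current count; ties broken lexicographically by sequence
    pick <- eligible[order(-parent_count[eligible], seqs[eligible],
                           method = "radix")][1]
    parent_count[pick] <- parent_count[pick] + parent_count[i]
    parent_count[i] <- 0
    active[i] <- FALSE
  }
  keep <- which(active)
  stats::setNames(parent_count[keep], seqs[keep])
}

#' Absorb likely sequencing-error barcodes into their parents
#'
#' Greedy error-correction clustering: barcodes are processed from the
#' smallest count upward, and each is absorbed into the highest-count
#' barcode within Levenshtein distance `max_distance` whose current count is
#' at least `merge_ratio` times its own. Absorbed counts add to the parent;
#' the total count is conserved. For `max_distance = 1` neighbor search uses
#' a deletion-fingerprint index (verified with exact distances), so large
#' tables cluster quickly; results are identical to all-pairs search.
#'
#' @param table A [count_table()] (or named count vector).
#' @param params A [clustering_params()].
#' @return A [count_table()] whose keys are cluster centroids.
#' @export
cluster_counts <- function(table, params = clustering_params()) {
  ct <- if (inherits(table, "count_table")) table
        else count_table(table)
  counts <- ct$counts
  if (!length(counts)) stop("empty count table")
  seqs <- names(counts)
  n <- length(seqs)
  if (n == 1L || params$max_distance == 0L) return(ct)

  if (params$max_distance == 1L) {
    cand <- neighbor_candidates_d1(seqs)
    neighbors_of <- function(i) {
      cs <- cand[[i]]
      if (!length(cs)) return(integer(0))
      d <- utils::adist(seqs[i], seqs[cs])[1, ]
      cs[d <= 1L]
    }
  } else {
    dmat <- utils::adist(seqs)
    neighbors_of <- function(i) {
      which(dmat[i, ] <= params$max_distance & seq_len(n) != i)
    }
  }
  out <- greedy_absorb(seqs, counts, params, neighbors_of)
  count_table(out, sample_id = ct$sample_id,
              total_reads_in = ct$total_reads_in,
              reads_extracted = ct$reads_extracted)
}

# Reference clustering via all-pairs distance matrix; used as the
# brute-force oracle the fast path must reproduce.
cluster_counts_bruteforce <- function(table, params = clustering_params()) {
  ct <- if (inherits(table, "count_table")) table else count_table(table)
  counts <- ct$counts
  if (!length(counts)) stop("empty count table")
  seqs <- names(counts)
  n <- length(seqs)
  if (n == 1L || params$max_distance == 0L) return(ct)
  dmat <- utils::adist(seqs)
  neighbors_of <- function(i)
    which(dmat[i, ] <= params$max_distance & seq_len(n) != i)
  out <- greedy_absorb(seqs, counts, params, neighbors_of)
  count_table(out, sample_id = ct$sample_id,
              total_reads_in = ct$total_reads_in,
              reads_extracted = ct$reads_extracted)
}

#' Knee point of a rank-abundance count distribution
#'
#' On the curve of (log10 rank, log10 count) for counts sorted in
#' decreasing order, finds the point with the maximum perpendicular
#' distance to the chord joining the first and last points. When that
#' point lies below the chord it marks the start of the low-count error
#' tail and its count is the threshold; when it lies above the chord it
#' marks the end of the genuine plateau and the threshold is the count at
#' the following rank (the first tail point). Counts strictly above the
#' threshold are treated as genuine. A curve that never departs from the
#' chord by more than `tol` log10 units (e.g. a flat plateau with no error
#' tail, or a perfect power law) has no knee and is flagged degenerate, as
#' is any input with fewer than 3 distinct count values.
#'
#' @param counts Positive counts (sorted internally in decreasing order).
#' @param tol Minimum perpendicular chord distance (log10 units) for a
#'   knee to be considered real (default 0.05, i.e. counts must leave the
#'   chord by more than ~12 percent).
#' @return List with `threshold` (count at the knee), `knee_rank`,
#'   `degenerate` (`TRUE` when no knee exists, in which case `threshold`
#'   is `NA` and callers keep all barcodes).
#' @export
knee_point_threshold <- function(counts, tol = 0.05) {
  counts <- sort(as.numeric(counts), decreasing = TRUE)
  if (any(counts <= 0)) stop("counts must be positive")
  n <- length(counts)
  if (length(unique(counts)) < 3L)
    return(list(threshold = NA_real_, knee_rank = NA_integer_,
                degenerate = TRUE))
  x <- log10(seq_len(n))
  y <- log10(counts)
  x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  # signed distance: negative below the chord (count drops under the line)
  signed <- ((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)) / len
  k <- which.max(abs(signed))
  if (abs(signed[k]) < tol)
    return(list(threshold = NA_real_, knee_rank = NA_integer_,
                degenerate = TRUE))
  if (signed[k] > 0) k <- k + 1L  # plateau end -> first tail point
  list(threshold = counts[k], knee_rank = as.integer(k), degenerate = FALSE)
}

#' Call genuine clone barcodes
#'
#' Runs error clustering ([cluster_counts()]) followed by the unbiased
#' knee-point threshold ([knee_point_threshold()]); genuine barcodes are
#' those with clustered counts strictly above the threshold. When the knee
#' is undefined (fewer than 3 distinct counts, or a straight rank curve)
#' all clustered barcodes are kept, with a warning.
#'
#' @param table A [count_table()] or named count vector.
#' @param params A [clustering_params()].
#' @return An object of class `call_result`: `genuine` (character vector),
#'   `threshold`, `knee_rank`, `clustered_counts` ([count_table()]),
#'   `degenerate`.
#' @export
call_genuine <- function(table, params = clustering_params()) {
  clustered <- cluster_counts(table, params)
  cc <- sort(clustered$counts, decreasing = TRUE)
  cc <- cc[cc > 0]
  kp <- knee_point_threshold(cc)
  if (kp$degenerate) {
    warning("knee point undefined; keeping all clustered barcodes")
    genuine <- names(cc)
  } else {
    genuine <- names(cc)[cc > kp$threshold]
  }
  structure(list(genuine = genuine, threshold = kp$threshold,
                 knee_rank = kp$knee_rank, clustered_counts = clustered,
                 degenerate = kp$degenerate),
            class = "call_result")
}

#' @export
print.call_result <- function(x, ...) {
  cat(sprintf("call_result: %d genuine barcode(s), threshold %s (rank %s)\n",
              length(x$genuine),
              ifelse(is.na(x$threshold), "undefined", format(x$threshold)),
              ifelse(is.na(x$knee_rank), "-", x$knee_rank)))
  invisible(x)
}

#' Cross-contamination report for a well or sample
#'
#' Flags samples whose genuine-barcode count exceeds the expected number of
#' clones and reports the read fraction of each genuine barcode, so minor
#' contaminating clones are quantified.
#'
#' @param result A [call_result()] from [call_genuine()].
#' @param expected_n Expected number of clones (>= 1).
#' @return List with `pass`, `n_genuine`, `expected_n` and `fractions`
#'   (named fractions of clustered reads per genuine barcode).
#' @export
cross_contamination_report <- function(result, expected_n = 1L) {
  if (expected_n < 1L) stop("expected_n must be >= 1")
  cc <- result$clustered_counts$counts
  g <- result$genuine
  fr <- cc[g] / sum(cc)
  fr <- sort(fr, decreasing = TRUE)
  list(pass = length(g) <= expected_n,
       n_genuine = length(g),
       expected_n = as.integer(expected_n),
       fractions = fr)
}
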