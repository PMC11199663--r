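#' Flanking-sequence specification for barcode extraction
#'
#' A barcode is located as the sequence between a known left and right flank
#' in the merged amplicon read; only inserts of exactly `expected_length`
#' nucleotides are accepted. Flank matching is exact by default; a small
#' mismatch allowance can be configured.
#'
#' @param left_flank,right_flank Anchor sequences (A/C/G/T).
#' @param expected_length Required barcode length between the flanks.
#' @param max_flank_mismatches Mismatches tolerated per flank (default 0).
#' @return An object of class `flank_spec`.
#' @export
flank_spec <- function(left_flank, right_flank, expected_length = 15L,
                       max_flank_mismatches = 0L) {
  if (!nzchar(left_flank) || !nzchar(right_flank)) stop("flanks must be non-empty")
  if (expected_length < 1L) stop("expected_length must be >= 1")
  structure(list(left_flank = toupper(left_flank),
                 right_flank = toupper(right_flank),
                 expected_length = as.integer(expected_length),
                 max_flank_mismatches = as.integer(max_flank_mismatches)),
            class = "flank_spec")
}

#' Built-in amplicon flank presets
#'
#' Flank anchor pairs for the three molecule-specific amplicon designs
#' (M1/M2/M3) used with the 15-nt randomized barcode.
#'
#' @param name One of "M1", "M2", "M3".
#' @return A [flank_spec()].
#' @export
flank_preset <- function(name = c("M1", "M2", "M3")) {
  name <- match.arg(name)
  presets <- list(
    M1 = c("GCTTAGCCGCTTAAT", "AACATCTAATGCGTA"),
    M2 = c("CTTAGCCGCTTAAT",  "AACTTAGCTCGCGTA"),
    M3 = c("GCTTAGCCGCTTAAT", "AACCTCGCTTGCGTA"))
  p <- presets[[name]]
  flank_spec(p[1], p[2])
}

#' Reverse complement of nucleotide strings
#' @param x Character vector of A/C/G/T(/N) sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' A paired-end read
#'
#' @param forward,reverse Mate sequences.
#' @param qual_forward,qual_reverse Per-base Phred qualities (integer
#'   vectors, same lengths as the sequences). Default Q30 throughout.
#' @param id Read identifier.
#' @return An object of class `read_pair`.
#' @export
read_pair <- function(forward, reverse, qual_forward = NULL,
                      qual_reverse = NULL, id = "read") {
  if (is.null(qual_forward)) qual_forward <- rep(30L, nchar(forward))
  if (is.null(qual_reverse)) qual_reverse <- rep(30L, nchar(reverse))
  if (length(qual_forward) != nchar(forward) ||
      length(qual_reverse) != nchar(reverse))
    stop("sequence and quality lengths must match within each mate")
  structure(list(forward = forward, reverse = reverse,
                 qual_forward = as.integer(qual_forward),
                 qual_reverse = as.integer(qual_reverse), id = id),
            class = "read_pair")
}

trim_one <- function(seq, qual, adapter, min_overlap) {
  n <- nchar(seq)
  alen <- nchar(adapter)
  # full internal adapter occurrence: cut at first occurrence
  hit <- regexpr(adapter, seq, fixed = TRUE)
  if (hit > 0L) {
    keep <- hit - 1L
    return(list(seq = substr(seq, 1L, keep), qual = qual[seq_len(keep)]))
  }
  # partial adapter at the 3' end: longest suffix equal to an adapter prefix
  max_o <- min(n, alen - 1L)
  for (o in rev(seq_len(max_o))) {
    if (o < min_overlap) break
    if (substr(seq, n - o + 1L, n) == substr(adapter, 1L, o)) {
      keep <- n - o
      return(list(seq = substr(seq, 1L, keep), qual = qual[seq_len(keep)]))
    }
  }
  list(seq = seq, qual = qual)
}

#' Trim adapter read-through from both mates
#'
#' Removes a full adapter occurrence (and everything 3' of it), or the
#' longest 3' suffix matching a prefix of the adapter with at least
#' `min_overlap` bases. Qualities are trimmed in lockstep. Reads without
#' adapter content are returned unchanged.
#'
#' @param pair A [read_pair()].
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum suffix/prefix overlap (default 3).
#' @return The trimmed [read_pair()].
#' @export
trim_adapters <- function(pair, adapter, min_overlap = 3L) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  f <- trim_one(pair$forward, pair$qual_forward, adapter, min_overlap)
  r <- trim_one(pair$reverse, pair$qual_reverse, adapter, min_overlap)
  read_pair(f$seq, r$seq, f$qual, r$qual, id = pair$id)
}

#' Merge a read pair by best overlap
#'
#' Scans all overlaps between the forward mate and the reverse complement of
#' the reverse mate and takes the one with the most matching bases (ties go
#' to the longer overlap). The merge is accepted when the best overlap is at
#' least `min_overlap` long with a mismatch fraction at most
#' `max_mismatch_frac`; at mismatched positions the base with the higher
#' Phred quality wins. Rejection is a normal, counted outcome.
#'
#' @param pair A [read_pair()].
#' @param min_overlap Minimum acceptable overlap (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap.
#' @return List with `merged` (sequence or `NA`), `overlap`, `mismatches`,
#'   and `accepted`.
#' @export
merge_pair <- function(pair, min_overlap = 10L, max_mismatch_frac = 0.25) {
  f <- pair$forward
  r <- reverse_complement(pair$reverse)
  rq <- rev(pair$qual_reverse)
  nf <- nchar(f); nr <- nchar(r)
  if (nf == 0L || nr == 0L) stop("both mates must be non-empty")
  fv <- strsplit(f, "", fixed = TRUE)[[1]]
  rv <- strsplit(r, "", fixed = TRUE)[[1]]
  best <- list(o = 0L, matches = -1L, mm = NA_integer_)
  for (o in rev(seq_len(min(nf, nr)))) {
    eq <- fv[(nf - o + 1L):nf] == rv[1:o]
    matches <- sum(eq)
    if (matches > best$matches) best <- list(o = o, matches = matches, mm = o - matches)
  }
  o <- best$o
  if (o < min_overlap || best$mm / o > max_mismatch_frac)
    return(list(merged = NA_character_, overlap = o,
                mismatches = best$mm, accepted = FALSE))
  fq <- pair$qual_forward[(nf - o + 1L):nf]
  rq_o <- rq[1:o]
  fo <- fv[(nf - o + 1L):nf]
  ro <- rv[1:o]
  cons <- ifelse(fo == ro, fo, ifelse(fq >= rq_o, fo, ro))
  merged <- paste(c(fv[seq_len(nf - o)], cons,
                    if (o < nr) rv[(o + 1L):nr]), collapse = "")
  list(merged = merged, overlap = o, mismatches = best$mm, accepted = TRUE)
}

find_flank <- function(seq, flank, max_mm) {
  if (max_mm == 0L) {
    hits <- gregexpr(flank, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(integer(0))
    return(as.integer(hits))
  }
  m <- Biostrings::matchPattern(flank, Biostrings::DNAString(seq),
                                max.mismatch = max_mm)
  Biostrings::start(m)
}

extract_one_orientation <- function(seq, flanks) {
  lf <- find_flank(seq, flanks$left_flank, flanks$max_flank_mismatches)
  if (length(lf) == 0L) return(list(barcode = NA_character_, reason = "flank_not_found"))
  if (length(lf) > 1L) return(list(barcode = NA_character_, reason = "ambiguous_multiple_hits"))
  start <- lf + nchar(flanks$left_flank)
  rest <- substr(seq, start, nchar(seq))
  rf <- find_flank(rest, flanks$right_flank, flanks$max_flank_mismatches)
  if (length(rf) == 0L) return(list(barcode = NA_character_, reason = "flank_not_found"))
  if (length(rf) > 1L) return(list(barcode = NA_character_, reason = "ambiguous_multiple_hits"))
  insert <- substr(rest, 1L, rf - 1L)
  if (nchar(insert) != flanks$expected_length)
    return(list(barcode = NA_character_, reason = "wrong_length"))
  list(barcode = insert, reason = NA_character_)
}

#' Extract the barcode between known flanks
#'
#' Locates the left then right flank (allowing up to
#' `max_flank_mismatches` per flank); if neither flank pair is found in
#' forward orientation the reverse complement is searched. The intervening
#' sequence is returned iff its length equals `expected_length`. When both
#' orientations contain the flanks, the forward orientation wins.
#'
#' @param seq Merged read sequence.
#' @param flanks A [flank_spec()].
#' @return List with `barcode` (or `NA`) and `reason` (`NA` on success, else
#'   one of `"flank_not_found"`, `"wrong_length"`,
#'   `"ambiguous_multiple_hits"`).
#' @export
extract_barcode <- function(seq, flanks) {
  if (!nzchar(seq)) stop("sequence must be non-empty")
  fwd <- extract_one_orientation(seq, flanks)
  if (!is.na(fwd$barcode) || fwd$reason != "flank_not_found") return(fwd)
  extract_one_orientation(reverse_complement(seq), flanks)
}

#' Vectorized exact-match barcode extraction from merged reads
#'
#' Fast path for large read sets with `max_flank_mismatches = 0`: both
#' orientations are searched with fixed-string matching across the whole
#' vector at once. Semantics match [extract_barcode()].
#'
#' @param seqs Character vector of merged read sequences.
#' @param flanks A [flank_spec()] (exact matching only).
#' @return List with `barcodes` (character, `NA` where rejected) and
#'   `reasons` (`NA` where extracted).
#' @export
extract_barcodes <- function(seqs, flanks) {
  if (flanks$max_flank_mismatches != 0L)
    stop("vectorized extraction supports exact flank matching only")
  # amplicon read sets are highly redundant: work on unique sequences
  uniq <- unique(seqs)
  if (length(uniq) < length(seqs)) {
    res <- extract_barcodes(uniq, flanks)
    idx <- match(seqs, uniq)
    return(list(barcodes = res$barcodes[idx], reasons = res$reasons[idx]))
  }
  n <- length(seqs)
  barcodes <- rep(NA_character_, n)
  reasons <- rep(NA_character_, n)
  lf <- flanks$left_flank; rf <- flanks$right_flank
  lw <- nchar(lf); bw <- flanks$expected_length

  run <- function(s) {
    # returns list(bc, reason) vectors for one orientation
    bc <- rep(NA_character_, length(s))
    rs <- rep("flank_not_found", length(s))
    lhits <- gregexpr(lf, s, fixed = TRUE)
    l1 <- vapply(lhits, function(h) h[[1]], 0L)
    nl <- vapply(lhits, function(h) if (h[[1]] == -1L) 0L else length(h), 0L)
    rs[nl > 1L] <- "ambiguous_multiple_hits"
    cand <- which(nl == 1L)
    if (length(cand)) {
      rest <- substr(s[cand], l1[cand] + lw, nchar(s[cand]))
      rhits <- gregexpr(rf, rest, fixed = TRUE)
      r1 <- vapply(rhits, function(h) h[[1]], 0L)
      nr <- vapply(rhits, function(h) if (h[[1]] == -1L) 0L else length(h), 0L)
      rs[cand[nr > 1L]] <- "ambiguous_multiple_hits"
      ok <- nr == 1L
      ins_len <- r1 - 1L
      good <- ok & ins_len == bw
      wrong <- ok & ins_len != bw
      rs[cand[wrong]] <- "wrong_length"
      idx <- cand[good]
      bc[idx] <- substr(rest[good], 1L, bw)
      rs[idx] <- NA_character_
    }
    list(bc = bc, rs = rs)
  }

  fwd <- run(seqs)
  barcodes <- fwd$bc
  reasons <- fwd$rs
  retry <- which(reasons == "flank_not_found")
  if (length(retry)) {
    rev <- run(reverse_complement(seqs[retry]))
    barcodes[retry] <- rev$bc
    reasons[retry] <- rev$rs
  }
  list(barcodes = barcodes, reasons = reasons)
}

tabulate_barcodes <- function(barcodes, reasons, sample_id, total_in) {
  ok <- !is.na(barcodes)
  rej <- table(reasons[!ok])
  rejections <- stats::setNames(as.numeric(rej), names(rej))
  counts <- if (any(ok)) {
    tb <- table(barcodes[ok])
    stats::setNames(as.numeric(tb), names(tb))
  } else stats::setNames(numeric(0), character(0))
  list(table = count_table(counts, sample_id = sample_id,
                           total_reads_in = total_in,
                           reads_extracted = sum(ok)),
       rejections = as.list(rejections))
}

#' Count barcodes in merged reads
#'
#' Vectorized extraction + tabulation for merged read sequences; returns the
#' [count_table()] and a per-reason rejection report. The conservation
#' invariant holds: `total_reads_in = reads_extracted + sum(rejections)`.
#'
#' @param seqs Character vector of merged reads.
#' @param flanks A [flank_spec()].
#' @param sample_id Sample label.
#' @return List with `table` ([count_table()]) and `rejections` (named list).
#' @export
count_barcodes_merged <- function(seqs, flanks, sample_id = NA_character_) {
  ex <- extract_barcodes(seqs, flanks)
  tabulate_barcodes(ex$barcodes, ex$reasons, sample_id, length(seqs))
}

read_fastq_seqs <- function(path) {
  # readQualityScaledDNAStringSet warns about dropping the FASTQ id line's
  # metadata columns; only sequence, quality and id are needed here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(seqs = as.character(x),
       quals = lapply(as(Biostrings::quality(x), "IntegerList"), as.integer),
       ids = names(x))
}

#' Process paired FASTQ files into a barcode count table
#'
#' Full pipeline on raw paired-end amplicon reads: adapter trimming, overlap
#' merging, flank-anchored barcode extraction with length filtering and
#' orientation normalization. Unmerged pairs are dropped and counted under
#' `"merge_failed"`.
#'
#' @param r1,r2 FASTQ(.gz) paths for forward and reverse mates.
#' @param flanks A [flank_spec()].
#' @param adapter Adapter sequence to trim, or `NULL` to skip trimming.
#' @param sample_id Sample label; defaults to the R1 file name.
#' @param min_overlap,max_mismatch_frac Merge parameters, see [merge_pair()].
#' @return List with `table` ([count_table()]) and `rejections`.
#' @export
count_barcodes <- function(r1, r2, flanks, adapter = NULL,
                           sample_id = NULL, min_overlap = 10L,
                           max_mismatch_frac = 0.25) {
  if (is.null(sample_id)) sample_id <- basename(r1)
  f <- read_fastq_seqs(r1)
  r <- read_fastq_seqs(r2)
  if (length(f$seqs) != length(r$seqs))
    stop("R1 and R2 contain different numbers of reads")
  n <- length(f$seqs)
  merged <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pr <- read_pair(f$seqs[i], r$seqs[i], f$quals[[i]], r$quals[[i]],
                    id = f$ids[i])
    if (!is.null(adapter)) pr <- trim_adapters(pr, adapter)
    m <- merge_pair(pr, min_overlap = min_overlap,
                    max_mismatch_frac = max_mismatch_frac)
    if (m$accepted) merged[i] <- m$merged
  }
  ok <- !is.na(merged)
  res <- if (any(ok)) extract_barcodes(merged[ok], flanks)
         else list(barcodes = character(0), reasons = character(0))
  barcodes <- rep(NA_character_, n)
  reasons <- rep("merge_failed", n)
  barcodes[ok] <- res$barcodes
  reasons[ok] <- res$reasons
  tabulate_barcodes(barcodes, reasons, sample_id, n)
}
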