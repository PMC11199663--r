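# shared fixture builders; everything is generated in code at test time

make_barcodes <- function(n, len = 15L, seed = 42L) {
  set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    fresh <- vapply(seq_len(n - length(out) + 4L), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      "")
    out <- unique(c(out, fresh))
  }
  out[seq_len(n)]
}

# independent brute-force greedy error clustering: all-pairs Levenshtein
# distance matrix, smallest-count-first absorption into the highest-count
# eligible neighbor (ties lexicographic); written separately from the
# package's implementation
oracle_cluster <- function(counts, max_distance = 1L, merge_ratio = 5) {
  seqs <- names(counts)
  n <- length(seqs)
  cnt <- as.numeric(counts)
  if (n <= 1L) return(counts)
  d <- utils::adist(seqs)
  alive <- rep(TRUE, n)
  ord <- order(cnt, seqs, method = "radix")
  for (i in ord) {
    nb <- which(d[i, ] <= max_distance & seq_len(n) != i & alive)
    nb <- nb[cnt[nb] >= merge_ratio * cnt[i]]
    if (!length(nb)) next
    j <- nb[order(-cnt[nb], seqs[nb], method = "radix")][1]
    cnt[j] <- cnt[j] + cnt[i]
    cnt[i] <- 0
    alive[i] <- FALSE
  }
  stats::setNames(cnt[alive], seqs[alive])
}

# independent knee-point search: explicit loop over every point computing
# its perpendicular distance to the endpoint chord in log-log space
oracle_knee <- function(counts, tol = 0.05) {
  counts <- sort(as.numeric(counts), decreasing = TRUE)
  n <- length(counts)
  if (length(unique(counts)) < 3L) return(NA_real_)
  x <- log10(seq_len(n)); y <- log10(counts)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  len <- sqrt(dx^2 + dy^2)
  best_i <- NA_integer_; best_d <- 0
  for (i in seq_len(n)) {
    s <- (dx * (y[i] - y[1]) - dy * (x[i] - x[1])) / len
    if (abs(s) > best_d) { best_d <- abs(s); best_i <- i; best_s <- s }
  }
  if (best_d < tol) return(NA_real_)
  if (best_s > 0) best_i <- best_i + 1L
  counts[best_i]
}

# term-by-term probability-of-clonality summation, independent of the
# package's vectorized implementation
oracle_poc <- function(lam, a, p0, k_max = 10L) {
  total <- 0
  for (k in 2:k_max) {
    pk <- lam^k * exp(-lam) / factorial(k)
    coll <- 1 - (1 - p0)^k
    gk <- if (k == 1) a else k * a * (1 - a)^(k - 1)
    total <- total + pk * coll * gk
  }
  1 - total
}
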