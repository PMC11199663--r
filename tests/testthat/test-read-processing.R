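M1 <- flank_preset("M1")

test_that("adapter trimming removes full and partial read-through", {
  adapter <- "AGATCGGAAGAGC"
  body <- "ACGTACGTACGTACGTACGT"
  full <- read_pair(paste0(body, adapter), paste0(body, adapter))
  tr <- trim_adapters(full, adapter)
  expect_identical(tr$forward, body)
  expect_identical(tr$reverse, body)
  expect_length(tr$qual_forward, nchar(body))

  # partial: read ends in the first 5 adapter bases
  part <- read_pair(paste0(body, substr(adapter, 1, 5)), body)
  tr2 <- trim_adapters(part, adapter)
  expect_identical(tr2$forward, body)
  expect_identical(tr2$reverse, body)

  none <- read_pair(body, body)
  expect_identical(trim_adapters(none, adapter)$forward, body)
})

test_that("error-free mates reconstruct their template exactly", {
  set.seed(7)
  template <- paste(sample(c("A", "C", "G", "T"), 180, TRUE), collapse = "")
  fwd <- substr(template, 1, 150)
  rev <- reverse_complement(substr(template, 31, 180))
  m <- merge_pair(read_pair(fwd, rev))
  expect_true(m$accepted)
  expect_identical(m$overlap, 120L)
  expect_identical(m$mismatches, 0L)
  expect_identical(m$merged, template)
})

test_that("non-overlapping random mates are rejected, a counted outcome", {
  set.seed(8)
  a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  m <- merge_pair(read_pair(a, b))
  expect_false(m$accepted)
  expect_true(is.na(m$merged))
})

test_that("the higher-quality base wins at overlap mismatches", {
  set.seed(19)
  template <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  fwd <- substr(template, 1, 80)
  rev_part <- substr(template, 41, 120)
  # substitute position 59 (inside the 41..80 overlap) in the forward mate
  true_base <- substr(template, 59, 59)
  err_base <- setdiff(c("A", "C", "G", "T"), true_base)[1]
  fwd_err <- paste0(substr(fwd, 1, 58), err_base, substr(fwd, 60, 80))
  rev <- reverse_complement(rev_part)
  # forward mate low quality, reverse high: template base must win
  m <- merge_pair(read_pair(fwd_err, rev,
                            qual_forward = rep(10L, 80),
                            qual_reverse = rep(38L, 80)))
  expect_true(m$accepted)
  expect_identical(m$merged, template)
  expect_identical(m$mismatches, 1L)
  # reversed quality relationship: the erroneous base wins instead
  m2 <- merge_pair(read_pair(fwd_err, rev,
                             qual_forward = rep(38L, 80),
                             qual_reverse = rep(10L, 80)))
  expect_identical(substr(m2$merged, 59, 59), err_base)
})

test_that("flank-anchored extraction honors length filter and orientation", {
  bc <- "TTACGGATCCATGCA"
  good <- paste0("AAAA", M1$left_flank, bc, M1$right_flank, "GGGG")
  expect_identical(extract_barcode(good, M1)$barcode, bc)

  short <- paste0("AAAA", M1$left_flank, substr(bc, 1, 14), M1$right_flank)
  r <- extract_barcode(short, M1)
  expect_true(is.na(r$barcode))
  expect_identical(r$reason, "wrong_length")

  rc <- extract_barcode(reverse_complement(good), M1)
  expect_identical(rc$barcode, bc)

  none <- extract_barcode(strrep("ACGT", 20), M1)
  expect_identical(none$reason, "flank_not_found")

  double <- paste0(M1$left_flank, bc, M1$right_flank,
                   M1$left_flank, bc, M1$right_flank)
  expect_identical(extract_barcode(double, M1)$reason,
                   "ambiguous_multiple_hits")
})

test_that("orientation invariance holds across random constructs", {
  set.seed(21)
  for (i in 1:25) {
    bc <- paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = "")
    ctx1 <- paste(sample(c("A", "C", "G", "T"), sample(0:12, 1), TRUE),
                  collapse = "")
    ctx2 <- paste(sample(c("A", "C", "G", "T"), sample(0:12, 1), TRUE),
                  collapse = "")
    s <- paste0(ctx1, M1$left_flank, bc, M1$right_flank, ctx2)
    expect_identical(extract_barcode(s, M1)$barcode,
                     extract_barcode(reverse_complement(s), M1)$barcode)
  }
})

test_that("vectorized extraction matches the scalar path", {
  set.seed(22)
  bcs <- make_barcodes(30, seed = 22)
  seqs <- paste0("AC", M1$left_flank, bcs, M1$right_flank, "GT")
  seqs[5] <- substr(seqs[5], 3, nchar(seqs[5]))           # still fine
  seqs[9] <- paste0("AC", M1$left_flank, "TTT", M1$right_flank) # wrong length
  seqs[12] <- strrep("ACGT", 15)                          # no flank
  seqs[c(2, 14)] <- reverse_complement(seqs[c(2, 14)])
  vec <- extract_barcodes(seqs, M1)
  for (i in seq_along(seqs)) {
    sc <- extract_barcode(seqs[i], M1)
    expect_identical(vec$barcodes[i], sc$barcode)
    expect_identical(vec$reasons[i], sc$reason)
  }
})

test_that("read accounting is conserved: extracted + rejections = total", {
  bcs <- make_barcodes(10, seed = 5)
  sim <- simulate_merged_reads(stats::setNames(rep(1, 10), bcs), M1,
                               5000, error_rate = 0.01, seed = 5)
  res <- count_barcodes_merged(sim$reads, M1)
  expect_identical(res$table$total_reads_in, 5000)
  expect_equal(res$table$reads_extracted + sum(unlist(res$rejections)),
               res$table$total_reads_in)
  expect_equal(sum(res$table$counts), res$table$reads_extracted)
})

test_that("error-free reads round-trip the simulated multiplicities", {
  bcs <- make_barcodes(25, seed = 6)
  ab <- stats::setNames(sample(1:50, 25, TRUE), bcs)
  sim <- simulate_merged_reads(ab, M1, 20000, error_rate = 0, seed = 6)
  res <- count_barcodes_merged(sim$reads, M1)
  expect_identical(length(res$rejections), 0L)
  truth <- sim$truth[sim$truth > 0]
  expect_mapequal(res$table$counts, truth)
})

test_that("at 0.1%/base error nearly all reads yield the true barcode or a neighbor", {
  bcs <- make_barcodes(5, seed = 9)
  sim <- simulate_merged_reads(stats::setNames(rep(1, 5), bcs), M1,
                               50000, error_rate = 0.001, seed = 9)
  res <- count_barcodes_merged(sim$reads, M1)
  got <- names(res$table$counts)
  d <- utils::adist(got, bcs)
  near <- apply(d, 1, min) <= 1
  frac_near <- sum(res$table$counts[near]) / sum(res$table$counts)
  # extracted reads resolve to a true barcode or a distance-1 neighbor
  expect_gte(frac_near, 0.99)
  # and >= 99% of all reads make it through extraction at this error rate
  expect_gte(res$table$reads_extracted / res$table$total_reads_in, 0.95)
})

test_that("empty input gives an empty table", {
  res <- count_barcodes_merged(character(0), M1)
  expect_identical(res$table$total_reads_in, 0)
  expect_length(res$table$counts, 0)
})

test_that("full FASTQ pipeline recovers abundances from paired files", {
  dir <- withr::local_tempdir()
  bcs <- make_barcodes(8, seed = 10)
  ab <- stats::setNames(rep(1, 8), bcs)
  files <- simulate_read_files(ab, M1, 400, dir, error_rate = 0, seed = 10)
  res <- count_barcodes(files$r1, files$r2, M1)
  truth <- files$counts[files$counts > 0]
  expect_mapequal(res$table$counts, truth)
  expect_identical(res$table$total_reads_in, 400)
})
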