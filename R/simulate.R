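#' Simulation configuration for the cell line development process
#'
#' Default values emulate the study conditions of a targeted-integration
#' CHO campaign: 4.5e6 transfected cells, an RMCE integration rate around
#' 1e-3 before selection, roughly 30 percent of integrants surviving
#' selection (pre- versus post-selection pool diversity ratio of ~3.5),
#' exponential clone growth near one doubling per day with clone-intrinsic
#' rate variation, passaging every 3.5 days, 0.1 percent per-base
#' substitution sequencing error.
#'
#' @param n_transfected Number of transfected cells.
#' @param rmce_rate Fraction of transfected cells with a successful
#'   integration event before selection.
#' @param selection_survival Fraction of integrants surviving selection.
#' @param growth_rate_mean,growth_rate_sd Clone growth rate distribution
#'   (1/day); rates are truncated at 0.
#' @param passage_interval Days between passages.
#' @param passage_bottleneck Cells kept at each passage.
#' @param error_rate Per-base substitution probability in sequencing.
#' @param reads_per_sample Reads generated per sequencing sample.
#' @param seed Random seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_transfected = 4.5e6, rmce_rate = 1e-3,
                       selection_survival = 0.3,
                       growth_rate_mean = 0.69, growth_rate_sd = 0.05,
                       passage_interval = 3.5, passage_bottleneck = 1e6,
                       error_rate = 0.001, reads_per_sample = 1e6,
                       seed = 1L) {
  stopifnot(rmce_rate >= 0, rmce_rate <= 1,
            selection_survival >= 0, selection_survival <= 1,
            error_rate >= 0, error_rate <= 1)
  structure(list(n_transfected = n_transfected, rmce_rate = rmce_rate,
                 selection_survival = selection_survival,
                 growth_rate_mean = growth_rate_mean,
                 growth_rate_sd = growth_rate_sd,
                 passage_interval = passage_interval,
                 passage_bottleneck = passage_bottleneck,
                 error_rate = error_rate,
                 reads_per_sample = reads_per_sample,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_barcodes <- function(n, length) {
  if (n > 4^length) stop("n_variants exceeds 4^", length, " possible sequences")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    fresh <- vapply(seq_len(need + ceiling(need * 0.05) + 8L), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), "")
    out <- unique(c(out, fresh))
  }
  out[seq_len(n)]
}

#' Simulate a barcode library
#'
#' Draws `n_variants` distinct random sequences and assigns log-normal
#' abundances whose coefficient of variation equals `skew` (`skew = 0`
#' gives a perfectly uniform library).
#'
#' @param spec A [barcode_spec()]; sequences have length
#'   `random_length + meta_length` (the metadata block is all-A unless a
#'   `tag` is given).
#' @param n_variants Number of distinct barcodes.
#' @param skew Target abundance CV (log-normal dispersion).
#' @param seed Random seed.
#' @param tag Optional [metadata_tag()] encoded into the metadata block.
#' @return A [barcode_library()].
#' @export
simulate_library <- function(spec = barcode_spec(), n_variants = 1000L,
                             skew = 0.3, seed = 1L, tag = NULL) {
  set.seed(seed)
  seqs <- random_barcodes(n_variants, spec$random_length)
  if (spec$meta_length > 0L) {
    meta <- if (is.null(tag)) strrep("A", spec$meta_length)
            else encode_metadata(tag, spec)
    seqs <- paste0(seqs, meta)
  }
  ab <- if (skew == 0) rep(1000, n_variants) else {
    sdlog <- sqrt(log(1 + skew^2))
    stats::rlnorm(n_variants, meanlog = log(1000) - sdlog^2 / 2, sdlog = sdlog)
  }
  barcode_library(stats::setNames(ab, seqs), spec = spec)
}

#' Simulate pool founding: transfection, RMCE and selection
#'
#' Draws `n_transfected * rmce_rate` founder integration events from the
#' library (with replacement, proportional to abundance, so barcode
#' collisions between independent integrants are possible and tracked),
#' assigns each surviving founder lineage a clone-intrinsic growth rate,
#' and thins founders by `selection_survival`.
#'
#' @param lib A [barcode_library()].
#' @param cfg A [sim_config()].
#' @return An object of class `sim_pool`: `clones` (data.frame barcode,
#'   abundance, growth_rate), `time` (days), `founding` (bookkeeping:
#'   n_founders, n_distinct, collision_fraction, n_after_selection).
#' @export
simulate_pool_founding <- function(lib, cfg = sim_config()) {
  set.seed(cfg$seed)
  n_founders <- round(cfg$n_transfected * cfg$rmce_rate)
  if (n_founders == 0) {
    return(structure(list(clones = data.frame(barcode = character(0),
                                              abundance = numeric(0),
                                              growth_rate = numeric(0)),
                          time = 0,
                          founding = list(n_founders = 0, n_distinct = 0,
                                          collision_fraction = NA_real_,
                                          n_after_selection = 0)),
                     class = "sim_pool"))
  }
  probs <- lib$entries / sum(lib$entries)
  picks <- sample(names(lib$entries), n_founders, replace = TRUE, prob = probs)
  n_distinct <- length(unique(picks))
  collision_fraction <- 1 - n_distinct / n_founders
  keep <- stats::runif(n_founders) < cfg$selection_survival
  picks <- picks[keep]
  if (!length(picks)) {
    clones <- data.frame(barcode = character(0), abundance = numeric(0),
                         growth_rate = numeric(0))
  } else {
    tb <- table(picks)
    rates <- stats::rnorm(length(tb), cfg$growth_rate_mean, cfg$growth_rate_sd)
    rates <- pmax(rates, 0)
    clones <- data.frame(barcode = names(tb),
                         abundance = as.numeric(tb),
                         growth_rate = rates)
  }
  structure(list(clones = clones, time = 0,
                 founding = list(n_founders = n_founders,
                                 n_distinct = n_distinct,
                                 collision_fraction = collision_fraction,
                                 n_after_selection = sum(keep))),
            class = "sim_pool")
}

#' @export
print.sim_pool <- function(x, ...) {
  cat(sprintf("sim_pool: %d clones, %s cells, day %g\n", nrow(x$clones),
              format(round(sum(x$clones$abundance)), big.mark = ","), x$time))
  invisible(x)
}

# multivariate hypergeometric draw: sample `size` cells without replacement
# from integer abundances
rmvhyper <- function(abundances, size) {
  k <- length(abundances)
  out <- numeric(k)
  remaining <- sum(abundances)
  left <- size
  for (i in seq_len(k)) {
    if (left == 0) break
    remaining <- remaining - abundances[i]
    out[i] <- stats::rhyper(1, abundances[i], remaining, left)
    left <- left - out[i]
  }
  out
}

#' Simulate prolonged pool cultivation with passaging
#'
#' Clones grow deterministically and exponentially at their intrinsic rates
#' between passages; each passage subsamples the pool without replacement
#' (multivariate hypergeometric) down to `passage_bottleneck` cells.
#' Abundance snapshots are emitted at the requested timepoints.
#'
#' @param pool A `sim_pool` from [simulate_pool_founding()].
#' @param days Total days of cultivation.
#' @param cfg A [sim_config()].
#' @param timepoints Days at which to record a snapshot (taken at the
#'   nearest passage); defaults to start and end.
#' @return List with `timepoints` and `tables` (named count vectors of cell
#'   abundance per barcode, one per timepoint).
#' @export
simulate_passaging <- function(pool, days, cfg = sim_config(),
                               timepoints = c(0, days)) {
  if (!nrow(pool$clones)) stop("empty pool")
  set.seed(cfg$seed + 1L)
  ab <- pool$clones$abundance
  rates <- pool$clones$growth_rate
  bcs <- pool$clones$barcode
  snap_times <- sort(unique(timepoints))
  snaps <- vector("list", length(snap_times))
  t <- 0
  record <- function(t_now) {
    due <- which(vapply(seq_along(snap_times), function(i)
      is.null(snaps[[i]]) && snap_times[i] <= t_now + 1e-9, TRUE))
    for (i in due) {
      keep <- ab > 0
      snaps[[i]] <<- stats::setNames(ab[keep], bcs[keep])
    }
  }
  record(t)
  while (t < days - 1e-9) {
    dt <- min(cfg$passage_interval, days - t)
    ab <- ab * exp(rates * dt)
    t <- t + dt
    total <- sum(ab)
    if (total > cfg$passage_bottleneck) {
      ab <- rmvhyper(round(ab), cfg$passage_bottleneck)
    }
    record(t)
  }
  record(days + cfg$passage_interval)  # flush any remaining snapshots
  list(timepoints = snap_times, tables = snaps)
}

#' Simulate limited-dilution well seeding and outgrowth
#'
#' Each well receives `k ~ Poisson(lam)` cells whose barcodes are drawn
#' proportionally to pool abundance. Each cell recovers independently with
#' probability `a`. Under the default growth model, a multi-cell well is
#' scored as grown only when exactly one cell recovers (the colony then
#' carries that cell's barcode), mirroring the `G_k` outgrowth term of the
#' clonality model; `both_grow = TRUE` scores growth when at least one cell
#' recovers and keeps all recovered barcodes.
#'
#' @param pool A `sim_pool`, or a named abundance vector.
#' @param lam Poisson seeding mean (> 0).
#' @param a Single-cell recovery rate in \[0, 1\].
#' @param n_wells Number of wells.
#' @param seed Random seed.
#' @param both_grow Alternative growth model (see above).
#' @return data.frame with columns well, k, grew, and `barcodes`
#'   (list-column of the outgrowing clone barcode(s)).
#' @export
simulate_limited_dilution <- function(pool, lam, a, n_wells, seed = 1L,
                                      both_grow = FALSE) {
  if (lam <= 0) stop("lam must be > 0")
  if (a < 0 || a > 1) stop("a must be in [0, 1]")
  ab <- if (inherits(pool, "sim_pool"))
    stats::setNames(pool$clones$abundance, pool$clones$barcode) else pool
  probs <- ab / sum(ab)
  set.seed(seed)
  k <- stats::rpois(n_wells, lam)
  grew <- logical(n_wells)
  barcodes <- vector("list", n_wells)
  nz <- which(k > 0)
  for (i in nz) {
    cells <- sample(names(probs), k[i], replace = TRUE, prob = probs)
    rec <- stats::runif(k[i]) < a
    if (both_grow) {
      grew[i] <- any(rec)
      barcodes[[i]] <- unique(cells[rec])
    } else {
      grew[i] <- sum(rec) == 1L
      barcodes[[i]] <- if (grew[i]) cells[rec] else character(0)
    }
  }
  data.frame(well = seq_len(n_wells), k = k, grew = grew,
             barcodes = I(barcodes))
}

mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  width <- nchar(reads[1])
  n_err <- stats::rbinom(length(reads), width, error_rate)
  idx <- which(n_err > 0L)
  if (!length(idx)) return(reads)
  m <- matrix(unlist(strsplit(reads[idx], "", fixed = TRUE), use.names = FALSE),
              nrow = length(idx), byrow = TRUE)
  row <- rep(seq_along(idx), n_err[idx])
  pos <- sample.int(width, length(row), replace = TRUE)
  cur <- m[cbind(row, pos)]
  alt <- c("A", "C", "G", "T")[
    (match(cur, c("A", "C", "G", "T")) - 1L +
       sample.int(3L, length(row), replace = TRUE)) %% 4L + 1L]
  m[cbind(row, pos)] <- alt
  reads[idx] <- do.call(paste0, lapply(seq_len(width), function(j) m[, j]))
  reads
}

# rare single-base insertions/deletions for robustness testing; an indel
# inside the barcode shifts its length so the length-15 filter drops it
apply_indels <- function(reads, indel_rate) {
  if (indel_rate <= 0) return(reads)
  width <- nchar(reads[1])
  hit <- which(stats::rbinom(length(reads), width, indel_rate) > 0L)
  for (i in hit) {
    pos <- sample.int(nchar(reads[i]), 1L)
    if (stats::runif(1) < 0.5) {   # deletion
      reads[i] <- paste0(substr(reads[i], 1L, pos - 1L),
                         substr(reads[i], pos + 1L, nchar(reads[i])))
    } else {                       # insertion
      reads[i] <- paste0(substr(reads[i], 1L, pos),
                         sample(c("A", "C", "G", "T"), 1L),
                         substr(reads[i], pos + 1L, nchar(reads[i])))
    }
  }
  reads
}

#' Simulate merged amplicon reads from a barcode abundance vector
#'
#' Fast path producing already-merged reads: each read is
#' `left_context + left_flank + barcode + right_flank + right_context`,
#' with per-base substitution errors at `error_rate` and roughly half of
#' the reads emitted reverse-complemented. Read counts per barcode follow
#' a multinomial on the relative abundances. The returned truth table
#' allows exact round-trip checks downstream.
#'
#' @param abundances Named abundance vector (barcode -> abundance).
#' @param flanks A [flank_spec()].
#' @param n_reads Total reads to emit.
#' @param error_rate Per-base substitution probability.
#' @param indel_rate Per-base probability of a single-base
#'   insertion/deletion (default 0; substitutions are the modeled error
#'   class — an in-barcode indel fails the length filter instead).
#' @param seed Random seed.
#' @param left_context,right_context Constant sequence outside the flanks.
#' @return List with `reads` (character vector) and `truth` (named read
#'   counts per barcode before errors).
#' @export
simulate_merged_reads <- function(abundances, flanks, n_reads,
                                  error_rate = 0.001, indel_rate = 0,
                                  seed = 1L,
                                  left_context = "ACGTGACTGGAC",
                                  right_context = "GTCCAGTCACGT") {
  set.seed(seed)
  probs <- abundances / sum(abundances)
  counts <- as.numeric(stats::rmultinom(1, n_reads, probs))
  names(counts) <- names(abundances)
  templates <- paste0(left_context, flanks$left_flank, names(abundances),
                      flanks$right_flank, right_context)
  reads <- rep(templates, counts)
  reads <- mutate_reads(reads, error_rate)
  reads <- apply_indels(reads, indel_rate)
  flip <- stats::runif(length(reads)) < 0.5
  if (any(flip)) reads[flip] <- reverse_complement(reads[flip])
  if (length(reads)) {
    perm <- sample.int(length(reads))
    reads <- reads[perm]
  }
  list(reads = reads, truth = counts)
}

#' Simulate paired-end FASTQ files for an amplicon sample
#'
#' Builds full amplicon templates as in [simulate_merged_reads()], extends
#' the context so the template reaches `2 * read_length - overlap`
#' nucleotides, fragments each template into overlapping forward/reverse
#' 150-nt mates, applies substitution errors, and writes a FASTQ pair plus
#' a truth table TSV.
#'
#' @param abundances Named abundance vector (barcode -> abundance).
#' @param flanks A [flank_spec()].
#' @param n_reads Read pairs to emit.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @param read_length Mate length (default 150).
#' @param error_rate Per-base substitution probability.
#' @param seed Random seed.
#' @return List with paths `r1`, `r2`, `truth` and the truth counts.
#' @export
simulate_read_files <- function(abundances, flanks, n_reads, dir,
                                prefix = "sim", read_length = 150L,
                                error_rate = 0.001, seed = 1L) {
  set.seed(seed)
  probs <- abundances / sum(abundances)
  counts <- as.numeric(stats::rmultinom(1, n_reads, probs))
  names(counts) <- names(abundances)
  core <- paste0(flanks$left_flank, names(abundances), flanks$right_flank)
  template_len <- 2L * read_length - 60L  # 60 nt overlap between mates
  pad_total <- template_len - nchar(core[1])
  lpad <- pad_total %/% 2L
  rpad <- pad_total - lpad
  ctx <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  templates <- paste0(ctx(lpad), core, ctx(rpad))
  tmpl <- rep(templates, counts)
  if (length(tmpl)) tmpl <- tmpl[sample.int(length(tmpl))]
  r1 <- substr(tmpl, 1L, read_length)
  r2 <- reverse_complement(substr(tmpl, nchar(tmpl[1]) - read_length + 1L,
                                  nchar(tmpl[1])))
  r1 <- mutate_reads(r1, error_rate)
  r2 <- mutate_reads(r2, error_rate)
  ids <- sprintf("%s_read%06d", prefix, seq_along(r1))
  write_fastq <- function(seqs, path, ids) {
    qual <- strrep("I", nchar(seqs[1]))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  }
  r1_path <- file.path(dir, paste0(prefix, "_R1.fastq"))
  r2_path <- file.path(dir, paste0(prefix, "_R2.fastq"))
  write_fastq(r1, r1_path, ids)
  write_fastq(r2, r2_path, ids)
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_count_table(counts[counts > 0], truth_path)
  list(r1 = r1_path, r2 = r2_path, truth = truth_path, counts = counts)
}

#' Simulate clone phenotypes with a lineage variance structure
#'
#' Each lineage (barcode) draws a lineage mean from
#' `Normal(global_mean, between_sd)`; each clone then draws its phenotype
#' from `Normal(lineage mean, within_sd)`. Sibling clones (same barcode)
#' therefore share a lineage mean and differ only by the within-lineage
#' component.
#'
#' @param barcodes Character vector, one entry per clone (repeated barcode
#'   = sibling clones).
#' @param global_mean Cohort-level phenotype mean.
#' @param between_sd Between-lineage SD.
#' @param within_sd Within-lineage SD.
#' @param seed Random seed.
#' @param phenotype Name of the phenotype column.
#' @return data.frame with clone_id, barcode and the phenotype column.
#' @export
simulate_phenotypes <- function(barcodes, global_mean = 1000,
                                between_sd = 100, within_sd = 20,
                                seed = 1L, phenotype = "titer") {
  if (between_sd < 0 || within_sd < 0) stop("SDs must be >= 0")
  set.seed(seed)
  lineages <- unique(barcodes)
  lin_mean <- stats::setNames(
    stats::rnorm(length(lineages), global_mean, between_sd), lineages)
  vals <- stats::rnorm(length(barcodes), lin_mean[barcodes], within_sd)
  out <- data.frame(clone_id = sprintf("clone%03d", seq_along(barcodes)),
                    barcode = barcodes)
  out[[phenotype]] <- vals
  out
}
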