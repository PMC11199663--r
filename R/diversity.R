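#' Chao1 richness estimator
#'
#' Capture-recapture estimate of the true number of barcode variants from
#' the observed abundance distribution. With `f1` singletons and `f2`
#' doubletons: the classic form is `S_obs + f1^2 / (2 f2)` (requires
#' `f2 > 0`), the bias-corrected form `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`,
#' which stays defined at `f2 = 0` and is the default. Both are always at
#' least `S_obs`.
#'
#' @param abundances Positive integer abundances, one per observed barcode
#'   (a [count_table()] is also accepted).
#' @param bias_corrected Use the bias-corrected form (default `TRUE`).
#' @return Estimated richness (numeric scalar).
#' @export
chao1 <- function(abundances, bias_corrected = TRUE) {
  if (inherits(abundances, "count_table")) abundances <- abundances$counts
  abundances <- abundances[abundances > 0]
  if (!length(abundances)) stop("empty abundance vector")
  s_obs <- length(abundances)
  f1 <- sum(abundances == 1)
  f2 <- sum(abundances == 2)
  if (bias_corrected || f2 == 0) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else {
    s_obs + f1^2 / (2 * f2)
  }
}

# draw a without-replacement subsample of reads and return per-barcode
# counts of the sampled reads (multivariate hypergeometric)
subsample_counts <- function(abundances, depth) {
  total <- sum(abundances)
  idx <- sample.int(total, depth)
  breaks <- cumsum(abundances)
  bc <- findInterval(idx - 1L, c(0, breaks), rightmost.closed = TRUE)
  tab <- tabulate(bc, nbins = length(abundances))
  tab
}

#' Observed and Chao1 richness under replicate resampling
#'
#' Draws reads without replacement at each requested depth (replicated) and
#' reports mean and SD of observed richness and of the Chao1 estimate,
#' emulating diversity estimation from subsampled sequencing libraries.
#'
#' @param abundances Positive abundances per barcode (or [count_table()]).
#' @param depths Read depths to resample at; each must not exceed the total.
#' @param replicates Number of replicate draws per depth.
#' @param seed Random seed.
#' @return data.frame with columns depth, observed_mean, observed_sd,
#'   chao1_mean, chao1_sd.
#' @export
resampled_richness <- function(abundances, depths, replicates = 20L,
                               seed = 1L) {
  if (inherits(abundances, "count_table")) abundances <- abundances$counts
  abundances <- as.numeric(abundances[abundances > 0])
  total <- sum(abundances)
  if (any(depths > total)) stop("depth exceeds total abundance")
  if (any(depths < 1)) stop("depths must be >= 1")
  set.seed(seed)
  rows <- lapply(depths, function(d) {
    obs <- numeric(replicates)
    ch <- numeric(replicates)
    for (r in seq_len(replicates)) {
      sub <- subsample_counts(abundances, d)
      sub <- sub[sub > 0]
      obs[r] <- length(sub)
      ch[r] <- chao1(sub)
    }
    data.frame(depth = d,
               observed_mean = mean(obs), observed_sd = stats::sd(obs),
               chao1_mean = mean(ch), chao1_sd = stats::sd(ch))
  })
  do.call(rbind, rows)
}

#' Barcode collision probability
#'
#' Probability that independently labeled cells coincidentally share a
#' barcode. `n_cells` barcodes are sampled without replacement from the
#' pool (each physical copy is a sampling unit, so sampling probability is
#' proportional to abundance); `p` is the fraction of sampled items whose
#' barcode occurs exactly once within the sample, and the collision
#' probability is `1 - p`, averaged over replicates.
#'
#' @param abundances Positive abundances per barcode (or [count_table()]).
#' @param n_cells Number of cells to label (must not exceed the total pool).
#' @param replicates Monte-Carlo replicates.
#' @param seed Random seed.
#' @return List with `collision` (mean), `sd`, and `replicates`.
#' @export
collision_probability <- function(abundances, n_cells, replicates = 20L,
                                  seed = 1L) {
  if (inherits(abundances, "count_table")) abundances <- abundances$counts
  abundances <- as.numeric(abundances[abundances > 0])
  total <- sum(abundances)
  if (n_cells > total) stop("n_cells exceeds total pool size")
  set.seed(seed)
  vals <- vapply(seq_len(replicates), function(r) {
    sub <- subsample_counts(abundances, n_cells)
    unique_items <- sum(sub == 1L)
    1 - unique_items / n_cells
  }, 0)
  list(collision = mean(vals), sd = stats::sd(vals), replicates = replicates)
}

#' Diversity trajectory of a pool time series
#'
#' Applies genuine-barcode calling per timepoint and tracks the number of
#' genuine barcodes, the fraction of the first timepoint's genuine barcodes
#' still called genuine (retention), and the read fraction of the most
#' abundant barcode (dominance).
#'
#' @param tables List of [count_table()] (or named count vectors), one per
#'   timepoint, in time order.
#' @param timepoints Numeric timepoints (e.g. days), strictly increasing.
#' @param params [clustering_params()] passed to [call_genuine()].
#' @return data.frame with columns timepoint, n_genuine, retention,
#'   top_clone_fraction.
#' @export
diversity_trajectory <- function(tables, timepoints = seq_along(tables),
                                 params = clustering_params()) {
  if (length(tables) < 1L) stop("need at least one timepoint")
  if (length(timepoints) != length(tables))
    stop("timepoints and tables lengths differ")
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  calls <- lapply(tables, function(tb)
    suppressWarnings(call_genuine(tb, params)))
  first_set <- calls[[1]]$genuine
  rows <- lapply(seq_along(calls), function(i) {
    cl <- calls[[i]]
    cc <- cl$clustered_counts$counts
    data.frame(
      timepoint = timepoints[i],
      n_genuine = length(cl$genuine),
      retention = if (length(first_set)) mean(first_set %in% cl$genuine) else NA_real_,
      top_clone_fraction = max(cc) / sum(cc))
  })
  do.call(rbind, rows)
}

#' RMCE efficiency
#'
#' Fraction of transfected cells that yielded a surviving, genuinely
#' barcoded integrant: genuine barcode count divided by the number of
#' transfected cells.
#'
#' @param genuine_count Number of genuine barcodes in the recovered pool.
#' @param transfected_cells Number of transfected cells (> 0).
#' @return Efficiency as a fraction.
#' @export
rmce_efficiency <- function(genuine_count, transfected_cells) {
  if (transfected_cells <= 0) stop("transfected_cells must be > 0")
  genuine_count / transfected_cells
}
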