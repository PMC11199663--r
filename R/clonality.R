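#' Plate-level limited-dilution statistics
#'
#' @param n_wells_plated Total number of wells seeded (N).
#' @param n_wells_grown Number of wells with cell growth (W), e.g. defined
#'   as > 10 percent confluence on day 18 after limited dilution.
#' @param seeding_mean Average number of cells per well (the Poisson
#'   parameter, > 0).
#' @param growth_definition Free-text description of the growth criterion.
#' @return An object of class `plate_stats`.
#' @export
plate_stats <- function(n_wells_plated, n_wells_grown, seeding_mean,
                        growth_definition = "> 10% confluence on day 18") {
  if (n_wells_grown < 0 || n_wells_grown > n_wells_plated)
    stop("need 0 <= n_wells_grown <= n_wells_plated")
  if (seeding_mean <= 0) stop("seeding_mean must be > 0")
  structure(list(n_wells_plated = n_wells_plated,
                 n_wells_grown = n_wells_grown,
                 seeding_mean = seeding_mean,
                 growth_definition = growth_definition),
            class = "plate_stats")
}

#' Poisson probability mass
#'
#' Mass of observing `k` cells in a well at seeding mean `lam`
#' (`lam^k e^{-lam} / k!`). Thin wrapper over [stats::dpois()].
#'
#' @param k Non-negative integer count(s).
#' @param lam Positive mean.
#' @return Probability mass.
#' @export
poisson_pmf <- function(k, lam) {
  if (any(k < 0)) stop("k must be non-negative")
  if (lam <= 0) stop("lam must be > 0")
  stats::dpois(k, lam)
}

#' Single-cell recovery rate from plate statistics
#'
#' Solves for the recovery rate `a` (the probability that a single seeded
#' cell outgrows into a colony) in the well-growth balance
#' `N * sum_{k=1}^{k_trunc} P_mu(k) * (1 - (1 - a)^k) = W`,
#' where `P_mu` is the Poisson mass at the seeding mean. The truncated sum
#' telescopes to `N (1 - e^{-mu a})`, so the root agrees with the closed
#' form `-log(1 - W/N) / mu` up to truncation error. Root-finding is by
#' bisection on (1e-12, 1) to absolute tolerance 1e-10.
#'
#' @param plate A [plate_stats()].
#' @param k_trunc Truncation point of the Poisson sum (default 100).
#' @return Recovery rate `a` in (0, 1].
#' @export
solve_recovery_rate <- function(plate, k_trunc = 100L) {
  N <- plate$n_wells_plated
  W <- plate$n_wells_grown
  mu <- plate$seeding_mean
  if (W == 0) {
    warning("no wells grew; recovery rate is 0 (boundary)")
    return(0)
  }
  occ <- 1 - exp(-mu)
  if (W >= N * occ)
    stop("infeasible: wells with growth (", W, ") >= expected occupied wells (",
         round(N * occ, 2), "); no recovery rate in (0, 1) satisfies the model")
  ks <- seq_len(k_trunc)
  pk <- stats::dpois(ks, mu)
  f <- function(a) N * sum(pk * (1 - (1 - a)^ks)) - W
  lo <- 1e-12; hi <- 1
  flo <- f(lo)
  if (flo > 0) stop("no root: W too small for the model")
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Colony-outgrowth probability for a k-cell well
#'
#' `G_k = a` for `k = 1` and `G_k = k a (1 - a)^(k-1)` for `k > 1`: with
#' more than one cell per well, growth is scored when exactly one of the
#' `k` cells recovers while the others do not.
#'
#' @param k Integer cell count(s), >= 1.
#' @param a Recovery rate in \[0, 1\].
#' @return Growth probability G_k.
#' @export
growth_probability <- function(k, a) {
  if (any(k < 1)) stop("k must be >= 1")
  if (a < 0 || a > 1) stop("a must be in [0, 1]")
  ifelse(k == 1, a, k * a * (1 - a)^(k - 1))
}

#' Worst-case probability of a barcode collision among k cells
#'
#' Treats every cell as carrying the most frequent clone's probability
#' `p0` (the worst case for clonality): the probability that all `k` cells
#' are different clones is taken as a product of `k` factors `(1 - p0)`,
#' so the collision probability is `1 - (1 - p0)^k`. The
#' `convention = "k_minus_1"` variant uses `k - 1` factors (the standard
#' birthday-type bound); the k-factor form is the default.
#'
#' @param k Integer cell count(s), >= 1.
#' @param p0 Highest normalized clone frequency, in \[0, 1\].
#' @param convention `"as_printed"` (k factors) or `"k_minus_1"`.
#' @return Probability that at least two of the k cells are the same clone.
#' @export
p_at_least_two_identical <- function(k, p0,
                                     convention = c("as_printed", "k_minus_1")) {
  convention <- match.arg(convention)
  if (any(k < 1)) stop("k must be >= 1")
  if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
  expo <- if (convention == "as_printed") k else k - 1
  1 - (1 - p0)^expo
}

#' Probability of clonality from plate statistics and barcode frequencies
#'
#' Combines (i) the Poisson probability of `k > 1` cells in a well,
#' (ii) the worst-case probability that at least two of those cells are the
#' same clone, and (iii) the probability `G_k` that the well nevertheless
#' shows colony outgrowth, summed over `k = 2..k_max`:
#' `P(>=2 identical) = sum_k P_lambda(k) * (1 - (1 - P0)^k) * G_k`,
#' with `P0` the largest normalized barcode frequency at the time of
#' limited dilution and the recovery rate `a` solved from the plate
#' statistics. The probability of clonality is one minus that sum.
#'
#' @param plate A [plate_stats()]; its `seeding_mean` is the Poisson lambda.
#' @param frequencies Barcode frequencies (or raw counts; normalized
#'   internally). `P0` is their maximum.
#' @param k_max Largest cell count considered (default 10; higher counts
#'   are negligibly likely at limiting dilution).
#' @param convention Collision convention, see [p_at_least_two_identical()].
#' @param a Recovery rate; solved from `plate` when `NULL`.
#' @return An object of class `poc_result`: `poc`, `p_collision`,
#'   `recovery_rate`, `p0`, and `per_k_terms` (named, k = 2..k_max).
#' @export
probability_of_clonality <- function(plate, frequencies, k_max = 10L,
                                     convention = c("as_printed", "k_minus_1"),
                                     a = NULL) {
  convention <- match.arg(convention)
  if (k_max < 2L) stop("k_max must be >= 2")
  frequencies <- as.numeric(frequencies)
  if (any(frequencies < 0)) stop("frequencies must be >= 0")
  tot <- sum(frequencies)
  if (tot <= 0) stop("frequencies sum to 0")
  p <- frequencies / tot
  p0 <- max(p)
  if (is.null(a)) a <- solve_recovery_rate(plate)
  lam <- plate$seeding_mean
  ks <- 2:k_max
  terms <- poisson_pmf(ks, lam) *
    p_at_least_two_identical(ks, p0, convention) *
    growth_probability(ks, a)
  names(terms) <- paste0("k", ks)
  p_coll <- sum(terms)
  structure(list(poc = 1 - p_coll, p_collision = p_coll,
                 recovery_rate = a, p0 = p0, per_k_terms = terms,
                 convention = convention, k_max = as.integer(k_max)),
            class = "poc_result")
}

#' @export
print.poc_result <- function(x, ...) {
  cat(sprintf("probability of clonality: %.2f%% (P0 = %.4g, a = %.4g)\n",
              100 * x$poc, x$p0, x$recovery_rate))
  invisible(x)
}

#' Recover the recovery rate from simulated well outcomes
#'
#' Validation harness: takes simulated limited-dilution wells (see
#' [simulate_limited_dilution()]), computes observed (N, W), and re-solves
#' the well-growth equation at the known seeding mean.
#'
#' @param wells data.frame with at least a logical `grew` column.
#' @param seeding_mean Poisson mean used in the simulation.
#' @return Estimated recovery rate.
#' @export
estimate_recovery_rate_from_simulation <- function(wells, seeding_mean) {
  N <- nrow(wells)
  W <- sum(wells$grew)
  solve_recovery_rate(plate_stats(N, W, seeding_mean))
}
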