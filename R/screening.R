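#' Classify clones into sibling and relative lineage groups
#'
#' Sibling clones share a barcode (descended from the same integration
#' event and split only at single-cell cloning); a barcode is considered a
#' sibling group when it occurs at least `sibling_min` times in the cohort.
#' Relative clones carry a cohort-unique barcode (independent integration
#' events). Clones whose barcode occurs more than once but fewer than
#' `sibling_min` times belong to neither group.
#'
#' @param cohort data.frame with at least `clone_id` and `barcode` columns.
#' @param sibling_min Minimum barcode multiplicity for a sibling group
#'   (default 3).
#' @return An object of class `lineage_groups`: `siblings` (named list of
#'   clone-id vectors per barcode), `relatives` (clone ids),
#'   `unclassified` (clone ids), and the input `cohort`.
#' @export
classify_lineages <- function(cohort, sibling_min = 3L) {
  if (!nrow(cohort)) stop("empty cohort")
  stopifnot(all(c("clone_id", "barcode") %in% names(cohort)))
  mult <- table(cohort$barcode)
  sib_bc <- names(mult)[mult >= sibling_min]
  rel_bc <- names(mult)[mult == 1L]
  siblings <- lapply(sib_bc, function(b)
    cohort$clone_id[cohort$barcode == b])
  names(siblings) <- sib_bc
  structure(list(
    siblings = siblings,
    relatives = cohort$clone_id[cohort$barcode %in% rel_bc],
    unclassified = cohort$clone_id[!(cohort$barcode %in% c(sib_bc, rel_bc))],
    sibling_min = as.integer(sibling_min),
    cohort = cohort), class = "lineage_groups")
}

#' @export
print.lineage_groups <- function(x, ...) {
  cat(sprintf("lineage_groups: %d sibling clones in %d groups, %d relatives, %d unclassified\n",
              sum(lengths(x$siblings)), length(x$siblings),
              length(x$relatives), length(x$unclassified)))
  invisible(x)
}

pairwise_abs_diff <- function(values) {
  if (length(values) < 2L) return(numeric(0))
  abs(as.numeric(stats::dist(matrix(values, ncol = 1))))
}

#' Sibling-versus-relative pairwise difference test
#'
#' Compares phenotype dispersion between lineage classes: builds all
#' pairwise absolute differences within each sibling group (pooled across
#' groups) and all pairwise absolute differences among relative clones,
#' then tests the two sets with a two-sided Wilcoxon rank-sum test. A
#' significantly smaller sibling mean difference indicates that clonal
#' origin (the integration event) explains phenotypic variance.
#' Pairwise differences are not mutually independent; the test is applied
#' to them as-is, so p-values are descriptive rather than exact.
#'
#' @param groups A [classify_lineages()] result.
#' @param phenotype Name of the phenotype column in the cohort.
#' @return List with `sibling_mean_diff`, `relative_mean_diff`,
#'   `statistic` (rank-sum W), `p_value`, and the two difference sets.
#' @export
pairwise_difference_test <- function(groups, phenotype) {
  cohort <- groups$cohort
  if (!phenotype %in% names(cohort))
    stop("phenotype '", phenotype, "' not in cohort")
  vals <- stats::setNames(cohort[[phenotype]], cohort$clone_id)
  sib_diffs <- unlist(lapply(groups$siblings, function(ids)
    pairwise_abs_diff(vals[ids])), use.names = FALSE)
  rel_diffs <- pairwise_abs_diff(vals[groups$relatives])
  if (length(sib_diffs) < 2L || length(rel_diffs) < 2L)
    stop("degenerate comparison sets for phenotype '", phenotype, "'")
  wt <- stats::wilcox.test(sib_diffs, rel_diffs, alternative = "two.sided",
                           exact = (length(sib_diffs) + length(rel_diffs)) <= 20L,
                           correct = TRUE)
  list(phenotype = phenotype,
       sibling_mean_diff = mean(sib_diffs),
       relative_mean_diff = mean(rel_diffs),
       statistic = unname(wt$statistic),
       p_value = wt$p.value,
       sibling_diffs = sib_diffs,
       relative_diffs = rel_diffs)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (delegates to [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Design diversity-controlled screening arms
#'
#' Splits a clone cohort into an enrichment arm (`arm_size` clones with
#' pairwise-distinct barcodes, maximizing lineage diversity) and a
#' depletion arm (`arm_size` clones drawn from exactly
#' `n_lineages_depletion` barcodes, minimizing lineage diversity). A clone
#' is used in at most one arm.
#'
#' @param cohort data.frame with `clone_id` and `barcode` columns.
#' @param arm_size Clones per arm (default 48).
#' @param n_lineages_depletion Distinct barcodes in the depletion arm
#'   (default 15).
#' @param seed Random seed for the draws.
#' @return List with `enrichment` and `depletion` (data.frame subsets of
#'   the cohort).
#' @export
design_arms <- function(cohort, arm_size = 48L, n_lineages_depletion = 15L,
                        seed = 1L) {
  stopifnot(all(c("clone_id", "barcode") %in% names(cohort)))
  set.seed(seed)
  mult <- sort(table(cohort$barcode), decreasing = TRUE)
  # depletion arm first: most-multiplied lineages provide the clones
  dep_bc <- names(mult)[seq_len(min(n_lineages_depletion, length(mult)))]
  if (length(dep_bc) < n_lineages_depletion)
    stop("infeasible: cohort has only ", length(mult),
         " distinct barcodes, need ", n_lineages_depletion,
         " for the depletion arm")
  dep_pool <- cohort[cohort$barcode %in% dep_bc, ]
  if (nrow(dep_pool) < arm_size)
    stop("infeasible: the ", n_lineages_depletion,
         " largest lineages contain ", nrow(dep_pool),
         " clones, need ", arm_size, " for the depletion arm")
  # one clone per depletion lineage first, then fill randomly
  first <- do.call(rbind, lapply(dep_bc, function(b) {
    cand <- dep_pool[dep_pool$barcode == b, ]
    cand[sample.int(nrow(cand), 1L), ]
  }))
  rest_pool <- dep_pool[!dep_pool$clone_id %in% first$clone_id, ]
  need <- arm_size - nrow(first)
  if (need > 0) {
    fill <- rest_pool[sample.int(nrow(rest_pool), need), ]
    depletion <- rbind(first, fill)
  } else depletion <- first[seq_len(arm_size), ]
  # enrichment arm: one clone per barcode, from clones not used above
  enr_pool <- cohort[!cohort$clone_id %in% depletion$clone_id, ]
  enr_bc <- unique(enr_pool$barcode)
  if (length(enr_bc) < arm_size)
    stop("infeasible: only ", length(enr_bc),
         " distinct barcodes available for the enrichment arm, need ",
         arm_size)
  pick_bc <- sample(enr_bc, arm_size)
  enrichment <- do.call(rbind, lapply(pick_bc, function(b) {
    cand <- enr_pool[enr_pool$barcode == b, ]
    cand[sample.int(nrow(cand), 1L), ]
  }))
  rownames(enrichment) <- rownames(depletion) <- NULL
  list(enrichment = enrichment, depletion = depletion)
}

#' Maximum titer as a function of screening depth
#'
#' For each screening depth `n`, repeatedly draws `n` titer values without
#' replacement and records the maximum; reports mean and SD of the maximum
#' over replicates. A pool whose diversity is enriched reaches its plateau
#' (the best clone) at a smaller screening depth and with lower SD.
#'
#' @param titers Measured titer values.
#' @param depths Screening depths (each <= `length(titers)`).
#' @param replicates Independent draws per depth (default 3).
#' @param seed Random seed.
#' @return data.frame with columns depth, max_mean, max_sd.
#' @export
max_titer_curve <- function(titers, depths, replicates = 3L, seed = 1L) {
  titers <- as.numeric(titers)
  if (any(depths > length(titers))) stop("depth exceeds number of titers")
  if (any(depths < 1)) stop("depths must be >= 1")
  set.seed(seed)
  rows <- lapply(depths, function(d) {
    mx <- vapply(seq_len(replicates), function(r)
      max(sample(titers, d)), 0)
    data.frame(depth = d, max_mean = mean(mx), max_sd = stats::sd(mx))
  })
  do.call(rbind, rows)
}

#' Read a clone table CSV (clone_id, barcode, phenotype columns)
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_clone_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("clone_id", "barcode") %in% names(df)))
    stop("clone table needs 'clone_id' and 'barcode' columns")
  df
}
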