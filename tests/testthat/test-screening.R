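cohort_from <- function(barcodes) {
  data.frame(clone_id = sprintf("c%02d", seq_along(barcodes)),
             barcode = barcodes)
}

test_that("lineage classification partitions by barcode multiplicity", {
  g <- classify_lineages(cohort_from(c("X", "X", "X", "Y", "Z")))
  expect_named(g$siblings, "X")
  expect_length(g$siblings$X, 3)
  expect_setequal(g$relatives, c("c04", "c05"))
  expect_length(g$unclassified, 0)

  all_unique <- classify_lineages(cohort_from(letters[1:6]))
  expect_length(all_unique$siblings, 0)
  expect_length(all_unique$relatives, 6)

  # multiplicity-2 barcodes are in neither class
  g2 <- classify_lineages(cohort_from(c("X", "X", "Y")))
  expect_length(g2$siblings, 0)
  expect_setequal(g2$unclassified, c("c01", "c02"))
})

test_that("simulated cohorts round-trip their group structure", {
  # 34 clones in multiplicity->=3 lineages + 33 unique, as in a screening
  # campaign with sibling and relative clones
  bcs <- c(rep(make_barcodes(10, seed = 81)[1:10],
               times = c(4, 4, 4, 3, 3, 3, 3, 4, 3, 3)),
           make_barcodes(43, seed = 82)[11:43])
  g <- classify_lineages(cohort_from(bcs))
  expect_identical(sum(lengths(g$siblings)), 34L)
  expect_length(g$relatives, 33)
})

test_that("identical siblings against spread relatives gives a tiny p", {
  barcodes <- c(rep("S1", 4), rep("S2", 4), paste0("R", 1:12))
  cohort <- cohort_from(barcodes)
  set.seed(83)
  vals <- c(rep(10, 4), rep(20, 4), stats::rnorm(12, 15, 6))
  cohort$titer <- vals
  g <- classify_lineages(cohort)
  res <- pairwise_difference_test(g, "titer")
  expect_identical(res$sibling_mean_diff, 0)
  expect_gt(res$relative_mean_diff, 0)
  expect_lt(res$p_value, 1e-4)
})

test_that("the test has no power when lineage means do not differ", {
  pvals <- vapply(1:100, function(s) {
    bcs <- c(rep(make_barcodes(8, seed = 84)[1:8], each = 4),
             make_barcodes(40, seed = 85)[9:40])
    cohort <- simulate_phenotypes(bcs, between_sd = 0, within_sd = 10,
                                  seed = 8400 + s)
    g <- classify_lineages(cohort)
    pairwise_difference_test(g, "titer")$p_value
  }, 0)
  # pairwise differences share clones, so the rank-sum null is only
  # approximate: p-values are spread rather than uniform, and far from
  # the concentration near zero seen under a real lineage effect
  expect_gt(median(pvals), 0.1)
  expect_lt(mean(pvals < 0.05), 0.5)
  expect_gt(mean(pvals > 0.5), 0.2)
})

test_that("lineage variance structure is detected with high power", {
  hits <- vapply(1:20, function(s) {
    bcs <- c(rep(make_barcodes(10, seed = 86)[1:10],
                 times = c(4, 4, 4, 3, 3, 3, 3, 4, 3, 3)),
             make_barcodes(43, seed = 87)[11:43])
    cohort <- simulate_phenotypes(bcs, between_sd = 100, within_sd = 20,
                                  seed = 8600 + s)
    g <- classify_lineages(cohort)
    pairwise_difference_test(g, "titer")$p_value
  }, 0)
  expect_gte(mean(fdr_adjust(hits) < 0.05), 0.9)
})

test_that("BH adjustment matches the hand-evaluated step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.04, 0.9, 0.012)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_identical(order(adj), order(p))
  expect_error(fdr_adjust(c(0.1, 1.3)), "0, 1")
})

test_that("screening arms have the designed lineage structure", {
  # 15 lineages of 4 clones + 60 singleton lineages
  bcs <- c(rep(make_barcodes(15, seed = 88), each = 4),
           make_barcodes(80, seed = 89)[16:75])
  cohort <- cohort_from(bcs)
  arms <- design_arms(cohort, arm_size = 48L, n_lineages_depletion = 15L,
                      seed = 88)
  expect_identical(nrow(arms$enrichment), 48L)
  expect_identical(nrow(arms$depletion), 48L)
  expect_identical(length(unique(arms$enrichment$barcode)), 48L)
  expect_identical(length(unique(arms$depletion$barcode)), 15L)
  expect_length(intersect(arms$enrichment$clone_id,
                          arms$depletion$clone_id), 0)
  # reproducible under seed
  arms2 <- design_arms(cohort, 48L, 15L, seed = 88)
  expect_identical(arms$enrichment$clone_id, arms2$enrichment$clone_id)

  tiny <- design_arms(cohort, arm_size = 1L, n_lineages_depletion = 1L)
  expect_identical(nrow(tiny$enrichment), 1L)

  few <- cohort_from(rep(make_barcodes(10, seed = 90), each = 2))
  expect_error(design_arms(few, arm_size = 48L), "infeasible")
})

test_that("max-titer curve plateaus with depth and has zero SD at full depth", {
  set.seed(91)
  titers <- stats::rnorm(60, 1000, 150)
  res <- max_titer_curve(titers, depths = c(5, 15, 30, 60),
                         replicates = 200, seed = 91)
  expect_true(all(diff(res$max_mean) >= 0))
  expect_equal(res$max_mean[4], max(titers))
  expect_equal(res$max_sd[4], 0)

  const <- max_titer_curve(rep(7, 10), depths = c(2, 5, 10), seed = 1)
  expect_true(all(const$max_mean == 7))
  expect_error(max_titer_curve(titers, depths = 100), "depth")
})

test_that("enriched-diversity arms reach higher maxima at shallow depth", {
  # between-lineage variance >> within: an enrichment arm of 48 distinct
  # lineages spans more of the titer distribution than a depletion arm of
  # 48 clones from 15 lineages, so its expected subset maximum is higher
  # at every screening depth
  depths <- c(4, 8, 16, 32)
  gaps <- vapply(1:20, function(s) {
    set.seed(900 + s)
    enrich_titers <- stats::rnorm(48, stats::rnorm(48, 1000, 200), 20)
    dep_lin <- stats::rnorm(15, 1000, 200)
    depl_titers <- stats::rnorm(48, rep(dep_lin, length.out = 48), 20)
    enr <- max_titer_curve(enrich_titers, depths, replicates = 50,
                           seed = 900 + s)
    dep <- max_titer_curve(depl_titers, depths, replicates = 50,
                           seed = 1900 + s)
    mean(enr$max_mean - dep$max_mean)
  }, 0)
  expect_gt(mean(gaps), 0)
  expect_gt(mean(gaps > 0), 0.7)
})
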