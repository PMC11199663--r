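---
title: "Models and methods: barcode-based clonality and diversity analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: barcode-based clonality and diversity analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrace)
```

# The workflow in one paragraph

Targeted-integration CHO cell line development (CLD) inserts the expression
cassette at a single genomic landing pad via recombinase-mediated cassette
exchange (RMCE). Tagging the cassette with a randomized 15-nt barcode makes
every successful integration event a traceable lineage: amplicon sequencing
of the barcode locus reports which clones exist in a pool, how their
abundances drift, whether a "monoclonal" well really grew from one cell,
and which picked clones are siblings (same integration event) versus
relatives (independent events). `clonotrace` implements the computational
side of that workflow end to end, plus a simulator that generates every
input the pipeline consumes so each stage can be validated against known
truth.

# Barcode design and the metadata codebook

A barcode is a randomized N15 region (about 1.07e9 sequences) adjacent to a
block of 10 fixed positions that encode campaign metadata. The nucleotide
layout of those 10 positions is an in-house convention in the original
workflow and is not published, so this package defines its own documented
codebook and treats it as a configuration artifact (`default_codebook()`,
JSON-serializable via `write_codebook()`): positional base-4 encoding with
A=0, C=1, G=2, T=3 and fixed field widths — year offset (2 nt, 16 years
from a base year), CLD campaign number (3 nt, 64 values), host cell line id
(2 nt, 16 values), molecule id (3 nt, 64 values). Encode and decode are
exact inverses over the whole tag space, and the all-A code is the codebook
origin. Users with a different in-house layout swap the codebook JSON;
nothing downstream depends on the field semantics.

`library_uniformity()` summarizes a sequenced plasmid library by its
abundance-weighted per-position nucleotide frequencies (each position sums
to 1) and by abundance dispersion (CV and Gini). A well-synthesized library
shows near-uniform composition and low dispersion.

# Read processing

Paired 2x150 amplicon reads are adapter-trimmed, merged by best overlap,
and scanned for the barcode between two known flank anchors.

* **Trimming** removes a full adapter occurrence or the longest 3' suffix
  matching an adapter prefix (minimum overlap 3 nt), qualities in lockstep.
* **Merging** scans every overlap length, keeps the one with the most
  matching bases (ties to the longer overlap), and accepts it when it is at
  least 10 nt with at most 25% mismatches; mismatched positions take the
  higher-quality base. Unmerged pairs are dropped and counted — rejection
  is a normal outcome, never silent.
* **Extraction** finds the left flank, then the right flank after it, and
  accepts the intervening sequence only if it is exactly 15 nt
  (`wrong_length` otherwise). Flank matching is exact by default because
  flank errors are rarer than barcode errors and exact matching keeps the
  error model simple; a per-flank mismatch allowance is available via
  `flank_spec(max_flank_mismatches=)`. If the flanks are not found, the
  reverse complement is searched; forward orientation wins when both match,
  and multiple left-flank hits in one orientation are rejected as
  `ambiguous_multiple_hits`. Three flank presets (M1/M2/M3) cover the three
  amplicon designs.

Accounting is conserved at every stage:
`total_reads_in = reads_extracted + sum(rejections by reason)`.

# Genuine-barcode calling

Sequencing errors scatter each true barcode into a cloud of low-count
neighbors. Calling proceeds in two steps.

**Error clustering** (`cluster_counts()`): barcodes are processed from the
smallest count upward; each is absorbed into the highest-count barcode
within Levenshtein distance 1 whose current count is at least 5x its own
(the 5:1 ratio is the default of the standard greedy message-passing
clusterers). Ties — equal counts during ordering, or equal parent counts —
break lexicographically by sequence, so the result is fully deterministic.
Total counts are conserved and the operation is idempotent. Neighbor search
uses a deletion-fingerprint index (two sequences within distance 1 must
share a one-deletion fingerprint; candidates are verified with an exact
distance computation), so tables with 1e5 barcodes cluster in seconds; on
tables up to 2,000 barcodes the result is tested to be identical to a
brute-force all-pairs search.

**Knee-point threshold** (`knee_point_threshold()`): on the curve of
(log10 rank, log10 count) with counts sorted in decreasing order, the knee
is the point of maximum perpendicular distance to the chord joining the
first and last points. The geometry needs one refinement that matters in
practice: the maximum-distance point can fall on either side of the chord.
A point *below* the chord is the start of the low-count error tail and its
count is the threshold; a point *above* the chord is the end of the genuine
plateau, and the threshold is then the count at the next rank (the first
tail point). Both conventions coincide on long error tails but the
distinction is essential for heavily clustered tables where only a handful
of points remain. Barcodes with counts *strictly above* the threshold are
genuine; ties at the threshold are not.

Two degenerate cases are flagged instead of thresholded, and the caller
(`call_genuine()`) keeps all barcodes with a warning: fewer than 3 distinct
count values, and curves whose maximum chord distance is below 0.05 log10
units (~12% departure). The second rule covers both a perfect power law
(no corner at all) and the flat plateau of an error-free or fully clustered
sample, where every remaining barcode is genuine and any "knee" inside the
plateau would be an artifact of multinomial noise.

`cross_contamination_report()` compares the genuine count against the
expected clone number (N = 1 for monoclonality checks, N = 2 for
cross-contamination screening) and reports each genuine barcode's read
fraction.

# Diversity estimation

* **Chao1** (`chao1()`): with `f1` singletons and `f2` doubletons, the
  bias-corrected form `S_obs + f1(f1-1) / (2(f2+1))` is the default because
  it stays defined at `f2 = 0`; the classic `S_obs + f1^2/(2 f2)` is behind
  a flag. Cross-checked in the test suite against `vegan::estimateR()`.
* **Resampled richness** (`resampled_richness()`): reads are drawn without
  replacement (multivariate hypergeometric) at each depth; observed and
  Chao1 richness are reported as mean +/- SD over replicates.
* **Collision probability** (`collision_probability()`): N barcodes are
  sampled without replacement from the pool with probability proportional
  to abundance; `p` is the fraction of sampled items unique within the
  sample and the collision probability is `1 - p`. On small uniform pools
  this converges to the closed form `1 - (1 - 1/D)^(N-1)`.
* **Trajectories** (`diversity_trajectory()`): genuine (knee-filtered)
  barcode counts per timepoint, retention of the first timepoint's genuine
  set, and the dominant clone's fraction.
* **RMCE efficiency** (`rmce_efficiency()`): genuine barcodes divided by
  transfected cells.

# The probability-of-clonality model

Limited dilution seeds wells at a Poisson mean of `lambda` cells per well
(0.6 in the reference campaign). The model combines three ingredients for
each possible cell count `k >= 2`:

1. Poisson occupancy `P_lambda(k) = lambda^k e^-lambda / k!`.
2. A worst-case barcode collision probability: every cell is treated as
   carrying the most frequent clone's probability `P0` (the maximum of the
   normalized barcode frequencies at the time of limited dilution), giving
   `P(>=2 identical | k) = 1 - (1 - P0)^k`. The product is written with
   `k` factors; a `k - 1`-factor birthday-type variant is available via
   `convention = "k_minus_1"` but the k-factor form is the default and the
   one used in validation.
3. The colony-outgrowth probability `G_k = a` for `k = 1` and
   `G_k = k a (1-a)^(k-1)` for `k > 1` — for multi-cell wells, the
   probability that exactly one cell recovers while the rest do not.

The recovery rate `a` is solved from plate-level statistics via
`N * sum_{k=1}^{100} P_mu(k) (1 - (1-a)^k) = W`, with `N` wells plated,
`W` wells grown and `mu` the seeding mean. The truncated sum telescopes to
`N (1 - e^{-mu a})`, so the bisection root (tolerance 1e-10 on the
bracket) agrees with the closed form `-log(1 - W/N)/mu` to well below
1e-10; the test suite verifies this across a grid of `mu` and `W/N`.
Infeasible inputs (`W >= N(1 - e^{-mu})`) raise an error rather than
returning a boundary value; `W = 0` returns 0 with a warning.

The collision probability is `sum_{k=2}^{k_max}` of the three factors
(k_max = 10 by default; higher counts are negligible at limiting dilution)
and the probability of clonality (PoC) is its complement. With the
reference plate statistics (7767 wells, 1552 grown, mean 0.6) the solver
gives `a = 0.372`, and a dominant clone at about 3% of the pool puts the
PoC just above 99.6%.

Two modeling subtleties are worth stating explicitly:

* The recovery-rate equation counts a well as grown when *any* cell
  recovers (`1 - (1-a)^k`), while `G_k` scores the *exactly-one-survivor*
  outcome. The package implements both as printed. Consequently the
  simulator's well model (`simulate_limited_dilution()`) defaults to the
  exactly-one-survivor rule to stay consistent with `G_k`, and offers
  `both_grow = TRUE` (growth when any cell recovers, all recovered
  barcodes persist), which is the mode that satisfies the analytic
  identity `W/N ~ 1 - e^{-lambda a}` and is therefore used when
  re-identifying `a` from simulated wells.
* PoC is monotone non-increasing in `P0` and in `lambda`, but in `a` only
  while `k a (1-a)^(k-1)` is increasing (up to `a ~ 0.44` at
  `lambda = 0.6`). At `a = 1` a multi-cell well can never produce the
  single outgrowing colony the model scores, so PoC returns to exactly 1.
  The tests assert monotonicity on the increasing branch and the `a = 1`
  limit separately.

# Lineage-aware screening

`classify_lineages()` splits a clone cohort by barcode multiplicity:
sibling groups (>= 3 occurrences by default), relatives (unique barcodes),
and an unclassified middle band (multiplicity 2) that belongs to neither
comparison set. `pairwise_difference_test()` pools all within-group
absolute pairwise differences across sibling groups, builds all pairwise
differences among relatives, and compares the two sets with a two-sided
Wilcoxon rank-sum test (exact for combined n <= 20, normal approximation
with continuity and tie correction otherwise, via `stats::wilcox.test`);
`fdr_adjust()` applies Benjamini-Hochberg across phenotypes. The pairwise
differences share clones and are therefore not independent; the procedure
is reproduced as defined, and under a true null the rank-sum p-values are
spread but not uniform (empirically ~25% fall below 0.05). The p-values
should be read as descriptive effect rankings, which is how they are used:
the signal of interest — lower sibling dispersion under a real lineage
effect — produces p-values orders of magnitude smaller.

`design_arms()` builds the two diversity-controlled screening arms: an
enrichment arm of 48 clones with 48 distinct barcodes and a depletion arm
of 48 clones from exactly 15 lineages (defaults match the reference
campaign; both configurable). The depletion lineages are the
most-multiplied barcodes (one clone from each, then random fill), the
enrichment arm draws one clone per barcode from the remainder; arms never
share a clone and are reproducible under a seed. `max_titer_curve()`
draws `n` titers without replacement per screening depth (3 replicates by
default, as in the reference analysis) and reports the mean and SD of the
subset maximum — the curve that shows how deep one must screen before the
best clone is likely included.

# The synthetic-data generator

The simulator emulates the CLD campaign stage by stage, with defaults set
to the study conditions: 4.5e6 transfected cells, an RMCE rate of 1e-3
(pre-selection founder pools in the 1e4 range), selection survival 0.3
(post- to pre-selection diversity ratio ~3.5), clone-intrinsic exponential
growth rates near 0.69/day (one doubling per day, a typical CHO rate) with
SD 0.05/day, passaging every 3.5 days, 0.1%/base substitution sequencing
error. Growth heterogeneity is modeled as fixed clone-intrinsic rates
because phenotypic diversity in this system is dominated by pre-existing,
integration-event-linked differences, not by ongoing stochastic drift.
Passage bottlenecks are multivariate-hypergeometric draws; growth between
passages is deterministic.

Amplicon reads are built as context + left flank + barcode + right flank +
context, with multinomial read counts, per-base substitution errors and
~50% of reads reverse-complemented. Substitutions are the only error type
by design: an indel inside the barcode would fail the fixed-length-15
filter rather than create a miscallable barcode, so substitutions are the
error class the calling stage actually has to separate. Errors are applied
by drawing a Binomial(read length, error rate) count per read and mutating
only affected reads, which keeps 1e6-read simulations fast.
`simulate_merged_reads()` emits merged reads directly (the pipeline merges
before extraction, so tests exercise extraction onward);
`simulate_read_files()` writes genuine paired FASTQ files for the full
trim-merge-extract path.

What the generator does *not* emulate: PCR amplification bias and
chimeras, quality-score degradation along the read, library synthesis
biases, and molecule-specific selection kinetics. A rare-indel mode
(`indel_rate`) exists for robustness testing — it confirms that in-read
indels are shed by the length filter rather than miscalled. Passing tests
therefore demonstrate correctness of the analysis logic under a clean
substitution-error model, not robustness to every artifact of real
sequencing runs.

# Problem sizes and reproducibility

Every stochastic function takes an explicit seed and is byte-reproducible
under it. The validation suite runs the mixture-sensitivity check (two
clones at 1:10, 1:100, 1:1000) at 1e6 reads x 20 replicates per ratio, the
defined-pool checks (3/5/17 clones) at 1e5 reads x 20 replicates, and the
recovery-rate re-identification at 1e5 wells; these sizes give binomial
error bars comfortably inside the asserted margins while keeping the whole
suite in the minutes range. Chao1 subsampling checks use 500 true variants
at 10% depth over 20 replicates.

# Known limitations

* The metadata codebook is this package's own convention; decoded fields
  from libraries built with a different codebook are meaningless until the
  matching JSON is supplied.
* Knee-point calling assumes a rank-count curve with a plateau/tail
  structure; samples whose genuine clones span several orders of magnitude
  of abundance can place the knee inside the genuine range. The 1:1000
  mixture tests bound how far this can be pushed at realistic error rates.
* The PoC model is a worst-case bound (every cell gets the dominant
  clone's frequency) and inherits the printed exactly-one-survivor
  outgrowth term; see the clonality section for where that makes its
  behavior non-obvious.
* Rank-sum p-values on pooled pairwise differences are descriptive, not
  calibrated tests (dependence between pairs).
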