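# Composition: gene assignment, normalization, Welch test, coverage.

paired_fragment <- function(fragment, reference, start, end, sense,
                            sample = "s1", read_length = 100L) {
  r <- min(read_length, end - start)
  m2_start <- if (sense == "+") start else end - r
  m1_start <- if (sense == "+") end - r else start
  aligned_reads(
    read_id = paste0(fragment, c("/1", "/2")),
    fragment_id = fragment, mate = c(1L, 2L), reference = reference,
    start = c(m1_start, m2_start), end = c(m1_start + r, m2_start + r),
    strand = c(if (sense == "+") "-" else "+", sense), sample = sample)
}

test_that("fragments are assigned strand-aware at gene level", {
  ref <- toy_reference()
  rd <- rbind(
    paired_fragment("f1", "bee1", 200L, 500L, "+"),    # inside pc1 (+)
    paired_fragment("f2", "bee1", 200L, 500L, "-"),    # antisense to pc1
    paired_fragment("f3", "bee1", 4200L, 4500L, "+"),  # gap -> Other
    paired_fragment("f4", "bee1", 1550L, 2050L, "-"))  # trna1(-) & mir1(+)
  class(rd) <- c("aligned_reads", "data.frame")
  cm <- assign_reads_to_genes(rd, ref)
  expect_identical(cm["pc1", "s1"], 1L)   # only the sense fragment
  expect_identical(cm["trna1", "s1"], 1L) # f4: sole sense-eligible gene
  expect_identical(sum(cm), 2L)
  expect_identical(unname(attr(cm, "other")["s1"]), 2L)  # f2 + f3
})

test_that("sense-filtering precedes the ambiguity rule", {
  ref <- toy_reference()
  # fragment spanning trna1 (-) and mir1 (+): only one sense-eligible gene
  rd <- paired_fragment("f1", "bee1", 1550L, 2050L, "-")
  cm <- assign_reads_to_genes(rd, ref)
  expect_identical(cm["trna1", "s1"], 1L)
  expect_identical(unname(attr(cm, "ambiguous")["s1"]), 0L)

  # two sense-eligible genes -> ambiguous, dropped
  feats <- gene_features(c("gA", "gB"), "chr", c(0L, 150L), c(200L, 400L),
                         c("+", "+"), c("protein_coding", "protein_coding"))
  ref2 <- annotated_reference(
    c(chr = strrep("A", 500)), feats, c(chr = "apis"))
  rd2 <- paired_fragment("f1", "chr", 100L, 300L, "+")
  cm2 <- assign_reads_to_genes(rd2, ref2)
  expect_identical(sum(cm2), 0L)
  expect_identical(unname(attr(cm2, "ambiguous")["s1"]), 1L)
})

test_that("mean-ratio size factors follow total counts and average to 1", {
  totals <- c(s1 = 100, s2 = 300, s3 = 200)
  expect_equal(unname(size_factors_mean_ratio(totals)),
               c(0.5, 1.5, 1.0))
  m <- matrix(c(50, 50, 150, 150, 100, 100), 2, 3,
              dimnames = list(NULL, names(totals)))
  expect_equal(unname(size_factors_mean_ratio(m)), c(0.5, 1.5, 1.0))
  expect_equal(unname(size_factors_mean_ratio(c(a = 7, b = 7))), c(1, 1))
  set.seed(8)
  r <- matrix(rpois(40, 30) + 1, 8, 5,
              dimnames = list(NULL, letters[1:5]))
  expect_equal(mean(size_factors_mean_ratio(r)), 1)
  expect_error(size_factors_mean_ratio(c(a = 0, b = 10)), "zero total")
})

test_that("composition summary filters sub-threshold groups, keeps full", {
  counts <- matrix(c(990, 5, 5, 980, 8, 12), 3, 2,
                   dimnames = list(c("apis/protein_coding", "apis/tRNA",
                                     "vdv1/NA"), c("s1", "s2")))
  comp <- summarize_composition(counts, min_fraction = 0.01)
  expect_false("apis/tRNA" %in% rownames(comp$fractions))  # < 1% everywhere
  expect_true("vdv1/NA" %in% rownames(comp$fractions))     # 1.2% in s2
  full <- attr(comp, "full_fractions")
  expect_true("apis/tRNA" %in% rownames(full))
  # fractions sum to 1 per sample before filtering
  expect_equal(unname(colSums(full)), c(1, 1))
  # normalization preserves within-sample rank order
  expect_identical(order(comp$normalized[, 1]), order(counts[, 1]))
})

test_that("Welch test reproduces the textbook statistic", {
  wt <- welch_t_test(c(1, 2, 3), c(2, 4, 6))
  # means 2 and 4, variances 1 and 4: t = -2 / sqrt(1/3 + 4/3)
  expect_equal(wt$t, -2 / sqrt(5 / 3), tolerance = 1e-6)
  expect_equal(wt$df, (5 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2),
               tolerance = 1e-3)
  expect_equal(wt$p, 2 * stats::pt(wt$t, wt$df), tolerance = 1e-9)

  # identical groups
  wt0 <- welch_t_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(wt0$t, 0)
  expect_equal(wt0$p, 1)

  # antisymmetry
  a <- c(0.3, 1.1, 2.2); b <- c(4, 4.5, 9)
  expect_equal(welch_t_test(a, b)$t, -welch_t_test(b, a)$t)
  expect_equal(welch_t_test(a, b)$p, welch_t_test(b, a)$p)

  expect_error(welch_t_test(c(1, 1), c(2, 2)), "zero variance")
})

test_that("species enrichment is detected only where planted", {
  ref <- make_reference(13, bee_length = 30000,
                        viral_lengths = c(vdv1 = 5000))
  cfg <- sim_config(
    seed = 14, n_fragments = 400,
    species_mix = list(total_rj = c(apis = 0.97, vdv1 = 0.03),
                       mrjp3_bound = c(apis = 0.55, vdv1 = 0.45)))
  reads <- simulate_fragments(ref, cfg)
  cc <- composition_counts(reads, ref)
  grp <- stats::setNames(cfg$samples$group, cfg$samples$sample_id)
  comp <- summarize_composition(cc, group_of_sample = grp)
  rep <- enrichment_report(comp, "apis", "vdv1")
  expect_setequal(rep$fraction, c("total_rj", "mrjp3_bound"))
  expect_true(rep$significant[rep$fraction == "mrjp3_bound"])
  # bee dominates the total fraction overwhelmingly, so that test is
  # significant in the OPPOSITE sense; what distinguishes the fractions is
  # the sign of t (bee >> virus in total; bound fraction is virus-rich)
  expect_gt(rep$t[rep$fraction == "total_rj"],
            rep$t[rep$fraction == "mrjp3_bound"])

  # fewer than 2 replicates: warned and skipped
  comp2 <- comp
  comp2$group_of_sample <- stats::setNames(
    c("total_rj", "total_rj", "total_rj", "total_rj", "lone"),
    names(grp))
  expect_warning(enrichment_report(comp2, "apis", "vdv1"), "replicates")
})

test_that("strand coverage counts depth per base and conserves mass", {
  rd <- data.frame(reference = "r", start = c(0L, 1L), end = c(3L, 4L),
                   strand = "+")
  cov <- strand_coverage(rd, "r", 6L)
  expect_equal(cov$plus, c(1, 2, 2, 1, 0, 0))
  expect_equal(cov$minus, rep(0, 6))
  expect_equal(strand_coverage(rd, "r", 6L, "log10p1")$plus,
               log10(c(1, 2, 2, 1, 0, 0) + 1))
  # empty -> all zero; log10p1 of zero is zero
  none <- strand_coverage(rd[0, ], "r", 5L, "log10p1")
  expect_equal(none$plus, rep(0, 5))

  # conservation: sum of depth equals sum of read lengths per strand
  set.seed(5)
  n <- 200
  st <- sample.int(900, n, replace = TRUE)
  rd2 <- data.frame(reference = "r", start = st,
                    end = st + sample(20:100, n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE))
  rd2$end <- pmin(rd2$end, 1000L)
  cov2 <- strand_coverage(rd2, "r", 1000L)
  expect_equal(sum(cov2$plus),
               sum((rd2$end - rd2$start)[rd2$strand == "+"]))
  expect_equal(sum(cov2$minus),
               sum((rd2$end - rd2$start)[rd2$strand == "-"]))
})
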