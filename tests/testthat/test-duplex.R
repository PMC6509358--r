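# Duplex screen: overlap/overhang rule, oracle equivalence, dedup,
# classification, counting, normalization.

test_that("overlap/overhang rule matches worked geometry", {
  params <- screen_params()
  # [0,100)+ vs [60,160)-: overlap [60,100) = 40 nt, overhangs 60/60
  rd <- interval_reads(c(0L, 60L), c(100L, 160L), c("+", "-"))
  cand <- call_duplexes(rd, params)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$overlap_start, 60L)
  expect_identical(cand$overlap_end, 100L)
  expect_identical(cand$overlap_len, 40L)
  expect_identical(cand$left_overhang, 60L)
  expect_identical(cand$right_overhang, 60L)
  expect_identical(cand$union_start, 0L)
  expect_identical(cand$union_end, 160L)

  # left overhang 150 > 100: rejected despite a 50 nt overlap
  rd2 <- interval_reads(c(0L, 150L), c(200L, 400L), c("+", "-"))
  expect_identical(nrow(call_duplexes(rd2, params)), 0L)

  # overlap 24 < 25: rejected
  rd3 <- interval_reads(c(0L, 76L), c(100L, 176L), c("+", "-"))
  expect_identical(nrow(call_duplexes(rd3, params)), 0L)
  expect_identical(nrow(call_duplexes(
    rd3, screen_params(min_overlap = 24))), 1L)
})

test_that("mates are excluded as one molecule unless disabled", {
  rd <- aligned_reads(
    read_id = c("f1/1", "f1/2"), fragment_id = "f1", mate = c(1L, 2L),
    reference = "bee1", start = c(0L, 50L), end = c(100L, 150L),
    strand = c("+", "-"), sample = "s1")
  expect_identical(nrow(call_duplexes(rd, screen_params())), 0L)
  expect_identical(
    nrow(call_duplexes(rd, screen_params(exclude_mates = FALSE))), 1L)
})

test_that("pairs never cross samples or references", {
  rd <- rbind(
    interval_reads(0L, 100L, "+", sample = "s1", fragment = "a"),
    interval_reads(50L, 150L, "-", sample = "s2", fragment = "b"),
    interval_reads(50L, 150L, "-", reference = "vdv1", sample = "s1",
                   fragment = "c"))
  class(rd) <- c("aligned_reads", "data.frame")
  expect_identical(nrow(call_duplexes(rd, screen_params())), 0L)
})

test_that("interval-join caller equals the all-pairs oracle", {
  params <- screen_params()
  set.seed(123)
  for (rep in 1:20) {
    n <- sample(50:200, 1)
    rd <- interval_reads(
      start = st <- sample.int(3000, n, replace = TRUE),
      end = st + sample(30:150, n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      reference = sample(c("r1", "r2"), n, replace = TRUE),
      sample = sample(c("s1", "s2"), n, replace = TRUE))
    got <- call_duplexes(rd, params)
    want <- brute_force_duplexes(rd, params)
    expect_identical(candidate_key(got), candidate_key(want))
  }
})

test_that("mirroring coordinates yields mirrored candidates", {
  set.seed(7)
  L <- 5000L
  n <- 120
  st <- sample.int(4000, n, replace = TRUE)
  en <- st + sample(40:140, n, replace = TRUE)
  sd <- sample(c("+", "-"), n, replace = TRUE)
  rd <- interval_reads(st, en, sd)
  mirrored <- interval_reads(L - en, L - st,
                             ifelse(sd == "+", "-", "+"))
  a <- call_duplexes(rd, screen_params())
  b <- call_duplexes(mirrored, screen_params())
  expect_identical(nrow(a), nrow(b))
  expect_identical(sort(L - a$overlap_end), sort(b$overlap_start))
  expect_identical(sort(a$overlap_len), sort(b$overlap_len))
})

test_that("fragment unit requires paired reads", {
  rd <- interval_reads(c(0L, 60L), c(100L, 160L), c("+", "-"))
  expect_error(call_duplexes(rd, screen_params(unit = "fragment")),
               "merge")
})

test_that("deduplication groups by overlap key and classifies loci", {
  ref <- toy_reference()
  # two candidate pairs with the same overlap interval inside the tRNA gene
  rd <- interval_reads(
    start = c(1480L, 1500L, 1480L, 1500L),
    end = c(1560L, 1580L, 1560L, 1580L),
    strand = c("+", "-", "+", "-"),
    fragment = c("a", "b", "c", "d"))
  cand <- call_duplexes(rd, screen_params())
  # a-b, a-d, c-b, c-d all share overlap [1500, 1560)
  uq <- dedupe_and_classify(cand, ref)
  expect_identical(nrow(uq), 1L)
  expect_identical(uq$support, 4L)
  expect_identical(uq$length, 60L)
  expect_identical(uq$biotype_class, "tRNA")
  expect_identical(uq$assigned_genes[[1]], "trna1")

  # overlap spanning a gene boundary is assigned by any positional overlap
  rd2 <- interval_reads(c(1050L, 1060L), c(1150L, 1160L), c("+", "-"))
  uq2 <- dedupe_and_classify(call_duplexes(rd2, screen_params()), ref)
  expect_identical(uq2$assigned_genes[[1]], "pc1")
  expect_identical(uq2$biotype_class, "protein_coding")

  # overlap in a gap is unannotated
  rd3 <- interval_reads(c(4100L, 4120L), c(4200L, 4220L), c("+", "-"))
  uq3 <- dedupe_and_classify(call_duplexes(rd3, screen_params()), ref)
  expect_identical(uq3$biotype_class, "unannotated")
  expect_identical(length(uq3$assigned_genes[[1]]), 0L)

  # union keying distinguishes what overlap keying merges: two forward
  # reads ending at the same position against one reverse read share the
  # overlap interval but not the union interval
  rd4 <- interval_reads(
    start = c(100L, 120L, 150L), end = c(200L, 200L, 250L),
    strand = c("+", "+", "-"), fragment = c("u", "w", "v"))
  cand4 <- call_duplexes(rd4, screen_params())
  expect_identical(nrow(cand4), 2L)
  expect_identical(nrow(dedupe_and_classify(cand4, ref)), 1L)
  expect_identical(dedupe_and_classify(cand4, ref)$support, 2L)
  expect_identical(nrow(dedupe_and_classify(cand4, ref, key = "union")),
                   2L)
})

test_that("length histogram bins counts and conserves the total", {
  expect_identical(nrow(length_distribution(
    dedupe_and_classify(call_duplexes(interval_reads(integer(0), integer(0),
                                                     character(0))),
                        toy_reference()))), 0L)
  uq <- data.frame(length = c(30L, 30L, 90L))
  h <- length_distribution(uq, bin_width = 50)
  expect_identical(h$count, c(2L, 1L))
  expect_identical(h$bin_start, c(0L, 50L))
  for (bw in c(1, 7, 25, 100))
    expect_identical(sum(length_distribution(uq, bw)$count), 3L)
  expect_error(length_distribution(uq, 0), "bin_width")
})

test_that("per-gene duplex counting increments every overlapped gene", {
  ref <- toy_reference()
  rd <- rbind(
    # one duplex inside pc1 in sample s1
    interval_reads(c(200L, 220L), c(300L, 320L), c("+", "-"),
                   sample = "s1", fragment = c("a", "b")),
    # one duplex spanning trna1 and mir1 region boundary in s2: overlap
    # [1990, 2070) intersects trna1? no - trna1 ends 1580; use pc2/mir1:
    # overlap [2080, 2160) hits mir1 (2000-2100) and pc2 (2500-)? no.
    interval_reads(c(2080L, 2090L), c(2160L, 2170L), c("+", "-"),
                   sample = "s2", fragment = c("c", "d")))
  class(rd) <- c("aligned_reads", "data.frame")
  uq <- dedupe_and_classify(call_duplexes(rd, screen_params()), ref)
  cm <- count_duplexes_per_gene(uq, samples = c("s1", "s2"))
  expect_identical(cm["pc1", "s1"], 1L)
  expect_identical(sum(cm[, "s1"]), 1L)
  expect_identical(cm["mir1", "s2"], 1L)

  # a duplex overlapping two genes increments both rows
  ref2 <- toy_reference()
  rd2 <- interval_reads(c(1560L, 1570L), c(2060L, 2070L), c("+", "-"),
                        sample = "s1", fragment = c("e", "f"))
  uq2 <- dedupe_and_classify(
    call_duplexes(rd2, screen_params(max_overhang = 600)), ref2)
  expect_setequal(uq2$assigned_genes[[1]], c("trna1", "mir1"))
  cm2 <- count_duplexes_per_gene(uq2)
  expect_identical(sum(cm2), 2L)  # one duplex, two gene rows
})

test_that("median-of-ratios size factors reproduce the worked example", {
  counts <- matrix(c(10, 20, 20, 40), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- size_factors_median_ratio(counts)
  # geometric means sqrt(200), sqrt(800); ratios 10/14.142 and 20/28.284
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)

  # identical samples -> unit factors
  m <- matrix(rep(c(3, 8, 1), 3), 3, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(size_factors_median_ratio(m)), rep(1, 3))

  # scaling one sample scales its factor proportionally
  set.seed(4)
  m2 <- matrix(rpois(30, 20) + 1, 10, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  sf1 <- size_factors_median_ratio(m2)
  m3 <- m2
  m3[, 2] <- m3[, 2] * 5
  sf2 <- size_factors_median_ratio(m3)
  expect_equal(unname(sf2[2] / sf1[2]), 5 * unname(sf2[1] / sf1[1]),
               tolerance = 1e-9)
  expect_equal(unname(sf2[2] / sf1[2]), 5 * unname(sf2[3] / sf1[3]),
               tolerance = 1e-9)

  # every gene touching zero somewhere -> informative error
  z <- matrix(c(0, 5, 3, 0), 2, 2)
  expect_error(size_factors_median_ratio(z), "mean-ratio")
})

test_that("median-of-ratios agrees with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  counts <- matrix(rpois(200, 50) + 1, 50, 4,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%d", 1:4)))
  expect_equal(unname(size_factors_median_ratio(counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-8)
})
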