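# Base-coverage enrichment with the shuffled-location null.

test_that("covered_bases agrees with per-base enumeration", {
  reads <- gr1(0, 50)
  cat_ <- gr1(25, 100)
  expect_equal(covered_bases(reads, cat_), 25)
  expect_equal(covered_bases(gr1(0, 10), gr1(500, 600)), 0)
  r <- gr1(c(0, 200, 300), c(40, 240, 320))  # 100 distinct bases
  expect_equal(covered_bases(r, gr1(0, 1000)), 100)

  # random cases vs the brute-force mask oracle, with internal overlaps
  set.seed(9)
  for (i in 1:25) {
    rs <- sample(0:900, 12, replace = TRUE)
    re <- rs + sample(5:80, 12, replace = TRUE)
    cs <- sample(0:900, 6, replace = TRUE)
    ce <- cs + sample(5:150, 6, replace = TRUE)
    got <- covered_bases(gr1(rs, pmin(re, 1000)), gr1(cs, pmin(ce, 1000)))
    want <- sum(base_mask(rs, pmin(re, 1000), 1000) &
                  base_mask(cs, pmin(ce, 1000), 1000))
    expect_equal(got, want)
  }
})

test_that("shuffling preserves lengths, respects bounds and the seed", {
  genome <- c(chr1 = 1000)
  iv <- gr1(c(0, 300), c(100, 450))
  s1 <- shuffle_category(iv, genome, seed = 4)
  s2 <- shuffle_category(iv, genome, seed = 4)
  expect_identical(plateletTx:::.gr0(s1), plateletTx:::.gr0(s2))
  expect_equal(GenomicRanges::width(s1), GenomicRanges::width(iv))
  expect_true(all(GenomicRanges::end(s1) <= 1000 &
                    GenomicRanges::start(s1) >= 1))

  # interval as long as the chromosome has a single forced placement
  forced <- shuffle_category(gr1(0, 1000), genome, seed = 1)
  expect_equal(plateletTx:::.gr0(forced)[, c("start", "end")],
               data.frame(start = 0, end = 1000))
  expect_error(shuffle_category(gr1(0, 1001 - 1), c(chr1 = 500)), "longer")

  # uniform placement: mean start of a 100-base interval on 1000 bases ~ 450
  set.seed(8)
  starts <- replicate(4000, GenomicRanges::start(
    shuffle_category(gr1(0, 100), genome)) - 1)
  expect_lt(abs(mean(starts) - 450), 3 * 260 / sqrt(4000) + 5)
})

test_that("enrichment saturates at fold 1 when the category is the genome", {
  set.seed(2)
  rs <- sample(0:950, 200, replace = TRUE)
  reads <- gr1(rs, rs + 30)
  res <- enrichment_test(reads, gr1(0, 1000), c(chr1 = 1000),
                         n_shuffles = 200, seed = 3)
  expect_equal(res$fold, 1.0)
  expect_gt(res$p_value, 0.5)
  expect_false(res$significant)
})

test_that("a fully planted category recovers the analytic fold", {
  # toy genome of 1000 bases; all reads inside the 100-base category, which
  # they cover completely.  Exact null expectation for a width-100 interval
  # uniform on integer starts 0..900 against covered bases [0,100):
  # sum_{k=1..100} k / 901 = 5050/901
  reads <- gr1(seq(0, 80, 20), seq(20, 100, 20))
  res <- enrichment_test(reads, gr1(0, 100), c(chr1 = 1000),
                         n_shuffles = 2000, seed = 6)
  e_exact <- 5050 / 901
  expect_equal(res$observed_bases, 100)
  expect_lt(abs(res$expected_bases - e_exact), 1.5)
  expect_lt(abs(res$fold - 100 / e_exact), 5)
  expect_true(res$significant)

  # with category pieces far smaller than the chromosome, edge effects
  # vanish and the length-share approximation observed/(B * f) holds
  starts <- seq(0, 9500, 500)           # 20 x 10-base pieces, f = 0.02
  cat_small <- gr1(starts, starts + 10)
  rs <- rep(starts[1:10], each = 20)    # reads concentrated on 10 pieces
  reads2 <- gr1(rs, rs + 10)
  res2 <- enrichment_test(reads2, cat_small, c(chr1 = 1e4),
                          n_shuffles = 2000, seed = 7)
  B <- covered_bases(reads2, gr1(0, 1e4))
  approx_expected <- B * (200 / 1e4)
  expect_lt(abs(res2$expected_bases - approx_expected) / approx_expected,
            0.15)
})

test_that("the empirical p-value is (b+1)/(n+1)", {
  # 50 two-base read blocks; the category sits exactly on them, so no
  # shuffle can match the observed coverage and b = 0
  starts <- seq(0, 9800, length.out = 50)
  reads <- gr1(starts, starts + 2)
  res <- enrichment_test(reads, gr1(starts, starts + 2), c(chr1 = 1e4),
                         n_shuffles = 1000, seed = 1)
  expect_equal(res$observed_bases, 100)
  expect_equal(res$p_value, 1 / 1001)
  expect_true(res$significant)
})

test_that("identical seeds give identical results and folds are monotone", {
  set.seed(5)
  rs <- sample(0:900, 100, replace = TRUE)
  reads <- gr1(rs, rs + 25)
  cat_ <- gr1(c(100, 600), c(250, 700))
  a <- enrichment_test(reads, cat_, c(chr1 = 1000), n_shuffles = 300, seed = 9)
  b <- enrichment_test(reads, cat_, c(chr1 = 1000), n_shuffles = 300, seed = 9)
  expect_identical(a, b)

  # moving reads into the category (same read count/lengths) never lowers fold
  inside <- gr1(rep(c(100, 600), 50), rep(c(125, 625), 50))
  hi <- enrichment_test(inside, cat_, c(chr1 = 1000), n_shuffles = 300,
                        seed = 9)
  expect_gte(hi$fold, a$fold)
})

test_that("enrichment_table covers requested categories deterministically", {
  b <- make_genome(cohort_config(n_genes = 30, n_pseudogenes = 8,
                                 n_lncRNA = 5, n_repeats_per_class = 3,
                                 reads_per_sample = 3000, seed = 12))
  cfg <- cohort_config(n_genes = 30, n_pseudogenes = 8, n_lncRNA = 5,
                       n_repeats_per_class = 3, reads_per_sample = 3000,
                       n_individuals = 2, groups = c("W", "B"), seed = 12)
  reads <- simulate_read_sets(b, cfg)[[1]]
  et1 <- enrichment_table(reads, b, categories = c("rRNA", "LINE"),
                          n_shuffles = 200, seed = 31)
  et2 <- enrichment_table(reads, b, categories = c("rRNA", "LINE"),
                          n_shuffles = 200, seed = 31)
  expect_identical(et1, et2)
  expect_equal(et1$category, c("rRNA", "LINE"))
  # rRNA receives ~37% of reads on a small length share: strongly enriched
  expect_gt(et1$fold[1], 1.5)
  expect_true(et1$significant[1])
})
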