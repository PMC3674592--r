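test_that("allele frequencies count the counted allele among called genotypes", {
  d <- cbind(c(0L, 1L, 1L, 2L), c(0L, 0L, NA, 0L), c(NA, NA, NA, NA))
  g <- make_geno(d, c("case", "control", "control", "control"))
  f <- allele_frequencies(g)
  expect_equal(f$frequency, c(0.5, 0, NA))
  expect_equal(f$n_called, c(4L, 3L, 0L))
})

test_that("cohort filtering selects the named cohort and rejects absent labels", {
  g <- dplyr::bind_rows(
    make_geno(matrix(2L, 2, 1), "control", cohort = "a",
              sample_ids = c("a1", "a2")),
    make_geno(matrix(0L, 2, 1), "control", cohort = "b",
              sample_ids = c("b1", "b2"))
  )
  expect_equal(allele_frequencies(g, "a")$frequency, 1)
  expect_equal(allele_frequencies(g, "b")$frequency, 0)
  expect_equal(allele_frequencies(g, "all")$frequency, 0.5)
  expect_error(allele_frequencies(g, "c"), "not present")
})

test_that("minor allele designation is relative to the reference with a 0.5 tie-break", {
  ref <- tibble::tibble(
    cohort = "uk", snp_id = c("rs1", "rs2", "rs3"),
    counted_allele = c("G", "G", "A"), other_allele = c("A", "A", "G"),
    frequency = c(0.44, 0.93, 0.5), n_called = 100L
  )
  map <- minor_allele_map(ref)
  expect_equal(map$minor_is_counted, c(TRUE, FALSE, TRUE))
  expect_equal(map$minor_allele, c("G", "A", "A"))
  ref$frequency[2] <- NA
  expect_error(minor_allele_map(ref), "undefined.*rs2")
})

test_that("alignment re-expresses other cohorts on the reference minor allele", {
  ref <- tibble::tibble(cohort = "uk", snp_id = c("rs1", "rs2"),
                        counted_allele = "G", other_allele = "A",
                        frequency = c(0.44, 0.93), n_called = 100L)
  other <- tibble::tibble(cohort = "africa", snp_id = c("rs1", "rs2"),
                          counted_allele = "G", other_allele = "A",
                          frequency = c(0.93, 0.80), n_called = 80L)
  al <- align_minor_frequencies(ref, other)
  # rs1: G minor in reference, so maf_africa may exceed 0.5 by construction
  expect_equal(al$maf_uk, c(0.44, 1 - 0.93))
  expect_equal(al$maf_africa, c(0.93, 1 - 0.80))
})

test_that("MAF correlation matches hand-computed Pearson values", {
  expect_equal(maf_correlation(c(0.1, 0.2, 0.3), c(0.1, 0.3, 0.2))$r, 0.5,
               tolerance = 1e-12)
  expect_equal(maf_correlation(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1))$r, -1,
               tolerance = 1e-12)
  a <- c(0.1, 0.25, 0.3, 0.42)
  expect_equal(maf_correlation(a, a)$r, 1, tolerance = 1e-12)
  expect_error(maf_correlation(a, rep(0.2, 4)), "constant")
  expect_error(maf_correlation(a, a[1:3]), "equal length")
})

test_that("MAF correlation is symmetric, affine-invariant, and lm-consistent", {
  set.seed(5)
  a <- runif(10, 0.05, 0.45)
  b <- runif(10, 0.05, 0.45)
  expect_equal(maf_correlation(a, b), maf_correlation(b, a))
  expect_equal(maf_correlation(a, b)$r,
               maf_correlation(a, 0.3 + 0.2 * b)$r, tolerance = 1e-12)
  # p equals the regression-slope t-test p-value
  lm_p <- summary(lm(b ~ a))$coefficients["a", "Pr(>|t|)"]
  expect_equal(maf_correlation(a, b)$p, lm_p, tolerance = 1e-10)
})

test_that("MAF difference bins use a strict lower cutoff and partition the panel", {
  bins <- maf_difference_bins(c(0.10, 0.40, 0.45), c(0.15, 0.15, 0.90))
  expect_equal(unlist(bins), c(n_below_low = 1, n_between = 0,
                               n_above_high = 2))
  same <- maf_difference_bins(rep(0.3, 7), rep(0.3, 7))
  expect_equal(same$n_below_low, 7)
  # a difference of exactly 0.10 falls in the middle bin
  edge <- maf_difference_bins(0.30, 0.40)
  expect_equal(edge$n_between, 1)
})

test_that("pooling concatenates cohorts on the SNP intersection", {
  a <- make_geno(matrix(c(0L, 1L, 2L, 0L, 1L, 2L), 2, 3), "case",
                 cohort = "a", sample_ids = c("a1", "a2"),
                 snp_ids = c("rs1", "rs2", "rs3"))
  b <- make_geno(matrix(c(2L, 2L, 0L, 0L), 2, 2), "control",
                 cohort = "b", sample_ids = c("b1", "b2"),
                 snp_ids = c("rs2", "rs3"))
  pooled <- pool_cohorts(list(a, b))
  expect_equal(sort(unique(pooled$snp_id)), c("rs2", "rs3"))
  expect_equal(dplyr::n_distinct(pooled$sample_id), 4)
  # identity element
  expect_equal(pool_cohorts(list(a, a[0, ])), a)
  # disjoint SNP sets cannot pool
  c_tbl <- make_geno(matrix(0L, 1, 1), "control", cohort = "c",
                     sample_ids = "c1", snp_ids = "rs9")
  expect_error(pool_cohorts(list(a, c_tbl)), "shared")
})

test_that("colliding sample ids are disambiguated by cohort prefix", {
  a <- make_geno(matrix(1L, 1, 1), "case", cohort = "a", sample_ids = "s1",
                 snp_ids = "rs1")
  b <- make_geno(matrix(2L, 1, 1), "control", cohort = "b",
                 sample_ids = "s1", snp_ids = "rs1")
  pooled <- pool_cohorts(list(a, b))
  expect_setequal(unique(pooled$sample_id), c("a:s1", "b:s1"))
})

test_that("pooled frequency is the n_called-weighted mean of cohort frequencies", {
  set.seed(9)
  for (i in 1:5) {
    a <- make_geno(matrix(sample(c(0:2, NA), 30, TRUE), 10, 3), "control",
                   cohort = "a", sample_ids = sprintf("a%02d", 1:10))
    b <- make_geno(matrix(sample(c(0:2, NA), 15, TRUE), 5, 3), "control",
                   cohort = "b", sample_ids = sprintf("b%02d", 1:5))
    fa <- allele_frequencies(a)
    fb <- allele_frequencies(b)
    fp <- allele_frequencies(pool_cohorts(list(a, b)))
    manual <- (fa$frequency * fa$n_called + fb$frequency * fb$n_called) /
      (fa$n_called + fb$n_called)
    expect_equal(fp$frequency, manual, tolerance = 1e-12)
  }
})

test_that("panel assembly keeps only SNPs genotyped in every dataset", {
  panel <- make_panel(sprintf("rs%d", 1:5), rep(0.1, 5))
  avail <- tidyr::expand_grid(snp_id = panel$snp_id,
                              dataset = c("d1", "d2", "d3")) |>
    dplyr::mutate(status = "genotyped")
  expect_equal(intersect_panel(panel, avail), panel)
  avail$status[avail$snp_id == "rs2" & avail$dataset == "d2"] <- "failed"
  avail$status[avail$snp_id == "rs4" & avail$dataset == "d3"] <- "unavailable"
  kept <- intersect_panel(panel, avail)
  expect_equal(kept$snp_id, c("rs1", "rs3", "rs5"))
  expect_error(intersect_panel(panel, avail[-1, ]), "no availability status")
})

test_that("two same-population samples of 120 individuals give concordant MAFs", {
  set.seed(123)
  n_rep <- 200
  hits <- 0
  for (i in seq_len(n_rep)) {
    freqs <- runif(28, 0.05, 0.45)
    fa <- colMeans(matrix(rbinom(120 * 28, 2, rep(freqs, each = 120)),
                          120, 28)) / 2
    fb <- colMeans(matrix(rbinom(120 * 28, 2, rep(freqs, each = 120)),
                          120, 28)) / 2
    if (maf_correlation(fa, fb)$r > 0.9) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})
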