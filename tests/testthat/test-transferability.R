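test_that("subsample draws are stratified, exact-sized and seed-reproducible", {
  set.seed(17)
  d <- matrix(sample(0:2, 30 * 4, TRUE), 30, 4)
  g <- make_geno(d, rep(c("case", "control", "control"), 10))
  sub <- draw_subsample(g, 5, 8, seed = 99)
  info <- sample_info(sub)
  expect_equal(sum(info$phenotype == "case"), 5)
  expect_equal(sum(info$phenotype == "control"), 8)
  expect_equal(draw_subsample(g, 5, 8, seed = 99), sub)
  expect_false(identical(draw_subsample(g, 5, 8, seed = 100), sub))
  # the full cohort is recovered as a set
  all_of_it <- draw_subsample(g, 10, 20, seed = 1)
  expect_setequal(unique(all_of_it$sample_id), unique(g$sample_id))
  expect_error(draw_subsample(g, 11, 5, seed = 1), "only 10 available")
})

test_that("the empirical null is deterministic under a fixed seed", {
  cfg <- simulation_config(n_snps = 6, freq_ref = rep(0.3, 6),
                           weights_gen = rep(0.2, 6), intercept = -2,
                           n_case = 60, n_control = 120, seed = 5)
  g <- simulate_cohort(cfg, "reference", seed = 5)
  panel <- simulation_panel(cfg)
  n1 <- null_or_distribution(g, panel, 15, 30, B = 5, seed = 7)
  n2 <- null_or_distribution(g, panel, 15, 30, B = 5, seed = 7)
  expect_equal(n1$or_samples, n2$or_samples)
  # growing B keeps the earlier draws
  n3 <- null_or_distribution(g, panel, 15, 30, B = 8, seed = 7)
  expect_equal(n3$or_samples[1:5], n1$or_samples)
})

test_that("the resampling loop reproduces the public GRS + logistic path", {
  cfg <- simulation_config(n_snps = 6, freq_ref = rep(0.3, 6),
                           weights_gen = rep(0.25, 6), intercept = -2,
                           n_case = 80, n_control = 120,
                           missing_rate = 0.05, seed = 8)
  g <- simulate_cohort(cfg, "reference", seed = 8)
  panel <- simulation_panel(cfg)
  null <- null_or_distribution(g, panel, 20, 40, B = 3, seed = 13)
  for (b in 1:3) {
    sub <- draw_subsample(g, 20, 40,
                          seed = grstransfer:::substream_seed(13, b))
    manual <- fit_association(compute_grs(sub, panel))
    expect_equal(null$or_samples[b], manual$or_value, tolerance = 1e-10)
    expect_equal(null$p_samples[b], manual$p, tolerance = 1e-10)
  }
})

test_that("a subsample equal to the full cohort reproduces the full-cohort OR", {
  cfg <- simulation_config(n_snps = 5, freq_ref = rep(0.4, 5),
                           weights_gen = rep(0.3, 5), intercept = -2,
                           n_case = 50, n_control = 80, seed = 2)
  g <- simulate_cohort(cfg, "reference", seed = 2)
  panel <- simulation_panel(cfg)
  full_or <- fit_association(compute_grs(g, panel))$or_value
  null <- null_or_distribution(g, panel, 50, 80, B = 4, seed = 3)
  expect_equal(null$or_samples, rep(full_or, 4), tolerance = 1e-10)
})

test_that("under a null-effect cohort about half the subsample ORs exceed 1", {
  cfg <- simulation_config(n_snps = 10, freq_ref = runif(10, 0.2, 0.4),
                           weights_gen = rep(0, 10), intercept = -2,
                           n_case = 150, n_control = 300, seed = 19)
  g <- simulate_cohort(cfg, "reference", seed = 19)
  panel <- simulation_panel(cfg, weights = log(seq(1.1, 1.4,
                                                   length.out = 10)))
  null <- null_or_distribution(g, panel, 43, 100, B = 200, seed = 4)
  # symmetry of the null: binomial(200, 0.5) within ~4 SD
  expect_gt(null$summary$prop_or_gt1, 0.5 - 4 * sqrt(0.25 / 200))
  expect_lt(null$summary$prop_or_gt1, 0.5 + 4 * sqrt(0.25 / 200))
})

test_that("empirical p uses the add-one lower-tail rule", {
  null <- structure(list(B = 4, or_samples = c(1, 2, 3, 4),
                         p_samples = rep(0.5, 4), n_case = 5,
                         n_control = 5, seed = 1, n_failures = 0,
                         summary = list()), class = "resampling_null")
  expect_equal(empirical_p(null, 2.5), 3 / 5)
  expect_equal(empirical_p(null, 4), 1)
  expect_equal(empirical_p(null, 0.5), 1 / 5)
  big <- structure(list(B = 1000, or_samples = seq(0.93, 10, length.out = 1000),
                        p_samples = rep(0.5, 1000), n_case = 43,
                        n_control = 163, seed = 1, n_failures = 0,
                        summary = list()), class = "resampling_null")
  expect_equal(empirical_p(big, 0.71), 1 / 1001)
})

test_that("empirical p is monotone in the target OR with floor 1/(B+1)", {
  set.seed(23)
  null <- structure(list(B = 50, or_samples = rlnorm(50, 0.5, 0.4),
                         p_samples = rep(0.5, 50), n_case = 5, n_control = 5,
                         seed = 1, n_failures = 0, summary = list()),
                    class = "resampling_null")
  targets <- sort(c(0.01, runif(20, 0.5, 6), 100))
  ps <- vapply(targets, function(t) empirical_p(null, t), numeric(1))
  expect_true(all(diff(ps) >= 0))
  expect_equal(min(ps), 1 / 51)
  expect_equal(max(ps), 1)
  # two-sided doubles the smaller tail
  expect_equal(empirical_p(null, 0.01, "two.sided"), 2 / 51)
})

test_that("effect-size ratio arithmetic reproduces the combined-SE interval", {
  r <- effect_size_ratio(2.87, c(2.60, 3.17), 0.71, c(0.29, 1.74))
  expect_equal(round(r$ratio, 2), 4.04)
  expect_equal(signif(r$conf.low, 2), 1.6)
  expect_equal(signif(r$conf.high, 2), 10)
  same <- effect_size_ratio(1.5, c(1.2, 1.9), 1.5, c(1.2, 1.9))
  expect_equal(same$ratio, 1, tolerance = 1e-12)
  expect_lt(same$conf.low, 1)
  expect_gt(same$conf.high, 1)
  expect_error(effect_size_ratio(2, c(2.5, 3), 1, c(0.5, 1.5)), "bracket")
})

test_that("null objects tidy, summarize and plot", {
  cfg <- simulation_config(n_snps = 4, freq_ref = rep(0.3, 4),
                           weights_gen = rep(0.2, 4), intercept = -2,
                           n_case = 40, n_control = 60, seed = 6)
  g <- simulate_cohort(cfg, "reference", seed = 6)
  null <- null_or_distribution(g, simulation_panel(cfg), 10, 20, B = 6,
                               seed = 2)
  expect_equal(nrow(tidy(null)), 6)
  gl <- glance(null)
  expect_equal(gl$or_min, min(null$or_samples))
  p <- autoplot(null, or_target = 0.7)
  expect_s3_class(p, "ggplot")
})
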