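# Monte-Carlo checks compare sample means with closed-form mixture means
# within 3 standard errors under a fixed seed.

test_that("uniform sampler covers 0.005-20 mM with the right mean", {
  set.seed(1)
  x <- sample_uniform(1e5)
  expect_gte(min(x), 0.005)
  expect_lte(max(x), 20)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - (0.005 + 20) / 2), 3 * se)
  expect_equal(sample_uniform(5, lo = 1, hi = 1), rep(1, 5))
  expect_error(sample_uniform(5, lo = 2, hi = 1))
})

test_that("low-concentration sampler is the even three-uniform mixture", {
  set.seed(2)
  x <- sample_low_concentration(1e5)
  expect_gte(min(x), 0.005)
  expect_lte(max(x), 0.2)
  mix_mean <- (0.0275 + 0.0525 + 0.1025) / 3
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mix_mean), 3 * se)
  expect_length(sample_low_concentration(0), 0)
})

test_that("tissue-mimicking sampler matches its log-normal mixture", {
  set.seed(3)
  x <- sample_mimic_tissue(1e5)
  expect_gte(min(x), 0.005)
  expect_lte(max(x), 20)
  # most mass below 1 mM with a heavy tail
  expect_gte(mean(x < 1), 0.70)
  expect_gt(max(x), 10)
  # clipping mass under the defaults is below 2%
  expect_lt(mean(x == 0.005 | x == 20), 0.02)
  # mean posterior probability of component 1 is an unbiased estimate of
  # its weight (E[w f1 / f] = w)
  p <- mimic_tissue_params()
  f1 <- p$weight * stats::dlnorm(x, p$meanlog[1], p$sdlog[1])
  f2 <- (1 - p$weight) * stats::dlnorm(x, p$meanlog[2], p$sdlog[2])
  post <- f1 / (f1 + f2)
  se <- sd(post) / sqrt(length(post))
  expect_lt(abs(mean(post) - p$weight), 3 * se + 0.005)
  # degenerate parameters collapse to 1 mM exactly
  deg <- list(weight = 0.5, meanlog = c(0, 0), sdlog = c(0, 0))
  expect_equal(sample_mimic_tissue(10, deg), rep(1, 10))
  expect_error(sample_mimic_tissue(5, list(weight = 1, meanlog = c(0, 0),
                                           sdlog = c(-1, 1))))
})

test_that("high-dynamic-range sampler matches its analytic mixture mean", {
  set.seed(4)
  x <- sample_high_dynamic(1e5)
  expect_gte(min(x), 0.005)
  expect_lte(max(x), 20)
  p <- high_dynamic_params()
  mix_mean <- p$weights[1] * p$shape[1] * p$scale[1] +
    p$weights[2] * p$shape[2] * p$scale[2] +
    p$weights[3] * mean(p$unif)
  se <- sd(x) / sqrt(length(x))
  # clipping perturbs the mean by well under 0.01 mM for the defaults
  expect_lt(abs(mean(x) - mix_mean), 3 * se + 0.01)
  expect_lt(mean(x == 0.005 | x == 20), 0.02)
  # uniform weight 1 reduces to the plain uniform sampler
  set.seed(5)
  u <- sample_high_dynamic(1e4, list(weights = c(0, 0, 1), shape = c(1, 1),
                                     scale = c(1, 1), unif = c(0.005, 20)))
  set.seed(6)
  ref <- sample_uniform(1e4)
  expect_gt(stats::ks.test(u, ref)$p.value, 0.01)
  expect_error(sample_high_dynamic(5, list(weights = c(0.5, 0.2, 0.2),
                                           shape = c(1, 1), scale = c(1, 1),
                                           unif = c(0.005, 20))),
               "sum to 1")
})

test_that("interference concentrations have mean 0.85 mM, mostly under 5", {
  set.seed(7)
  x <- sample_interference(1e5)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.85), 3 * se)
  expect_gte(mean(x < 5), 0.95)
  expect_length(sample_interference(0), 0)
})

test_that("combined sampler assigns one source per spectrum at 25% each", {
  set.seed(8)
  m <- sample_combined(1e4, 5)
  src <- attr(m, "source")
  freq <- table(src) / length(src)
  se <- sqrt(0.25 * 0.75 / length(src))
  expect_true(all(abs(freq - 0.25) < 3 * se))
  expect_gte(min(m), 0.005)
  expect_lte(max(m), 20)
  # stratified n = 4: exactly one spectrum per source
  s4 <- attr(sample_combined(4, 3, stratified = TRUE), "source")
  expect_identical(sort(as.integer(table(s4))), rep(1L, 4))
  # conditional distribution given the source equals the standalone sampler
  vals <- as.vector(m[src == "uniform", ])
  set.seed(9)
  expect_gt(stats::ks.test(vals, sample_uniform(length(vals)))$p.value, 0.01)
  vals_low <- as.vector(m[src == "low_concentration", ])
  expect_gt(stats::ks.test(vals_low,
                           sample_low_concentration(length(vals_low)))$p.value,
            0.01)
})

test_that("leave-out schemes give the expected presence fractions", {
  set.seed(10)
  expect_true(all(leave_out_mask(50, 7, "all_present")))
  n <- 2000
  a <- 20
  m50 <- leave_out_mask(n, a, "half50")
  expect_true(all(m50[1:(n / 2), ]))
  se <- sqrt(0.75 * 0.25 / (n * a))
  expect_lt(abs(mean(m50) - 0.75), 3 * se)
  mt <- leave_out_mask(n, a, "tiered")
  expect_true(all(mt[1:(n / 3), ]))
  se_t <- sqrt(0.58333 * (1 - 0.58333) / (n * a))
  expect_lt(abs(mean(mt) - (1 + 0.5 + 0.25) / 3), 3 * se_t)
  expect_error(leave_out_mask(10, 3, "bogus"))
})

test_that("samplers are reproducible under a fixed seed", {
  set.seed(11)
  a <- sample_mimic_tissue(100)
  set.seed(11)
  b <- sample_mimic_tissue(100)
  expect_identical(a, b)
  set.seed(12)
  m1 <- sample_combined(20, 4)
  set.seed(12)
  m2 <- sample_combined(20, 4)
  expect_identical(m1, m2)
})
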