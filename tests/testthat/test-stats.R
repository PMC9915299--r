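test_that("descriptive statistics match closed forms", {
  d <- descriptiveStats(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$median, 2)
  # t_{0.975, 2} = 4.3027 -> CI 2 -/+ 4.3027 / sqrt(3)
  expect_equal(d$ci_lo, -0.484, tolerance = 1e-3)
  expect_equal(d$ci_hi, 4.484, tolerance = 1e-3)

  cst <- descriptiveStats(c(5, 5, 5, 5))
  expect_identical(cst$sd, 0)
  expect_identical(c(cst$ci_lo, cst$ci_hi), c(5, 5))

  expect_error(descriptiveStats(0.1), "insufficient")
})

test_that("the power transform is the documented monotone map", {
  expect_identical(powerTransform(c(0.5, 1, 2), 1), c(0.5, 1, 2))
  expect_equal(powerTransform(0.125, 1 / 3), 0.5)
  set.seed(1)
  v <- stats::rlnorm(50)
  expect_identical(rank(powerTransform(v, 0.2)), rank(v))
  expect_error(powerTransform(c(1, -0.1), 0.5), "domain error")
  # floor keeps zeros finite and monotone
  expect_equal(powerTransform(0, 0.125), 1e-6^0.125)
})

test_that("Shapiro-Wilk calibration on normal and lognormal samples", {
  set.seed(123)
  p_norm <- replicate(100, shapiroWilk(stats::rnorm(25))$p)
  expect_gte(mean(p_norm > 0.05), 0.90)
  p_logn <- replicate(100, shapiroWilk(stats::rlnorm(25, 0, 1.5))$p)
  expect_gte(mean(p_logn < 0.05), 0.90)
  expect_error(shapiroWilk(c(1, 2)), "domain error")
})

test_that("the power search finds the normalizing exponent", {
  set.seed(5)
  normal <- lapply(1:3, function(i) stats::rnorm(25, 1, 0.1))
  selN <- selectPower(normal)
  expect_identical(selN$power, 1)
  expect_length(selN$pValues, 3)

  # v = u^8 with u normal-positive is normalized by power near 1/8
  skew <- lapply(1:3, function(i) stats::rnorm(25, 2, 0.25)^8)
  selS <- selectPower(skew)
  expect_gte(selS$power, 0.05)
  expect_lte(selS$power, 0.3)

  fx <- selectPower(skew, fixed = 0.25)
  expect_identical(fx$power, 0.25)
})

test_that("one-way ANOVA matches the hand-computed toy design", {
  res <- oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  # SSB = 6, SSW = 6, MSB = 3, MSW = 1
  expect_equal(res@F, 3, tolerance = 1e-10)
  expect_identical(res@dfBetween, 2L)
  expect_identical(res@dfWithin, 6L)
  expect_equal(res@p, stats::pf(3, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("identical groups give F = 0, p = 1", {
  res <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res@F, 0, tolerance = 1e-12)
  expect_equal(res@p, 1)
})

test_that("the study design 3 x 25 has df (2, 72)", {
  set.seed(9)
  res <- oneWayAnova(lapply(1:3, function(i) stats::rnorm(25)))
  expect_identical(res@dfBetween, 2L)
  expect_identical(res@dfWithin, 72L)
})

test_that("ANOVA agrees with the raw sum-of-squares definition", {
  bruteF <- function(groups) {
    all <- unlist(groups)
    gm <- mean(all)
    ssb <- sum(vapply(groups, function(g)
      length(g) * (mean(g) - gm)^2, numeric(1)))
    ssw <- sum(vapply(groups, function(g)
      sum((g - mean(g))^2), numeric(1)))
    k <- length(groups)
    (ssb / (k - 1)) / (ssw / (length(all) - k))
  }
  set.seed(31)
  for (i in 1:20) {
    groups <- lapply(1:3, function(g)
      stats::rlnorm(sample(5:30, 1), g * 0.1, 1))
    expect_equal(oneWayAnova(groups)@F, bruteF(groups),
                 tolerance = 1e-10)
  }
})

test_that("Tukey HSD flags only genuinely separated pairs", {
  g <- c(1, 2, 3, 4, 5)
  same <- tukeyHsd(list(a = g, b = g, c = g))
  expect_true(all(abs(same@pairs$difference) < 1e-12))
  expect_true(all(same@pairs$p_adj > 0.999))

  set.seed(7)
  base <- stats::rnorm(25)
  far <- tukeyHsd(list(a = base, b = base, c = base + 10 * stats::sd(base)))
  p <- far@pairs
  expect_lt(max(p$p_adj[p$group1 == "a" & p$group2 == "c"],
                p$p_adj[p$group1 == "b" & p$group2 == "c"]), 1e-6)
  expect_gt(p$p_adj[p$group1 == "a" & p$group2 == "b"], 0.99)
})

test_that("Tukey differences are antisymmetric under group reordering", {
  set.seed(8)
  g1 <- stats::rnorm(20, 0)
  g2 <- stats::rnorm(20, 1)
  d12 <- tukeyHsd(list(a = g1, b = g2))@pairs$difference
  d21 <- tukeyHsd(list(a = g2, b = g1))@pairs$difference
  expect_equal(d12, -d21, tolerance = 1e-12)
})

test_that("sample size reproduces the normal-approximation values", {
  res <- sampleSizeNormalApprox(0.006, 0.007, alpha = 0.05, power = 0.8)
  expect_identical(res$d, 0.86)
  expect_identical(res$nPerGroup, 22L)
  # d = 1: 2 (1.95996 + 0.84162)^2 = 15.698 -> 16
  expect_identical(sampleSizeNormalApprox(1, 1)$nPerGroup, 16L)
  # power 0.5: z_{1-beta} = 0 -> 2 z_{0.975}^2 = 7.68 -> 8
  expect_identical(sampleSizeNormalApprox(1, 1, power = 0.5)$nPerGroup, 8L)
  expect_error(sampleSizeNormalApprox(0, 1), "divergence")
})

test_that("group median ordering is invariant under the transform", {
  set.seed(13)
  groups <- lapply(c(0.1, 0.4, 0.2), function(m) stats::rlnorm(25, log(m), 0.7))
  meds <- vapply(groups, stats::median, numeric(1))
  tg <- lapply(groups, powerTransform, power = 0.125)
  tmeds <- vapply(tg, stats::median, numeric(1))
  expect_identical(order(meds), order(tmeds))
})

test_that("endpoint analysis couples transform, gate, ANOVA and Tukey", {
  set.seed(14)
  groups <- lapply(c(0.24, 0.07, 0.12), function(m)
    stats::rlnorm(25, log(m), 1))
  res <- analyzeEndpoint(groups, power = 0.125)
  expect_identical(res$power, 0.125)
  expect_identical(res$anova@dfWithin, 72L)
  expect_equal(nrow(res$tukey@pairs), 3L)
})
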