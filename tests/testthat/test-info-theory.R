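test_that("equal-frequency binning balances counts and is rank-invariant", {
  set.seed(11)
  x <- rnorm(127)
  b <- equal_frequency_bins(x, 12)
  expect_true(all(b$counts %in% c(10L, 11L)))
  expect_equal(sum(b$counts), 127L)
  # the worked 127-sample / 12-bin case: near-uniform per-bin probability
  # of about 10/127 ~ 0.083
  expect_true(all(abs(b$p - 10 / 127) < 0.01))
  # monotone transform leaves assignments untouched
  b3 <- equal_frequency_bins(x^3, 12)
  expect_identical(b$assignments, b3$assignments)
  # 12 distinct samples in 12 bins: one each
  b1 <- equal_frequency_bins(rnorm(12), 12)
  expect_equal(b1$counts, rep(1L, 12))
  expect_equal(b1$p, rep(1 / 12, 12))
  # edges bracket the data and are increasing
  expect_true(all(diff(b$edges) >= 0))
  expect_equal(b$edges[1], min(x))
  expect_equal(b$edges[13], max(x))
  expect_error(equal_frequency_bins(rep(1, 50), 12), "degenerate")
  expect_error(equal_frequency_bins(rnorm(5), 12), "at least")
})

test_that("binning maximizes marginal entropy near log2(B)", {
  set.seed(3)
  for (n in c(127, 500, 1000)) {
    b <- equal_frequency_bins(rexp(n), 12)
    expect_lt(log2(12) - shannon_entropy(b$p), 0.02)
  }
})

test_that("entropy matches analytic values", {
  expect_equal(shannon_entropy(rep(1 / 12, 12)), log2(12))
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("joint distribution agrees with a brute-force cross-tabulation", {
  set.seed(21)
  x <- rnorm(20)
  y <- rnorm(20)
  bx <- equal_frequency_bins(x, 4)
  by <- equal_frequency_bins(y, 4)
  jd <- joint_distribution(bx, by)
  manual <- matrix(0L, 4, 4)
  for (k in 1:20) {
    manual[bx$assignments[k], by$assignments[k]] <-
      manual[bx$assignments[k], by$assignments[k]] + 1L
  }
  expect_equal(jd$joint_counts, manual)
  expect_equal(sum(jd$joint_p), 1)
  expect_equal(jd$marginal_px, bx$p)
  expect_equal(jd$marginal_py, by$p)
  # same variable twice: diagonal joint
  jself <- joint_distribution(bx, bx)
  expect_true(all(jself$joint_counts[row(jself$joint_counts) !=
                                       col(jself$joint_counts)] == 0))
  expect_error(joint_distribution(bx, equal_frequency_bins(rnorm(25), 4)),
               "different numbers")
})

test_that("plug-in MI matches identities and the brute-force sum", {
  # exact product distribution -> 0 bits
  px <- c(0.2, 0.3, 0.5)
  py <- c(0.6, 0.4)
  expect_equal(mutual_information_plugin(outer(px, py)), 0)
  # diagonal uniform joint -> log2(B)
  expect_equal(mutual_information_plugin(diag(12) / 12), log2(12))
  # random 5x5 joint vs brute force
  set.seed(8)
  p <- matrix(rexp(25), 5)
  p <- p / sum(p)
  expect_equal(mutual_information_plugin(p), brute_mi(p), tolerance = 1e-12)
  # I(X;X) = H(X) through the binning path
  set.seed(9)
  x <- rnorm(200)
  b <- equal_frequency_bins(x, 8)
  jd <- joint_distribution(b, b)
  expect_equal(mutual_information_plugin(jd), shannon_entropy(b$p),
               tolerance = 1e-9)
})

test_that("Miller-Madow correction has the stated occupied-count form", {
  set.seed(14)
  x <- rnorm(127)
  y <- rnorm(127)
  mm <- mutual_information_mm(x, y, 12)
  # fully occupied 12x12 joint would give 121 / (254 ln 2) bits
  full_corr <- (144 - 12 - 12 + 1) / (2 * 127 * log(2))
  expect_equal(full_corr, 121 / (254 * log(2)))
  jc <- table(equal_frequency_bins(x, 12)$assignments,
              equal_frequency_bins(y, 12)$assignments)
  expect_equal(attr(mm, "correction"),
               (sum(jc > 0) - 12 - 12 + 1) / (2 * 127 * log(2)))
  expect_equal(as.numeric(mm),
               max(attr(mm, "plugin") - attr(mm, "correction"), 0))
  # corrected MI is floored at zero
  expect_gte(as.numeric(mm), 0)
})

test_that("MI is symmetric and the copy case approaches log2(B)", {
  set.seed(15)
  x <- rnorm(396)  # divisible by 12: reversed ranks map bins exactly
  y <- x^2 + rnorm(396, 0, 0.1)
  expect_equal(as.numeric(mutual_information_mm(x, y)),
               as.numeric(mutual_information_mm(y, x)), tolerance = 1e-12)
  mi_copy <- as.numeric(mutual_information_mm(x, x, 12))
  expect_equal(mi_copy, log2(12), tolerance = 0.05)
  # perfect anticorrelation is the same dependence under rank binning
  expect_equal(as.numeric(mutual_information_mm(x, -x, 12)), mi_copy,
               tolerance = 1e-9)
})

test_that("corrected MI of independent data sits inside its permutation null", {
  set.seed(16)
  x <- rnorm(127)
  y <- rnorm(127)
  pt <- permutation_test_mi(x, y, n_perm = 200, n_bins = 12, seed = 17)
  expect_lt(abs(pt$mi_obs - mean(pt$null_mi)), 3 * sd(pt$null_mi))
})

test_that("MI decays with added noise on average", {
  set.seed(18)
  means <- sapply(c(0.1, 0.5, 2), function(ns) {
    mean(sapply(1:20, function(i) {
      x <- rnorm(300)
      as.numeric(mutual_information_mm(x, x + rnorm(300, 0, ns), 12))
    }))
  })
  expect_true(all(diff(means) < 0))
})

test_that("permutation test hits the analytic floor and is rank-invariant", {
  set.seed(19)
  x <- rnorm(200)
  pt <- permutation_test_mi(x, x, n_perm = 999, seed = 20)
  expect_equal(pt$p_value, 1 / 1000)
  # identical seed and monotone-transformed y give identical p
  y <- x + rnorm(200, 0, 0.2)
  p1 <- permutation_test_mi(x, y, n_perm = 200, seed = 21)$p_value
  p2 <- permutation_test_mi(x, exp(y), n_perm = 200, seed = 21)$p_value
  expect_identical(p1, p2)
  # determinism
  p3 <- permutation_test_mi(x, y, n_perm = 200, seed = 21)$p_value
  expect_identical(p1, p3)
})

test_that("permutation p-values are roughly uniform under independence", {
  set.seed(22)
  ps <- sapply(1:100, function(i) {
    permutation_test_mi(rnorm(100), rnorm(100), n_perm = 99, n_bins = 8,
                        seed = i)$p_value
  })
  expect_gte(mean(ps <= 0.05), 0.01)
  expect_lte(mean(ps <= 0.05), 0.12)
})

test_that("Pearson screen contrasts linear and nonlinear dependence", {
  x <- seq(-1, 1, length.out = 201)
  ln <- pearson_screen(x, 2 * x + 1)
  expect_equal(ln$r, 1)
  set.seed(23)
  xs <- rnorm(600)
  quad <- pearson_screen(xs, xs^2)
  expect_lt(abs(quad$r), 0.1)
  expect_gt(as.numeric(mutual_information_mm(xs, xs^2, 12)), 1)
  expect_error(pearson_screen(rep(1, 10), rnorm(10)), "constant")
})

test_that("Bonferroni threshold is alpha / m", {
  expect_equal(round(bonferroni_threshold(0.05, 6), 4), 0.0083)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 7) * 7, 0.01)
})
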