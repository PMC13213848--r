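test_that("Pearson correlation matches the product-moment formula", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  r <- pearsonCor(x, y)
  expect_equal(r$r, 3 / sqrt(2 * 42 / 9), tolerance = 1e-10)
  expect_equal(r$r, 0.9820, tolerance = 1e-4)
  # exact linearity
  set.seed(1); v <- runif(10)
  expect_equal(pearsonCor(v, 2 * v)$r, 1)
  expect_equal(pearsonCor(v, -3 * v + 1)$r, -1)
  # constant input is undefined with a reason
  pc <- pearsonCor(rep(0.5, 5), v[1:5])
  expect_true(is.na(pc$r))
  expect_match(pc$reason, "constant")
})

test_that("Spearman is exactly Pearson on mid-ranks, including ties", {
  set.seed(7)
  for (i in 1:20) {
    x <- sample(round(runif(11), 1))          # coarse grid forces ties
    y <- sample(round(runif(11), 1))
    s <- spearmanCor(x, y)
    oracle <- cor(rank(x), rank(y))
    expect_equal(s$rho, oracle, tolerance = 1e-12)
    expect_equal(s$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  # rank invariance under strictly monotone transforms
  x <- runif(15)
  expect_equal(spearmanCor(x, exp(3 * x))$rho, 1)
  expect_equal(spearmanCor(x, -x^3)$rho, -1)
  expect_equal(spearmanCor(x, 1 - x)$p, 0)
})

test_that("ICC(A,1) reproduces the two-way mean-square formula", {
  # worked case: constant offset of 1 between two raters
  expect_equal(iccAbsoluteSingle(cbind(c(1, 2, 3), c(2, 3, 4)))$icc, 2 / 3,
               tolerance = 1e-12)
  # identical columns are perfect agreement
  expect_equal(iccAbsoluteSingle(cbind(c(1, 5, 9), c(1, 5, 9)))$icc, 1)
  # against an independent aov decomposition on random matrices
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k), n, k)
    df <- data.frame(y = as.vector(m),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    ms <- anova(aov(y ~ subj + rater, data = df))[["Mean Sq"]]
    oracle <- (ms[1] - ms[3]) /
      (ms[1] + (k - 1) * ms[3] + k * (ms[2] - ms[3]) / n)
    expect_equal(iccAbsoluteSingle(m)$icc, oracle, tolerance = 1e-10)
  }
  # independent noise is near zero, and negative values are reachable
  set.seed(8)
  big <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(iccAbsoluteSingle(big)$icc), 0.1)
  neg <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1) + 10)
  expect_lt(iccAbsoluteSingle(neg)$icc, 0)
})

test_that("Bland-Altman limits follow mean +/- 1.96 SD of differences", {
  ba <- blandAltman(c(1, 2), c(0, 3))     # d = (+1, -1)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_upper, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_lower, -1.96 * sqrt(2), tolerance = 1e-12)
  # x = y collapses everything to zero
  z <- blandAltman(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(unlist(z[c("mean_diff", "sd_diff", "loa_lower",
                          "loa_upper")]),
               c(mean_diff = 0, sd_diff = 0, loa_lower = 0, loa_upper = 0))
  # shifting one arm translates the bias and both limits equally
  set.seed(2); x <- runif(20); y <- runif(20)
  b0 <- blandAltman(x, y); b1 <- blandAltman(x, y + 0.3)
  expect_equal(b1$mean_diff, b0$mean_diff - 0.3, tolerance = 1e-12)
  expect_equal(b1$loa_lower, b0$loa_lower - 0.3, tolerance = 1e-12)
  expect_equal(b1$loa_upper, b0$loa_upper - 0.3, tolerance = 1e-12)
  expect_equal(b1$sd_diff, b0$sd_diff, tolerance = 1e-12)
})

test_that("limits of agreement cover about 95% of normal differences", {
  set.seed(99)
  x <- rnorm(10000); y <- x + rnorm(10000, sd = 0.5)
  ba <- blandAltman(x, y)
  d <- x - y
  cover <- mean(d >= ba$loa_lower & d <= ba$loa_upper)
  expect_gt(cover, 0.94); expect_lt(cover, 0.96)
})

test_that("Levene's test matches car::leveneTest and behaves at the null", {
  g1 <- c(1, 2, 3, 4, 5); g2 <- c(2, 4, 6, 8, 12)
  lv <- leveneVariance(list(g1, g2))
  ref <- car::leveneTest(c(g1, g2),
                         factor(rep(1:2, times = c(5, 5))),
                         center = mean)
  expect_equal(lv$F, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(lv$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  # median centre = Brown-Forsythe
  lvm <- leveneVariance(list(g1, g2), center = "median")
  refm <- car::leveneTest(c(g1, g2), factor(rep(1:2, each = 5)),
                          center = median)
  expect_equal(lvm$F, refm[1, "F value"], tolerance = 1e-10)
  # identical groups: F = 0, p = 1
  same <- leveneVariance(list(g1, g1))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  # relabeling invariance
  set.seed(4)
  a <- rnorm(30); b <- rnorm(30, sd = 2)
  expect_equal(leveneVariance(list(a, b))$F,
               leveneVariance(list(b, a))$F, tolerance = 1e-12)
  # unequal spread is detected in simulation
  set.seed(5)
  hits <- mean(replicate(200, {
    leveneVariance(list(rnorm(100), rnorm(100, sd = 5)))$p < 0.01
  }))
  expect_gt(hits, 0.95)
})

test_that("pairwise agreement block is complete on a simulated study", {
  at <- generateStudy(referenceConfig(), seed = 3)
  blk <- pairwiseAgreement(at, "model", "radiologist1")
  expect_named(blk, c("pearson", "spearman", "icc", "kappa",
                      "bland_altman", "levene"))
  expect_true(is.finite(blk$pearson$r))
  expect_true(is.finite(blk$icc$icc))
  expect_true(blk$bland_altman$loa_lower <= blk$bland_altman$mean_diff)
  expect_true(blk$bland_altman$mean_diff <= blk$bland_altman$loa_upper)
})
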