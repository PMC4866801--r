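# From-scratch LDA: screening, fitting, nearest-Mahalanobis classification,
# forward selection, diagnostics. Oracles: textbook ANOVA, stats::aov,
# stats::mahalanobis, MASS::lda, closed-form Gaussian accuracy.

test_that("one-way F matches the hand-worked case and stats::aov", {
  x <- data.frame(f1 = c(0, 1, 1, 2))
  g <- c("a", "a", "b", "b")
  rep <- screen_features(x, g)
  expect_equal(rep$table$F, 2)               # SSB/1 / (SSW/2) = 1 / 0.5
  expect_identical(rep$table$df1, 1L)
  expect_identical(rep$table$df2, 2L)

  set.seed(31)
  x2 <- data.frame(f1 = rnorm(30), f2 = rnorm(30, rep(c(0, 2, 4), each = 10)))
  g2 <- rep(c("a", "b", "c"), each = 10)
  rep2 <- screen_features(x2, g2)
  expect_equal(rep2$table$F[1], anova_f_oracle(x2$f1, g2))
  expect_equal(rep2$table$F[2], anova_f_oracle(x2$f2, g2))
})

test_that("F is zero under identical group means", {
  x <- data.frame(f1 = c(1, 3, 1, 3, 1, 3))
  g <- rep(c("a", "b", "c"), each = 2)
  expect_equal(screen_features(x, g)$table$F, 0)
})

test_that("screening flags rank deficiency and small groups", {
  set.seed(5)
  x <- data.frame(f1 = rnorm(12), f2 = rnorm(12))
  x$f3 <- x$f1                               # duplicated column
  g <- rep(c("a", "b"), each = 6)
  rep <- screen_features(x, g)
  expect_false(rep$full_rank)
  expect_true(all(diff(rep$singular_values) <= 0))
  expect_true(screen_features(x[, 1:2], g)$full_rank)
  expect_error(screen_features(x, c("a", rep("b", 11))), "fewer than 2")
})

test_that("pooled variance of two unit-variance 1-D classes is 1", {
  x <- data.frame(f1 = c(0, sqrt(2), 10, 10 + sqrt(2)))  # unit variances
  g <- c("a", "a", "b", "b")
  expect_equal(unname(fit_lda(x, g)$pooled_cov[1, 1]), 1)
  # unequal df weighting: classes of size 3 and 2
  x2 <- data.frame(f1 = c(0, 1, 2, 10, 14))
  m2 <- fit_lda(x2, c("a", "a", "a", "b", "b"))
  expect_equal(unname(m2$pooled_cov[1, 1]), (2 * 1 + 1 * 8) / 3)
})

test_that("fit_lda recovers simulated class means and covariance", {
  d <- gauss_classes(200, list(c(0, 0), c(10, 5)), sd = 1, seed = 3)
  m <- fit_lda(d$x, d$g)
  expect_lt(max(abs(m$class_means - rbind(c(0, 0), c(10, 5)))), 0.2)
  expect_lt(max(abs(m$pooled_cov - diag(2))), 0.2)
})

test_that("rank-deficient fits fail with advice", {
  x <- data.frame(f1 = rnorm(4), f2 = rnorm(4), f3 = rnorm(4))
  g <- c("a", "a", "b", "b")                # N - K = 2 < p = 3
  expect_error(fit_lda(x, g), "reduce")
  expect_error(fit_lda(x[1:3, 1, drop = FALSE], c("a", "b", "b")),
               "at least 2")
})

test_that("classification distances match stats::mahalanobis and MASS::lda", {
  skip_if_not_installed("MASS")
  d <- gauss_classes(60, list(c(0, 0, 0), c(4, 0, 2), c(0, 4, -2)), seed = 3)
  m <- fit_lda(d$x, d$g)
  pred <- classify(m, d$x)
  # distance oracle per class
  for (j in seq_along(m$class_labels)) {
    expect_equal(pred[[paste0("dist_", m$class_labels[j])]],
                 mahal_oracle(as.matrix(d$x), m$class_means[j, ], m$pooled_cov))
  }
  # agreement with MASS on well-separated data
  mass <- MASS::lda(as.matrix(d$x), grouping = d$g)
  expect_identical(pred$predicted,
                   as.character(predict(mass, as.matrix(d$x))$class))
})

test_that("worked 1-D example and exact-mean/tie behaviour", {
  x <- data.frame(f1 = c(-1, 1, 9, 11))
  g <- c("lo", "lo", "hi", "hi")
  m <- fit_lda(x, g)                         # means 0 and 10, pooled var 2
  m$pooled_cov[] <- 1; m$pooled_cov_inv[] <- 1
  p <- classify(m, data.frame(f1 = 4))
  expect_equal(unname(c(p$dist_lo, p$dist_hi)), c(4, 6))
  expect_identical(p$predicted, "lo")
  # record at a class mean
  p0 <- classify(m, data.frame(f1 = 10))
  expect_identical(p0$predicted, "hi")
  expect_equal(p0$nearest_distance, 0)
  # equidistant: first declared label wins
  expect_identical(classify(m, data.frame(f1 = 5))$predicted, "lo")
})

test_that("argmin distance equals argmax linear discriminant score", {
  set.seed(11)
  for (rep in 1:200) {
    p <- sample(1:3, 1); k <- sample(2:4, 1)
    a <- matrix(rnorm(p * p), p)
    sigma <- crossprod(a) + diag(p) * 0.5
    means <- matrix(rnorm(k * p, sd = 2), k)
    x <- rnorm(p)
    d2 <- apply(means, 1, function(mu) {
      stats::mahalanobis(matrix(x, 1), mu, sigma)
    })
    score <- apply(means, 1, function(mu) {
      drop(mu %*% solve(sigma, x)) - 0.5 * drop(mu %*% solve(sigma, mu))
    })
    expect_identical(which.min(d2), which.max(score))
  }
})

test_that("Mahalanobis classification is invariant under joint affine maps", {
  d <- gauss_classes(40, list(c(0, 0), c(3, 1)), seed = 9)
  m <- fit_lda(d$x, d$g)
  base <- classify(m, d$x)
  set.seed(10)
  a <- matrix(rnorm(4), 2); a <- a + diag(2) * 2   # invertible
  b <- c(5, -3)
  xt <- sweep(as.matrix(d$x) %*% t(a), 2, b, "+")
  colnames(xt) <- colnames(d$x)
  mt <- fit_lda(as.data.frame(xt), d$g)
  trans <- classify(mt, xt)
  expect_identical(trans$predicted, base$predicted)
  expect_equal(trans$nearest_distance, base$nearest_distance)
})

test_that("two-Gaussian accuracy approaches Phi(Delta/2)", {
  # 1-D classes at Mahalanobis separation Delta = 4: Bayes accuracy
  # Phi(2) ~= 0.977
  set.seed(20)
  n <- 4000
  x <- data.frame(f1 = c(rnorm(n, 0), rnorm(n, 4)))
  g <- rep(c("a", "b"), each = n)
  m <- fit_lda(x, g)
  acc <- mean(classify(m, x)$predicted == g)
  expect_lt(abs(acc - pnorm(2)), 3 * sqrt(pnorm(2) * (1 - pnorm(2)) / (2 * n)) + 0.003)
})

test_that("forward selection keeps only strictly improving features", {
  # f1 separates perfectly: nothing after it can strictly improve
  d <- gauss_classes(50, list(c(0), c(20)), seed = 4)
  x <- d$x; x$f2 <- rnorm(100)
  expect_identical(forward_select(x, d$g, c("f1", "f2")), "f1")

  # pure-noise candidate appended last is never retained
  set.seed(6)
  d2 <- gauss_classes(80, list(c(0, 0), c(2.5, 1)), seed = 6)
  x2 <- d2$x; x2$noise <- rnorm(160)
  kept <- forward_select(x2, d2$g, c("f1", "f2", "noise"))
  expect_false("noise" %in% kept)
  # output order is a subsequence of input order
  expect_identical(kept, intersect(c("f1", "f2", "noise"), kept))
})

test_that("mahalanobis_summary splits by defect flag with SE = sd/sqrt(n)", {
  d <- gauss_classes(20, list(c(0, 0), c(5, 5)), seed = 8)
  m <- fit_lda(d$x, d$g)
  # records exactly at class means: distance 0, SE 0
  at_means <- as.data.frame(m$class_means)
  s <- mahalanobis_summary(m, at_means, c(FALSE, FALSE))
  expect_equal(s$mean_distance, 0)
  expect_equal(s$se, 0)
  # single record: SE missing
  s1 <- mahalanobis_summary(m, at_means[1, , drop = FALSE], TRUE)
  expect_true(is.na(s1$se))
  # shifted 'defective' records sit further from their nearest mean
  set.seed(12)
  clean <- d$x
  shifted <- d$x + 3
  s2 <- mahalanobis_summary(m, rbind(clean, shifted),
                            rep(c(FALSE, TRUE), each = nrow(clean)))
  expect_gt(s2$mean_distance[s2$defective], s2$mean_distance[!s2$defective])
  hand <- classify(m, shifted)$nearest_distance
  expect_equal(s2$se[s2$defective], sd(hand) / sqrt(length(hand)))
})
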