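test_that("multilevel split reconstructs exactly with zero-sum within rows", {
  expect_equal(unname(multilevel_split(matrix(c(5, 3), 2, 1), c("s", "s"))$between),
               matrix(4))
  expect_equal(unname(multilevel_split(matrix(c(5, 3), 2, 1), c("s", "s"))$within),
               matrix(c(1, -1), 2, 1))

  set.seed(12)
  x <- matrix(rnorm(24 * 6), 24, 6)
  subject <- rep(sprintf("s%02d", 1:8), each = 3)
  sp <- multilevel_split(x, subject)
  expect_equal(sp$between[subject, , drop = FALSE] + sp$within, x,
               ignore_attr = TRUE, tolerance = 1e-12)
  for (s in unique(subject)) {
    expect_equal(unname(colSums(sp$within[subject == s, , drop = FALSE])),
                 rep(0, 6), tolerance = 1e-12)
  }
  expect_error(multilevel_split(x[1:5, ], rep(c("a", "b"), c(3, 2))),
               "same number")
  expect_error(multilevel_split(x[1:4, ], c("a", "a", "a", "b")), "single sample")
})

test_that("mPCA spectra: rank-1 gives 100%, two equal patterns give 50/50", {
  subject <- rep(c("s1", "s2"), each = 2)
  v <- c(1, 2, 3, 4)
  x <- rbind(2 * v, -2 * v, 1 * v, -1 * v)  # within part rank 1
  p1 <- mpca(x, subject, k = 1)
  expect_equal(p1$variance_fraction[1], 100)

  # two orthogonal within-patterns of equal norm -> 50%/50%
  a <- c(1, 1, 0, 0); b <- c(0, 0, 1, 1)
  x2 <- rbind(a, -a, b, -b)
  p2 <- mpca(x2, rep(c("s1", "s2"), each = 2), k = 2)
  expect_equal(p2$variance_fraction[1:2], c(50, 50), tolerance = 1e-9)

  # scores = centered within matrix projected on loadings; loadings orthonormal
  set.seed(13)
  x3 <- matrix(rnorm(20 * 7), 20, 7)
  sub3 <- rep(sprintf("s%d", 1:10), each = 2)
  p3 <- mpca(x3, sub3, k = 3)
  w <- scale(multilevel_split(x3, sub3)$within, scale = FALSE)
  expect_equal(w %*% p3$loadings, p3$scores, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_equal(crossprod(p3$loadings), diag(3), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_true(all(diff(p3$variance_fraction) <= 1e-9))
})

test_that("mPCA is invariant to per-subject offsets (between variation removed)", {
  set.seed(14)
  x <- matrix(rnorm(16 * 5), 16, 5)
  subject <- rep(sprintf("s%d", 1:8), each = 2)
  offs <- matrix(rnorm(8 * 5, sd = 50), 8, 5)
  x_shift <- x + offs[rep(1:8, each = 2), ]
  p0 <- mpca(x, subject, k = 2)
  p1 <- mpca(x_shift, subject, k = 2)
  expect_equal(p0$variance_fraction, p1$variance_fraction, tolerance = 1e-8)
  expect_equal(abs(p0$scores), abs(p1$scores), tolerance = 1e-6)
})

test_that("mPLS-DA separates separable classes and deflates orthogonally", {
  fm <- generate_feature_matrix(8, 15, class_effect = 4, seed = 15)
  x <- log(fm$x)
  fit <- mplsda(x, fm$subject, fm$class, n_lv = 2)
  # the +1-coded class ("B", second level) scores higher on LV1 by construction
  s1 <- fit$scores[, 1]
  expect_gt(min(s1[fm$class == "B"]) - max(s1[fm$class == "A"]), 0)
  # deflation: LV2 scores orthogonal to LV1 scores
  expect_equal(sum(fit$scores[, 1] * fit$scores[, 2]), 0, tolerance = 1e-8)
  expect_equal(fit$sensitivity, 100)
  expect_equal(fit$specificity, 100)

  expect_error(mplsda(x, fm$subject, rep(c("A", "B", "C"), length.out = 16)),
               "two classes|exactly one")
  # class code orthogonal to the data: zero matrix has no covariance
  zero <- matrix(0, 16, 5)
  expect_error(mplsda(zero, fm$subject, fm$class), "zero covariance")
})

test_that("cv_roc keeps the class-code orientation", {
  cvp <- data.frame(y = c(1, 1, 1, -1, -1, -1),
                    yhat = c(3, 2.5, 2, 1, 0.5, 0))
  r <- cv_roc(cvp)
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  # anti-ranked scores are not silently sign-flipped to a perfect classifier
  anti <- cvp; anti$yhat <- -anti$yhat
  ra <- cv_roc(anti)
  expect_lte(ra$sensitivity + ra$specificity, 100)
  expect_error(cv_roc(data.frame(y = c(1, 1), yhat = c(0, 1))), "single class")
})

test_that("cv_roc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(16)
  y <- rep(c(1, -1), each = 20)
  yhat <- rnorm(40, mean = ifelse(y > 0, 0.8, 0))
  r <- cv_roc(data.frame(y = y, yhat = yhat))
  pr <- pROC::roc(response = factor(y), predictor = yhat, quiet = TRUE,
                  direction = "<")
  best <- pROC::coords(pr, "best", best.method = "youden",
                       ret = c("sensitivity", "specificity"))
  expect_equal(r$sensitivity / 100 + r$specificity / 100,
               max(best$sensitivity + best$specificity), tolerance = 1e-9)
})

test_that("permutation p is 1/(n_perm+1) for separable data and never 0", {
  fm <- generate_feature_matrix(8, 15, class_effect = 4, seed = 17)
  pv <- permutation_validate(log(fm$x), fm$subject, fm$class,
                             n_perm = 99, seed = 18)
  expect_equal(pv$p, 0.01)
  expect_true(all(pv$perm_stats < pv$observed))

  null <- generate_feature_matrix(8, 15, class_effect = 0, seed = 19)
  pn <- permutation_validate(log(null$x), null$subject, null$class,
                             n_perm = 39, seed = 20)
  expect_gt(pn$p, 0)
  expect_lte(pn$p, 1)
})
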