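test_that("K = 1 reduces to the closed-form Gaussian MLE", {
  set.seed(1)
  x <- cbind(rnorm(50, 2), rnorm(50, -1, 2))
  fit <- fit_em(x, 1, seed = 1)
  expect_equal(fit$means[1, ], colMeans(x), tolerance = 1e-12)
  expect_equal(fit$covariances[, , 1], cov(x) * 49 / 50, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$weights, 1)
})

test_that("well-separated blobs are recovered exactly up to label permutation", {
  set.seed(2)
  x <- rbind(cbind(rnorm(80, 0), rnorm(80, 0)),
             cbind(rnorm(70, 10), rnorm(70, 8)))
  truth <- rep(1:2, c(80, 70))
  fit <- fit_em(x, 2, seed = 5)
  expect_equal(ari(fit$hard_labels, truth), 1)
})

test_that("EM log-likelihood is non-decreasing within every run", {
  set.seed(3)
  for (i in 1:10) {
    x <- cbind(rnorm(60, sample(0:3, 1)), rnorm(60, 0, sample(1:2, 1)))
    fit <- fit_em(x, 3, seed = i)
    expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$log_likelihood)))
  }
})

test_that("the BIC formula and direction follow the lower-is-better convention", {
  fake <- list(log_likelihood = 0, n_params = 5)
  expect_equal(mixture_bic(fake, exp(1)), 5)
  richer <- list(log_likelihood = 0, n_params = 10)
  expect_gt(mixture_bic(richer, 100), mixture_bic(fake, 100))
  expect_error(mixture_bic(fake, 0), "positive")
  # hand computation for a K = 1 fit: -2*ll + 5*log(n) in 2-D
  set.seed(4)
  x <- cbind(rnorm(10), rnorm(10))
  fit <- fit_em(x, 1)
  mu <- colMeans(x); S <- cov(x) * 9 / 10
  ll_hand <- sum(apply(x, 1, function(r) {
    d <- r - mu
    -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * drop(t(d) %*% solve(S) %*% d)
  }))
  expect_equal(fit$bic, -2 * ll_hand + 5 * log(10), tolerance = 1e-8)
})

test_that("ICL is BIC plus twice the responsibility entropy", {
  fake <- list(log_likelihood = -10, n_params = 11,
               responsibilities = matrix(c(1, 0, 0, 1, 1, 0), 3, 2, byrow = TRUE))
  expect_equal(mixture_icl(fake, 20), mixture_bic(fake, 20))  # hard partition
  fake$responsibilities <- matrix(0.5, 10, 2)
  expect_equal(mixture_icl(fake, 10), mixture_bic(fake, 10) + 2 * 10 * log(2))
  # entropy is non-negative, so ICL >= BIC on real fits
  set.seed(5)
  x <- cbind(rnorm(100), rnorm(100))
  fit <- fit_em(x, 3, seed = 6)
  expect_gte(fit$icl, fit$bic)
})

test_that("reported criteria are invariant to component relabeling", {
  set.seed(6)
  x <- rbind(cbind(rnorm(60), rnorm(60)), cbind(rnorm(60, 6), rnorm(60, 6)))
  fit <- fit_em(x, 2, seed = 7)
  perm <- c(2, 1)
  permuted <- fit
  permuted$weights <- fit$weights[perm]
  permuted$means <- fit$means[perm, ]
  permuted$covariances <- fit$covariances[, , perm]
  permuted$responsibilities <- fit$responsibilities[, perm]
  expect_equal(mixture_bic(permuted, fit$n), fit$bic)
  expect_equal(mixture_icl(permuted, fit$n), fit$icl)
})

test_that("fits are deterministic given a seed", {
  set.seed(8)
  x <- cbind(rnorm(120), rnorm(120))
  f1 <- fit_em(x, 3, seed = 42)
  f2 <- fit_em(x, 3, seed = 42)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$hard_labels, f2$hard_labels)
})

test_that("final log-likelihood matches an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(9)
  for (i in 1:8) {
    x <- rbind(cbind(rnorm(70, 0), rnorm(70, 0)),
               cbind(rnorm(60 + i, 6), rnorm(60 + i, 5, 0.8)))
    fit <- fit_em(x, 2, seed = i, tol = 1e-9)
    ref <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
    expect_lt(abs(fit$log_likelihood - ref$loglik), 1e-3)
    expect_equal(ari(fit$hard_labels, ref$classification), 1)
  }
})

test_that("planted component means are recovered within 0.5 Mahalanobis units", {
  for (s in 1:20) {
    set.seed(s)
    mu1 <- c(0, 0); mu2 <- c(5, 4)
    x <- rbind(cbind(rnorm(500, mu1[1]), rnorm(500, mu1[2])),
               cbind(rnorm(500, mu2[1], 1.5), rnorm(500, mu2[2], 0.8)))
    fit <- fit_em(x, 2, seed = s, n_restarts = 4)
    # match components to planted means by proximity
    ord <- order(fit$means[, 1])
    d1 <- sqrt(drop(t(fit$means[ord[1], ] - mu1) %*%
                      solve(diag(2), fit$means[ord[1], ] - mu1)))
    S2 <- diag(c(1.5^2, 0.8^2))
    d2 <- sqrt(drop(t(fit$means[ord[2], ] - mu2) %*%
                      solve(S2, fit$means[ord[2], ] - mu2)))
    expect_lt(d1, 0.5); expect_lt(d2, 0.5)
  }
})

test_that("model selection scans the K range and penalises overfitting", {
  set.seed(10)
  # one tight blob: adding components only adds parameters
  x <- cbind(rnorm(150, 0, 0.5), rnorm(150, 0, 0.5))
  sel <- suppressMessages(select_model(x, 4:7, seed = 3))
  expect_identical(sel$table$K, 4:7)
  expect_identical(nrow(sel$table), 4L)
  fit1 <- fit_em(x, 1, seed = 3)
  expect_true(all(sel$table$BIC > fit1$bic))
  expect_error(select_model(x, integer(0), seed = 1), "empty")
  expect_error(select_model(x[1:5, ], 4:7, seed = 1), "more observations")
})

test_that("confidence ellipses follow the chi-squared geometry", {
  # identity covariance: circle with radius sqrt(chi2 quantile) ~ 2.4477
  e <- confidence_ellipse(c(0, 0), diag(2))
  expect_equal(e$axes, rep(sqrt(qchisq(0.95, 2)), 2), tolerance = 1e-9)
  expect_equal(e$axes[1], 2.4477, tolerance = 1e-4)
  # diagonal covariance (4, 1): axis ratio 2, rotation 0 (mod 180)
  e2 <- confidence_ellipse(c(1, 2), diag(c(4, 1)))
  expect_equal(e2$axes[1] / e2$axes[2], 2, tolerance = 1e-9)
  expect_true(abs(e2$rotation) %in% c(0, 180) ||
                abs(abs(e2$rotation) - 180) < 1e-9)
  # level -> 0 shrinks the axes to zero
  e3 <- confidence_ellipse(c(0, 0), diag(2), level = 1e-12)
  expect_lt(max(e3$axes), 1e-5)
  expect_error(confidence_ellipse(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  pts <- ellipse_points(e2, 64)
  expect_identical(dim(pts), c(64L, 2L))
  # all points satisfy the quadratic form at the confidence level
  q <- apply(sweep(pts, 2, c(1, 2)), 1, function(v)
    drop(t(v) %*% solve(diag(c(4, 1)), v)))
  expect_equal(q, rep(qchisq(0.95, 2), 64), tolerance = 1e-9)
})
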