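test_that("cluster and scenario validation enforce the documented invariants", {
  expect_error(cluster_spec(1, c(-20, 0.9), matrix(c(1, 2, 2, 1), 2), 0.5),
               "positive semi-definite")
  expect_error(cluster_spec(1, c(-20, 0.9), matrix(c(1, 0.5, 0.2, 1), 2), 0.5),
               "symmetric")
  expect_error(cluster_spec(1, c(-20, 1.2), diag(2), 0.5), "limb-length mean")
  expect_error(cluster_spec(1, c(-20, 0.9), diag(2), 0.5,
                            list(nonesuch = 1)), "unknown clinical variable")
  good <- cluster_spec(1, c(-20, 0.9), diag(c(1, 1e-4)), 1)
  expect_error(gait_scenario(list(good), n_participants = 5, seed = NULL),
               "seed is mandatory")
  half <- cluster_spec(1, c(-20, 0.9), diag(c(1, 1e-4)), 0.5)
  expect_error(gait_scenario(list(half), n_participants = 5, seed = 1),
               "sum to 1")
})

test_that("degenerate mixtures sample exactly as specified", {
  # zero covariance: every draw is exactly the mean
  sc <- gait_scenario(list(cluster_spec(1, c(-15, 0.95), matrix(0, 2, 2), 1)),
                      n_participants = 5, seed = 3)
  f <- sample_features(sc)
  expect_equal(f$limb_angle_ext, rep(-15, 5))
  expect_equal(f$limb_length, rep(0.95, 5))
  # degenerate weights: all participants from the unit-weight cluster
  sc2 <- gait_scenario(list(
    cluster_spec(1, c(-15, 0.9), diag(c(1, 1e-4)), 1),
    cluster_spec(2, c(-30, 0.8), diag(c(1, 1e-4)), 0),
    cluster_spec(3, c(-5, 0.7), diag(c(1, 1e-4)), 0)),
    n_participants = 30, seed = 4)
  expect_true(all(sample_features(sc2)$cluster_truth == 1))
})

test_that("sampling is reproducible and converges to the planted moments", {
  sc <- test_scenario(11L)
  expect_identical(sample_features(sc), sample_features(sc))
  # law of large numbers at n = 1e4 in a single cluster: within 2%
  big <- gait_scenario(list(cluster_spec(1, c(-20, 0.9),
                                         diag(c(2^2, 0.012^2)), 1)),
                       n_participants = 1e4, seed = 8)
  f <- sample_features(big)
  expect_lt(abs(mean(f$limb_angle_ext) - (-20)) / 20, 0.02)
  expect_lt(abs(mean(f$limb_length) - 0.9) / 0.9, 0.02)
  expect_lt(abs(sd(f$limb_angle_ext) - 2) / 2, 0.05)
  # per-cluster means within 3 standard errors in the default mixture
  sc5 <- default_scenario(n_participants = 670, seed = 9)
  f5 <- sample_features(sc5)
  for (cl in sc5$clusters) {
    sub <- f5[f5$cluster_truth == cl$label, ]
    se <- sqrt(diag(cl$covariance)) / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$limb_angle_ext) - cl$mean[1]), 3.5 * se[1])
    expect_lt(abs(mean(sub$limb_length) - cl$mean[2]), 3.5 * se[2])
  }
})

test_that("walk synthesis rejects infeasible feature pairs", {
  sc <- test_scenario()
  expect_error(make_walk(-20, 1.02), "infeasible")
  expect_error(make_walk(-20, 0.4), "outside")
  expect_error(make_walk(5, 0.9), "outside")
  expect_error(make_walk(-70, 0.9), "outside")
})

test_that("a nearly vertical extension peak round-trips to about zero", {
  ks <- make_walk(-0.001, 0.9)
  f <- analyze_walk(ks)
  expect_lt(abs(f$limb_angle_ext_peak), 0.1)
})

test_that("walks carry ground-truth events and planted attributes", {
  ks <- make_walk(-25, 0.85)
  expect_s3_class(ks, "keypoint_series")
  expect_gt(length(ks$events$heel_contacts), 15)
  expect_true(all(diff(ks$events$heel_contacts) > 0))
  expect_equal(unname(attr(ks, "planted")), c(-25, 0.85))
})

test_that("keypoint noise perturbs features but preserves participant ranking", {
  sc <- test_scenario(21L)
  angles <- seq(-45, -6, length.out = 12)
  get_feats <- function(noise) {
    set.seed(500)
    vapply(angles, function(a) {
      ks <- synthesize_walk(list(limb_angle_ext = a, limb_length = 0.9), sc,
                            stride_period = 1.1, noise_sd_px = noise)
      suppressWarnings(analyze_walk(ks))$limb_angle_ext_peak
    }, numeric(1))
  }
  f0 <- get_feats(0); f2 <- get_feats(2)
  expect_false(isTRUE(all.equal(f0, f2)))
  expect_gt(cor(f0, f2, method = "spearman"), 0.95)
})

test_that("clinical scores are bounded, cluster-shifted, and exchangeable under the null", {
  sc <- default_scenario(n_participants = 250, seed = 31)
  f <- sample_features(sc)
  cli <- sample_clinical(f, sc)
  scales <- clinical_scales()
  for (j in seq_len(nrow(scales))) {
    v <- cli[[scales$variable[j]]]
    expect_true(all(v >= scales$min[j] & v <= scales$max[j]))
  }
  # the large positive MAS shift in cluster 1 makes its median maximal
  meds <- tapply(cli$mas, cli$cluster_truth, median)
  expect_identical(names(which.max(meds)), "1")
  # no values escape the scale bounds across many draws
  big <- gait_scenario(list(cluster_spec(1, c(-20, 0.9), diag(c(1, 1e-4)), 1,
                                         list(fms = 3))),
                       n_participants = 1e4, seed = 32)
  cli_big <- sample_clinical(sample_features(big), big)
  expect_true(all(cli_big$fms >= 0 & cli_big$fms <= 22))
  # zero planted effects: Kruskal-Wallis p-values roughly uniform
  sc0 <- default_scenario(n_participants = 67, seed = 33)
  sc0$clusters <- lapply(sc0$clusters, function(cl) {
    cl$clinical_effects <- list(); cl
  })
  set.seed(34)
  w <- vapply(sc0$clusters, `[[`, numeric(1), "weight")
  p <- replicate(400, {
    lab <- sample.int(5, 67, TRUE, prob = w)
    y <- rbinom(67, 28, 0.75)
    kruskal_wallis(y, lab)$p
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("scenarios round-trip through YAML", {
  sc <- default_scenario(seed = 77)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    seed = 77, n_participants = 67,
    clusters = lapply(sc$clusters, function(cl) list(
      label = cl$label, mean = cl$mean,
      covariance = as.numeric(t(cl$covariance)),
      weight = cl$weight, clinical_effects = cl$clinical_effects))), path)
  sc2 <- read_scenario_yaml(path)
  expect_identical(sample_features(sc), sample_features(sc2))
  yaml::write_yaml(list(n_participants = 5), path)
  expect_error(read_scenario_yaml(path), "seed")
})
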