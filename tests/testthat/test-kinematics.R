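test_that("limb angle follows the flexion-positive sign convention", {
  expect_equal(limb_angle(c(0, 1), c(0, 0)), 0)
  # direct trigonometry: atan(0.5 / 1)
  expect_equal(limb_angle(c(0, 1), c(0.5, 0)), atan(0.5) * 180 / pi,
               tolerance = 1e-10)
  expect_equal(limb_angle(c(0, 1), c(0.5, 0)), 26.5650512, tolerance = 1e-6)
  # mirror symmetry: posterior ankle gives the negated angle
  expect_equal(limb_angle(c(0, 1), c(-0.5, 0)), -26.5650512, tolerance = 1e-6)
  expect_error(limb_angle(c(1, 1), c(1, 1)), "coincide")
})

test_that("effective limb length is the hip-ankle over thigh+shank ratio", {
  expect_equal(limb_length(c(0, 1), c(0, 0.5), c(0, 0)), 1.0)
  # sqrt(0.5) / (0.5 + 0.5) by direct computation
  expect_equal(limb_length(c(0, 1), c(0, 0.5), c(0.5, 0.5)),
               sqrt(0.5), tolerance = 1e-10)
  # any knee flexion shortens the ratio below 1
  expect_lt(limb_length(c(0, 1), c(0.2, 0.5), c(0, 0)), 1)
  expect_error(limb_length(c(0, 1), c(0, 1), c(0, 0)), "coincident")
})

test_that("limb geometry is invariant under similarity transforms", {
  set.seed(11)
  for (i in 1:25) {
    hip <- rnorm(2); knee <- hip + rnorm(2, sd = 0.5); ankle <- knee + rnorm(2, sd = 0.5)
    len0 <- limb_length(hip, knee, ankle)
    ang0 <- limb_angle(hip, ankle)
    # translation + uniform scaling (angle and length both invariant)
    shift <- rnorm(2); s <- exp(rnorm(1))
    expect_equal(limb_length(s * hip + shift, s * knee + shift, s * ankle + shift),
                 len0, tolerance = 1e-9)
    expect_equal(limb_angle(s * hip + shift, s * ankle + shift), ang0,
                 tolerance = 1e-9)
    # rotation: length invariant
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(limb_length(as.numeric(R %*% hip), as.numeric(R %*% knee),
                             as.numeric(R %*% ankle)), len0,
                 tolerance = 1e-9)
    # reflection about the vertical axis flips the angle sign
    refl <- function(p) c(-p[1], p[2])
    expect_equal(limb_angle(refl(hip), refl(ankle)), -ang0, tolerance = 1e-9)
  }
})

test_that("zero-lag Butterworth filter matches its magnitude response", {
  fs <- 120
  # DC gain 1: constant passes unchanged
  expect_equal(lowpass_filter(rep(5, 400), fs), rep(5, 400), tolerance = 1e-9)
  t <- seq(0, 4, by = 1 / fs)
  mid <- 150:330
  # 1 Hz well below the 6 Hz cutoff: attenuation < 1%
  y1 <- lowpass_filter(sin(2 * pi * 1 * t), fs)
  expect_gt(max(abs(y1[mid])), 0.99)
  # 30 Hz far above cutoff: attenuation > 99%
  y30 <- lowpass_filter(sin(2 * pi * 30 * t), fs)
  expect_lt(max(abs(y30[mid])), 0.01)
  expect_error(lowpass_filter(rnorm(10), fs), "warm-up")
  expect_error(lowpass_filter(rnorm(100), fs, cutoff_hz = 60), "Nyquist")
})

test_that("differentiation is exact on polynomials and accurate on sinusoids", {
  fs <- 120
  t <- seq(0, 2, by = 1 / fs)
  expect_equal(differentiate(5 * t, fs), rep(5, length(t)), tolerance = 1e-9)
  expect_equal(differentiate(rep(3, 100), fs), rep(0, 100))
  # analytic derivative of sin(2 pi t) is 2 pi cos(2 pi t)
  d <- differentiate(sin(2 * pi * t), fs)
  interior <- 10:(length(t) - 10)
  expect_lt(max(abs(d[interior] - 2 * pi * cos(2 * pi * t[interior]))) / (2 * pi),
            1e-3)
  expect_error(differentiate(c(1, 2), fs), "at least 3")
})

test_that("cycle normalization is a cubic-spline resampling with exact knots", {
  # a stride spanning exactly 201 frames maps onto itself
  x <- cumsum(rnorm(300))
  out <- normalize_cycles(x, c(50, 250))
  expect_identical(dim(out), c(1L, 201L))
  expect_equal(as.numeric(out), x[50:250], tolerance = 1e-9)
  # linear series stay linear under cubic-spline resampling
  lin <- 0.5 * seq_len(400)
  out2 <- normalize_cycles(lin, c(10, 143, 276))
  expect_equal(out2[1, ], seq(lin[10], lin[143], length.out = 201),
               tolerance = 1e-9)
  # sinusoid: interpolation error far below 1e-3 of amplitude at 120 Hz
  t <- seq(0, 3, by = 1 / 120)
  s <- sin(2 * pi * t)
  out3 <- normalize_cycles(s, c(1, 121, 241))
  truth <- sin(2 * pi * (seq(0, 120, length.out = 201)) / 120)
  expect_lt(max(abs(out3[1, ] - truth)), 1e-3)
  # endpoints preserved exactly
  expect_equal(out3[1, 1], s[1]); expect_equal(out3[1, 201], s[121])
  expect_warning(normalize_cycles(x, c(10, 12, 200)), "dropped")
  expect_error(normalize_cycles(x, c(200, 100)), "strictly increasing")
})

test_that("gait events are rejected on flat input and periodic on periodic input", {
  expect_error(detect_gait_events(rep(0, 500), 120), "no strides")
  ks <- make_walk(-20, 0.9)
  kin <- limb_kinematics(ks)
  ev <- detect_gait_events(kin$shank_angular_velocity, 120)
  # identical strides: heel contacts exactly one stride period apart
  expect_true(all(abs(diff(ev$heel_contacts) - 132) <= 1))
  # events alternate: exactly one toe off inside each stride
  for (i in seq_len(length(ev$heel_contacts) - 1)) {
    inside <- sum(ev$toe_offs > ev$heel_contacts[i] &
                    ev$toe_offs < ev$heel_contacts[i + 1])
    expect_identical(inside, 1L)
  }
})

test_that("detected heel contacts match generator ground truth within 2 frames", {
  for (case in list(c(-30, 0.95), c(-10, 0.88), c(-45, 0.70))) {
    ks <- make_walk(case[1], case[2])
    kin <- limb_kinematics(ks)
    ev <- detect_gait_events(kin$shank_angular_velocity, 120)
    err <- vapply(ev$heel_contacts,
                  function(h) min(abs(h - ks$events$heel_contacts)), numeric(1))
    expect_lte(max(err), 2)
  }
})

test_that("feature extraction trims, averages, and derives gait parameters", {
  # hand-built stride set: 16 strides with known per-stride minima
  fake <- structure(list(
    heel_contacts = seq(1, by = 120, length.out = 17),
    toe_offs = seq(73, by = 120, length.out = 16),
    stride_index = 1:16,
    stride_frames = rep(120, 16),
    angle_min = -(10:25), length_min_swing = rep(0.9, 16),
    hip_x_hc = seq(0, by = 1000, length.out = 17),
    sampling_rate = 120, n_strides = 16L), class = "stride_set")
  f <- extract_features(fake, trim = 3, n_keep = 10, meters_per_pixel = 1e-3)
  # strides 4..13 retained: mean of -(13:22)
  expect_equal(f$limb_angle_ext_peak, mean(-(13:22)))
  expect_identical(f$n_strides_used, 10L)
  # 120-frame strides at 120 Hz: 1 s periods, 2 steps each -> 120 steps/min
  expect_equal(f$cadence, 120)
  # 1000 px/stride at 1e-3 m/px -> 1 m/s; ratio = 120 / 60 = 2 steps/m
  expect_equal(f$gait_speed, 1.0)
  expect_equal(f$gait_stability_ratio, 2.0)
  fake$n_strides <- 6L
  expect_error(extract_features(fake, trim = 3), "at least 7")
})

test_that("explicit stride minima average as stated", {
  fake <- structure(list(
    heel_contacts = seq(1, by = 120, length.out = 11),
    toe_offs = seq(73, by = 120, length.out = 10),
    stride_index = 1:10, stride_frames = rep(120, 10),
    angle_min = -(10:19), length_min_swing = rep(0.85, 10),
    hip_x_hc = seq(0, by = 900, length.out = 11),
    sampling_rate = 120, n_strides = 10L), class = "stride_set")
  f <- extract_features(fake, trim = 0, n_keep = 10)
  expect_equal(f$limb_angle_ext_peak, -14.5)
  expect_true(is.na(f$gait_speed))
})

test_that("noise-free round trip recovers planted features", {
  for (case in list(c(-20, 0.90), c(-35, 0.96), c(-8, 0.75))) {
    ks <- make_walk(case[1], case[2])
    f <- analyze_walk(ks)
    expect_lt(abs(f$limb_angle_ext_peak - case[1]), 0.5)
    expect_lt(abs(f$limb_length_min_swing - case[2]), 0.005)
  }
})

test_that("keypoint noise leaves only a small feature bias", {
  # regression guard at the scale of markerless-capture jitter
  sc <- test_scenario(7L)
  set.seed(123)
  errs_a <- errs_l <- numeric(40)
  for (i in 1:40) {
    a <- runif(1, -40, -5); l <- runif(1, 0.7, 0.97)
    ks <- synthesize_walk(list(limb_angle_ext = a, limb_length = l), sc,
                          stride_period = 1.1, noise_sd_px = 2)
    f <- suppressWarnings(analyze_walk(ks))
    errs_a[i] <- f$limb_angle_ext_peak - a
    errs_l[i] <- f$limb_length_min_swing - l
  }
  expect_lt(abs(mean(errs_a)), 1)
  expect_lt(abs(mean(errs_l)), 0.01)
})
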