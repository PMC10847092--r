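#' Define one mixture component of a synthetic cohort
#'
#' @param label cluster id (integer or character).
#' @param mean length-2 numeric: (limb extension angle in degrees, negative in
#'   extension; effective limb length, dimensionless in (0, 1\]).
#' @param covariance 2 x 2 symmetric positive semi-definite matrix.
#' @param weight mixing proportion in \[0, 1\].
#' @param clinical_effects named list of location shifts (logit scale) applied
#'   to that cluster's clinical score distributions; names must be clinical
#'   variables known to [clinical_scales()].
#' @return object of class `cluster_spec`.
#' @export
cluster_spec <- function(label, mean, covariance, weight,
                         clinical_effects = list()) {
  mean <- as.numeric(mean)
  if (length(mean) != 2L) stop("cluster mean must have length 2")
  covariance <- as.matrix(covariance)
  if (!all(dim(covariance) == 2L)) stop("covariance must be 2 x 2")
  if (max(abs(covariance - t(covariance))) > 1e-8) {
    stop("covariance must be symmetric")
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop(sprintf("cluster %s: covariance is not positive semi-definite (min eigenvalue %.3g)",
                 label, min(ev)))
  }
  if (!(weight >= 0 && weight <= 1)) stop("weight must be in [0, 1]")
  if (!(mean[2] > 0 && mean[2] <= 1)) stop("limb-length mean must be in (0, 1]")
  unknown <- setdiff(names(clinical_effects), clinical_scales()$variable)
  if (length(unknown)) {
    stop("unknown clinical variable(s) in clinical_effects: ",
         paste(unknown, collapse = ", "))
  }
  structure(list(label = label, mean = mean, covariance = covariance,
                 weight = weight, clinical_effects = clinical_effects),
            class = "cluster_spec")
}

#' Define a synthetic cohort scenario
#'
#' A scenario bundles the mixture components and the recording conditions a
#' synthetic cohort is generated under: cohort size, video sampling rate,
#' strides per trial, stride-period distribution and keypoint jitter.
#'
#' @param clusters list of [cluster_spec()] objects; weights must sum to 1.
#' @param n_participants cohort size (at least the number of clusters).
#' @param sampling_rate video sampling rate in Hz (default 120).
#' @param n_strides complete strides generated per participant (default 16,
#'   so 10 usable strides remain after trimming 3 from each end).
#' @param stride_period_mean,stride_period_sd stride period distribution
#'   across participants, seconds.
#' @param noise_sd_px isotropic Gaussian keypoint jitter, pixels (default 1
#'   at the nominal 1000 px leg length).
#' @param leg_length_px total hip-to-ankle leg length in pixels when fully
#'   extended (thigh and shank each half of it).
#' @param meters_per_pixel calibration used for synthetic gait speed.
#' @param seed integer seed; mandatory, all sampling is derived from it.
#' @return object of class `gait_scenario`.
#' @export
gait_scenario <- function(clusters, n_participants, sampling_rate = 120,
                          n_strides = 16L, stride_period_mean = 1.1,
                          stride_period_sd = 0.08, noise_sd_px = 1,
                          leg_length_px = 1000, meters_per_pixel = 9e-4,
                          seed) {
  if (missing(seed) || is.null(seed)) stop("scenario seed is mandatory")
  if (!all(vapply(clusters, inherits, logical(1), "cluster_spec"))) {
    stop("clusters must be a list of cluster_spec objects")
  }
  w <- vapply(clusters, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-6) stop("cluster weights must sum to 1")
  ## renormalise exactly (configs often carry weights at limited precision)
  for (i in seq_along(clusters)) clusters[[i]]$weight <- w[i] / sum(w)
  if (n_participants < length(clusters)) {
    stop("n_participants must be at least the number of clusters")
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (stride_period_mean <= 0) stop("stride_period_mean must be positive")
  structure(list(clusters = clusters, n_participants = as.integer(n_participants),
                 sampling_rate = sampling_rate, n_strides = as.integer(n_strides),
                 stride_period_mean = stride_period_mean,
                 stride_period_sd = stride_period_sd,
                 noise_sd_px = noise_sd_px, leg_length_px = leg_length_px,
                 meters_per_pixel = meters_per_pixel,
                 seed = as.integer(seed)),
            class = "gait_scenario")
}

#' @export
print.gait_scenario <- function(x, ...) {
  cat(sprintf("<gait_scenario> %d participants, %d clusters, %g Hz, seed %d\n",
              x$n_participants, length(x$clusters), x$sampling_rate, x$seed))
  for (cl in x$clusters) {
    cat(sprintf("  cluster %s: angle %.1f deg, length %.3f, weight %.3f\n",
                cl$label, cl$mean[1], cl$mean[2], cl$weight))
  }
  invisible(x)
}

#' Default five-cluster scenario
#'
#' Ships a five-component scenario whose component layout mirrors the
#' qualitative structure reported for post-stroke cohorts: in
#' (extension-angle magnitude x limb length) space, components sit at
#' high/high, mid/high, low/high, high/low and mid/low. Means are
#' illustrative, not estimated from any dataset. Mixing weights follow the
#' 10/17/11/10/19 cluster sizes of a 67-participant cohort. Cluster-level
#' clinical shifts encode the qualitative clinical profile of each group
#' (e.g. higher plantar-flexor spasticity in the high-limb-length clusters,
#' reduced balance in clusters 2-3, mild profiles in 4-5).
#'
#' @param n_participants cohort size (default 67).
#' @param seed integer seed.
#' @param ... overrides passed to [gait_scenario()].
#' @return a [gait_scenario()].
#' @export
default_scenario <- function(n_participants = 67L, seed = 1L, ...) {
  cl <- list(
    cluster_spec(1L, c(-29, 0.960), diag(c(2.5^2, 0.010^2)), 10 / 67,
                 list(fms = -1.0, mas = 1.5, sf_bbs = 0.5)),
    cluster_spec(2L, c(-18, 0.945), diag(c(1.8^2, 0.010^2)), 17 / 67,
                 list(mas = 1.2, sf_bbs = -1.0)),
    cluster_spec(3L, c(-7, 0.935), diag(c(1.8^2, 0.012^2)), 11 / 67,
                 list(fms = -1.5, mas = 1.2, sf_bbs = -1.5)),
    cluster_spec(4L, c(-27, 0.855), diag(c(1.8^2, 0.012^2)), 10 / 67,
                 list(fms = 0.5, mas = -0.8, sf_bbs = 0.8)),
    cluster_spec(5L, c(-15, 0.845), diag(c(1.8^2, 0.012^2)), 19 / 67,
                 list(fms = 0.5, mas = -1.2, sf_bbs = 0.5))
  )
  gait_scenario(cl, n_participants = n_participants, seed = seed, ...)
}

## factor A with S = A %*% t(A) for a symmetric PSD matrix (handles the
## zero-variance degenerate case the Cholesky cannot)
psd_factor <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-10 * max(abs(e$values), 1)) {
    stop("covariance is not positive semi-definite")
  }
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = 2L)
}

#' Sample participant features from a scenario's mixture
#'
#' Draws each participant's (limb extension angle, limb length) pair from its
#' cluster's bivariate Gaussian and records the generating cluster. Samples
#' outside the feasible feature region (angle in (-60, 0) degrees, length in
#' (0.5, 1\]) are rejected and redrawn, so the planted pairs can always be
#' realized as walks.
#'
#' @param scenario a [gait_scenario()].
#' @return data.frame with columns `participant`, `limb_angle_ext`,
#'   `limb_length`, `cluster_truth`. Deterministic given the scenario seed.
#' @export
sample_features <- function(scenario) {
  stopifnot(inherits(scenario, "gait_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_participants
  K <- length(scenario$clusters)
  w <- vapply(scenario$clusters, `[[`, numeric(1), "weight")
  z <- sample.int(K, n, replace = TRUE, prob = w)
  A <- lapply(scenario$clusters, function(cl) psd_factor(cl$covariance))
  out <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    cl <- scenario$clusters[[z[i]]]
    for (try in 1:100) {
      x <- cl$mean + as.numeric(A[[z[i]]] %*% rnorm(2))
      if (x[1] > -60 && x[1] < 0 && x[2] > 0.5 && x[2] <= 1) break
      x <- NULL
    }
    if (is.null(x)) {
      stop(sprintf("cluster %s: could not draw a feasible feature pair; check its mean/covariance",
                   cl$label))
    }
    out[i, ] <- x
  }
  data.frame(
    participant = sprintf("P%03d", seq_len(n)),
    limb_angle_ext = out[, 1L],
    limb_length = out[, 2L],
    cluster_truth = vapply(scenario$clusters, `[[`, numeric(1), "label")[z]
  )
}

## closed-form gait profiles used by the walk generator, phase in [0, 1),
## heel contact nominally at phase 0, extension peak at phase 0.5
synth_profiles <- function(theta_ext_deg, r_min,
                           theta_flex_deg = 25, curve_b = 2,
                           ext_center = 0.58,
                           swing_center = 0.78, swing_width = 0.11,
                           lr_center = 0.08, lr_rise_width = 0.07,
                           lr_fall_width = 0.14,
                           lr_amp_deg = NULL, swing_amp = NULL) {
  A <- (theta_flex_deg - theta_ext_deg - 4 * curve_b) / 2
  H_sw <- swing_amp %||% acos(r_min)
  ## braking-wave amplitude grows with the limb-angle excursion so the
  ## heel-contact dip survives low-pass filtering even for strong extenders,
  ## while mild walks keep a small wave (no spurious rebound peak)
  H_lr <- deg2rad(lr_amp_deg %||% min(11, 5 + A / 6))
  list(
    theta = function(phi) {
      x <- 2 * pi * (wrap_phase(phi) - ext_center)
      deg2rad(theta_ext_deg + A * (1 - cos(x)) + curve_b * (1 - cos(x))^2)
    },
    ## loading-response knee flexion is skewed: a steep rise produces the
    ## post-swing braking dip of shank angular velocity that marks heel
    ## contact, while the gentle fall keeps the rebound below the event
    ## detector's prominence threshold
    half_knee = function(phi) {
      d <- wrap_phase(phi - lr_center)
      d <- ifelse(d > 0.5, d - 1, d)
      w <- ifelse(d < 0, lr_rise_width, lr_fall_width)
      H_sw * exp(-(phase_dist(phi, swing_center) / swing_width)^2) +
        H_lr * exp(-(d / w)^2)
    }
  )
}

## The 6 Hz zero-lag low-pass of the analysis stage slightly attenuates the
## swing-phase limb-length dip, so an uncalibrated dip would be recovered a
## few thousandths too shallow. The generator therefore tunes the swing
## knee-flexion amplitude until the *filtered* limb-length minimum over the
## swing window equals the planted value (solved by root finding on a
## replicated noise-free cycle).
calibrate_swing_amp <- function(theta_ext_deg, r_min, T_s, fs,
                                cutoff_hz = 6, order = 4) {
  filtered_min <- function(H) {
    prof <- synth_profiles(theta_ext_deg, r_min, swing_amp = H)
    nfr <- round(7 * T_s * fs)
    phi <- (0:(nfr - 1L)) / (T_s * fs)
    r <- cos(prof$half_knee(phi))
    rf <- lowpass_filter(r, fs, cutoff_hz, order)
    min(rf[phi >= 3.55 & phi <= 4.05])
  }
  H0 <- acos(r_min)
  res <- tryCatch(
    stats::uniroot(function(H) filtered_min(H) - r_min,
                   interval = c(max(0, H0 - 0.02), min(pi / 2 - 0.01, H0 + 0.35)),
                   extendInt = "downX", tol = 1e-6),
    error = function(e) NULL)
  if (is.null(res)) H0 else res$root
}

## locate the generator's ground-truth event phases from the analytic shank
## angle on a fine grid (independent of the sampled/filtered detector path)
synth_event_phases <- function(prof) {
  np <- 10000L
  phi <- (0:(np - 1L)) / np
  psi <- prof$theta(phi) - prof$half_knee(phi)
  ## periodic derivative with respect to phase, central differences
  dpsi <- (psi[c(2:np, 1L)] - psi[c(np, 1:(np - 1L))]) * np / 2
  pk <- which.max(dpsi)
  prv <- c(dpsi[np], dpsi[1:(np - 1L)])
  nxt <- c(dpsi[2:np], dpsi[1L])
  mins <- which(dpsi < prv & dpsi <= nxt)
  if (length(mins) == 0L) stop("degenerate profile: no shank angular velocity minima")
  fwd <- wrap_phase((mins - pk) / np); fwd[fwd == 0] <- 1
  bwd <- wrap_phase((pk - mins) / np); bwd[bwd == 0] <- 1
  list(hc = (mins[which.min(fwd)] - 1L) / np,
       to = (mins[which.min(bwd)] - 1L) / np)
}

#' Synthesize a walking trial with planted limb kinematics
#'
#' Builds a smooth periodic hip/knee/ankle trajectory whose extracted
#' features equal the planted values: the hip translates forward at constant
#' mean speed (plus a small sinusoidal bob), the limb angle follows a smooth
#' two-harmonic cycle whose extension peak equals the planted angle, and the
#' swing-phase knee flexion is scaled so the minimum effective limb length
#' equals the planted length. A small loading-response knee-flexion bump just
#' after ground contact reproduces the physiological post-swing minimum of
#' shank angular velocity that gait-event detectors key on. Isotropic
#' Gaussian keypoint noise is added per frame and ground-truth event frames
#' are stored in the result.
#'
#' @param features_row list or one-row data.frame with `limb_angle_ext`
#'   (degrees, in (-60, 0)) and `limb_length` (in (0.5, 1\]).
#' @param scenario a [gait_scenario()] providing the recording conditions.
#' @param stride_period optional stride period in seconds; drawn from the
#'   scenario's distribution (current RNG stream) when NULL.
#' @param noise_sd_px keypoint jitter; defaults to the scenario's value.
#' @return a [keypoint_series()] with ground-truth `events` and attributes
#'   `planted` (the feature pair) and `stride_period`.
#' @export
synthesize_walk <- function(features_row, scenario, stride_period = NULL,
                            noise_sd_px = NULL) {
  stopifnot(inherits(scenario, "gait_scenario"))
  th <- as.numeric(features_row$limb_angle_ext)
  rmin <- as.numeric(features_row$limb_length)
  if (!(th > -60 && th < 0)) {
    stop(sprintf("planted limb extension angle %.2f outside (-60, 0) degrees", th))
  }
  if (rmin > 1) stop("infeasible planted limb length > 1")
  if (!(rmin > 0.5)) stop(sprintf("planted limb length %.3f outside (0.5, 1]", rmin))
  noise_sd_px <- noise_sd_px %||% scenario$noise_sd_px
  T_s <- stride_period %||%
    max(0.6, rnorm(1, scenario$stride_period_mean, scenario$stride_period_sd))
  fs <- scenario$sampling_rate
  L <- scenario$leg_length_px
  prof <- synth_profiles(th, rmin,
                         swing_amp = calibrate_swing_amp(th, rmin, T_s, fs))

  nfr <- round((scenario$n_strides + 1.5) * T_s * fs)
  t <- (0:(nfr - 1L)) / fs
  phi0 <- 0.3                      # start mid-stance so the first heel contact is early
  phi <- t / T_s + phi0
  theta <- prof$theta(phi)
  h <- prof$half_knee(phi)
  alpha <- theta + h               # thigh angle
  d <- L * cos(h)                  # hip-ankle distance; ratio cos(h) by construction

  v <- L * (sin(deg2rad(abs(th))) + sin(deg2rad(25))) / T_s
  hip <- cbind(v * t + 6 * sin(2 * pi * phi),
               1.05 * L + 12 * sin(4 * pi * phi))
  knee <- hip + (L / 2) * cbind(sin(alpha), -cos(alpha))
  ankle <- hip + d * cbind(sin(theta), -cos(theta))
  if (noise_sd_px > 0) {
    hip <- hip + matrix(rnorm(2L * nfr, 0, noise_sd_px), ncol = 2L)
    knee <- knee + matrix(rnorm(2L * nfr, 0, noise_sd_px), ncol = 2L)
    ankle <- ankle + matrix(rnorm(2L * nfr, 0, noise_sd_px), ncol = 2L)
  }

  ph <- synth_event_phases(prof)
  frame_at <- function(event_phase) {
    k <- seq(-2L, scenario$n_strides + 3L)
    fr <- round((k + event_phase - phi0) * T_s * fs) + 1L
    fr[fr >= 1L & fr <= nfr]
  }
  ks <- keypoint_series(
    time = t, hip = hip, knee = knee, ankle = ankle, sampling_rate = fs,
    side = "right",
    events = list(heel_contacts = frame_at(ph$hc), toe_offs = frame_at(ph$to))
  )
  attr(ks, "planted") <- c(limb_angle_ext = th, limb_length = rmin)
  attr(ks, "stride_period") <- T_s
  ks
}

#' Scale registry for the clinical variables
#'
#' Declared ranges of the ordinal clinical scores the pipeline consumes:
#' lower-extremity motor synergy score (`fms`, 0-22), sensory score
#' (`fma_sensory`, 0-12), plantar-flexor spasticity on the converted 0-5
#' scale (`mas`), short-form balance scale (`sf_bbs`, 0-28) and functional
#' ambulation category (`fac`, 0-5).
#'
#' @return data.frame with columns `variable`, `min`, `max`, `baseline_prob`.
#' @export
clinical_scales <- function() {
  data.frame(
    variable = c("fms", "fma_sensory", "mas", "sf_bbs", "fac"),
    min = 0L,
    max = c(22L, 12L, 5L, 28L, 5L),
    baseline_prob = c(0.70, 0.80, 0.30, 0.75, 0.85)
  )
}

#' Sample cluster-conditional clinical scores
#'
#' Ordinal scores are drawn as binomial-discretized variables: for a scale
#' with range 0..m and baseline success probability p, a participant in a
#' cluster with logit shift delta scores Binomial(m, plogis(logit(p) +
#' delta)). Scores are bounded to the scale range by construction.
#'
#' @param features a [sample_features()] table (must carry `cluster_truth`).
#' @param scenario the generating [gait_scenario()].
#' @param seed seed for the clinical draw; defaults to a stream derived from
#'   the scenario seed.
#' @return data.frame with `participant`, `cluster_truth` and one column per
#'   clinical variable.
#' @export
sample_clinical <- function(features, scenario,
                            seed = derive_seed(scenario$seed, 7L)) {
  stopifnot(inherits(scenario, "gait_scenario"))
  if (is.null(features$cluster_truth)) stop("features must contain cluster_truth")
  set.seed(seed)
  scales <- clinical_scales()
  labels <- vapply(scenario$clusters, `[[`, numeric(1), "label")
  shift_of <- function(cluster, var) {
    cl <- scenario$clusters[[match(cluster, labels)]]
    eff <- cl$clinical_effects[[var]]
    if (is.null(eff)) 0 else eff
  }
  out <- data.frame(participant = features$participant,
                    cluster_truth = features$cluster_truth)
  for (j in seq_len(nrow(scales))) {
    var <- scales$variable[j]
    delta <- vapply(features$cluster_truth, shift_of, numeric(1), var = var)
    p <- plogis(qlogis(scales$baseline_prob[j]) + delta)
    out[[var]] <- rbinom(nrow(features), size = scales$max[j], prob = p)
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Draws the feature table, synthesizes one walking trial per participant and
#' draws cluster-conditional clinical scores, all deterministically from the
#' scenario seed.
#'
#' @param scenario a [gait_scenario()].
#' @param walks also synthesize keypoint trajectories (default TRUE).
#' @return list with `features` (planted values), `clinical`, and `walks`
#'   (list of [keypoint_series()], or NULL).
#' @export
simulate_cohort <- function(scenario, walks = TRUE) {
  features <- sample_features(scenario)
  clinical <- sample_clinical(features, scenario)
  walk_list <- NULL
  if (walks) {
    set.seed(derive_seed(scenario$seed, 13L))
    walk_list <- lapply(seq_len(nrow(features)), function(i)
      synthesize_walk(features[i, ], scenario))
    names(walk_list) <- features$participant
  }
  list(features = features, clinical = clinical, walks = walk_list)
}

#' Read a scenario from a YAML configuration
#'
#' Expected layout: top-level `n_participants`, `seed` (mandatory), optional
#' `sampling_rate`, `n_strides`, `stride_period_mean`, `stride_period_sd`,
#' `noise_sd_px`, `leg_length_px`, `meters_per_pixel`, and a `clusters` list
#' whose entries have `label`, `mean` (2 numbers), `covariance` (4 numbers,
#' row-major), `weight` and optional `clinical_effects` mapping.
#'
#' @param path YAML file path.
#' @return a [gait_scenario()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("scenario YAML must declare a seed")
  clusters <- lapply(y$clusters, function(cl) {
    cluster_spec(cl$label, unlist(cl$mean),
                 matrix(unlist(cl$covariance), 2L, 2L, byrow = TRUE),
                 cl$weight, cl$clinical_effects %||% list())
  })
  args <- y[setdiff(names(y), "clusters")]
  args$clusters <- clusters
  do.call(gait_scenario, args)
}
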