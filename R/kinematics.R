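#' Zero-lag low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward so the net
#' phase lag is zero; the bidirectional pass doubles the effective order and
#' squares the magnitude response. Edge transients are controlled by odd
#' (point-symmetric) reflection padding at both ends before filtering, so a
#' constant series passes through unchanged.
#'
#' @param x numeric series, uniformly sampled.
#' @param sampling_rate sampling rate in Hz.
#' @param cutoff_hz cutoff frequency in Hz (default 6). Must be below the
#'   Nyquist frequency.
#' @param order filter order of each directional pass (default 4).
#' @return filtered numeric series, same length as `x`.
#' @export
lowpass_filter <- function(x, sampling_rate, cutoff_hz = 6, order = 4) {
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_rate / 2) {
    stop("cutoff_hz must lie strictly between 0 and the Nyquist frequency")
  }
  n <- length(x)
  ## reflection padding long enough for the filter transient to settle
  npad <- max(3L * (order + 1L), ceiling(3 * sampling_rate / cutoff_hz))
  if (n <= npad) {
    stop(sprintf("series of length %d is shorter than the filter warm-up length (%d)",
                 n, npad + 1L))
  }
  ba <- signal::butter(order, cutoff_hz / (sampling_rate / 2), type = "low")
  ## one directional pass started in steady state at the first sample, so a
  ## constant series passes through bit-exactly
  pass <- function(v) {
    as.numeric(signal::filter(ba, v, init.x = rep(v[1], order),
                              init.y = rep(v[1], order)))
  }
  xp <- c(2 * x[1] - x[(npad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - npad)])
  y <- pass(xp)
  y <- rev(pass(rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Signed limb angle from hip and ankle joint centers
#'
#' Angle of the hip-to-ankle vector measured from the downward vertical in the
#' sagittal plane, in degrees. Positive when the ankle is anterior to the hip
#' (flexion), negative when posterior (extension). Accepts single points
#' (length-2 vectors) or n x 2 matrices.
#'
#' @param hip,ankle 2-D coordinates (x forward, y up).
#' @return numeric vector of angles in degrees.
#' @export
limb_angle <- function(hip, ankle) {
  hip <- rbind_xy(hip)
  ankle <- rbind_xy(ankle)
  v <- ankle - hip
  if (any(rowSums(v^2) == 0)) stop("hip and ankle joint centers coincide")
  rad2deg(atan2(v[, 1], -v[, 2]))
}

#' Effective limb length
#'
#' Hip-to-ankle distance divided by the sum of the hip-to-knee and
#' knee-to-ankle distances. Dimensionless, in (0, 1]; equal to 1 only when
#' the three joints are collinear with the knee between hip and ankle
#' (fully extended knee).
#'
#' @param hip,knee,ankle 2-D coordinates (single points or n x 2 matrices).
#' @return numeric vector of dimensionless ratios.
#' @export
limb_length <- function(hip, knee, ankle) {
  hip <- rbind_xy(hip); knee <- rbind_xy(knee); ankle <- rbind_xy(ankle)
  d_ha <- sqrt(rowSums((ankle - hip)^2))
  d_hk <- sqrt(rowSums((knee - hip)^2))
  d_ka <- sqrt(rowSums((ankle - knee)^2))
  if (any(d_hk == 0) || any(d_ka == 0)) {
    stop("coincident joint centers: knee coincides with hip or ankle")
  }
  denom <- d_hk + d_ka
  if (any(denom == 0)) stop("zero segment-length denominator")
  d_ha / denom
}

#' Shank angle
#'
#' Signed angle of the knee-to-ankle vector from the downward vertical,
#' degrees; same sign convention as [limb_angle()].
#'
#' @param knee,ankle 2-D coordinates.
#' @return numeric vector of angles in degrees.
#' @export
shank_angle <- function(knee, ankle) limb_angle(knee, ankle)

rbind_xy <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 2L) else as.matrix(p)
}

#' Numerical time derivative
#'
#' Central differences in the interior, one-sided differences at the ends.
#'
#' @param x numeric series, uniformly sampled.
#' @param sampling_rate sampling rate in Hz.
#' @return series of the same length, in units of `x` per second.
#' @export
differentiate <- function(x, sampling_rate) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * sampling_rate / 2
  d[1] <- (x[2] - x[1]) * sampling_rate
  d[n] <- (x[n] - x[n - 1L]) * sampling_rate
  d
}

#' Detect gait events from shank angular velocity
#'
#' During each stride the swing phase produces a dominant positive peak of
#' shank angular velocity (forward rotation of the shank). Heel contact is
#' taken as the local minimum immediately following that peak and toe off as
#' the local minimum immediately preceding it -- the standard shank-gyroscope
#' heuristic. Peaks are screened by topographic prominence.
#'
#' @param shank_angular_velocity filtered shank angular velocity, deg/s.
#' @param sampling_rate sampling rate in Hz (kept for interface symmetry).
#' @param min_prominence_frac keep peaks whose prominence is at least this
#'   fraction of the largest peak prominence (default 0.2).
#' @return list with integer vectors `heel_contacts`, `toe_offs` and
#'   `swing_peaks` (frame indices, strictly increasing).
#' @export
detect_gait_events <- function(shank_angular_velocity, sampling_rate,
                               min_prominence_frac = 0.2) {
  omega <- shank_angular_velocity
  pk <- local_maxima(omega)
  pk <- pk[omega[pk] > 0]
  if (length(pk) == 0L) stop("no strides detected: no positive shank angular velocity peaks")
  prom <- peak_prominence(omega, pk)
  if (max(prom) <= 0) stop("no strides detected: flat shank angular velocity")
  pk <- pk[prom >= min_prominence_frac * max(prom)]
  mins <- local_minima(omega)
  hc <- integer(); to <- integer(); kept <- integer()
  for (p in pk) {
    after <- mins[mins > p]
    before <- mins[mins < p]
    if (length(after) && length(before)) {
      hc <- c(hc, after[1L])
      to <- c(to, before[length(before)])
      kept <- c(kept, p)
    }
  }
  if (length(hc) == 0L) stop("no strides detected: no flanked swing peaks")
  keep <- !duplicated(hc)
  list(heel_contacts = hc[keep], toe_offs = to[keep], swing_peaks = kept[keep])
}

#' Time-normalize gait cycles onto a fixed-length basis
#'
#' Each heel-contact-to-heel-contact interval is resampled by cubic spline
#' onto `n_points` equally spaced samples (default 201, i.e. 0.5% of the gait
#' cycle per sample). Endpoints are interpolation knots and are preserved
#' exactly. Strides shorter than 4 frames are dropped with a warning.
#'
#' @param x numeric series (e.g. limb angle per frame).
#' @param heel_contacts strictly increasing frame indices of heel contacts.
#' @param n_points samples per normalized cycle (default 201).
#' @return matrix with one row per stride and `n_points` columns.
#' @export
normalize_cycles <- function(x, heel_contacts, n_points = 201L) {
  hc <- as.integer(heel_contacts)
  if (is.unsorted(hc, strictly = TRUE)) stop("heel_contacts must be strictly increasing")
  if (length(hc) < 2L) stop("need at least one complete heel-contact-to-heel-contact interval")
  out <- list()
  for (i in seq_len(length(hc) - 1L)) {
    a <- hc[i]; b <- hc[i + 1L]
    if (b - a < 4L) {
      warning(sprintf("stride %d spans only %d frames; dropped", i, b - a))
      next
    }
    out[[length(out) + 1L]] <-
      spline(x = a:b, y = x[a:b], xout = seq(a, b, length.out = n_points),
             method = "fmm")$y
  }
  if (length(out) == 0L) stop("no usable strides after dropping short ones")
  do.call(rbind, out)
}

#' Compute limb kinematics time series from a keypoint series
#'
#' Derives the limb angle, effective limb length, shank angle and shank
#' angular velocity from the joint-center trajectories. By default the
#' derived angle and length series are low-pass filtered (6 Hz zero-lag
#' Butterworth, order 4 per pass); set `filter_coords = TRUE` to filter the
#' raw coordinates instead and leave the derived series unfiltered
#' (sensitivity-analysis switch).
#'
#' @param ks a [keypoint_series()].
#' @param cutoff_hz,order low-pass filter settings (defaults 6 Hz, order 4).
#' @param filter_coords filter coordinates instead of derived series.
#' @return object of class `limb_kinematics_series`: list with elements
#'   `limb_angle`, `limb_length`, `shank_angle`, `shank_angular_velocity`
#'   (all per frame) and `sampling_rate`.
#' @export
limb_kinematics <- function(ks, cutoff_hz = 6, order = 4, filter_coords = FALSE) {
  stopifnot(inherits(ks, "keypoint_series"))
  fs <- ks$sampling_rate
  hip <- ks$hip; knee <- ks$knee; ankle <- ks$ankle
  if (filter_coords) {
    f <- function(m) apply(m, 2L, lowpass_filter, sampling_rate = fs,
                           cutoff_hz = cutoff_hz, order = order)
    hip <- f(hip); knee <- f(knee); ankle <- f(ankle)
  }
  ang <- limb_angle(hip, ankle)
  len <- limb_length(hip, knee, ankle)
  shk <- shank_angle(knee, ankle)
  ## triangle inequality holds exactly on the raw geometry; filtering may
  ## overshoot 1 by a small ripple, which is left in place
  if (max(len) > 1 + 1e-6) {
    stop("limb length exceeds 1 beyond tolerance; check joint coordinates")
  }
  if (!filter_coords) {
    ang <- lowpass_filter(ang, fs, cutoff_hz, order)
    len <- lowpass_filter(len, fs, cutoff_hz, order)
    shk <- lowpass_filter(shk, fs, cutoff_hz, order)
  }
  structure(
    list(limb_angle = ang, limb_length = len, shank_angle = shk,
         shank_angular_velocity = differentiate(shk, fs),
         sampling_rate = fs, n = length(ang)),
    class = "limb_kinematics_series"
  )
}

#' @export
print.limb_kinematics_series <- function(x, ...) {
  cat(sprintf("<limb_kinematics_series> %d frames @ %g Hz\n", x$n, x$sampling_rate))
  cat(sprintf("  limb angle range [%.1f, %.1f] deg; limb length range [%.3f, %.3f]\n",
              min(x$limb_angle), max(x$limb_angle),
              min(x$limb_length), max(x$limb_length)))
  invisible(x)
}

#' Segment a walk into strides
#'
#' Detects gait events from the shank angular velocity, splits the limb-angle
#' and limb-length series into heel-contact-to-heel-contact strides, and
#' time-normalizes each stride onto a 201-point gait-cycle basis. Also records
#' per-stride scalar features: the limb-angle cycle minimum (peak extension)
#' and the limb-length minimum restricted to the swing phase (detected toe off
#' to the next heel contact). Ties at equal minima resolve to the earliest
#' frame.
#'
#' @param ks a [keypoint_series()].
#' @param kin optional precomputed [limb_kinematics()] result.
#' @param min_prominence_frac peak-prominence threshold for event detection.
#' @param n_points samples per normalized cycle (default 201).
#' @param ... passed to [limb_kinematics()] when `kin` is NULL.
#' @return object of class `stride_set`.
#' @export
segment_strides <- function(ks, kin = NULL, min_prominence_frac = 0.2,
                            n_points = 201L, ...) {
  stopifnot(inherits(ks, "keypoint_series"))
  kin <- kin %||% limb_kinematics(ks, ...)
  ev <- detect_gait_events(kin$shank_angular_velocity, kin$sampling_rate,
                           min_prominence_frac)
  hc <- ev$heel_contacts
  if (length(hc) < 2L) stop("fewer than two heel contacts detected; cannot form strides")
  n_str <- length(hc) - 1L
  angle_min <- len_min_sw <- rep(NA_real_, n_str)
  toe_in <- rep(NA_integer_, n_str)
  ok <- rep(TRUE, n_str)
  for (i in seq_len(n_str)) {
    a <- hc[i]; b <- hc[i + 1L]
    if (b - a < 4L) { ok[i] <- FALSE; next }
    seg <- kin$limb_angle[a:b]
    angle_min[i] <- min(seg)
    tos <- ev$toe_offs[ev$toe_offs > a & ev$toe_offs < b]
    if (length(tos) == 0L) { ok[i] <- FALSE; next }
    toe_in[i] <- tos[1L]
    len_min_sw[i] <- min(kin$limb_length[toe_in[i]:b])
  }
  if (!all(ok)) {
    warning(sprintf("%d stride(s) dropped (too short or no toe off inside)", sum(!ok)))
  }
  hc_ok <- which(ok)
  if (length(hc_ok) == 0L) stop("no usable strides")
  ## normalized curves for the usable strides only
  norm_one <- function(x, a, b) {
    spline(x = a:b, y = x[a:b], xout = seq(a, b, length.out = n_points),
           method = "fmm")$y
  }
  angle_cycles <- t(vapply(hc_ok, function(i)
    norm_one(kin$limb_angle, hc[i], hc[i + 1L]), numeric(n_points)))
  length_cycles <- t(vapply(hc_ok, function(i)
    norm_one(kin$limb_length, hc[i], hc[i + 1L]), numeric(n_points)))
  structure(
    list(heel_contacts = hc, toe_offs = ev$toe_offs,
         stride_index = hc_ok,
         stride_frames = (hc[hc_ok + 1L] - hc[hc_ok]),
         angle_cycles = angle_cycles, length_cycles = length_cycles,
         angle_min = angle_min[hc_ok], length_min_swing = len_min_sw[hc_ok],
         hip_x_hc = ks$hip[hc, 1L],
         sampling_rate = kin$sampling_rate,
         n_strides = length(hc_ok)),
    class = "stride_set"
  )
}

#' @export
print.stride_set <- function(x, ...) {
  cat(sprintf("<stride_set> %d strides @ %g Hz (mean period %.3f s)\n",
              x$n_strides, x$sampling_rate,
              mean(x$stride_frames) / x$sampling_rate))
  invisible(x)
}

#' Extract per-participant gait features from a stride set
#'
#' Removes the first and last `trim` strides (acceleration/deceleration
#' guard), retains up to `n_keep` of the remaining strides, and averages the
#' per-stride features: the limb-angle cycle minimum (limb extension angle,
#' negative in extension) and the swing-phase minimum of effective limb
#' length. Cadence is computed from heel-contact times (two steps per
#' stride); gait speed from the net hip displacement over the retained
#' strides, if a meters-per-pixel calibration is supplied; and the gait
#' stability ratio as cadence / speed in steps per meter.
#'
#' @param strides a [segment_strides()] result.
#' @param trim strides removed at each end (default 3).
#' @param n_keep maximum strides retained after trimming (default 10). If
#'   fewer remain, all are used with a warning.
#' @param meters_per_pixel optional calibration for gait speed.
#' @return one-row data.frame with columns `limb_angle_ext_peak` (deg),
#'   `limb_length_min_swing`, `gait_speed` (m/s or NA), `cadence`
#'   (steps/min), `gait_stability_ratio` (steps/m or NA), `n_strides_used`.
#' @export
extract_features <- function(strides, trim = 3L, n_keep = 10L,
                             meters_per_pixel = NULL) {
  stopifnot(inherits(strides, "stride_set"))
  S <- strides$n_strides
  if (S < 2L * trim + 1L) {
    stop(sprintf("only %d usable strides; need at least %d to trim %d from each end",
                 S, 2L * trim + 1L, trim))
  }
  idx <- seq.int(trim + 1L, S - trim)
  if (length(idx) > n_keep) {
    idx <- idx[seq_len(n_keep)]
  } else if (length(idx) < n_keep) {
    warning(sprintf("only %d strides remain after trimming; using all of them",
                    length(idx)))
  }
  fs <- strides$sampling_rate
  first_hc <- strides$stride_index[idx[1L]]
  last_hc <- strides$stride_index[idx[length(idx)]] + 1L
  duration <- (strides$heel_contacts[last_hc] - strides$heel_contacts[first_hc]) / fs
  cadence <- 2 * 60 * length(idx) / duration
  speed <- if (!is.null(meters_per_pixel)) {
    (strides$hip_x_hc[last_hc] - strides$hip_x_hc[first_hc]) *
      meters_per_pixel / duration
  } else NA_real_
  gsr <- if (is.finite(speed)) cadence / (speed * 60) else NA_real_
  data.frame(
    limb_angle_ext_peak = mean(strides$angle_min[idx]),
    limb_length_min_swing = mean(strides$length_min_swing[idx]),
    gait_speed = speed,
    cadence = cadence,
    gait_stability_ratio = gsr,
    n_strides_used = length(idx)
  )
}

#' One-call kinematic analysis of a walking trial
#'
#' Convenience wrapper: [limb_kinematics()] then [segment_strides()] then
#' [extract_features()].
#'
#' @param ks a [keypoint_series()].
#' @param cutoff_hz,order,filter_coords filter settings, see [limb_kinematics()].
#' @param min_prominence_frac event-detection threshold.
#' @param trim,n_keep stride trimming/retention, see [extract_features()].
#' @param meters_per_pixel optional speed calibration.
#' @return one-row feature data.frame (see [extract_features()]).
#' @export
analyze_walk <- function(ks, cutoff_hz = 6, order = 4, filter_coords = FALSE,
                         min_prominence_frac = 0.2, trim = 3L, n_keep = 10L,
                         meters_per_pixel = NULL) {
  kin <- limb_kinematics(ks, cutoff_hz = cutoff_hz, order = order,
                         filter_coords = filter_coords)
  ss <- segment_strides(ks, kin = kin, min_prominence_frac = min_prominence_frac)
  extract_features(ss, trim = trim, n_keep = n_keep,
                   meters_per_pixel = meters_per_pixel)
}
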