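#' Construct a keypoint series
#'
#' Container for the per-frame 2-D joint-center coordinates of one walking
#' trial. Internal convention: x is the direction of progression (positive
#' forward), y is up. All three joints must be sampled on the same uniform
#' time base.
#'
#' @param time numeric vector of sample times in seconds (uniform).
#' @param hip,knee,ankle n x 2 numeric matrices of (x, y) coordinates.
#' @param sampling_rate sampling rate in Hz.
#' @param side which leg the keypoints belong to ("right" or "left").
#' @param confidence optional n x 3 matrix of per-frame per-joint detection
#'   confidences in \[0, 1\] (columns hip, knee, ankle).
#' @param events optional list with integer vectors `heel_contacts` and
#'   `toe_offs` (ground-truth frame indices, used by the synthetic generator).
#'
#' @return An object of class `keypoint_series`.
#' @export
keypoint_series <- function(time, hip, knee, ankle, sampling_rate,
                            side = c("right", "left"),
                            confidence = NULL, events = NULL) {
  side <- match.arg(side)
  hip <- as_xy_matrix(hip, "hip")
  knee <- as_xy_matrix(knee, "knee")
  ankle <- as_xy_matrix(ankle, "ankle")
  n <- length(time)
  if (nrow(hip) != n || nrow(knee) != n || nrow(ankle) != n) {
    stop("hip, knee, ankle and time must all have the same number of frames")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number")
  }
  if (n >= 3L) {
    dt <- diff(time)
    if (max(abs(dt - 1 / sampling_rate)) > 1e-6 * max(1, 1 / sampling_rate)) {
      stop("time stamps are not uniform at the stated sampling rate")
    }
  }
  if (!is.null(confidence)) {
    confidence <- as.matrix(confidence)
    if (nrow(confidence) != n || ncol(confidence) != 3L) {
      stop("confidence must be an n x 3 matrix (hip, knee, ankle)")
    }
  }
  structure(
    list(time = as.numeric(time), hip = hip, knee = knee, ankle = ankle,
         sampling_rate = sampling_rate, side = side,
         confidence = confidence, events = events),
    class = "keypoint_series"
  )
}

as_xy_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (ncol(m) != 2L) stop(sprintf("%s must have two columns (x, y)", what))
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

#' @export
print.keypoint_series <- function(x, ...) {
  cat(sprintf("<keypoint_series> %d frames @ %g Hz (%.2f s), %s side\n",
              length(x$time), x$sampling_rate,
              length(x$time) / x$sampling_rate, x$side))
  if (!is.null(x$events)) {
    cat(sprintf("  ground-truth events: %d heel contacts, %d toe offs\n",
                length(x$events$heel_contacts), length(x$events$toe_offs)))
  }
  invisible(x)
}

#' Number of frames in a keypoint series
#' @param ks a `keypoint_series`.
#' @return integer frame count.
#' @export
n_frames <- function(ks) length(ks$time)
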