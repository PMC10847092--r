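KEYPOINT_SCHEMA <- "# limbkin keypoint series, schema v1"
KEYPOINT_COLS <- c("frame", "time_s", "hip_x", "hip_y", "knee_x", "knee_y",
                   "ankle_x", "ankle_y")

#' Write a keypoint series as CSV
#'
#' Columns: frame, time_s, hip_x, hip_y, knee_x, knee_y, ankle_x, ankle_y,
#' preceded by a schema-version header comment.
#'
#' @param ks a [keypoint_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_keypoint_csv <- function(ks, path) {
  stopifnot(inherits(ks, "keypoint_series"))
  df <- data.frame(frame = seq_along(ks$time), time_s = ks$time,
                   hip_x = ks$hip[, 1], hip_y = ks$hip[, 2],
                   knee_x = ks$knee[, 1], knee_y = ks$knee[, 2],
                   ankle_x = ks$ankle[, 1], ankle_y = ks$ankle[, 2])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(KEYPOINT_SCHEMA, con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a keypoint series from CSV
#'
#' Reads the schema written by [write_keypoint_csv()] (round-trip lossless up
#' to numeric printing). Unknown extra columns are ignored with a warning; a
#' missing required column is an error naming it. Time stamps must be uniform.
#'
#' @param path CSV file.
#' @param side leg label for the series (default "right").
#' @return a [keypoint_series()].
#' @export
read_keypoint_csv <- function(path, side = "right") {
  df <- read.csv(path, comment.char = "#")
  missing_cols <- setdiff(KEYPOINT_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), KEYPOINT_COLS)
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  if (nrow(df) < 2L) stop("keypoint CSV must contain at least two frames")
  dt <- diff(df$time_s)
  if (max(dt) - min(dt) > 1e-6 * max(abs(dt))) {
    stop("non-uniform time stamps beyond tolerance")
  }
  fs <- 1 / median(dt)
  keypoint_series(time = df$time_s,
                  hip = cbind(df$hip_x, df$hip_y),
                  knee = cbind(df$knee_x, df$knee_y),
                  ankle = cbind(df$ankle_x, df$ankle_y),
                  sampling_rate = fs, side = side)
}

## BODY_25 0-based keypoint indices for (hip, knee, ankle)
body25_indices <- function(side) {
  switch(side, right = c(9L, 10L, 11L), left = c(12L, 13L, 14L),
         stop("side must be 'right' or 'left'"))
}

#' Write a keypoint series as OpenPose-style per-frame JSON
#'
#' One JSON file per frame (`frame_%06d_keypoints.json`), BODY_25 layout,
#' with the requested side's hip/knee/ankle filled in and all other
#' keypoints zeroed. The internal y-up coordinates are converted back to
#' image y-down coordinates.
#'
#' @param ks a [keypoint_series()].
#' @param dir output directory (created if needed).
#' @param confidence constant confidence written for the three joints.
#' @return `dir`, invisibly.
#' @export
write_openpose_json <- function(ks, dir, confidence = 0.9) {
  stopifnot(inherits(ks, "keypoint_series"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- body25_indices(ks$side)
  for (i in seq_along(ks$time)) {
    kp <- numeric(75L)
    pts <- rbind(ks$hip[i, ], ks$knee[i, ], ks$ankle[i, ])
    for (j in 1:3) {
      kp[3L * idx[j] + 1L] <- pts[j, 1]
      kp[3L * idx[j] + 2L] <- -pts[j, 2]          # image coordinates are y-down
      kp[3L * idx[j] + 3L] <- confidence
    }
    obj <- list(version = 1.3,
                people = list(list(pose_keypoints_2d = kp)))
    jsonlite::write_json(obj, file.path(dir, sprintf("frame_%06d_keypoints.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read an OpenPose per-frame JSON directory
#'
#' Parses BODY_25 per-frame JSON files (sorted by file name), extracts the
#' hip/knee/ankle joint centers of the requested side, converts image y-down
#' to internal y-up coordinates, and normalizes the direction of progression
#' to positive x (inferred from the net hip displacement). When several
#' people are detected in a frame, the one with the largest mean bounding-box
#' area across frames is followed. Frames with no detection or with joint
#' confidence below `confidence_floor` are marked missing and linearly
#' interpolated, up to `max_gap` consecutive frames.
#'
#' @param path directory of `*_keypoints.json` files.
#' @param side paretic side, "right" or "left".
#' @param sampling_rate recording rate in Hz (default 120).
#' @param confidence_floor joints below this confidence are treated missing.
#' @param max_gap longest interpolatable run of missing frames (default 5).
#' @param max_missing_frac error if more than this fraction of frames has no
#'   detected person (default 0.1).
#' @return a [keypoint_series()] with per-frame confidences.
#' @export
read_openpose_dir <- function(path, side = c("right", "left"),
                              sampling_rate = 120, confidence_floor = 0.3,
                              max_gap = 5L, max_missing_frac = 0.1) {
  side <- match.arg(side)
  files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) stop("no OpenPose JSON files found in ", path)
  idx <- body25_indices(side)
  n <- length(files)
  coords <- array(NA_real_, c(n, 3L, 2L))
  conf <- matrix(0, n, 3L)
  n_empty <- 0L
  for (i in seq_len(n)) {
    obj <- jsonlite::read_json(files[i], simplifyVector = TRUE)
    people <- obj$people
    kp <- NULL
    if (is.data.frame(people) && nrow(people) > 0L) {
      kps <- people$pose_keypoints_2d
      if (!is.list(kps)) kps <- list(kps)
      if (length(kps) > 1L) {
        area <- vapply(kps, function(k) {
          m <- matrix(unlist(k), ncol = 3L, byrow = TRUE)
          m <- m[m[, 3] > 0, , drop = FALSE]
          if (nrow(m) == 0L) return(0)
          diff(range(m[, 1])) * diff(range(m[, 2]))
        }, numeric(1))
        kp <- unlist(kps[[which.max(area)]])
      } else {
        kp <- unlist(kps[[1L]])
      }
    } else if (is.list(people) && length(people) > 0L) {
      kp <- unlist(people[[1L]]$pose_keypoints_2d)
    }
    if (is.null(kp) || length(kp) != 75L) {
      n_empty <- n_empty + 1L
      next
    }
    for (j in 1:3) {
      coords[i, j, 1L] <- kp[3L * idx[j] + 1L]
      coords[i, j, 2L] <- -kp[3L * idx[j] + 2L]   # to y-up
      conf[i, j] <- kp[3L * idx[j] + 3L]
    }
  }
  if (n_empty > max_missing_frac * n) {
    stop(sprintf("%d of %d frames have no detected person (limit %.0f%%)",
                 n_empty, n, 100 * max_missing_frac))
  }
  ## interpolate low-confidence / missing frames, bounded gap length
  for (j in 1:3) {
    bad <- is.na(coords[, j, 1L]) | conf[, j] < confidence_floor
    if (any(bad)) {
      runs <- rle(bad)
      if (any(runs$lengths[runs$values] > max_gap)) {
        stop(sprintf("missing-frame gap longer than %d frames; cannot interpolate", max_gap))
      }
      if (bad[1L] || bad[n]) stop("missing frames at the series boundary cannot be interpolated")
      good <- which(!bad)
      for (d in 1:2) {
        coords[bad, j, d] <- approx(good, coords[good, j, d], xout = which(bad))$y
      }
    }
  }
  ## normalize direction of progression to positive x
  if (coords[n, 1L, 1L] - coords[1L, 1L, 1L] < 0) {
    coords[, , 1L] <- -coords[, , 1L]
  }
  keypoint_series(time = (seq_len(n) - 1L) / sampling_rate,
                  hip = coords[, 1L, ], knee = coords[, 2L, ],
                  ankle = coords[, 3L, ],
                  sampling_rate = sampling_rate, side = side,
                  confidence = conf)
}

#' Read and validate a clinical table
#'
#' One row per participant with an `id` (or `participant`) column. Known
#' clinical variables (see [clinical_scales()]) are validated against their
#' declared scale ranges; an out-of-range value is an error citing the
#' participant and variable. Duplicate ids are an error.
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_clinical_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  id_col <- intersect(c("id", "participant"), names(df))[1]
  if (is.na(id_col)) stop("clinical table must have an 'id' or 'participant' column")
  if (anyDuplicated(df[[id_col]])) {
    stop("duplicate participant id(s): ",
         paste(unique(df[[id_col]][duplicated(df[[id_col]])]), collapse = ", "))
  }
  scales <- clinical_scales()
  for (j in seq_len(nrow(scales))) {
    var <- scales$variable[j]
    if (!var %in% names(df)) next
    bad <- which(!is.na(df[[var]]) &
                   (df[[var]] < scales$min[j] | df[[var]] > scales$max[j]))
    if (length(bad)) {
      stop(sprintf("participant %s: %s = %s outside scale range [%d, %d]",
                   df[[id_col]][bad[1L]], var, df[[var]][bad[1L]],
                   scales$min[j], scales$max[j]))
    }
  }
  df
}
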