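`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## row-wise log(sum(exp(x))) with the usual max shift
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

wrap_phase <- function(phi) phi - floor(phi)

## absolute distance between phases on the unit circle
phase_dist <- function(phi, center) {
  d <- abs(wrap_phase(phi) - wrap_phase(center))
  pmin(d, 1 - d)
}

## indices of strict local maxima / minima of a numeric series
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

## topographic prominence of the peaks at `peaks` (indices into x)
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) {
      min(left[(max(higher_l) + 1L):(p - 1L)])
    } else {
      min(c(left, h))
    }
    right <- x[seq(p + 1L, length(x))]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r) - 1L)])
    } else {
      min(c(right, h))
    }
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Derive a stage seed from a root seed
#'
#' All pipeline stages draw their randomness from sub-seeds derived from one
#' root seed, so a whole run is reproducible from a single integer. The
#' derived value stays inside the 32-bit integer range R requires.
#'
#' @param seed integer root seed.
#' @param offset integer stage offset.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

stars_for_p <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
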