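# shared fixtures and small oracles used across test files

# quiet scenario used by most walk-synthesis tests
test_scenario <- function(seed = 42L, ...) {
  default_scenario(seed = seed, ...)
}

make_walk <- function(angle, length, seed = 42L, noise = 0, period = 1.1,
                      scenario = test_scenario(seed)) {
  synthesize_walk(list(limb_angle_ext = angle, limb_length = length),
                  scenario, stride_period = period, noise_sd_px = noise)
}

# adjusted Rand index (hand-rolled so the clustering code is not its own judge)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# exhaustive Steel-Dwass permutation null for k = 3 equal groups: returns the
# permutation distribution of the maximum studentized-range statistic
sd_permutation_max_q <- function(x, n_per = 4L) {
  stopifnot(length(x) == 3L * n_per)
  idx <- seq_along(x)
  c1 <- utils::combn(idx, n_per)
  out <- numeric(0)
  for (i in seq_len(ncol(c1))) {
    g1 <- c1[, i]
    rest <- setdiff(idx, g1)
    c2 <- utils::combn(rest, n_per)
    for (j in seq_len(ncol(c2))) {
      g2 <- c2[, j]
      g3 <- setdiff(rest, g2)
      qs <- abs(c(limbkin:::pairwise_rank_z(x[g1], x[g2]),
                  limbkin:::pairwise_rank_z(x[g1], x[g3]),
                  limbkin:::pairwise_rank_z(x[g2], x[g3])))
      out <- c(out, sqrt(2) * max(qs))
    }
  }
  out
}
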