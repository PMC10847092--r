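#' Epsilon-squared effect size for the Kruskal-Wallis test
#'
#' `epsilon^2 = H / (n - 1)`, equivalently `H (n + 1) / (n^2 - 1)`: the
#' rank-based analogue of the proportion of variance explained, in \[0, 1\].
#'
#' @param H Kruskal-Wallis chi-squared statistic.
#' @param n total sample size.
#' @return scalar effect size.
#' @export
epsilon_squared <- function(H, n) {
  if (n < 2) stop("n must be at least 2")
  H / (n - 1)
}

## t-approximation p-value for a Spearman coefficient
spearman_p_value <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t_stat), df = n - 2)
}

## Fisher z confidence interval for a correlation coefficient
fisher_z_ci <- function(rho, n, level = 0.95) {
  se <- 1 / sqrt(n - 3)
  z <- atanh(rho)
  q <- qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Spearman rank correlation with confidence interval
#'
#' The coefficient uses average ranks for ties; the two-sided p-value comes
#' from the t-approximation `t = rho sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom, and the 95% CI from the Fisher z-transform with standard error
#' `1/sqrt(n-3)`.
#'
#' @param x,y paired numeric vectors (pairs with missing values are dropped).
#' @param level confidence level (default 0.95).
#' @return object of class `correlation_result` (one-row data.frame with
#'   `rho`, `ci_low`, `ci_high`, `p`, `n`).
#' @export
spearman_ci <- function(x, y, level = 0.95) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    stop("zero variance in ranks; correlation undefined")
  }
  rho <- cor(x, y, method = "spearman")
  ci <- fisher_z_ci(rho, n, level)
  out <- data.frame(rho = rho, ci_low = ci[1], ci_high = ci[2],
                    p = spearman_p_value(rho, n), n = n)
  class(out) <- c("correlation_result", "data.frame")
  out
}

#' Kruskal-Wallis test with epsilon-squared effect size
#'
#' Tie-corrected H statistic and chi-squared p-value (delegated to
#' [stats::kruskal.test()]) plus the epsilon-squared effect size
#' `H / (n - 1)`. If every observation is identical, H = 0 and p = 1.
#'
#' @param x numeric response.
#' @param g group labels (coerced to factor), at least 2 non-empty groups.
#' @return object of class `kw_result` (one-row data.frame with `H`, `df`,
#'   `epsilon_sq`, `p`, `n`, `n_groups`).
#' @export
kruskal_wallis <- function(x, g) {
  g <- factor(g)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("need at least 2 non-empty groups")
  n <- length(x)
  if (n < 5L) stop("need a total sample size of at least 5")
  if (length(unique(x)) == 1L) {
    out <- data.frame(H = 0, df = nlevels(g) - 1L, epsilon_sq = 0, p = 1,
                      n = n, n_groups = nlevels(g))
  } else {
    kt <- kruskal.test(x, g)
    out <- data.frame(H = unname(kt$statistic), df = as.integer(unname(kt$parameter)),
                      epsilon_sq = epsilon_squared(unname(kt$statistic), n),
                      p = kt$p.value, n = n, n_groups = nlevels(g))
  }
  class(out) <- c("kw_result", "data.frame")
  out
}

## standardized tie-corrected pairwise Wilcoxon statistic for one group pair
pairwise_rank_z <- function(xi, xj) {
  ni <- length(xi); nj <- length(xj); N <- ni + nj
  r <- rank(c(xi, xj))
  W <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  V <- ni * nj / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(0)                      # fully tied pair
  (W - E) / sqrt(V)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For each pair of groups, the pooled two-group ranking (average ranks for
#' ties) gives a tie-corrected standardized Wilcoxon statistic z; the
#' quantity `q = |z| sqrt(2)` is referred to the studentized range
#' distribution with `k` groups and infinite degrees of freedom, which
#' controls the family-wise error across all pairs. A fully tied pair gets
#' p = 1.
#'
#' @param x numeric response.
#' @param g group labels (coerced to factor); at least 3 groups of size >= 2
#'   for a meaningful family.
#' @return object of class `posthoc_matrix`: list with symmetric matrices
#'   `p` (diagonal NA) and `z`, and `k`.
#' @export
steel_dwass <- function(x, g) {
  g <- factor(g)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 observations")
  lev <- levels(g)
  p <- z <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      zij <- pairwise_rank_z(x[g == lev[i]], x[g == lev[j]])
      pij <- ptukey(sqrt(2) * abs(zij), nmeans = k, df = Inf,
                    lower.tail = FALSE)
      z[i, j] <- z[j, i] <- zij
      p[i, j] <- p[j, i] <- pij
    }
  }
  structure(list(p = p, z = z, k = k), class = "posthoc_matrix")
}

#' @export
print.posthoc_matrix <- function(x, ...) {
  cat(sprintf("<posthoc_matrix> Steel-Dwass all-pairs p-values, %d groups\n", x$k))
  print(round(x$p, 4))
  invisible(x)
}

#' Pearson chi-squared test for a contingency table
#'
#' Without continuity correction, df = (r-1)(c-1). Expected counts below 5
#' trigger a warning; a zero row or column margin is an error.
#'
#' @param tab r x c matrix or table of counts.
#' @return one-row data.frame with `statistic`, `df`, `p`.
#' @export
chi_squared_categorical <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero margin")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected counts below 5; chi-squared approximation may be poor")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  data.frame(statistic = unname(ct$statistic), df = unname(ct$parameter),
             p = ct$p.value)
}

#' Compare clinical and gait variables across clusters
#'
#' For each continuous/ordinal variable: Kruskal-Wallis test with
#' epsilon-squared effect size and a Steel-Dwass all-pairs post-hoc matrix.
#' For each categorical variable: a Pearson chi-squared test on the
#' cluster-by-category table. Significance stars use the 0.05 / 0.01 / 0.001
#' thresholds. Post-hoc testing is skipped with a warning for variables when
#' any cluster has fewer than 2 members.
#'
#' @param data data.frame holding the variables (one row per participant).
#' @param labels cluster labels aligned with `data` rows.
#' @param ordinal_vars character vector of continuous/ordinal column names.
#' @param categorical_vars character vector of categorical column names.
#' @return object of class `group_comparison`: `kw` (per-variable H, df,
#'   epsilon_sq, p, stars), `posthoc` (long data.frame variable, cluster_a,
#'   cluster_b, p, stars), `posthoc_matrices` (named list), `categorical`.
#' @export
compare_clusters <- function(data, labels, ordinal_vars,
                             categorical_vars = character()) {
  labels <- factor(labels)
  stopifnot(nrow(data) == length(labels))
  missing_vars <- setdiff(c(ordinal_vars, categorical_vars), names(data))
  if (length(missing_vars)) {
    stop("variable(s) not in data: ", paste(missing_vars, collapse = ", "))
  }
  kw_rows <- list(); ph_rows <- list(); ph_mats <- list()
  small_cluster <- any(table(labels) < 2L)
  for (v in ordinal_vars) {
    kw <- kruskal_wallis(data[[v]], labels)
    kw_rows[[v]] <- data.frame(variable = v, kw, stars = stars_for_p(kw$p))
    if (small_cluster) {
      warning(sprintf("cluster with < 2 members: post-hoc skipped for %s", v))
      next
    }
    sd_res <- steel_dwass(data[[v]], labels)
    ph_mats[[v]] <- sd_res
    lev <- rownames(sd_res$p)
    pairs <- which(upper.tri(sd_res$p), arr.ind = TRUE)
    ph_rows[[v]] <- data.frame(
      variable = v,
      cluster_a = lev[pairs[, 1]], cluster_b = lev[pairs[, 2]],
      p = sd_res$p[pairs], stars = stars_for_p(sd_res$p[pairs])
    )
  }
  cat_rows <- lapply(categorical_vars, function(v) {
    tab <- table(labels, data[[v]])
    res <- chi_squared_categorical(tab)
    data.frame(variable = v, res, stars = stars_for_p(res$p))
  })
  structure(list(
    kw = do.call(rbind, c(kw_rows, list(make.row.names = FALSE))),
    posthoc = if (length(ph_rows)) do.call(rbind, c(ph_rows, list(make.row.names = FALSE))) else NULL,
    posthoc_matrices = ph_mats,
    categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
    n_clusters = nlevels(labels)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %d clusters\n", x$n_clusters))
  cat("Kruskal-Wallis:\n")
  print(x$kw, row.names = FALSE)
  if (!is.null(x$categorical)) {
    cat("Chi-squared (categorical):\n")
    print(x$categorical, row.names = FALSE)
  }
  if (!is.null(x$posthoc)) {
    cat(sprintf("Steel-Dwass post-hoc: %d pairwise tests (see $posthoc)\n",
                nrow(x$posthoc)))
  }
  invisible(x)
}
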