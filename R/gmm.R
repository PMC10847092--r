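## log density of N(mu, S) at the rows of x, via Cholesky
mvn_logdensity <- function(x, mu, S) {
  R <- chol(S)
  z <- forwardsolve(t(R), t(x) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * ncol(x) * log(2 * pi)
}

## k-means++ seeding: spread initial centers by squared-distance sampling
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (k in seq_len(K - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[k, ] <- x[sample.int(n, 1L, prob = prob), ]
    d2k <- rowSums((x - matrix(centers[k, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, d2k)
  }
  centers
}

## Cholesky factor, or NULL when the matrix is numerically non-PD; the
## factor is reused for the density evaluation, so degeneracy detection
## costs nothing extra per EM iteration
safe_chol <- function(S, scale) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R) || any(diag(R) < sqrt(1e-10 * scale))) NULL else R
}

#' Fit a Gaussian mixture model by EM
#'
#' Full (unequal, unrestricted) covariance per component, maximum-likelihood
#' EM with k-means++ initialisation and multiple restarts; the best restart
#' by final log-likelihood is returned. Within a run the log-likelihood is
#' non-decreasing by construction; convergence is declared when its relative
#' change falls below `tol`. Near-singular component covariances are
#' stabilised by adding a trace-scaled ridge; a run whose components still
#' collapse is restarted, and an error is raised if every restart collapses.
#'
#' @param x n x d numeric matrix of features (d = 2 in the gait pipeline).
#' @param K number of components (n >= K).
#' @param seed integer seed for the restarts (optional but recommended).
#' @param n_restarts number of k-means++ restarts (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter iteration cap per run (default 500).
#' @param reg ridge scale for near-singular covariances (default 1e-6).
#' @return object of class `mixture_model`: `K`, `weights`, `means` (K x d),
#'   `covariances` (d x d x K), `responsibilities` (n x K),
#'   `log_likelihood`, `loglik_trace`, `n_params`, `bic`, `icl`,
#'   `hard_labels`, `n`, `converged`.
#' @export
fit_em <- function(x, K, seed = NULL, n_restarts = 10L, tol = 1e-6,
                   max_iter = 500L, reg = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); d <- ncol(x)
  if (!all(is.finite(x))) stop("features must be finite")
  if (n < K) stop("need at least K observations")
  if (!is.null(seed)) set.seed(seed)
  scale0 <- mean(diag(stats::cov(x)))
  best <- NULL
  n_collapsed <- 0L
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      em_single_run(x, K, tol = tol, max_iter = max_iter,
                    reg = reg, scale0 = scale0),
      limbkin_collapse = function(e) NULL
    )
    if (is.null(fit)) {
      ## one retry with stronger regularisation before giving up on this run
      fit <- tryCatch(
        em_single_run(x, K, tol = tol, max_iter = max_iter,
                      reg = reg * 100, scale0 = scale0),
        limbkin_collapse = function(e) NULL
      )
    }
    if (is.null(fit)) { n_collapsed <- n_collapsed + 1L; next }
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  if (is.null(best)) {
    stop(sprintf("all %d EM restarts collapsed (K = %d, n = %d)", n_restarts, K, n))
  }
  finalize_mixture(best, n)
}

em_collapse <- function(msg) {
  stop(structure(class = c("limbkin_collapse", "error", "condition"),
                 list(message = msg, call = NULL)))
}

em_single_run <- function(x, K, tol, max_iter, reg, scale0) {
  n <- nrow(x); d <- ncol(x)
  mu <- kmeanspp_centers(x, K)
  ## initial hard assignment to the seeded centers
  dist2 <- sapply(seq_len(K), function(k)
    rowSums((x - matrix(mu[k, ], n, d, byrow = TRUE))^2))
  lab <- max.col(-dist2)
  w <- tabulate(lab, K) / n
  S <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    xk <- x[lab == k, , drop = FALSE]
    Sk <- if (nrow(xk) > 1L) stats::cov(xk) * (nrow(xk) - 1) / nrow(xk)
          else diag(scale0, d)
    S[, , k] <- Sk + diag(reg * scale0, d)
    mu[k, ] <- if (nrow(xk) > 0L) colMeans(xk) else mu[k, ]
  }
  w <- pmax(w, 1e-10); w <- w / sum(w)
  ll_prev <- -Inf
  trace <- numeric(0)
  logp <- matrix(0, n, K)
  const <- -0.5 * d * log(2 * pi)
  for (it in seq_len(max_iter)) {
    for (k in seq_len(K)) {
      R <- safe_chol(S[, , k], scale0)
      if (is.null(R)) {
        S[, , k] <- S[, , k] + diag(reg * scale0, d)
        R <- safe_chol(S[, , k], scale0)
        if (is.null(R)) em_collapse("component covariance collapsed")
      }
      z <- forwardsolve(t(R), t(x) - mu[k, ])
      logp[, k] <- const - sum(log(diag(R))) - 0.5 * colSums(z^2) + log(w[k])
    }
    lse <- row_logsumexp(logp)
    ll <- sum(lse)
    resp <- exp(logp - lse)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll)) break
    ll_prev <- ll
    ## M step
    Nk <- colSums(resp)
    if (any(Nk < d + 1e-8)) em_collapse("component emptied")
    w <- Nk / n
    for (k in seq_len(K)) {
      mu[k, ] <- colSums(resp[, k] * x) / Nk[k]
      xc <- sweep(x, 2L, mu[k, ])
      S[, , k] <- crossprod(xc * sqrt(resp[, k])) / Nk[k]
    }
  }
  list(K = K, weights = w, means = mu, covariances = S,
       responsibilities = resp, log_likelihood = ll, loglik_trace = trace,
       converged = it < max_iter)
}

finalize_mixture <- function(fit, n) {
  d <- ncol(fit$means)
  fit$n <- n
  fit$n_params <- (fit$K - 1L) + fit$K * d + fit$K * d * (d + 1L) / 2L
  fit$hard_labels <- max.col(fit$responsibilities, ties.method = "first")
  fit$bic <- mixture_bic(fit, n)
  fit$icl <- mixture_icl(fit, n)
  class(fit) <- "mixture_model"
  fit
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> K = %d, n = %d, logLik = %.3f, BIC = %.2f, ICL = %.2f\n",
              x$K, x$n, x$log_likelihood, x$bic, x$icl))
  tab <- data.frame(weight = round(x$weights, 3),
                    round(x$means, 3))
  names(tab)[-1] <- paste0("mean_", seq_len(ncol(x$means)))
  print(tab)
  invisible(x)
}

#' Bayesian information criterion of a fitted mixture (lower is better)
#'
#' `-2 logLik + n_params log(n)`; the sign convention is chosen so that a
#' smaller value indicates a better fit.
#'
#' @param model a [fit_em()] result (or any list with `log_likelihood` and
#'   `n_params`).
#' @param n number of observations.
#' @return scalar BIC.
#' @export
mixture_bic <- function(model, n) {
  if (n <= 0) stop("n must be positive")
  -2 * model$log_likelihood + model$n_params * log(n)
}

#' Integrated complete-data likelihood criterion (lower is better)
#'
#' `BIC + 2 * EN`, where `EN = -sum_i sum_k z_ik log z_ik` is the total
#' entropy of the posterior responsibilities (0 log 0 = 0). The entropy term
#' penalises poorly separated components, so ICL >= BIC always, with
#' equality for a hard partition.
#'
#' @param model a fitted [fit_em()] model with responsibilities.
#' @param n number of observations.
#' @return scalar ICL.
#' @export
mixture_icl <- function(model, n) {
  z <- model$responsibilities
  en <- -sum(ifelse(z > 0, z * log(z), 0))
  mixture_bic(model, n) + 2 * en
}

#' Fit and select a Gaussian mixture over a range of K
#'
#' Fits a full-covariance mixture for each K in `K_range` and assembles a
#' selection table of BIC and ICL (both lower-is-better). The default
#' selection is the lowest BIC; if the ICL minimum disagrees, that is
#' reported in the table's attributes and as a message, since the final call
#' between close models is an analyst judgment (theoretical validity), not a
#' mechanical rule.
#'
#' @param x n x d feature matrix.
#' @param K_range candidate component counts (default 4:7).
#' @param seed integer seed; each K gets a derived sub-seed.
#' @param n_restarts restarts per K (default 10).
#' @param ... passed to [fit_em()].
#' @return list of class `gmm_selection`: `model` (best by BIC), `table`
#'   (data.frame K, log_likelihood, n_params, BIC, ICL), `fits` (all
#'   models), `selected_K`.
#' @export
select_model <- function(x, K_range = 4:7, seed = NULL, n_restarts = 10L, ...) {
  if (length(K_range) == 0L) stop("K_range must not be empty")
  x <- as.matrix(x)
  if (nrow(x) <= max(K_range)) stop("need more observations than max(K_range)")
  fits <- lapply(seq_along(K_range), function(i) {
    tryCatch(
      fit_em(x, K_range[i],
             seed = if (is.null(seed)) NULL else derive_seed(seed, K_range[i]),
             n_restarts = n_restarts, ...),
      error = function(e) {
        message(sprintf("K = %d dropped from the scan: %s", K_range[i],
                        conditionMessage(e)))
        NULL
      })
  })
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) stop("no candidate K could be fitted")
  fits <- fits[keep]
  K_range <- K_range[keep]
  tab <- data.frame(
    K = K_range,
    log_likelihood = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    BIC = vapply(fits, `[[`, numeric(1), "bic"),
    ICL = vapply(fits, `[[`, numeric(1), "icl")
  )
  i_bic <- which.min(tab$BIC)
  i_icl <- which.min(tab$ICL)
  if (i_bic != i_icl) {
    message(sprintf("BIC selects K = %d but ICL selects K = %d; reporting both, K = %d retained",
                    K_range[i_bic], K_range[i_icl], K_range[i_bic]))
  }
  structure(list(model = fits[[i_bic]], table = tab, fits = fits,
                 selected_K = K_range[i_bic],
                 icl_K = K_range[i_icl]),
            class = "gmm_selection")
}

#' @export
print.gmm_selection <- function(x, ...) {
  cat(sprintf("<gmm_selection> K selected by BIC: %d (ICL minimum at K = %d)\n",
              x$selected_K, x$icl_K))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Confidence ellipse of a bivariate Gaussian component
#'
#' Semi-axes are `sqrt(qchisq(level, 2) * eigenvalues)` of the covariance;
#' the rotation is the angle of the leading eigenvector. At the default 95%
#' level the chi-squared quantile is 5.9915.
#'
#' @param mean length-2 center.
#' @param covariance 2 x 2 positive-definite covariance.
#' @param level confidence level (default 0.95).
#' @return object of class `gauss_ellipse`: `center`, `axes` (semi-axis
#'   lengths, major first), `rotation` (degrees), `level`.
#' @export
confidence_ellipse <- function(mean, covariance, level = 0.95) {
  covariance <- as.matrix(covariance)
  e <- eigen(covariance, symmetric = TRUE)
  if (min(e$values) <= 0) stop("covariance must be positive definite")
  q <- qchisq(level, df = 2)
  structure(list(center = as.numeric(mean),
                 axes = sqrt(q * e$values),
                 rotation = rad2deg(atan2(e$vectors[2, 1], e$vectors[1, 1])),
                 level = level),
            class = "gauss_ellipse")
}

#' @export
print.gauss_ellipse <- function(x, ...) {
  cat(sprintf("<gauss_ellipse> center (%.3f, %.3f), semi-axes %.3f x %.3f, rotation %.1f deg, level %.2f\n",
              x$center[1], x$center[2], x$axes[1], x$axes[2], x$rotation, x$level))
  invisible(x)
}

#' Points on a confidence ellipse (for plotting)
#'
#' @param ellipse a [confidence_ellipse()].
#' @param n number of points (default 100).
#' @return n x 2 matrix of (x, y) coordinates.
#' @export
ellipse_points <- function(ellipse, n = 100L) {
  th <- seq(0, 2 * pi, length.out = n)
  rot <- deg2rad(ellipse$rotation)
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2L, 2L)
  pts <- cbind(ellipse$axes[1] * cos(th), ellipse$axes[2] * sin(th)) %*% t(R)
  sweep(pts, 2L, ellipse$center, `+`)
}
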