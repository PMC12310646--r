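#' Expected count under drug-event independence
#'
#' The baseline for shrinkage methods: with 2x2 cells (a, b, c, d) and
#' database size n, the count expected if drug and event reported
#' independently is `E = (a+b)(a+c)/n`.
#'
#' @param a,b,c,d Cell counts (vectorized).
#' @return Numeric vector of expected counts.
#' @export
expected_count <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  if (any(n == 0)) abort("empty table: n must be positive")
  (a + b) * (a + c) / n
}

# log of the two-component negative-binomial mixture marginal of the
# gamma-Poisson model: a | lambda ~ Poisson(lambda E),
# lambda ~ w Gamma(a1, b1) + (1-w) Gamma(a2, b2)
.log_marginal_components <- function(a, e, p) {
  l1 <- dnbinom(a, size = p[1], prob = p[2] / (p[2] + e), log = TRUE)
  l2 <- dnbinom(a, size = p[3], prob = p[4] / (p[4] + e), log = TRUE)
  cbind(as.vector(l1), as.vector(l2), deparse.level = 0)
}

.logsumexp2 <- function(x, y) {
  m <- pmax(x, y)
  m + log(exp(x - m) + exp(y - m))
}

#' Fit the DuMouchel gamma-mixture prior (MGPS)
#'
#' The multi-item gamma Poisson shrinker models the relative reporting
#' rate of every drug-event pair as drawn from a two-component gamma
#' mixture `w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)`.
#' The prior is fitted by maximizing the marginal likelihood -- a mixture
#' of negative binomials -- over all supplied (a, E) cells, by bounded
#' quasi-Newton (L-BFGS-B) from the canonical start
#' `(0.2, 0.1, 2.0, 4.0, 1/3)`. Deterministic given data and start; if
#' the likelihood is non-finite at the start, a fixed log-spaced grid of
#' restarts is tried in order.
#'
#' @param a Observed counts per cell.
#' @param e Expected counts per cell (all positive).
#' @param start Numeric 5-vector `(alpha1, beta1, alpha2, beta2, w)`.
#' @param truncated Fit conditional on `a >= 1` (zero cells excluded from
#'   the likelihood by renormalization).
#' @return A `gps_prior` object: list with `alpha1`, `beta1`, `alpha2`,
#'   `beta2`, `w`, `loglik`, `convergence`, `n_cells`.
#' @export
fit_gamma_mixture_prior <- function(a, e,
                                    start = c(0.2, 0.1, 2.0, 4.0, 1 / 3),
                                    truncated = FALSE) {
  keep <- is.finite(a) & is.finite(e) & e > 0
  a <- a[keep]; e <- e[keep]
  if (truncated) { e <- e[a >= 1]; a <- a[a >= 1] }
  if (length(a) < 2) abort("need at least 2 cells to fit the prior")
  lo <- c(rep(1e-4, 4), 1e-4)
  hi <- c(rep(1e4, 4), 1 - 1e-4)
  negll <- function(p) {
    lm <- .log_marginal_components(a, e, p)
    ll <- .logsumexp2(log(p[5]) + lm[, 1], log(1 - p[5]) + lm[, 2])
    if (truncated) {
      l0 <- .log_marginal_components(0, e, p)
      p0 <- exp(.logsumexp2(log(p[5]) + l0[, 1], log(1 - p[5]) + l0[, 2]))
      ll <- ll - log1p(-p0)
    }
    v <- -sum(ll)
    if (!is.finite(v)) 1e12 else v
  }
  starts <- list(start)
  # deterministic fallback grid, tried in order only if needed
  for (s in c(0.5, 2)) starts <- c(starts, list(pmin(pmax(start * s, lo), hi)))
  fit <- NULL
  for (s0 in starts) {
    if (!is.finite(negll(s0)) || negll(s0) >= 1e12) next
    fit <- optim(s0, negll, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 500))
    break
  }
  if (is.null(fit)) abort("gamma-mixture likelihood non-finite at all starts")
  structure(list(alpha1 = fit$par[1], beta1 = fit$par[2],
                 alpha2 = fit$par[3], beta2 = fit$par[4],
                 w = fit$par[5], loglik = -fit$value,
                 convergence = fit$convergence, n_cells = length(a),
                 truncated = truncated),
            class = "gps_prior")
}

#' @export
print.gps_prior <- function(x, ...) {
  cat("<gps_prior> w =", signif(x$w, 4),
      "| Gamma(", signif(x$alpha1, 4), ",", signif(x$beta1, 4), ") /",
      "Gamma(", signif(x$alpha2, 4), ",", signif(x$beta2, 4), ")",
      "| loglik", signif(x$loglik, 6), "on", x$n_cells, "cells\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @exportS3Method generics::tidy
tidy.gps_prior <- function(x, ...) {
  tibble(term = c("alpha1", "beta1", "alpha2", "beta2", "w"),
         estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$w))
}

#' @exportS3Method generics::glance
glance.gps_prior <- function(x, ...) {
  tibble(loglik = x$loglik, n_cells = x$n_cells,
         convergence = x$convergence,
         prior_mean = x$w * x$alpha1 / x$beta1 +
           (1 - x$w) * x$alpha2 / x$beta2)
}

#' Posterior mixture for one or more cells
#'
#' Conjugate update: each gamma component becomes
#' `Gamma(alpha_i + a, beta_i + E)`; the posterior weight of component 1
#' is the Bayes factor of the two negative-binomial marginals times the
#' prior odds, normalized.
#'
#' @param a,e Observed and expected counts (vectorized).
#' @param prior A `gps_prior`.
#' @return Tibble with columns `q`, `shape1`, `rate1`, `shape2`, `rate2`.
#' @export
gps_posterior <- function(a, e, prior) {
  stopifnot(inherits(prior, "gps_prior"))
  if (any(e <= 0)) abort("expected counts must be positive")
  p <- c(prior$alpha1, prior$beta1, prior$alpha2, prior$beta2, prior$w)
  lm <- .log_marginal_components(a, e, p)
  lq1 <- log(p[5]) + lm[, 1]
  lq2 <- log(1 - p[5]) + lm[, 2]
  q <- 1 / (1 + exp(lq2 - lq1))
  if (prior$w == 1) q <- rep(1, length(a))
  tibble(q = q,
         shape1 = prior$alpha1 + a, rate1 = prior$beta1 + e,
         shape2 = prior$alpha2 + a, rate2 = prior$beta2 + e)
}

#' Empirical-Bayes geometric mean (EBGM)
#'
#' The geometric mean of the posterior relative reporting rate:
#' `exp(E[log lambda])` with
#' `E[log lambda] = q (psi(shape1) - log rate1) +
#'  (1-q)(psi(shape2) - log rate2)`, `psi` the digamma function.
#'
#' @param post Posterior tibble from [gps_posterior()].
#' @return Numeric vector of EBGM values.
#' @export
ebgm_from_posterior <- function(post) {
  exp(post$q * (digamma(post$shape1) - log(post$rate1)) +
        (1 - post$q) * (digamma(post$shape2) - log(post$rate2)))
}

#' Lower posterior percentile (EB05)
#'
#' Solves `q F(x; shape1, rate1) + (1-q) F(x; shape2, rate2) = p` for x
#' by bisection between the two component quantiles, to relative
#' tolerance 1e-8.
#'
#' @param post Posterior tibble from [gps_posterior()].
#' @param p Probability level (default 0.05).
#' @return Numeric vector of mixture p-quantiles.
#' @export
eb05_from_posterior <- function(post, p = 0.05) {
  vapply(seq_len(nrow(post)), function(i) {
    q <- post$q[i]
    q1 <- qgamma(p, post$shape1[i], post$rate1[i])
    q2 <- qgamma(p, post$shape2[i], post$rate2[i])
    lo <- min(q1, q2); hi <- max(q1, q2)
    if (hi - lo < 1e-14) return(lo)
    cdf <- function(x) {
      q * pgamma(x, post$shape1[i], post$rate1[i]) +
        (1 - q) * pgamma(x, post$shape2[i], post$rate2[i])
    }
    for (iter in 1:200) {
      mid <- (lo + hi) / 2
      if (cdf(mid) < p) lo <- mid else hi <- mid
      if ((hi - lo) <= 1e-8 * max(hi, 1e-12)) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' BCPNN information component
#'
#' Two conventions are supported. `"noren"` is the self-contained
#' credibility-interval approximation:
#' `ic = log2((a + 0.5)/(E + 0.5))`,
#' `ic025 = ic - 3.3 (a + 0.5)^{-1/2} - 2.0 (a + 0.5)^{-3/4}`.
#' `"mgps"` derives the IC from the gamma-Poisson shrinkage estimate:
#' `ic = log2(ebgm)` with a normal-approximation lower bound
#' `ic025 = ic - z / (sqrt(a) ln 2)`, undefined at `a = 0`.
#'
#' @param a,e Observed and expected counts.
#' @param ebgm EBGM values (required for the `"mgps"` convention).
#' @param convention `"mgps"` or `"noren"`.
#' @param z Normal quantile for the `"mgps"` lower bound.
#' @return Tibble with columns `ic`, `ic025`.
#' @export
compute_ic <- function(a, e, ebgm = NULL,
                       convention = c("mgps", "noren"), z = 1.96) {
  convention <- match.arg(convention)
  if (convention == "noren") {
    ic <- log2((a + 0.5) / (e + 0.5))
    ic025 <- ic - 3.3 * (a + 0.5)^(-1 / 2) - 2.0 * (a + 0.5)^(-3 / 4)
  } else {
    if (is.null(ebgm)) abort("ebgm required for the mgps IC convention")
    ic <- log2(ebgm)
    ic025 <- ifelse(a > 0, ic - z / (sqrt(a) * log(2)), NA_real_)
  }
  tibble(ic = ic, ic025 = ic025)
}
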