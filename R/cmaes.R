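# Compact (mu/mu_w, lambda) CMA-ES with cumulative step-size adaptation
# and rank-one + rank-mu covariance updates. Box constraints are
# enforced by projection with a quadratic repair penalty. Deterministic
# given the RNG state at entry.

#' Covariance matrix adaptation evolution strategy
#'
#' Minimizes \code{fn} over a box. Standard parametrization: population
#' \code{4 + floor(3 log n)}, weighted recombination of the best half,
#' cumulative step-size control and covariance adaptation. Out-of-box
#' proposals are evaluated at the projected point plus a quadratic
#' distance penalty. Uses the current R RNG stream; seed with
#' \code{set.seed()} (the fitting front-end does this) for reproducible
#' runs.
#'
#' @param fn objective, a function of a numeric vector.
#' @param x0 start point.
#' @param sigma0 initial step size (same scale as \code{x0}).
#' @param lower,upper box bounds.
#' @param max_evals evaluation budget.
#' @param ftol stop when the best value improves by less than this over
#'   a full generation window.
#' @return List with \code{par}, \code{value}, \code{evals},
#'   \code{n_iter}.
#' @keywords internal
cmaes_minimize <- function(fn, x0, sigma0, lower, upper,
                           max_evals = 2000, ftol = 1e-10) {
  n <- length(x0)
  lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)
  cc <- (4 + mu_eff / n) / (n + 4 + 2 * mu_eff / n)
  cs <- (mu_eff + 2) / (n + mu_eff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((n + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n); invsqrtC <- diag(n)
  eigen_stale <- 0
  best_x <- xmean; best_f <- Inf
  evals <- 0L; iter <- 0L; last_best <- Inf; stall <- 0L

  penalized <- function(x) {
    xr <- pmin(pmax(x, lower), upper)
    f <- fn(xr)
    if (!is.finite(f)) f <- 1e10
    f + 1e4 * sum((x - xr)^2)
  }

  while (evals < max_evals) {
    iter <- iter + 1L
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    BD <- t(chol(C + diag(1e-14, n)))
    Y <- BD %*% Z
    X <- xmean + sigma * Y
    f <- apply(X, 2, penalized)
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) {
      best_f <- f[ord[1]]
      best_x <- pmin(pmax(X[, ord[1]], lower), upper)
    }
    sel <- ord[seq_len(mu)]
    ymean <- as.numeric(Y[, sel, drop = FALSE] %*% w)
    xmean <- xmean + sigma * ymean
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mu_eff) * (invsqrtC %*% (ymean))
    hsig <- as.numeric(sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * iter)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * ymean
    artmp <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %*% t(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sigma) || sigma > 1e3 * sigma0) sigma <- sigma0
    eigen_stale <- eigen_stale + 1
    if (eigen_stale >= max(1, floor(1 / (10 * n * (c1 + cmu))))) {
      eigen_stale <- 0
      eg <- eigen(C, symmetric = TRUE)
      ev <- pmax(eg$values, 1e-14)
      invsqrtC <- eg$vectors %*% (t(eg$vectors) / sqrt(ev))
      if (max(ev) / min(ev) > 1e14) C <- diag(n) * mean(ev)
    }
    if (abs(last_best - best_f) < ftol) stall <- stall + 1L else stall <- 0L
    last_best <- best_f
    if (stall >= 10L + ceiling(30 * n / lambda)) break
  }
  list(par = best_x, value = best_f, evals = evals, n_iter = iter)
}
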