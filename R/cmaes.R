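#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Standard (mu/mu_w, lambda) CMA-ES minimiser with rank-based recombination
#' weights, cumulative step-size adaptation and rank-one plus rank-mu
#' covariance updates. Box constraints are handled by repairing samples to
#' the box and adding a quadratic repair penalty to the objective.
#' Deterministic given `seed`.
#'
#' @param fn objective function of a numeric vector; may return `Inf`.
#' @param x0 initial mean.
#' @param sigma0 initial step size (on the scale of `x0`).
#' @param lower,upper box bounds (recycled).
#' @param seed integer RNG seed.
#' @param maxeval evaluation budget.
#' @param lambda population size; default `4 + floor(3 log n)`.
#' @param tolfun stop when the best-cost range over the last 10 + 30n/lambda
#'   generations falls below this.
#' @param tolx stop when the search distribution's axis lengths fall below
#'   `tolx * sigma0`.
#' @return List with `par`, `value`, `counts`, `trace` (best cost per
#'   generation), `convergence` (0 converged, 1 budget exhausted).
#' @export
cma_es <- function(fn, x0, sigma0 = 0.3, lower = -Inf, upper = Inf,
                   seed = 1, maxeval = 5000, lambda = NULL,
                   tolfun = 1e-10, tolx = 1e-12) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  set.seed(seed)
  if (is.null(lambda)) lambda <- 4 + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n); invsqrtC <- diag(n)
  eigen_stale <- 0
  best_x <- xmean; best_f <- Inf
  trace <- numeric(0)
  evals <- 0; gen <- 0
  hist_len <- ceiling(10 + 30 * n / lambda)
  repair_pen <- 1e6

  while (evals < maxeval) {
    gen <- gen + 1
    Z <- matrix(stats::rnorm(n * lambda), nrow = n)
    Y <- t(chol(C)) %*% Z
    X <- xmean + sigma * Y
    Xr <- pmin(pmax(X, lower), upper)
    f <- numeric(lambda)
    for (k in seq_len(lambda)) {
      fk <- fn(Xr[, k])
      if (!is.finite(fk)) fk <- 1e12
      f[k] <- fk + repair_pen * sum((X[, k] - Xr[, k])^2)
    }
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) { best_f <- f[ord[1]]; best_x <- Xr[, ord[1]] }
    trace <- c(trace, best_f)

    ysel <- Y[, ord[seq_len(mu)], drop = FALSE]
    ymean <- drop(ysel %*% w)
    xmean <- xmean + sigma * ymean
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% ymean)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * ysel %*% (w * t(ysel))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    eigen_stale <- eigen_stale + 1
    if (eigen_stale > 1 / ((c1 + cmu) * n * 10)) {
      eigen_stale <- 0
      C <- (C + t(C)) / 2
      e <- eigen(C, symmetric = TRUE)
      e$values <- pmax(e$values, 1e-20)
      invsqrtC <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
      C <- e$vectors %*% (t(e$vectors) * e$values)
    }
    if (length(trace) >= hist_len) {
      recent <- trace[(length(trace) - hist_len + 1):length(trace)]
      if (max(recent) - min(recent) < tolfun) break
    }
    if (sigma * sqrt(max(diag(C))) < tolx * sigma0) break
    if (!is.finite(sigma) || sigma > 1e8) break
  }
  list(par = best_x, value = best_f, counts = evals, trace = trace,
       convergence = if (evals >= maxeval) 1L else 0L)
}
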