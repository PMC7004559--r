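#' Sobol variance-based sensitivity indices
#'
#' First-order and total-effect Sobol indices of a scalar function over a
#' bounded parameter box, by Saltelli-type sampling with the Jansen
#' estimators. Parameters whose total index falls below `threshold` are
#' flagged non-identifiable in the sense that the cost surface carries no
#' information about them.
#'
#' @param fn scalar function of a numeric parameter vector.
#' @param lower,upper box bounds (finite, equal length).
#' @param n base sample size (total evaluations `n * (k + 2)`).
#' @param seed RNG seed.
#' @param threshold total-index cutoff flagging poor sensitivity.
#' @param names optional parameter names.
#' @return Data frame `parameter, first_order, total, non_identifiable`,
#'   with the output variance as attribute `"variance"`.
#' @export
sobol_sensitivity <- function(fn, lower, upper, n = 1024, seed = 1,
                              threshold = 0.01, names = NULL) {
  k <- length(lower)
  stopifnot(length(upper) == k, all(is.finite(lower)), all(is.finite(upper)))
  if (any(upper <= lower)) stop("degenerate bounds")
  if (is.null(names)) names <- paste0("x", seq_len(k))
  set.seed(seed)
  scale_mat <- function(U) sweep(sweep(U, 2, upper - lower, "*"), 2, lower, "+")
  A <- scale_mat(matrix(stats::runif(n * k), n, k))
  B <- scale_mat(matrix(stats::runif(n * k), n, k))
  evals <- function(M) apply(M, 1, fn)
  fA <- evals(A); fB <- evals(B)
  V <- stats::var(c(fA, fB))
  first <- total <- numeric(k)
  for (i in seq_len(k)) {
    ABi <- A; ABi[, i] <- B[, i]
    fABi <- evals(ABi)
    first[i] <- (V - mean((fB - fABi)^2) / 2) / V   # Jansen first-order
    total[i] <- mean((fA - fABi)^2) / 2 / V         # Jansen total
  }
  out <- data.frame(parameter = names, first_order = first, total = total,
                    non_identifiable = total < threshold)
  attr(out, "variance") <- V
  out
}

#' Likelihood profile of one parameter
#'
#' Cost profile over a grid of fixed values of one parameter, with all
#' other free parameters re-optimised at each grid point (warm-started at
#' the fit optimum). A flat profile indicates practical non-identifiability;
#' the confidence interval is where the profile stays below
#' `min + qchisq(level, 1)`.
#'
#' @param fit a [fit_pk()] result.
#' @param parameter name of the profiled parameter.
#' @param grid values of the parameter (natural scale).
#' @param maxeval CMA-ES budget per grid point.
#' @param level confidence level of the threshold crossing.
#' @param flat_tol profile range (in cost units) below which the parameter
#'   is declared practically non-identifiable.
#' @return Object of class `likelihood_profile`: data frame of
#'   `value, cost, convergence` plus `verdict`, `ci` and `threshold`.
#' @export
likelihood_profile <- function(fit, parameter, grid, maxeval = 400,
                               level = 0.95,
                               flat_tol = stats::qchisq(0.95, 1)) {
  stopifnot(parameter %in% fit$free)
  others <- setdiff(fit$free, parameter)
  cost <- numeric(length(grid))
  conv <- integer(length(grid))
  failed <- logical(length(grid))
  for (i in seq_along(grid)) {
    template <- fit$coef
    template[parameter] <- grid[i]
    model_fn <- make_model_fn(fit$drug, fit$data, fit$vols, fit$delivery,
                              template, others,
                              horizon = fit$constraints$horizon)
    obj <- function(lx) wls_cost(10^lx, fit$data, model_fn, fit$error_cv,
                                 fit$lloq, fit$constraints)
    if (length(others)) {
      x0 <- log10(unclass(fit$coef)[others])
      res <- tryCatch(
        cma_es(obj, x0, sigma0 = 0.2, lower = x0 - 2, upper = x0 + 2,
               seed = fit$optimizer$seed + i, maxeval = maxeval),
        error = function(e) NULL)
      if (is.null(res)) { failed[i] <- TRUE; cost[i] <- NA; next }
      cost[i] <- res$value; conv[i] <- res$convergence
    } else cost[i] <- obj(numeric(0))
  }
  ok <- !failed
  rng <- diff(range(cost[ok]))
  threshold <- min(cost[ok]) + stats::qchisq(level, 1)
  inside <- grid[ok][cost[ok] <= threshold]
  structure(list(profile = data.frame(value = grid, cost = cost,
                                      convergence = conv, failed = failed),
                 verdict = if (rng < flat_tol) "practically non-identifiable"
                           else "identifiable",
                 ci = range(inside), threshold = threshold),
            class = "likelihood_profile")
}

#' @export
print.likelihood_profile <- function(x, ...) {
  cat(sprintf("Likelihood profile: %s; 95%% CI [%.4g, %.4g] (threshold %.3g)\n",
              x$verdict, x$ci[1], x$ci[2], x$threshold))
  if (any(x$profile$failed))
    cat(sprintf("  %d grid point(s) failed to optimise\n",
                sum(x$profile$failed)))
  invisible(x)
}

#' @export
plot.likelihood_profile <- function(x, ...) {
  graphics::plot(x$profile$value, x$profile$cost, type = "b",
                 xlab = "parameter value", ylab = "profile cost", ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
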