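#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("PK model fit [%s]: %d observations, %d free parameter(s)\n",
              x$drug, nrow(x$data), length(x$free)))
  cat(sprintf("  weighted SSR %.4g, pooled R-squared %.4f\n",
              x$ssr_weighted, x$r_squared[["pooled"]]))
  cat("  estimates:\n")
  print(round(unclass(x$coef)[x$free], 6))
  invisible(x)
}

#' @export
summary.pk_fit <- function(object, ...) {
  g <- goodness(object)
  out <- list(drug = object$drug, coef = unclass(object$coef),
              free = object$free, ssr = g$ssr,
              ssr_unweighted = g$ssr_unweighted, r_squared = g$r_squared,
              constraint_residuals = object$constraint_residuals,
              optimizer = object$optimizer[c("seed", "evaluations",
                                             "convergence")])
  class(out) <- "summary.pk_fit"
  out
}

#' @export
print.summary.pk_fit <- function(x, ...) {
  cat(sprintf("PK model fit [%s]\n", x$drug))
  cat("Parameters (fitted marked *):\n")
  mark <- ifelse(names(x$coef) %in% x$free, "*", " ")
  for (i in seq_along(x$coef))
    cat(sprintf("  %s %-10s %.6g\n", mark[i], names(x$coef)[i], x$coef[i]))
  cat(sprintf("Weighted SSR: %.6g (unweighted %.6g)\n",
              x$ssr, x$ssr_unweighted))
  cat("R-squared:\n"); print(round(x$r_squared, 4))
  if (!is.null(x$constraint_residuals)) {
    cat("Clearance-constraint residuals (percentage points):\n")
    print(round(x$constraint_residuals, 2))
  }
  cat(sprintf("Optimizer: seed %d, %d evaluations, %s\n",
              x$optimizer$seed, x$optimizer$evaluations,
              if (x$optimizer$convergence == 0) "converged"
              else "budget exhausted"))
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) unclass(object$coef)

#' @export
fitted.pk_fit <- function(object, ...) object$fitted_values

#' @export
residuals.pk_fit <- function(object,
                             type = c("response", "weighted"), ...) {
  type <- match.arg(type)
  r <- object$data$conc_mg_per_L - object$fitted_values
  if (type == "weighted")
    r <- r / pmax(object$error_cv * object$data$conc_mg_per_L,
                  object$error_cv * object$lloq)
  r
}

#' Predict blood concentrations from a fitted PK model
#'
#' @param object a [fit_pk()] result.
#' @param times prediction times (hours post infusion onset); defaults to a
#'   dense grid over the data range.
#' @param analyte analyte name(s); all model analytes when `NULL`.
#' @param ... unused.
#' @return Data frame `analyte, time_h, conc_mg_per_L`.
#' @export
predict.pk_fit <- function(object, times = NULL, analyte = NULL, ...) {
  if (is.null(times))
    times <- seq(0, max(object$data$time_h), length.out = 200)
  sim <- simulate_pk(object$drug, object$coef, object$vols,
                     object$delivery, max(times),
                     times = sort(unique(c(0, times))))
  out <- sample_concentrations(sim, times, analyte = analyte,
                               patient_id = "prediction")
  out[c("analyte", "time_h", "conc_mg_per_L")]
}

#' Simulate noisy datasets from a fitted PK model
#'
#' Parametric simulation: model predictions at the observed design times
#' multiplied by `(1 + error_cv * N(0,1))`, truncated at zero.
#'
#' @param object a [fit_pk()] result.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return List of data frames shaped like the fitting data.
#' @export
simulate.pk_fit <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    d <- object$data
    eps <- stats::rnorm(nrow(d))
    d$conc_mg_per_L <- pmax(0, object$fitted_values *
                              (1 + object$error_cv * eps))
    d
  })
}

#' @export
plot.pk_fit <- function(x, ...) {
  analytes <- unique(x$data$analyte)
  old <- graphics::par(mfrow = c(1, length(analytes)))
  on.exit(graphics::par(old))
  pred <- predict(x)
  for (a in analytes) {
    d <- x$data[x$data$analyte == a, ]
    p <- pred[pred$analyte == a, ]
    graphics::plot(d$time_h, d$conc_mg_per_L, xlab = "time (h)",
                   ylab = "conc (mg/L)", main = a,
                   ylim = range(0, d$conc_mg_per_L, p$conc_mg_per_L), ...)
    graphics::lines(p$time_h, p$conc_mg_per_L)
  }
  invisible(x)
}
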