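#' Literature-derived clearance-route targets
#'
#' Percent-of-dose constraints placed on the clearance routes during
#' fitting: irinotecan 25% renal, 60% combined biliary + intestinal CPT11,
#' 15% total SN38 elimination; oxaliplatin 54% renal with 84% / 12% of the
#' dose bound in Organs / Liver at the end of the observation window;
#' 5-fluorouracil about 80% hepatic.
#'
#' @param drug `"CPT11"`, `"LOHP"` or `"FU5"`.
#' @return Named numeric vector of target percentages.
#' @export
clearance_targets <- function(drug = c("CPT11", "LOHP", "FU5")) {
  switch(match.arg(drug),
         CPT11 = c(renal = 25, biliary_intestinal = 60, sn38 = 15),
         LOHP = c(renal = 54, bound_organs = 84, bound_liver = 12),
         FU5 = c(hepatic = 80))
}

## prediction closure aligned with the rows of `data`
make_model_fn <- function(drug, data, vols, delivery, template, free,
                          horizon = NULL, rtol = 1e-8) {
  if (is.null(horizon))
    horizon <- max(data$time_h, if (!is.null(delivery)) max(delivery$times))
  sim_times <- sort(unique(c(0, data$time_h, horizon)))
  analytes <- unique(data$analyte)
  idx <- lapply(analytes, function(a) which(data$analyte == a))
  names(idx) <- analytes
  function(theta) {
    params <- template
    params[free] <- theta
    sim <- simulate_pk(drug, params, vols, delivery, horizon,
                       times = sim_times, rtol = rtol)
    pred <- numeric(nrow(data))
    for (a in analytes) {
      if (!a %in% colnames(sim$conc))
        stop("analyte not produced by the ", drug, " model: ", a)
      pred[idx[[a]]] <- stats::approx(sim$times, sim$conc[, a],
                                      data$time_h[idx[[a]]], rule = 2)$y
    }
    list(pred = pred, sim = sim)
  }
}

#' Weighted least-squares cost with proportional error
#'
#' Sum over all observations of `((pred - obs) / max(0.1 obs, 0.1 LLOQ))^2`
#' (proportional measurement error of 10%, floored at the quantification
#' limit so baseline-zero samples keep finite weights), plus quadratic
#' penalties on clearance-fraction constraint violations. Simulation
#' failures return `Inf` so derivative-free optimisers can proceed.
#'
#' @param theta values of the free parameters.
#' @param data concentration data frame
#'   (`patient_id, analyte, time_h, conc_mg_per_L`).
#' @param model_fn closure from the fit setup mapping `theta` to
#'   predictions (see [fit_pk()]); it receives the free-parameter vector.
#' @param error_cv proportional error (default 0.10).
#' @param lloq lower limit of quantification, mg/L, flooring the weights.
#' @param constraints optional list with `targets` (named percentages),
#'   `weight` (penalty weight per squared percentage point) and `dose`.
#' @return Scalar cost.
#' @export
wls_cost <- function(theta, data, model_fn, error_cv = 0.1, lloq = 0.01,
                     constraints = NULL) {
  res <- tryCatch(model_fn(theta), error = function(e) NULL)
  if (is.null(res)) return(Inf)
  denom <- pmax(error_cv * data$conc_mg_per_L, error_cv * lloq)
  cost <- sum(((res$pred - data$conc_mg_per_L) / denom)^2)
  if (!is.null(constraints)) {
    fr <- clearance_fractions(res$sim, dose = constraints$dose)
    tg <- constraints$targets
    w <- constraints$weight %||% 1
    cost <- cost + w * sum((fr[names(tg)] - tg)^2)
  }
  cost
}

#' Fit a drug PK model to concentration data
#'
#' Minimises the 10%-proportional-error weighted least-squares cost (plus
#' optional clearance-route penalties) over the chosen free parameters by
#' CMA-ES in log-parameter space, deterministically under `seed`. Fixed
#' parameters keep their values from `start`. Pooled fits are supported by
#' passing the concatenated series of several patients.
#'
#' @param data concentration data frame with columns
#'   `patient_id, analyte, time_h, conc_mg_per_L`.
#' @param drug `"CPT11"`, `"LOHP"` or `"FU5"`.
#' @param vols a [compute_compartment_volumes()] result.
#' @param delivery a [delivery_profile()] driving the Liver compartment.
#' @param start full parameter vector (e.g. [irinotecan_params()]); values
#'   of the free parameters are the search start, the rest stay fixed
#'   (`Km` is always fixed).
#' @param free names of the parameters to estimate.
#' @param lower,upper bounds on the free parameters (natural scale);
#'   default spans two orders of magnitude either side of `start`.
#' @param constraints optional list(`targets`, `weight`, `horizon`): see
#'   [clearance_targets()]. `NULL` disables the penalties.
#' @param error_cv,lloq proportional error model, see [wls_cost()].
#' @param seed RNG seed (optimizer is deterministic given the seed).
#' @param maxeval CMA-ES evaluation budget.
#' @param sigma0 initial CMA-ES step size in log10-parameter space.
#' @param rtol ODE solver relative tolerance.
#' @return An object of class `pk_fit` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate` and `plot` methods.
#' @export
fit_pk <- function(data, drug = c("CPT11", "LOHP", "FU5"), vols, delivery,
                   start, free = NULL, lower = NULL, upper = NULL,
                   constraints = NULL, error_cv = 0.1, lloq = 0.01,
                   seed = 1, maxeval = 1500, sigma0 = 0.3, rtol = 1e-8) {
  drug <- match.arg(drug)
  stopifnot(all(c("analyte", "time_h", "conc_mg_per_L") %in% names(data)))
  if (is.null(free)) free <- setdiff(names(start), "Km")
  free <- setdiff(free, "Km")          # Km is fixed during fitting
  stopifnot(all(free %in% names(start)))
  if (length(free) > sum(data$conc_mg_per_L > 0))
    warning("fewer informative data points than free parameters")
  if (is.null(lower)) lower <- unclass(start)[free] / 100
  if (is.null(upper)) upper <- unclass(start)[free] * 100
  horizon <- if (!is.null(constraints)) constraints$horizon else NULL
  model_fn <- make_model_fn(drug, data, vols, delivery, start, free,
                            horizon = horizon, rtol = rtol)
  if (!is.null(constraints)) {
    constraints$targets <- constraints$targets %||% clearance_targets(drug)
    constraints$dose <- constraints$dose %||%
      (if (!is.null(delivery)) max(delivery$cumulative) else NULL)
  }
  obj <- function(lx) wls_cost(10^lx, data, model_fn, error_cv, lloq,
                               constraints)
  res <- cma_es(obj, log10(unclass(start)[free]), sigma0 = sigma0,
                lower = log10(lower), upper = log10(upper),
                seed = seed, maxeval = maxeval)
  theta <- 10^res$par
  best <- model_fn(theta)
  params <- start
  params[free] <- theta
  denom <- pmax(error_cv * data$conc_mg_per_L, error_cv * lloq)
  ssr_w <- sum(((best$pred - data$conc_mg_per_L) / denom)^2)
  constraint_resid <- if (!is.null(constraints)) {
    fr <- clearance_fractions(best$sim, dose = constraints$dose)
    fr[names(constraints$targets)] - constraints$targets
  } else NULL
  fit <- structure(list(
    coef = params, free = free, drug = drug, data = data,
    vols = vols, delivery = delivery,
    fitted_values = best$pred, cost = res$value, ssr_weighted = ssr_w,
    constraint_residuals = constraint_resid, constraints = constraints,
    error_cv = error_cv, lloq = lloq, model_fn = model_fn,
    optimizer = list(seed = seed, evaluations = res$counts,
                     trace = res$trace, convergence = res$convergence)),
    class = "pk_fit")
  fit$r_squared <- goodness(fit)$r_squared
  fit
}

#' Goodness of fit: SSR and R-squared
#'
#' `R^2 = 1 - SSR_unweighted / SS_total` computed on unweighted residuals,
#' per analyte and pooled over all observations; the weighted SSR of the
#' fit is reported alongside.
#'
#' @param fit a [fit_pk()] result.
#' @return List with `ssr` (weighted), `ssr_unweighted` and `r_squared`
#'   (named vector per analyte plus `"pooled"`).
#' @export
goodness <- function(fit) {
  obs <- fit$data$conc_mg_per_L
  pred <- fit$fitted_values
  by_a <- split(seq_along(obs), fit$data$analyte)
  r2_one <- function(i) {
    sst <- sum((obs[i] - mean(obs[i]))^2)
    if (sst == 0) stop("constant data: total sum of squares is zero")
    1 - sum((obs[i] - pred[i])^2) / sst
  }
  r2 <- vapply(by_a, r2_one, numeric(1))
  r2 <- c(r2, pooled = r2_one(seq_along(obs)))
  list(ssr = fit$ssr_weighted, ssr_unweighted = sum((obs - pred)^2),
       r_squared = r2)
}

#' Realign samples scheduled at the glucose flush start
#'
#' Blood draws scheduled at the flush start may have been taken during the
#' flush spike. For each patient/analyte series the sample at `flush_time`
#' is moved to the glucose peak time (`flush_time + shift`, 15 min after
#' flush start) when its concentration exceeds the preceding point's;
#' otherwise (preceding point greater) the flush had presumably not yet
#' occurred and the time is unchanged.
#'
#' @param data concentration data frame
#'   (`patient_id, analyte, time_h, conc_mg_per_L`).
#' @param flush_time scheduled sampling time coinciding with the flush
#'   start, hours post infusion onset.
#' @param shift flush peak offset, hours (default 0.25 = 15 min).
#' @param tol time-matching tolerance, hours.
#' @return The data frame with adjusted times; the per-patient adjustments
#'   are attached as attribute `"realigned"`.
#' @export
realign_flush_timepoints <- function(data, flush_time, shift = 0.25,
                                     tol = 1e-6) {
  key <- interaction(data$patient_id, data$analyte, drop = TRUE)
  moved <- character(0)
  for (g in levels(key)) {
    i <- which(key == g)
    i <- i[order(data$time_h[i])]
    j <- which(abs(data$time_h[i] - flush_time) < tol)
    if (!length(j)) next
    j <- i[j[1]]
    pos <- match(j, i)
    if (pos == 1) stop("missing preceding point before the flush sample")
    prev <- i[pos - 1]
    if (data$conc_mg_per_L[j] > data$conc_mg_per_L[prev]) {
      data$time_h[j] <- flush_time + shift
      moved <- c(moved, g)
    }
  }
  attr(data, "realigned") <- moved
  data
}
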