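#' Trial sampling grids
#'
#' Post-infusion-onset blood sampling times (hours) of the OPTILIV
#' schedules: irinotecan at 0, 2, 3, 4, 6, 8 h 15 and 31 h 45; oxaliplatin
#' at 0, 3, 6, 9, 11 h 30 and 17 h 15; 5-fluorouracil at 0, ~3 (fixed at
#' 3.0), 5 h 45, 9 and 11 h 30.
#'
#' @param drug `"CPT11"`, `"LOHP"` or `"FU5"`.
#' @return Numeric vector of sampling times in hours.
#' @export
sampling_grid <- function(drug = c("CPT11", "LOHP", "FU5")) {
  switch(match.arg(drug),
         CPT11 = c(0, 2, 3, 4, 6, 8.25, 31.75),
         LOHP = c(0, 3, 6, 9, 11.5, 17.25),
         FU5 = c(0, 3, 5.75, 9, 11.5))
}

#' Default PK parameter means of the synthetic cohort
#'
#' Order-of-magnitude physiologic values chosen so that simulated plasma
#' profiles qualitatively reproduce the observed shapes (rapid irinotecan
#' rise, free-platinum spike at the glucose flush, fast 5-fluorouracil
#' decay) and so that the clearance-route fractions sit near their
#' literature targets. They are synthetic defaults, not estimates of any
#' patient's values.
#'
#' @param drug `"CPT11"`, `"LOHP"` or `"FU5"`.
#' @return A `pk_params` vector.
#' @export
default_pk_params <- function(drug = c("CPT11", "LOHP", "FU5")) {
  switch(match.arg(drug),
    CPT11 = irinotecan_params(
      k_LB_cpt = 1.5, k_BO_cpt = 0.4, k_LB_sn = 1.0, k_BO_sn = 0.5,
      Vmax_L = 25, Vmax_O = 5, Km = 59.2,
      Cl_B_cpt = 0.7, Cl_L_cpt = 0.35, Cl_O_cpt = 0.1, Cl_L_sn = 1.0),
    LOHP = oxaliplatin_params(
      k_LB = 3, k_BO = 1, k_on = 0.3, k_off = 0.03, Cl_B = 3),
    FU5 = fluorouracil_params(
      k_LB = 2.5, k_BO = 0.8, Cl_L = 7, Cl_B = 1))
}

#' Specification of a synthetic patient cohort
#'
#' Defines the virtual population: anthropometric ranges (the trial cohort
#' was 11 colorectal cancer patients, 7 men and 4 women), log-normal
#' inter-patient variation around per-drug parameter means with optional
#' subpopulation structure, and a 10% proportional measurement-error model.
#'
#' @param n_patients cohort size (>= 2).
#' @param drug `"CPT11"`, `"LOHP"` or `"FU5"`.
#' @param male_fraction fraction of male patients.
#' @param height_range,weight_range uniform anthropometric ranges (m, kg).
#' @param param_means named parameter means ([default_pk_params()] if
#'   `NULL`); for subpopulations, a list of named vectors (one per group).
#' @param param_cv log-normal coefficient of variation of each parameter
#'   across patients (scalar or named vector).
#' @param group_weights mixing weights when `param_means` is a list.
#' @param noise_cv proportional measurement error (default 0.10).
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 11, drug = c("CPT11", "LOHP", "FU5"),
                        male_fraction = 7 / 11,
                        height_range = c(1.55, 1.90),
                        weight_range = c(55, 95),
                        param_means = NULL, param_cv = 0.3,
                        group_weights = NULL, noise_cv = 0.1, seed = 1) {
  drug <- match.arg(drug)
  if (n_patients < 2) stop("cohort needs at least 2 patients")
  if (any(param_cv < 0)) stop("parameter CVs must be nonnegative")
  if (is.null(param_means)) param_means <- default_pk_params(drug)
  groups <- if (is.list(param_means)) param_means else list(param_means)
  if (is.null(group_weights)) group_weights <- rep(1, length(groups))
  group_weights <- group_weights / sum(group_weights)
  if (noise_cv < 0) stop("noise CV must be nonnegative")
  structure(list(n_patients = n_patients, drug = drug,
                 male_fraction = male_fraction,
                 height_range = height_range, weight_range = weight_range,
                 groups = groups, param_cv = param_cv,
                 group_weights = group_weights, noise_cv = noise_cv,
                 seed = seed),
            class = "cohort_spec")
}

#' Draw a virtual cohort
#'
#' Samples anthropometrics (sex, height, weight, Du Bois BSA, compartment
#' volumes) and true PK parameters, log-normal around the group means with
#' the specified CV (`meanlog` shifted so the arithmetic mean equals the
#' group mean and the log-normal CV equals `param_cv`). Deterministic under
#' the cohort specification's seed.
#'
#' @param spec a [cohort_spec()].
#' @return List of class `cohort`: `patients` data frame, `params` matrix
#'   (patients x parameters, true values), `vols` list, `group` vector.
#' @export
sample_cohort <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_patients
  sex <- ifelse(stats::runif(n) < spec$male_fraction, "male", "female")
  height <- stats::runif(n, spec$height_range[1], spec$height_range[2])
  weight <- stats::runif(n, spec$weight_range[1], spec$weight_range[2])
  bsa <- bsa_dubois(height, weight)
  group <- sample.int(length(spec$groups), n, replace = TRUE,
                      prob = spec$group_weights)
  pnames <- names(spec$groups[[1]])
  cv <- rep_len(unlist(spec$param_cv), length(pnames))
  names(cv) <- pnames
  cv["Km" == pnames] <- 0                    # Km is a fixed constant
  sdlog <- sqrt(log(1 + cv^2))
  params <- matrix(NA_real_, n, length(pnames),
                   dimnames = list(paste0("p", seq_len(n)), pnames))
  for (i in seq_len(n)) {
    m <- unclass(spec$groups[[group[i]]])
    meanlog <- log(m) - sdlog^2 / 2
    params[i, ] <- exp(meanlog + sdlog * stats::rnorm(length(pnames)))
  }
  vols <- lapply(seq_len(n), function(i)
    compute_compartment_volumes(sex[i], height[i], weight[i], bsa = bsa[i]))
  structure(list(
    patients = data.frame(patient_id = paste0("p", seq_len(n)), sex = sex,
                          height_m = height, weight_kg = weight, bsa = bsa),
    params = params, vols = vols, group = group, spec = spec),
    class = "cohort")
}

## rebuild a pk_params vector of the right drug from a named numeric row
params_from_row <- function(drug, row) {
  structure(row, class = "pk_params", drug = drug)
}

#' Generate a noisy synthetic concentration dataset
#'
#' End-to-end forward simulation: for each patient the trial pump program
#' (scaled to the patient's BSA) is run through the characteristics
#' transport solver, the PK model is integrated, the blood concentrations
#' are sampled on the trial grid and multiplied by `(1 + noise_cv * eps)`
#' with standard-normal `eps`, truncated at zero. Deterministic under
#' `seed`.
#'
#' @param cohort a [sample_cohort()] result.
#' @param grid sampling times; defaults to [sampling_grid()] of the drug.
#' @param noise_cv proportional error; defaults to the cohort spec's.
#' @param seed RNG seed; defaults to the cohort spec's seed + 1.
#' @return Data frame `patient_id, analyte, time_h, conc_mg_per_L` with the
#'   noise-free predictions as column `conc_true` and the per-patient
#'   deliveries attached as attribute `"deliveries"`.
#' @export
generate_dataset <- function(cohort, grid = NULL, noise_cv = NULL,
                             seed = NULL) {
  spec <- cohort$spec
  drug <- spec$drug
  if (is.null(grid)) grid <- sampling_grid(drug)
  if (is.null(noise_cv)) noise_cv <- spec$noise_cv
  if (is.null(seed)) seed <- spec$seed + 1
  horizon <- max(grid)
  rows <- list(); deliveries <- list()
  for (i in seq_len(nrow(cohort$patients))) {
    id <- cohort$patients$patient_id[i]
    prog <- optiliv_program(drug, reference_bsa = cohort$patients$bsa[i])
    delivery <- solve_transport_characteristics(prog)
    sim <- simulate_pk(drug, params_from_row(drug, cohort$params[i, ]),
                       cohort$vols[[i]], delivery, horizon,
                       times = sort(unique(c(0, grid, delivery$times))))
    d <- sample_concentrations(sim, grid, patient_id = id)
    d$conc_true <- d$conc_mg_per_L
    rows[[i]] <- d
    deliveries[[id]] <- delivery
  }
  out <- do.call(rbind, rows)
  set.seed(seed)
  eps <- stats::rnorm(nrow(out))
  out$conc_mg_per_L <- pmax(0, out$conc_true * (1 + noise_cv * eps))
  attr(out, "deliveries") <- deliveries
  out
}

#' Parameter-recovery study
#'
#' End-to-end validation of the estimation pipeline on synthetic patients:
#' for each replicate one virtual patient is drawn, a dataset is generated
#' (trial grid, proportional noise), the model is fitted starting from the
#' population means, and the estimates are compared with the known truth.
#'
#' @param drug `"CPT11"`, `"LOHP"` or `"FU5"`.
#' @param free names of the fitted parameters (identifiable subset); the
#'   rest are fixed at their true values.
#' @param n_replicates number of simulated patients.
#' @param noise_cv proportional measurement error (0 for noise-free).
#' @param param_cv inter-patient CV used to draw the true parameters.
#' @param seed base RNG seed (replicate r uses `seed + r`).
#' @param maxeval CMA-ES budget per fit.
#' @param rtol ODE solver tolerance used during fitting.
#' @param grid sampling grid override.
#' @return Object of class `recovery_study`: per-replicate table of true
#'   vs estimated values with relative errors, per-parameter bias and
#'   RMSE, and the count of non-converged fits.
#' @export
recovery_study <- function(drug = c("CPT11", "LOHP", "FU5"), free,
                           n_replicates = 20, noise_cv = 0.1,
                           param_cv = 0.3, seed = 1, maxeval = 1200,
                           rtol = 1e-8, grid = NULL) {
  drug <- match.arg(drug)
  if (is.null(grid)) grid <- sampling_grid(drug)
  means <- default_pk_params(drug)
  rows <- list()
  n_fail <- 0L
  for (r in seq_len(n_replicates)) {
    spec <- cohort_spec(n_patients = 2, drug = drug, param_cv = param_cv,
                        noise_cv = noise_cv, seed = seed + r)
    cohort <- sample_cohort(spec)
    data <- generate_dataset(cohort, grid = grid, noise_cv = noise_cv,
                             seed = seed + r)
    id <- cohort$patients$patient_id[1]
    d1 <- data[data$patient_id == id,
               c("patient_id", "analyte", "time_h", "conc_mg_per_L")]
    truth <- cohort$params[1, ]
    start <- params_from_row(drug, truth)
    start[free] <- unclass(means)[free]      # start at population means
    fit <- fit_pk(d1, drug, cohort$vols[[1]],
                  attr(data, "deliveries")[[id]], start = start,
                  free = free, seed = seed + r, maxeval = maxeval,
                  rtol = rtol)
    if (fit$optimizer$convergence != 0) n_fail <- n_fail + 1L
    est <- unclass(fit$coef)[free]
    rows[[r]] <- data.frame(replicate = r, parameter = free,
                            true = truth[free], estimated = est,
                            rel_error = (est - truth[free]) / truth[free],
                            row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$parameter), function(d)
    data.frame(parameter = d$parameter[1], bias = mean(d$rel_error),
               rmse = sqrt(mean(d$rel_error^2)),
               median_abs_rel_error = stats::median(abs(d$rel_error)),
               row.names = NULL)))
  structure(list(table = tab, summary = summ, n_nonconverged = n_fail,
                 drug = drug, noise_cv = noise_cv),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter recovery [%s], noise CV %.0f%%, %d replicate(s), %d non-converged\n",
              x$drug, 100 * x$noise_cv, max(x$table$replicate),
              x$n_nonconverged))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec [%s]: n = %d, %d group(s), param CV %s, noise %.0f%%, seed %d\n",
              x$drug, x$n_patients, length(x$groups),
              paste(signif(unique(unlist(x$param_cv)), 3), collapse = "/"),
              100 * x$noise_cv, x$seed))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d male / %d female, BSA %.2f-%.2f m2\n",
              sum(x$patients$sex == "male"), sum(x$patients$sex == "female"),
              min(x$patients$bsa), max(x$patients$bsa)))
  invisible(x)
}
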