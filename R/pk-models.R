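## Molar masses (g/mol) used for mole-consistent CPT11 -> SN38 conversion
## and for the Michaelis constant unit change (uM -> mg/L).
MW_CPT11 <- 586.68
MW_SN38 <- 392.4

#' Irinotecan / SN38 model parameters
#'
#' Rate constants of the six-compartment irinotecan model: CPT11 and its
#' active metabolite SN38 in Liver, Blood and Organs. Transfers are passive
#' and volume-scaled (see [simulate_irinotecan()]); CPT11 is converted to
#' SN38 by Michaelis-Menten kinetics in Liver and Organs only (the
#' activating carboxylesterases are absent from blood). SN38 is cleared in
#' the Liver (lumping deactivation to SN38G) and in the Organs at twice the
#' liver rate.
#'
#' @param k_LB_cpt,k_BO_cpt,k_LB_sn,k_BO_sn interface transfer rate
#'   constants, 1/h.
#' @param Vmax_L,Vmax_O maximal conversion rates, mg/h.
#' @param Km Michaelis constant in uM (fixed at 59.2 during fitting).
#' @param Cl_B_cpt,Cl_L_cpt,Cl_O_cpt CPT11 clearance rate constants, 1/h
#'   (renal, biliary, intestinal routes respectively).
#' @param Cl_L_sn SN38 liver clearance, 1/h; the Organs clearance is fixed
#'   at `2 * Cl_L_sn`.
#' @return Named numeric vector of class `pk_params`.
#' @export
irinotecan_params <- function(k_LB_cpt, k_BO_cpt, k_LB_sn, k_BO_sn,
                              Vmax_L, Vmax_O, Km = 59.2,
                              Cl_B_cpt, Cl_L_cpt, Cl_O_cpt, Cl_L_sn) {
  p <- c(k_LB_cpt = k_LB_cpt, k_BO_cpt = k_BO_cpt, k_LB_sn = k_LB_sn,
         k_BO_sn = k_BO_sn, Vmax_L = Vmax_L, Vmax_O = Vmax_O, Km = Km,
         Cl_B_cpt = Cl_B_cpt, Cl_L_cpt = Cl_L_cpt, Cl_O_cpt = Cl_O_cpt,
         Cl_L_sn = Cl_L_sn)
  if (any(p < 0)) stop("irinotecan parameters must be nonnegative")
  structure(p, class = "pk_params", drug = "CPT11")
}

#' Oxaliplatin (platinum) model parameters
#'
#' Six-compartment model of free and protein-bound platinum in Liver, Blood
#' and Organs. Only the free species moves between compartments; binding
#' (`k_on`) and unbinding (`k_off`, protein degradation) occur in all
#' compartments; the only elimination is renal clearance of free blood
#' platinum (hepatic and intestinal clearance are negligible for
#' oxaliplatin).
#'
#' @param k_LB,k_BO free-Pt transfer rate constants, 1/h.
#' @param k_on,k_off binding and unbinding rate constants, 1/h.
#' @param Cl_B renal clearance rate constant of free blood Pt, 1/h.
#' @return Named numeric vector of class `pk_params`.
#' @export
oxaliplatin_params <- function(k_LB, k_BO, k_on, k_off, Cl_B) {
  p <- c(k_LB = k_LB, k_BO = k_BO, k_on = k_on, k_off = k_off, Cl_B = Cl_B)
  if (any(p < 0)) stop("oxaliplatin parameters must be nonnegative")
  structure(p, class = "pk_params", drug = "LOHP")
}

#' 5-fluorouracil model parameters
#'
#' Three-compartment linear model; protein binding is neglected and there
#' is no Organs clearance (5-FU is cleared mainly by hepatic metabolism,
#' biliary excretion and renal elimination).
#'
#' @param k_LB,k_BO transfer rate constants, 1/h.
#' @param Cl_L,Cl_B hepatic and renal clearance rate constants, 1/h.
#' @return Named numeric vector of class `pk_params`.
#' @export
fluorouracil_params <- function(k_LB, k_BO, Cl_L, Cl_B) {
  p <- c(k_LB = k_LB, k_BO = k_BO, Cl_L = Cl_L, Cl_B = Cl_B)
  if (any(p < 0)) stop("5-FU parameters must be nonnegative")
  structure(p, class = "pk_params", drug = "FU5")
}

## delivery forcing function (mg/h) from a delivery profile
delivery_forcing <- function(delivery) {
  if (is.null(delivery)) return(function(t) 0)
  stats::approxfun(delivery$times, delivery$rate, yleft = 0, yright = 0,
                   rule = 2)
}

pk_integrate <- function(y0, rhs, times, rtol = 1e-8, atol = 1e-10,
                         hmax = 0.1) {
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol,
                        atol = atol, hmax = hmax, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) stop("ODE integration failure")
  if (min(out[, -1]) < -1e-6 * max(abs(out[, -1]), 1))
    stop("integration failure: negative state beyond solver tolerance")
  out
}

pk_sim_result <- function(drug, out, conc_cols, vols, params, delivery) {
  times <- out[, "time"]
  dcum <- if ("delivered" %in% colnames(out)) out[, "delivered"]
    else if (is.null(delivery)) rep(0, length(times)) else
    stats::approx(delivery$times, delivery$cumulative, times, rule = 2)$y
  structure(list(drug = drug, times = times,
                 conc = conc_cols, amounts = out[, -1, drop = FALSE],
                 delivered = dcum, params = params, vols = vols),
            class = "pk_sim")
}

#' Simulate the irinotecan / SN38 model
#'
#' Amount-based (mg) six-state ODE system driven by the delivery profile
#' `d(t)` (mg CPT11/h) entering the Liver (hepatic artery infusion).
#' Inter-compartment transfer fluxes are `k * V_tissue * (C_i - C_j)` so
#' that equal concentrations give zero net flux. Conversion to SN38 is
#' Michaelis-Menten in Liver and Organs (`Vmax C / (Km + C)` on the CPT11
#' liver/organ concentration, mass-converted by the molar-mass ratio).
#' Cumulative cleared amounts per route are tracked as auxiliary states.
#'
#' @param params an [irinotecan_params()] vector.
#' @param vols a [compute_compartment_volumes()] result.
#' @param delivery a [delivery_profile()] in mg CPT11/h.
#' @param horizon simulation end, hours.
#' @param times optional output times (hours).
#' @param rtol relative solver tolerance.
#' @return A `pk_sim` object; `$conc` holds blood concentrations (mg/L) of
#'   `CPT11` and `SN38`.
#' @export
simulate_irinotecan <- function(params, vols, delivery, horizon,
                                times = NULL, rtol = 1e-8) {
  p <- as.list(unclass(params))
  Km_mgL <- p$Km * MW_CPT11 / 1000      # uM -> mg/L
  fr <- MW_SN38 / MW_CPT11              # mg SN38 per mg CPT11 converted
  din <- delivery_forcing(delivery)
  V_L <- vols$V_L; V_B <- vols$V_B; V_O <- vols$V_O
  rhs <- function(t, y, parms) {
    cL <- y[1] / V_L; cB <- y[2] / V_B; cO <- y[3] / V_O
    sL <- y[4] / V_L; sB <- y[5] / V_B; sO <- y[6] / V_O
    mmL <- p$Vmax_L * cL / (Km_mgL + cL)
    mmO <- p$Vmax_O * cO / (Km_mgL + cO)
    fLB <- p$k_LB_cpt * V_L * (cL - cB)
    fBO <- p$k_BO_cpt * V_O * (cB - cO)
    gLB <- p$k_LB_sn * V_L * (sL - sB)
    gBO <- p$k_BO_sn * V_O * (sB - sO)
    list(c(
      din(t) - fLB - mmL - p$Cl_L_cpt * y[1],
      fLB - fBO - p$Cl_B_cpt * y[2],
      fBO - mmO - p$Cl_O_cpt * y[3],
      fr * mmL - gLB - p$Cl_L_sn * y[4],
      gLB - gBO,
      gBO + fr * mmO - 2 * p$Cl_L_sn * y[6],
      p$Cl_B_cpt * y[2],                 # cleared CPT11: renal
      p$Cl_L_cpt * y[1],                 #   biliary
      p$Cl_O_cpt * y[3],                 #   intestinal
      p$Cl_L_sn * y[4],                  # cleared SN38: liver
      2 * p$Cl_L_sn * y[6],              #   organs
      din(t)))                           # delivered-to-date
  }
  if (is.null(times)) times <- seq(0, horizon, length.out = 512)
  y0 <- stats::setNames(numeric(12),
    c("cptL", "cptB", "cptO", "snL", "snB", "snO",
      "clr_cpt_B", "clr_cpt_L", "clr_cpt_O", "clr_sn_L", "clr_sn_O",
      "delivered"))
  out <- pk_integrate(y0, rhs, times, rtol = rtol)
  conc <- cbind(CPT11 = out[, "cptB"] / V_B, SN38 = out[, "snB"] / V_B)
  pk_sim_result("CPT11", out, conc, vols, params, delivery)
}

#' Simulate the oxaliplatin (platinum) model
#'
#' Six-state model of free and bound platinum amounts (mg Pt) in Liver,
#' Blood and Organs; delivery enters the Liver as free Pt. Only free Pt is
#' transferred (`k * V_tissue * (C_i - C_j)`); binding/unbinding occur in
#' every compartment; free blood Pt is cleared renally.
#'
#' @inheritParams simulate_irinotecan
#' @param params an [oxaliplatin_params()] vector.
#' @return A `pk_sim` object; `$conc` holds blood `Pt_free` and `Pt_total`
#'   (mg/L).
#' @export
simulate_oxaliplatin <- function(params, vols, delivery, horizon,
                                 times = NULL, rtol = 1e-8) {
  p <- as.list(unclass(params))
  din <- delivery_forcing(delivery)
  V_L <- vols$V_L; V_B <- vols$V_B; V_O <- vols$V_O
  rhs <- function(t, y, parms) {
    cL <- y[1] / V_L; cB <- y[2] / V_B; cO <- y[3] / V_O
    fLB <- p$k_LB * V_L * (cL - cB)
    fBO <- p$k_BO * V_O * (cB - cO)
    list(c(
      din(t) - fLB - p$k_on * y[1] + p$k_off * y[4],
      fLB - fBO - p$k_on * y[2] + p$k_off * y[5] - p$Cl_B * y[2],
      fBO - p$k_on * y[3] + p$k_off * y[6],
      p$k_on * y[1] - p$k_off * y[4],
      p$k_on * y[2] - p$k_off * y[5],
      p$k_on * y[3] - p$k_off * y[6],
      p$Cl_B * y[2],
      din(t)))
  }
  if (is.null(times)) times <- seq(0, horizon, length.out = 512)
  y0 <- stats::setNames(numeric(8),
    c("fL", "fB", "fO", "bL", "bB", "bO", "clr_B", "delivered"))
  out <- pk_integrate(y0, rhs, times, rtol = rtol)
  conc <- cbind(Pt_free = out[, "fB"] / V_B,
                Pt_total = (out[, "fB"] + out[, "bB"]) / V_B)
  pk_sim_result("LOHP", out, conc, vols, params, delivery)
}

#' Simulate the 5-fluorouracil model
#'
#' Three-state linear model (amounts, mg) with hepatic and renal clearance;
#' delivery enters the Liver.
#'
#' @inheritParams simulate_irinotecan
#' @param params a [fluorouracil_params()] vector.
#' @return A `pk_sim` object; `$conc` holds blood `FU5` (mg/L).
#' @export
simulate_5fu <- function(params, vols, delivery, horizon,
                         times = NULL, rtol = 1e-8) {
  p <- as.list(unclass(params))
  din <- delivery_forcing(delivery)
  V_L <- vols$V_L; V_B <- vols$V_B; V_O <- vols$V_O
  rhs <- function(t, y, parms) {
    cL <- y[1] / V_L; cB <- y[2] / V_B; cO <- y[3] / V_O
    fLB <- p$k_LB * V_L * (cL - cB)
    fBO <- p$k_BO * V_O * (cB - cO)
    list(c(
      din(t) - fLB - p$Cl_L * y[1],
      fLB - fBO - p$Cl_B * y[2],
      fBO,
      p$Cl_L * y[1],
      p$Cl_B * y[2],
      din(t)))
  }
  if (is.null(times)) times <- seq(0, horizon, length.out = 512)
  y0 <- stats::setNames(numeric(6),
    c("fuL", "fuB", "fuO", "clr_L", "clr_B", "delivered"))
  out <- pk_integrate(y0, rhs, times, rtol = rtol)
  conc <- cbind(FU5 = out[, "fuB"] / V_B)
  pk_sim_result("FU5", out, conc, vols, params, delivery)
}

#' Simulate any of the three drug models
#'
#' Dispatcher used by the estimation and synthetic-cohort pipelines.
#'
#' @param drug `"CPT11"`, `"LOHP"` or `"FU5"`.
#' @inheritParams simulate_irinotecan
#' @return A `pk_sim` object.
#' @export
simulate_pk <- function(drug = c("CPT11", "LOHP", "FU5"), params, vols,
                        delivery, horizon, times = NULL, rtol = 1e-8) {
  drug <- match.arg(drug)
  switch(drug,
         CPT11 = simulate_irinotecan(params, vols, delivery, horizon, times, rtol),
         LOHP = simulate_oxaliplatin(params, vols, delivery, horizon, times, rtol),
         FU5 = simulate_5fu(params, vols, delivery, horizon, times, rtol))
}

#' Mass balance of a PK simulation
#'
#' Delivered-to-date mass minus (stored + cleared) at every output time,
#' mole-consistent for SN38 (metabolite amounts are converted back to
#' CPT11-equivalents by the molar-mass ratio).
#'
#' @param sim a `pk_sim` object.
#' @return Numeric vector of relative balance errors per output time.
#' @export
mass_balance_error <- function(sim) {
  a <- sim$amounts
  stored_cleared <- switch(sim$drug,
    CPT11 = rowSums(a[, c("cptL", "cptB", "cptO"), drop = FALSE]) +
      rowSums(a[, c("snL", "snB", "snO"), drop = FALSE]) / (MW_SN38 / MW_CPT11) +
      rowSums(a[, c("clr_cpt_B", "clr_cpt_L", "clr_cpt_O"), drop = FALSE]) +
      rowSums(a[, c("clr_sn_L", "clr_sn_O"), drop = FALSE]) / (MW_SN38 / MW_CPT11),
    LOHP = rowSums(a[, c("fL", "fB", "fO", "bL", "bB", "bO", "clr_B"),
                     drop = FALSE]),
    FU5 = rowSums(a[, c("fuL", "fuB", "fuO", "clr_L", "clr_B"),
                    drop = FALSE]))
  (sim$delivered - stored_cleared) / max(sim$delivered, 1e-12)
}

#' Clearance-route fractions at the end of a simulation
#'
#' Fractions of the administered dose eliminated through each route (and,
#' for platinum, bound in tissues) at the simulation horizon, used for the
#' literature-derived clearance constraints during fitting.
#'
#' @param sim a `pk_sim` object.
#' @param dose administered dose in mg (defaults to total delivered mass).
#' @return Named numeric vector of percentages.
#' @export
clearance_fractions <- function(sim, dose = NULL) {
  if (is.null(dose)) dose <- max(sim$delivered)
  a <- sim$amounts[nrow(sim$amounts), ]
  fr <- MW_SN38 / MW_CPT11
  100 * switch(sim$drug,
    CPT11 = c(renal = a[["clr_cpt_B"]],
              biliary_intestinal = a[["clr_cpt_L"]] + a[["clr_cpt_O"]],
              sn38 = (a[["clr_sn_L"]] + a[["clr_sn_O"]]) / fr) / dose,
    LOHP = c(renal = a[["clr_B"]], bound_organs = a[["bO"]],
             bound_liver = a[["bL"]]) / dose,
    FU5 = c(hepatic = a[["clr_L"]]) / dose)
}

#' Extract a concentration series from a simulation
#'
#' @param sim a `pk_sim` object.
#' @param times sampling times (hours post infusion onset).
#' @param analyte analyte name; all analytes when `NULL`.
#' @param patient_id identifier copied into the output.
#' @return Data frame `patient_id, analyte, time_h, conc_mg_per_L`.
#' @export
sample_concentrations <- function(sim, times, analyte = NULL,
                                  patient_id = "p1") {
  analytes <- colnames(sim$conc)
  if (!is.null(analyte)) analytes <- intersect(analytes, analyte)
  do.call(rbind, lapply(analytes, function(a) {
    v <- stats::approx(sim$times, sim$conc[, a], times, rule = 2)$y
    data.frame(patient_id = patient_id, analyte = a, time_h = times,
               conc_mg_per_L = v)
  }))
}

#' @export
print.pk_sim <- function(x, ...) {
  cat(sprintf("PK simulation [%s]: %d times over %.1f h, analytes: %s\n",
              x$drug, length(x$times), max(x$times),
              paste(colnames(x$conc), collapse = ", ")))
  invisible(x)
}

#' @export
plot.pk_sim <- function(x, ...) {
  graphics::matplot(x$times, x$conc, type = "l", lty = 1,
                    xlab = "time (h)", ylab = "blood concentration (mg/L)", ...)
  graphics::legend("topright", colnames(x$conc), lty = 1,
                   col = seq_len(ncol(x$conc)))
  invisible(x)
}
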