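test_that("compartment volumes follow the published formulas", {
  v <- compute_compartment_volumes("male", 1.75, 75)
  # Nadler, male, 1.75 m / 75 kg: 0.3669*1.75^3 + 0.03219*75 + 0.6041
  expect_equal(v$V_B, 4.984705, tolerance = 1e-7)
  # total body volume is weight / mean body density by construction
  expect_equal(v$V_L + v$V_B + v$V_O, 75 / 1.05, tolerance = 1e-9)
  expect_gt(v$V_O, v$V_L)

  # Vauthey liver volume increases with BSA
  v2 <- compute_compartment_volumes("male", 1.75, 75, bsa = 2 * v$bsa)
  expect_gt(v2$V_L, v$V_L)

  # female Nadler branch differs from male
  vf <- compute_compartment_volumes("female", 1.75, 75)
  expect_lt(vf$V_B, v$V_B)

  # non-physiologic input: liver volume would be negative
  expect_error(compute_compartment_volumes("male", 0.4, 3), "non-physiologic")

  # formula overrides are honoured
  vo <- compute_compartment_volumes("male", 1.75, 75,
    formulas = list(total = function(sex, h, w) 100))
  expect_equal(vo$V_L + vo$V_B + vo$V_O, 100)
})

test_that("zero delivery gives identically zero concentrations", {
  vols <- fixture_vols()
  for (d in c("CPT11", "LOHP", "FU5")) {
    sim <- simulate_pk(d, default_pk_params(d), vols, NULL, horizon = 5)
    expect_equal(max(abs(sim$conc)), 0)
  }
})

test_that("mass is conserved in every PK model", {
  vols <- fixture_vols()
  for (d in c("CPT11", "LOHP", "FU5")) {
    prog <- optiliv_program(d)
    delivery <- solve_transport_characteristics(prog)
    sim <- simulate_pk(d, default_pk_params(d), vols, delivery,
                       max(sampling_grid(d)))
    expect_lt(max(abs(mass_balance_error(sim))), 1e-6)
  }
})

test_that("states stay nonnegative across random parameter sets", {
  vols <- fixture_vols()
  delivery <- solve_transport_characteristics(optiliv_program("FU5"))
  set.seed(7)
  for (i in 1:15) {
    p <- fluorouracil_params(k_LB = runif(1, 0.1, 10),
                             k_BO = runif(1, 0.1, 10),
                             Cl_L = runif(1, 0.1, 10),
                             Cl_B = runif(1, 0.1, 10))
    sim <- simulate_5fu(p, vols, delivery, 14, rtol = 1e-8)
    expect_gte(min(sim$amounts), -1e-8 * max(sim$amounts))
  }
})

test_that("Michaelis-Menten conversion linearises when C << Km", {
  vols <- fixture_vols()
  # scale the dose down 1000x so liver CPT11 concentration is far below Km
  prog <- optiliv_program("CPT11", reference_bsa = 1.84e-3)
  delivery <- solve_transport_characteristics(prog)
  p <- default_pk_params("CPT11")
  sim_mm <- simulate_irinotecan(p, vols, delivery, 10)

  # linear oracle: replace Vmax C/(Km + C) by (Vmax/Km) C via a huge Km
  # with Vmax rescaled to keep Vmax/Km fixed
  p_lin <- p
  p_lin["Km"] <- p["Km"] * 1e6
  p_lin["Vmax_L"] <- p["Vmax_L"] * 1e6
  p_lin["Vmax_O"] <- p["Vmax_O"] * 1e6
  sim_lin <- simulate_irinotecan(p_lin, vols, delivery, 10)
  i <- sim_mm$times > 1
  expect_equal(sim_mm$conc[i, "CPT11"], sim_lin$conc[i, "CPT11"],
               tolerance = 0.01)
  expect_equal(sim_mm$conc[i, "SN38"], sim_lin$conc[i, "SN38"],
               tolerance = 0.01)
})

test_that("platinum binding behaves: no binding, and equilibrium ratio k_on/k_off", {
  vols <- fixture_vols()
  delivery <- solve_transport_characteristics(optiliv_program("LOHP"))
  p0 <- oxaliplatin_params(k_LB = 3, k_BO = 1, k_on = 0, k_off = 0.03,
                           Cl_B = 3)
  s0 <- simulate_oxaliplatin(p0, vols, delivery, 17.25)
  expect_equal(max(abs(s0$amounts[, c("bL", "bB", "bO")])), 0)
  expect_equal(s0$conc[, "Pt_total"], s0$conc[, "Pt_free"])

  # no clearance: binding reaches stationarity with bound/free = k_on/k_off
  p1 <- oxaliplatin_params(k_LB = 3, k_BO = 1, k_on = 0.5, k_off = 0.25,
                           Cl_B = 0)
  s1 <- simulate_oxaliplatin(p1, vols, delivery, 400,
                             times = c(0, 12, 400))
  last <- nrow(s1$amounts)
  for (cmp in c("L", "B", "O")) {
    ratio <- s1$amounts[last, paste0("b", cmp)] /
      s1$amounts[last, paste0("f", cmp)]
    expect_equal(unname(ratio), 0.5 / 0.25, tolerance = 1e-3)
  }
})

test_that("5-FU model is linear and decays mono-exponentially without transport", {
  vols <- fixture_vols()
  # no transport out of the liver: after the infusion stops, the liver
  # amount decays as exp(-Cl_L t)
  p <- fluorouracil_params(k_LB = 0, k_BO = 0.8, Cl_L = 2, Cl_B = 1)
  short <- pump_program(list(
    infusion_segment(0, 0.5, "constant", 4, "drug", 50)),
    tube_spec(volume = 1e-9, radius = 0.5))
  delivery <- solve_transport_characteristics(short, dt = 0.001)
  sim <- simulate_5fu(p, vols, delivery, 4, times = c(0, 1, 2, 3))
  aL <- sim$amounts[, "fuL"]
  expect_equal(aL[3] / aL[2], exp(-2), tolerance = 1e-5)
  expect_equal(aL[4] / aL[3], exp(-2), tolerance = 1e-5)
  expect_equal(max(sim$conc[, "FU5"]), 0)    # nothing reaches the blood

  # superposition: response to the sum of two deliveries = sum of responses
  p2 <- default_pk_params("FU5")
  d1 <- solve_transport_characteristics(constant_program(4, 1, 10), dt = 0.002)
  d2 <- solve_transport_characteristics(constant_program(8, 2, 5), dt = 0.002)
  tt <- seq(0, 6, by = 0.5)
  # knife-edge points just past each pump stop keep the rate jumps sharp
  g <- sort(unique(c(d1$times, d2$times, 1 + 1e-9, 2 + 1e-9)))
  at <- function(prof, val, t) {
    f <- approxfun(prof$times, prof[[val]], yleft = 0,
                   yright = if (val == "cumulative")
                     max(prof$cumulative) else 0)
    f(t)
  }
  dsum <- delivery_profile(g, at(d1, "rate", g) + at(d2, "rate", g),
                           at(d1, "cumulative", g) + at(d2, "cumulative", g))
  s1 <- simulate_5fu(p2, vols, d1, 6, times = tt)
  s2 <- simulate_5fu(p2, vols, d2, 6, times = tt)
  s12 <- simulate_5fu(p2, vols, dsum, 6, times = tt)
  expect_equal(s12$conc[, "FU5"], s1$conc[, "FU5"] + s2$conc[, "FU5"],
               tolerance = 1e-6)
})

test_that("equal concentrations give zero net transfer flux", {
  vols <- fixture_vols()
  # without clearance the system relaxes to concentration equality
  p <- fluorouracil_params(k_LB = 2, k_BO = 1, Cl_L = 0, Cl_B = 0)
  delivery <- solve_transport_characteristics(constant_program(4, 1, 10),
                                              dt = 0.002)
  sim <- simulate_5fu(p, vols, delivery, 300, times = c(0, 10, 300))
  last <- nrow(sim$amounts)
  cL <- unname(sim$amounts[last, "fuL"]) / vols$V_L
  cB <- unname(sim$amounts[last, "fuB"]) / vols$V_B
  cO <- unname(sim$amounts[last, "fuO"]) / vols$V_O
  expect_equal(cL, cB, tolerance = 1e-6)
  expect_equal(cB, cO, tolerance = 1e-6)
})

test_that("a constraint-satisfying parameter set clears ~54% of platinum renally", {
  vols <- fixture_vols()
  prog <- optiliv_program("LOHP")
  delivery <- solve_transport_characteristics(prog)
  base <- default_pk_params("LOHP")
  renal_at <- function(clb) {
    p <- base; p["Cl_B"] <- clb
    sim <- simulate_oxaliplatin(p, vols, delivery, 17.25,
                                times = c(0, 10, 17.25), rtol = 1e-7)
    clearance_fractions(sim, prog$dose)[["renal"]]
  }
  # construct the set by root-finding on the renal clearance rate
  clb <- uniroot(function(x) renal_at(x) - 54, c(0.5, 30), tol = 1e-4)$root
  expect_equal(renal_at(clb), 54, tolerance = 1e-2)
})

test_that("the late 5-FU flush spike carries an AUC share close to the spike dose fraction", {
  vols <- fixture_vols()
  prog <- optiliv_program("FU5")
  delivery <- solve_transport_characteristics(prog)
  # fast-clearing parameters: blood concentration is near zero when the
  # flush starts, so the spike AUC fraction mirrors the dose fraction
  p <- fluorouracil_params(k_LB = 3, k_BO = 0.005, Cl_L = 10, Cl_B = 4)
  tt <- seq(0, 30, by = 0.02)
  sim <- simulate_5fu(p, vols, delivery, 30, times = tt)
  cb <- sim$conc[, "FU5"]
  auc <- function(i) sum((cb[i][-1] + cb[i][-sum(i)]) / 2) * 0.02
  spike_share <- 100 * auc(tt >= 11.5) / auc(tt >= 0)
  expect_equal(spike_share, flush_spike_fraction(prog), tolerance = 0.25)
})
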