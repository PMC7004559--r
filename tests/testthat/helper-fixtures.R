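# Shared fixtures: everything is generated in code at test time.

fixture_vols <- function() {
  compute_compartment_volumes("male", 1.75, 75)
}

# constant-rate single-drug-segment program on the default tube
constant_program <- function(rate = 3.68, duration = 2, stock = 3,
                             tube = tube_spec()) {
  pump_program(list(
    infusion_segment(0, duration, "constant", rate, "drug", stock)), tube)
}

# random piecewise program: drug segment(s) followed by a tube-emptying
# glucose flush; deterministic under seed
random_program <- function(seed, tube = tube_spec()) {
  set.seed(seed)
  n_drug <- sample(1:2, 1)
  segs <- list()
  t0 <- 0
  for (i in seq_len(n_drug)) {
    dur <- runif(1, 0.5, 2)
    shape <- sample(c("constant", "half_sin_squared"), 1)
    peak <- runif(1, 4, 30)
    stock <- runif(1, 1, 10)
    segs <- c(segs, list(infusion_segment(t0, dur, shape, peak, "drug", stock)))
    t0 <- t0 + dur + runif(1, 0, 0.5)          # possible flow gap
  }
  flush_dur <- 0.5
  flush_peak <- 2.5 * tube$volume / flush_dur  # sin^2 volume >= tube volume
  segs <- c(segs, list(infusion_segment(t0, flush_dur, "half_sin_squared",
                                        flush_peak, "glucose")))
  pump_program(segs, tube)
}

# uniform-grid L1 distance between two delivery profiles
profile_l1 <- function(a, b, t_end, dt = 0.005) {
  g <- seq(0, t_end, by = dt)
  ra <- approx(a$times, a$rate, g, rule = 2)$y
  rb <- approx(b$times, b$rate, g, rule = 2)$y
  sum(abs(ra - rb)) * dt
}

# quick synthetic single-patient dataset with known truth
quick_patient <- function(drug, seed, noise_cv = 0, param_cv = 0.3) {
  spec <- cohort_spec(2, drug, param_cv = param_cv, noise_cv = noise_cv,
                      seed = seed)
  cohort <- sample_cohort(spec)
  data <- generate_dataset(cohort, noise_cv = noise_cv, seed = seed)
  id <- cohort$patients$patient_id[1]
  list(data = data[data$patient_id == id,
                   c("patient_id", "analyte", "time_h", "conc_mg_per_L")],
       truth = cohort$params[1, ],
       vols = cohort$vols[[1]],
       delivery = attr(data, "deliveries")[[id]])
}

free_params_for <- function(drug) {
  switch(drug,
         CPT11 = c("k_LB_cpt", "Vmax_L", "Cl_B_cpt"),
         LOHP = c("k_LB", "k_on", "Cl_B"),
         FU5 = c("k_LB", "Cl_L", "Cl_B"))
}
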