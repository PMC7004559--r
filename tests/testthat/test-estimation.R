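test_that("weighted least-squares cost follows the proportional error model", {
  d <- data.frame(patient_id = "p1", analyte = "FU5",
                  time_h = c(1, 2), conc_mg_per_L = c(10, 10))
  # perfect prediction: zero cost
  mf <- function(theta) list(pred = c(10, 10), sim = NULL)
  expect_equal(wls_cost(1, d, mf), 0)

  # single point obs 10, pred 11: ((11 - 10) / (0.1 * 10))^2 = 1
  d1 <- d[1, ]
  mf1 <- function(theta) list(pred = 11, sim = NULL)
  expect_equal(wls_cost(1, d1, mf1), 1)

  # zero observation: weight floored at 0.1 * LLOQ, stays finite
  d0 <- data.frame(patient_id = "p1", analyte = "FU5", time_h = 1,
                   conc_mg_per_L = 0)
  mf0 <- function(theta) list(pred = 0.5, sim = NULL)
  expect_equal(wls_cost(1, d0, mf0, lloq = 1), (0.5 / 0.1)^2)

  # simulation failure maps to +Inf
  mferr <- function(theta) stop("boom")
  expect_equal(wls_cost(1, d, mferr), Inf)

  # vectorised cost equals an explicit loop oracle
  set.seed(2)
  obs <- runif(20, 1, 10); pred <- obs * (1 + 0.2 * rnorm(20))
  dd <- data.frame(patient_id = "p1", analyte = "FU5",
                   time_h = seq_len(20), conc_mg_per_L = obs)
  mfv <- function(theta) list(pred = pred, sim = NULL)
  loop <- 0
  for (i in 1:20) loop <- loop + ((pred[i] - obs[i]) / (0.1 * obs[i]))^2
  expect_equal(wls_cost(1, dd, mfv), loop, tolerance = 1e-12)
})

test_that("goodness of fit reproduces the R-squared definition", {
  fake_fit <- function(obs, pred, analyte = "FU5") {
    structure(list(
      data = data.frame(patient_id = "p1", analyte = analyte,
                        time_h = seq_along(obs), conc_mg_per_L = obs),
      fitted_values = pred, ssr_weighted = 0), class = "pk_fit")
  }
  obs <- c(1, 2, 3, 4, 6)
  g <- goodness(fake_fit(obs, obs))
  expect_equal(unname(g$r_squared[["pooled"]]), 1)
  expect_equal(g$ssr_unweighted, 0)

  # predicting the mean gives R^2 = 0
  g0 <- goodness(fake_fit(obs, rep(mean(obs), 5)))
  expect_equal(unname(g0$r_squared[["pooled"]]), 0)

  # hand-computed fixture
  pred <- c(1.1, 1.9, 3.2, 3.8, 6.1)
  sst <- sum((obs - mean(obs))^2); sse <- sum((obs - pred)^2)
  gh <- goodness(fake_fit(obs, pred))
  expect_equal(unname(gh$r_squared[["pooled"]]), 1 - sse / sst,
               tolerance = 1e-12)

  expect_error(goodness(fake_fit(rep(2, 4), rep(2, 4))), "constant")
})

test_that("CMA-ES minimises standard test functions deterministically", {
  sphere <- function(x) sum((x - c(1, -2))^2)
  r1 <- cma_es(sphere, c(5, 5), sigma0 = 1, seed = 4, maxeval = 2000)
  expect_equal(r1$par, c(1, -2), tolerance = 1e-4)

  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  r2 <- cma_es(rosen, c(-1.2, 1), sigma0 = 0.5, seed = 4, maxeval = 6000)
  expect_equal(r2$par, c(1, 1), tolerance = 1e-3)

  # determinism and monotone best-cost trace
  r3 <- cma_es(sphere, c(5, 5), sigma0 = 1, seed = 4, maxeval = 2000)
  expect_identical(r1$par, r3$par)
  expect_identical(r1$trace, r3$trace)
  expect_true(all(diff(r1$trace) <= 0))

  # box bounds are respected
  rb <- cma_es(sphere, c(5, 5), sigma0 = 1, lower = c(2, 0), upper = c(8, 8),
               seed = 1, maxeval = 1500)
  expect_gte(rb$par[1], 2)
  expect_equal(rb$par, c(2, 0), tolerance = 1e-3)
})

test_that("model fitting is deterministic under a fixed seed", {
  qp <- quick_patient("FU5", seed = 21, noise_cv = 0.1)
  start <- chronopump:::params_from_row("FU5", qp$truth)
  start["Cl_L"] <- unclass(default_pk_params("FU5"))[["Cl_L"]]
  f1 <- fit_pk(qp$data, "FU5", qp$vols, qp$delivery, start = start,
               free = "Cl_L", seed = 5, maxeval = 120, rtol = 1e-6)
  f2 <- fit_pk(qp$data, "FU5", qp$vols, qp$delivery, start = start,
               free = "Cl_L", seed = 5, maxeval = 120, rtol = 1e-6)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$cost, f2$cost)
  expect_true(all(diff(f1$optimizer$trace) <= 0))

  # methods behave
  expect_s3_class(f1, "pk_fit")
  expect_equal(length(fitted(f1)), nrow(qp$data))
  expect_equal(length(residuals(f1)), nrow(qp$data))
  pr <- predict(f1, times = c(1, 2, 3), analyte = "FU5")
  expect_equal(nrow(pr), 3)
  sims <- simulate(f1, nsim = 2, seed = 9)
  expect_equal(dim(sims[[1]]), dim(qp$data))
  expect_output(print(summary(f1)), "R-squared")
})

test_that("clearance constraints contribute quadratic penalties", {
  qp <- quick_patient("FU5", seed = 31, noise_cv = 0)
  start <- chronopump:::params_from_row("FU5", qp$truth)
  mf <- chronopump:::make_model_fn("FU5", qp$data, qp$vols, qp$delivery,
                                   start, "Cl_L")
  base <- wls_cost(qp$truth[["Cl_L"]], qp$data, mf)
  res <- mf(qp$truth[["Cl_L"]])
  fr <- clearance_fractions(res$sim, max(qp$delivery$cumulative))
  tgt <- clearance_targets("FU5")
  with_pen <- wls_cost(qp$truth[["Cl_L"]], qp$data, mf,
                       constraints = list(targets = tgt, weight = 2,
                                          dose = max(qp$delivery$cumulative)))
  expect_equal(with_pen - base, 2 * sum((fr[names(tgt)] - tgt)^2),
               tolerance = 1e-8)
})

test_that("flush-start sampling times are realigned by the stated rule", {
  d <- data.frame(
    patient_id = rep(c("p1", "p2"), each = 3),
    analyte = "Pt_free",
    time_h = rep(c(9, 11.5, 17.25), 2),
    conc_mg_per_L = c(8, 5, 2,      # preceding greater: unchanged
                      4, 9, 3))     # concentration rose: moved to +15 min
  out <- realign_flush_timepoints(d, flush_time = 11.5)
  expect_equal(out$time_h[out$patient_id == "p1"][2], 11.5)
  expect_equal(out$time_h[out$patient_id == "p2"][2], 11.75)
  expect_equal(attr(out, "realigned"), "p2.Pt_free")

  # all-zero series unchanged
  z <- data.frame(patient_id = "p3", analyte = "FU5",
                  time_h = c(9, 11.5), conc_mg_per_L = c(0, 0))
  expect_equal(realign_flush_timepoints(z, 11.5)$time_h, c(9, 11.5))

  # missing preceding point
  m <- data.frame(patient_id = "p4", analyte = "FU5",
                  time_h = 11.5, conc_mg_per_L = 1)
  expect_error(realign_flush_timepoints(m, 11.5), "preceding")
})

test_that("Sobol indices recover analytic variance shares", {
  # additive function on [0,1]^3: f = x1 + 2 x2 (x3 ignored)
  # V1 = 1/12, V2 = 4/12: S1 = 0.2, S2 = 0.8, S3 = 0
  f <- function(x) x[1] + 2 * x[2]
  s <- sobol_sensitivity(f, c(0, 0, 0), c(1, 1, 1), n = 4000, seed = 2)
  expect_equal(s$first_order[1], 0.2, tolerance = 0.05)
  expect_equal(s$first_order[2], 0.8, tolerance = 0.05)
  expect_lt(abs(s$total[3]), 0.01)
  expect_true(s$non_identifiable[3])
  # first-order never exceeds total (within MC error)
  expect_true(all(s$first_order <= s$total + 0.05))
  expect_error(sobol_sensitivity(f, c(0, 0, 0), c(1, 1, 0)), "degenerate")
})

test_that("likelihood profiles separate identifiable from flat parameters", {
  qp <- quick_patient("FU5", seed = 51, noise_cv = 0)
  start <- chronopump:::params_from_row("FU5", qp$truth)
  # one-parameter fit: the profile of Cl_L is a curved valley at the truth
  fake_fit <- structure(list(
    coef = start, free = "Cl_L", drug = "FU5", data = qp$data,
    vols = qp$vols, delivery = qp$delivery, constraints = NULL,
    error_cv = 0.1, lloq = 0.01, optimizer = list(seed = 1)),
    class = "pk_fit")
  grid <- qp$truth[["Cl_L"]] * c(0.6, 0.8, 1, 1.25, 1.6)
  lp <- likelihood_profile(fake_fit, "Cl_L", grid)
  expect_equal(lp$profile$value[which.min(lp$profile$cost)],
               qp$truth[["Cl_L"]])
  expect_equal(min(lp$profile$cost), 0, tolerance = 1e-6)
  expect_equal(lp$verdict, "identifiable")
  expect_true(all(diff(lp$profile$cost[1:3]) < 0))
  expect_true(all(diff(lp$profile$cost[3:5]) > 0))

  # a parameter with no influence on the observations is flat: zero data
  zero <- qp$data; zero$conc_mg_per_L <- 0
  flat_fit <- fake_fit; flat_fit$data <- zero; flat_fit$delivery <- NULL
  lpf <- likelihood_profile(flat_fit, "Cl_L", grid)
  expect_equal(lpf$verdict, "practically non-identifiable")
})
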