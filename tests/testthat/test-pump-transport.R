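test_that("tube geometry is validated and delivery depends only on volume", {
  tb <- tube_spec()
  expect_equal(tb$volume, pi * tb$radius^2 * tb$length / 1000)
  expect_error(tube_spec(volume = 1.84, radius = 1, length = 2340),
               "inconsistent")
  expect_error(tube_spec(volume = -1))

  # equal volume, different (radius, length) => identical delivery
  t1 <- tube_spec(volume = 1.84, radius = 0.5)
  t2 <- tube_spec(volume = 1.84, radius = 1.25)
  p1 <- optiliv_program("LOHP", tube = t1)
  p2 <- optiliv_program("LOHP", tube = t2)
  d1 <- solve_transport_characteristics(p1)
  d2 <- solve_transport_characteristics(p2)
  expect_equal(d1$rate, d2$rate, tolerance = 1e-12)
  expect_equal(attr(d1, "onset"), attr(d2, "onset"), tolerance = 1e-10)
})

test_that("trial programs reproduce the published rates and doses", {
  cpt <- optiliv_program("CPT11", reference_bsa = 1.84)
  seg <- cpt$segments[[1]]
  expect_equal(seg$peak_rate, 18.02 * 1.84)
  expect_equal(seg$stock_concentration, 3.33)
  expect_equal(seg$duration, 6)
  # sin^2 construction: peak = 2 * dose / (stock * duration)
  expect_equal(2 * 180 / (3.33 * 6), 18.02, tolerance = 1e-3)

  # analytic integral of a sin^2 segment: mean rate = peak / 2
  lohp <- optiliv_program("LOHP", reference_bsa = 1.84)
  vol <- chronopump:::segment_volume(lohp$segments[[1]])
  expect_equal(vol, 28 / 3 * 1.84, tolerance = 1e-2)

  # per-m2 rates scale linearly with BSA
  f1 <- optiliv_program("FU5", reference_bsa = 1.0)
  f2 <- optiliv_program("FU5", reference_bsa = 1.84)
  expect_equal(f2$segments[[1]]$peak_rate / f1$segments[[1]]$peak_rate, 1.84)
  expect_equal(f2$dose / f1$dose, 1.84)

  expect_error(optiliv_program("XYZ"))
  expect_error(pump_program(list(
    infusion_segment(0, 2, "constant", 1, "drug", 1),
    infusion_segment(1, 2, "constant", 1, "glucose")), tube_spec()),
    "overlap")
})

test_that("characteristics solution is exact plug flow for constant rates", {
  # tube 1.84 ml at 3.68 ml/h: delay exactly 0.5 h, then inlet mass rate
  prog <- constant_program(rate = 3.68, duration = 2, stock = 3)
  prof <- solve_transport_characteristics(prog, dt = 0.001)
  expect_equal(attr(prof, "onset"), 0.5, tolerance = 1e-9)
  after <- prof$times > 0.5 + 1e-9 & prof$times < 2
  expect_equal(prof$rate[after], rep(3.68 * 3, sum(after)))
  before <- prof$times < 0.5 - 1e-9
  expect_equal(prof$rate[before], rep(0, sum(before)))

  # delay law: fill delay = tube volume / rate, for random rates
  for (rate in c(0.92, 1.84, 7.36)) {
    p <- constant_program(rate = rate, duration = 3 * 1.84 / rate)
    expect_equal(attr(solve_transport_characteristics(p), "onset"),
                 1.84 / rate, tolerance = 1e-9)
  }
})

test_that("mass is conserved through the tube", {
  for (seed in 1:5) {
    prog <- random_program(seed)
    prof <- solve_transport_characteristics(prog)
    inlet <- chronopump:::program_inlet_mass(prog, chronopump:::program_end(prog))
    expect_lt(abs(max(prof$cumulative) - inlet) / inlet, 1e-6)
  }
})

test_that("fill delay matches the printed trial values and scales with volume", {
  fu <- solve_transport_characteristics(optiliv_program("FU5"))
  expect_equal(fill_delay(fu), 140)          # 2 h 20 min

  one <- constant_program(rate = 1.84, duration = 2)
  expect_equal(fill_delay(solve_transport_characteristics(one)), 60)
  big <- pump_program(one$segments, tube_spec(volume = 3.68, radius = 0.5))
  expect_equal(fill_delay(solve_transport_characteristics(big)), 120)

  # tube never filled: total pumped volume below dead volume
  tiny <- constant_program(rate = 0.5, duration = 1)
  expect_warning(d <- fill_delay(solve_transport_characteristics(tiny)),
                 "never filled")
  expect_true(is.na(d))
})

test_that("flush spike fraction equals the closed form", {
  # closed form: tube_volume * stock / dose
  lohp <- optiliv_program("LOHP")
  expect_equal(flush_spike_fraction(lohp),
               100 * 1.84 * 3 / (28 * 1.84), tolerance = 1e-6)

  # zero stock concentration => 0%
  p0 <- pump_program(list(
    infusion_segment(0, 2, "constant", 2, "drug", 0),
    infusion_segment(2, 0.5, "constant", 8, "glucose")), tube_spec(),
    dose = 1)
  expect_equal(flush_spike_fraction(p0), 0)

  # flush smaller than the tube volume: partial-spike warning
  partial <- pump_program(list(
    infusion_segment(0, 2, "constant", 4, "drug", 3),
    infusion_segment(2, 0.1, "constant", 4, "glucose")), tube_spec())
  expect_warning(fr <- flush_spike_fraction(partial), "partial")
  expect_lt(fr, 100 * 1.84 * 3 / partial$dose)

  # not ending in glucose
  expect_error(flush_spike_fraction(constant_program()), "glucose")
})

test_that("delivery is proportional to pump rate once the tube is full", {
  prog <- optiliv_program("LOHP")
  prof <- solve_transport_characteristics(prog, dt = 0.002)
  full <- prof$times > attr(prof, "onset") + 1e-6 & prof$times < 11.5
  q <- chronopump:::program_rate(prog, prof$times[full])
  ratio <- prof$rate[full] / q
  expect_lt(diff(range(ratio)), 1e-9)        # constant = stock concentration
  expect_equal(ratio[1], 3)
})

test_that("upwind FD solver honours CFL, conserves mass and converges to the characteristics solution", {
  prog <- random_program(101)
  expect_error(solve_transport_fd(prog, dt = 1), "CFL")

  # discrete conservation: outlet + stored = inlet with matching quadrature
  fd <- solve_transport_fd(prog, dx = prog$tube$length / 400)
  ch <- solve_transport_characteristics(prog)
  inlet <- chronopump:::program_inlet_mass(prog, chronopump:::program_end(prog))
  expect_lt(abs(max(fd$profile$cumulative) - inlet) / inlet, 1e-3)

  # L1 error decreases monotonically under grid refinement
  t_end <- chronopump:::program_end(prog)
  for (seed in 102:104) {
    p <- random_program(seed)
    te <- chronopump:::program_end(p)
    chp <- solve_transport_characteristics(p)
    e <- vapply(c(100, 200, 400), function(nx)
      profile_l1(solve_transport_fd(p, dx = p$tube$length / nx)$profile,
                 chp, te), numeric(1))
    expect_true(all(diff(e) < 0))
  }
})

test_that("FD field state is nonnegative and initially zero", {
  prog <- optiliv_program("LOHP")
  fd <- solve_transport_fd(prog, dx = prog$tube$length / 200,
                           t_end = 2, store_state = TRUE, n_out = 50)
  expect_true(all(fd$state$u >= 0))
  expect_true(all(fd$state$u[1, -1] == 0))
})
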