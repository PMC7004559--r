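#' Infusion tube geometry
#'
#' Describes the infusion line between the pump outlet and the catheter tip.
#' Delivery at the patient end depends only on the total dead volume, not on
#' the exact geometry, so either the volume or the (radius, length) pair can
#' be given; the missing quantity is derived from
#' `volume [ml] = pi * radius^2 * length / 1000` (radius and length in mm).
#'
#' The default reproduces the clinical set-up used with the Melodie pump:
#' a two-section line with a total dead volume of 1.84 ml, simplified to a
#' single tube of radius 0.5 mm.
#'
#' @param volume total tube volume in ml.
#' @param radius tube radius in mm.
#' @param length tube length in mm; derived from `volume` when `NULL`.
#' @return An object of class `tube_spec` with fields `volume`, `radius`,
#'   `length` and the cross-section `sa` (mm^2).
#' @export
tube_spec <- function(volume = 1.84, radius = 0.5, length = NULL) {
  if (is.null(length)) {
    stopifnot(volume > 0, radius > 0)
    length <- volume * 1000 / (pi * radius^2)
  } else if (missing(volume)) {
    volume <- pi * radius^2 * length / 1000
  }
  if (abs(volume - pi * radius^2 * length / 1000) > 1e-6 * volume)
    stop("inconsistent tube geometry: volume != pi * radius^2 * length")
  if (volume <= 0) stop("tube volume must be positive")
  structure(list(volume = volume, radius = radius, length = length,
                 sa = pi * radius^2),
            class = "tube_spec")
}

#' A single pump delivery segment
#'
#' @param start segment start, hours from pump program origin.
#' @param duration segment duration in hours (> 0).
#' @param shape `"constant"`, `"half_sin_squared"` (rate =
#'   `peak * sin^2(pi t / duration)`, mean rate = peak/2) or
#'   `"sin_squared_tail"` (the tail of a sine-squared arch:
#'   `peak * sin^2(pi (t + offset) / period)`), used by corrected rinses.
#' @param peak_rate peak volumetric rate in ml/h at the tube (absolute,
#'   i.e. already scaled by body surface area).
#' @param solution `"drug"` or `"glucose"`.
#' @param stock_concentration drug concentration of the pumped solution in
#'   mg/ml (0 for glucose).
#' @param period,offset parameters of the `"sin_squared_tail"` shape (hours).
#' @return An object of class `infusion_segment`.
#' @export
infusion_segment <- function(start, duration,
                             shape = c("constant", "half_sin_squared",
                                       "sin_squared_tail"),
                             peak_rate, solution = c("drug", "glucose"),
                             stock_concentration = 0,
                             period = duration, offset = 0) {
  shape <- match.arg(shape)
  solution <- match.arg(solution)
  if (duration <= 0) stop("segment duration must be positive")
  if (peak_rate < 0) stop("segment peak rate must be nonnegative")
  if (solution == "glucose") stock_concentration <- 0
  structure(list(start = start, duration = duration, shape = shape,
                 peak_rate = peak_rate, solution = solution,
                 stock_concentration = stock_concentration,
                 period = period, offset = offset),
            class = "infusion_segment")
}

## volumetric rate of one segment at elapsed time tau in [0, duration]
segment_rate <- function(seg, tau) {
  r <- switch(seg$shape,
    constant = rep_len(seg$peak_rate, length(tau)),
    half_sin_squared = seg$peak_rate * sin(pi * tau / seg$duration)^2,
    sin_squared_tail = seg$peak_rate * sin(pi * (tau + seg$offset) / seg$period)^2)
  r[tau < 0 | tau > seg$duration] <- 0
  r
}

## analytic cumulative volume pumped by one segment after elapsed time tau
segment_cumvol <- function(seg, tau) {
  tau <- pmin(pmax(tau, 0), seg$duration)
  G <- function(s, p) s / 2 - (p / (4 * pi)) * sin(2 * pi * s / p)
  switch(seg$shape,
    constant = seg$peak_rate * tau,
    half_sin_squared = seg$peak_rate * G(tau, seg$duration),
    sin_squared_tail = seg$peak_rate *
      (G(tau + seg$offset, seg$period) - G(seg$offset, seg$period)))
}

segment_volume <- function(seg) segment_cumvol(seg, seg$duration)

#' A pump program: ordered segments on one infusion line
#'
#' Segments share the tube, must not overlap in time, and between segments
#' the flow velocity is zero (the tube contents are frozen in place).
#'
#' @param segments list of [infusion_segment()] objects.
#' @param tube a [tube_spec()].
#' @param dose nominal total programmed drug dose in mg (denominator of
#'   [flush_spike_fraction()]); when `NULL`, the total inlet drug mass is
#'   used.
#' @param t0_clock optional clock time "HH:MM" of the program origin.
#' @param drug optional drug label.
#' @return An object of class `pump_program`.
#' @export
pump_program <- function(segments, tube = tube_spec(), dose = NULL,
                         t0_clock = NULL, drug = NULL) {
  stopifnot(length(segments) >= 1)
  ord <- order(vapply(segments, `[[`, numeric(1), "start"))
  segments <- segments[ord]
  ends <- vapply(segments, function(s) s$start + s$duration, numeric(1))
  starts <- vapply(segments, `[[`, numeric(1), "start")
  if (length(segments) > 1 && any(starts[-1] < ends[-length(ends)] - 1e-12))
    stop("pump program segments overlap in time")
  if (is.null(dose))
    dose <- sum(vapply(segments, function(s)
      s$stock_concentration * segment_volume(s), numeric(1)))
  structure(list(segments = segments, tube = tube, dose = dose,
                 t0_clock = t0_clock, drug = drug),
            class = "pump_program")
}

## program-level volumetric rate (ml/h), vectorized in t; at a shared
## segment boundary the later segment takes precedence (right-continuity)
program_rate <- function(program, t) {
  r <- numeric(length(t))
  for (seg in program$segments) {
    idx <- t >= seg$start & t <= seg$start + seg$duration
    if (any(idx)) r[idx] <- segment_rate(seg, t[idx] - seg$start)
  }
  r
}

## cumulative pumped volume (ml) from program origin, vectorized
program_cumvol <- function(program, t) {
  v <- numeric(length(t))
  for (seg in program$segments)
    v <- v + segment_cumvol(seg, t - seg$start)
  v
}

## cumulative drug mass (mg) pushed into the tube inlet, vectorized
program_inlet_mass <- function(program, t) {
  m <- numeric(length(t))
  for (seg in program$segments)
    if (seg$stock_concentration > 0)
      m <- m + seg$stock_concentration * segment_cumvol(seg, t - seg$start)
  m
}

## concentration (mg/ml) of the solution entering the tube at time t
## (stock of the active segment; 0 for glucose segments and flow gaps)
program_inlet_conc <- function(program, t) {
  cc <- numeric(length(t))
  for (seg in program$segments) {
    idx <- t >= seg$start & t <= seg$start + seg$duration
    cc[idx] <- seg$stock_concentration
  }
  cc
}

program_end <- function(program) {
  max(vapply(program$segments, function(s) s$start + s$duration, numeric(1)))
}

program_total_volume <- function(program) {
  sum(vapply(program$segments, segment_volume, numeric(1)))
}

#' Chronomodulated trial pump programs
#'
#' Builds the per-drug hepatic-artery-infusion schedule used in the OPTILIV
#' trial: irinotecan (CPT11) as a 6-h sine-squared infusion starting at
#' 02:00 (dose 180 mg/m2, stock 3.33 mg/ml, peak 18.02 ml/m2/h), oxaliplatin
#' (LOHP) as an 11.5-h infusion from 10:15 (28 mg/m2, 3 mg/ml, peak 1.63)
#' and 5-fluorouracil (FU5) as an 11.5-h infusion from 22:15 (933 mg/m2,
#' 50 mg/ml, peak 3.4), each followed by its 30-min glucose flush (peak
#' rates 7.38 / 7.28 / 6.96 ml/m2/h) starting at 09:45 (CPT11, FU5) or
#' 21:45 (LOHP). Per-m2 rates and doses are scaled by `reference_bsa`.
#'
#' @param drug `"CPT11"`, `"LOHP"` or `"FU5"`.
#' @param reference_bsa body surface area (m2) used to convert per-m2 pump
#'   rates to absolute ml/h; default 1.84.
#' @param tube a [tube_spec()].
#' @return A [pump_program()] whose time origin is the drug's pump start.
#' @export
optiliv_program <- function(drug = c("CPT11", "LOHP", "FU5"),
                            reference_bsa = 1.84, tube = tube_spec()) {
  drug <- match.arg(drug)
  stopifnot(reference_bsa > 0)
  p <- switch(drug,
    CPT11 = list(dur = 6, peak = 18.02, stock = 3.33, dose = 180,
                 flush_start = 7.75, flush_peak = 7.38, t0 = "02:00"),
    LOHP  = list(dur = 11.5, peak = 1.63, stock = 3, dose = 28,
                 flush_start = 11.5, flush_peak = 7.28, t0 = "10:15"),
    FU5   = list(dur = 11.5, peak = 3.4, stock = 50, dose = 933,
                 flush_start = 11.5, flush_peak = 6.96, t0 = "22:15"))
  segs <- list(
    infusion_segment(0, p$dur, "half_sin_squared",
                     p$peak * reference_bsa, "drug", p$stock),
    infusion_segment(p$flush_start, 0.5, "half_sin_squared",
                     p$flush_peak * reference_bsa, "glucose"))
  pump_program(segs, tube, dose = p$dose * reference_bsa,
               t0_clock = p$t0, drug = drug)
}

#' @export
print.tube_spec <- function(x, ...) {
  cat(sprintf("Infusion tube: volume %.3f ml (radius %.2f mm, length %.0f mm)\n",
              x$volume, x$radius, x$length))
  invisible(x)
}

#' @export
print.pump_program <- function(x, ...) {
  cat(sprintf("Pump program%s%s: %d segment(s), tube %.2f ml, dose %.1f mg\n",
              if (!is.null(x$drug)) paste0(" [", x$drug, "]") else "",
              if (!is.null(x$t0_clock)) paste0(" (start ", x$t0_clock, ")") else "",
              length(x$segments), x$tube$volume, x$dose))
  for (s in x$segments)
    cat(sprintf("  %6.2f h  +%5.2f h  %-16s peak %7.3f ml/h  %s (%.2f mg/ml)\n",
                s$start, s$duration, s$shape, s$peak_rate, s$solution,
                s$stock_concentration))
  invisible(x)
}
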