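#' Clinically intended infusion profile
#'
#' The exposure intended by the clinician: a sine-squared arch in mass rate,
#' `m(t) = stock * w(t)` with volumetric rate
#' `w(t) = peak_v * sin^2(pi (t - start) / duration)` and
#' `peak_v = 2 (dose/stock) / duration`, so the integral of the mass rate
#' equals the dose.
#'
#' @param start intended clinical start, hours on the program time axis.
#' @param duration intended infusion duration, hours.
#' @param dose total intended drug mass, mg.
#' @param stock_concentration drug solution concentration, mg/ml.
#' @return An object of class `intended_profile`.
#' @export
intended_profile <- function(start, duration, dose, stock_concentration) {
  stopifnot(duration > 0, dose > 0, stock_concentration > 0)
  structure(list(start = start, duration = duration, dose = dose,
                 stock_concentration = stock_concentration,
                 peak_volumetric = 2 * (dose / stock_concentration) / duration),
            class = "intended_profile")
}

## intended mass rate (mg/h), vectorized over the program time axis
intended_rate <- function(intended, t) {
  tau <- t - intended$start
  r <- intended$stock_concentration * intended$peak_volumetric *
    sin(pi * tau / intended$duration)^2
  r[tau < 0 | tau > intended$duration] <- 0
  r
}

## cumulative intended volume (ml) pumped after elapsed time tau
intended_cumvol <- function(intended, tau) {
  tau <- pmin(pmax(tau, 0), intended$duration)
  D <- intended$duration
  intended$peak_volumetric * (tau / 2 - (D / (4 * pi)) * sin(2 * pi * tau / D))
}

#' Design the corrected three-part pump program
#'
#' Constructs the pump program whose delivered profile at the patient end
#' equals the clinically intended sine-squared profile, in three parts:
#' (1) an initial bolus at the channel's maximum rate that fills the tube
#' dead volume exactly at the intended clinical start; (2) the intended
#' sinusoid, interrupted at the truncation time `t_cut` where the drug-bag
#' volume `dose/stock` is exhausted (bolus volume included); (3) a glucose
#' rinse whose volumetric rate continues the sinusoid's tail so the drug
#' still in the tube exits at the intended rate, emptying the tube exactly
#' at the intended end. Stock concentration is kept unchanged. Optionally
#' the legacy 30-min glucose peak is appended after the rate-matched rinse.
#'
#' @param intended an [intended_profile()].
#' @param tube a [tube_spec()].
#' @param max_pump_rate channel maximum volumetric rate, ml/h (default 125).
#' @param legacy_rinse optional [infusion_segment()] appended unchanged
#'   after the rate-matched rinse (e.g. the original 30-min glucose peak).
#' @return A [pump_program()] (also classed `corrected_program`) on the same
#'   time axis as `intended`, with the intended profile attached as an
#'   attribute.
#' @export
design_corrected_program <- function(intended, tube = tube_spec(),
                                     max_pump_rate = 125,
                                     legacy_rinse = NULL) {
  vol <- tube$volume
  bag_vol <- intended$dose / intended$stock_concentration
  t_bolus <- vol / max_pump_rate
  if (intended$start - t_bolus < -1e-12)
    stop("infeasible bolus: max pump rate too low to fill the tube before ",
         "the intended start")
  if (bag_vol - vol <= 1e-12)
    stop("dose/volume inconsistency: tube volume exceeds the drug-bag volume")
  ## truncation: cumulative sinusoid volume = bag volume - bolus volume
  target <- bag_vol - vol
  if (target >= intended_cumvol(intended, intended$duration) - 1e-12)
    stop("dose/volume inconsistency: truncation time not reached before ",
         "the intended end")
  f <- function(tau) intended_cumvol(intended, tau) - target
  t_cut <- stats::uniroot(f, lower = 0, upper = intended$duration,
                          tol = 1e-9 / max(intended$peak_volumetric, 1))$root

  segs <- list()
  if (t_bolus > 1e-12)
    segs <- c(segs, list(infusion_segment(
      intended$start - t_bolus, t_bolus, "constant", max_pump_rate,
      "drug", intended$stock_concentration)))
  segs <- c(segs, list(infusion_segment(
    intended$start, t_cut, "sin_squared_tail", intended$peak_volumetric,
    "drug", intended$stock_concentration,
    period = intended$duration, offset = 0)))
  if (intended$duration - t_cut > 1e-12)
    segs <- c(segs, list(infusion_segment(
      intended$start + t_cut, intended$duration - t_cut, "sin_squared_tail",
      intended$peak_volumetric, "glucose",
      period = intended$duration, offset = t_cut)))
  if (!is.null(legacy_rinse)) segs <- c(segs, list(legacy_rinse))

  prog <- pump_program(segs, tube, dose = intended$dose)
  attr(prog, "intended") <- intended
  attr(prog, "t_cut") <- t_cut
  class(prog) <- c("corrected_program", class(prog))
  prog
}

#' Compare a delivered profile with the intended profile
#'
#' Interpolates both mass-rate curves onto a common grid and reports the L1
#' mismatch (as a fraction of the dose), the Linf mismatch (relative to the
#' intended peak rate), the onset shift in minutes, and the paired
#' cumulative curves in percent of dose.
#'
#' @param delivered a [delivery_profile()].
#' @param intended an [intended_profile()].
#' @param n_grid number of points of the comparison grid.
#' @return An object of class `profile_comparison`: list with `l1`, `linf`,
#'   `onset_shift_min` and a `cumulative` data frame.
#' @export
compare_profiles <- function(delivered, intended, n_grid = 4001) {
  if (intended$dose <= 0) stop("zero-dose intended profile")
  t0 <- min(delivered$times, intended$start)
  t1 <- max(delivered$times, intended$start + intended$duration)
  grid <- seq(t0, t1, length.out = n_grid)
  dt <- grid[2] - grid[1]
  dv <- stats::approx(delivered$times, delivered$rate, grid,
                      yleft = 0, yright = 0)$y
  iv <- intended_rate(intended, grid)
  l1 <- sum(abs(dv - iv)) * dt / intended$dose
  linf <- max(abs(dv - iv)) / max(iv)
  onset_d <- attr(delivered, "onset")
  if (is.null(onset_d) || is.na(onset_d)) {
    nz <- which(delivered$rate > 1e-12)
    onset_d <- if (length(nz)) delivered$times[nz[1]] else NA_real_
  }
  onset_shift <- round((onset_d - intended$start) * 60)
  cum_d <- cumsum(dv) * dt / intended$dose * 100
  cum_i <- cumsum(iv) * dt / intended$dose * 100
  structure(list(l1 = l1, linf = linf, onset_shift_min = onset_shift,
                 cumulative = data.frame(time_h = grid,
                                         delivered_pct = cum_d,
                                         intended_pct = cum_i)),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf(paste0("Profile mismatch: L1 = %.3f%% of dose, ",
                     "Linf = %.3f%% of peak, onset shift = %d min\n"),
              100 * x$l1, 100 * x$linf, x$onset_shift_min))
  invisible(x)
}

#' @export
plot.profile_comparison <- function(x, ...) {
  graphics::plot(x$cumulative$time_h, x$cumulative$intended_pct, type = "l",
                 xlab = "time (h)", ylab = "cumulative dose (%)", lty = 2, ...)
  graphics::lines(x$cumulative$time_h, x$cumulative$delivered_pct)
  graphics::legend("bottomright", c("delivered", "intended"), lty = c(1, 2))
  invisible(x)
}
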