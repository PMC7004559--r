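#' Delivery profile at the patient end of the infusion line
#'
#' Container for the drug mass rate entering the patient, `rate` (mg/h) on
#' the grid `times` (hours from pump start), with the cumulative delivered
#' mass (mg). Built by [solve_transport_characteristics()] and
#' [solve_transport_fd()].
#'
#' @param times time grid, hours from pump start.
#' @param rate drug mass rate into the patient, mg/h.
#' @param cumulative cumulative delivered mass, mg (nondecreasing).
#' @param onset exact onset time of nonzero delivery (h), if known.
#' @param dose total programmed dose (mg), if known.
#' @return An object of class `delivery_profile`.
#' @export
delivery_profile <- function(times, rate, cumulative, onset = NA_real_,
                             dose = NA_real_) {
  stopifnot(length(times) == length(rate),
            length(times) == length(cumulative))
  if (any(diff(cumulative) < -1e-9 * max(cumulative, 1)))
    stop("cumulative delivered mass must be nondecreasing")
  structure(list(times = times, rate = rate, cumulative = cumulative),
            onset = onset, dose = dose, class = "delivery_profile")
}

## output time grid: regular steps plus segment boundaries
profile_time_grid <- function(program, dt, t_end = NULL) {
  if (is.null(t_end)) t_end <- program_end(program)
  brk <- unlist(lapply(program$segments,
                       function(s) c(s$start, s$start + s$duration)))
  sort(unique(pmin(c(seq(0, t_end, by = dt), t_end, brk), t_end)))
}

## entry time tau(t): cumulative pumped volume between tau and t equals the
## tube volume; NA while the tube has pumped less than its own volume
program_tau <- function(program, t, tube_volume) {
  W <- program_cumvol(program, t)
  vapply(seq_along(t), function(i) {
    if (W[i] < tube_volume - 1e-12) return(NA_real_)
    target <- W[i] - tube_volume
    if (target <= 0) return(0)
    stats::uniroot(function(s) program_cumvol(program, s) - target,
                   lower = 0, upper = t[i], tol = 1e-12)$root
  }, numeric(1))
}

#' Solve the pump-to-patient transport by the method of characteristics
#'
#' The drug concentration along the tube obeys the pure advection equation
#' `du/dt = -V(t) du/dx` with inlet boundary value equal to the stock
#' concentration of the active segment. Along characteristics the fluid
#' parcel leaving the tube at time `t` entered at time `tau(t)` defined by
#' the pumped volume between `tau` and `t` equalling the tube dead volume,
#' so the delivery rate is `d(t) = q(t) * s(tau(t))` with `q` the pump
#' volumetric rate (ml/h) and `s` the inlet concentration (mg/ml). The
#' cumulative delivered mass is exactly the inlet mass pushed in by time
#' `tau(t)` (plug flow), so mass is conserved to root-finding tolerance.
#'
#' @param program a [pump_program()].
#' @param dt output grid step in hours (the solution itself is exact;
#'   `dt` only controls the reporting grid).
#' @param t_end end of the reported grid (defaults to program end).
#' @return A [delivery_profile()] with the exact delivery onset attached.
#' @export
solve_transport_characteristics <- function(program, dt = 0.005,
                                            t_end = NULL) {
  vol <- program$tube$volume
  times <- profile_time_grid(program, dt, t_end)
  tau <- program_tau(program, times, vol)
  rate <- ifelse(is.na(tau), 0,
                 program_rate(program, times) *
                   program_inlet_conc(program, ifelse(is.na(tau), 0, tau)))
  cum <- ifelse(is.na(tau), 0,
                program_inlet_mass(program, ifelse(is.na(tau), 0, tau)))
  total_vol <- program_total_volume(program)
  onset <- if (total_vol < vol) NA_real_ else
    stats::uniroot(function(t) program_cumvol(program, t) - vol,
                   lower = 0, upper = program_end(program), tol = 1e-12)$root
  delivery_profile(times, rate, cum, onset = onset, dose = program$dose)
}

#' Solve the pump-to-patient transport by upwind finite differences
#'
#' First-order upwind discretisation (backward in space for positive
#' velocity), explicit in time, of the advection equation along the tube.
#' The inlet cell takes the stock concentration of the active segment while
#' the pump is running and the field is frozen when the velocity is zero.
#' Delivered and injected masses use the same discrete quadrature as the
#' scheme, so the discrete mass balance telescopes exactly.
#'
#' @param program a [pump_program()].
#' @param dx spatial step in mm; must divide the tube length (default
#'   length/1000).
#' @param dt time step in hours; when `NULL`, chosen from the CFL target.
#' @param cfl CFL number used to pick `dt` (must be <= 1).
#' @param t_end simulation horizon (defaults to program end).
#' @param n_out number of reported time points.
#' @param store_state keep the full concentration field u(x, t)?
#' @return A list with components `profile` (a [delivery_profile()]) and
#'   `state` (grid_x, grid_t, u matrix; `NULL` unless `store_state`).
#' @export
solve_transport_fd <- function(program, dx = program$tube$length / 1000,
                               dt = NULL, cfl = 0.9, t_end = NULL,
                               n_out = 2000, store_state = FALSE) {
  tube <- program$tube
  L <- tube$length
  sa <- tube$sa
  nx <- round(L / dx)
  if (abs(nx * dx - L) > 1e-6 * L) stop("dx must divide the tube length")
  if (is.null(t_end)) t_end <- program_end(program)
  ## peak velocity (mm/h): q [ml/h] * 1000 / sa [mm^2]
  qmax <- max(program_rate(program, seq(0, t_end, length.out = 4096)),
              vapply(program$segments, `[[`, numeric(1), "peak_rate"))
  vmax <- qmax * 1000 / sa
  if (is.null(dt)) dt <- cfl * dx / vmax
  if (vmax * dt / dx > 1 + 1e-9)
    stop("CFL condition violated: max(V) * dt / dx > 1")
  nt <- ceiling(t_end / dt)
  keep <- unique(round(seq(1, nt + 1, length.out = min(n_out, nt + 1))))

  u <- numeric(nx + 1)                       # mg/ml at x = 0, dx, ..., L
  t_now <- 0
  out_t <- numeric(length(keep)); out_rate <- numeric(length(keep))
  out_cum <- numeric(length(keep))
  if (store_state) U <- matrix(0, nrow = length(keep), ncol = nx + 1)
  cum <- 0; ki <- 1
  if (1 %in% keep) { out_t[ki] <- 0; ki <- ki + 1 }
  for (n in seq_len(nt)) {
    q <- program_rate(program, t_now)
    if (q > 0) {
      u[1] <- program_inlet_conc(program, t_now)
      v <- q * 1000 / sa
      cnum <- v * dt / dx
      rate_out <- q * u[nx + 1]              # mg/h, old-step quadrature
      cum <- cum + rate_out * dt
      u[2:(nx + 1)] <- u[2:(nx + 1)] - cnum * diff(u)
    } else rate_out <- 0
    t_now <- n * dt
    if ((n + 1) %in% keep) {
      out_t[ki] <- t_now
      out_rate[ki] <- program_rate(program, t_now) * u[nx + 1]
      out_cum[ki] <- cum
      if (store_state) U[ki, ] <- u
      ki <- ki + 1
    }
  }
  profile <- delivery_profile(out_t, out_rate, out_cum, dose = program$dose)
  state <- if (store_state)
    list(grid_x = seq(0, L, by = dx), grid_t = out_t, u = U) else NULL
  list(profile = profile, state = state)
}

#' Tube fill delay
#'
#' Time from pump start until drug first reaches the patient, i.e. until
#' the pumped volume fills the tube dead volume; reported to the nearest
#' minute, matching clinical reporting granularity.
#'
#' @param profile a [delivery_profile()] whose first active segment is a
#'   drug segment.
#' @return Delay in minutes (integer). `NA` with a warning when the tube
#'   is never filled.
#' @export
fill_delay <- function(profile) {
  onset <- attr(profile, "onset")
  if (is.null(onset) || is.na(onset)) {
    nz <- which(profile$rate > 1e-12)
    if (!length(nz)) {
      warning("tube never filled: delivery rate is zero everywhere")
      return(NA_integer_)
    }
    onset <- profile$times[nz[1]]
  }
  as.integer(round(onset * 60))
}

#' Drug fraction delivered during the terminal glucose flush
#'
#' The pump stops with the tube still holding one dead volume of drug
#' solution; the glucose rinse expels it as a delivery spike. This returns
#' the drug mass delivered during the final glucose segment as a percentage
#' of the total programmed dose.
#'
#' @param program a [pump_program()] ending with a glucose segment.
#' @param profile optionally, a precomputed characteristics solution.
#' @return Spike fraction in percent of total dose. If the flush volume is
#'   smaller than the tube volume a warning flags the partial spike.
#' @export
flush_spike_fraction <- function(program, profile = NULL) {
  segs <- program$segments
  last <- segs[[length(segs)]]
  if (last$solution != "glucose")
    stop("program does not end with a glucose flush segment")
  if (segment_volume(last) < program$tube$volume - 1e-9)
    warning("flush volume below tube volume: partial spike reported")
  if (program$dose <= 0) return(0)
  t0 <- last$start
  t1 <- last$start + last$duration
  tau <- program_tau(program, c(t0, t1), program$tube$volume)
  mass <- function(i, t)
    if (is.na(tau[i])) 0 else program_inlet_mass(program, tau[i])
  spike <- mass(2, t1) - mass(1, t0)
  100 * spike / program$dose
}

#' @export
print.delivery_profile <- function(x, ...) {
  onset <- attr(x, "onset")
  cat(sprintf("Delivery profile: %d points over %.2f h, delivered %.2f mg",
              length(x$times), max(x$times), max(x$cumulative)))
  if (!is.null(onset) && !is.na(onset))
    cat(sprintf(", onset %.0f min", onset * 60))
  cat("\n")
  invisible(x)
}

#' @export
plot.delivery_profile <- function(x, ...) {
  graphics::plot(x$times, x$rate, type = "l", xlab = "time (h)",
                 ylab = "delivery rate (mg/h)", ...)
  invisible(x)
}

#' @export
as.data.frame.delivery_profile <- function(x, ...) {
  data.frame(time_h = x$times, rate_mg_h = x$rate,
             cumulative_mg = x$cumulative)
}
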