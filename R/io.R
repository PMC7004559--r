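#' Convert a clock time to hours past an anchor
#'
#' `"HH:MM"` clock strings are mapped to hours past the anchor clock time,
#' rolling over midnight (e.g. anchor "22:15", time "09:45" gives 11.5 h).
#'
#' @param clock character vector of `"HH:MM"` times.
#' @param anchor anchor clock time `"HH:MM"` (hour zero).
#' @return Numeric hours in `[0, 24)`.
#' @export
clock_to_hours <- function(clock, anchor = "00:00") {
  parse1 <- function(s) {
    m <- regmatches(s, regexec("^([0-9]{1,2}):([0-9]{2})$", s))[[1]]
    if (length(m) != 3) stop("malformed clock time: ", s)
    h <- as.numeric(m[2]); mi <- as.numeric(m[3])
    if (h >= 24 || mi >= 60) stop("malformed clock time: ", s)
    h + mi / 60
  }
  a <- parse1(anchor)
  vapply(clock, function(s) (parse1(s) - a) %% 24, numeric(1),
         USE.NAMES = FALSE)
}

#' Read a concentration CSV
#'
#' Expects columns `patient_id, analyte, time_h, conc_mg_per_L`. `time_h`
#' may contain clock strings `"HH:MM"` which are converted to hours past
#' `anchor` (the infusion onset). Rows are validated (negative
#' concentrations and duplicate patient/analyte/time triples are rejected,
#' naming the offending rows) and sorted by patient, analyte, time.
#'
#' @param path CSV file.
#' @param anchor infusion-onset clock time used for `"HH:MM"` values.
#' @return Validated, sorted data frame.
#' @export
read_concentration_csv <- function(path, anchor = "00:00") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "analyte", "time_h", "conc_mg_per_L")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "))
  if (is.character(d$time_h)) {
    is_clock <- grepl(":", d$time_h)
    t <- suppressWarnings(as.numeric(d$time_h))
    t[is_clock] <- clock_to_hours(d$time_h[is_clock], anchor)
    if (anyNA(t))
      stop("unparseable time_h in rows: ",
           paste(which(is.na(t)), collapse = ", "))
    d$time_h <- t
  }
  d$conc_mg_per_L <- as.numeric(d$conc_mg_per_L)
  bad <- which(is.na(d$conc_mg_per_L) | d$conc_mg_per_L < 0)
  if (length(bad))
    stop("negative or missing concentrations in rows: ",
         paste(bad, collapse = ", "))
  key <- paste(d$patient_id, d$analyte, signif(d$time_h, 12))
  if (anyDuplicated(key))
    stop("duplicate (patient, analyte, time) in rows: ",
         paste(which(duplicated(key)), collapse = ", "))
  d[order(d$patient_id, d$analyte, d$time_h), , drop = FALSE]
}

#' Write a concentration CSV
#'
#' @param data data frame with the standard concentration columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_concentration_csv <- function(data, path) {
  cols <- c("patient_id", "analyte", "time_h", "conc_mg_per_L")
  utils::write.csv(data[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a delivery profile CSV
#'
#' Columns `time_h` (from pump start), `rate_mg_h`, `cumulative_mg`.
#'
#' @param profile a [delivery_profile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_delivery_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a delivery profile CSV
#'
#' @param path CSV written by [write_delivery_csv()].
#' @return A [delivery_profile()].
#' @export
read_delivery_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_h", "rate_mg_h", "cumulative_mg")
  if (!all(need %in% names(d)))
    stop("missing columns in ", path, ": ",
         paste(setdiff(need, names(d)), collapse = ", "))
  delivery_profile(d$time_h, d$rate_mg_h, d$cumulative_mg)
}

#' Save a pump program as YAML
#'
#' Schema: a `tube` block (`volume_ml` or `radius_mm`/`length_mm`), the
#' nominal `dose_mg`, optional `t0_clock` and `drug`, and a `segments` list
#' with `start_h, duration_h, shape, peak_rate_ml_h, solution,
#' stock_mg_per_ml` (plus `period_h`/`offset_h` for tail-shaped rinses).
#'
#' @param program a [pump_program()].
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_program_yaml <- function(program, path) {
  obj <- list(
    tube = list(volume_ml = program$tube$volume,
                radius_mm = program$tube$radius),
    dose_mg = program$dose,
    t0_clock = program$t0_clock,
    drug = program$drug,
    segments = lapply(program$segments, function(s) list(
      start_h = s$start, duration_h = s$duration, shape = s$shape,
      peak_rate_ml_h = s$peak_rate, solution = s$solution,
      stock_mg_per_ml = s$stock_concentration,
      period_h = s$period, offset_h = s$offset)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a pump program from YAML (or JSON)
#'
#' Accepts the schema of [write_program_yaml()]; segment start times may be
#' clock strings `"HH:MM"` interpreted against `t0_clock`. Per-m2 peak
#' rates (`peak_rate_ml_per_m2_h`) are scaled by `reference_bsa`.
#'
#' @param path YAML or JSON file.
#' @param reference_bsa BSA (m2) used to scale per-m2 rates.
#' @return A [pump_program()].
#' @export
read_program_yaml <- function(path, reference_bsa = 1.84) {
  obj <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = FALSE)
         else yaml::read_yaml(path)
  tb <- obj$tube
  tube <- if (!is.null(tb$volume_ml))
    tube_spec(volume = tb$volume_ml, radius = tb$radius_mm %||% 0.5)
  else tube_spec(volume = pi * tb$radius_mm^2 * tb$length_mm / 1000,
                 radius = tb$radius_mm, length = tb$length_mm)
  t0 <- obj$t0_clock
  segs <- lapply(obj$segments, function(s) {
    start <- s$start_h %||% s$start
    if (is.character(start)) {
      if (is.null(t0)) stop("clock segment start needs a t0_clock anchor")
      start <- clock_to_hours(start, t0)
    }
    peak <- s$peak_rate_ml_h %||% (s$peak_rate_ml_per_m2_h * reference_bsa)
    shape <- s$shape %||% "constant"
    if (!shape %in% c("constant", "half_sin_squared", "sin_squared_tail"))
      stop("unknown segment shape: ", shape)
    infusion_segment(start, s$duration_h, shape, peak,
                     s$solution %||% "drug", s$stock_mg_per_ml %||% 0,
                     period = s$period_h %||% s$duration_h,
                     offset = s$offset_h %||% 0)
  })
  pump_program(segs, tube, dose = obj$dose_mg, t0_clock = t0,
               drug = obj$drug)
}

#' Write a fit result (or list of fits) as JSON
#'
#' Per-patient parameters, weighted SSR, R-squared values, constraint
#' residuals and optimizer seed, in a stable schema.
#'
#' @param fits a named list of [fit_pk()] results (or a single fit).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  if (inherits(fits, "pk_fit")) fits <- list(fit = fits)
  obj <- lapply(fits, function(f) list(
    drug = f$drug,
    parameters = as.list(unclass(f$coef)),
    free = f$free,
    ssr = f$ssr_weighted,
    r_squared = as.list(f$r_squared),
    constraint_residuals = if (!is.null(f$constraint_residuals))
      as.list(f$constraint_residuals),
    seed = f$optimizer$seed))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
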