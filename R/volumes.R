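#' Body surface area (Du Bois)
#'
#' @param height_m height in metres.
#' @param weight_kg weight in kg.
#' @return BSA in m2.
#' @export
bsa_dubois <- function(height_m, weight_kg) {
  0.007184 * weight_kg^0.425 * (100 * height_m)^0.725
}

#' Patient-individualised compartment volumes
#'
#' Computes the Liver, Blood and Organs volumes of the semi-physiological
#' PK models from patient anthropometrics: total liver volume from the
#' BSA-based Vauthey formula, blood volume from the sex-specific Nadler
#' formula, and the Organs volume as the total body volume (Sendroy-style,
#' weight over mean body density) minus liver and blood. Each formula can
#' be overridden through `formulas` for sensitivity analyses.
#'
#' @param sex `"male"` or `"female"`.
#' @param height_m height in metres.
#' @param weight_kg weight in kg.
#' @param bsa body surface area in m2; Du Bois estimate when `NULL`.
#' @param formulas optional list of overrides: functions `liver(bsa)`,
#'   `blood(sex, height_m, weight_kg)`, `total(sex, height_m, weight_kg)`
#'   each returning litres.
#' @return An object of class `compartment_volumes`: list with `V_L`, `V_B`,
#'   `V_O` (litres) and the BSA used.
#' @export
compute_compartment_volumes <- function(sex = c("male", "female"),
                                        height_m, weight_kg, bsa = NULL,
                                        formulas = list()) {
  sex <- match.arg(sex)
  stopifnot(height_m > 0, weight_kg > 0)
  if (is.null(bsa)) bsa <- bsa_dubois(height_m, weight_kg)
  stopifnot(bsa > 0)

  liver <- formulas$liver %||%
    function(bsa) (-794.41 + 1267.28 * bsa) / 1000     # Vauthey, ml -> L
  blood <- formulas$blood %||% function(sex, h, w) {   # Nadler, L
    if (sex == "male") 0.3669 * h^3 + 0.03219 * w + 0.6041
    else               0.3561 * h^3 + 0.03308 * w + 0.1833
  }
  total <- formulas$total %||%
    function(sex, h, w) w / 1.05                       # mean body density kg/L

  V_L <- liver(bsa)
  V_B <- blood(sex, height_m, weight_kg)
  V_tot <- total(sex, height_m, weight_kg)
  V_O <- V_tot - V_L - V_B
  if (V_L <= 0 || V_B <= 0 || V_O <= 0)
    stop("non-physiologic anthropometrics: a compartment volume is <= 0")
  structure(list(V_L = V_L, V_B = V_B, V_O = V_O, bsa = bsa),
            class = "compartment_volumes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.compartment_volumes <- function(x, ...) {
  cat(sprintf("Compartment volumes (L): Liver %.2f, Blood %.2f, Organs %.2f (BSA %.2f m2)\n",
              x$V_L, x$V_B, x$V_O, x$bsa))
  invisible(x)
}
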