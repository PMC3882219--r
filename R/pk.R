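#' Carboplatin three-compartment pharmacokinetic derivatives
#'
#' Intraperitoneally administered carboplatin is absorbed from the
#' peritoneal cavity (first compartment) into the central plasma compartment
#' (second), exchanges bidirectionally with poorly-perfused peripheral
#' tissue (third, where the tumor resides) and is cleared from plasma.
#' Fluxes are written in amount-conserving form with explicit compartment
#' volumes, so inter-compartment mass fluxes balance pairwise and total
#' mass (compartments + cumulative elimination) is conserved.
#'
#' @param state named vector `C_p`, `C_c`, `C_t`: peritoneal, plasma and
#'   tissue concentrations (ug/ml).
#' @param input_rate drug mass flow into the peritoneum (ug/day).
#' @param params `xeno_params` (uses the `carbo_*` fields).
#' @return named vector of time derivatives (ug/ml/day) plus `E`, the
#'   elimination mass rate (ug/day).
#' @export
carboplatin_pk_derivatives <- function(state, input_rate, params) {
  state <- state[c("C_p", "C_c", "C_t")]
  if (any(is.na(state)) || any(state < 0))
    stop("concentrations must be non-negative")
  if (input_rate < 0) stop("input_rate must be non-negative")
  p <- params
  if (p$carbo_V_p <= 0 || p$carbo_V_c <= 0 || p$carbo_V_t <= 0)
    stop("compartment volumes must be positive")
  c(
    C_p = input_rate / p$carbo_V_p - p$carbo_k_pc * state[["C_p"]],
    C_c = (p$carbo_k_pc * state[["C_p"]] * p$carbo_V_p -
             p$carbo_k_ct * state[["C_c"]] * p$carbo_V_c +
             p$carbo_k_tc * state[["C_t"]] * p$carbo_V_t -
             p$carbo_k_el * state[["C_c"]] * p$carbo_V_c) / p$carbo_V_c,
    C_t = (p$carbo_k_ct * state[["C_c"]] * p$carbo_V_c -
             p$carbo_k_tc * state[["C_t"]] * p$carbo_V_t) / p$carbo_V_t,
    E = p$carbo_k_el * state[["C_c"]] * p$carbo_V_c
  )
}

#' ABT-737 three-compartment pharmacokinetic derivatives
#'
#' Same structure as carboplatin except that the third compartment is
#' intracellular: drug permeates from the systemic circulation into the
#' cells, where it is additionally consumed (or released) by the Bcl-xL
#' binding reaction at the signed rate `binding_flux`.
#'
#' @param state named vector `A_p`, `A_c`, `A_i`: peritoneal, plasma and
#'   intracellular concentrations (nM).
#' @param input_rate drug flow into the peritoneum (nmol/day).
#' @param binding_flux net intracellular consumption by Bcl-xL binding
#'   (nM/day, association minus dissociation; may be negative).
#' @param params `xeno_params` (uses the `abt_*` fields).
#' @return named vector of derivatives (nM/day) plus `E` (nmol/day
#'   eliminated from plasma).
#' @export
abt737_pk_derivatives <- function(state, input_rate, binding_flux, params) {
  state <- state[c("A_p", "A_c", "A_i")]
  if (any(is.na(state)) || any(state < 0))
    stop("concentrations must be non-negative")
  if (input_rate < 0) stop("input_rate must be non-negative")
  p <- params
  if (p$abt_V_p <= 0 || p$abt_V_c <= 0 || p$abt_V_i <= 0)
    stop("compartment volumes must be positive")
  c(
    A_p = input_rate / p$abt_V_p - p$abt_k_pc * state[["A_p"]],
    A_c = (p$abt_k_pc * state[["A_p"]] * p$abt_V_p -
             p$abt_k_ci * state[["A_c"]] * p$abt_V_c +
             p$abt_k_ic * state[["A_i"]] * p$abt_V_i -
             p$abt_k_el * state[["A_c"]] * p$abt_V_c) / p$abt_V_c,
    A_i = (p$abt_k_ci * state[["A_c"]] * p$abt_V_c -
             p$abt_k_ic * state[["A_i"]] * p$abt_V_i) / p$abt_V_i -
      binding_flux - p$abt_k_loss * state[["A_i"]],
    E = p$abt_k_el * state[["A_c"]] * p$abt_V_c
  )
}

#' Convert an mg/kg dose to the compartment amount unit
#'
#' Carboplatin amounts are tracked in ug; ABT-737 in nmol (its
#' concentrations are molar).  Linear in dose; uses the configured body
#' mass and molecular weight.
#'
#' @param dose dose in mg per kg body mass.
#' @param drug `"carboplatin"` or `"abt737"`.
#' @param params `xeno_params`.
#' @return amount delivered per dose (ug for carboplatin, nmol for ABT-737).
#' @examples
#' p <- model_params()
#' dose_to_input_amount(30, "carboplatin", p)   # 600 ug in a 20 g mouse
#' @export
dose_to_input_amount <- function(dose, drug = c("carboplatin", "abt737"),
                                 params) {
  drug <- match.arg(drug)
  if (any(dose < 0)) stop("dose must be non-negative")
  mg <- dose * params$body_mass_kg
  if (drug == "carboplatin") {
    mg * 1000                        # ug
  } else {
    mg * 1e6 / params$abt_mw         # mg -> nmol via MW (g/mol)
  }
}
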