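#' Mass-action derivatives of the Bcl-xL / Bax / ABT-737 network
#'
#' The intracellular apoptosis switch: Bcl-xL sequesters Bax in an inert
#' heterodimer; intracellular ABT-737 competes for Bcl-xL, displacing Bax.
#' All species are produced constitutively and degrade first-order.
#'
#' @param state named numeric vector with elements `x_L` (free Bcl-xL, nM),
#'   `x_B` (free Bax, nM), `x_LB` (Bcl-xL.Bax, nM), `x_LA`
#'   (Bcl-xL.ABT-737, nM).
#' @param a_i intracellular ABT-737 concentration (nM).
#' @param params `xeno_params` object (or any list with the `bcl_*` fields).
#' @return list with `derivatives` (named vector, nM/day) and
#'   `binding_flux`, the net rate of intracellular ABT-737 consumption by
#'   Bcl-xL binding (nM/day), to be subtracted from the drug's intracellular
#'   pharmacokinetic balance.
#' @export
bcl_network_derivatives <- function(state, a_i, params) {
  state <- state[c("x_L", "x_B", "x_LB", "x_LA")]
  if (any(is.na(state)) || any(state < 0) || a_i < 0)
    stop("network state and intracellular drug must be non-negative")
  p <- params
  hetero <- p$bcl_kon_bax * state[["x_L"]] * state[["x_B"]] -
    p$bcl_koff_bax * state[["x_LB"]]
  bind <- p$bcl_kon_abt * state[["x_L"]] * a_i -
    p$bcl_koff_abt * state[["x_LA"]]
  d <- c(
    x_L = p$bcl_prod_bclxl - p$bcl_deg_bclxl * state[["x_L"]] - hetero - bind,
    x_B = p$bcl_prod_bax - p$bcl_deg_bax * state[["x_B"]] - hetero,
    x_LB = hetero - p$bcl_deg_dimer * state[["x_LB"]],
    x_LA = bind - p$bcl_deg_drug_complex * state[["x_LA"]]
  )
  list(derivatives = d, binding_flux = unname(bind))
}

#' Closed-form free Bax at heterodimer equilibrium
#'
#' For a pure two-species binding equilibrium at fixed totals, free Bax
#' solves the quadratic `x_B (L_tot - (B_tot - x_B)) = kd (B_tot - x_B)`.
#' The unique non-negative root is returned.  Serves as the independent
#' oracle for the simulated network equilibrium.
#'
#' @param total_bclxl total Bcl-xL (free + bound, nM).
#' @param total_bax total Bax (nM).
#' @param kd dissociation constant of the Bcl-xL.Bax complex (nM).
#' @return free Bax concentration (nM).
#' @examples
#' free_bax_equilibrium(200, 150, 20)
#' @export
free_bax_equilibrium <- function(total_bclxl, total_bax, kd) {
  if (total_bclxl < 0 || total_bax < 0) stop("totals must be non-negative")
  if (!is.finite(kd) || kd <= 0) stop("kd must be > 0")
  # x_B^2 + (L - B + kd) x_B - kd B = 0
  b <- total_bclxl - total_bax + kd
  c0 <- -kd * total_bax
  xb <- (-b + sqrt(b^2 - 4 * c0)) / 2
  max(xb, 0)
}

#' Drug-free (or clamped-drug) equilibrium of the full network
#'
#' Solves the steady state of the four-species network with production and
#' degradation active and intracellular ABT-737 clamped at `a_i`.
#' Reduction: both complex equations are linear in their complex at fixed
#' free species, and the free Bcl-xL balance is linear in `x_L` at fixed
#' `x_B`, leaving a single monotone residual in free Bax solved by
#' bisection.
#'
#' @inheritParams bcl_network_derivatives
#' @return named vector `x_L`, `x_B`, `x_LB`, `x_LA` (nM).
#' @export
bcl_equilibrium <- function(params, a_i = 0) {
  p <- params
  xL_of_xB <- function(xB) {
    # from the two complex balances: x_LB = kon_b xL xB / (koff_b + d_LB)
    #                                x_LA = kon_a xL a_i / (koff_a + d_LA)
    q_b <- p$bcl_kon_bax * p$bcl_deg_dimer / (p$bcl_koff_bax + p$bcl_deg_dimer)
    q_a <- p$bcl_kon_abt * p$bcl_deg_drug_complex /
      (p$bcl_koff_abt + p$bcl_deg_drug_complex)
    p$bcl_prod_bclxl / (p$bcl_deg_bclxl + q_b * xB + q_a * a_i)
  }
  resid <- function(xB) {
    xL <- xL_of_xB(xB)
    xLB <- p$bcl_kon_bax * xL * xB / (p$bcl_koff_bax + p$bcl_deg_dimer)
    hetero <- p$bcl_kon_bax * xL * xB - p$bcl_koff_bax * xLB
    p$bcl_prod_bax - p$bcl_deg_bax * xB - hetero
  }
  hi <- if (p$bcl_deg_bax > 0) p$bcl_prod_bax / p$bcl_deg_bax else
    p$bcl_prod_bax * 1e6 + 1
  root <- uniroot(resid, c(0, hi * (1 + 1e-9)), tol = 1e-12)$root
  xL <- xL_of_xB(root)
  xLB <- p$bcl_kon_bax * xL * root / (p$bcl_koff_bax + p$bcl_deg_dimer)
  xLA <- p$bcl_kon_abt * xL * a_i /
    (p$bcl_koff_abt + p$bcl_deg_drug_complex)
  c(x_L = xL, x_B = root, x_LB = xLB, x_LA = xLA)
}

#' Integrate the isolated network with clamped intracellular drug
#'
#' Small fixed-step RK4 helper used mostly as a test oracle (detailed
#' balance, dose-response monotonicity); the production-quality coupled
#' solver lives in the compiled core.
#'
#' @inheritParams bcl_network_derivatives
#' @param t_end integration horizon (day).
#' @param dt step (day).
#' @return named state vector at `t_end`.
#' @export
simulate_network <- function(state, a_i, params, t_end, dt = 1e-3) {
  f <- function(s) bcl_network_derivatives(s, a_i, params)$derivatives
  rk4_integrate(state[c("x_L", "x_B", "x_LB", "x_LA")], f, t_end, dt)
}
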