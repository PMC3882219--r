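#' Carboplatin-induced arrest rate
#'
#' Saturating Hill response of the cell-cycle arrest rate to the tissue
#' carboplatin concentration: zero without drug, half-maximal at
#' `arrest_carbo_half`, approaching `arrest_max` at high exposure.
#'
#' @param c_t tissue carboplatin concentration (ug/ml), vectorized.
#' @param params `xeno_params`.
#' @return arrest rate (1/day).
#' @export
arrest_rate <- function(c_t, params) {
  if (any(c_t < 0)) stop("c_t must be non-negative")
  ch <- c_t^params$arrest_hill
  params$arrest_max * ch / (ch + params$arrest_carbo_half^params$arrest_hill)
}

#' Bax-driven death rate of proliferating cells
#'
#' Hill response to the excess of free intracellular Bax over its
#' constitutive baseline (`bax_baseline`); baseline apoptosis is folded
#' into the net growth rate, so this is exactly zero in an untreated tumor.
#'
#' @param x_b_free free intracellular Bax (nM), vectorized.
#' @param params `xeno_params`.
#' @return death rate (1/day), saturating at `death_max`.
#' @export
proliferating_death_rate <- function(x_b_free, params) {
  if (any(x_b_free < 0)) stop("free Bax must be non-negative")
  u <- pmax(x_b_free - params$bax_baseline, 0)
  uh <- u^params$death_hill
  params$death_max * uh / (uh + params$death_bax_half^params$death_hill)
}

#' Death rate of arrested cells
#'
#' Product form: proportional to the tissue carboplatin concentration
#' remembered from the moment of arrest (a proxy for the DNA damage
#' sustained) times a Bax-dependent factor
#' `delta_M0 + lambda_s * max(x_b_free - bax_baseline, 0)`.  `lambda_s` is
#' the sensitivity of arrested cells to drug-induced changes in free Bax
#' and quantifies the synergy between carboplatin and ABT-737; the
#' constitutive Bax contribution is carried by `delta_M0`.
#'
#' @param c_at_arrest tissue carboplatin at the time of arrest (ug/ml).
#' @param x_b_free current free intracellular Bax (nM).
#' @param params `xeno_params`.
#' @return death rate (1/day).
#' @export
arrested_death_rate <- function(c_at_arrest, x_b_free, params) {
  if (any(c_at_arrest < 0) || any(x_b_free < 0))
    stop("inputs must be non-negative")
  c_at_arrest * (params$arrest_death_coef +
                   params$bax_sensitivity *
                     pmax(x_b_free - params$bax_baseline, 0))
}

#' Advance the cell populations by one step
#'
#' Reference R implementation of a single population step, mirroring the
#' compiled solver: RK4 on the proliferating pools with instantaneous rates
#' frozen, pointwise survival of each arrest-age cohort, advection of the
#' age grid by one bin (`delta_a = dt`), recovery of the terminal cohort
#' split `(1 - p_mut) / p_mut` between sensitive and resistant pools, and a
#' new cohort of freshly arrested cells at age zero.
#'
#' @param state list with `N`, `Nr` (million cells), `M` (cohort cell
#'   counts, youngest first, length `psi/dt`), `Carr` (tissue carboplatin
#'   at each cohort's arrest, ug/ml).
#' @param alpha instantaneous arrest rate (1/day).
#' @param delta_N instantaneous proliferating death rate (1/day).
#' @param delta_M per-cohort death rates (1/day), same length as `M`.
#' @param dt time step (day); the age advance equals `dt`.
#' @param params `xeno_params`.
#' @param c_t tissue carboplatin recorded with the new cohort (ug/ml).
#' @return updated state list.
#' @export
population_step <- function(state, alpha, delta_N, delta_M, dt, params,
                            c_t = 0) {
  if (dt <= 0) stop("dt must be positive")
  n_age <- round(params$arrest_duration / dt)
  if (length(state$M) != n_age)
    stop("dt does not match the age grid (expected ", n_age, " bins)")
  if (length(delta_M) != n_age) stop("delta_M must have one value per bin")
  if (any(state$M < 0)) stop("negative arrested-cell density")
  M_tot <- sum(state$M)
  f <- function(v) {
    crowd <- 1 - (v[1] + v[2] + M_tot) / params$carrying_capacity
    c(params$growth_rate * v[1] * crowd - delta_N * v[1] - alpha * v[1],
      params$growth_rate * v[2] * crowd - delta_N * v[2],
      alpha * v[1])
  }
  v <- c(state$N, state$Nr, 0)
  k1 <- f(v); k2 <- f(v + dt / 2 * k1); k3 <- f(v + dt / 2 * k2)
  k4 <- f(v + dt * k3)
  v <- v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  M <- state$M * exp(-delta_M * dt)
  recov <- M[n_age]
  list(N = v[1] + (1 - params$p_mut) * recov,
       Nr = v[2] + params$p_mut * recov,
       M = c(v[3], M[-n_age]),
       Carr = c(c_t, state$Carr[-n_age]))
}
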