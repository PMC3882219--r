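#' Per-arm tumor-growth time-course dataset
#'
#' The calibration currency: measurement days, arm-mean tumor sizes and
#' their dispersions, plus the protocol that generated the arm.
#'
#' @param arm one of `"control"`, `"abt_only"`, `"carbo_only"`, `"combo"`.
#' @param days measurement days (strictly increasing, day post-transplant).
#' @param sizes measured tumor sizes (million cells), positive for the
#'   control arm.
#' @param sd per-point dispersion (same units).
#' @param protocol list with `regimens` (list of [regimen()]), `start_day`
#'   and `initial_cells`.
#' @param truth optional noiseless model curve (kept by the generator).
#' @return object of class `tgi_dataset`.
#' @export
tgi_dataset <- function(arm, days, sizes, sd = rep(0, length(days)),
                        protocol, truth = NULL) {
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (length(sizes) != length(days)) stop("days/sizes length mismatch")
  if (arm == "control" && any(sizes <= 0))
    stop("control sizes must be positive")
  structure(list(arm = arm, days = days, sizes = sizes, sd = sd,
                 protocol = protocol, truth = truth),
            class = "tgi_dataset")
}

#' @export
as.data.frame.tgi_dataset <- function(x, ...) {
  data.frame(arm = x$arm, day = x$days, size = x$sizes, sd = x$sd)
}

#' Closed-form logistic growth curve
#'
#' @param t times (day).
#' @param T0 size at `t0` (million cells).
#' @param g growth rate (1/day).
#' @param K carrying capacity (million cells).
#' @param t0 reference time (day).
#' @return sizes at `t` (million cells).
#' @export
logistic_solution <- function(t, T0, g, K, t0 = 0) {
  e <- exp(pmin(g * (t - t0), 700))
  K * T0 * e / (K + T0 * (e - 1))
}

# weighted SSE on log sizes; the loss used by every calibration stage
log_sse <- function(pred, obs, w = 1) {
  if (any(pred <= 0) || any(!is.finite(pred))) return(1e12)
  sum(w * (log(pred) - log(pmax(obs, 1e-12)))^2)
}

# Multi-start Nelder-Mead on box-bounded log-parameters.  Parameters are
# searched as log(p) = log(init) + box * tanh(z): a smooth, unconstrained
# reparameterization confined to +/- box log-units around the start, which
# keeps noisy fits from escaping along quasi-degenerate directions.  A
# weakly-informative quadratic penalty on the log-parameters (MAP with a
# broad log-normal prior centred on the start) regularizes directions the
# data barely constrain; prior_weight = 0.05 corresponds to a prior SD of
# about 3 log-units per parameter at the typical noise level.  An
# accepted-improvement trace is recorded (used to verify monotone objective
# decrease).
multi_start_fit <- function(obj, init, n_starts = 10, seed = 101,
                            reltol = 1e-10, maxit = 1500, box = 1.5,
                            prior_weight = 0.05) {
  trace_env <- new.env(parent = emptyenv())
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  lp0 <- log(init)
  to_par <- function(z) exp(lp0 + box * tanh(z))
  wrapped <- function(z) {
    v <- obj(to_par(z)) + prior_weight * sum((box * tanh(z))^2)
    if (is.finite(v) && v < trace_env$best) {
      trace_env$best <- v
      trace_env$trace <- c(trace_env$trace, v)
    }
    v
  }
  z0 <- numeric(length(lp0))
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1) z0 else rnorm(length(z0), 0, 0.6)
  }))
  run_one <- function(s) {
    if (length(z0) == 1L)
      return(optim(s, wrapped, method = "Brent", lower = -6, upper = 6))
    fit <- optim(s, wrapped, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = maxit))
    # restart polish: Nelder-Mead converges prematurely in >2 dimensions;
    # re-seeding a fresh simplex at the optimum recovers the last digits
    for (r in 1:8) {
      nxt <- optim(fit$par, wrapped, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = maxit))
      improved <- nxt$value < fit$value - 1e-10 * max(1, abs(fit$value))
      fit <- nxt
      if (!improved) break
    }
    fit
  }
  best <- NULL
  for (s in starts) {
    fit <- run_one(s)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(par = setNames(to_par(best$par), names(init)), value = best$value,
       converged = best$convergence == 0, trace = trace_env$trace)
}

sim_arm <- function(params, ds, dt, extra_days = 0) {
  pr <- ds$protocol
  tr <- simulate_model(params, pr$regimens,
                       system_state(params, pr$initial_cells),
                       t0 = pr$start_day,
                       horizon = max(ds$days) - pr$start_day + extra_days,
                       dt = dt)
  total_cells_at(tr, ds$days)
}

arm_has_drug <- function(ds, drug) {
  any(vapply(ds$protocol$regimens, function(r)
    r$drug == drug && r$dose > 0 && r$n_doses > 0, logical(1)))
}

#' Stage 1: fit logistic growth to the control arm
#'
#' Weighted least squares of the closed-form logistic solution on log tumor
#' size (proportional measurement error), from the known burden at therapy
#' start.
#'
#' @param control `tgi_dataset` for the vehicle arm (at least 4 points).
#' @param init named starting values `growth_rate`, `carrying_capacity`
#'   (defaults: schema values).
#' @param n_starts,seed multi-start settings.
#' @return list: `par` (named estimates), `value` (residual norm),
#'   `converged`, `trace` (accepted objective values).
#' @export
fit_growth <- function(control, init = NULL, n_starts = 10, seed = 101) {
  if (length(control$days) < 4)
    stop("growth fit unidentifiable: need at least 4 control points")
  if (is.null(init)) {
    d <- schema_defaults("parameters")
    init <- c(growth_rate = d$growth_rate,
              carrying_capacity = d$carrying_capacity)
  }
  T0 <- control$protocol$initial_cells
  t0 <- control$protocol$start_day
  obj <- function(p)
    log_sse(logistic_solution(control$days, T0, p[1], p[2], t0),
            control$sizes)
  # the two-parameter logistic stage is well identified; no prior needed
  multi_start_fit(obj, init, n_starts, seed, prior_weight = 0)
}

#' Stage 2: fit the ABT-737 death response
#'
#' Fits the maximal Bax-driven death rate `death_max` to the ABT-737
#' single-agent arm by full model simulation, with the growth parameters
#' frozen at the stage-1 estimates.  The response shape constants
#' (`death_bax_half`, `death_hill`) are held at known values by default: a
#' single-dose arm cannot identify them separately from `death_max` (set
#' `fit_shape = TRUE` to fit `death_bax_half` as well, e.g. on
#' dose-ranging data).
#'
#' @param abt_arm `tgi_dataset` for the ABT-737 arm.
#' @param params `xeno_params` carrying the frozen stage-1 values.
#' @param dt solver step for objective evaluations.
#' @param fit_shape also fit `death_bax_half`.
#' @inheritParams fit_growth
#' @return as [fit_growth()], plus `identifiable = FALSE` (with a warning)
#'   when the arm carries no ABT-737 dose.
#' @export
fit_abt_params <- function(abt_arm, params, dt = 0.02, init = NULL,
                           n_starts = 6, seed = 102, fit_shape = FALSE) {
  if (!arm_has_drug(abt_arm, "abt737")) {
    warning("arm has no ABT-737 dose: death parameters unidentifiable")
    return(list(par = c(death_max = params$death_max,
                        death_bax_half = params$death_bax_half),
                value = NA_real_, converged = FALSE, identifiable = FALSE,
                trace = numeric(0)))
  }
  if (is.null(init)) {
    init <- c(death_max = params$death_max)
    if (fit_shape)
      init <- c(init, death_bax_half = params$death_bax_half)
  }
  obj <- function(p) {
    pp <- params
    for (nm in names(init)) pp[[nm]] <- unname(p[match(nm, names(init))])
    log_sse(sim_arm(pp, abt_arm, dt), abt_arm$sizes)
  }
  out <- multi_start_fit(obj, init, n_starts, seed)
  if (!fit_shape)
    out$par <- c(out$par, death_bax_half = unname(params$death_bax_half))
  out$identifiable <- TRUE
  out
}

#' Stage 3: fit the carboplatin response and the synergy parameter
#'
#' Joint weighted least squares over the carboplatin-only and combination
#' arms for the maximal arrest rate `arrest_max`, the baseline
#' arrested-death coefficient `arrest_death_coef` and the Bax sensitivity
#' `bax_sensitivity` (lambda_s).  lambda_s is identified only by the
#' combination arm; if that arm is missing it is fixed at zero with a
#' warning.  Earlier-stage parameters stay frozen.
#'
#' @param carbo_arm,combo_arm `tgi_dataset` objects.
#' @param fit_c_half also fit the arrest half-effect concentration
#'   `arrest_carbo_half` (off by default: the shape constants of the arrest
#'   response are not identifiable from single-dose arms — the objective has
#'   an exact ridge trading them against `arrest_max` — and are treated as
#'   known biology).
#' @inheritParams fit_abt_params
#' @return as [fit_growth()].
#' @export
fit_carbo_params <- function(carbo_arm, combo_arm = NULL, params,
                             dt = 0.02, init = NULL, n_starts = 6,
                             seed = 103, fit_c_half = FALSE) {
  if (!arm_has_drug(carbo_arm, "carboplatin"))
    stop("carbo_arm carries no carboplatin dose")
  with_combo <- !is.null(combo_arm)
  if (!with_combo)
    warning("combination arm missing: lambda_s fixed at 0")
  if (is.null(init)) {
    init <- c(arrest_max = params$arrest_max,
              arrest_death_coef = params$arrest_death_coef)
    if (fit_c_half)
      init <- c(init, arrest_carbo_half = params$arrest_carbo_half)
    if (with_combo)
      init <- c(init, bax_sensitivity = max(params$bax_sensitivity, 1e-4))
  }
  obj <- function(p) {
    pp <- params
    for (nm in names(init)) pp[[nm]] <- unname(p[match(nm, names(init))])
    if (!with_combo) pp$bax_sensitivity <- 0
    v <- log_sse(sim_arm(pp, carbo_arm, dt), carbo_arm$sizes)
    if (with_combo)
      v <- v + log_sse(sim_arm(pp, combo_arm, dt), combo_arm$sizes)
    v
  }
  out <- multi_start_fit(obj, init, n_starts, seed)
  if (!fit_c_half)
    out$par <- c(out$par,
                 arrest_carbo_half = unname(params$arrest_carbo_half))
  if (!with_combo) out$par <- c(out$par, bax_sensitivity = 0)
  out
}

#' Full staged calibration pipeline
#'
#' Replicates the staged fitting order: (1) logistic growth on the control
#' arm; (2) ABT-737 death response on the ABT arm with growth frozen;
#' (3) carboplatin arrest/death and lambda_s on the carboplatin and
#' combination arms with stages 1-2 frozen.
#'
#' @param study `xeno_study` (or named list of `tgi_dataset`s with arms
#'   `control`, `abt_only`, `carbo_only`, `combo`).
#' @param params starting `xeno_params` (non-fitted fields are kept).
#' @param dt solver step for objective evaluations.
#' @param n_starts multi-starts per stage.
#' @param seed base RNG seed for the multi-starts.
#' @return list: `params` (calibrated `xeno_params`), `stages` (per-stage
#'   fit diagnostics).
#' @export
fit_study <- function(study, params = model_params(), dt = 0.02,
                      n_starts = 6, seed = 100) {
  s1 <- fit_growth(study$control, n_starts = n_starts, seed = seed + 1)
  params$growth_rate <- unname(s1$par["growth_rate"])
  params$carrying_capacity <- unname(s1$par["carrying_capacity"])
  s2 <- fit_abt_params(study$abt_only, params, dt = dt,
                       n_starts = n_starts, seed = seed + 2)
  params$death_max <- unname(s2$par["death_max"])
  params$death_bax_half <- unname(s2$par["death_bax_half"])
  s3 <- fit_carbo_params(study$carbo_only, study$combo, params, dt = dt,
                         n_starts = n_starts, seed = seed + 3)
  params$arrest_max <- unname(s3$par["arrest_max"])
  params$arrest_carbo_half <- unname(s3$par["arrest_carbo_half"])
  params$arrest_death_coef <- unname(s3$par["arrest_death_coef"])
  params$bax_sensitivity <- unname(s3$par["bax_sensitivity"])
  # sanity contract: untreated net growth must stay positive at baseline
  if (params$growth_rate <= proliferating_death_rate(params$bax_baseline,
                                                     params))
    warning("calibration rejected consistency check: baseline death ",
            "exceeds net growth")
  list(params = params, stages = list(growth = s1, abt = s2, carbo = s3))
}

#' Read a study CSV written by [write_study_csv()]
#'
#' @param path CSV with columns `arm`, `day`, `size`, `sd`.
#' @param cfg resolved config supplying the protocol for each arm.
#' @return named list of `tgi_dataset` objects.
#' @export
read_study_csv <- function(path, cfg = resolve_config()) {
  df <- read.csv(path)
  pr <- cfg$protocol
  end_day <- pr$start_day + 7 * pr$treatment_weeks
  regs <- list(
    control = list(),
    abt_only = protocol_regimens(cfg, carbo_dose = 0, end_day = end_day),
    carbo_only = protocol_regimens(cfg, abt_dose = 0, end_day = end_day),
    combo = protocol_regimens(cfg, end_day = end_day))
  arms <- lapply(split(df, df$arm), function(d) {
    d <- d[order(d$day), ]
    tgi_dataset(d$arm[1], d$day, d$size, d$sd,
                protocol = list(regimens = regs[[d$arm[1]]],
                                start_day = pr$start_day,
                                initial_cells = pr$initial_cells))
  })
  arms[intersect(names(regs), names(arms))]
}
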