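sim_treatment <- function(params, cfg, carbo_dose, abt_dose, ti_hours,
                          end_day, horizon = NULL, dt = 0.02,
                          initial = NULL) {
  pr <- cfg$protocol
  regs <- protocol_regimens(cfg, carbo_dose, abt_dose, ti_hours, end_day)
  if (is.null(initial)) initial <- system_state(params, pr$initial_cells)
  if (is.null(horizon)) horizon <- end_day - pr$start_day
  simulate_model(params, regs, initial, t0 = pr$start_day,
                 horizon = horizon, dt = dt)
}

#' Tumor growth inhibition achieved by a dose pair
#'
#' Simulates treated and control tumors over a fixed treatment course and
#' returns the percent inhibition at its end.
#'
#' @param params `xeno_params`.
#' @param cfg resolved config (protocol section is used).
#' @param carbo_dose weekly carboplatin dose (mg/kg).
#' @param abt_dose daily ABT-737 dose (mg/kg).
#' @param ti_hours carboplatin infusion duration (h; 0 = bolus).
#' @param weeks treatment length (week).
#' @param dt solver step (day).
#' @param control optional pre-computed control trajectory (reused across
#'   calls for speed).
#' @return percent TGI at the end of treatment.
#' @export
tgi_at_doses <- function(params, cfg = resolve_config(), carbo_dose,
                         abt_dose, ti_hours = 0, weeks = 4, dt = 0.02,
                         control = NULL) {
  end_day <- cfg$protocol$start_day + 7 * weeks
  if (is.null(control))
    control <- sim_treatment(params, cfg, 0, 0, 0, end_day, dt = dt)
  treated <- sim_treatment(params, cfg, carbo_dose, abt_dose, ti_hours,
                           end_day, dt = dt)
  tumor_growth_inhibition(treated, control, end_day)
}

#' Single-agent dose achieving a target growth inhibition
#'
#' Bisection on dose until the end-of-treatment TGI is within `tol`
#' percentage points of the target; monotonicity of TGI in dose is asserted
#' during the search.
#'
#' @param drug `"carboplatin"` or `"abt737"`.
#' @param target_tgi percent inhibition to achieve.
#' @param params,cfg,weeks,dt see [tgi_at_doses()].
#' @param ti_hours infusion duration for carboplatin doses.
#' @param bracket dose search bracket (mg/kg).
#' @param tol tolerance (percentage points).
#' @return list: `dose` (mg/kg), `tgi` (achieved percent), `evals`.
#' @export
single_agent_dose <- function(drug = c("carboplatin", "abt737"),
                              target_tgi, params, cfg = resolve_config(),
                              weeks = 4, ti_hours = 0,
                              bracket = c(0, 2000), tol = 0.1, dt = 0.02) {
  drug <- match.arg(drug)
  if (target_tgi <= 0) return(list(dose = 0, tgi = 0, evals = 0))
  end_day <- cfg$protocol$start_day + 7 * weeks
  control <- sim_treatment(params, cfg, 0, 0, 0, end_day, dt = dt)
  f <- function(d) {
    if (drug == "carboplatin")
      tgi_at_doses(params, cfg, d, 0, ti_hours, weeks, dt, control)
    else
      tgi_at_doses(params, cfg, 0, d, 0, weeks, dt, control)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- if (lo == 0) 0 else f(lo)
  f_hi <- f(hi)
  evals <- 2L
  if (f_hi < target_tgi)
    stop(sprintf(
      "target TGI %.1f%% unreachable for %s in [%g, %g] mg/kg (TGI at ",
      target_tgi, drug, bracket[1], bracket[2]),
      sprintf("max dose: %.2f%%)", f_hi))
  last <- f_lo
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- f(mid); evals <- evals + 1L
    if (abs(fm - target_tgi) < tol || (hi - lo) < 1e-6) {
      return(list(dose = mid, tgi = fm, evals = evals))
    }
    if (fm >= target_tgi) { hi <- mid; f_hi <- fm }
    else {
      if (fm < f_lo - 1e-6)
        stop("TGI is not monotone in dose during the bisection")
      lo <- mid; f_lo <- fm
    }
  }
  list(dose = (lo + hi) / 2, tgi = f((lo + hi) / 2), evals = evals + 1L)
}

#' Iso-effect curve (isobole) of the drug combination
#'
#' For each ABT-737 dose on a grid between 0 and its single-agent
#' iso-effective dose, solves for the weekly carboplatin dose that meets
#' the TGI constraint, and reports the combination index
#' `CI = D_c / D_c_single + D_a / D_a_single`.  Both single-agent endpoints
#' have `CI = 1` by construction; interior `CI < 1` indicates synergy.
#'
#' @inheritParams single_agent_dose
#' @param n_points grid points along the ABT-737 axis (including both
#'   endpoints).
#' @return data.frame of class `xeno_isobole`: `D_a`, `D_c`, `CI`,
#'   `feasible`; attributes `D_a_single`, `D_c_single`, `target_tgi`.
#' @export
isobole <- function(target_tgi = 67, params, cfg = resolve_config(),
                    weeks = 4, ti_hours = 0, n_points = 7,
                    bracket = c(0, 2000), tol = 0.1, dt = 0.02) {
  sa_c <- single_agent_dose("carboplatin", target_tgi, params, cfg, weeks,
                            ti_hours, bracket, tol, dt)
  sa_a <- single_agent_dose("abt737", target_tgi, params, cfg, weeks,
                            0, bracket, tol, dt)
  end_day <- cfg$protocol$start_day + 7 * weeks
  control <- sim_treatment(params, cfg, 0, 0, 0, end_day, dt = dt)
  da_grid <- seq(0, sa_a$dose, length.out = n_points)
  solve_dc <- function(da) {
    if (da <= 0) return(sa_c$dose)
    g <- function(dc) tgi_at_doses(params, cfg, dc, da, ti_hours, weeks,
                                   dt, control) - target_tgi
    if (g(0) >= -tol) return(0)
    lo <- 0; hi <- sa_c$dose
    if (g(hi) < 0) return(NA_real_)
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      gm <- g(mid)
      if (abs(gm) < tol || hi - lo < 1e-6) return(mid)
      if (gm > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  dc <- vapply(da_grid, solve_dc, numeric(1))
  dc[length(dc)] <- 0  # full single-agent ABT endpoint
  out <- data.frame(D_a = da_grid, D_c = dc,
                    CI = dc / sa_c$dose + da_grid / sa_a$dose,
                    feasible = !is.na(dc))
  structure(out, D_a_single = sa_a$dose, D_c_single = sa_c$dose,
            target_tgi = target_tgi,
            class = c("xeno_isobole", "data.frame"))
}

#' Minimize the combination index along an isobole
#'
#' Grid minimum over the feasible isobole points; exact ties are broken
#' toward the smallest ABT-737 dose.  An optional golden-section refinement
#' re-solves the TGI constraint between the neighbours of the grid minimum.
#'
#' @param iso `xeno_isobole` from [isobole()].
#' @param refine optional closure `function(D_a) -> D_c` re-solving the
#'   constraint (golden-section refinement is skipped when `NULL`).
#' @return list: `D_c`, `D_a` (mg/kg), `CI`.
#' @export
minimize_ci <- function(iso, refine = NULL) {
  feas <- iso[iso$feasible, ]
  if (nrow(feas) < 3)
    stop("need at least 3 feasible isobole points")
  i <- which(feas$CI <= min(feas$CI) + 1e-12)[1]  # tie-break: smallest D_a
  best <- feas[i, ]
  if (!is.null(refine)) {
    lo <- feas$D_a[max(i - 1, 1)]; hi <- feas$D_a[min(i + 1, nrow(feas))]
    Dcs <- attr(iso, "D_c_single"); Das <- attr(iso, "D_a_single")
    ci_of <- function(da) {
      dc <- refine(da)
      if (is.na(dc)) Inf else dc / Dcs + da / Das
    }
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- ci_of(x1); f2 <- ci_of(x2)
    for (k in 1:25) {
      if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- ci_of(x1)
      } else { a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- ci_of(x2) }
    }
    da <- if (f1 <= f2) x1 else x2
    dc <- refine(da)
    if (!is.na(dc) && dc / Dcs + da / Das < best$CI)
      best <- data.frame(D_a = da, D_c = dc,
                         CI = dc / Dcs + da / Das, feasible = TRUE)
  }
  list(D_c = best$D_c, D_a = best$D_a, CI = best$CI)
}

#' Simulate to the steady state of weekly-averaged burden
#'
#' Extends the simulation in chunks until the relative change of the weekly
#' average drops below the steady-state criterion, the average falls below
#' the minimal-residual-disease threshold, or the cap is reached
#' (non-convergence is reported, never silently truncated).
#'
#' @param params `xeno_params`.
#' @param regimens list of [regimen()] (doses repeat up to the cap).
#' @param initial starting `xeno_state`.
#' @param t0 start time (day).
#' @param dt solver step (day).
#' @param chunk_days simulation chunk length.
#' @param max_days cap (default 20 simulated years).
#' @param mrd_threshold million-cell threshold for minimal residual
#'   disease.
#' @return list: `value` (steady-state weekly average), `converged`,
#'   `t_m` (days from `t0` to minimal residual disease, `NA` if not
#'   reached), `t_end`, `weekly` (data.frame of weekly averages).
#' @export
simulate_to_steady_state <- function(params, regimens, initial, t0,
                                     dt = 0.02, chunk_days = 70,
                                     max_days = 7300,
                                     mrd_threshold = 1e-6) {
  state <- initial
  t <- t0
  weekly <- NULL
  repeat {
    h <- min(chunk_days, max_days - (t - t0))
    tr <- simulate_model(params, regimens, state, t0 = t, horizon = h,
                         dt = dt)
    state <- attr(tr, "final_state")
    wa <- windowed_average(tr, 7, anchor = t)
    weekly <- rbind(weekly, wa)
    t <- t + h
    n <- nrow(weekly)
    if (n >= 2) {
      rel <- abs(weekly$avg_total[n] - weekly$avg_total[n - 1]) /
        max(weekly$avg_total[n - 1], .Machine$double.eps)
      below <- weekly$avg_total[n] < mrd_threshold
      if (below || rel < 1e-5 || (t - t0) >= max_days) {
        t_m <- if (any(weekly$avg_total < mrd_threshold))
          weekly$t_end[which(weekly$avg_total < mrd_threshold)[1]] - t0
        else NA_real_
        return(list(value = weekly$avg_total[n],
                    converged = below || rel < 1e-5, t_m = t_m,
                    t_end = t, weekly = weekly))
      }
    }
  }
}

#' Scan carboplatin infusion duration
#'
#' One long-horizon combination-therapy simulation per infusion duration
#' (30 mg/kg weekly carboplatin + 100 mg/kg daily ABT-737 unless
#' overridden), reporting the steady-state weekly-averaged burden and the
#' time to minimal residual disease.
#'
#' @param ti_hours infusion durations to scan (h, within 0 to 120).
#' @param params,cfg model and protocol.
#' @param carbo_dose,abt_dose doses (mg/kg).
#' @param dt solver step.
#' @param max_days horizon cap per run.
#' @return data.frame: `ti_hours`, `ss_avg`, `converged`, `t_m`.
#' @export
scan_infusion_time <- function(ti_hours, params, cfg = resolve_config(),
                               carbo_dose = 30, abt_dose = 100, dt = 0.02,
                               max_days = 7300) {
  if (any(ti_hours < 0 | ti_hours > 120))
    stop("infusion durations must lie in [0, 120] hours")
  pr <- cfg$protocol
  rows <- lapply(ti_hours, function(ti) {
    regs <- protocol_regimens(cfg, carbo_dose, abt_dose, ti,
                              end_day = pr$start_day + max_days + 14)
    res <- tryCatch(
      simulate_to_steady_state(params, regs,
                               system_state(params, pr$initial_cells),
                               t0 = pr$start_day, dt = dt,
                               max_days = max_days),
      error = function(e) e)
    if (inherits(res, "error"))
      data.frame(ti_hours = ti, ss_avg = NA_real_, converged = FALSE,
                 t_m = NA_real_, error = conditionMessage(res))
    else
      data.frame(ti_hours = ti, ss_avg = res$value,
                 converged = res$converged, t_m = res$t_m, error = "")
  })
  do.call(rbind, rows)
}

#' Scan the arrested-cell Bax sensitivity
#'
#' Nested scan: for each lambda_s, the minimum over infusion durations of
#' the time to minimal residual disease, and the minimizing duration
#' (exact ties broken toward the smallest duration).
#'
#' @param lambda_s values of the Bax sensitivity to scan.
#' @param ti_hours infusion durations scanned inside each row.
#' @inheritParams scan_infusion_time
#' @return data.frame: `lambda_s`, `min_t_m`, `argmin_ti_hours`.
#' @export
scan_bax_sensitivity <- function(lambda_s, ti_hours, params,
                                 cfg = resolve_config(), carbo_dose = 30,
                                 abt_dose = 100, dt = 0.02,
                                 max_days = 7300) {
  rows <- lapply(lambda_s, function(ls) {
    pp <- params
    pp$bax_sensitivity <- ls
    tab <- scan_infusion_time(ti_hours, pp, cfg, carbo_dose, abt_dose,
                              dt, max_days)
    if (all(is.na(tab$t_m)))
      data.frame(lambda_s = ls, min_t_m = NA_real_,
                 argmin_ti_hours = NA_real_)
    else {
      i <- which(tab$t_m <= min(tab$t_m, na.rm = TRUE) + 1e-12)[1]
      data.frame(lambda_s = ls, min_t_m = tab$t_m[i],
                 argmin_ti_hours = tab$ti_hours[i])
    }
  })
  do.call(rbind, rows)
}

#' Simulate a drug-resistance scenario
#'
#' Treatment of a late-stage tumor (starting at carrying capacity).  In the
#' acquired scenario resistant cells arise only by mutation of cells
#' recovering from carboplatin arrest (probability `p_mut` per recovering
#' cell, no resistant cells initially); in the intrinsic scenario a small
#' resistant fraction pre-exists and `p_mut = 0`.  Resistant cells are
#' never arrested by carboplatin but respond to ABT-737 exactly like
#' sensitive cells.
#'
#' @param scenario `"acquired"` or `"intrinsic"`.
#' @param params `xeno_params`.
#' @param cfg resolved config; `scenario$p_mut` is required in acquired
#'   mode (no silent default), `scenario$intrinsic_fraction` defaults to
#'   1/60000.
#' @param carbo_dose,abt_dose,ti_hours regimen overrides.
#' @param horizon therapy length (day; default one year).
#' @param dt solver step.
#' @param allow_both permit `p_mut > 0` together with a pre-existing
#'   resistant fraction (the scenarios are normally exclusive).
#' @return `xeno_trajectory` (columns `N`, `N_r`, `M_tot`, `total`) with an
#'   extra attribute `weekly`: 7-day averages of sensitive, resistant and
#'   total cells.
#' @export
simulate_resistance <- function(scenario = c("acquired", "intrinsic"),
                                params, cfg = resolve_config(),
                                carbo_dose = 30, abt_dose = 100,
                                ti_hours = 0, horizon = NULL, dt = 0.02,
                                allow_both = FALSE) {
  scenario <- match.arg(scenario)
  sc <- cfg$scenario
  if (is.null(horizon)) horizon <- sc$resistance_horizon_days
  pr <- cfg$protocol
  if (scenario == "acquired") {
    if (is.null(sc$p_mut))
      stop("scenario field 'p_mut' is required for the acquired mode")
    params$p_mut <- sc$p_mut
    frac <- 0
  } else {
    frac <- sc$intrinsic_fraction
    if (params$p_mut > 0 && frac > 0 && !allow_both)
      stop("p_mut > 0 and a pre-existing resistant fraction are mutually ",
           "exclusive (set allow_both = TRUE to combine them)")
    if (!allow_both) params$p_mut <- 0
  }
  init <- system_state(params, params$carrying_capacity, frac)
  regs <- protocol_regimens(cfg, carbo_dose, abt_dose, ti_hours,
                            end_day = pr$start_day + horizon)
  tr <- simulate_model(params, regs, init, t0 = pr$start_day,
                       horizon = horizon, dt = dt)
  if (horizon >= 7) {
    wa <- windowed_average(tr, 7, anchor = pr$start_day)
    for (v in c("N", "N_r")) {
      wa[[paste0("avg_", v)]] <- vapply(wa$t_end, function(e) {
        sel <- tr$time >= e - 7 - 1e-9 & tr$time <= e + 1e-9
        trapz(tr$time[sel], tr[[v]][sel]) / 7
      }, numeric(1))
    }
    attr(tr, "weekly") <- wa
  }
  tr
}

#' One-at-a-time parameter sensitivity
#'
#' Perturbs selected parameters by a relative amount and reports the
#' percent change of a scalar model output.
#'
#' @param params `xeno_params`.
#' @param fields parameter names to perturb.
#' @param metric function `xeno_params -> numeric(1)`.
#' @param rel_delta relative perturbation (default +10%).
#' @return data.frame: `field`, `baseline`, `perturbed`,
#'   `pct_change`.
#' @export
sensitivity_scan <- function(params, fields, metric, rel_delta = 0.1) {
  base <- metric(params)
  rows <- lapply(fields, function(f) {
    pp <- params
    pp[[f]] <- pp[[f]] * (1 + rel_delta)
    v <- metric(pp)
    data.frame(field = f, baseline = base, perturbed = v,
               pct_change = 100 * (v - base) / base)
  })
  do.call(rbind, rows)
}
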