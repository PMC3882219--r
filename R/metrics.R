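first_carbo_dose <- function(traj) {
  regs <- attr(traj, "regimens")
  tt <- unlist(lapply(regs, function(r)
    if (r$drug == "carboplatin" && r$n_doses > 0) r$start_day else NULL))
  if (length(tt)) min(tt) else NULL
}

#' Windowed average of total cell number
#'
#' Trailing means over consecutive non-overlapping windows, anchored at the
#' carboplatin dose times (the dosing period sets the averaging window in
#' all the response metrics); falls back to the trajectory start when the
#' regimen carries no carboplatin.  Values are trapezoid time-averages, so
#' a linear ramp averages to its window-midpoint value.
#'
#' @param traj `xeno_trajectory`.
#' @param window window length (day), default 7.
#' @param anchor window start (day); default first carboplatin dose, else
#'   trajectory start.
#' @return data.frame with `t_end` (window end, day) and `avg_total`
#'   (million cells).
#' @export
windowed_average <- function(traj, window = 7, anchor = NULL) {
  t0 <- attr(traj, "t0"); t1 <- attr(traj, "t_end")
  if (is.null(anchor)) anchor <- first_carbo_dose(traj)
  if (is.null(anchor)) anchor <- t0
  anchor <- max(anchor, t0)
  if (t1 - anchor < window - 1e-9)
    stop("trajectory span after the anchor is shorter than the window")
  n_win <- floor((t1 - anchor) / window + 1e-9)
  ends <- anchor + window * seq_len(n_win)
  avg <- vapply(ends, function(e) {
    sel <- traj$time >= e - window - 1e-9 & traj$time <= e + 1e-9
    trapz(traj$time[sel], traj$total[sel]) / window
  }, numeric(1))
  data.frame(t_end = ends, avg_total = avg)
}

#' Steady-state weekly average
#'
#' Scans successive weekly averages and returns the first whose relative
#' change from the previous week is below `tol` (the convergence criterion
#' is a relative change under 0.001% between successive weeks).
#'
#' @param traj `xeno_trajectory`.
#' @param window averaging window (day).
#' @param tol relative-change threshold (default `1e-5`, i.e. 0.001%).
#' @param anchor see [windowed_average()].
#' @return list: `value` (million cells), `converged` (flag), `t_end`
#'   (end of the converged window, or the last window if not converged).
#' @export
steady_state_average <- function(traj, window = 7, tol = 1e-5,
                                 anchor = NULL) {
  wa <- windowed_average(traj, window, anchor)
  if (nrow(wa) < 2) stop("trajectory must contain at least two windows")
  rel <- abs(diff(wa$avg_total)) /
    pmax(abs(wa$avg_total[-nrow(wa)]), .Machine$double.eps)
  hit <- which(rel < tol)
  if (length(hit)) {
    i <- hit[1] + 1L
    list(value = wa$avg_total[i], converged = TRUE, t_end = wa$t_end[i])
  } else {
    list(value = wa$avg_total[nrow(wa)], converged = FALSE,
         t_end = wa$t_end[nrow(wa)])
  }
}

#' Time to minimal residual disease
#'
#' First time, measured from therapy start, at which the 7-day trailing
#' average of total cell number drops below one cell (`1e-6` million).
#' The threshold is applied to the averaged series, not the raw
#' oscillating one.
#'
#' @param traj `xeno_trajectory`.
#' @param start therapy start (day); default first carboplatin dose, else
#'   trajectory start.
#' @param window averaging window (day).
#' @param threshold million-cell threshold (default one cell).
#' @return days from `start` to crossing, or `NA` if never reached.
#' @export
time_to_minimal_residual <- function(traj, start = NULL, window = 7,
                                     threshold = 1e-6) {
  t0 <- attr(traj, "t0"); t1 <- attr(traj, "t_end")
  if (is.null(start)) start <- first_carbo_dose(traj)
  if (is.null(start)) start <- t0
  tt <- traj$time
  # rolling trailing mean via the cumulative integral
  cum <- c(0, cumsum((traj$total[-1] + traj$total[-length(tt)]) / 2 *
                       diff(tt)))
  lower <- approx(tt, cum, xout = pmax(tt - window, t0), rule = 2)$y
  width <- pmin(tt - t0, window)
  ok <- width >= window - 1e-9 & tt >= start + window - 1e-9
  avg <- (cum - lower) / pmax(width, .Machine$double.eps)
  idx <- which(ok & avg < threshold)
  if (!length(idx)) return(NA_real_)
  tt[idx[1]] - start
}

#' Tumor growth inhibition at a time point
#'
#' `TGI(t) = 100 (1 - T_treated(t) / T_control(t))` percent: 0 when the
#' arms coincide, 100 when the treated tumor is eradicated.  Invariant to a
#' common rescaling of both trajectories, so cell number and tumor volume
#' give the same value.
#'
#' @param treated,control `xeno_trajectory` objects defined at `t`.
#' @param t evaluation time (day).
#' @return percent inhibition.
#' @export
tumor_growth_inhibition <- function(treated, control, t) {
  Tc <- total_cells_at(control, t)
  if (any(Tc <= 0)) stop("control size is zero at t")
  100 * (1 - total_cells_at(treated, t) / Tc)
}
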