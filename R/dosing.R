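#' Define a periodic dosing regimen
#'
#' @param drug `"carboplatin"` or `"abt737"`.
#' @param dose dose per administration (mg/kg).
#' @param period_days dosing period (default 7 for carboplatin, 1 for
#'   ABT-737, matching weekly/daily schedules).
#' @param ti_hours infusion duration in hours; 0 means an instantaneous
#'   bolus into the peritoneal compartment.
#' @param start_day day of first dose (post-transplant).
#' @param n_doses number of doses; alternatively give `end_day` (last day by
#'   which dosing stops; doses strictly before it are given).
#' @param end_day optional end of treatment (days post-transplant).
#' @return object of class `xeno_regimen`.
#' @examples
#' regimen("carboplatin", 30, ti_hours = 8, n_doses = 4)
#' @export
regimen <- function(drug = c("carboplatin", "abt737"), dose,
                    period_days = NULL, ti_hours = 0, start_day = 19,
                    n_doses = NULL, end_day = NULL) {
  drug <- match.arg(drug)
  if (is.null(period_days))
    period_days <- if (drug == "carboplatin") 7 else 1
  if (dose < 0) stop("dose must be non-negative")
  if (period_days <= 0) stop("period must be positive")
  if (ti_hours < 0 || ti_hours >= period_days * 24)
    stop("infusion duration must satisfy 0 <= T_i < period (overlapping ",
         "infusion windows)")
  if (is.null(n_doses)) {
    if (is.null(end_day)) stop("give either n_doses or end_day")
    n_doses <- max(0L, ceiling((end_day - start_day) / period_days))
  }
  structure(list(drug = drug, dose = dose, period_days = period_days,
                 ti_hours = ti_hours, start_day = start_day,
                 n_doses = as.integer(n_doses)),
            class = "xeno_regimen")
}

#' @export
print.xeno_regimen <- function(x, ...) {
  cat(sprintf("<regimen> %s %g mg/kg every %g d x %d, %s, from day %g\n",
              x$drug, x$dose, x$period_days, x$n_doses,
              if (x$ti_hours > 0) sprintf("%g h infusion", x$ti_hours)
              else "bolus", x$start_day))
  invisible(x)
}

#' Instantaneous drug input rate of a regimen
#'
#' Piecewise-constant infusion rate into the peritoneal compartment.  For a
#' bolus regimen (`ti_hours = 0`) the rate is zero everywhere and the dose
#' enters as a state jump at the dose times (see [dose_times()]); the
#' integral of the rate over one period always equals one full dose amount.
#'
#' @param t time or vector of times (day).
#' @param reg `xeno_regimen`.
#' @param params `xeno_params`.
#' @return input rate (ug/day for carboplatin, nmol/day for ABT-737).
#' @export
input_rate <- function(t, reg, params) {
  if (any(t < 0)) stop("t must be non-negative")
  amt <- dose_to_input_amount(reg$dose, reg$drug, params)
  if (reg$ti_hours == 0 || reg$n_doses == 0) return(rep(0, length(t)))
  ti <- reg$ti_hours / 24
  rate <- amt / ti
  rel <- t - reg$start_day
  j <- floor(rel / reg$period_days)
  inwin <- rel >= 0 & j < reg$n_doses & (rel - j * reg$period_days) < ti
  ifelse(inwin, rate, 0)
}

#' Bolus dose times of a regimen
#'
#' @inheritParams input_rate
#' @return numeric vector of dose times (day); empty unless `ti_hours = 0`.
#' @export
dose_times <- function(reg) {
  if (reg$n_doses == 0) return(numeric(0))
  reg$start_day + reg$period_days * (seq_len(reg$n_doses) - 1)
}

# Build the compiled-core schedule representation for one drug from a list
# of regimens (bolus regimens expand to time/amount vectors; infusion
# regimens are passed analytically).
build_sched <- function(regimens, drug, params) {
  bt <- numeric(0); ba <- numeric(0)
  is_ <- numeric(0); ip <- numeric(0); iti <- numeric(0)
  ir <- numeric(0); inn <- numeric(0)
  for (reg in regimens) {
    if (reg$drug != drug || reg$dose == 0 || reg$n_doses == 0) next
    amt <- dose_to_input_amount(reg$dose, reg$drug, params)
    if (reg$ti_hours == 0) {
      tt <- dose_times(reg)
      bt <- c(bt, tt); ba <- c(ba, rep(amt, length(tt)))
    } else {
      ti <- reg$ti_hours / 24
      is_ <- c(is_, reg$start_day); ip <- c(ip, reg$period_days)
      iti <- c(iti, ti); ir <- c(ir, amt / ti); inn <- c(inn, reg$n_doses)
    }
  }
  o <- order(bt)
  list(bolus_times = bt[o], bolus_amounts = ba[o], inf_start = is_,
       inf_period = ip, inf_ti = iti, inf_rate = ir, inf_n = inn)
}

# default protocol regimens from a resolved config
protocol_regimens <- function(cfg, carbo_dose = NULL, abt_dose = NULL,
                              carbo_ti_hours = NULL, end_day = NULL) {
  pr <- cfg$protocol
  cd <- if (is.null(carbo_dose)) pr$carbo_dose else carbo_dose
  ad <- if (is.null(abt_dose)) pr$abt_dose else abt_dose
  ti <- if (is.null(carbo_ti_hours)) pr$carbo_ti_hours else carbo_ti_hours
  ed <- if (is.null(end_day)) pr$start_day + 7 * pr$treatment_weeks else
    end_day
  regs <- list()
  if (cd > 0)
    regs <- c(regs, list(regimen("carboplatin", cd, pr$carbo_period, ti,
                                 pr$start_day, end_day = ed)))
  if (ad > 0)
    regs <- c(regs, list(regimen("abt737", ad, pr$abt_period, 0,
                                 pr$start_day, end_day = ed)))
  regs
}
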