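#' Generate a synthetic four-arm xenograft study
#'
#' Emulates the source protocol: vehicle, 100 mg/kg ABT-737 daily,
#' 30 mg/kg carboplatin weekly, and the combination, with treatment
#' starting on day 19 post-transplant and tumors measured twice weekly for
#' four weeks (the untreated arm is followed for `control_extra_weeks`
#' beyond that, so the growth plateau is observed).  Each arm is simulated
#' at the supplied true parameters; per-mouse measurements apply
#' independent multiplicative log-normal noise with coefficient of
#' variation `noise_cv` (mean-one, so arm means are unbiased), and the
#' returned per-arm means and standard deviations are the calibration
#' currency.  Bit-reproducible for a given seed.
#'
#' @param true_params `xeno_params` used to generate the data.
#' @param cfg resolved configuration (see [resolve_config()]); supplies the
#'   protocol and defaults for the remaining arguments.
#' @param noise_cv proportional measurement noise per mouse.
#' @param n_mice_per_arm mice per arm.
#' @param seed RNG seed (required for reproducibility).
#' @param dt solver step used for the generating simulations.
#' @return object of class `xeno_study`: named list of [tgi_dataset()]
#'   objects (`control`, `abt_only`, `carbo_only`, `combo`) plus attributes
#'   `true_params`, `noise_cv`, `seed`.
#' @export
generate_study <- function(true_params, cfg = resolve_config(),
                           noise_cv = cfg$synthetic$noise_cv,
                           n_mice_per_arm = cfg$synthetic$n_mice_per_arm,
                           seed, dt = cfg$simulation$fit_dt) {
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (missing(seed)) stop("a seed is required")
  pr <- cfg$protocol
  days <- pr$start_day + pr$measurement_days_offset
  # the untreated arm is followed further so the growth plateau (carrying
  # capacity) is actually observed
  days_control <- c(days, max(days) + 7 * seq_len(pr$control_extra_weeks))
  end_day <- pr$start_day + 7 * pr$treatment_weeks
  arm_regs <- list(
    control = list(),
    abt_only = protocol_regimens(cfg, carbo_dose = 0, end_day = end_day),
    carbo_only = protocol_regimens(cfg, abt_dose = 0, end_day = end_day),
    combo = protocol_regimens(cfg, end_day = end_day))
  sdlog <- sqrt(log(1 + noise_cv^2))
  arms <- with_seed(seed, lapply(names(arm_regs), function(arm) {
    days <- if (arm == "control") days_control else days
    tr <- simulate_model(true_params, arm_regs[[arm]],
                         system_state(true_params, pr$initial_cells),
                         t0 = pr$start_day,
                         horizon = max(days) - pr$start_day, dt = dt)
    truth <- total_cells_at(tr, days)
    mice <- vapply(seq_len(n_mice_per_arm), function(m)
      truth * exp(rnorm(length(days), -sdlog^2 / 2, sdlog)),
      numeric(length(days)))
    mice <- matrix(mice, nrow = length(days))
    tgi_dataset(arm = arm, days = days,
                sizes = rowMeans(mice),
                sd = if (n_mice_per_arm > 1) apply(mice, 1, sd)
                     else rep(0, length(days)),
                protocol = list(regimens = arm_regs[[arm]],
                                start_day = pr$start_day,
                                initial_cells = pr$initial_cells),
                truth = truth)
  }))
  names(arms) <- names(arm_regs)
  structure(arms, true_params = true_params, noise_cv = noise_cv,
            n_mice_per_arm = n_mice_per_arm, seed = seed,
            class = "xeno_study")
}

#' @export
print.xeno_study <- function(x, ...) {
  cat("<xeno_study> arms:", paste(names(x), collapse = ", "),
      "| noise_cv =", attr(x, "noise_cv"),
      "| n/arm =", attr(x, "n_mice_per_arm"), "\n")
  invisible(x)
}

#' Write / read a study as the calibration CSV format
#'
#' Columns `arm`, `day`, `size`, `sd` (million cells).  Protocol metadata
#' is not serialized; supply it again on read.
#'
#' @param study `xeno_study` or list of [tgi_dataset()].
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_study_csv <- function(study, path) {
  df <- do.call(rbind, lapply(study, as.data.frame))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
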