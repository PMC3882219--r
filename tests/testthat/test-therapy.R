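test_that("single-agent dose search honours its contracts", {
  expect_equal(single_agent_dose("carboplatin", 0, default_p)$dose, 0)
  sa <- single_agent_dose("carboplatin", 50, default_p, default_cfg)
  expect_lt(abs(sa$tgi - 50), 0.1)
  # returned dose re-simulated hits the target
  expect_lt(abs(tgi_at_doses(default_p, default_cfg, sa$dose, 0) - 50), 0.1)
  # required dose is monotone in the target level
  doses <- vapply(c(20, 40, 60), function(tg)
    single_agent_dose("carboplatin", tg, default_p, default_cfg)$dose,
    numeric(1))
  expect_true(all(diff(doses) > 0))
  expect_error(single_agent_dose("carboplatin", 99.9, default_p,
                                 default_cfg, bracket = c(0, 1)),
               "unreachable")
})

test_that("minimize_ci recovers a constructed quadratic minimum", {
  da <- seq(0, 100, length.out = 21)
  ci <- 0.6 + (da - 37)^2 / 4000  # analytic minimum at D_a = 37
  iso <- structure(data.frame(D_a = da, D_c = 50 * (1 - da / 100),
                              CI = ci, feasible = TRUE),
                   D_a_single = 100, D_c_single = 50,
                   class = c("xeno_isobole", "data.frame"))
  opt <- minimize_ci(iso)
  expect_lt(abs(opt$D_a - 37), 5 + 1e-9)  # grid tolerance
  # constant CI ties break toward the smallest ABT-737 dose
  iso$CI <- rep(1, 21)
  expect_equal(minimize_ci(iso)$D_a, 0)
  expect_error(minimize_ci(iso[iso$D_a > 98, ]), "at least 3")
})

test_that("infusion-time scan distinguishes schedules and is deterministic", {
  tab <- scan_infusion_time(c(0, 8), default_p, default_cfg, dt = dt_fast,
                            max_days = 120)
  expect_equal(nrow(tab), 2)
  expect_false(isTRUE(all.equal(tab$ss_avg[1], tab$ss_avg[2])))
  tab2 <- scan_infusion_time(c(0, 8), default_p, default_cfg,
                             dt = dt_fast, max_days = 120)
  expect_identical(tab, tab2)
  expect_error(scan_infusion_time(c(-1, 8), default_p), "0, 120")
})

test_that("long-run burden is U-shaped in the infusion duration", {
  tab <- scan_infusion_time(c(0, 8, 16, 48, 120), default_p, default_cfg,
                            dt = dt_fast, max_days = 700)
  i <- which.min(tab$ss_avg)
  expect_true(i > 1 && i < nrow(tab))      # interior minimum
  expect_gt(tab$ss_avg[1] / tab$ss_avg[i], 10)   # decreases, then
  expect_gt(tab$ss_avg[nrow(tab)] / tab$ss_avg[i], 10)  # increases
})

test_that("minimal-residual time falls with the Bax sensitivity, then plateaus", {
  # nested scan at a curing infusion duration; NA (no cure) ranks as Inf
  tab <- scan_bax_sensitivity(c(0, 0.011, 0.05, 0.2, 0.8), ti_hours = 16,
                              params = default_p, cfg = default_cfg,
                              dt = dt_fast, max_days = 900)
  tm <- ifelse(is.na(tab$min_t_m), Inf, tab$min_t_m)
  expect_true(all(diff(tm) <= 0))
  expect_true(tm[1] >= max(tm))  # lambda_s = 0 is slowest
  expect_true(all(is.finite(tm[3:5])))
  # plateau at large sensitivity: arrested kill saturates
  expect_lt(abs(tm[5] / tm[4] - 1), 0.01)
})

test_that("resistance scenarios implement their gating rules", {
  cfg <- default_cfg
  cfg$scenario$p_mut <- 1e-6
  # acquired mode with no carboplatin: no arrest, no recovery, no mutants
  tr <- simulate_resistance("acquired", default_p, cfg, carbo_dose = 0,
                            abt_dose = 100, horizon = 60, dt = dt_fast)
  expect_true(all(tr$N_r == 0))
  # mutually exclusive scenario settings are rejected
  p2 <- default_p
  p2$p_mut <- 1e-6
  expect_error(simulate_resistance("intrinsic", p2, cfg, horizon = 10,
                                   dt = dt_fast), "exclusive")
  # missing p_mut is a named validation error
  cfg3 <- default_cfg
  cfg3$scenario$p_mut <- NULL
  expect_error(simulate_resistance("acquired", default_p, cfg3),
               "p_mut")
})

test_that("one-at-a-time sensitivity reports relative output changes", {
  met <- function(p) p$growth_rate * p$carrying_capacity
  out <- sensitivity_scan(default_p, c("growth_rate", "arrest_max"), met,
                          rel_delta = 0.1)
  expect_equal(out$pct_change, c(10, 0), tolerance = 1e-9)
})
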