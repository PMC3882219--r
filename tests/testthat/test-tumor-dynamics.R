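test_that("rate functions satisfy their contracts", {
  p <- default_p
  expect_equal(arrest_rate(0, p), 0)
  expect_equal(arrest_rate(p$arrest_carbo_half, p), p$arrest_max / 2)
  grid <- sort(with_seed(7, runif(40, 0, 50)))
  expect_true(all(diff(arrest_rate(grid, p)) >= 0))
  expect_lt(arrest_rate(1e6, p), p$arrest_max + 1e-12)
  expect_error(arrest_rate(-1, p), "non-negative")

  expect_equal(proliferating_death_rate(0, p), 0)
  expect_equal(proliferating_death_rate(p$bax_baseline, p), 0)
  expect_equal(proliferating_death_rate(p$bax_baseline + p$death_bax_half,
                                        p), p$death_max / 2)
  xg <- seq(0, 500, by = 10)
  expect_true(all(diff(proliferating_death_rate(xg, p)) >= 0))

  expect_equal(arrested_death_rate(0, 100, p), 0)
  p0 <- p; p0$bax_sensitivity <- 0
  expect_equal(arrested_death_rate(4, 10, p0), arrested_death_rate(4, 99, p0))
  p2 <- p; p2$bax_sensitivity <- 2 * p$bax_sensitivity
  excess1 <- arrested_death_rate(4, 50, p) - arrested_death_rate(4, 50, p0)
  excess2 <- arrested_death_rate(4, 50, p2) - arrested_death_rate(4, 50, p0)
  expect_equal(excess2, 2 * excess1)
})

test_that("population_step: logistic oracle, conservation, mutation split", {
  p <- default_p
  dt <- 0.01
  n_age <- round(p$arrest_duration / dt)
  st <- list(N = 50, Nr = 0, M = numeric(n_age), Carr = numeric(n_age))
  for (i in 1:500)
    st <- population_step(st, 0, 0, numeric(n_age), dt, p)
  expect_equal(st$N, logistic_solution(5, 50, p$growth_rate,
                                       p$carrying_capacity),
               tolerance = 1e-6)

  # arrest pulse returns after exactly psi with zero death, mass conserved
  pz <- p; pz$growth_rate <- 0
  st <- list(N = 10, Nr = 0, M = c(0, 0, 8, numeric(n_age - 3)),
             Carr = numeric(n_age))
  for (i in seq_len(n_age - 3)) {
    st <- population_step(st, 0, 0, numeric(n_age), dt, pz)
    expect_equal(st$N + st$Nr + sum(st$M), 18, tolerance = 1e-12)
  }
  expect_equal(sum(st$M), 8)            # pulse still arrested
  st <- population_step(st, 0, 0, numeric(n_age), dt, pz)
  expect_equal(st$N, 18)                # returned exactly at age psi
  expect_equal(sum(st$M), 0)

  # splitting rule
  pm <- pz; pm$p_mut <- 0.01
  st <- list(N = 0, Nr = 0, M = c(numeric(n_age - 1), 5),
             Carr = numeric(n_age))
  st <- population_step(st, 0, 0, numeric(n_age), dt, pm)
  expect_equal(st$N, 0.99 * 5)
  expect_equal(st$Nr, 0.01 * 5)

  expect_error(population_step(st, 0, 0, numeric(n_age), dt = 0.013,
                               pm), "age grid")
})

test_that("drug-free simulation matches the logistic closed form", {
  p <- default_p
  tr <- logistic_run(horizon = 28, dt = 0.005)
  exact <- logistic_solution(tr$time, 50, p$growth_rate,
                             p$carrying_capacity, 19)
  expect_lt(max(abs(tr$total / exact - 1)), 1e-6)
})

test_that("untreated tumor approaches carrying capacity monotonically", {
  p <- default_p
  tr <- logistic_run(T0 = 100, horizon = 150)
  expect_true(all(diff(tr$total) > -1e-9))
  expect_equal(tr$total[nrow(tr)], p$carrying_capacity, tolerance = 1e-3)
})

test_that("saturating carboplatin dose forces decline at alpha_max - g", {
  p <- default_p
  r <- regimen("carboplatin", 2000, n_doses = 1, start_day = 19)
  tr <- simulate_model(p, list(r), system_state(p, 50), t0 = 19,
                       horizon = 1, dt = 0.005, sample_dt = 0.005)
  # inside (0, psi) after the bolus no arrested cells have recovered yet
  # and C_t stays far above the half-effect, so alpha is close to its
  # maximum; allow 5% slack on the differential inequality
  n1 <- tr$N[tr$time == 19.2]
  n2 <- tr$N[tr$time == 19.8]
  expect_lt(n2 / n1, exp(-(0.95 * p$arrest_max - p$growth_rate) * 0.6))
})

test_that("weekly carboplatin induces 7-day-periodic oscillations", {
  p <- default_p
  r <- regimen("carboplatin", 30, n_doses = 30, start_day = 19)
  tr <- simulate_model(p, list(r), system_state(p, 50), t0 = 19,
                       horizon = 180, dt = dt_fast)
  late <- tr[tr$time >= 150 & tr$time <= 171, ]
  f <- function(t) approx(late$time, late$total, xout = t)$y
  tt <- seq(150, 164, by = 0.25)
  period_err <- max(abs(f(tt + 7) / f(tt) - 1))
  within_week <- max(f(tt)) / min(f(tt))
  expect_lt(period_err, 0.01)     # period-7 repetition after transients
  expect_gt(within_week, 1.02)    # genuine oscillation, not a constant
})

test_that("every state component stays non-negative under random regimens", {
  p <- default_p
  sets <- with_seed(11, lapply(1:5, function(i) {
    regs <- list()
    if (runif(1) < 0.8)
      regs <- c(regs, list(regimen("carboplatin", runif(1, 0, 300),
                                   period_days = sample(c(3.5, 7, 14), 1),
                                   ti_hours = sample(c(0, 2, 8, 30), 1),
                                   n_doses = 5)))
    if (runif(1) < 0.8)
      regs <- c(regs, list(regimen("abt737", runif(1, 0, 600),
                                   n_doses = 30)))
    regs
  }))
  for (regs in sets) {
    tr <- simulate_model(p, regs, system_state(p, 20), t0 = 19,
                         horizon = 35, dt = dt_fast)
    expect_true(all(as.matrix(tr[, setdiff(names(tr), "time")]) >= 0))
  }
})

test_that("age-structured solution matches the characteristics oracle", {
  p <- default_p
  p$bax_sensitivity <- 0   # survival then depends only on stored C_t
  r <- regimen("carboplatin", 40, ti_hours = 36, n_doses = 1,
               start_day = 0.5)
  tr <- simulate_model(p, list(r), system_state(p, 50), t0 = 0,
                       horizon = 3, dt = 0.005, sample_dt = 0.005)
  # oracle: integrate arrivals along each characteristic directly,
  # M_tot(t) = int_0^psi alpha(C_t(t-a)) N(t-a) exp(-C_t(t-a) dM0 a) da
  f_ct <- function(t) approx(tr$time, tr$C_t, xout = t, rule = 2)$y
  f_n <- function(t) approx(tr$time, tr$N, xout = t, rule = 2)$y
  oracle <- function(t) {
    a <- seq(0, min(t, p$arrest_duration), by = 5e-4)
    y <- arrest_rate(f_ct(t - a), p) * f_n(t - a) *
      exp(-f_ct(t - a) * p$arrest_death_coef * a)
    xenopkpd:::trapz(a, y)
  }
  for (t in c(1.5, 2, 3)) {
    expect_equal(tr$M_tot[abs(tr$time - t) < 1e-9], oracle(t),
                 tolerance = 5e-3)
  }
})

test_that("refining dt changes the final burden by less than 0.1%", {
  p <- default_p
  regs <- list(regimen("carboplatin", 30, ti_hours = 8, n_doses = 3),
               regimen("abt737", 100, n_doses = 21))
  finals <- vapply(c(0.01, 0.005, 0.0025), function(dt) {
    tr <- simulate_model(p, regs, system_state(p, 50), t0 = 19,
                         horizon = 21, dt = dt)
    tr$total[nrow(tr)]
  }, numeric(1))
  expect_lt(abs(finals[2] / finals[1] - 1), 1e-3)
  expect_lt(abs(finals[3] / finals[2] - 1), 1e-3)
})

test_that("resistant cells ignore carboplatin but respond to ABT-737", {
  p <- default_p
  rc <- regimen("carboplatin", 30, n_doses = 4)
  # pure resistant tumor: no arrest, carboplatin has no effect at all
  tr <- simulate_model(p, list(rc), system_state(p, 50, 1), t0 = 19,
                       horizon = 28, dt = dt_fast)
  expect_equal(tr$M_tot, rep(0, nrow(tr)))
  expect_lt(max(abs(tr$total / logistic_solution(
    tr$time, 50, p$growth_rate, p$carrying_capacity, 19) - 1)), 1e-6)
  # ABT-737 response identical for sensitive and resistant pools
  ra <- regimen("abt737", 100, n_doses = 28)
  tr_s <- simulate_model(p, list(ra), system_state(p, 50, 0), t0 = 19,
                         horizon = 28, dt = dt_fast)
  tr_r <- simulate_model(p, list(ra), system_state(p, 50, 1), t0 = 19,
                         horizon = 28, dt = dt_fast)
  expect_equal(tr_r$N_r, tr_s$N, tolerance = 1e-12)
})
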