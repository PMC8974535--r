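test_that("schooling gain is linear in the HAZ improvement", {
  expect_equal(schooling_gain_per_child(1.0), 0.47)
  expect_equal(schooling_gain_per_child(0.0), 0)
  expect_equal(schooling_gain_per_child(0.5), 0.235)
  expect_equal(schooling_gain_per_child(1.0, coefficient = 0.3), 0.3)
  expect_error(schooling_gain_per_child(-0.1), "nonnegative")
})

test_that("base wage follows GNI x labor share / effective LFPR", {
  p <- make_profile(gni = 1000, labor_share = 0.5, lfpr = 0.625,
                    pop014 = 0.2)
  expect_equal(base_wage(p), 1000)
  # wage equals GNI pc when everyone works and all income is wages
  p <- make_profile(gni = 3000, labor_share = 1, lfpr = 1, pop014 = 0)
  expect_equal(base_wage(p), 3000)
  # re-keyed arithmetic
  p <- make_profile(gni = 2120, labor_share = 0.5, lfpr = 0.58,
                    pop014 = 0.31)
  expect_equal(base_wage(p), 2120 * 0.5 / (0.58 * (1 - 0.31)))
})

test_that("wage trajectories compound the per-period growth rates", {
  flat <- make_profile(growth = 0)
  tr <- wage_trajectory(1000, flat, 2020, 2080)
  expect_true(all(tr$wages == 1000))
  expect_identical(unname(tr$wages["2020"]), tr$base_wage)

  g2 <- make_profile(growth = 0.02)
  tr <- wage_trajectory(1000, g2, 2020, 2030)
  expect_equal(unname(tr$wages["2030"]), 1000 * 1.02^10)

  # rate switches at the five-year period boundary
  p <- make_profile()
  p$growth_rates <- c("2020" = 0.01, "2025" = 0.03)
  tr <- wage_trajectory(1000, p, 2020, 2030)
  expect_equal(unname(tr$wages["2027"]), 1000 * 1.01^5 * 1.03^2)
  # year-by-year loop oracle
  w <- 1000
  for (t in 2020:2029) w <- w * (1 + if (t < 2025) 0.01 else 0.03)
  expect_equal(unname(tr$wages["2030"]), w)

  # the final period's rate is held beyond 2084
  p <- make_profile(growth = 0.02)
  p$growth_rates["2080"] <- 0.05
  tr <- wage_trajectory(1000, p, 2080, 2090)
  expect_equal(unname(tr$wages["2090"]), 1000 * 1.05^10)

  expect_error(wage_trajectory(1000, flat, 2025, 2020), "horizon")
  incomplete <- make_profile()
  incomplete$growth_rates <- c("2020" = 0.02)
  expect_error(wage_trajectory(1000, incomplete, 2020, 2030),
               "period 2025 missing")
})

test_that("per-child PV matches the closed-form constant-growth oracle", {
  wl <- worklife()
  expect_equal(wl$working_years, 44)
  for (g in c(0, 0.01, 0.03, 0.05)) {
    p <- make_profile(growth = g, ret = 0.06)
    traj <- wage_trajectory(base_wage(p), p, 2020, 2085)
    for (d in c(0, 0.03, 0.05, 0.10)) {
      got <- pv_earnings_per_child(traj, p, schooling_gain = 0.2,
                                   birth_year = 2020, wl = wl,
                                   spec = discount_spec(rates = d))
      expect_equal(unname(got),
                   oracle_pv_closed_form(base_wage(p), 0.06, 0.2, g, d),
                   tolerance = 1e-10)
    }
  }
  # undiscounted, zero growth: a flat 44-payment annuity
  p <- make_profile(growth = 0)
  traj <- wage_trajectory(base_wage(p), p, 2020, 2085)
  got <- pv_earnings_per_child(traj, p, 0.2, 2020,
                               spec = discount_spec(rates = 0))
  expect_equal(unname(got), 44 * base_wage(p) * p$return_per_school_year * 0.2)
  # zero schooling gain: zero at every rate
  got <- pv_earnings_per_child(traj, p, 0, 2020)
  expect_true(all(got == 0))
  # strictly decreasing in the discount rate
  got <- pv_earnings_per_child(traj, p, 0.2, 2020,
                               spec = discount_spec(c(0.03, 0.05, 0.10)))
  expect_true(all(diff(unname(got)) < 0))
})

test_that("discounting reference and uplift mode are honoured", {
  p <- make_profile(growth = 0.02)
  traj <- wage_trajectory(base_wage(p), p, 2020, 2090)
  own <- pv_earnings_per_child(traj, p, 0.2, 2025,
                               spec = discount_spec(rates = 0.05))
  fixed <- pv_earnings_per_child(
    traj, p, 0.2, 2025,
    spec = discount_spec(rates = 0.05, reference = "fixed_base_year",
                         fixed_base = 2020))
  # five extra years of discounting back to 2020
  expect_equal(unname(fixed), unname(own) / 1.05^5, tolerance = 1e-12)
  lin <- pv_earnings_per_child(traj, p, 3, 2020,
                               spec = discount_spec(rates = 0.05))
  cmp <- pv_earnings_per_child(traj, p, 3, 2020,
                               spec = discount_spec(rates = 0.05),
                               uplift_mode = "compound")
  # compounding beats the linearization for multi-year gains
  expect_gt(unname(cmp), unname(lin))
  expect_equal(unname(cmp) / unname(lin),
               ((1 + 0.05)^3 - 1) / (0.05 * 3), tolerance = 1e-12)
})

test_that("cohort impacts satisfy their accounting invariants", {
  p <- make_profile()
  years <- 2020:2025
  base <- lapply(years, function(y) shares_from_prevalence(y, 0.40))
  ramp <- linear_trajectory(0.40, 0.26, 2020, 2025)
  cf <- lapply(years, function(y)
    shares_from_prevalence(y, ramp[[as.character(y)]]))
  sc <- build_cohort_scenarios(scenario_trajectory("AAA", base, cf),
                               p$births)
  im <- cohort_impacts(sc, p)
  expect_equal(im$schooling_total, im$schooling_per_child * im$n_stunted)
  for (tag in c("3", "5", "10"))
    expect_equal(im[[paste0("pv_total_", tag)]],
                 im[[paste0("pv_per_child_", tag)]] * im$n_stunted)
  expect_true(all(as.matrix(im[vapply(im, is.numeric, TRUE)]) >= 0))

  # doubling the cohort doubles totals, leaves per-child values unchanged
  sc2 <- sc
  sc2$n_births <- 2 * sc$n_births
  sc2$n_stunted <- 2 * sc$n_stunted
  im2 <- cohort_impacts(sc2, p)
  expect_equal(im2$schooling_total, 2 * im$schooling_total)
  expect_equal(im2$pv_total_5, 2 * im$pv_total_5)
  expect_equal(im2$pv_per_child_5, im$pv_per_child_5)

  # identical baseline/counterfactual: every downstream figure exactly 0
  sc0 <- build_cohort_scenarios(scenario_trajectory("AAA", base, base),
                                p$births)
  im0 <- cohort_impacts(sc0, p)
  expect_true(all(im0$schooling_total == 0))
  expect_true(all(im0$pv_total_3 == 0 & im0$pv_total_5 == 0 &
                    im0$pv_total_10 == 0))
})

test_that("outputs are homogeneous of degree one in each scale factor", {
  years <- 2020:2025
  base <- lapply(years, function(y) shares_from_prevalence(y, 0.40))
  cf <- lapply(years, function(y)
    shares_from_prevalence(y, linear_trajectory(0.40, 0.26, 2020,
                                                2025)[[as.character(y)]]))
  tr <- scenario_trajectory("AAA", base, cf)
  pv5 <- function(profile, config = projection_config()) {
    sc <- build_cohort_scenarios(tr, profile$births)
    sum(cohort_impacts(sc, profile, config)$pv_total_5)
  }
  p <- make_profile()
  ref <- pv5(p)
  # schooling coefficient
  expect_equal(pv5(p, projection_config(schooling_coefficient = 2 * 0.47)),
               2 * ref)
  # Mincerian return (linear uplift mode)
  expect_equal(pv5(make_profile(ret = 2 * 0.05)), 2 * ref)
  # base wage via GNI per capita
  expect_equal(pv5(make_profile(gni = 2 * 2000)), 2 * ref)
  # cohort size
  p2 <- make_profile()
  p2$births <- 2 * p2$births
  expect_equal(pv5(p2), 2 * ref)
})
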