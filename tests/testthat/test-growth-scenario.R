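test_that("SDG target is a 40% reduction from 2012 prevalence", {
  expect_equal(sdg_target_prevalence(0.50), 0.30)
  expect_equal(sdg_target_prevalence(0), 0)
  expect_equal(sdg_target_prevalence(0.4517), 0.6 * 0.4517)
  expect_error(sdg_target_prevalence(1.2), "\\[0, 1\\]")
  expect_error(sdg_target_prevalence(-0.1), "\\[0, 1\\]")
})

test_that("linear trajectories interpolate exactly between endpoints", {
  tr <- linear_trajectory(0.40, 0.28, 2020, 2025)
  expect_equal(tr, c("2020" = 0.40, "2021" = 0.376, "2022" = 0.352,
                     "2023" = 0.328, "2024" = 0.304, "2025" = 0.28))
  expect_equal(unique(linear_trajectory(0.3, 0.3, 2020, 2025)), 0.3)
  # independent affine oracle at interior years
  tr <- linear_trajectory(0.30, 0.18, 2020, 2023)
  affine <- function(y) 0.30 + (0.18 - 0.30) * (y - 2020) / 3
  for (y in 2020:2023)
    expect_equal(unname(tr[as.character(y)]), affine(y))
  # endpoints exact, interior on the chord
  set.seed(11)
  for (i in 1:20) {
    p <- sort(stats::runif(2)); y <- sort(sample(2000:2100, 2))
    tr <- linear_trajectory(p[2], p[1], y[1], y[2])
    expect_identical(unname(tr[1]), p[2])
    expect_identical(unname(tr[length(tr)]), p[1])
    yy <- y[1]:y[2]
    chord <- p[2] + (p[1] - p[2]) * (yy - y[1]) / (y[2] - y[1])
    expect_lt(max(abs(tr - chord)), 1e-12)
  }
  expect_error(linear_trajectory(0.5, 0.4, 2025, 2020), "exceed")
  expect_error(linear_trajectory(1.5, 0.4, 2020, 2025), "\\[0, 1\\]")
})

test_that("delta HAZ extraction follows the rank-preserving contract", {
  m <- haz_category_model()
  d <- function(shares) stunting_distribution(2020, shares)
  # identity
  expect_equal(delta_haz_stunted(d(c(0.2, 0.3, 0.3, 0.2)),
                                 d(c(0.2, 0.3, 0.3, 0.2)), m), 0)
  # whole-category shift from <-3 to -2..-3
  expect_equal(delta_haz_stunted(d(c(0, 0, 0, 1)), d(c(0, 0, 1, 0)), m), 1.0)
  # pro-rata split of a partially covered category (hand arithmetic:
  # baseline stunted mean -2.9; counterfactual lowest 50% mean -2.4)
  expect_equal(delta_haz_stunted(d(c(0.2, 0.3, 0.3, 0.2)),
                                 d(c(0.3, 0.35, 0.25, 0.1)), m), 0.5)
  expect_equal(oracle_delta_haz(c(0.2, 0.3, 0.3, 0.2),
                                c(0.3, 0.35, 0.25, 0.1)), 0.5,
               tolerance = 1e-3)
  expect_error(delta_haz_stunted(d(c(0.7, 0.3, 0, 0)),
                                 d(c(1, 0, 0, 0)), m), "prevalence is zero")
})

test_that("delta HAZ is translation-equivariant and matches brute force", {
  set.seed(19)
  for (i in 1:10) {
    sb <- random_shares(); sc <- random_shares()
    m <- haz_category_model()
    v <- delta_haz_stunted(stunting_distribution(2020, sb),
                           stunting_distribution(2020, sc), m)
    # shifting every representative by a constant changes nothing
    shift <- stats::runif(1, -3, 0)
    m2 <- structure(list(representatives = m$representatives + shift),
                    class = "haz_category_model")
    v2 <- delta_haz_stunted(stunting_distribution(2020, sb),
                            stunting_distribution(2020, sc), m2)
    expect_equal(v, v2, tolerance = 1e-12)
    expect_equal(v, oracle_delta_haz(sb, sc, n = 1e5), tolerance = 5e-3)
  }
})

test_that("stunted counts are real-valued products", {
  expect_equal(stunted_count(1e6, 0.3), 3e5)
  expect_equal(stunted_count(0, 0.5), 0)
  expect_equal(stunted_count(2345678, 0.271), 2345678 * 0.271)
  expect_error(stunted_count(-1, 0.3), "nonnegative")
  expect_error(stunted_count(10, 1.3), "\\[0, 1\\]")
})

test_that("distributions derived from a prevalence reproduce it", {
  for (p in c(0.05, 0.271, 0.45, 0.9)) {
    d <- shares_from_prevalence(2022, p)
    expect_equal(prevalence(d), p, tolerance = 1e-12)
    expect_equal(sum(d$shares), 1)
  }
  expect_error(shares_from_prevalence(2022, 0), "inside")
})

test_that("scenario trajectories reject worsening counterfactuals", {
  base <- lapply(2020:2022, function(y) shares_from_prevalence(y, 0.30))
  worse <- lapply(2020:2022, function(y) shares_from_prevalence(y, 0.35))
  expect_error(scenario_trajectory("IND", base, worse),
               "exceeds baseline in 2020")
  better <- lapply(2020:2022, function(y) shares_from_prevalence(y, 0.25))
  tr <- scenario_trajectory("IND", base, better)
  expect_s3_class(tr, "scenario_trajectory")
  # non-contiguous years rejected
  gap <- lapply(c(2020, 2022), function(y) shares_from_prevalence(y, 0.3))
  expect_error(scenario_trajectory("IND", gap, gap), "contiguous")
})

test_that("cohort scenarios use baseline prevalence and ramp monotonically", {
  years <- 2020:2025
  base <- lapply(years, function(y) shares_from_prevalence(y, 0.40))
  ramp <- linear_trajectory(0.40, 0.24, 2020, 2025)
  cf <- lapply(years, function(y)
    shares_from_prevalence(y, ramp[[as.character(y)]]))
  tr <- scenario_trajectory("IND", base, cf)
  births <- stats::setNames(rep(2e6, 6), years)
  sc <- build_cohort_scenarios(tr, births)
  expect_equal(sc$birth_year, years)
  expect_equal(sc$n_stunted, rep(2e6 * 0.40, 6))  # baseline denominator
  # flat baseline + linear SDG ramp: HAZ gain strictly increases by cohort
  expect_true(all(diff(sc$delta_haz) > 0))
  # per-year recomputation agrees
  for (i in seq_along(years))
    expect_equal(sc$delta_haz[i],
                 delta_haz_stunted(base[[i]], cf[[i]]))
  # identical scenarios give all-zero gains
  sc0 <- build_cohort_scenarios(scenario_trajectory("IND", base, base),
                                births)
  expect_true(all(sc0$delta_haz == 0))
  # missing births fail loudly
  expect_error(build_cohort_scenarios(tr, births[-3]),
               "no births recorded for cohort year 2022")
  # delta-HAZ override bypasses the category extraction
  sc2 <- build_cohort_scenarios(tr, births,
                                delta_haz_override = c("2020" = 0.123))
  expect_equal(sc2$delta_haz[1], 0.123)
  expect_equal(sc2$delta_haz[-1], sc$delta_haz[-1])
})

test_that("cohort lag shifts the evaluation year", {
  years <- 2020:2025
  base <- lapply(years, function(y) shares_from_prevalence(y, 0.40))
  ramp <- linear_trajectory(0.40, 0.24, 2020, 2025)
  cf <- lapply(years, function(y)
    shares_from_prevalence(y, ramp[[as.character(y)]]))
  tr <- scenario_trajectory("IND", base, cf)
  births <- stats::setNames(rep(1e6, 6), years)
  lagged <- build_cohort_scenarios(tr, births, cohort_lag = 1L)
  expect_equal(lagged$birth_year, 2020:2024)  # last cohort has no year b+1
  plain <- build_cohort_scenarios(tr, births)
  expect_equal(lagged$delta_haz, plain$delta_haz[-1])
})

test_that("stunting tables read from long-form CSV", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("iso3,year,scenario,prevalence",
               "ind,2020,baseline,0.40", "ind,2021,baseline,0.40",
               "ind,2020,counterfactual,0.40",
               "ind,2021,counterfactual,0.35"), path)
  trs <- read_stunting_table(path)
  expect_named(trs, "IND")
  expect_equal(vapply(trs$IND$counterfactual, prevalence, numeric(1)),
               c("2020" = 0.40, "2021" = 0.35), tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("iso3,year,scenario,prevalence", "ind,2020,baseline,1.4"),
             bad)
  expect_error(read_stunting_table(bad), "outside \\[0, 1\\]")
})
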