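# Synthetic country panels and stunting trajectories: every stage of the
# pipeline is testable offline, with no downloaded indicator data.

.iso3_codes <- function(n) {
  stopifnot(n >= 1, n <= 26 * 26)
  paste0("S", LETTERS[((seq_len(n) - 1) %/% 26) + 1],
         LETTERS[((seq_len(n) - 1) %% 26) + 1])
}

#' Generate synthetic country profiles
#'
#' Draws a deterministic panel of plausible LMIC profiles: GNI per capita
#' log-uniform on [500, 12 000] USD, 15+ LFPR uniform on [0.40, 0.85], 0-14
#' population share uniform on [0.20, 0.45], returns to schooling uniform on
#' [0.01, 0.15], and per-period growth rates from a mean-reverting walk
#' clamped to [-0.02, 0.08]. WHO regions and income groups are assigned
#' round-robin; births per year 2020-2025 are log-uniform on
#' [5e4, 5e6] with small year-to-year jitter. A configurable fraction of the
#' imputable fields is blanked to exercise imputation.
#'
#' @param n number of countries.
#' @param seed integer seed; the same seed always yields the same panel.
#' @param missing_fraction probability that each imputable field
#'   (GNI, LFPR, population share, return, each growth period) is blanked.
#' @param birth_years years for which live births are generated.
#' @return named list of [country_profile()] objects.
#' @export
generate_profiles <- function(n, seed, missing_fraction = 0,
                              birth_years = 2020:2025) {
  stopifnot(n >= 1)
  set.seed(seed)
  isos <- .iso3_codes(n)
  regions <- rep_len(who_regions(), n)
  incomes <- rep_len(income_groups(), n)
  periods <- growth_periods()
  profiles <- lapply(seq_len(n), function(i) {
    gr <- numeric(length(periods))
    gr[1] <- stats::runif(1, 0.00, 0.06)
    for (k in seq_along(periods)[-1])
      gr[k] <- min(max(gr[k - 1] + 0.4 * (0.03 - gr[k - 1]) +
                         stats::rnorm(1, 0, 0.008), -0.02), 0.08)
    names(gr) <- periods
    births <- round(exp(stats::runif(1, log(5e4), log(5e6))) *
                      exp(cumsum(stats::rnorm(length(birth_years), 0, 0.01))))
    names(births) <- birth_years
    blank <- stats::runif(4 + length(periods)) < missing_fraction
    p <- country_profile(
      iso3 = isos[i], name = paste("Synthetic country", i),
      who_region = regions[i], income_group = incomes[i],
      gni_pc = if (blank[1]) NA_real_ else exp(stats::runif(1, log(500), log(12000))),
      lfpr_15plus = if (blank[2]) NA_real_ else stats::runif(1, 0.40, 0.85),
      pop_share_0_14 = if (blank[3]) NA_real_ else stats::runif(1, 0.20, 0.45),
      return_per_school_year = if (blank[4]) NA_real_ else stats::runif(1, 0.01, 0.15),
      growth_rates = gr[!blank[-(1:4)]],
      births = births)
    p
  })
  stats::setNames(profiles, isos)
}

#' Generate synthetic baseline/counterfactual stunting trajectories
#'
#' For each profile, draws a 2020 baseline stunting prevalence from a beta
#' distribution centred in the 0.20-0.45 range, lets the baseline stay flat
#' or decline gently over 2020-2025, and builds the counterfactual as the
#' SDG-target ramp: a linear path from the 2020 baseline to
#' [sdg_target_prevalence()] of an implied (higher) 2012 prevalence. Four
#' category shares are derived from a discretized normal matching each
#' prevalence ([shares_from_prevalence()]).
#'
#' @param profiles list of [country_profile()] objects.
#' @param seed integer seed.
#' @param years trajectory years.
#' @return named list of [scenario_trajectory()] objects, one per country.
#' @export
generate_trajectories <- function(profiles, seed, years = 2020:2025) {
  set.seed(seed)
  out <- lapply(profiles, function(p) {
    m <- stats::runif(1, 0.20, 0.45)
    p0 <- stats::rbeta(1, m * 50, (1 - m) * 50)
    drift <- stats::runif(1, 0, 0.004)           # baseline decline per year
    base_prev <- pmax(p0 - drift * (years - years[1]), 0.01)
    prev_2012 <- min(p0 * stats::runif(1, 1.05, 1.25), 0.95)
    target <- sdg_target_prevalence(prev_2012)
    target <- min(target, base_prev[length(years)])  # improvement only
    cf_prev <- linear_trajectory(p0, target, years[1], years[length(years)])
    scenario_trajectory(
      p$iso3,
      baseline = lapply(seq_along(years), function(i)
        shares_from_prevalence(years[i], base_prev[i])),
      counterfactual = lapply(seq_along(years), function(i)
        shares_from_prevalence(years[i], cf_prev[i])))
  })
  stats::setNames(out, names(profiles))
}

#' Packaged South Asia reference tables
#'
#' Published reference estimates for the South Asia SDG stunting-target
#' scenario (Bangladesh, Bhutan, India, Nepal, Pakistan; birth cohorts
#' 2020-2025), shipped as plain CSV under `inst/extdata`:
#' regional medians of the wage increase per HAZ unit; additional schooling
#' per birth cohort (thousands of school years); present value of additional
#' lifetime earnings by discount rate and by country (USD millions, 5%
#' discounting for the by-country table); and per-stunted-child present
#' values (USD). Body cells and the independently printed Total/Average
#' margins are kept in separate columns so the margins can be recomputed and
#' compared.
#'
#' @return named list of data frames: `region_medians`, `schooling`,
#'   `earnings_by_rate`, `earnings_by_country`, `per_child`.
#' @export
south_asia_tables <- function() {
  rd <- function(f) utils::read.csv(
    system.file("extdata", f, package = "growthgains", mustWork = TRUE),
    stringsAsFactors = FALSE, check.names = FALSE)
  list(region_medians = rd("south_asia_region_medians.csv"),
       schooling = rd("south_asia_schooling.csv"),
       earnings_by_rate = rd("south_asia_earnings_by_rate.csv"),
       earnings_by_country = rd("south_asia_earnings_by_country.csv"),
       per_child = rd("south_asia_per_child.csv"),
       sdg_prevalence_2025 = rd("south_asia_sdg_prevalence_2025.csv"))
}
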