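# column tag for a discount rate: 0.03 -> "3", 0.10 -> "10"
.rate_tag <- function(rates) formatC(100 * rates, format = "g")

#' Working-life assumptions
#'
#' The projection assumes 44 working years, entering the labor market at age
#' 16 and retiring at 60: earnings accrue at integer ages in the half-open
#' range `[entry_age, exit_age)`, i.e. 16..59 by default.
#'
#' @param entry_age age at labor-market entry (years).
#' @param exit_age retirement age (years); must exceed `entry_age`.
#' @return object of class `worklife`.
#' @export
worklife <- function(entry_age = 16L, exit_age = 60L) {
  entry_age <- as.integer(entry_age); exit_age <- as.integer(exit_age)
  if (exit_age <= entry_age) stop("exit_age must exceed entry_age")
  structure(list(entry_age = entry_age, exit_age = exit_age,
                 working_years = exit_age - entry_age), class = "worklife")
}

#' Discounting specification
#'
#' Present values are reported at one or more annual discount rates (default
#' 3%, 5% and 10%). The reference year of the discounting is each cohort's
#' own birth year by default; a fixed calendar year can be used instead via
#' `reference = "fixed_base_year"`.
#'
#' @param rates nonnegative annual discount rates, fractions.
#' @param reference `"cohort_birth_year"` or `"fixed_base_year"`.
#' @param fixed_base reference calendar year, required iff
#'   `reference == "fixed_base_year"`.
#' @return object of class `discount_spec`.
#' @export
discount_spec <- function(rates = c(0.03, 0.05, 0.10),
                          reference = c("cohort_birth_year",
                                        "fixed_base_year"),
                          fixed_base = NULL) {
  reference <- match.arg(reference)
  if (any(rates < 0)) stop("discount rates must be nonnegative")
  if (reference == "fixed_base_year" && is.null(fixed_base))
    stop("fixed_base required when reference = 'fixed_base_year'")
  if (reference == "cohort_birth_year") fixed_base <- NULL
  structure(list(rates = sort(rates), reference = reference,
                 fixed_base = fixed_base), class = "discount_spec")
}

#' Additional schooling per stunted child from a HAZ gain
#'
#' Education gains are a linear function of the height-for-age improvement:
#' 0.47 additional years of schooling per unit increase in HAZ at age two
#' among stunted children (pooled estimate from five LMIC birth-cohort
#' studies), applied uniformly across countries. The coefficient is
#' configurable.
#'
#' @param delta_haz nonnegative mean HAZ gain among stunted children.
#' @param coefficient years of schooling per HAZ unit.
#' @return additional years of schooling per stunted child.
#' @export
schooling_gain_per_child <- function(delta_haz, coefficient = 0.47) {
  if (any(delta_haz < 0)) stop("delta_haz must be nonnegative")
  coefficient * delta_haz
}

#' Base-year wage per worker
#'
#' Average annual wage per worker: GNI per capita times the labor share of
#' income (wage per capita), divided by the labor force participation rate
#' expressed against the total population (the published 15+ LFPR re-based
#' via the 0-14 population share; see [effective_lfpr()]).
#'
#' @param profile a [country_profile()].
#' @return USD per worker per year.
#' @export
base_wage <- function(profile) {
  if (is.na(profile$gni_pc))
    stop(sprintf("country %s: gni_pc missing (impute first)", profile$iso3))
  profile$gni_pc * profile$labor_share / effective_lfpr(profile)
}

# annual growth rate applicable over calendar year t (the step t -> t+1):
# the rate of the five-year period [p, p+5) containing t, clamped to the
# available 2020-2080 periods (years beyond 2084 reuse the final rate).
.rate_for_year <- function(profile, t) {
  p <- 5L * (t %/% 5L)
  p <- min(max(p, 2020L), 2080L)
  v <- unname(profile$growth_rates[as.character(p)])
  if (!length(v) || is.na(v))
    stop(sprintf("country %s: growth rate for period %d missing (impute first)",
                 profile$iso3, p))
  v
}

#' Project the wage path from a base year
#'
#' Wages compound annually at the country's projected annual GNI-per-capita
#' growth rate; the rate is constant within each five-year projection period
#' (2020-2084) and the final period's rate is held beyond 2084. Averaging of
#' the growth projections across models happens upstream in data
#' preparation: the profile stores one rate per period. The labor share and
#' LFPR are held constant, so wage growth equals income growth.
#'
#' @param base wage in `base_year`, USD/worker/year (see [base_wage()]).
#' @param profile a [country_profile()] with growth rates present.
#' @param base_year first calendar year of the path.
#' @param horizon last calendar year of the path.
#' @return object of class `wage_trajectory` with fields `base_year`,
#'   `base_wage` and `wages` (named vector, one value per year).
#' @export
wage_trajectory <- function(base, profile, base_year, horizon) {
  if (horizon < base_year) stop("horizon before base_year")
  years <- base_year:horizon
  w <- numeric(length(years))
  w[1] <- base
  for (i in seq_along(years)[-1])
    w[i] <- w[i - 1] * (1 + .rate_for_year(profile, years[i] - 1L))
  structure(list(base_year = base_year, base_wage = base,
                 wages = stats::setNames(w, years)),
            class = "wage_trajectory")
}

#' @export
print.wage_trajectory <- function(x, ...) {
  cat(sprintf("<wage_trajectory> %d-%d, base %.2f USD/worker/yr\n",
              x$base_year, x$base_year + length(x$wages) - 1L, x$base_wage))
  invisible(x)
}

#' Present value of additional lifetime earnings per stunted child
#'
#' The wage gain accrues once per child as the cohort passes through its
#' working life: for each working age the child earns the projected wage of
#' that calendar year times the proportional uplift from the additional
#' schooling, and the stream is discounted back to the reference year. With
#' the default linear uplift the annual gain is
#' `wage * return_per_school_year * schooling_gain`; the compound option
#' uses `wage * ((1 + return)^schooling_gain - 1)`.
#'
#' @param traj a [wage_trajectory()] covering every working year of the
#'   cohort.
#' @param profile a [country_profile()] (supplies the return to schooling).
#' @param schooling_gain additional years of schooling per stunted child.
#' @param birth_year the cohort's birth year.
#' @param wl a [worklife()].
#' @param spec a [discount_spec()].
#' @param uplift_mode `"linear"` or `"compound"`.
#' @return named numeric vector: present value in USD per stunted child, one
#'   entry per discount rate.
#' @export
pv_earnings_per_child <- function(traj, profile, schooling_gain, birth_year,
                                  wl = worklife(), spec = discount_spec(),
                                  uplift_mode = c("linear", "compound")) {
  uplift_mode <- match.arg(uplift_mode)
  ages <- wl$entry_age:(wl$exit_age - 1L)
  years <- birth_year + ages
  wages <- traj$wages[as.character(years)]
  if (anyNA(wages))
    stop(sprintf("wage trajectory does not cover %d-%d",
                 min(years), max(years)))
  r <- profile$return_per_school_year
  if (is.na(r))
    stop(sprintf("country %s: return_per_school_year missing", profile$iso3))
  uplift <- if (uplift_mode == "linear") r * schooling_gain
            else (1 + r)^schooling_gain - 1
  t0 <- if (spec$reference == "cohort_birth_year") birth_year
        else spec$fixed_base
  vapply(spec$rates,
         function(d) sum(wages * uplift * (1 + d)^(-(years - t0))),
         numeric(1)) |>
    stats::setNames(format(spec$rates))
}

#' Per-cohort schooling and earnings impacts for one country
#'
#' Composes the scenario outputs (stunted counts and HAZ gains per birth
#' cohort) with the schooling coefficient, the country wage level and growth
#' path, and discounting, into one impact record per cohort.
#'
#' @param scenarios data frame from [build_cohort_scenarios()].
#' @param profile a [country_profile()], post-imputation.
#' @param config a [projection_config()].
#' @return data frame of class `cohort_impacts`: one row per cohort with
#'   columns `iso3`, `birth_year`, `n_births`, `n_stunted`, `delta_haz`,
#'   `schooling_per_child`, `schooling_total`, and per discount rate `d`
#'   `pv_per_child_<d>` and `pv_total_<d>` (USD).
#' @export
cohort_impacts <- function(scenarios, profile, config = projection_config()) {
  wl <- worklife(config$entry_age, config$exit_age)
  spec <- .config_discount_spec(config)
  base_year <- config$wage_base_year
  horizon <- max(scenarios$birth_year) + wl$exit_age - 1L
  traj <- wage_trajectory(base_wage(profile), profile, base_year, horizon)
  s_per <- schooling_gain_per_child(scenarios$delta_haz,
                                    config$schooling_coefficient)
  pv <- t(vapply(seq_len(nrow(scenarios)), function(i)
    pv_earnings_per_child(traj, profile, s_per[i],
                          scenarios$birth_year[i], wl, spec,
                          config$uplift_mode),
    numeric(length(spec$rates))))
  rate_tag <- .rate_tag(spec$rates)
  out <- data.frame(
    iso3 = profile$iso3,
    scenarios[c("birth_year", "n_births", "n_stunted", "delta_haz")],
    schooling_per_child = s_per,
    schooling_total = s_per * scenarios$n_stunted,
    stringsAsFactors = FALSE)
  for (j in seq_along(spec$rates)) {
    out[[paste0("pv_per_child_", rate_tag[j])]] <- pv[, j]
    out[[paste0("pv_total_", rate_tag[j])]] <- pv[, j] * scenarios$n_stunted
  }
  attr(out, "discount_rates") <- spec$rates
  class(out) <- c("cohort_impacts", "data.frame")
  out
}
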