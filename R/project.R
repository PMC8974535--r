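#' Projection configuration
#'
#' Collects every tunable of the schooling/earnings projection with its
#' default: the schooling coefficient (0.47 years per HAZ unit), discount
#' rates (3/5/10%), the discounting reference (`"birth_year"` for each
#' cohort's own birth year, or `"fixed:<year>"`), working ages (16-60, 44
#' earning years), the wage uplift mode (`"linear"`: wage x return x years;
#' `"compound"`: (1+return)^years - 1), the wage base year, the
#' representative HAZ value per category, and the cohort-to-calendar-year
#' lag (see [build_cohort_scenarios()]).
#'
#' @param schooling_coefficient years of schooling per HAZ unit.
#' @param discount_rates annual discount rates, fractions.
#' @param discount_reference `"birth_year"` or `"fixed:<year>"`.
#' @param entry_age,exit_age working-life bounds, see [worklife()].
#' @param uplift_mode `"linear"` or `"compound"`.
#' @param wage_base_year calendar year of the base wage.
#' @param haz_representatives four representative z-scores, see
#'   [haz_category_model()].
#' @param cohort_lag 0 or 1.
#' @param delta_haz_override optional list {iso3 -> named vector
#'   {birth year -> HAZ gain}} bypassing the category-based extraction.
#' @return list of class `projection_config`.
#' @export
projection_config <- function(schooling_coefficient = 0.47,
                              discount_rates = c(0.03, 0.05, 0.10),
                              discount_reference = "birth_year",
                              entry_age = 16L, exit_age = 60L,
                              uplift_mode = "linear",
                              wage_base_year = 2020L,
                              haz_representatives = c(0, -1.5, -2.5, -3.5),
                              cohort_lag = 0L,
                              delta_haz_override = NULL) {
  if (!(identical(discount_reference, "birth_year") ||
        grepl("^fixed:[0-9]{4}$", discount_reference)))
    stop("discount_reference must be 'birth_year' or 'fixed:<year>'")
  haz_category_model(haz_representatives)  # validates
  worklife(entry_age, exit_age)            # validates
  structure(list(
    schooling_coefficient = schooling_coefficient,
    discount_rates = sort(discount_rates),
    discount_reference = discount_reference,
    entry_age = as.integer(entry_age), exit_age = as.integer(exit_age),
    uplift_mode = match.arg(uplift_mode, c("linear", "compound")),
    wage_base_year = as.integer(wage_base_year),
    haz_representatives = haz_representatives,
    cohort_lag = as.integer(cohort_lag),
    delta_haz_override = delta_haz_override), class = "projection_config")
}

.config_discount_spec <- function(config) {
  if (identical(config$discount_reference, "birth_year"))
    discount_spec(config$discount_rates, "cohort_birth_year")
  else
    discount_spec(config$discount_rates, "fixed_base_year",
                  fixed_base = as.integer(sub("fixed:", "",
                                              config$discount_reference)))
}

#' Read a projection configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take their
#' [projection_config()] defaults. The file must carry
#' `schema: growthgains-config-v1`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [projection_config()].
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(raw$schema, "growthgains-config-v1"))
    stop(sprintf("%s: missing or unsupported schema key", path))
  raw$schema <- NULL
  known <- names(formals(projection_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop(sprintf("%s: unknown config key(s): %s", path,
                 paste(bad, collapse = ", ")))
  do.call(projection_config, raw)
}

#' Project schooling and lifetime-earnings gains from improved linear growth
#'
#' The central entry point. For each country it pairs the imputed profile
#' with its baseline/counterfactual stunting trajectory, extracts per-cohort
#' stunted counts and mean HAZ gains, converts them to additional schooling
#' (0.47 years per HAZ unit by default) and to discounted lifetime-earnings
#' gains through the country's wage level and projected income growth, and
#' collects one impact record per country and birth cohort.
#'
#' @param profiles named list of [country_profile()] objects
#'   (post-[impute_missing()], or complete).
#' @param trajectories named list of [scenario_trajectory()] objects; names
#'   must cover the profiles to be projected (profiles without a trajectory
#'   are dropped with a warning).
#' @param config a [projection_config()].
#' @return object of class `growth_projection` with elements `impacts`
#'   (a [cohort_impacts()] data frame over all countries), `profiles`,
#'   `trajectories` and `config`. Methods: `print`, `summary`, `plot`,
#'   `as.data.frame`.
#' @export
project_growth_benefits <- function(profiles, trajectories,
                                    config = projection_config()) {
  stopifnot(inherits(config, "projection_config"))
  isos <- intersect(names(profiles), names(trajectories))
  if (!length(isos)) stop("no country has both a profile and a trajectory")
  dropped <- setdiff(names(profiles), isos)
  if (length(dropped))
    warning("no trajectory for: ", paste(dropped, collapse = ", "))
  model <- haz_category_model(config$haz_representatives)
  impacts <- lapply(isos, function(iso) {
    p <- profiles[[iso]]
    sc <- build_cohort_scenarios(
      trajectories[[iso]], p$births, model,
      cohort_lag = config$cohort_lag,
      delta_haz_override = config$delta_haz_override[[iso]])
    cohort_impacts(sc, p, config)
  })
  out <- do.call(rbind, impacts)
  attr(out, "discount_rates") <- config$discount_rates
  class(out) <- c("cohort_impacts", "data.frame")
  structure(list(impacts = out, profiles = profiles[isos],
                 trajectories = trajectories[isos], config = config),
            class = "growth_projection")
}

#' @export
print.growth_projection <- function(x, ...) {
  im <- x$impacts
  cat(sprintf("<growth_projection> %d countries, cohorts %d-%d\n",
              length(unique(im$iso3)), min(im$birth_year),
              max(im$birth_year)))
  cat(sprintf("  stunted children (baseline): %s\n",
              format(round(sum(im$n_stunted)), big.mark = " ")))
  cat(sprintf("  schooling gained: %s thousand school years\n",
              format(round(sum(im$schooling_total) / 1000, 1),
                     big.mark = " ")))
  for (d in x$config$discount_rates)
    cat(sprintf("  PV lifetime earnings at %s%%: %s USD millions\n",
                .rate_tag(d),
                format(round(sum(im[[paste0("pv_total_", .rate_tag(d))]]) / 1e6),
                       big.mark = " ")))
  invisible(x)
}

#' @export
summary.growth_projection <- function(object, ...) {
  rates <- object$config$discount_rates
  im <- object$impacts
  per_iso <- split(im, im$iso3)
  tab <- data.frame(
    iso3 = names(per_iso),
    n_stunted = vapply(per_iso, function(d) sum(d$n_stunted), numeric(1)),
    schooling_thousand_years = vapply(per_iso, function(d)
      sum(d$schooling_total) / 1000, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  for (d in rates)
    tab[[paste0("pv_musd_", .rate_tag(d))]] <- vapply(per_iso, function(x)
      sum(x[[paste0("pv_total_", .rate_tag(d))]]) / 1e6, numeric(1))
  structure(list(by_country = tab, config = object$config),
            class = "summary.growth_projection")
}

#' @export
print.summary.growth_projection <- function(x, ...) {
  cat("Projected gains from improved linear growth, by country\n")
  tab <- x$by_country
  tab[-1] <- lapply(tab[-1], function(v) round(v, 1))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.growth_projection <- function(x, ...) {
  out <- x$impacts
  class(out) <- "data.frame"
  out
}

#' @export
plot.growth_projection <- function(x, rate = 0.05, ...) {
  im <- x$impacts
  col <- paste0("pv_total_", .rate_tag(rate))
  m <- .impact_matrix(im, col, scale = 1e6)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    xlab = "Birth cohort",
                    ylab = sprintf("PV earnings gain at %s%% (USD millions)",
                                   .rate_tag(rate)), ...)
  invisible(x)
}

# -- pipeline runner --------------------------------------------------------

#' Validate a projection input directory
#'
#' Checks that `countries.csv`, `growth_rates.csv`, `births.csv` and
#' `stunting.csv` exist and parse, and that every country with a stunting
#' trajectory has a profile.
#'
#' @param input_dir directory of input CSVs.
#' @return invisibly, a list with the parsed `profiles` and `trajectories`.
#' @export
validate_inputs <- function(input_dir) {
  need <- c("countries.csv", "growth_rates.csv", "births.csv",
            "stunting.csv")
  paths <- file.path(input_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("missing input file(s) in %s: %s", input_dir,
                 paste(missing, collapse = ", ")))
  profiles <- read_country_table(paths[1], paths[2], paths[3])
  trajectories <- read_stunting_table(paths[4])
  orphan <- setdiff(names(trajectories), names(profiles))
  if (length(orphan))
    stop("stunting trajectories without a country profile: ",
         paste(orphan, collapse = ", "))
  invisible(list(profiles = profiles, trajectories = trajectories))
}

#' Run the full projection pipeline over an input directory
#'
#' Reads and validates the input CSVs, imputes missing indicators, runs
#' [project_growth_benefits()], and writes to `output_dir`: the imputation
#' audit (`imputation_audit.csv`), the per-cohort impact records
#' (`cohort_impacts.csv`), and the four report tables. Outputs are
#' deterministic: rerunning on identical inputs yields byte-identical files.
#'
#' @param input_dir directory containing `countries.csv`,
#'   `growth_rates.csv`, `births.csv`, `stunting.csv`.
#' @param output_dir directory to write results into (created if needed).
#' @param config a [projection_config()], or a path to a YAML/JSON config.
#' @param per_child_rate,by_country_rate discount rate used for the
#'   per-child and by-country tables.
#' @return invisibly, the [project_growth_benefits()] object.
#' @export
run_project <- function(input_dir, output_dir,
                        config = projection_config(),
                        per_child_rate = 0.05, by_country_rate = 0.05) {
  if (is.character(config)) config <- read_config(config)
  parsed <- validate_inputs(input_dir)
  profiles <- impute_missing(parsed$profiles)
  proj <- project_growth_benefits(profiles, parsed$trajectories, config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(attr(profiles, "audit"),
                   file.path(output_dir, "imputation_audit.csv"),
                   row.names = FALSE)
  im <- as.data.frame(proj)
  im[] <- lapply(im, function(v)
    if (is.numeric(v)) as.numeric(formatC(v, format = "g", digits = 17)) else v)
  utils::write.csv(im, file.path(output_dir, "cohort_impacts.csv"),
                   row.names = FALSE)
  write_report_table(schooling_table(proj$impacts),
                     file.path(output_dir, "table_schooling.csv"))
  write_report_table(earnings_by_rate_table(proj$impacts),
                     file.path(output_dir, "table_earnings_by_rate.csv"))
  write_report_table(earnings_by_country_table(proj$impacts, by_country_rate),
                     file.path(output_dir, "table_earnings_by_country.csv"))
  write_report_table(per_child_table(proj$impacts, per_child_rate),
                     file.path(output_dir, "table_per_child.csv"))
  invisible(proj)
}

#' Write a complete synthetic input bundle
#'
#' Generates a synthetic country panel and SDG-ramp trajectories
#' ([generate_profiles()], [generate_trajectories()]) and writes them in the
#' exact input format [run_project()] consumes, plus a default YAML config.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the bundle is a deterministic function of it.
#' @param n number of countries.
#' @param missing_fraction fraction of imputable fields blanked.
#' @return invisibly, `dir`.
#' @export
write_demo_bundle <- function(dir, seed = 20220402, n = 8,
                              missing_fraction = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- generate_profiles(n, seed, missing_fraction)
  trajectories <- generate_trajectories(profiles, seed + 1L)
  num <- function(v) formatC(v, format = "g", digits = 17)
  countries <- data.frame(
    iso3 = names(profiles),
    name = vapply(profiles, `[[`, "", "name"),
    who_region = vapply(profiles, `[[`, "", "who_region"),
    income_group = vapply(profiles, `[[`, "", "income_group"),
    gni_pc = num(vapply(profiles, `[[`, numeric(1), "gni_pc")),
    labor_share_frac = num(vapply(profiles, `[[`, numeric(1), "labor_share")),
    lfpr_15plus_frac = num(vapply(profiles, `[[`, numeric(1), "lfpr_15plus")),
    pop_share_0_14_frac = num(vapply(profiles, `[[`, numeric(1),
                                     "pop_share_0_14")),
    return_per_school_year_frac = num(vapply(profiles, `[[`, numeric(1),
                                             "return_per_school_year")),
    stringsAsFactors = FALSE)
  countries[countries == "NA"] <- NA
  gr <- do.call(rbind, lapply(profiles, function(p)
    if (length(p$growth_rates)) data.frame(
      iso3 = p$iso3, period_start = as.integer(names(p$growth_rates)),
      rate_frac = num(unname(p$growth_rates)), stringsAsFactors = FALSE)))
  bi <- do.call(rbind, lapply(profiles, function(p) data.frame(
    iso3 = p$iso3, year = as.integer(names(p$births)),
    births = unname(p$births), stringsAsFactors = FALSE)))
  st <- do.call(rbind, lapply(trajectories, function(tr)
    do.call(rbind, lapply(c("baseline", "counterfactual"), function(sc)
      data.frame(iso3 = tr$iso3, year = tr$years, scenario = sc,
                 t(vapply(tr[[sc]], function(d)
                   stats::setNames(num(d$shares),
                                   c("share_gt_m1", "share_m1_m2",
                                     "share_m2_m3", "share_lt_m3")),
                   character(4))),
                 stringsAsFactors = FALSE)))))
  utils::write.csv(countries, file.path(dir, "countries.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(gr, file.path(dir, "growth_rates.csv"), row.names = FALSE)
  utils::write.csv(bi, file.path(dir, "births.csv"), row.names = FALSE)
  utils::write.csv(st, file.path(dir, "stunting.csv"), row.names = FALSE)
  writeLines(c("schema: growthgains-config-v1",
               "schooling_coefficient: 0.47",
               "discount_rates: [0.03, 0.05, 0.10]",
               "discount_reference: birth_year",
               "entry_age: 16", "exit_age: 60",
               "uplift_mode: linear", "wage_base_year: 2020",
               "cohort_lag: 0"),
             file.path(dir, "config.yaml"))
  invisible(dir)
}
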