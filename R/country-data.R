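#' @keywords internal
"_PACKAGE"

#' WHO regions and income groups recognised by the model
#'
#' The tool models low- and middle-income countries (LMICs) only; the three
#' World Bank income groups below are accepted and high-income countries are
#' rejected at read time, because the imputation donor pools are defined over
#' LMICs.
#'
#' @export
who_regions <- function() {
  c("Africa", "Americas", "Eastern-Mediterranean", "European",
    "South-East Asia", "Western-Pacific")
}

#' @rdname who_regions
#' @export
income_groups <- function() c("low", "lower-middle", "upper-middle")

#' Period start years of the long-run income growth projections
#'
#' Growth rates are supplied per five-year period, 2020 through 2080.
#' @export
growth_periods <- function() seq(2020L, 2080L, by = 5L)

#' Construct a country profile
#'
#' A country profile collects every economic and demographic parameter the
#' earnings projection needs for one country: GNI per capita (Atlas USD), the
#' labor share of income (default 0.5, the global assumption; overridable per
#' country), the labor force participation rate of the 15+ population, the
#' population share aged 0-14 (used to re-base the LFPR to the total
#' population), the Mincerian return to schooling (fraction wage gain per
#' additional school year), annual GNI-per-capita growth rates per five-year
#' period 2020-2080, and live births per calendar year.
#'
#' Percent-like quantities are stored as fractions. Missing values are `NA`
#' (or `NULL` maps) and can be filled by [impute_missing()].
#'
#' @param iso3 three-letter country code.
#' @param name country name.
#' @param who_region one of [who_regions()].
#' @param income_group one of [income_groups()].
#' @param gni_pc GNI per capita, USD/person/year (Atlas method).
#' @param labor_share fraction of national income paid as wages.
#' @param lfpr_15plus labor force participation rate among the 15+
#'   population, fraction.
#' @param pop_share_0_14 share of the total population aged 0-14, fraction.
#' @param return_per_school_year fraction wage gain per additional year of
#'   schooling.
#' @param growth_rates named numeric vector, names = period start years
#'   (multiples of 5 in 2020-2080), values = annual growth rate fractions.
#' @param births named numeric vector, names = birth years, values = live
#'   births.
#' @param imputed character vector of field names filled by imputation.
#' @return an object of class `country_profile`.
#' @export
country_profile <- function(iso3, name = iso3, who_region, income_group,
                            gni_pc = NA_real_, labor_share = 0.5,
                            lfpr_15plus = NA_real_,
                            pop_share_0_14 = NA_real_,
                            return_per_school_year = NA_real_,
                            growth_rates = NULL, births = NULL,
                            imputed = character()) {
  stopifnot(is.character(iso3), nchar(iso3) == 3L)
  who_region <- match.arg(who_region, who_regions())
  income_group <- match.arg(income_group, income_groups())
  if (!is.null(growth_rates)) {
    ps <- as.integer(names(growth_rates))
    if (anyNA(ps) || any(ps %% 5L != 0L) || any(ps < 2020L | ps > 2080L))
      stop("growth-rate period starts must be multiples of 5 in [2020, 2080]")
  }
  x <- structure(list(
    iso3 = toupper(iso3), name = name, who_region = who_region,
    income_group = income_group, gni_pc = gni_pc, labor_share = labor_share,
    lfpr_15plus = lfpr_15plus, pop_share_0_14 = pop_share_0_14,
    return_per_school_year = return_per_school_year,
    growth_rates = growth_rates, births = births,
    imputed = imputed), class = "country_profile")
  validate_country_profile(x)
  x
}

#' @export
print.country_profile <- function(x, ...) {
  cat(sprintf("<country_profile> %s (%s) - %s, %s income\n",
              x$iso3, x$name, x$who_region, x$income_group))
  cat(sprintf("  GNI pc: %s USD  labor share: %s  LFPR 15+: %s  pop 0-14: %s\n",
              format(x$gni_pc), format(x$labor_share),
              format(x$lfpr_15plus), format(x$pop_share_0_14)))
  cat(sprintf("  return/school yr: %s  growth periods: %d  birth years: %d\n",
              format(x$return_per_school_year),
              length(x$growth_rates), length(x$births)))
  if (length(x$imputed))
    cat("  imputed:", paste(x$imputed, collapse = ", "), "\n")
  invisible(x)
}

validate_country_profile <- function(x) {
  chk <- function(cond, msg) if (!is.na(cond) && !cond)
    stop(sprintf("country %s: %s", x$iso3, msg), call. = FALSE)
  chk(x$labor_share > 0 && x$labor_share <= 1, "labor_share outside (0, 1]")
  chk(is.na(x$lfpr_15plus) || (x$lfpr_15plus > 0 && x$lfpr_15plus <= 1),
      "lfpr_15plus outside (0, 1]")
  chk(is.na(x$pop_share_0_14) ||
        (x$pop_share_0_14 >= 0 && x$pop_share_0_14 < 1),
      "pop_share_0_14 outside [0, 1)")
  chk(is.na(x$gni_pc) || x$gni_pc > 0, "gni_pc must be positive")
  chk(is.na(x$return_per_school_year) || x$return_per_school_year >= 0,
      "return_per_school_year must be nonnegative")
  invisible(x)
}

#' Effective labor force participation rate of the total population
#'
#' Published LFPRs refer to the 15+ population; the wage formula needs the
#' share of workers in the total population, so the 15+ rate is scaled by the
#' share of the population that is 15 or older.
#'
#' @param profile a [country_profile()].
#' @return fraction of the total population in the labor force.
#' @export
effective_lfpr <- function(profile) {
  v <- profile$lfpr_15plus * (1 - profile$pop_share_0_14)
  if (is.na(v) || v <= 0)
    stop(sprintf("country %s: effective LFPR is not positive", profile$iso3))
  v
}

# -- CSV reading ------------------------------------------------------------

# Percent-like columns must declare units through a column-name suffix:
# `<field>_pct` (values in [0, 100]) or `<field>_frac` (values in [0, 1]).
# Internal representation is always a fraction.
.unit_col <- function(df, field, file, required = TRUE) {
  pct <- paste0(field, "_pct"); fr <- paste0(field, "_frac")
  has_pct <- pct %in% names(df); has_fr <- fr %in% names(df)
  if (has_pct && has_fr)
    stop(sprintf("%s: both %s and %s present", file, pct, fr))
  if (!has_pct && !has_fr) {
    if (field %in% names(df))
      stop(sprintf(
        "%s: column '%s' must declare units via a '_pct' or '_frac' suffix",
        file, field))
    if (required)
      stop(sprintf("%s: missing required column %s_pct or %s_frac",
                   file, field, field))
    return(rep(NA_real_, nrow(df)))
  }
  col <- if (has_pct) pct else fr
  v <- suppressWarnings(as.numeric(df[[col]]))
  lim <- if (has_pct) 100 else 1
  bad <- which(!is.na(v) & (v < 0 | v > lim))
  if (length(bad))
    stop(sprintf("%s: row %d, column %s: value %g outside [0, %g]",
                 file, bad[1], col, v[bad[1]], lim))
  if (has_pct) v / 100 else v
}

#' Read country profiles from CSV tables
#'
#' Reads the static country table plus optional long-form growth-rate and
#' births tables, returning one [country_profile()] per country. Missing
#' cells are recorded as absent (`NA`), not zero, and can be filled later by
#' [impute_missing()].
#'
#' `countries_csv` columns: `iso3`, `name` (optional), `who_region`,
#' `income_group`, `gni_pc`, `labor_share_frac` (optional; default 0.5), and
#' the unit-suffixed percent-like columns `lfpr_15plus_pct|_frac`,
#' `pop_share_0_14_pct|_frac`, `return_per_school_year_pct|_frac`.
#' `growth_rates_csv` columns: `iso3`, `period_start`, `rate_pct|rate_frac`.
#' `births_csv` columns: `iso3`, `year`, `births`.
#'
#' High-income countries are rejected: the model covers LMICs only and the
#' imputation donor pools are defined over LMICs.
#'
#' @param countries_csv path to the static country table.
#' @param growth_rates_csv,births_csv optional paths to the long-form tables.
#' @return list of `country_profile` objects, named by iso3.
#' @export
read_country_table <- function(countries_csv, growth_rates_csv = NULL,
                               births_csv = NULL) {
  df <- utils::read.csv(countries_csv, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  need <- c("iso3", "who_region", "income_group", "gni_pc")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", countries_csv,
                 paste(miss, collapse = ", ")))
  dup <- df$iso3[duplicated(df$iso3)]
  if (length(dup))
    stop(sprintf("%s: duplicate iso3 code(s): %s", countries_csv,
                 paste(unique(dup), collapse = ", ")))
  if (any(df$income_group %in% c("high", "high-income")))
    stop(sprintf("%s: high-income countries are not modelled (rows: %s)",
                 countries_csv,
                 paste(which(df$income_group %in% c("high", "high-income")),
                       collapse = ", ")))
  gni <- suppressWarnings(as.numeric(df$gni_pc))
  bad <- which(!is.na(gni) & gni <= 0)
  if (length(bad))
    stop(sprintf("%s: row %d, column gni_pc: value %g must be positive",
                 countries_csv, bad[1], gni[bad[1]]))
  lfpr <- .unit_col(df, "lfpr_15plus", countries_csv)
  p014 <- .unit_col(df, "pop_share_0_14", countries_csv)
  ret <- .unit_col(df, "return_per_school_year", countries_csv,
                   required = FALSE)
  lsh <- if ("labor_share_frac" %in% names(df))
    as.numeric(df$labor_share_frac) else rep(NA_real_, nrow(df))
  lsh[is.na(lsh)] <- 0.5

  gr_by <- list()
  if (!is.null(growth_rates_csv)) {
    g <- utils::read.csv(growth_rates_csv, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
    rate_col <- intersect(c("rate_pct", "rate_frac"), names(g))
    if (length(rate_col) != 1L)
      stop(sprintf("%s: need exactly one of rate_pct / rate_frac",
                   growth_rates_csv))
    r <- as.numeric(g[[rate_col]])
    if (rate_col == "rate_pct") r <- r / 100
    g <- g[!is.na(r), , drop = FALSE]; r <- r[!is.na(r)]
    gr_by <- split(stats::setNames(r, g$period_start), g$iso3)
  }
  bi_by <- list()
  if (!is.null(births_csv)) {
    b <- utils::read.csv(births_csv, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
    bad <- which(!is.na(b$births) & b$births < 0)
    if (length(bad))
      stop(sprintf("%s: row %d, column births: negative value", births_csv,
                   bad[1]))
    bi_by <- split(stats::setNames(as.numeric(b$births), b$year), b$iso3)
  }

  profiles <- lapply(seq_len(nrow(df)), function(i) {
    iso <- toupper(df$iso3[i])
    country_profile(
      iso3 = iso,
      name = if ("name" %in% names(df) && !is.na(df$name[i])) df$name[i]
             else iso,
      who_region = df$who_region[i], income_group = df$income_group[i],
      gni_pc = gni[i], labor_share = lsh[i], lfpr_15plus = lfpr[i],
      pop_share_0_14 = p014[i], return_per_school_year = ret[i],
      growth_rates = gr_by[[iso]], births = bi_by[[iso]])
  })
  stats::setNames(profiles, vapply(profiles, `[[`, "", "iso3"))
}

# -- Imputation -------------------------------------------------------------

.median_or_na <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) NA_real_ else stats::median(v)
}

#' Impute missing country indicators by region / income-group medians
#'
#' Returns to schooling and each five-year growth rate are imputed with the
#' WHO-region median of the non-missing values; GNI per capita, the 15+
#' LFPR, and the 0-14 population share with the income-group median. When a
#' region (or income group) has no donor at all, the global median is used.
#' Every imputed field is recorded in the profile's `imputed` set, and a full
#' audit table (iso3, field, donor pool, value) is attached as attribute
#' `"audit"`.
#'
#' Imputation is idempotent and never alters a non-missing field.
#'
#' @param profiles list of [country_profile()] objects.
#' @return the list with missing fields filled; attribute `"audit"` holds a
#'   data frame of every imputation performed.
#' @export
impute_missing <- function(profiles) {
  get_field <- function(p, f) {
    if (startsWith(f, "growth_")) {
      per <- sub("growth_", "", f)
      v <- unname(p$growth_rates[per])
      if (!length(v)) NA_real_ else v
    } else p[[f]]
  }
  region <- vapply(profiles, `[[`, "", "who_region")
  income <- vapply(profiles, `[[`, "", "income_group")
  fields <- c(
    stats::setNames(rep("region", 1L + length(growth_periods())),
                    c("return_per_school_year",
                      paste0("growth_", growth_periods()))),
    stats::setNames(rep("income", 3L),
                    c("gni_pc", "lfpr_15plus", "pop_share_0_14")))
  audit <- list()
  for (f in names(fields)) {
    vals <- vapply(profiles, get_field, numeric(1), f = f)
    if (all(is.na(vals)))
      stop(sprintf("field %s is missing for every country; cannot impute", f))
    if (!anyNA(vals)) next
    pool <- if (fields[[f]] == "region") region else income
    med_by <- tapply(vals, pool, .median_or_na)
    glob <- .median_or_na(vals)
    for (i in which(is.na(vals))) {
      m <- med_by[[pool[i]]]
      donor <- if (is.na(m)) "global" else
        paste0(fields[[f]], ":", pool[i])
      if (is.na(m)) m <- glob
      p <- profiles[[i]]
      if (startsWith(f, "growth_")) {
        per <- sub("growth_", "", f)
        gr <- p$growth_rates
        if (is.null(gr)) gr <- numeric()
        gr[[per]] <- m
        p$growth_rates <- gr[order(as.integer(names(gr)))]
      } else p[[f]] <- m
      p$imputed <- union(p$imputed, f)
      profiles[[i]] <- p
      audit[[length(audit) + 1L]] <- data.frame(
        iso3 = p$iso3, field = f, donor_pool = donor, value = m,
        stringsAsFactors = FALSE)
    }
  }
  attr(profiles, "audit") <- if (length(audit))
    do.call(rbind, audit)
  else
    data.frame(iso3 = character(), field = character(),
               donor_pool = character(), value = numeric(),
               stringsAsFactors = FALSE)
  profiles
}

#' Wage increase per unit increase in HAZ
#'
#' Composes the schooling gain per HAZ unit (0.47 years of schooling per
#' z-score unit among stunted children, from pooled LMIC cohort studies) with
#' the country's Mincerian return to schooling, yielding the fraction wage
#' gain per unit increase in height-for-age z-score.
#'
#' @param profile a [country_profile()] with `return_per_school_year` set.
#' @param schooling_coefficient years of schooling gained per HAZ unit.
#' @return fraction wage increase per HAZ unit.
#' @export
wage_increase_per_haz <- function(profile, schooling_coefficient = 0.47) {
  r <- profile$return_per_school_year
  if (is.na(r))
    stop(sprintf("country %s: return_per_school_year missing (impute first)",
                 profile$iso3))
  schooling_coefficient * r
}

#' Median wage increase per HAZ unit by WHO region
#'
#' One row per WHO region present in the data plus an `Overall` row; the
#' statistic is the median over countries of [wage_increase_per_haz()].
#' Empty regions are omitted with a warning.
#'
#' @inheritParams wage_increase_per_haz
#' @param profiles list of post-imputation [country_profile()] objects.
#' @return data frame with columns `region`, `median_wage_increase_per_haz`,
#'   `n_countries`.
#' @export
regional_medians <- function(profiles, schooling_coefficient = 0.47) {
  v <- vapply(profiles, wage_increase_per_haz, numeric(1),
              schooling_coefficient = schooling_coefficient)
  region <- vapply(profiles, `[[`, "", "who_region")
  empty <- setdiff(who_regions(), region)
  if (length(empty))
    warning("no countries in region(s): ", paste(empty, collapse = ", "))
  regs <- intersect(who_regions(), unique(region))
  out <- data.frame(
    region = c(regs, "Overall"),
    median_wage_increase_per_haz = c(
      vapply(regs, function(r) stats::median(v[region == r]), numeric(1)),
      stats::median(v)),
    n_countries = c(vapply(regs, function(r) sum(region == r), integer(1)),
                    length(v)),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}
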