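# HAZ categories, worst to mildest, as used in the four-category
# re-analysis of survey data: <-3, -3 to -2, -2 to -1, >-1. Stored here
# mildest-first to match the published category order (>-1, -1 to -2,
# -2 to -3, <-3). Stunting prevalence = share of the last two categories.

#' Four-category HAZ distribution of 12-23-month-old children
#'
#' Shares over the height-for-age z-score categories (>-1, -1 to -2,
#' -2 to -3, <-3) for one calendar year and scenario. Shares must be
#' nonnegative and sum to one (tolerance 1e-9). Stunting prevalence is the
#' mass below -2, i.e. the sum of the last two shares.
#'
#' @param year calendar year.
#' @param shares numeric vector of four category shares, mildest first.
#' @return object of class `stunting_distribution`.
#' @export
stunting_distribution <- function(year, shares) {
  shares <- as.numeric(shares)
  if (length(shares) != 4L || anyNA(shares))
    stop("shares must be four non-missing numbers")
  if (any(shares < 0)) stop("shares must be nonnegative")
  if (abs(sum(shares) - 1) > 1e-9)
    stop(sprintf("shares must sum to 1 (got %.12f)", sum(shares)))
  structure(list(year = as.integer(year), shares = shares),
            class = "stunting_distribution")
}

#' @rdname stunting_distribution
#' @param x a `stunting_distribution`.
#' @export
prevalence <- function(x) UseMethod("prevalence")

#' @export
prevalence.stunting_distribution <- function(x) sum(x$shares[3:4])

#' @export
print.stunting_distribution <- function(x, ...) {
  cat(sprintf(
    "<stunting_distribution> %d: >-1: %.3f | -1..-2: %.3f | -2..-3: %.3f | <-3: %.3f (stunting %.1f%%)\n",
    x$year, x$shares[1], x$shares[2], x$shares[3], x$shares[4],
    100 * prevalence(x)))
  invisible(x)
}

#' Representative HAZ value per category
#'
#' Maps each of the four HAZ categories to a single representative z-score
#' used when averaging over category distributions. Defaults are the interval
#' midpoints with conservative values for the open tails:
#' 0.0, -1.5, -2.5, -3.5. Representatives must be strictly decreasing and the
#' two stunted categories must lie below -2.
#'
#' @param representatives numeric vector of four z-scores, mildest first.
#' @return object of class `haz_category_model`.
#' @export
haz_category_model <- function(representatives = c(0, -1.5, -2.5, -3.5)) {
  representatives <- as.numeric(representatives)
  if (length(representatives) != 4L || anyNA(representatives))
    stop("need four representative HAZ values")
  if (any(diff(representatives) >= 0))
    stop("representative HAZ values must be strictly decreasing")
  if (any(representatives[3:4] >= -2))
    stop("stunted-category representatives must lie below -2")
  structure(list(representatives = representatives),
            class = "haz_category_model")
}

#' SDG 2.2 stunting target
#'
#' The SDG target for stunting is a 40% reduction in prevalence from 2012
#' levels, i.e. a 2025 prevalence of 0.6 times the 2012 prevalence.
#'
#' @param prev_2012 stunting prevalence in 2012, fraction in `[0, 1]`.
#' @return the target prevalence.
#' @export
sdg_target_prevalence <- function(prev_2012) {
  if (any(is.na(prev_2012)) || any(prev_2012 < 0 | prev_2012 > 1))
    stop("prev_2012 must lie in [0, 1]")
  0.6 * prev_2012
}

#' Linear prevalence trajectory between two years
#'
#' Equally spaced interpolation from `prev_start` in `year_start` to
#' `prev_end` in `year_end`, inclusive of both endpoints.
#'
#' @param prev_start,prev_end prevalences in `[0, 1]`.
#' @param year_start,year_end calendar years, `year_end > year_start`.
#' @return named numeric vector, one prevalence per year.
#' @export
linear_trajectory <- function(prev_start, prev_end, year_start, year_end) {
  if (year_end <= year_start) stop("year_end must exceed year_start")
  if (any(c(prev_start, prev_end) < 0 | c(prev_start, prev_end) > 1))
    stop("prevalences must lie in [0, 1]")
  years <- year_start:year_end
  w <- (years - year_start) / (year_end - year_start)
  # two-weight form so both endpoints are reproduced exactly
  stats::setNames((1 - w) * prev_start + w * prev_end, years)
}

#' Average HAZ gain among stunted children between two scenarios
#'
#' Rank-preserving extraction of the mean height-for-age improvement for the
#' children who are stunted at baseline. Children keep their rank in the HAZ
#' distribution across scenarios: the baseline-stunted population is the
#' lowest-`p` mass of both distributions, where `p` is the baseline stunting
#' prevalence. The baseline stunted mean is the share-weighted mean of the
#' representative HAZ over the two stunted categories; the counterfactual
#' mean is taken over the lowest-`p` mass of the counterfactual distribution,
#' splitting a category pro-rata when `p` falls inside it. The result is the
#' counterfactual mean minus the baseline mean, and is nonnegative whenever
#' the counterfactual distribution first-order stochastically dominates the
#' baseline.
#'
#' @param baseline,counterfactual [stunting_distribution()] objects;
#'   baseline prevalence must be positive.
#' @param model a [haz_category_model()].
#' @return mean HAZ gain (z-score units) among baseline-stunted children.
#' @export
delta_haz_stunted <- function(baseline, counterfactual,
                              model = haz_category_model()) {
  p <- prevalence(baseline)
  if (p <= 0)
    stop("baseline stunting prevalence is zero: no stunted children")
  rep_haz <- model$representatives
  base_mean <- sum(baseline$shares[3:4] * rep_haz[3:4]) / p
  # lowest-p mass of the counterfactual, filled from the worst category up
  cf_shares <- rev(counterfactual$shares)
  cf_rep <- rev(rep_haz)
  remaining <- p
  acc <- 0
  for (k in 1:4) {
    take <- min(cf_shares[k], remaining)
    acc <- acc + take * cf_rep[k]
    remaining <- remaining - take
    if (remaining <= 0) break
  }
  if (remaining > 1e-9)
    stop("counterfactual shares do not cover the baseline stunted mass")
  acc / p - base_mean
}

#' Number of stunted children in a birth cohort
#'
#' @param births live births in the cohort.
#' @param prev stunting prevalence, fraction in `[0, 1]`.
#' @return real-valued count (rounding happens only at report time).
#' @export
stunted_count <- function(births, prev) {
  if (any(births < 0)) stop("births must be nonnegative")
  if (any(prev < 0 | prev > 1)) stop("prevalence must lie in [0, 1]")
  births * prev
}

#' Paired baseline/counterfactual stunting trajectory
#'
#' Holds, for one country and a contiguous run of calendar years, the
#' baseline and counterfactual four-category HAZ distributions (or scalar
#' prevalences, from which distributions are derived via
#' [shares_from_prevalence()]). The counterfactual prevalence may not exceed
#' the baseline in any year: the tool models improvements only, and a
#' worsening counterfactual is rejected rather than clamped.
#'
#' @param iso3 country code.
#' @param baseline,counterfactual lists of [stunting_distribution()] covering
#'   the same contiguous years.
#' @return object of class `scenario_trajectory`.
#' @export
scenario_trajectory <- function(iso3, baseline, counterfactual) {
  yb <- vapply(baseline, `[[`, integer(1), "year")
  yc <- vapply(counterfactual, `[[`, integer(1), "year")
  if (!identical(yb, yc)) stop("baseline/counterfactual years differ")
  if (length(yb) > 1L && any(diff(yb) != 1L))
    stop("trajectory years must be contiguous")
  pb <- vapply(baseline, prevalence, numeric(1))
  pc <- vapply(counterfactual, prevalence, numeric(1))
  bad <- which(pc > pb + 1e-12)
  if (length(bad))
    stop(sprintf(
      "%s: counterfactual prevalence exceeds baseline in %d",
      iso3, yb[bad[1]]))
  structure(list(iso3 = toupper(iso3), years = yb,
                 baseline = stats::setNames(baseline, yb),
                 counterfactual = stats::setNames(counterfactual, yc)),
            class = "scenario_trajectory")
}

#' @export
print.scenario_trajectory <- function(x, ...) {
  pb <- vapply(x$baseline, prevalence, numeric(1))
  pc <- vapply(x$counterfactual, prevalence, numeric(1))
  cat(sprintf("<scenario_trajectory> %s, %d-%d\n", x$iso3,
              min(x$years), max(x$years)))
  print(data.frame(year = x$years, baseline = round(pb, 4),
                   counterfactual = round(pc, 4), row.names = NULL))
  invisible(x)
}

#' Derive a four-category HAZ distribution from a scalar prevalence
#'
#' Discretizes a normal HAZ distribution whose mean is chosen so that the
#' mass below -2 equals the requested stunting prevalence, with a fixed
#' standard deviation (default 1.1, a typical anthropometric z-score spread).
#' The four shares are the normal masses over (>-1), (-1,-2), (-2,-3), (<-3).
#'
#' @param year calendar year.
#' @param prev stunting prevalence, strictly inside (0, 1).
#' @param sd standard deviation of the underlying HAZ distribution.
#' @return a [stunting_distribution()] with `prevalence()` equal to `prev`.
#' @export
shares_from_prevalence <- function(year, prev, sd = 1.1) {
  if (prev <= 0 || prev >= 1) stop("prev must lie strictly inside (0, 1)")
  mu <- -2 - sd * stats::qnorm(prev)
  cuts <- c(-1, -2, -3)
  cdf <- stats::pnorm(cuts, mean = mu, sd = sd)
  stunting_distribution(year, c(1 - cdf[1], cdf[1] - cdf[2],
                                cdf[2] - cdf[3], cdf[3]))
}

#' Per-cohort stunted counts and HAZ gains from a scenario trajectory
#'
#' Evaluates each birth cohort against the trajectory year it indexes into
#' (`cohort_lag = 0` pairs the cohort born in year b with the distributions
#' of calendar year b, reproducing the one-to-one cohort/year pairing of the
#' published South Asia projections; `cohort_lag = 1` implements the strict
#' age-timing reading, where the cohort is 12-23 months old in year b+1).
#' The stunted count uses the baseline prevalence (the denominator is the
#' population whose growth improves); the HAZ gain comes from
#' [delta_haz_stunted()] unless a per-cohort override is supplied.
#'
#' @param trajectory a [scenario_trajectory()].
#' @param births named numeric vector of live births per birth year.
#' @param model a [haz_category_model()].
#' @param cohort_lag 0 or 1, see above.
#' @param delta_haz_override optional named vector {birth year -> HAZ gain}
#'   that bypasses the category-based extraction (mirrors supplying the mean
#'   HAZ improvement directly).
#' @return data frame with columns `birth_year`, `n_births`, `prevalence`,
#'   `n_stunted`, `delta_haz`.
#' @export
build_cohort_scenarios <- function(trajectory, births,
                                   model = haz_category_model(),
                                   cohort_lag = 0L,
                                   delta_haz_override = NULL) {
  stopifnot(cohort_lag %in% c(0L, 1L))
  cohort_years <- trajectory$years[
    (trajectory$years + cohort_lag) %in% trajectory$years]
  rows <- lapply(cohort_years, function(b) {
    if (!as.character(b) %in% names(births))
      stop(sprintf("%s: no births recorded for cohort year %d",
                   trajectory$iso3, b))
    idx <- as.character(b + cohort_lag)
    base <- trajectory$baseline[[idx]]
    cf <- trajectory$counterfactual[[idx]]
    dh <- if (!is.null(delta_haz_override) &&
              as.character(b) %in% names(delta_haz_override)) {
      delta_haz_override[[as.character(b)]]
    } else delta_haz_stunted(base, cf, model)
    n <- births[[as.character(b)]]
    p <- prevalence(base)
    data.frame(birth_year = b, n_births = n, prevalence = p,
               n_stunted = stunted_count(n, p), delta_haz = dh)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read baseline/counterfactual stunting tables
#'
#' Long-form CSV with columns `iso3`, `year`, `scenario` (one of `baseline`,
#' `counterfactual`) and either `prevalence` (fraction) or the four share
#' columns `share_gt_m1`, `share_m1_m2`, `share_m2_m3`, `share_lt_m3`.
#' Scalar prevalences are expanded to category shares with
#' [shares_from_prevalence()].
#'
#' @param path CSV path.
#' @param sd standard deviation used when expanding scalar prevalences.
#' @return named list of [scenario_trajectory()] objects, one per iso3.
#' @export
read_stunting_table <- function(path, sd = 1.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  share_cols <- c("share_gt_m1", "share_m1_m2", "share_m2_m3", "share_lt_m3")
  has_shares <- all(share_cols %in% names(df))
  if (!has_shares && !"prevalence" %in% names(df))
    stop(sprintf("%s: need either a prevalence column or the four share columns",
                 path))
  if (!has_shares) {
    bad <- which(!is.na(df$prevalence) &
                   (df$prevalence < 0 | df$prevalence > 1))
    if (length(bad))
      stop(sprintf("%s: row %d, column prevalence: value outside [0, 1]",
                   path, bad[1]))
  }
  mk <- function(rows) {
    rows <- rows[order(rows$year), , drop = FALSE]
    lapply(seq_len(nrow(rows)), function(i) {
      if (has_shares)
        stunting_distribution(rows$year[i],
                              unlist(rows[i, share_cols], use.names = FALSE))
      else shares_from_prevalence(rows$year[i], rows$prevalence[i], sd = sd)
    })
  }
  out <- lapply(split(df, df$iso3), function(d) {
    scenario_trajectory(d$iso3[1],
                        baseline = mk(d[d$scenario == "baseline", ]),
                        counterfactual = mk(d[d$scenario == "counterfactual", ]))
  })
  stats::setNames(out, toupper(names(out)))
}
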