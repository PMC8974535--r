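# Shared fixture builders and independent oracles.

# complete profile with constant growth everywhere, no missing fields
make_profile <- function(iso3 = "AAA", region = "South-East Asia",
                         income = "lower-middle", gni = 2000,
                         labor_share = 0.5, lfpr = 0.6, pop014 = 0.3,
                         ret = 0.05, growth = 0.02,
                         births = c("2020" = 1e6, "2021" = 1e6,
                                    "2022" = 1e6, "2023" = 1e6,
                                    "2024" = 1e6, "2025" = 1e6)) {
  country_profile(
    iso3, who_region = region, income_group = income, gni_pc = gni,
    labor_share = labor_share, lfpr_15plus = lfpr, pop_share_0_14 = pop014,
    return_per_school_year = ret,
    growth_rates = stats::setNames(rep(growth, length(growth_periods())),
                                   growth_periods()),
    births = births)
}

# random four-category shares (Dirichlet-ish) with positive stunting mass
random_shares <- function() {
  repeat {
    s <- stats::rgamma(4, shape = c(3, 2, 2, 1))
    s <- s / sum(s)
    if (sum(s[3:4]) > 0.02) return(s)
  }
}

# brute-force rank-preserving oracle: n pseudo-children ordered worst-first
# in both worlds, each assigned its category representative; average the
# within-world representatives over the baseline-stunted lowest-p block.
oracle_delta_haz <- function(base_shares, cf_shares,
                             reps = c(0, -1.5, -2.5, -3.5), n = 1e6) {
  u <- (seq_len(n) - 0.5) / n                 # rank from the worst child up
  assign_rep <- function(shares) {
    cum <- cumsum(rev(shares))                # worst category first
    rev(reps)[findInterval(u, cum, left.open = TRUE) + 1L]
  }
  p <- sum(base_shares[3:4])
  stunted <- u < p
  mean(assign_rep(cf_shares)[stunted]) - mean(assign_rep(base_shares)[stunted])
}

# sort-based median oracle (both parities)
oracle_median <- function(v) {
  v <- sort(unname(v[!is.na(v)]))
  n <- length(v)
  if (n %% 2L == 1L) v[(n + 1L) / 2L] else (v[n / 2L] + v[n / 2L + 1L]) / 2
}

# closed-form PV of the earnings uplift under constant growth g, discount d,
# wage base year = birth year, discount reference = birth year:
# w0 * r * s * sum_{a=entry}^{exit-1} ((1+g)/(1+d))^a
oracle_pv_closed_form <- function(w0, r, s, g, d, entry = 16, exit = 60) {
  x <- (1 + g) / (1 + d)
  k <- exit - entry
  w0 * r * s * (if (abs(x - 1) < 1e-15) k * x^entry
                else x^entry * (x^k - 1) / (x - 1))
}

# expand a data.frame fixture (body rows only) into a plain numeric matrix
fixture_matrix <- function(df, label_col) {
  body <- df[df[[label_col]] != "Total", , drop = FALSE]
  m <- as.matrix(body[, grep("^y[0-9]{4}$", names(df)), drop = FALSE])
  rownames(m) <- body[[label_col]]
  colnames(m) <- sub("^y", "", colnames(m))
  m
}
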