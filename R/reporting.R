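#' Report table with recomputed margins
#'
#' The projection's outputs are presented as country (or discount-rate) by
#' birth-cohort tables with a margin column (`Total` = row-wise sum, or
#' `Average` = unweighted mean of the cohort cells) and, where meaningful, a
#' `Total` row summing over countries. Margins are always recomputed from
#' the unrounded body cells; rounding happens only at render time
#' ([render_report_table()]).
#'
#' @param title table title.
#' @param cells numeric matrix, rows = countries or discount rates, columns
#'   = birth cohorts.
#' @param units one of `"thousand school years"`, `"USD millions"`, `"USD"`.
#' @param margin `"total"` (row-wise sum) or `"average"` (row-wise mean).
#' @param total_row add a column-wise `Total` row over countries.
#' @return object of class `report_table`.
#' @export
report_table <- function(title, cells, units = c("thousand school years",
                                                 "USD millions", "USD"),
                         margin = c("total", "average"),
                         total_row = FALSE) {
  units <- match.arg(units)
  margin <- match.arg(margin)
  cells <- as.matrix(cells)
  if (!is.numeric(cells)) stop("cells must be numeric")
  m <- cbind(cells,
             if (margin == "total") rowSums(cells) else rowMeans(cells))
  colnames(m) <- c(colnames(cells),
                   if (margin == "total") "Total" else "Average")
  if (total_row) {
    m <- rbind(m, colSums(m))
    rownames(m) <- c(rownames(cells), "Total")
  }
  structure(list(title = title, cells = m, units = units, margin = margin,
                 total_row = total_row,
                 cohort_cols = colnames(cells)), class = "report_table")
}

#' @export
print.report_table <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$title, x$units))
  print(render_report_table(x))
  invisible(x)
}

#' Round a report table to its printed precision
#'
#' Schooling (thousands of school years) keeps one decimal for values below
#' ten and none above; monetary cells round to whole millions or dollars.
#'
#' @param x a [report_table()].
#' @return numeric matrix of rounded cells.
#' @export
render_report_table <- function(x) {
  m <- x$cells
  if (x$units == "thousand school years")
    ifelse(abs(m) < 10, round(m, 1), round(m))
  else round(m)
}

# pull the country x cohort matrix of one impact column
.impact_matrix <- function(impacts, col, scale = 1) {
  years <- sort(unique(impacts$birth_year))
  isos <- unique(impacts$iso3)
  per_iso <- split(impacts, factor(impacts$iso3, levels = isos))
  rows <- lapply(per_iso, function(d) {
    if (!identical(sort(d$birth_year), years))
      stop("ragged cohort coverage across countries")
    d[[col]][order(d$birth_year)] / scale
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(isos, years)
  m
}

.pv_col <- function(impacts, prefix, rate) {
  col <- paste0(prefix, .rate_tag(rate))
  if (!col %in% names(impacts))
    stop(sprintf("no %s column for discount rate %g (available: %s)",
                 prefix, rate,
                 paste(grep(prefix, names(impacts), value = TRUE),
                       collapse = ", ")))
  col
}

#' Schooling gains per birth cohort (thousands of school years)
#'
#' @param impacts a [cohort_impacts()] data frame (one or more countries).
#' @return a [report_table()], rows = countries plus a Total row.
#' @export
schooling_table <- function(impacts) {
  report_table("Additional years of schooling gained per birth cohort",
               .impact_matrix(impacts, "schooling_total", scale = 1000),
               units = "thousand school years", total_row = TRUE)
}

#' Present value of earnings gains by discount rate (USD millions)
#'
#' Aggregated over the supplied countries; one row per discount rate. For a
#' positive earnings stream the rows are strictly decreasing in the rate.
#'
#' @param impacts a [cohort_impacts()] data frame.
#' @param rates discount rates to report (default: those in `impacts`).
#' @return a [report_table()].
#' @export
earnings_by_rate_table <- function(impacts,
                                   rates = attr(impacts, "discount_rates")) {
  rows <- lapply(rates, function(d)
    colSums(.impact_matrix(impacts, .pv_col(impacts, "pv_total_", d),
                           scale = 1e6)))
  m <- do.call(rbind, rows)
  rownames(m) <- paste0(.rate_tag(rates), "%")
  report_table("Present value of additional lifetime earnings per birth cohort, by discount rate",
               m, units = "USD millions")
}

#' Present value of earnings gains by country (USD millions)
#'
#' @param impacts a [cohort_impacts()] data frame.
#' @param rate single discount rate.
#' @return a [report_table()], rows = countries plus a Total row.
#' @export
earnings_by_country_table <- function(impacts, rate = 0.05) {
  report_table(
    sprintf("Present value of additional lifetime earnings per birth cohort at %s%% discount rate",
            .rate_tag(rate)),
    .impact_matrix(impacts, .pv_col(impacts, "pv_total_", rate),
                   scale = 1e6),
    units = "USD millions", total_row = TRUE)
}

#' Present value of earnings gains per stunted child (USD)
#'
#' Per-child values with an `Average` margin: the unweighted mean of the
#' cohort cells.
#'
#' @param impacts a [cohort_impacts()] data frame.
#' @param rate single discount rate.
#' @return a [report_table()].
#' @export
per_child_table <- function(impacts, rate = 0.05) {
  report_table(
    sprintf("Present value of additional lifetime earnings per stunted child at %s%% discount rate",
            .rate_tag(rate)),
    .impact_matrix(impacts, .pv_col(impacts, "pv_per_child_", rate)),
    units = "USD", margin = "average")
}

#' Write / read a report table as CSV
#'
#' Cells are written at full double precision so that a write/read round
#' trip reproduces every value bit-exactly. Metadata (title, units, margin
#' type) travels in `#`-prefixed header comments.
#'
#' @param x a [report_table()].
#' @param path CSV path.
#' @return `write_report_table` returns `path` invisibly;
#'   `read_report_table` returns the reconstructed [report_table()].
#' @export
write_report_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# title: ", x$title),
               paste0("# units: ", x$units),
               paste0("# margin: ", x$margin),
               paste0("# total_row: ", x$total_row)), con)
  body <- x$cells[if (x$total_row) -nrow(x$cells) else TRUE,
                  x$cohort_cols, drop = FALSE]
  writeLines(paste(c("row", colnames(body)), collapse = ","), con)
  for (i in seq_len(nrow(body)))
    writeLines(paste(c(rownames(body)[i],
                       formatC(body[i, ], format = "g", digits = 17)),
                     collapse = ","), con)
  invisible(path)
}

#' @rdname write_report_table
#' @export
read_report_table <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "# ")]
  get <- function(key) sub(paste0("# ", key, ": "), "",
                           meta[startsWith(meta, paste0("# ", key, ":"))])
  df <- utils::read.csv(text = lines[!startsWith(lines, "# ")],
                        check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$row
  report_table(get("title"), m, units = get("units"),
               margin = get("margin"),
               total_row = identical(get("total_row"), "TRUE"))
}
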