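#' Convert FAERS age codes to years
#'
#' FAERS reports age with a unit code: decades (DEC), years (YR), months
#' (MON), weeks (WK), days (DY) or hours (HR). Values converting outside
#' the plausible 0-120 year range, unknown codes and missing values are
#' returned as `NA`.
#'
#' @param value numeric age values.
#' @param unit_code character unit codes (recycled if length 1).
#' @return numeric vector of ages in years.
#' @export
normalize_age <- function(value, unit_code) {
  value <- as.numeric(value)
  unit_code <- toupper(trimws(as.character(unit_code)))
  if (length(unit_code) == 1L) unit_code <- rep(unit_code, length(value))
  factor_map <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.1786,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor_map[unit_code])
  yrs <- value * f
  yrs[is.na(f) | is.na(value)] <- NA_real_
  yrs[!is.na(yrs) & (yrs < 0 | yrs > 120)] <- NA_real_
  yrs
}

#' Time to onset per exposed case
#'
#' The onset interval is measured from the earliest full-precision therapy
#' start date of the case's primary-suspect drug to the adverse-event date,
#' in years (365.25-day). Records are excluded with a reason code when
#' either date is missing (`missing_date`), only partially reported
#' (`partial_date`, i.e. YYYY or YYYYMM; optionally imputed to the period
#' midpoint with `impute_partial = TRUE`) or when the interval is negative
#' (`negative`).
#'
#' @param cohort a `faers_cohort`.
#' @param drugs ingredients to include (default all exposed).
#' @param impute_partial impute partial dates to the midpoint of their
#'   period instead of excluding them.
#' @return data.frame: caseid, drug, onset_years, status (`ok` or the
#'   exclusion reason).
#' @export
compute_onset <- function(cohort, drugs = NULL, impute_partial = FALSE) {
  exps <- cohort$exposures
  if (!is.null(drugs)) exps <- exps[ingredient %in% tolower(drugs)]
  th <- cohort$therapies
  cs <- cohort$cases[, c("caseid", "event_dt")]

  expand_date <- function(x, end = FALSE) {
    # full dates pass through; partials go to midpoint when imputing
    x <- as.character(x)
    out <- rep(NA, length(x))
    d <- rep(as.Date(NA), length(x))
    full <- !is.na(x) & nchar(x) == 8L
    d[full] <- as.Date(x[full], format = "%Y%m%d")
    if (impute_partial) {
      ym <- !is.na(x) & nchar(x) == 6L
      d[ym] <- as.Date(paste0(x[ym], "15"), format = "%Y%m%d")
      yy <- !is.na(x) & nchar(x) == 4L
      d[yy] <- as.Date(paste0(x[yy], "0702"), format = "%Y%m%d")
    }
    d
  }
  date_status <- function(x) {
    x <- as.character(x)
    ifelse(is.na(x), "missing_date",
           ifelse(nchar(x) == 8L, "ok", "partial_date"))
  }

  recs <- merge(as.data.frame(exps), as.data.frame(cs), by = "caseid")
  if (nrow(th)) {
    thd <- as.data.frame(th)[, c("caseid", "drug_seq", "start_dt")]
    recs <- merge(recs, thd, by = c("caseid", "drug_seq"), all.x = TRUE)
  } else {
    recs$start_dt <- NA_integer_
  }

  recs$start_date <- expand_date(recs$start_dt)
  recs$event_date <- expand_date(recs$event_dt)
  recs$s_status <- date_status(recs$start_dt)
  recs$e_status <- date_status(recs$event_dt)

  # earliest usable start per (case, ingredient)
  dt <- as.data.table(recs)
  agg <- dt[, {
    usable <- !is.na(start_date)
    if (any(usable)) {
      sd <- min(start_date[usable])
      ss <- "ok"
    } else {
      sd <- as.Date(NA)
      ss <- if (any(s_status == "partial_date")) "partial_date" else "missing_date"
    }
    .(start_date = sd, s_status = ss,
      event_date = event_date[1L], e_status = e_status[1L])
  }, by = .(caseid, drug = ingredient)]

  status <- ifelse(agg$s_status != "ok", agg$s_status,
                   ifelse(is.na(agg$event_date),
                          ifelse(agg$e_status == "ok", "missing_date", agg$e_status),
                          "ok"))
  onset <- as.numeric(agg$event_date - agg$start_date) / 365.25
  status[status == "ok" & !is.na(onset) & onset < 0] <- "negative"
  onset[status != "ok"] <- NA_real_
  out <- data.frame(caseid = agg$caseid, drug = agg$drug,
                    onset_years = onset, status = status)
  out[order(out$drug, out$caseid), , drop = FALSE]
}

#' Summarize onset times per drug
#'
#' Median, quartiles (linear-interpolation / type-7 convention, so results
#' are reproducible bit-for-bit) and mean of onset years per drug. Drugs
#' with fewer than `min_n` usable records are flagged.
#'
#' @param records output of [compute_onset()] (rows with `status != "ok"`
#'   are ignored).
#' @param min_n minimum records for a stable summary.
#' @return data.frame: drug, n, median, q1, q3, mean, below_min_n.
#' @export
summarize_onset <- function(records, min_n = 3L) {
  ok <- records[records$status == "ok" & !is.na(records$onset_years), ]
  if (!nrow(ok)) {
    warning("no usable onset records")
    return(data.frame(drug = character(), n = integer(), median = numeric(),
                      q1 = numeric(), q3 = numeric(), mean = numeric(),
                      below_min_n = logical()))
  }
  dt <- as.data.table(ok)
  out <- dt[, {
    q <- stats::quantile(onset_years, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    .(n = .N, median = q[2], q1 = q[1], q3 = q[3], mean = mean(onset_years))
  }, by = drug]
  out <- as.data.frame(out[order(drug)])
  out$below_min_n <- out$n < min_n
  out
}
utils::globalVariables(c("onset_years", "start_date", "event_date",
                         "s_status", "e_status", "i.N", "analyzable"))

#' Percentage share with half-up rounding
#'
#' `100 * count / total` rounded half-up to two decimals, the convention
#' used for report-share tables (so 19.795 prints as 19.80, not 19.79).
#'
#' @param count numerator count(s).
#' @param total denominator (> 0).
#' @return numeric percentage(s).
#' @export
percent_share <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0 | count > total)) stop("count must be in [0, total]")
  floor(100 * count / total * 100 + 0.5) / 100
}

#' Descriptive summary of a cohort
#'
#' Per-drug and per-class report counts with percentage shares of the
#' exposed-report total, sex counts, median age with IQR (overall and per
#' drug), reporting-country counts and outcome-code counts. Outcome
#' percentages are reported against two denominators — outcome entries and
#' exposed reports — because a case may carry several outcome codes.
#'
#' @param cohort a `faers_cohort`.
#' @return object of class `cohort_descriptives`.
#' @export
summarize_descriptives <- function(cohort) {
  exps <- unique(cohort$exposures[, .(caseid, ingredient, class)])
  total <- data.table::uniqueN(exps$caseid)
  if (!total) stop("cohort has no exposed cases")

  by_drug <- exps[, .(n = data.table::uniqueN(caseid)), by = .(drug = ingredient, class)]
  by_drug <- by_drug[order(-n, drug)]
  by_drug[, share := percent_share(n, total)]
  by_class <- exps[, .(n = data.table::uniqueN(caseid)), by = class]
  by_class[, share := percent_share(n, total)]
  by_class <- by_class[order(class)]

  cs <- cohort$cases[cohort$cases$caseid %in% exps$caseid, ]
  sex_tab <- table(cs$sex, useNA = "no")
  age_overall <- stats::quantile(cs$age_years, c(0.25, 0.5, 0.75),
                                 na.rm = TRUE, type = 7, names = FALSE)
  age_by_drug <- merge(as.data.table(cs)[, .(caseid, age_years)],
                       exps, by = "caseid")[
    , .(n_age = sum(!is.na(age_years)),
        median_age = stats::median(age_years, na.rm = TRUE)),
    by = .(drug = ingredient)][order(drug)]
  country_tab <- sort(table(cs$country, useNA = "no"), decreasing = TRUE)

  oc <- cohort$outcomes
  if (nrow(oc)) {
    oc <- oc[caseid %in% exps$caseid]
    out_tab <- sort(table(toupper(trimws(oc$outc_cod))), decreasing = TRUE)
    n_entries <- sum(out_tab)
    outcomes <- data.frame(code = names(out_tab), n = as.integer(out_tab),
                           pct_of_entries = percent_share(as.integer(out_tab),
                                                          max(n_entries, 1L)),
                           pct_of_reports = percent_share(as.integer(out_tab),
                                                          total))
  } else {
    outcomes <- data.frame(code = character(), n = integer(),
                           pct_of_entries = numeric(), pct_of_reports = numeric())
  }

  structure(list(
    n_reports = total,
    by_drug = as.data.frame(by_drug),
    by_class = as.data.frame(by_class),
    sex = sex_tab,
    age_overall = stats::setNames(age_overall, c("q1", "median", "q3")),
    age_by_drug = as.data.frame(age_by_drug),
    country = country_tab,
    outcomes = outcomes
  ), class = "cohort_descriptives")
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  cat("Cohort descriptives:", x$n_reports, "exposed reports\n")
  cat("By class:\n")
  print(x$by_class, row.names = FALSE)
  cat("Top drugs:\n")
  print(utils::head(x$by_drug, 5), row.names = FALSE)
  cat(sprintf("Median age %.1f y (IQR %.1f-%.1f); sex: %s\n",
              x$age_overall["median"], x$age_overall["q1"], x$age_overall["q3"],
              paste(names(x$sex), as.integer(x$sex), collapse = ", ",
                    sep = "=")))
  invisible(x)
}
utils::globalVariables(c("share", "n", "age_years"))
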