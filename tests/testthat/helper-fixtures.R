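# hand-built cohort: exposures and reactions given explicitly, everything
# else minimal. caseids are "c1".."cN".
toy_cohort <- function(n, exposed = list(), reactions = list(),
                       sex = NULL, age_years = NULL, event_dt = NULL,
                       therapies = NULL, drugs_matched = NULL,
                       outcomes = NULL) {
  ids <- paste0("c", seq_len(n))
  cases <- data.table::data.table(
    caseid = ids, primaryid = paste0(ids, "0"),
    sex = if (is.null(sex)) rep("F", n) else sex,
    age_value = NA_real_, age_unit = "YR",
    country = "US",
    event_dt = if (is.null(event_dt)) rep(NA_integer_, n) else event_dt,
    age_years = if (is.null(age_years)) rep(60, n) else age_years,
    n_reactions = 1L, analyzable = TRUE)
  exp_dt <- data.table::rbindlist(lapply(names(exposed), function(ing) {
    data.table::data.table(caseid = paste0("c", exposed[[ing]]),
                           drug_seq = 1L, ingredient = ing,
                           class = "csDMARD")
  }))
  if (is.null(exp_dt) || !nrow(exp_dt)) {
    exp_dt <- data.table::data.table(caseid = character(), drug_seq = integer(),
                                     ingredient = character(), class = character())
  }
  rx <- data.table::rbindlist(lapply(names(reactions), function(pt) {
    data.table::data.table(caseid = paste0("c", reactions[[pt]]), pt = pt)
  }))
  if (is.null(rx) || !nrow(rx)) {
    rx <- data.table::data.table(caseid = character(), pt = character())
  }
  structure(list(
    cases = cases, exposures = exp_dt, reactions = rx,
    drugs_matched = if (is.null(drugs_matched))
      data.table::data.table(caseid = character(), drug_seq = integer(),
                             role_cod = character(), drugname = character(),
                             ingredient = character(), class = character())
      else data.table::as.data.table(drugs_matched),
    outcomes = if (is.null(outcomes))
      data.table::data.table(caseid = character(), outc_cod = character())
      else data.table::as.data.table(outcomes),
    therapies = if (is.null(therapies))
      data.table::data.table(caseid = character(), drug_seq = integer(),
                             start_dt = integer(), end_dt = integer())
      else data.table::as.data.table(therapies),
    dictionary = default_dmard_dictionary(),
    indication_terms = "Rheumatoid arthritis"
  ), class = "faers_cohort")
}

# write a minimal set of quarterly tables; each argument is a data.frame
write_quarter <- function(dir = tempfile("q"), demo, drug, reac,
                          indi = NULL, outc = NULL, ther = NULL,
                          deleted = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, paste0(name, ".txt"))
    data.table::fwrite(df, p, sep = "$", quote = FALSE, na = "")
    p
  }
  paths <- list(demo = w(demo, "DEMO"), drug = w(drug, "DRUG"),
                reac = w(reac, "REAC"))
  if (!is.null(indi)) paths$indi <- w(indi, "INDI")
  if (!is.null(outc)) paths$outc <- w(outc, "OUTC")
  if (!is.null(ther)) paths$ther <- w(ther, "THER")
  if (!is.null(deleted)) {
    paths$deleted <- file.path(dir, "DELETED.txt")
    writeLines(c("caseid", deleted), paths$deleted)
  }
  paths
}

# independent brute-force oracles, deliberately coded along a different path
# than the package implementation
oracle_ror <- function(a, b, c, d) {
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = or,
       lo = exp(log(a) + log(d) - log(b) - log(c) - 1.96 * se),
       hi = exp(log(a) + log(d) - log(b) - log(c) + 1.96 * se))
}

oracle_ic <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- (a + b) * ((a + c) / n)
  ic <- (log(a + 0.5) - log(e + 0.5)) / log(2)
  list(ic = ic, ic025 = ic - 3.3 / sqrt(a + 0.5) - 2 / (a + 0.5)^1.5)
}

# sort-based type-7 quantile, written independently of stats::quantile
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- pmin(lo + 1, n)
  x[lo] + (h - floor(h)) * (x[hi] - x[lo])
}
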