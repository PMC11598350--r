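#' @importFrom data.table fread fwrite as.data.table data.table setorder setnames :=
#' @importFrom stats quantile median qnorm rbinom rlnorm rnorm runif setNames coef
#' @importFrom utils head
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "caseid", "primaryid", "fda_dt", "pt", "drug_seq",
  "role_cod", "drugname", "indi_pt", "indi_drug_seq", "outc_cod",
  "start_dt", "end_dt", "ingredient", "class", "smq", "exposed",
  "a", "n_event", "ok", "..keep"
))

#' Parse FAERS-style numeric dates
#'
#' FAERS dates are YYYYMMDD integers, sometimes truncated to YYYYMM or YYYY
#' when the reporter gave a partial date. Values that do not form a valid
#' calendar date at their stated precision are returned as missing.
#'
#' @param x character or numeric vector of raw date fields.
#' @param precision `"day"` accepts only full 8-digit dates; `"any"` also
#'   accepts YYYY and YYYYMM partials (returned as-is, as integers).
#' @return integer vector; `NA` where unparseable (or partial when
#'   `precision = "day"`).
#' @export
parse_faers_date <- function(x, precision = c("day", "any")) {
  precision <- match.arg(precision)
  x <- trimws(as.character(x))
  x[x %in% c("", "NA")] <- NA_character_
  out <- rep(NA_integer_, length(x))
  digits <- !is.na(x) & grepl("^[0-9]+$", x)

  full <- digits & nchar(x) == 8L
  if (any(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    keep <- !is.na(d) & format(d, "%Y%m%d") == x[full]
    out[full][keep] <- as.integer(x[full][keep])
  }
  if (precision == "any") {
    ym <- digits & nchar(x) == 6L
    if (any(ym)) {
      mm <- as.integer(substr(x[ym], 5, 6))
      keep <- mm >= 1L & mm <= 12L
      out[ym][keep] <- as.integer(x[ym][keep])
    }
    yy <- digits & nchar(x) == 4L
    out[yy] <- as.integer(x[yy])
  }
  out
}

#' Convert a full-precision FAERS date to Date
#' @param x integer YYYYMMDD vector (partials give `NA`).
#' @return `Date` vector.
#' @export
faers_date_as_Date <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & nchar(x) != 8L] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

read_one_table <- function(path, sep, required, label) {
  if (!file.exists(path)) stop("input file not found for ", label, ": ", path)
  dt <- fread(path, sep = sep, colClasses = "character", header = TRUE,
              na.strings = c("", "NA"), quote = "")
  setnames(dt, tolower(names(dt)))
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols)) {
    stop("table ", label, " is missing mandatory column(s): ",
         paste(toupper(missing_cols), collapse = ", "))
  }
  n_in <- nrow(dt)
  bad <- is.na(dt$primaryid) | is.na(dt$caseid)
  malformed <- which(bad)
  dt <- dt[!bad]
  list(data = dt, n_read = nrow(dt), n_skipped = length(malformed),
       malformed_rows = malformed)
}

#' Read one quarter of FAERS-style ASCII tables
#'
#' Reads the dollar-delimited DEMO, DRUG, REAC, INDI, OUTC and THER tables
#' (header row, case-insensitive column names) plus an optional deleted-case
#' list. Rows lacking PRIMARYID or CASEID are logged as malformed and
#' skipped; unparseable dates are kept with the field flagged missing.
#'
#' @param paths named list/vector with elements `demo`, `drug`, `reac`,
#'   and optionally `indi`, `outc`, `ther`, `deleted`.
#' @param sep field delimiter (FAERS convention is `"$"`).
#' @param quarter label attached to every report version, e.g. `"2019Q1"`.
#' @return object of class `faers_quarter`: the parsed tables, the deleted
#'   caseid set, and a read log with per-table read/skipped counts.
#' @export
read_faers_quarter <- function(paths, sep = "$", quarter = NA_character_) {
  paths <- as.list(paths)
  stopifnot(all(c("demo", "drug", "reac") %in% names(paths)))

  demo <- read_one_table(paths$demo, sep, c("primaryid", "caseid", "fda_dt"), "DEMO")
  drug <- read_one_table(paths$drug, sep, c("primaryid", "caseid", "drug_seq",
                                            "role_cod", "drugname"), "DRUG")
  reac <- read_one_table(paths$reac, sep, c("primaryid", "caseid", "pt"), "REAC")

  opt <- list()
  specs <- list(indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
                outc = c("primaryid", "caseid", "outc_cod"),
                ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt"))
  for (nm in names(specs)) {
    if (!is.null(paths[[nm]])) {
      opt[[nm]] <- read_one_table(paths[[nm]], sep, specs[[nm]], toupper(nm))
    }
  }

  d <- demo$data
  d[, fda_dt := parse_faers_date(fda_dt)]
  if ("event_dt" %in% names(d)) {
    d$event_dt <- parse_faers_date(d$event_dt, precision = "any")
  } else {
    d$event_dt <- NA_integer_
  }
  if (!"sex" %in% names(d)) d$sex <- NA_character_
  if (!"age" %in% names(d)) d$age <- NA_character_
  if (!"age_cod" %in% names(d)) d$age_cod <- NA_character_
  if (!"occr_country" %in% names(d)) {
    d$occr_country <- if ("reporter_country" %in% names(d)) d$reporter_country else NA_character_
  }
  d$source_quarter <- quarter

  if (!is.null(opt$ther)) {
    opt$ther$data$start_dt <- parse_faers_date(opt$ther$data$start_dt, precision = "any")
    if ("end_dt" %in% names(opt$ther$data)) {
      opt$ther$data$end_dt <- parse_faers_date(opt$ther$data$end_dt, precision = "any")
    } else {
      opt$ther$data$end_dt <- NA_integer_
    }
  }

  deleted <- character(0)
  if (!is.null(paths$deleted) && file.exists(paths$deleted)) {
    del <- fread(paths$deleted, header = FALSE, colClasses = "character", quote = "")
    deleted <- trimws(del[[1]])
    deleted <- setdiff(deleted, c("", "caseid", "CASEID"))
  }

  log <- data.frame(
    table = c("DEMO", "DRUG", "REAC", toupper(names(opt))),
    n_read = c(demo$n_read, drug$n_read, reac$n_read,
               vapply(opt, function(t) t$n_read, 0L)),
    n_skipped = c(demo$n_skipped, drug$n_skipped, reac$n_skipped,
                  vapply(opt, function(t) t$n_skipped, 0L)),
    row.names = NULL
  )

  structure(list(
    demo = d, drug = drug$data, reac = reac$data,
    indi = if (is.null(opt$indi)) NULL else opt$indi$data,
    outc = if (is.null(opt$outc)) NULL else opt$outc$data,
    ther = if (is.null(opt$ther)) NULL else opt$ther$data,
    deleted_caseids = deleted, log = log
  ), class = "faers_quarter")
}

#' Combine several quarters into one version store
#' @param quarters list of `faers_quarter` objects.
#' @return single `faers_quarter` with row-bound tables and the union of
#'   deleted caseids.
#' @export
bind_quarters <- function(quarters) {
  stopifnot(length(quarters) >= 1L)
  if (length(quarters) == 1L) return(quarters[[1L]])
  comb <- function(el) data.table::rbindlist(
    Filter(Negate(is.null), lapply(quarters, `[[`, el)), fill = TRUE)
  structure(list(
    demo = comb("demo"), drug = comb("drug"), reac = comb("reac"),
    indi = comb("indi"), outc = comb("outc"), ther = comb("ther"),
    deleted_caseids = unique(unlist(lapply(quarters, `[[`, "deleted_caseids"))),
    log = do.call(rbind, lapply(quarters, `[[`, "log"))
  ), class = "faers_quarter")
}

# ordering key: numeric primaryids compare numerically (zero-padded),
# non-numeric ones lexicographically
primaryid_key <- function(pid) {
  num <- suppressWarnings(as.numeric(pid))
  key <- pid
  ok <- !is.na(num)
  key[ok] <- sprintf("%020.0f", num[ok])
  key
}

#' Deduplicate report versions the FDA-recommended way
#'
#' FAERS publishes every revision of a safety report; revisions share a
#' CASEID. For each CASEID the surviving version is the one with the latest
#' FDA_DT, ties broken by the higher PRIMARYID. Cases named in the quarterly
#' deleted-case lists are removed entirely. A missing FDA_DT sorts before any
#' valid date.
#'
#' @param demo data.frame/data.table of report versions with columns
#'   `caseid`, `primaryid` and (integer) `fda_dt`.
#' @param deleted_caseids character vector of caseids to drop.
#' @return object of class `faers_dedup`: `survivors` (data.table with one
#'   row per caseid: `caseid`, `primaryid`, `fda_dt`) plus conservation
#'   counts `n_versions`, `n_survivors`, `n_superseded`, `n_deleted`.
#' @export
deduplicate_reports <- function(demo, deleted_caseids = character(0)) {
  dt <- as.data.table(demo)[, .(caseid = as.character(caseid),
                                primaryid = as.character(primaryid),
                                fda_dt = as.integer(fda_dt))]
  n_versions <- nrow(dt)
  del <- dt$caseid %in% as.character(deleted_caseids)
  n_deleted <- sum(del)
  dt <- dt[!del]
  dt[, `:=`(.fda = data.table::fifelse(is.na(fda_dt), -1L, fda_dt),
            .pid = primaryid_key(primaryid))]
  setorder(dt, caseid, .fda, .pid)
  surv <- dt[, .SD[.N], by = caseid][, .(caseid, primaryid, fda_dt)]
  structure(list(
    survivors = surv,
    n_versions = n_versions,
    n_survivors = nrow(surv),
    n_superseded = n_versions - n_deleted - nrow(surv),
    n_deleted = n_deleted
  ), class = "faers_dedup")
}

#' @export
print.faers_dedup <- function(x, ...) {
  cat("FAERS deduplication:", x$n_versions, "versions ->",
      x$n_survivors, "cases (", x$n_superseded, "superseded,",
      x$n_deleted, "deleted )\n")
  invisible(x)
}

#' Assemble deduplicated case records
#'
#' Joins the child tables (DRUG, REAC, INDI, OUTC, THER) to the surviving
#' report version of each case. Child rows belonging to superseded versions
#' or to unknown versions (orphans) are dropped and counted. The per-case
#' reaction PT list is de-duplicated preserving first occurrence; a case
#' with no reaction rows is retained but flagged non-analyzable.
#'
#' @param quarter a `faers_quarter` (or compatible list of tables).
#' @param dedup result of [deduplicate_reports()]; computed from
#'   `quarter$demo` when `NULL`.
#' @return object of class `faers_cases`: `cases` (one row per case with
#'   demographics), `drugs`, `reactions`, `indications`, `outcomes`,
#'   `therapies` (all keyed by `caseid`), and a `log` of dropped orphans.
#' @export
assemble_cases <- function(quarter, dedup = NULL) {
  if (is.null(dedup)) dedup <- deduplicate_reports(quarter$demo, quarter$deleted_caseids)
  surv <- dedup$survivors
  keep_pid <- surv$primaryid

  demo <- as.data.table(quarter$demo)
  demo <- demo[primaryid %in% keep_pid]
  demo <- demo[!duplicated(primaryid)]

  filter_child <- function(tab, cols) {
    if (is.null(tab)) return(list(data = data.table(), orphans = 0L))
    tab <- as.data.table(tab)
    inside <- tab$primaryid %in% keep_pid
    n_all_versions <- unique(as.data.table(quarter$demo)$primaryid)
    orphan <- !inside & !(tab$primaryid %in% n_all_versions)
    kept <- tab[inside, intersect(c("caseid", "primaryid", cols), names(tab)), with = FALSE]
    list(data = kept, orphans = sum(orphan))
  }

  drugs <- filter_child(quarter$drug, c("drug_seq", "role_cod", "drugname"))
  reac  <- filter_child(quarter$reac, "pt")
  indi  <- filter_child(quarter$indi, c("indi_drug_seq", "indi_pt"))
  outc  <- filter_child(quarter$outc, "outc_cod")
  ther  <- filter_child(quarter$ther, c("dsg_drug_seq", "start_dt", "end_dt"))

  rx <- reac$data
  if (nrow(rx)) rx <- rx[!duplicated(rx[, .(caseid, pt)])]

  role_ok <- c("PS", "SS", "C", "I")
  dg <- drugs$data
  if (nrow(dg)) {
    dg[, role_cod := toupper(trimws(role_cod))]
    dg[!role_cod %in% role_ok, role_cod := NA_character_]
    dg[, drug_seq := as.integer(drug_seq)]
  }

  cases <- demo[, .(caseid, primaryid,
                    sex = toupper(trimws(ifelse(is.na(sex), "UNK", sex))),
                    age_value = suppressWarnings(as.numeric(age)),
                    age_unit = toupper(trimws(ifelse(is.na(age_cod), "UNK", age_cod))),
                    country = occr_country,
                    event_dt = as.integer(event_dt))]
  cases[!sex %in% c("F", "M"), sex := "UNK"]
  cases[, age_years := normalize_age(age_value, age_unit)]
  n_rx <- rx[, .N, by = caseid]
  cases[, n_reactions := 0L]
  cases[n_rx, n_reactions := i.N, on = "caseid"]
  cases[, analyzable := n_reactions > 0L]

  th <- ther$data
  if (nrow(th)) {
    setnames(th, "dsg_drug_seq", "drug_seq", skip_absent = TRUE)
    th[, drug_seq := as.integer(drug_seq)]
    th[, inconsistent := !is.na(start_dt) & !is.na(end_dt) &
         nchar(start_dt) == 8 & nchar(end_dt) == 8 & end_dt < start_dt]
  }

  structure(list(
    cases = cases, drugs = dg, reactions = rx,
    indications = indi$data, outcomes = outc$data, therapies = th,
    dedup = dedup,
    log = data.frame(
      table = c("DRUG", "REAC", "INDI", "OUTC", "THER"),
      orphan_rows = c(drugs$orphans, reac$orphans, indi$orphans,
                      outc$orphans, ther$orphans))
  ), class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat("FAERS case store:", nrow(x$cases), "cases,",
      sum(x$cases$analyzable), "analyzable;",
      nrow(x$drugs), "drug rows,", nrow(x$reactions), "reaction rows\n")
  invisible(x)
}
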