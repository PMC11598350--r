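#' Default SMQ universe for malignancy screening
#'
#' The nine Standardised MedDRA Query groupings used for cancer-risk
#' aggregation. SMQ membership content is licensed MedDRA material and must
#' be supplied by the user as a PT-to-SMQ mapping file; only the group names
#' ship here.
#'
#' @return character vector of nine SMQ names.
#' @export
default_smq_universe <- function() {
  c("Malignancies",
    "Breast neoplasms, malignant and unspecified",
    "Skin neoplasms, malignant and unspecified",
    "Premalignant disorders",
    "Malignant lymphomas",
    "Prostate neoplasms, malignant and unspecified",
    "Ovarian neoplasms, malignant and unspecified",
    "Uterine and fallopian tube neoplasms, malignant and unspecified",
    "Tumour lysis syndrome")
}

#' Load a PT-to-SMQ mapping
#'
#' Reads a delimited file with columns `pt` and `smq` (an optional `scope`
#' column is kept but not interpreted; narrow/broad scopes can be encoded as
#' distinct SMQ names). The mapping is many-to-many: a PT may belong to
#' several SMQs. Malformed rows (missing pt or smq) are counted and skipped;
#' duplicate memberships collapse to one.
#'
#' @param path delimited file path.
#' @param sep field delimiter.
#' @return object of class `smq_map`: data.frame `map` (pt, smq) plus the
#'   SMQ universe observed.
#' @export
load_smq_map <- function(path, sep = ",") {
  dt <- fread(path, sep = sep, colClasses = "character",
              na.strings = c("", "NA"))
  setnames(dt, tolower(names(dt)))
  if (!all(c("pt", "smq") %in% names(dt))) {
    stop("SMQ map must have columns pt and smq")
  }
  bad <- is.na(dt$pt) | is.na(dt$smq)
  n_bad <- sum(bad)
  dt <- dt[!bad]
  as_smq_map(dt, n_malformed = n_bad)
}

#' Build an SMQ map from a data.frame
#' @param map data.frame with columns `pt`, `smq`.
#' @param n_malformed rows dropped during loading (bookkeeping).
#' @return an `smq_map`.
#' @export
as_smq_map <- function(map, n_malformed = 0L) {
  map <- as.data.table(map)[, .(pt = tolower(trimws(pt)), smq = trimws(smq))]
  map <- unique(map)
  if (!nrow(map)) warning("SMQ map is empty")
  structure(list(map = map,
                 universe = sort(unique(map$smq)),
                 n_malformed = n_malformed),
            class = "smq_map")
}

#' @export
print.smq_map <- function(x, ...) {
  cat("SMQ map:", nrow(x$map), "PT memberships across",
      length(x$universe), "SMQs\n")
  invisible(x)
}

#' SMQs present in a set of reaction PTs
#'
#' Returns the union of SMQ memberships over the PTs: a case counts once per
#' SMQ no matter how many member PTs it carries.
#'
#' @param pts character vector of reaction preferred terms.
#' @param map an `smq_map`.
#' @return character vector of SMQ names (possibly empty).
#' @export
annotate_smq <- function(pts, map) {
  stopifnot(inherits(map, "smq_map"))
  pts <- tolower(trimws(pts))
  sort(unique(map$map$smq[map$map$pt %in% pts]))
}

#' Screen drug-SMQ pairs
#'
#' Identical statistics to [screen_signals()] with the event indicator
#' replaced by SMQ membership: a case has the event when any of its reaction
#' PTs belongs to the SMQ.
#'
#' @param cohort a `faers_cohort`.
#' @param drugs ingredients to screen (default: all exposed).
#' @param map an `smq_map` (or a data.frame with pt, smq columns).
#' @param min_reports signal rule minimum report count.
#' @return a `signal_screen` data.frame with `level = "SMQ"`.
#' @export
screen_smq <- function(cohort, drugs = NULL, map, min_reports = 3L) {
  if (!inherits(map, "smq_map")) map <- as_smq_map(map)
  if (!nrow(map$map)) {
    return(screen_core(cohort, character(0),
                       data.table(caseid = character(), event = character()),
                       "SMQ", min_reports))
  }
  if (is.null(drugs)) drugs <- sort(unique(cohort$exposures$ingredient))
  drugs <- tolower(drugs)
  rx <- as.data.table(cohort$reactions)[, .(caseid, pt = tolower(trimws(pt)))]
  ev <- merge(rx, map$map, by = "pt", allow.cartesian = TRUE)
  ev <- unique(ev[, .(caseid, event = smq)])
  screen_core(cohort, drugs, ev, "SMQ", min_reports)
}
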