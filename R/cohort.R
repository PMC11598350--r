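#' Default DMARD drug dictionary
#'
#' Maps verbatim drug-name patterns to twenty canonical DMARD ingredients in
#' three classes: conventional synthetic (csDMARD), biologic (bDMARD) and
#' targeted synthetic (tsDMARD). Common US/EU brand names are included as
#' synonyms; matching is case-insensitive on normalized strings. Fully
#' user-overridable via [read_drug_dictionary()] or a hand-built data.frame.
#'
#' @return data.frame with columns `pattern`, `ingredient`, `class`.
#' @export
default_dmard_dictionary <- function() {
  ing <- function(ingredient, class, ...) {
    pats <- unique(c(ingredient, ...))
    data.frame(pattern = pats, ingredient = ingredient, class = class)
  }
  dict <- rbind(
    ing("methotrexate", "csDMARD", "trexall", "rheumatrex", "otrexup", "rasuvo"),
    ing("leflunomide", "csDMARD", "arava"),
    ing("sulfasalazine", "csDMARD", "azulfidine", "salazopyrin"),
    ing("hydroxychloroquine", "csDMARD", "plaquenil"),
    ing("adalimumab", "bDMARD", "humira"),
    ing("etanercept", "bDMARD", "enbrel"),
    ing("infliximab", "bDMARD", "remicade"),
    ing("golimumab", "bDMARD", "simponi"),
    ing("certolizumab pegol", "bDMARD", "certolizumab", "cimzia"),
    ing("anakinra", "bDMARD", "kineret"),
    ing("tocilizumab", "bDMARD", "actemra"),
    ing("sarilumab", "bDMARD", "kevzara"),
    ing("abatacept", "bDMARD", "orencia"),
    ing("rituximab", "bDMARD", "rituxan", "mabthera"),
    ing("iguratimod", "tsDMARD", "careram", "kolbet"),
    ing("upadacitinib", "tsDMARD", "rinvoq"),
    ing("baricitinib", "tsDMARD", "olumiant"),
    ing("tofacitinib", "tsDMARD", "xeljanz"),
    ing("filgotinib", "tsDMARD", "jyseleca"),
    ing("peficitinib", "tsDMARD", "smyraf")
  )
  validate_dictionary(dict)
}

validate_dictionary <- function(dict) {
  stopifnot(all(c("pattern", "ingredient", "class") %in% names(dict)))
  dict$pattern <- tolower(trimws(dict$pattern))
  dict$ingredient <- tolower(trimws(dict$ingredient))
  cls <- unique(dict[, c("ingredient", "class")])
  if (anyDuplicated(cls$ingredient)) {
    stop("dictionary maps an ingredient to more than one class: ",
         paste(cls$ingredient[duplicated(cls$ingredient)], collapse = ", "))
  }
  if (!all(dict$class %in% c("csDMARD", "bDMARD", "tsDMARD"))) {
    stop("dictionary class must be one of csDMARD, bDMARD, tsDMARD")
  }
  dict <- dict[!duplicated(dict$pattern), ]
  rownames(dict) <- NULL
  dict
}

#' Read a drug dictionary from a delimited file
#' @param path file with columns pattern, ingredient, class.
#' @param sep field delimiter.
#' @return validated dictionary data.frame.
#' @export
read_drug_dictionary <- function(path, sep = ",") {
  validate_dictionary(as.data.frame(fread(path, sep = sep, colClasses = "character")))
}

# salt/formulation/dose tokens stripped before matching
.strip_tokens <- c(
  "sodium", "hcl", "hydrochloride", "citrate", "sulfate", "sulphate",
  "acetate", "phosphate", "tablet", "tablets", "capsule", "capsules",
  "injection", "solution", "oral", "subcutaneous", "prefilled", "syringe",
  "pen", "mg", "mcg", "ml", "g"
)

normalize_drug_string <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("[^a-z0-9 ]", " ", x)
  x <- gsub("\\b[0-9]+(\\.[0-9]+)?\\s*(mg|mcg|g|ml|iu)\\b", " ", x)
  x <- gsub("\\b[0-9]+(\\.[0-9]+)?\\b", " ", x)
  pat <- paste0("\\b(", paste(.strip_tokens, collapse = "|"), ")\\b")
  x <- gsub(pat, " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Match verbatim drug names against a dictionary
#'
#' Verbatim strings are normalized (trimmed, case-folded, dose/salt and
#' formulation tokens stripped) and matched against dictionary patterns as
#' whole words. When several patterns match, the longest wins (ties broken
#' alphabetically), making the mapping deterministic.
#'
#' @param verbatim character vector of reported drug names.
#' @param dict dictionary data.frame (see [default_dmard_dictionary()]).
#' @return data.frame with one row per input: `verbatim`, `ingredient`,
#'   `class` (`NA` for no match).
#' @export
match_drug <- function(verbatim, dict = default_dmard_dictionary()) {
  dict <- validate_dictionary(dict)
  norm <- normalize_drug_string(verbatim)
  u <- unique(norm)
  ord <- order(-nchar(dict$pattern), dict$pattern)
  dict <- dict[ord, ]
  hit_ing <- rep(NA_character_, length(u))
  hit_cls <- rep(NA_character_, length(u))
  todo <- seq_along(u)
  for (k in seq_len(nrow(dict))) {
    if (!length(todo)) break
    re <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1",
                             dict$pattern[k]), "\\b")
    m <- grepl(re, u[todo])
    if (any(m)) {
      hit_ing[todo[m]] <- dict$ingredient[k]
      hit_cls[todo[m]] <- dict$class[k]
      todo <- todo[!m]
    }
  }
  idx <- match(norm, u)
  data.frame(verbatim = as.character(verbatim),
             ingredient = hit_ing[idx], class = hit_cls[idx])
}

subset_by_case <- function(tab, ids) {
  if (is.null(tab) || !"caseid" %in% names(tab)) return(data.table())
  as.data.table(tab)[caseid %in% ids]
}

#' Restrict cases to an indication and identify primary-suspect exposures
#'
#' Keeps deduplicated cases where any drug in the case carries one of the
#' indication preferred terms (default: rheumatoid arthritis), then maps the
#' primary-suspect (PS) drug through the dictionary. Cases whose PS drug does
#' not match the dictionary are retained with no exposure and form part of the
#' analysis background; cases with no reactions are dropped as non-analyzable.
#' If several PS entries map to different ingredients the case contributes to
#' each ingredient's exposed set.
#'
#' @param cases a `faers_cases` store from [assemble_cases()].
#' @param dict drug dictionary data.frame.
#' @param indication_terms character vector of indication PTs
#'   (case-insensitive).
#' @return object of class `faers_cohort` with elements `cases` (demographics,
#'   one row per case), `exposures` (caseid, ingredient, class, drug_seq; PS
#'   matches only), `reactions`, `drugs_matched` (all roles, matched
#'   ingredients), `outcomes`, `therapies`.
#' @export
build_cohort <- function(cases, dict = default_dmard_dictionary(),
                         indication_terms = "Rheumatoid arthritis") {
  stopifnot(inherits(cases, "faers_cases"))
  dict <- validate_dictionary(dict)
  terms <- tolower(trimws(indication_terms))

  indi <- cases$indications
  if (is.null(indi) || !nrow(indi)) stop("case store has no indication rows")
  ra_ids <- unique(indi$caseid[tolower(trimws(indi$indi_pt)) %in% terms])

  cs <- cases$cases[cases$cases$caseid %in% ra_ids & cases$cases$analyzable, ]
  dg <- cases$drugs[cases$drugs$caseid %in% cs$caseid, ]
  rx <- cases$reactions[cases$reactions$caseid %in% cs$caseid, ]

  mm <- match_drug(dg$drugname, dict)
  dg <- cbind(dg, mm[, c("ingredient", "class")])
  matched <- as.data.table(dg[!is.na(dg$ingredient), ])

  exposures <- matched[role_cod == "PS",
                       .(caseid, drug_seq, ingredient, class)]
  exposures <- unique(exposures, by = c("caseid", "ingredient", "drug_seq"))

  structure(list(
    cases = cs,
    exposures = exposures,
    reactions = as.data.table(rx),
    drugs_matched = matched,
    outcomes = subset_by_case(cases$outcomes, cs$caseid),
    therapies = subset_by_case(cases$therapies, cs$caseid),
    dictionary = dict,
    indication_terms = indication_terms
  ), class = "faers_cohort")
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("Indication cohort (", paste(x$indication_terms, collapse = ", "), "):\n",
      sep = "")
  cat("  ", nrow(x$cases), "analyzable cases;",
      length(unique(x$exposures$caseid)), "with a primary-suspect DMARD (",
      length(unique(x$exposures$ingredient)), "ingredients )\n")
  invisible(x)
}

#' Exposed and background case sets for one ingredient
#' @param cohort a `faers_cohort`.
#' @param ingredient canonical ingredient name.
#' @return list with character vectors `exposed` and `background` (disjoint,
#'   union = all cohort caseids).
#' @export
cohort_partition <- function(cohort, ingredient) {
  exp_ids <- unique(cohort$exposures$caseid[
    cohort$exposures$ingredient == tolower(ingredient)])
  all_ids <- cohort$cases$caseid
  list(exposed = intersect(all_ids, exp_ids),
       background = setdiff(all_ids, exp_ids))
}

#' Flag concomitant medications per case
#'
#' A watchlist ingredient is flagged for a case when it appears in a non-PS
#' role (SS, C, I), or — when `index_ingredient` is given — in a PS role for
#' an ingredient other than the index drug. A case's own primary-suspect
#' exposure is never counted as co-medication.
#'
#' @param cohort a `faers_cohort`.
#' @param watchlist character vector of canonical ingredient names.
#' @param index_ingredient optional index drug whose PS entries are excluded.
#' @return logical matrix, rows = cohort cases (rownames caseid), columns =
#'   watchlist ingredients.
#' @export
flag_concomitants <- function(cohort, watchlist, index_ingredient = NULL) {
  watchlist <- tolower(watchlist)
  ids <- cohort$cases$caseid
  out <- matrix(FALSE, nrow = length(ids), ncol = length(watchlist),
                dimnames = list(ids, watchlist))
  if (!length(watchlist)) return(out)
  md <- cohort$drugs_matched
  if (!nrow(md)) return(out)
  eligible <- md$role_cod != "PS" | is.na(md$role_cod)
  if (!is.null(index_ingredient)) {
    eligible <- eligible |
      (md$role_cod == "PS" & md$ingredient != tolower(index_ingredient))
  }
  md <- md[eligible & md$ingredient %in% watchlist, ]
  if (nrow(md)) {
    i <- match(md$caseid, ids)
    j <- match(md$ingredient, watchlist)
    keep <- !is.na(i)
    out[cbind(i[keep], j[keep])] <- TRUE
  }
  out
}
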