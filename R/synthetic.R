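#' Default synthetic drug mix
#'
#' Primary-suspect marginal probabilities for the twenty DMARDs, shaped like
#' the report-share distribution seen in malignancy reporting for the RA
#' population (methotrexate and adalimumab dominant; three recently approved
#' agents with no reports). Probabilities sum to the DMARD-exposed fraction
#' of the generated population (0.60); the remainder receives a non-DMARD
#' primary suspect and forms the screening background.
#'
#' @return data.frame: ingredient, class, p_ps.
#' @export
default_synth_drugs <- function() {
  d <- data.frame(
    ingredient = c("methotrexate", "adalimumab", "tofacitinib", "abatacept",
                   "etanercept", "upadacitinib", "baricitinib", "infliximab",
                   "golimumab", "certolizumab pegol", "tocilizumab",
                   "sarilumab", "rituximab", "anakinra", "hydroxychloroquine",
                   "leflunomide", "sulfasalazine", "iguratimod", "filgotinib",
                   "peficitinib"),
    class = c("csDMARD", "bDMARD", "tsDMARD", "bDMARD", "bDMARD", "tsDMARD",
              "tsDMARD", "bDMARD", "bDMARD", "bDMARD", "bDMARD", "bDMARD",
              "bDMARD", "bDMARD", "csDMARD", "csDMARD", "csDMARD",
              "tsDMARD", "tsDMARD", "tsDMARD"),
    weight = c(18, 16, 11, 9.7, 9.3, 5.5, 3.5, 3.4, 2.9, 2.8, 2.7, 1.6,
               2.2, 1.2, 3.4, 3.6, 3.2, 0, 0, 0)
  )
  d$p_ps <- 0.60 * d$weight / sum(d$weight)
  d$weight <- NULL
  d
}

#' Default synthetic event universe
#'
#' Malignancy preferred terms with low background reporting probabilities
#' plus common non-neoplastic reactions that fill out realistic reports.
#'
#' @return data.frame: pt, p_background, malignancy (logical).
#' @export
default_synth_events <- function() {
  mal <- c("Squamous cell carcinoma of skin", "Skin cancer", "Breast cancer",
           "Breast cancer female", "Lymphoproliferative disorder",
           "Diffuse large B-cell lymphoma", "Angiocentric lymphoma",
           "Lung neoplasm malignant", "Uterine leiomyoma", "Renal cancer",
           "Squamous cell carcinoma", "Metastases to liver",
           "Neoplasm malignant", "Neoplasm recurrence", "Lipoma",
           "Benign breast neoplasm", "Melanocytic naevus", "Brain neoplasm",
           "Benign neoplasm of thyroid gland", "Colon cancer", "Leukaemia",
           "Myelodysplastic syndrome", "Non-small cell lung cancer",
           "Acute myeloid leukaemia", "Metastases to bone marrow",
           "Acrochordon", "Pituitary tumour", "Basal cell carcinoma",
           "Prostate cancer", "Ovarian cancer", "Malignant melanoma",
           "Bladder cancer", "Pancreatic carcinoma", "Thyroid cancer",
           "Gastric cancer", "Hepatic cancer", "Tumour lysis syndrome",
           "Rhabdomyosarcoma", "Neuroendocrine carcinoma of the skin",
           "B-cell lymphoma")
  p_mal <- rep(c(0.010, 0.006, 0.004, 0.0025), 10)
  common <- c("Arthralgia", "Drug ineffective", "Nausea", "Headache",
              "Fatigue", "Rash", "Pyrexia", "Diarrhoea")
  p_common <- c(0.25, 0.20, 0.12, 0.10, 0.10, 0.08, 0.06, 0.06)
  data.frame(pt = c(mal, common),
             p_background = c(p_mal, p_common),
             malignancy = c(rep(TRUE, length(mal)), rep(FALSE, length(common))))
}

#' Default injected drug-event associations
#'
#' Ground-truth relative reporting rates (odds multipliers) for a handful of
#' drug-event pairs; every pair not listed generates at its background rate
#' (RR = 1).
#'
#' @return data.frame: drug, event, rr.
#' @export
default_synth_associations <- function() {
  data.frame(
    drug = c("methotrexate", "methotrexate", "upadacitinib", "upadacitinib",
             "baricitinib", "adalimumab", "tofacitinib"),
    event = c("Lymphoproliferative disorder", "Diffuse large B-cell lymphoma",
              "Squamous cell carcinoma of skin", "Skin cancer",
              "Breast cancer", "Uterine leiomyoma", "Skin cancer"),
    rr = c(5, 4, 5, 5, 5, 4, 3)
  )
}

#' Synthetic PT-to-SMQ mapping
#'
#' A synthetic stand-in for the licensed MedDRA SMQ content, assigning the
#' generator's malignancy PTs to the nine analysis SMQs by obvious clinical
#' grouping. Suitable only for exercising the SMQ-level machinery; it is not
#' MedDRA.
#'
#' @return data.frame: pt, smq.
#' @export
default_synth_smq_map <- function() {
  u <- default_smq_universe()
  grp <- list(
    "Malignancies" = c(
      "Squamous cell carcinoma of skin", "Skin cancer", "Breast cancer",
      "Breast cancer female", "Lymphoproliferative disorder",
      "Diffuse large B-cell lymphoma", "Angiocentric lymphoma",
      "Lung neoplasm malignant", "Renal cancer", "Squamous cell carcinoma",
      "Metastases to liver", "Neoplasm malignant", "Colon cancer",
      "Leukaemia", "Non-small cell lung cancer", "Acute myeloid leukaemia",
      "Metastases to bone marrow", "Basal cell carcinoma", "Prostate cancer",
      "Ovarian cancer", "Malignant melanoma", "Bladder cancer",
      "Pancreatic carcinoma", "Thyroid cancer", "Gastric cancer",
      "Hepatic cancer", "Rhabdomyosarcoma",
      "Neuroendocrine carcinoma of the skin", "B-cell lymphoma"),
    "Breast neoplasms, malignant and unspecified" =
      c("Breast cancer", "Breast cancer female"),
    "Skin neoplasms, malignant and unspecified" = c(
      "Squamous cell carcinoma of skin", "Skin cancer", "Basal cell carcinoma",
      "Malignant melanoma", "Neuroendocrine carcinoma of the skin"),
    "Premalignant disorders" = c("Myelodysplastic syndrome",
                                 "Melanocytic naevus"),
    "Malignant lymphomas" = c("Lymphoproliferative disorder",
                              "Diffuse large B-cell lymphoma",
                              "Angiocentric lymphoma", "B-cell lymphoma"),
    "Prostate neoplasms, malignant and unspecified" = "Prostate cancer",
    "Ovarian neoplasms, malignant and unspecified" = "Ovarian cancer",
    "Uterine and fallopian tube neoplasms, malignant and unspecified" =
      "Uterine leiomyoma",
    "Tumour lysis syndrome" = "Tumour lysis syndrome"
  )
  stopifnot(all(names(grp) %in% u))
  do.call(rbind, lapply(names(grp), function(s)
    data.frame(pt = grp[[s]], smq = s)))
}

#' Synthetic-report generator configuration
#'
#' Assembles and validates all knobs of the spontaneous-report generator.
#' The association semantics are odds-based: an exposed case draws each
#' event with its background odds multiplied by the pair's RR, so the ROR
#' is the natural estimand and ground truth is directly comparable to the
#' screen's estimates.
#'
#' @param seed integer seed; fully determines the output.
#' @param n_cases number of cases (before duplicate versions).
#' @param drugs data.frame ingredient/class/p_ps (see
#'   [default_synth_drugs()]).
#' @param events data.frame pt/p_background/malignancy.
#' @param associations data.frame drug/event/rr.
#' @param duplicate_rate fraction of cases emitted as two report versions.
#' @param deleted_rate fraction of cases listed in the deleted-case file.
#' @param ra_fraction fraction of cases carrying the rheumatoid-arthritis
#'   indication (the rest carry other autoimmune indications).
#' @param female_fraction probability of female sex.
#' @param missing named list of missingness rates: age, sex, event_dt,
#'   start_dt, country.
#' @param partial_date_rate fraction of emitted dates truncated to YYYYMM.
#' @param tto_meanlog,tto_sdlog named vectors (csDMARD, bDMARD, tsDMARD,
#'   other) of log-normal time-to-onset parameters, in years.
#' @param confounding add age/sex/co-medication effects on malignancy odds
#'   (exercises the adjusted-ROR module).
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_cases = 5000L,
                         drugs = default_synth_drugs(),
                         events = default_synth_events(),
                         associations = default_synth_associations(),
                         duplicate_rate = 0.17,
                         deleted_rate = 0.02,
                         ra_fraction = 0.90,
                         female_fraction = 0.72,
                         missing = list(age = 0.10, sex = 0.05,
                                        event_dt = 0.12, start_dt = 0.20,
                                        country = 0.02),
                         partial_date_rate = 0.05,
                         tto_meanlog = c(csDMARD = log(4.5), bDMARD = log(2.0),
                                         tsDMARD = log(1.2), other = log(2.0)),
                         tto_sdlog = c(csDMARD = 0.7, bDMARD = 0.7,
                                       tsDMARD = 0.7, other = 0.9),
                         confounding = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_cases >= 1L,
            all(c("ingredient", "class", "p_ps") %in% names(drugs)),
            all(c("pt", "p_background", "malignancy") %in% names(events)),
            all(c("drug", "event", "rr") %in% names(associations)))
  probs <- c(drugs$p_ps, events$p_background, duplicate_rate, deleted_rate,
             ra_fraction, female_fraction, unlist(missing), partial_date_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (sum(drugs$p_ps) > 1) stop("drug marginal probabilities sum above 1")
  if (any(associations$rr < 0)) stop("relative reporting rates must be >= 0")
  if (!all(tolower(associations$drug) %in% tolower(drugs$ingredient))) {
    stop("association refers to a drug absent from the drug mix")
  }
  if (!all(associations$event %in% events$pt)) {
    stop("association refers to an event absent from the event universe")
  }
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 drugs = drugs, events = events, associations = associations,
                 duplicate_rate = duplicate_rate, deleted_rate = deleted_rate,
                 ra_fraction = ra_fraction, female_fraction = female_fraction,
                 missing = missing, partial_date_rate = partial_date_rate,
                 tto_meanlog = tto_meanlog, tto_sdlog = tto_sdlog,
                 confounding = confounding),
            class = "synth_config")
}

fmt_date <- function(d) format(d, "%Y%m%d")

#' Generate FAERS-style quarterly tables with known ground truth
#'
#' Writes dollar-delimited DEMO, DRUG, REAC, INDI, OUTC and THER tables plus
#' a deleted-case list into `dir`, in exactly the dialect
#' [read_faers_quarter()] reads. Exposed cases draw each event with odds
#' multiplied by the configured RR; a configurable fraction of cases is
#' emitted as two report versions sharing the CASEID (perturbed FDA_DT,
#' distinct PRIMARYIDs); therapy start precedes the event date by a
#' log-normal class-specific time-to-onset draw. The returned ground truth
#' is never read by the pipeline.
#'
#' @param config a `synth_config`.
#' @param dir output directory (created if needed).
#' @return list: `paths` (named file paths, suitable for
#'   [read_faers_quarter()]), `truth` (per-case and per-pair ground truth).
#' @export
generate_faers <- function(config, dir = tempfile("synthfaers")) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_cases

  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  ## --- indications -------------------------------------------------------
  ra <- runif(n) < config$ra_fraction
  other_ind <- c("Psoriasis", "Crohn's disease", "Ulcerative colitis",
                 "Ankylosing spondylitis")
  indi_pt <- ifelse(ra, "Rheumatoid arthritis",
                    other_ind[sample.int(length(other_ind), n, replace = TRUE)])

  ## --- primary suspect drug ---------------------------------------------
  drugs <- config$drugs
  drugs$ingredient <- tolower(drugs$ingredient)
  p_other <- 1 - sum(drugs$p_ps)
  ps_idx <- sample.int(nrow(drugs) + 1L, n, replace = TRUE,
                       prob = c(drugs$p_ps, p_other))
  is_dmard <- ps_idx <= nrow(drugs)
  ps_ing <- ifelse(is_dmard, drugs$ingredient[ps_idx], "__other__")
  ps_class <- ifelse(is_dmard, drugs$class[ps_idx], "other")

  other_ps <- c("PREDNISONE", "NAPROXEN", "IBUPROFEN", "OMEPRAZOLE",
                "PARACETAMOL", "DICLOFENAC")
  dict <- default_dmard_dictionary()
  brand_of <- vapply(drugs$ingredient, function(ing) {
    p <- dict$pattern[dict$ingredient == ing & dict$pattern != ing]
    if (length(p)) p[1] else ing
  }, "")
  style <- runif(n)
  verbatim <- toupper(ps_ing)
  verbatim[is_dmard & style < 0.25] <-
    toupper(brand_of[match(ps_ing[is_dmard & style < 0.25], drugs$ingredient)])
  dosey <- is_dmard & style >= 0.85
  verbatim[dosey] <- paste0(toupper(ps_ing[dosey]), " SODIUM 25MG")
  verbatim[!is_dmard] <- other_ps[sample.int(length(other_ps),
                                             sum(!is_dmard), replace = TRUE)]

  ## --- demographics ------------------------------------------------------
  sex <- ifelse(runif(n) < config$female_fraction, "F", "M")
  age_years <- pmin(pmax(rnorm(n, 62, 13), 18), 95)
  unit_draw <- runif(n)
  age_cod <- ifelse(unit_draw < 0.90, "YR", ifelse(unit_draw < 0.95, "DEC", "MON"))
  age_val <- ifelse(age_cod == "YR", round(age_years),
                    ifelse(age_cod == "DEC", round(age_years / 10, 1),
                           round(age_years * 12)))
  countries <- c("US", "CA", "GB", "DE", "FR", "JP", "IT")
  country <- countries[sample.int(7, n, replace = TRUE,
                                  prob = c(0.40, 0.22, 0.10, 0.08, 0.07, 0.07, 0.06))]

  ## --- events (odds multiplied by RR for exposed cases) ------------------
  ev <- config$events
  assoc <- config$associations
  assoc$drug <- tolower(assoc$drug)
  conf_mult <- if (config$confounding) {
    exp(0.02 * (age_years - 62) + 0.25 * (sex == "F"))
  } else rep(1, n)

  reac_list <- vector("list", nrow(ev))
  event_mat_cols <- character(0)
  for (k in seq_len(nrow(ev))) {
    p <- ev$p_background[k]
    odds <- p / (1 - p)
    rrk <- rep(1, n)
    hit <- assoc$event == ev$pt[k]
    if (any(hit)) {
      for (j in which(hit)) {
        rrk[ps_ing == assoc$drug[j]] <- assoc$rr[j]
      }
    }
    o <- odds * rrk * (if (ev$malignancy[k]) conf_mult else 1)
    pk <- o / (1 + o)
    drawn <- runif(n) < pk
    if (any(drawn)) {
      reac_list[[k]] <- data.table(primaryid = primaryid[drawn],
                                   caseid = caseid[drawn], pt = ev$pt[k])
    }
  }
  reac <- data.table::rbindlist(reac_list)
  has_rx <- caseid %in% reac$caseid
  if (any(!has_rx)) {
    reac <- rbind(reac, data.table(primaryid = primaryid[!has_rx],
                                   caseid = caseid[!has_rx],
                                   pt = "Drug ineffective"))
  }
  setorder(reac, caseid, pt)
  has_mal <- caseid %in% reac$caseid[reac$pt %in% ev$pt[ev$malignancy]]

  ## --- concomitant medications ------------------------------------------
  boosted <- ps_class %in% c("bDMARD", "tsDMARD")
  conco_p <- cbind(
    methotrexate = ifelse(boosted, 0.30, 0.08),
    tofacitinib = 0.04,
    leflunomide = 0.07,
    sulfasalazine = 0.07)
  conco_draw <- matrix(runif(n * 4), n, 4) < conco_p
  self_col <- match(ps_ing, colnames(conco_p))
  has_self <- !is.na(self_col)
  conco_draw[cbind(which(has_self), self_col[has_self])] <- FALSE
  aux_conco <- runif(n) < 0.30  # non-DMARD co-medication

  drug_rows <- list(data.table(primaryid = primaryid, caseid = caseid,
                               drug_seq = 1L, role_cod = "PS",
                               drugname = verbatim))
  seq_counter <- rep(1L, n)
  for (w in colnames(conco_p)) {
    sel <- which(conco_draw[, w])
    if (length(sel)) {
      seq_counter[sel] <- seq_counter[sel] + 1L
      drug_rows[[length(drug_rows) + 1L]] <-
        data.table(primaryid = primaryid[sel], caseid = caseid[sel],
                   drug_seq = seq_counter[sel],
                   role_cod = sample(c("C", "SS"), length(sel),
                                     replace = TRUE, prob = c(0.7, 0.3)),
                   drugname = toupper(w))
    }
  }
  sel <- which(aux_conco)
  seq_counter[sel] <- seq_counter[sel] + 1L
  drug_rows[[length(drug_rows) + 1L]] <-
    data.table(primaryid = primaryid[sel], caseid = caseid[sel],
               drug_seq = seq_counter[sel], role_cod = "C",
               drugname = c("FOLIC ACID", "PREDNISONE")[
                 1L + (sel %% 2L)])
  drug <- data.table::rbindlist(drug_rows)
  setorder(drug, caseid, drug_seq)

  ## --- dates and therapy --------------------------------------------------
  window_start <- as.Date("2019-01-01")
  event_date <- window_start + sample.int(1826L, n, replace = TRUE) - 1L
  tto_class <- ifelse(ps_class %in% names(config$tto_meanlog), ps_class, "other")
  true_onset <- rlnorm(n, config$tto_meanlog[tto_class], config$tto_sdlog[tto_class])
  start_date <- event_date - round(true_onset * 365.25)
  fda_date <- event_date + sample(30:365, n, replace = TRUE)

  mask <- function(x, rate) {
    x[runif(length(x)) < rate] <- NA
    x
  }
  truncate_partial <- function(s) {
    sel <- !is.na(s) & runif(length(s)) < config$partial_date_rate
    s[sel] <- substr(s[sel], 1, 6)
    s
  }
  event_dt_out <- truncate_partial(mask(fmt_date(event_date), config$missing$event_dt))
  start_dt_out <- truncate_partial(mask(fmt_date(start_date), config$missing$start_dt))
  age_out <- mask(as.character(age_val), config$missing$age)
  age_cod_out <- ifelse(is.na(age_out), "", age_cod)
  sex_out <- mask(sex, config$missing$sex)
  country_out <- mask(country, config$missing$country)

  ther <- data.table(primaryid = primaryid, caseid = caseid,
                     dsg_drug_seq = 1L, start_dt = start_dt_out,
                     end_dt = NA_character_)

  ## --- outcomes -----------------------------------------------------------
  out_codes <- c("OT", "HO", "DE", "LT", "DS", "CA", "RI")
  out_p <- c(0.52, 0.23, 0.07, 0.05, 0.03, 0.02, 0.08)
  oc1 <- out_codes[sample.int(7, n, replace = TRUE, prob = out_p)]
  extra <- runif(n) < 0.25
  oc2 <- out_codes[sample.int(7, n, replace = TRUE, prob = out_p)]
  outc <- rbind(
    data.table(primaryid = primaryid, caseid = caseid, outc_cod = oc1),
    data.table(primaryid = primaryid[extra], caseid = caseid[extra],
               outc_cod = oc2[extra]))
  outc <- unique(outc)
  setorder(outc, caseid, outc_cod)

  ## --- tables at version 1 -----------------------------------------------
  demo <- data.table(primaryid = primaryid, caseid = caseid,
                     fda_dt = fmt_date(fda_date), event_dt = event_dt_out,
                     sex = sex_out, age = age_out, age_cod = age_cod_out,
                     occr_country = country_out)
  indi <- data.table(primaryid = primaryid, caseid = caseid,
                     indi_drug_seq = 1L, indi_pt = indi_pt)

  ## --- duplicate versions -------------------------------------------------
  dup <- runif(n) < config$duplicate_rate
  dup_ids <- caseid[dup]
  same_dt <- runif(sum(dup)) < 0.20   # ties broken by higher PRIMARYID
  dup_fda <- fda_date[dup] + ifelse(same_dt, 0L, sample(30:200, sum(dup), replace = TRUE))
  dup_pid <- paste0(dup_ids, "2")
  add_version <- function(tab) {
    extra <- tab[caseid %in% dup_ids]
    extra[, primaryid := paste0(caseid, "2")]
    rbind(tab, extra)
  }
  demo2 <- demo[caseid %in% dup_ids]
  demo2[, primaryid := dup_pid[match(caseid, dup_ids)]]
  demo2[, fda_dt := fmt_date(dup_fda)[match(caseid, dup_ids)]]
  demo <- rbind(demo, demo2)
  drug <- add_version(drug); reac <- add_version(reac)
  indi <- add_version(indi); outc <- add_version(outc)
  ther <- add_version(ther)
  for (tab in list(demo, drug, reac, indi, outc, ther)) setorder(tab, caseid, primaryid)

  ## --- deleted cases ------------------------------------------------------
  deleted <- caseid[runif(n) < config$deleted_rate]

  ## --- write --------------------------------------------------------------
  paths <- list(demo = file.path(dir, "DEMO.txt"),
                drug = file.path(dir, "DRUG.txt"),
                reac = file.path(dir, "REAC.txt"),
                indi = file.path(dir, "INDI.txt"),
                outc = file.path(dir, "OUTC.txt"),
                ther = file.path(dir, "THER.txt"),
                deleted = file.path(dir, "DELETED.txt"))
  wr <- function(tab, path) fwrite(tab, path, sep = "$", quote = FALSE, na = "")
  wr(demo, paths$demo); wr(drug, paths$drug); wr(reac, paths$reac)
  wr(indi, paths$indi); wr(outc, paths$outc); wr(ther, paths$ther)
  writeLines(c("caseid", deleted), paths$deleted)

  # version 2 always wins: either its FDA_DT is later, or the tie is broken
  # by its higher PRIMARYID
  surviving_pid <- ifelse(caseid %in% dup_ids,
                          paste0(caseid, "2"), paste0(caseid, "1"))

  truth <- list(
    cases = data.frame(caseid = caseid, ps_ingredient = ps_ing,
                       ps_class = ps_class, ra = ra, sex = sex,
                       age_years = age_years, has_malignancy = has_mal,
                       true_onset_years = true_onset,
                       n_versions = 1L + (caseid %in% dup_ids),
                       surviving_primaryid = surviving_pid,
                       deleted = caseid %in% deleted),
    associations = assoc,
    config = config
  )
  list(paths = paths, truth = truth, dir = dir)
}

#' Run the full pipeline on generated data and score recovery
#'
#' Generates a dataset, runs ingestion, deduplication, cohort restriction
#' and the PT-level screen, then compares the result with the generator's
#' ground truth: sensitivity among injected pairs whose expected co-report
#' count is at least `min_expected_a`, false-signal fraction among RR = 1
#' pairs, mean log-scale ROR bias over injected pairs, and deduplication
#' recovery on the duplicate clusters.
#'
#' @param config a `synth_config`.
#' @param dir scratch directory for the generated tables.
#' @param min_expected_a expected-count threshold for the sensitivity
#'   denominator.
#' @return list of recovery metrics plus the intermediate objects.
#' @export
roundtrip_check <- function(config, dir = tempfile("synthrt"),
                            min_expected_a = 20) {
  gen <- generate_faers(config, dir)
  q <- read_faers_quarter(gen$paths, quarter = "SYNTH")
  cases <- assemble_cases(q)
  cohort <- build_cohort(cases)
  ev <- config$events
  mal_pts <- ev$pt[ev$malignancy]
  scr <- screen_signals(cohort, events = mal_pts)

  ## expected a per injected pair, among RA, non-deleted cases
  tr <- gen$truth$cases
  alive <- tr[!tr$deleted & tr$ra, ]
  assoc <- gen$truth$associations
  assoc$expected_a <- vapply(seq_len(nrow(assoc)), function(j) {
    p <- ev$p_background[ev$pt == assoc$event[j]]
    o <- p / (1 - p) * assoc$rr[j]
    sum(alive$ps_ingredient == assoc$drug[j]) * o / (1 + o)
  }, 0)

  key <- function(d, e) paste(tolower(d), tolower(e), sep = "\r")
  scr_key <- key(scr$drug, scr$event)
  inj <- assoc[assoc$rr > 1, ]
  eligible <- inj[inj$expected_a >= min_expected_a, ]
  found <- vapply(seq_len(nrow(eligible)), function(j) {
    i <- match(key(eligible$drug[j], eligible$event[j]), scr_key)
    !is.na(i) && scr$signal[i]
  }, TRUE)
  sens <- if (nrow(eligible)) mean(found) else NA_real_

  null_rows <- !(scr_key %in% key(inj$drug, inj$event))
  false_rate <- if (any(null_rows)) mean(scr$signal[null_rows]) else NA_real_

  inj_rows <- match(key(inj$drug, inj$event), scr_key)
  okr <- !is.na(inj_rows) & !is.na(scr$ror[inj_rows])
  ror_bias <- if (any(okr)) {
    mean(log(scr$ror[inj_rows[okr]] / inj$rr[okr]))
  } else NA_real_

  surv <- cases$dedup$survivors
  tr_alive <- tr[!tr$deleted, ]
  m <- match(tr_alive$caseid, surv$caseid)
  dedup_ok <- !anyNA(m) &&
    all(surv$primaryid[m] == tr_alive$surviving_primaryid)

  list(sensitivity = sens,
       n_eligible_injected = nrow(eligible),
       false_signal_rate = false_rate,
       n_null_pairs = sum(null_rows),
       ror_log_bias = ror_bias,
       dedup_recovered = dedup_ok,
       screen = scr, cohort = cohort, truth = gen$truth)
}

#' Simulate a confounded case-level dataset
#'
#' Draws a regression-style dataset with a known conditional odds ratio for
#' the exposure: age, sex and a co-medication flag shift both the exposure
#' probability and the outcome odds, so the crude odds ratio is biased while
#' the covariate-adjusted estimate targets `true_or`. Used to validate the
#' adjusted-ROR estimator.
#'
#' @param n rows.
#' @param true_or conditional odds ratio of exposure on outcome.
#' @param seed integer seed.
#' @param base_logit outcome intercept on the logit scale.
#' @return data.frame with columns y, x_drug, age_years, sex,
#'   conco_methotrexate (compatible with [fit_adjusted()]).
#' @export
simulate_confounded <- function(n = 20000L, true_or = 2.5, seed = 1L,
                                base_logit = -3) {
  set.seed(seed)
  age <- pmin(pmax(rnorm(n, 62, 12), 18), 95)
  sex <- rbinom(n, 1, 0.7)
  conco <- rbinom(n, 1, stats::plogis(-1.2 + 0.03 * (age - 62)))
  p_x <- stats::plogis(-1.5 + 0.05 * (age - 62) + 0.4 * sex + 0.9 * conco)
  x <- rbinom(n, 1, p_x)
  p_y <- stats::plogis(base_logit + log(true_or) * x + 0.05 * (age - 62) +
                         0.3 * sex + 0.7 * conco)
  y <- rbinom(n, 1, p_y)
  ds <- data.frame(y = y, x_drug = x, age_years = age, sex = sex,
                   conco_methotrexate = conco)
  attr(ds, "drug") <- "simulated"
  attr(ds, "covariates") <- c("age_years", "sex", "conco_methotrexate")
  class(ds) <- c("pv_regression_data", "data.frame")
  ds
}
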