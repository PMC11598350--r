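#' Drug-event 2x2 contingency table
#'
#' Counts cohort cases at report level: a case contributes once to cell `a`
#' even when the event PT is recorded several times on the report. The
#' background is every other case in the cohort, so the four cells always sum
#' to the cohort size.
#'
#' @param cohort a `faers_cohort`.
#' @param drug canonical ingredient name.
#' @param event a preferred term, or a character vector of PTs treated as one
#'   composite event (any member PT counts).
#' @return object of class `contingency_2x2`: integer `a`, `b`, `c`, `d`.
#' @export
build_table <- function(cohort, drug, event) {
  stopifnot(nrow(cohort$cases) > 0)
  part <- cohort_partition(cohort, drug)
  ev <- tolower(trimws(event))
  event_ids <- unique(cohort$reactions$caseid[
    tolower(trimws(cohort$reactions$pt)) %in% ev])
  n <- nrow(cohort$cases)
  a <- length(intersect(part$exposed, event_ids))
  b <- length(part$exposed) - a
  c_ <- length(intersect(part$background, event_ids))
  d <- n - a - b - c_
  structure(list(a = a, b = b, c = c_, d = d,
                 drug = tolower(drug),
                 event = paste(event, collapse = " | ")),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "other"), c("event", "no event")))
  cat("2x2 table for", x$drug, "x", x$event, "\n")
  print(m)
  invisible(x)
}

#' Reporting odds ratio with Wald 95\% interval
#'
#' ROR = (a d)/(b c); the interval is computed on the natural-log scale,
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell makes
#' the estimate and bounds undefined (`NA`); no continuity correction is
#' applied, since the signal rule's minimum-report requirement makes
#' corrected small-cell RORs irrelevant and a correction would silently
#' shift reported estimates.
#'
#' @param a,b,c,d cell counts (vectors allowed); alternatively pass a
#'   `contingency_2x2` as `a`.
#' @return data.frame with `ror`, `ror025`, `ror975`.
#' @export
compute_ror <- function(a, b = NULL, c = NULL, d = NULL) {
  if (inherits(a, "contingency_2x2")) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ror025 <- ror975 <- rep(NA_real_, length(a))
  ror[ok] <- (a[ok] * d[ok]) / (b[ok] * c[ok])
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  ror025[ok] <- exp(log(ror[ok]) - 1.96 * se)
  ror975[ok] <- exp(log(ror[ok]) + 1.96 * se)
  data.frame(ror = ror, ror025 = ror025, ror975 = ror975)
}

#' Shrinkage information component with lower credibility bound
#'
#' IC = log2((a + 0.5) / (E + 0.5)) where E = (a+b)(a+c)/N is the count
#' expected under independence. The lower end of the 95\% credibility
#' interval uses the Noren approximation
#' IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2).
#' The +0.5 shrinkage keeps every cell defined, including a = 0.
#'
#' @param a,b,c,d cell counts (vectors allowed); alternatively a
#'   `contingency_2x2` as `a`.
#' @return data.frame with `ic`, `ic025` (both in bits).
#' @export
compute_ic <- function(a, b = NULL, c = NULL, d = NULL) {
  if (inherits(a, "contingency_2x2")) {
    t <- a; a <- t$a; b <- t$b; c <- t$c; d <- t$d
  }
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  n <- a + b + c + d
  stopifnot(all(n > 0))
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  data.frame(ic = ic, ic025 = ic025)
}

#' Signal classification rule
#'
#' A drug-event pair is a signal when it has at least `min_reports` reports
#' and both interval bounds clear their thresholds strictly: ROR025 > 1 and
#' IC025 > 0. An undefined ROR025 (zero cell) is never a signal.
#'
#' @param n number of co-reports (cell `a`).
#' @param ror025 lower Wald bound of the ROR.
#' @param ic025 lower credibility bound of the IC.
#' @param min_reports minimum report count (default 3).
#' @return logical vector.
#' @export
classify_signal <- function(n, ror025, ic025, min_reports = 3L) {
  out <- !is.na(ror025) & !is.na(ic025) &
    n >= min_reports & ror025 > 1 & ic025 > 0
  out & !is.na(out)
}

# internal: vectorised screen over an exposure table and a per-case event
# membership table (caseid, event). Returns one row per (drug,event) with a>=1.
screen_core <- function(cohort, drugs, event_tab, level, min_reports = 3L) {
  n_total <- nrow(cohort$cases)
  exps <- unique(cohort$exposures[, .(caseid, ingredient, class)])
  exps <- exps[ingredient %in% drugs]
  ev <- unique(as.data.table(event_tab)[, .(caseid, event)])
  ev <- ev[caseid %in% cohort$cases$caseid]

  n_drug <- exps[, .(n_drug = data.table::uniqueN(caseid)), by = .(ingredient, class)]
  n_event <- ev[, .(n_event = .N), by = event]

  j <- merge(exps[, .(caseid, ingredient, class)], ev,
             by = "caseid", allow.cartesian = TRUE)
  if (!nrow(j)) {
    res <- data.table(drug = character(), class = character(),
                      event = character(), a = integer())
  } else {
    res <- j[, .(a = data.table::uniqueN(caseid)), by = .(drug = ingredient, class, event)]
  }
  res <- merge(res, n_drug, by.x = c("drug", "class"),
               by.y = c("ingredient", "class"))
  res <- merge(res, n_event, by = "event")
  res[, `:=`(b = n_drug - a, c = n_event - a)]
  res[, d := n_total - a - b - c]
  ror <- compute_ror(res$a, res$b, res$c, res$d)
  ic <- compute_ic(res$a, res$b, res$c, res$d)
  out <- cbind(
    data.frame(drug = res$drug, class = res$class, event = res$event,
               level = rep(level, nrow(res)),
               a = res$a, b = res$b, c = res$c, d = res$d),
    ror, ic)
  out$signal <- classify_signal(out$a, out$ror025, out$ic025, min_reports)
  out <- out[order(out$drug, out$event), ]
  rownames(out) <- NULL
  class(out) <- c("signal_screen", "data.frame")
  attr(out, "n_cohort") <- n_total
  attr(out, "min_reports") <- min_reports
  out
}

#' Screen drug-event pairs at preferred-term level
#'
#' Builds every 2x2 table of an exposure against an event PT within the
#' cohort background and computes ROR, IC, their lower bounds and the signal
#' flag. Only pairs with at least one co-report are returned; output order is
#' deterministic (drug, then event).
#'
#' @param cohort a `faers_cohort`.
#' @param drugs ingredients to screen; default all dictionary ingredients
#'   with at least one exposed case.
#' @param events event universe: character vector of PTs (e.g. all PTs under
#'   a MedDRA SOC, supplied by the user); default all observed PTs.
#' @param min_reports signal rule minimum report count.
#' @return a `signal_screen` data.frame with columns drug, class, event,
#'   level, a, b, c, d, ror, ror025, ror975, ic, ic025, signal.
#' @export
screen_signals <- function(cohort, drugs = NULL, events = NULL, min_reports = 3L) {
  if (is.null(drugs)) drugs <- sort(unique(cohort$exposures$ingredient))
  drugs <- tolower(drugs)
  if (!length(drugs)) {
    return(screen_core(cohort, character(0),
                       data.table(caseid = character(), event = character()),
                       "PT", min_reports))
  }
  rx <- as.data.table(cohort$reactions)[, .(caseid, event = tolower(trimws(pt)))]
  if (!is.null(events)) {
    events <- tolower(trimws(events))
    if (!length(events)) warning("empty event universe; no pairs screened")
    rx <- rx[event %in% events]
  }
  screen_core(cohort, drugs, rx, "PT", min_reports)
}

#' @export
print.signal_screen <- function(x, n = 10L, ...) {
  cat("Disproportionality screen (level ", unique(x$level), "): ",
      nrow(x), " drug-event pairs, ", sum(x$signal), " signals; cohort N = ",
      attr(x, "n_cohort"), "\n", sep = "")
  sig <- x[x$signal, ]
  if (nrow(sig)) {
    sig <- sig[order(-sig$ic025), ]
    cat("Top signals by IC025:\n")
    print(utils::head(
      data.frame(drug = sig$drug, event = sig$event, a = sig$a,
                 ROR = round(sig$ror, 2), ROR025 = round(sig$ror025, 2),
                 IC = round(sig$ic, 2), IC025 = round(sig$ic025, 2)), n),
      row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.signal_screen <- function(object, ...) {
  s <- object[object$signal, ]
  out <- list(
    level = unique(object$level),
    n_pairs = nrow(object),
    n_signals = nrow(s),
    signals_by_drug = if (nrow(s)) sort(table(s$drug), decreasing = TRUE) else table(character(0)),
    n_cohort = attr(object, "n_cohort"))
  class(out) <- "summary.signal_screen"
  out
}

#' @export
print.summary.signal_screen <- function(x, ...) {
  cat("Signal screen at", x$level, "level:", x$n_signals, "signals among",
      x$n_pairs, "pairs (cohort N =", x$n_cohort, ")\n")
  if (length(x$signals_by_drug)) {
    cat("Signals per drug:\n")
    print(x$signals_by_drug)
  }
  invisible(x)
}
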