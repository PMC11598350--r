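#' Default concomitant-medication watchlist
#'
#' The four frequently co-administered DMARDs with label-documented
#' malignancy potential that enter the adjusted models as confounder flags.
#' @return character vector.
#' @export
default_conco_watchlist <- function() {
  c("methotrexate", "tofacitinib", "leflunomide", "sulfasalazine")
}

#' Build the regression dataset for one index drug
#'
#' One row per cohort case whose primary-suspect drug is any dictionary
#' DMARD (the sensitivity-analysis population). The outcome `y` is 1 when
#' any reaction PT falls in the event universe; `x_drug` is 1 when the PS
#' exposure includes the index drug. Covariates: `age_years`, `sex` (F = 1,
#' M = 0, unknown missing) and one 0/1 flag per watchlist co-medication
#' (the index drug, if watched, is removed from the covariate list; a case's
#' own PS exposure never counts as co-medication).
#'
#' @param cohort a `faers_cohort`.
#' @param drug index ingredient.
#' @param event_universe character vector of event PTs defining the outcome.
#' @param watchlist concomitant ingredients (default
#'   [default_conco_watchlist()]).
#' @return data.frame of class `pv_regression_data` with attributes
#'   `drug` and `covariates`.
#' @export
build_regression_dataset <- function(cohort, drug,
                                     event_universe,
                                     watchlist = default_conco_watchlist()) {
  drug <- tolower(drug)
  watchlist <- setdiff(tolower(watchlist), drug)
  dmard_ids <- unique(cohort$exposures$caseid)
  cs <- cohort$cases[cohort$cases$caseid %in% dmard_ids, ]
  if (!nrow(cs)) stop("no cases with a primary-suspect DMARD exposure")

  ev <- tolower(trimws(event_universe))
  event_ids <- unique(cohort$reactions$caseid[
    tolower(trimws(cohort$reactions$pt)) %in% ev])
  y <- as.integer(cs$caseid %in% event_ids)
  if (length(unique(y)) < 2L) stop("degenerate outcome: all y identical")

  exp_ids <- unique(cohort$exposures$caseid[cohort$exposures$ingredient == drug])
  x_drug <- as.integer(cs$caseid %in% exp_ids)

  sex01 <- ifelse(cs$sex == "F", 1L, ifelse(cs$sex == "M", 0L, NA_integer_))

  ds <- data.frame(caseid = cs$caseid, y = y, x_drug = x_drug,
                   age_years = cs$age_years, sex = sex01)
  if (length(watchlist)) {
    fl <- flag_concomitants(cohort, watchlist, index_ingredient = drug)
    fl <- fl[match(cs$caseid, rownames(fl)), , drop = FALSE]
    colnames(fl) <- paste0("conco_", gsub("[^a-z0-9]+", "_", watchlist))
    ds <- cbind(ds, as.data.frame(fl + 0L))
  }
  attr(ds, "drug") <- drug
  attr(ds, "covariates") <- setdiff(names(ds), c("caseid", "y", "x_drug"))
  class(ds) <- c("pv_regression_data", "data.frame")
  ds
}

#' Fit the adjusted logistic model
#'
#' Maximum-likelihood logistic regression of the event indicator on drug
#' exposure plus covariates, by iteratively reweighted least squares
#' (`stats::glm`, binomial family; convergence tolerance `tol` on deviance
#' change, at most `max_iter` iterations). Missing covariates are handled by
#' complete-case analysis with the number of excluded rows reported.
#' Covariate columns that are constant after row exclusion are dropped to
#' keep the design full rank. The adjusted reporting odds ratio is
#' `exp(beta_drug)` with a Wald 95\% interval.
#'
#' @param ds a `pv_regression_data` (or any data.frame with `y`, `x_drug`
#'   and covariate columns).
#' @param covariates covariate column names; default every column except
#'   `caseid`, `y`, `x_drug`.
#' @param tol IRLS convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return object of class `adjusted_fit`: coefficients, standard errors,
#'   `adjusted_ror`, `ci95`, `n_used`, `n_dropped`, `converged`,
#'   `separation` flag and the underlying `glm` fit.
#' @export
fit_adjusted <- function(ds, covariates = NULL, tol = 1e-8, max_iter = 100L) {
  if (is.null(covariates)) {
    covariates <- setdiff(names(ds), c("caseid", "y", "x_drug"))
  }
  stopifnot(all(c("y", "x_drug") %in% names(ds)))
  cols <- c("y", "x_drug", covariates)
  dat <- as.data.frame(ds)[, cols, drop = FALSE]
  cc <- stats::complete.cases(dat)
  n_dropped <- sum(!cc)
  dat <- dat[cc, , drop = FALSE]
  if (length(unique(dat$y)) < 2L) stop("degenerate outcome: all y identical")
  if (length(unique(dat$x_drug)) < 2L) {
    stop("degenerate exposure: x_drug constant after complete-case restriction")
  }
  keep <- vapply(covariates, function(v) length(unique(dat[[v]])) > 1L, TRUE)
  dropped_cov <- covariates[!keep]
  covariates <- covariates[keep]

  fml <- stats::reformulate(c("x_drug", covariates), response = "y")
  fit <- stats::glm(fml, data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = tol, maxit = max_iter))
  sm <- summary(fit)
  beta <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  p <- stats::fitted(fit)
  separation <- any(p < 1e-10 | p > 1 - 1e-10) && any(abs(beta) > 10)

  b <- beta[["x_drug"]]
  s <- se[["x_drug"]]
  structure(list(
    beta = beta, se = se,
    adjusted_ror = exp(b),
    ci95 = exp(b + c(-1, 1) * 1.96 * s),
    n_used = nrow(dat), n_dropped = n_dropped,
    dropped_covariates = dropped_cov,
    converged = fit$converged, separation = separation,
    drug = attr(ds, "drug"), glm = fit
  ), class = "adjusted_fit")
}

#' @export
print.adjusted_fit <- function(x, ...) {
  cat("Adjusted reporting odds ratio",
      if (!is.null(x$drug)) paste0("for ", x$drug), "\n")
  cat(sprintf("  adj ROR = %.3f (95%% CI %.3f-%.3f), n = %d (%d dropped)\n",
              x$adjusted_ror, x$ci95[1], x$ci95[2], x$n_used, x$n_dropped))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  if (x$separation) cat("  WARNING: separation detected\n")
  invisible(x)
}

#' @export
coef.adjusted_fit <- function(object, ...) object$beta

#' @export
confint.adjusted_fit <- function(object, parm = NULL, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta - z * object$se, object$beta + z * object$se)
  colnames(ci) <- paste0(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, " %")
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.adjusted_fit <- function(object, ...) {
  tab <- cbind(estimate = object$beta, se = object$se,
               or = exp(object$beta),
               or_low = exp(object$beta - 1.96 * object$se),
               or_high = exp(object$beta + 1.96 * object$se))
  out <- list(coefficients = tab, adjusted_ror = object$adjusted_ror,
              ci95 = object$ci95, n_used = object$n_used,
              converged = object$converged, drug = object$drug)
  class(out) <- "summary.adjusted_fit"
  out
}

#' @export
print.summary.adjusted_fit <- function(x, ...) {
  cat("Logistic model for", if (is.null(x$drug)) "exposure" else x$drug,
      "- n =", x$n_used, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Crude and adjusted RORs for several drugs
#'
#' For each index drug: the crude ROR from the 2x2 table of exposure against
#' the pooled event indicator on the DMARD-restricted population, and the
#' covariate-adjusted ROR from the logistic model. Per-drug failures (zero
#' exposed cases, degenerate outcome) yield an NA row and the run continues.
#'
#' @param cohort a `faers_cohort`.
#' @param drugs ingredients (default all exposed).
#' @param event_universe event PT set (outcome definition).
#' @param watchlist concomitant confounder ingredients.
#' @return data.frame: drug, n_exposed, crude_ror, crude_low, crude_high,
#'   adj_ror, adj_low, adj_high, n_used, converged.
#' @export
adjusted_screen <- function(cohort, drugs = NULL, event_universe,
                            watchlist = default_conco_watchlist()) {
  if (is.null(drugs)) drugs <- sort(unique(cohort$exposures$ingredient))
  drugs <- tolower(drugs)
  rows <- lapply(drugs, function(dr) {
    base <- data.frame(drug = dr, n_exposed = NA_integer_,
                       crude_ror = NA_real_, crude_low = NA_real_,
                       crude_high = NA_real_, adj_ror = NA_real_,
                       adj_low = NA_real_, adj_high = NA_real_,
                       n_used = NA_integer_, converged = NA)
    tryCatch({
      ds <- build_regression_dataset(cohort, dr, event_universe, watchlist)
      base$n_exposed <- sum(ds$x_drug)
      a <- sum(ds$y == 1 & ds$x_drug == 1)
      b <- sum(ds$y == 0 & ds$x_drug == 1)
      cc <- sum(ds$y == 1 & ds$x_drug == 0)
      dd <- sum(ds$y == 0 & ds$x_drug == 0)
      cr <- compute_ror(a, b, cc, dd)
      base$crude_ror <- cr$ror; base$crude_low <- cr$ror025
      base$crude_high <- cr$ror975
      fit <- fit_adjusted(ds)
      base$adj_ror <- fit$adjusted_ror
      base$adj_low <- fit$ci95[1]; base$adj_high <- fit$ci95[2]
      base$n_used <- fit$n_used; base$converged <- fit$converged
      base
    }, error = function(e) base)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
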