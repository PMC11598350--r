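#' Pipeline configuration
#'
#' Collects and validates everything [run_pipeline()] needs: either input
#' paths for real quarterly tables or a synthetic-data configuration, the
#' drug dictionary, the event universe, the optional SMQ map, and output
#' options.
#'
#' @param input_paths named list of table paths (as for
#'   [read_faers_quarter()]), or `NULL` when `synth` is given.
#' @param synth a `synth_config` used to generate the inputs.
#' @param dictionary drug dictionary data.frame.
#' @param indication_terms indication PT(s) defining the cohort.
#' @param event_universe character vector of event PTs for the PT-level
#'   screen and the adjusted-model outcome.
#' @param smq_map an `smq_map`, a data.frame (pt, smq) or a file path;
#'   `NULL` skips the SMQ level unless `level` demands it.
#' @param watchlist concomitant confounder ingredients.
#' @param level `"pt"`, `"smq"` or `"both"`.
#' @param min_reports signal rule minimum report count.
#' @param out_dir output directory for stage tables.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_paths = NULL, synth = NULL,
                            dictionary = default_dmard_dictionary(),
                            indication_terms = "Rheumatoid arthritis",
                            event_universe = NULL,
                            smq_map = NULL,
                            watchlist = default_conco_watchlist(),
                            level = c("both", "pt", "smq"),
                            min_reports = 3L,
                            out_dir = tempfile("pvrun")) {
  level <- match.arg(level)
  if (is.null(input_paths) && is.null(synth)) {
    stop("either input_paths or a synth config is required")
  }
  if (min_reports < 1L) stop("min_reports must be >= 1")
  if (level %in% c("both", "smq") && is.null(smq_map)) {
    stop("missing input: smq_map is required when level = ", level)
  }
  if (is.character(smq_map)) smq_map <- load_smq_map(smq_map)
  if (!is.null(smq_map) && !inherits(smq_map, "smq_map")) {
    smq_map <- as_smq_map(smq_map)
  }
  structure(list(input_paths = input_paths, synth = synth,
                 dictionary = validate_dictionary(dictionary),
                 indication_terms = indication_terms,
                 event_universe = event_universe, smq_map = smq_map,
                 watchlist = watchlist, level = level,
                 min_reports = as.integer(min_reports), out_dir = out_dir),
            class = "pipeline_config")
}

write_stage <- function(obj, name, out_dir, counts, n_rows) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  fwrite(as.data.frame(obj), path, sep = "\t", quote = FALSE, na = "NA")
  counts[[name]] <- n_rows
  list(path = path, counts = counts)
}

#' Run the full screening pipeline
#'
#' Stage order: ingest, deduplicate, cohort restriction, PT-level screen,
#' SMQ-level screen, adjusted RORs, time-to-onset, descriptives. Every stage
#' writes a tab-delimited table into the output directory together with a
#' row-count log; a manifest records the parameters, the synthetic seed (if
#' any) and an md5 content hash per output file. A stage failure raises an
#' error naming the stage; tables already written are retained.
#'
#' @param config a `pipeline_config`.
#' @return invisible list: `out_dir`, `tables` (paths), `counts`,
#'   `manifest`, plus the in-memory `cohort` and result objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  tables <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  paths <- config$input_paths
  if (is.null(paths)) {
    gen <- stage("synthesize", generate_faers(config$synth,
                                              file.path(out_dir, "synth_input")))
    paths <- gen$paths
  }
  q <- stage("ingest", read_faers_quarter(paths))
  counts$ingest_versions <- nrow(q$demo)

  dedup <- stage("dedup", deduplicate_reports(q$demo, q$deleted_caseids))
  counts$dedup_survivors <- dedup$n_survivors
  cases <- stage("assemble", assemble_cases(q, dedup))

  cohort <- stage("cohort", build_cohort(cases, config$dictionary,
                                         config$indication_terms))
  counts$cohort_cases <- nrow(cohort$cases)
  counts$cohort_exposed <- length(unique(cohort$exposures$caseid))
  s <- write_stage(cohort$cases, "cohort_cases", out_dir, counts,
                   nrow(cohort$cases))
  tables$cohort_cases <- s$path; counts <- s$counts

  screen_pt <- NULL
  if (config$level %in% c("both", "pt")) {
    screen_pt <- stage("screen_pt",
                       screen_signals(cohort, events = config$event_universe,
                                      min_reports = config$min_reports))
    s <- write_stage(screen_pt, "signals_pt", out_dir, counts, nrow(screen_pt))
    tables$signals_pt <- s$path; counts <- s$counts
  }

  screen_smq_res <- NULL
  if (config$level %in% c("both", "smq")) {
    if (is.null(config$smq_map)) stop("pipeline stage 'screen_smq' failed: missing input smq_map")
    screen_smq_res <- stage("screen_smq",
                            screen_smq(cohort, map = config$smq_map,
                                       min_reports = config$min_reports))
    s <- write_stage(screen_smq_res, "signals_smq", out_dir, counts,
                     nrow(screen_smq_res))
    tables$signals_smq <- s$path; counts <- s$counts
  }

  events <- config$event_universe
  if (is.null(events)) events <- unique(cohort$reactions$pt)
  adj <- stage("adjusted", adjusted_screen(cohort, event_universe = events,
                                           watchlist = config$watchlist))
  s <- write_stage(adj, "adjusted_ror", out_dir, counts, nrow(adj))
  tables$adjusted_ror <- s$path; counts <- s$counts

  tto <- stage("tto", compute_onset(cohort))
  tto_sum <- stage("tto", summarize_onset(tto))
  s <- write_stage(tto, "onset_records", out_dir, counts, nrow(tto))
  tables$onset_records <- s$path; counts <- s$counts
  s <- write_stage(tto_sum, "onset_summary", out_dir, counts, nrow(tto_sum))
  tables$onset_summary <- s$path; counts <- s$counts

  desc <- stage("descriptives", summarize_descriptives(cohort))
  s <- write_stage(desc$by_drug, "descriptives_by_drug", out_dir, counts,
                   nrow(desc$by_drug))
  tables$descriptives_by_drug <- s$path; counts <- s$counts

  manifest <- data.frame(
    file = basename(unlist(tables)),
    md5 = unname(tools::md5sum(unlist(tables))),
    rows = unlist(counts[names(tables)])[seq_along(tables)]
  )
  meta <- c(sprintf("package: pvscreen %s",
                    as.character(utils::packageVersion("pvscreen"))),
            sprintf("level: %s", config$level),
            sprintf("min_reports: %d", config$min_reports),
            if (!is.null(config$synth)) sprintf("synth_seed: %d", config$synth$seed),
            sprintf("indication: %s",
                    paste(config$indication_terms, collapse = "; ")))
  writeLines(meta, file.path(out_dir, "manifest_meta.txt"))
  fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t")
  cnt <- data.frame(stage = names(counts), n = unlist(counts))
  fwrite(cnt, file.path(out_dir, "stage_counts.tsv"), sep = "\t")

  invisible(list(out_dir = out_dir, tables = tables, counts = counts,
                 manifest = manifest, cohort = cohort,
                 screen_pt = screen_pt, screen_smq = screen_smq_res,
                 adjusted = adj, onset = tto_sum, descriptives = desc))
}

#' Render a drug-by-event heatmap of a signal screen
#'
#' Purely presentational: a drugs-by-events grid coloured by the chosen
#' metric, with flagged signals annotated by an asterisk.
#'
#' @param screen a `signal_screen`.
#' @param metric column to colour by (default `"ic025"`).
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @return invisibly, the plotted matrix (`NULL` when skipped).
#' @export
render_heatmap <- function(screen, metric = "ic025", file = NULL) {
  if (!nrow(screen)) {
    warning("empty signal table; heatmap skipped")
    return(invisible(NULL))
  }
  if (!metric %in% names(screen)) stop("metric column not found: ", metric)
  drugs <- sort(unique(screen$drug))
  events <- sort(unique(screen$event))
  m <- matrix(NA_real_, length(drugs), length(events),
              dimnames = list(drugs, events))
  m[cbind(match(screen$drug, drugs), match(screen$event, events))] <-
    screen[[metric]]
  sig <- matrix(FALSE, length(drugs), length(events))
  sig[cbind(match(screen$drug, drugs), match(screen$event, events))] <-
    screen$signal

  if (!is.null(file)) {
    grDevices::png(file, width = 200 + 28 * length(events),
                   height = 160 + 22 * length(drugs))
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::hcl.colors(64, "Blue-Red 2")
  op <- graphics::par(mar = c(10, 9, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(seq_along(events), seq_along(drugs), t(m),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = paste("Signal screen:", metric))
  graphics::axis(1, seq_along(events), events, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(drugs), drugs, las = 2, cex.axis = 0.7)
  if (any(sig)) {
    w <- which(sig, arr.ind = TRUE)
    graphics::text(w[, 2], w[, 1], "*", cex = 1.2)
  }
  invisible(m)
}
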