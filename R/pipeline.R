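# End-to-end pipeline: tabulation, per-dose exact tests, dose-response fits
# (with the HRS alternative and F-test comparison), detection thresholds,
# and telomere comparisons, written out as a reproducible report bundle.

#' Pipeline configuration
#'
#' @param cell_tsv path to a per-cell scoring TSV ([read_cell_tsv()]), or
#'   `NULL` when `scoring_csv` is given.
#' @param scoring_csv path to a pre-aggregated per-dose CSV
#'   ([read_scoring_csv()]); ignored when `cell_tsv` is given.
#' @param telomere_tsv optional path to a per-metaphase telomere TSV.
#' @param out_dir output directory (created if missing).
#' @param family_map endpoint -> family mapping (see [threshold_table()]).
#' @param n_cells,alpha,sided detectability-criterion settings.
#' @param n_draws,seed Monte-Carlo settings for the upper confidence limits.
#' @param method fitting criterion (`"ml"` or `"wls"`).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(cell_tsv = NULL, scoring_csv = NULL,
                            telomere_tsv = NULL, out_dir = "cytodose_out",
                            family_map = .default_family_map,
                            n_cells = 200L, alpha = 0.05, sided = "greater",
                            n_draws = 1e5L, seed = 20130729L, method = "ml") {
  if (is.null(cell_tsv) && is.null(scoring_csv))
    stop("one of 'cell_tsv' or 'scoring_csv' is required")
  for (p in c(cell_tsv, scoring_csv, telomere_tsv))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  if (!all(.endpoints %in% names(family_map)))
    stop("family_map must cover all five endpoints")
  structure(list(cell_tsv = cell_tsv, scoring_csv = scoring_csv,
                 telomere_tsv = telomere_tsv, out_dir = out_dir,
                 family_map = family_map, n_cells = as.integer(n_cells),
                 alpha = alpha, sided = sided, n_draws = as.integer(n_draws),
                 seed = as.integer(seed), method = method),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' @param path YAML/JSON file whose keys match the [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (!is.null(raw$family_map)) raw$family_map <- unlist(raw$family_map)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes, per the configuration: tabulation of per-cell records (or
#' loading of the per-dose table), per-dose exact significance tests against
#' control, dose-response fits for every endpoint with the induced-repair
#' (HRS) alternative and its F-test where computable, the detection-threshold
#' table with Monte-Carlo upper confidence limits, and telomere comparisons
#' when telomere data are supplied. Writes `scoring_table.csv`,
#' `significance.csv`, `fits.json`, `thresholds.csv`, optionally
#' `telomere_summary.csv`, and a human-readable `summary.txt` into the
#' output directory. Deterministic given the configured seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the in-memory results: `scoring_table`,
#'   `significance`, `fits`, `model_comparison`, `thresholds`,
#'   `telomere_summary`, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message("[cytodose] ", msg)
    log_lines <<- c(log_lines, msg)
  }

  tab <- if (!is.null(config$cell_tsv)) {
    say("INFO tabulating per-cell records from %s", config$cell_tsv)
    tabulate_records(read_cell_tsv(config$cell_tsv))
  } else {
    say("INFO loading per-dose scoring table from %s", config$scoring_csv)
    read_scoring_csv(config$scoring_csv)
  }
  say("INFO %d dose levels, %d cells total", nrow(tab), sum(tab$cells_scored))
  write_scoring_csv(tab, file.path(config$out_dir, "scoring_table.csv"))

  # per-dose exact tests against control, all endpoints
  ctrl <- tab[tab$dose_gy == 0, ]
  if (nrow(ctrl) != 1L) stop("scoring table needs exactly one 0 Gy row")
  sig <- do.call(rbind, lapply(.endpoints, function(ep) {
    rows <- lapply(which(tab$dose_gy > 0), function(i) {
      p <- fisher_exact(tab[[ep]][i],
                        max(tab$cells_scored[i] - tab[[ep]][i], 0),
                        ctrl[[ep]], ctrl$cells_scored - ctrl[[ep]],
                        sided = config$sided)
      data.frame(endpoint = ep, dose_gy = tab$dose_gy[i], p_value = p,
                 flag = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
    })
    do.call(rbind, rows)
  }))
  utils::write.csv(sig, file.path(config$out_dir, "significance.csv"),
                   row.names = FALSE, quote = FALSE)

  # fits + HRS alternative
  fits <- list(); comparisons <- list()
  for (ep in .endpoints) {
    fam <- config$family_map[[ep]]
    fit <- fit_dose_response(tab, ep, fam, method = config$method)
    fits[[ep]] <- fit
    say("INFO fit %s / %s: deviance %.3g, convergence %d", ep, fam,
        fit$deviance, fit$convergence)
    if (fam %in% c("LINEAR", "LQ")) {
      cmp <- tryCatch({
        hrs <- fit_dose_response(tab, ep, "HRS_LQ", method = config$method)
        compare_models(fit, hrs)
      }, error = function(e) conditionMessage(e))
      comparisons[[ep]] <- cmp
      if (is.character(cmp)) say("WARN HRS comparison for %s: %s", ep, cmp)
      else say("INFO HRS F-test for %s: F = %.3g, p = %.3g", ep, cmp$F, cmp$p)
    }
  }
  writeLines(paste0("[",
    paste(vapply(names(fits), function(ep)
      as.character(fit_report_json(fits[[ep]])), character(1)),
      collapse = ","), "]"),
    file.path(config$out_dir, "fits.json"))

  say("INFO thresholds: alpha %.3g (%s), n_cells %d, %d draws, seed %d",
      config$alpha, config$sided, config$n_cells, config$n_draws, config$seed)
  thr <- threshold_table(tab, family_map = config$family_map,
                         n_cells = config$n_cells, alpha = config$alpha,
                         sided = config$sided, n_draws = config$n_draws,
                         seed = config$seed, method = config$method)
  for (i in which(!is.na(thr$d_star) & thr$d_star > 1))
    say("WARN threshold for %s extrapolated beyond 1 Gy", thr$endpoint[i])
  utils::write.csv(as.data.frame(thr), file.path(config$out_dir, "thresholds.csv"),
                   row.names = FALSE, quote = TRUE)

  telo <- NULL
  if (!is.null(config$telomere_tsv)) {
    say("INFO telomere comparisons from %s", config$telomere_tsv)
    tel <- read_telomere_tsv(config$telomere_tsv)
    telo <- withCallingHandlers(
      telomere_summary(tel),
      warning = function(w) { say("WARN %s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    utils::write.csv(telo, file.path(config$out_dir, "telomere_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  # human-readable summary
  con <- file.path(config$out_dir, "summary.txt")
  txt <- c("cytodose pipeline summary", "",
           utils::capture.output(print(tab)), "",
           "Significant increases over control (Fisher exact, * p<0.05, ** p<0.01):",
           utils::capture.output(print(sig[sig$flag != "", ], row.names = FALSE)),
           "", utils::capture.output(print(thr)))
  if (!is.null(telo))
    txt <- c(txt, "", "Telomere T/C% summary:",
             utils::capture.output(print(telo, row.names = FALSE)))
  txt <- c(txt, "", "Log:", paste(" ", log_lines))
  writeLines(txt, con)

  invisible(list(scoring_table = tab, significance = sig, fits = fits,
                 model_comparison = comparisons, thresholds = thr,
                 telomere_summary = telo, out_dir = config$out_dir,
                 summary_path = con))
}
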