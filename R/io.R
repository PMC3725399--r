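# Plain-text readers and writers: per-cell TSV, per-dose scoring CSV,
# per-metaphase telomere TSV, and JSON fit reports.

#' Read / write the per-cell scoring TSV
#'
#' Tab-separated, one row per scored cell, columns `cell_id`, `dose_gy`,
#' `event_codes` (a `";"`-separated list of codes accepted by
#' [classify_event()]; `"."` for an aberration-free cell).
#'
#' @param path file path.
#' @return `read_cell_tsv`: a data frame of per-cell records.
#' @export
read_cell_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(cell_id = "character",
                                          dose_gy = "numeric",
                                          event_codes = "character"))
  need <- c("cell_id", "dose_gy", "event_codes")
  if (!all(need %in% names(tab)))
    stop("per-cell TSV needs columns: ", paste(need, collapse = ", "))
  tab
}

#' @param records data frame with columns `cell_id`, `dose_gy`,
#'   `event_codes`.
#' @rdname read_cell_tsv
#' @export
write_cell_tsv <- function(records, path) {
  utils::write.table(records[c("cell_id", "dose_gy", "event_codes")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the per-dose scoring CSV
#'
#' Comma-separated, one row per dose, columns `dose_gy`, `cells_scored`,
#' `breaks`, `aberrant_cells`, `stable_exchanges`, `unstable_exchanges`,
#' `total_aberrations`. Frequencies are recomputed on read.
#'
#' @param path file path.
#' @return `read_scoring_csv`: a `scoring_table`.
#' @export
read_scoring_csv <- function(path) {
  as_scoring_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param table a `scoring_table`.
#' @rdname read_scoring_csv
#' @export
write_scoring_csv <- function(table, path) {
  cols <- c("dose_gy", "cells_scored", "breaks", "aberrant_cells",
            "stable_exchanges", "unstable_exchanges", "total_aberrations")
  utils::write.csv(as.data.frame(table)[cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write the per-metaphase telomere TSV
#'
#' Tab-separated, one row per metaphase, columns `metaphase_id`, `dose_gy`,
#' `time_h`, `centromere2_intensity`, `telomere_intensities`
#' (comma-separated fluorescence values).
#'
#' @param path file path.
#' @return `read_telomere_tsv`: a [telomere_set()].
#' @export
read_telomere_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metaphase_id", "dose_gy", "time_h", "centromere2_intensity",
            "telomere_intensities")
  if (!all(need %in% names(tab)))
    stop("telomere TSV needs columns: ", paste(need, collapse = ", "))
  tel <- lapply(strsplit(as.character(tab$telomere_intensities), ",",
                         fixed = TRUE), as.numeric)
  telomere_set(tab$metaphase_id, tab$dose_gy, tab$time_h,
               tab$centromere2_intensity, tel)
}

#' @param telomeres a [telomere_set()].
#' @rdname read_telomere_tsv
#' @export
write_telomere_tsv <- function(telomeres, path) {
  stopifnot(inherits(telomeres, "telomere_set"))
  sp <- split(telomeres, telomeres$metaphase_id)
  rows <- lapply(sp, function(s) data.frame(
    metaphase_id = s$metaphase_id[1L], dose_gy = s$dose_gy[1L],
    time_h = s$time_h[1L], centromere2_intensity = s$centromere2_intensity[1L],
    telomere_intensities = paste(format(s$telomere_intensity, trim = TRUE,
                                        digits = 10), collapse = ",")))
  out <- do.call(rbind, rows)
  out <- out[order(out$time_h, out$dose_gy, out$metaphase_id), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a dose-response fit to a JSON report
#'
#' @param fit a [fit_dose_response()] result.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
fit_report_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dose_response_fit"))
  rep <- list(
    family = fit$family$name, endpoint = fit$endpoint, method = fit$method,
    estimates = as.list(fit$estimates),
    standard_errors = as.list(stats::setNames(sqrt(pmax(diag(fit$covariance), 0)),
                                              fit$family$par_names)),
    covariance = fit$covariance,
    log_likelihood = fit$log_likelihood, deviance = fit$deviance,
    n_doses = fit$n_doses, observed_vs_predicted = fit$data,
    warnings = fit$warnings)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, na = "null",
                         matrix = "rowmajor")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
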