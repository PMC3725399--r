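# mFISH aberration scoring: mPAINT-style classification, minimal break
# counting, and aggregation of per-cell records into per-dose frequency
# tables.

# Recognized event codes and their classification. "cx<N>" (complex event
# scored as N breaks) is handled separately in classify_event().
.ab_codes <- data.frame(
  code     = c("dic", "r", "t(unbal)", "t(bal)", "ace"),
  category = c("UNSTABLE_EXCHANGE", "UNSTABLE_EXCHANGE", "UNSTABLE_EXCHANGE",
               "STABLE_EXCHANGE", "EXCESS_FRAGMENT"),
  subtype  = c("DICENTRIC", "CENTRIC_RING", "UNBALANCED_TRANSLOCATION",
               "BALANCED_TRANSLOCATION", "TERMINAL_FRAGMENT"),
  stringsAsFactors = FALSE
)

.ab_categories <- c("EXCESS_FRAGMENT", "STABLE_EXCHANGE", "UNSTABLE_EXCHANGE")

#' Classify a coded structural aberration descriptor
#'
#' Maps an mPAINT-style short code to an aberration event. Recognized codes
#' (case-insensitive): `"dic"` (dicentric), `"r"` (centric ring),
#' `"t(unbal)"` (unbalanced translocation) -- all unstable exchanges;
#' `"t(bal)"` (balanced translocation) -- a stable exchange; `"ace"` (excess
#' acentric fragment). A complex aberration whose minimal break count cannot
#' be derived from its type alone is coded `"cx<N>"` with `N` the number of
#' breaks it is scored as (e.g. `"cx4"`).
#'
#' @param descriptor character scalar, one of the recognized codes.
#' @param chromosomes optional character vector of chromosome identifiers
#'   (`"1"`--`"22"`, `"X"`, `"Y"`) involved in the event. An exchange
#'   requires at least two, a fragment at least one.
#' @return An object of class `aberration_event`: a list with fields
#'   `category`, `subtype`, `chromosomes` and `breaks` (the minimal break
#'   contribution of this event: 2 for any exchange, 1 for a fragment, `N`
#'   for `cx<N>`).
#' @examples
#' classify_event("dic")
#' classify_event("t(bal)", chromosomes = c("1", "15"))
#' @export
classify_event <- function(descriptor, chromosomes = NULL) {
  if (!is.character(descriptor) || length(descriptor) != 1L || is.na(descriptor))
    stop("'descriptor' must be a single character code")
  code <- tolower(trimws(descriptor))

  if (grepl("^cx[0-9]+$", code)) {
    nb <- as.integer(sub("^cx", "", code))
    if (nb < 1L) stop("complex event 'cx<N>' requires N >= 1")
    ev <- list(category = "UNSTABLE_EXCHANGE", subtype = NA_character_,
               chromosomes = chromosomes, breaks = nb)
    return(structure(ev, class = "aberration_event"))
  }

  i <- match(code, .ab_codes$code)
  if (is.na(i))
    stop(sprintf("unrecognized aberration descriptor '%s'; accepted codes: %s",
                 descriptor,
                 paste(c(.ab_codes$code, "cx<N>"), collapse = ", ")))
  category <- .ab_codes$category[i]
  if (!is.null(chromosomes)) {
    need <- if (category == "EXCESS_FRAGMENT") 1L else 2L
    if (length(chromosomes) < need)
      stop(sprintf("'%s' involves at least %d chromosome(s)", descriptor, need))
    ok <- chromosomes %in% c(as.character(1:22), "X", "Y")
    if (!all(ok))
      stop("chromosome identifiers must be in 1-22, X, Y")
  }
  breaks <- if (category == "EXCESS_FRAGMENT") 1L else 2L
  structure(list(category = category, subtype = .ab_codes$subtype[i],
                 chromosomes = chromosomes, breaks = breaks),
            class = "aberration_event")
}

#' @export
print.aberration_event <- function(x, ...) {
  st <- if (is.na(x$subtype)) "complex" else x$subtype
  cat(sprintf("<aberration_event> %s / %s (%d break%s)\n",
              x$category, st, x$breaks, if (x$breaks == 1L) "" else "s"))
  invisible(x)
}

# Split a ";"-separated event-code string ("." = no aberrations) into a
# character vector of codes.
.split_codes <- function(event_codes) {
  if (is.na(event_codes) || event_codes == "." || event_codes == "")
    return(character(0))
  trimws(strsplit(event_codes, ";", fixed = TRUE)[[1L]])
}

#' Construct a scored-cell record
#'
#' @param cell_id character scalar identifier.
#' @param dose_gy nonnegative dose in Gy the cell received.
#' @param events character vector of event codes (see [classify_event()]),
#'   or a single `";"`-separated string; `"."` or `character(0)` denote an
#'   aberration-free cell.
#' @return A `cell_record`: list with `cell_id`, `dose_gy`, `events`
#'   (a list of `aberration_event`s). A cell is aberrant iff it carries at
#'   least one event.
#' @export
cell_record <- function(cell_id, dose_gy, events = character(0)) {
  stopifnot(length(cell_id) == 1L, length(dose_gy) == 1L)
  dose_gy <- as.numeric(dose_gy)
  if (is.na(dose_gy) || dose_gy < 0) stop("'dose_gy' must be >= 0")
  if (is.character(events) && length(events) == 1L && grepl(";", events))
    events <- .split_codes(events)
  if (is.character(events) && identical(events, ".")) events <- character(0)
  evs <- lapply(events, function(e)
    if (inherits(e, "aberration_event")) e else classify_event(e))
  structure(list(cell_id = as.character(cell_id), dose_gy = dose_gy,
                 events = evs),
            class = "cell_record")
}

#' Is a cell aberrant?
#'
#' A cell is aberrant iff it carries any structural chromosome aberration.
#' @param record a `cell_record`.
#' @return logical scalar.
#' @export
is_aberrant <- function(record) {
  stopifnot(inherits(record, "cell_record"))
  length(record$events) > 0L
}

#' Minimal break count of a scored cell
#'
#' The break number of a cell is the smallest number of chromosome breaks
#' necessary and sufficient to produce the aberrations observed: two breaks
#' per two-way exchange (stable or unstable) and one per excess acentric
#' fragment. Complex events coded `cx<N>` contribute their recorded `N`.
#'
#' @param record a `cell_record`, or a character event-code string such as
#'   `"dic;ace"` (`"."` for none).
#' @return integer break count.
#' @examples
#' count_breaks(cell_record("c1", 0.5, c("t(bal)", "ace")))  # 3
#' count_breaks(".")                                          # 0
#' @export
count_breaks <- function(record) {
  if (is.character(record))
    record <- cell_record("cell", 0, record)
  stopifnot(inherits(record, "cell_record"))
  if (length(record$events) == 0L) return(0L)
  as.integer(sum(vapply(record$events, `[[`, numeric(1), "breaks")))
}

# --- fast vectorized scoring over code strings -------------------------------
# Per-cell event-code strings are the package's working representation of a
# scored sample (one string per cell, ";"-separated, "." = clean cell).
# Returns a matrix of per-cell endpoint counts.
.score_code_strings <- function(event_codes) {
  n <- length(event_codes)
  out <- matrix(0L, n, 5L,
                dimnames = list(NULL, c("excess_fragments", "stable_exchanges",
                                        "unstable_exchanges", "breaks",
                                        "aberrant")))
  clean <- is.na(event_codes) | event_codes == "." | event_codes == ""
  if (all(clean)) return(out)
  idx <- which(!clean)
  parts <- strsplit(event_codes[idx], ";", fixed = TRUE)
  for (j in seq_along(idx)) {
    codes <- tolower(trimws(parts[[j]]))
    codes <- codes[codes != "" & codes != "."]
    if (!length(codes)) next
    i <- idx[j]
    cx <- grepl("^cx[0-9]+$", codes)
    known <- match(codes[!cx], .ab_codes$code)
    if (anyNA(known))
      stop(sprintf("unrecognized aberration descriptor '%s'; accepted codes: %s",
                   codes[!cx][which(is.na(known))[1L]],
                   paste(c(.ab_codes$code, "cx<N>"), collapse = ", ")))
    cat_tab <- table(factor(.ab_codes$category[known], levels = .ab_categories))
    out[i, "excess_fragments"]   <- cat_tab[["EXCESS_FRAGMENT"]]
    out[i, "stable_exchanges"]   <- cat_tab[["STABLE_EXCHANGE"]]
    out[i, "unstable_exchanges"] <- cat_tab[["UNSTABLE_EXCHANGE"]] + sum(cx)
    out[i, "breaks"] <- cat_tab[["EXCESS_FRAGMENT"]] +
      2L * (cat_tab[["STABLE_EXCHANGE"]] + cat_tab[["UNSTABLE_EXCHANGE"]]) +
      sum(as.integer(sub("^cx", "", codes[cx])))
    out[i, "aberrant"] <- 1L
  }
  out
}

#' Aggregate per-cell records into a per-dose scoring table
#'
#' Counts, per dose level, the scored endpoints used throughout the package:
#' minimal breaks, aberrant cells, stable exchanges, unstable exchanges,
#' excess fragments and total aberrations (fragments + exchanges), together
#' with their frequencies as percent of cells scored.
#'
#' @param records either a list of [cell_record()]s or a data frame with
#'   columns `cell_id`, `dose_gy`, `event_codes` (the per-cell TSV layout,
#'   see [read_cell_tsv()]).
#' @return A `scoring_table`: a data frame with one row per dose, columns
#'   `dose_gy`, `cells_scored`, the six endpoint counts, and matching
#'   `*_pct` frequency columns.
#' @export
tabulate_records <- function(records) {
  if (inherits(records, "cell_record")) records <- list(records)
  if (is.data.frame(records)) {
    need <- c("cell_id", "dose_gy", "event_codes")
    if (!all(need %in% names(records)))
      stop("record data frame needs columns: ", paste(need, collapse = ", "))
    if (nrow(records) == 0L) stop("no records to tabulate")
    dose <- as.numeric(records$dose_gy)
    sc <- .score_code_strings(as.character(records$event_codes))
  } else if (is.list(records) && length(records) &&
             all(vapply(records, inherits, logical(1), "cell_record"))) {
    dose <- vapply(records, `[[`, numeric(1), "dose_gy")
    codes <- vapply(records, function(r) {
      if (!length(r$events)) return(".")
      paste(vapply(r$events, function(e) {
        if (is.na(e$subtype)) paste0("cx", e$breaks)
        else .ab_codes$code[match(e$subtype, .ab_codes$subtype)]
      }, character(1)), collapse = ";")
    }, character(1))
    sc <- .score_code_strings(codes)
  } else stop("no records to tabulate")
  if (anyNA(dose) || any(dose < 0)) stop("every record needs a dose >= 0")

  lev <- sort(unique(dose))
  g <- factor(dose, levels = lev)
  agg <- rowsum(sc, g)
  tab <- data.frame(
    dose_gy            = lev,
    cells_scored       = as.integer(tabulate(g)),
    breaks             = as.integer(agg[, "breaks"]),
    aberrant_cells     = as.integer(agg[, "aberrant"]),
    stable_exchanges   = as.integer(agg[, "stable_exchanges"]),
    unstable_exchanges = as.integer(agg[, "unstable_exchanges"]),
    excess_fragments   = as.integer(agg[, "excess_fragments"])
  )
  tab$total_aberrations <- tab$excess_fragments + tab$stable_exchanges +
    tab$unstable_exchanges
  as_scoring_table(tab)
}

#' Construct / validate a scoring table
#'
#' @param tab data frame with columns `dose_gy`, `cells_scored`, `breaks`,
#'   `aberrant_cells`, `stable_exchanges`, `unstable_exchanges`,
#'   `total_aberrations` (and optionally `excess_fragments`; derived as
#'   total - exchanges when absent). Frequency columns (`*_pct`, percent of
#'   cells scored) are (re)computed.
#' @return the validated `scoring_table`.
#' @export
as_scoring_table <- function(tab) {
  need <- c("dose_gy", "cells_scored", "breaks", "aberrant_cells",
            "stable_exchanges", "unstable_exchanges", "total_aberrations")
  if (!all(need %in% names(tab)))
    stop("scoring table needs columns: ", paste(need, collapse = ", "))
  tab <- as.data.frame(tab)[order(tab$dose_gy), , drop = FALSE]
  rownames(tab) <- NULL
  if (!"excess_fragments" %in% names(tab))
    tab$excess_fragments <- tab$total_aberrations - tab$stable_exchanges -
      tab$unstable_exchanges
  cnt <- c("breaks", "aberrant_cells", "stable_exchanges",
           "unstable_exchanges", "excess_fragments", "total_aberrations")
  if (any(tab$cells_scored < 1L)) stop("cells_scored must be >= 1 per dose")
  if (any(as.matrix(tab[cnt]) < 0L)) stop("counts must be >= 0")
  if (any(tab$total_aberrations != tab$excess_fragments +
          tab$stable_exchanges + tab$unstable_exchanges))
    stop("total_aberrations must equal excess_fragments + exchanges")
  if (any(tab$aberrant_cells > tab$cells_scored))
    stop("aberrant_cells cannot exceed cells_scored")
  if (any(tab$aberrant_cells > tab$total_aberrations))
    stop("aberrant_cells cannot exceed total_aberrations")
  canon <- c("dose_gy", "cells_scored", "breaks", "aberrant_cells",
             "stable_exchanges", "unstable_exchanges", "excess_fragments",
             "total_aberrations")
  tab <- tab[canon]
  for (v in cnt)
    tab[[paste0(v, "_pct")]] <- 100 * tab[[v]] / tab$cells_scored
  class(tab) <- c("scoring_table", "data.frame")
  tab
}

#' @export
print.scoring_table <- function(x, digits = 1, ...) {
  cat("Per-dose mFISH scoring table (counts, % of cells scored)\n")
  cnt <- c("breaks", "aberrant_cells", "stable_exchanges",
           "unstable_exchanges", "total_aberrations")
  disp <- data.frame(dose_gy = x$dose_gy, cells = x$cells_scored)
  for (v in cnt)
    disp[[v]] <- sprintf("%d (%.*f)", x[[v]], digits, x[[paste0(v, "_pct")]])
  print(disp, row.names = FALSE)
  invisible(x)
}

# Endpoint count column -> (count vector, cells vector) accessor used by the
# fitting and threshold code. aberrant_cells is a cell fraction; the others
# are per-cell event counts.
.endpoints <- c("breaks", "aberrant_cells", "stable_exchanges",
                "unstable_exchanges", "total_aberrations")

.endpoint_kind <- function(endpoint) {
  if (endpoint == "aberrant_cells") "CELL_FRACTION" else "COUNT_PER_CELL"
}
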