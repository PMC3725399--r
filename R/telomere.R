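# Telomere q-FISH analysis: per-telomere T/C% ratios against the
# chromosome-2 centromere internal reference, per-group summaries, and
# nonparametric detection of dose-dependent length modulation.

#' Telomere/centromere fluorescence ratio (T/C%)
#'
#' Telomere length proxy: the fluorescence of a telomere spot divided by the
#' fluorescence of the chromosome-2 centromere of the same metaphase (the
#' internal reference, whose sequence length is stable), times 100. The
#' ratio cancels metaphase-to-metaphase staining and exposure differences.
#'
#' @param telomere_intensity nonnegative fluorescence value(s).
#' @param centromere_intensity positive fluorescence value(s) of the
#'   chromosome-2 centromere.
#' @return T/C% value(s).
#' @examples
#' tc_percent(33, 100)  # 33
#' @export
tc_percent <- function(telomere_intensity, centromere_intensity) {
  if (any(!is.finite(centromere_intensity)) || any(centromere_intensity <= 0))
    stop("centromere reference intensity must be > 0 (reference signal missing)")
  if (any(telomere_intensity < 0))
    stop("telomere intensities must be >= 0")
  100 * telomere_intensity / centromere_intensity
}

#' Assemble a telomere measurement set
#'
#' @param metaphase_id character vector, one entry per metaphase.
#' @param dose_gy,time_h dose (Gy) and harvest time (hours, typically 24 or
#'   48) per metaphase.
#' @param centromere2_intensity positive chromosome-2 centromere
#'   fluorescence per metaphase.
#' @param telomere_intensities list of nonnegative numeric vectors, the
#'   per-telomere fluorescence values of each metaphase (92 per complete
#'   diploid metaphase: 46 chromosomes x 2 ends).
#' @return a `telomere_set`: long-format data frame with one row per
#'   telomere (`metaphase_id`, `dose_gy`, `time_h`, `telomere_intensity`,
#'   `centromere2_intensity`, `tc_pct`).
#' @export
telomere_set <- function(metaphase_id, dose_gy, time_h,
                         centromere2_intensity, telomere_intensities) {
  n <- length(metaphase_id)
  stopifnot(length(dose_gy) == n, length(time_h) == n,
            length(centromere2_intensity) == n,
            length(telomere_intensities) == n)
  if (any(lengths(telomere_intensities) < 1L))
    stop("every metaphase needs at least one telomere intensity")
  if (any(centromere2_intensity <= 0))
    stop("centromere reference intensity must be > 0 (reference signal missing)")
  k <- lengths(telomere_intensities)
  out <- data.frame(
    metaphase_id = rep(as.character(metaphase_id), k),
    dose_gy = rep(as.numeric(dose_gy), k),
    time_h = rep(as.numeric(time_h), k),
    telomere_intensity = unlist(telomere_intensities, use.names = FALSE),
    centromere2_intensity = rep(as.numeric(centromere2_intensity), k))
  out$tc_pct <- tc_percent(out$telomere_intensity, out$centromere2_intensity)
  class(out) <- c("telomere_set", "data.frame")
  out
}

#' Per-group telomere summary
#'
#' Mean T/C% and its standard error per (dose, harvest time) group, with a
#' Mann-Whitney comparison of each irradiated group against the sham (0 Gy)
#' group at the same harvest time. Groups with fewer than 1800 telomeres are
#' flagged as below the reference scoring depth.
#'
#' @param telomeres a [telomere_set()].
#' @param unit `"telomere"` (default: pool per-telomere T/C% values) or
#'   `"metaphase"` (analyze per-metaphase mean T/C%).
#' @return data frame with one row per (dose, time): `n_telomeres`,
#'   `n_metaphases`, `mean_tc_pct`, `se_tc_pct`, `U`, `p_vs_sham`,
#'   `depth_ok`.
#' @export
telomere_summary <- function(telomeres, unit = c("telomere", "metaphase")) {
  unit <- match.arg(unit)
  stopifnot(inherits(telomeres, "telomere_set"))
  grp <- unique(telomeres[c("dose_gy", "time_h")])
  grp <- grp[order(grp$time_h, grp$dose_gy), ]
  vals <- function(d, t) {
    sub <- telomeres[telomeres$dose_gy == d & telomeres$time_h == t, ]
    if (unit == "metaphase")
      tapply(sub$tc_pct, sub$metaphase_id, mean)
    else sub$tc_pct
  }
  out <- lapply(seq_len(nrow(grp)), function(i) {
    d <- grp$dose_gy[i]; t <- grp$time_h[i]
    sub <- telomeres[telomeres$dose_gy == d & telomeres$time_h == t, ]
    v <- vals(d, t)
    U <- NA_real_; p <- NA_real_
    if (d > 0 && any(telomeres$dose_gy == 0 & telomeres$time_h == t)) {
      mw <- mann_whitney_u(v, vals(0, t))
      U <- mw$U; p <- mw$p
    }
    nt <- nrow(sub)
    if (nt < 1800)
      warning(sprintf("group (%g Gy, %g h): %d telomeres, below the 1800-chromosome reference scoring depth",
                      d, t, nt), call. = FALSE)
    data.frame(dose_gy = d, time_h = t, n_telomeres = nt,
               n_metaphases = length(unique(sub$metaphase_id)),
               mean_tc_pct = mean(v), se_tc_pct = stats::sd(v) / sqrt(length(v)),
               U = U, p_vs_sham = p, depth_ok = nt >= 1800)
  })
  do.call(rbind, out)
}

#' Compare telomere length between two doses
#'
#' Pools T/C% values per group at one harvest time and applies the
#' Mann-Whitney U test ([mann_whitney_u()]).
#'
#' @param telomeres a [telomere_set()].
#' @param dose_a,dose_b the two doses (Gy) to compare.
#' @param time_h harvest time (hours) selecting the groups.
#' @param unit see [telomere_summary()].
#' @return list with `U`, `p`, `mean_diff` (mean T/C% of `dose_a` minus
#'   `dose_b`), `n_a`, `n_b`.
#' @export
compare_tc <- function(telomeres, dose_a, dose_b, time_h,
                       unit = c("telomere", "metaphase")) {
  unit <- match.arg(unit)
  stopifnot(inherits(telomeres, "telomere_set"))
  pick <- function(d) {
    sub <- telomeres[telomeres$dose_gy == d & telomeres$time_h == time_h, ]
    if (nrow(sub) == 0L)
      stop(sprintf("no measurements at %g Gy, %g h", d, time_h))
    if (unit == "metaphase") as.numeric(tapply(sub$tc_pct, sub$metaphase_id, mean))
    else sub$tc_pct
  }
  a <- pick(dose_a); b <- pick(dose_b)
  mw <- mann_whitney_u(a, b)
  list(U = mw$U, p = mw$p, mean_diff = mean(a) - mean(b),
       n_a = length(a), n_b = length(b))
}
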