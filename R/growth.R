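# Per-pen time series, proliferation ratios, growth classification, and
# capture-rate arithmetic.

#' Build per-pen growth time series from detections
#'
#' Counts detections per pen per timepoint; each pen with at least one
#' cell at t0 (the smallest timepoint present) receives a proliferation
#' ratio `final_count / t0_count` and a growth class: `PROLIFERATED` when
#' the ratio exceeds `1 + dead_band`, `APOPTOTIC` below `1 - dead_band`,
#' `NO_RESPONSE` otherwise (default `dead_band = 0`, a strict three-way
#' split at 1). Pens occupied only at later timepoints cannot be given a
#' ratio and are excluded; their ids are attached as
#' `attr(, "flagged_pens")`.
#'
#' If `detections` carries a `subtype` column, the pen's t0 composition
#' is recorded: the subtype when pure, `"MIXED"` otherwise.
#'
#' @param detections data frame with at least `pen` and `t_hours` (one
#'   row per detected cell), e.g. from [detect_cells()] across timepoints
#'   or [simulate_growth()].
#' @param final_timepoint hours used as the final count (default: the
#'   largest timepoint present).
#' @param dead_band half-width of the no-response band around ratio 1.
#' @return data frame of class `pen_timeseries`: `pen`, `t0_count`,
#'   `final_count`, `ratio`, `growth_class`, `subtype`; the long
#'   per-timepoint counts are attached as `attr(, "counts")`.
#' @export
build_timeseries <- function(detections, final_timepoint = NULL,
                             dead_band = 0) {
  stopifnot(all(c("pen", "t_hours") %in% names(detections)))
  if (!nrow(detections)) stopf("no detections supplied")
  t0 <- min(detections$t_hours)
  tf <- final_timepoint %||% max(detections$t_hours)
  if (!tf %in% detections$t_hours)
    stopf("final timepoint %g h has no detections", tf)
  counts <- as.data.frame(table(pen = detections$pen,
                                t_hours = detections$t_hours),
                          stringsAsFactors = FALSE)
  names(counts)[3L] <- "count"
  counts$t_hours <- as.numeric(counts$t_hours)
  t0n <- counts[counts$t_hours == t0, ]
  tfn <- counts[counts$t_hours == tf, ]
  pens <- t0n$pen[t0n$count > 0L]
  flagged <- setdiff(unique(detections$pen), pens)
  t0c <- t0n$count[match(pens, t0n$pen)]
  tfc <- tfn$count[match(pens, tfn$pen)]
  tfc[is.na(tfc)] <- 0L
  ratio <- tfc / t0c
  cls <- ifelse(ratio > 1 + dead_band, "PROLIFERATED",
                ifelse(ratio < 1 - dead_band, "APOPTOTIC", "NO_RESPONSE"))
  subtype <- rep(NA_character_, length(pens))
  if ("subtype" %in% names(detections)) {
    d0 <- detections[detections$t_hours == t0, ]
    comp <- tapply(as.character(d0$subtype), d0$pen,
                   function(s) if (length(unique(s)) == 1L) s[1] else "MIXED")
    subtype <- as.character(comp[pens])
  }
  out <- data.frame(pen = pens, t0_count = t0c, final_count = tfc,
                    ratio = ratio, growth_class = cls, subtype = subtype,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- counts[order(counts$pen, counts$t_hours), ]
  attr(out, "flagged_pens") <- flagged
  attr(out, "t0") <- t0
  attr(out, "final_timepoint") <- tf
  class(out) <- c("pen_timeseries", "data.frame")
  out
}

#' Stratified growth summary
#'
#' Mean and sd of the proliferation ratio and the growth-class fractions,
#' per stratum. Strata are either the pen's pure subtype at t0 (pens with
#' mixed composition are excluded, since attributing growth to one
#' subtype in a mixed pen is undefined) or the t0 cell count binned at
#' 1, 2, 3, 4 (larger counts grouped as `"5+"`). Empty strata yield a row
#' with `n = 0` and `NA` statistics rather than an error.
#'
#' @param series a [build_timeseries()] result.
#' @param stratify_by `"subtype"` or `"t0_count"`.
#' @return data frame: `stratum`, `n`, `mean_ratio`, `sd_ratio`,
#'   `frac_proliferated`, `frac_apoptotic`, `frac_no_response`.
#' @export
summarize_growth <- function(series, stratify_by = c("subtype", "t0_count")) {
  stratify_by <- match.arg(stratify_by)
  if (!nrow(series)) stopf("empty pen series")
  if (stratify_by == "subtype") {
    keep <- !is.na(series$subtype) & series$subtype != "MIXED"
    s <- series[keep, , drop = FALSE]
    strata <- c("P5", "P6", "P7", "P8", "UNASSIGNED")
    key <- s$subtype
  } else {
    s <- series
    key <- ifelse(s$t0_count >= 5L, "5+", as.character(s$t0_count))
    strata <- c("1", "2", "3", "4", if (any(key == "5+")) "5+")
  }
  rows <- lapply(strata, function(st) {
    r <- s$ratio[key == st]
    cl <- s$growth_class[key == st]
    n <- length(r)
    data.frame(stratum = st, n = n,
               mean_ratio = if (n) mean(r) else NA_real_,
               sd_ratio = if (n > 1L) stats::sd(r) else NA_real_,
               frac_proliferated = if (n) mean(cl == "PROLIFERATED") else NA_real_,
               frac_apoptotic = if (n) mean(cl == "APOPTOTIC") else NA_real_,
               frac_no_response = if (n) mean(cl == "NO_RESPONSE") else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent of occupied pens containing a target population
#'
#' `100 * pens_with_target / pens_with_cells`, rounded to one decimal —
#' the capture rate of a targeted subtype among all occupied nanopens.
#'
#' @param pens_with_cells occupied pen count (> 0).
#' @param pens_with_target pens containing the target subtype.
#' @return percent, one decimal.
#' @examples
#' capture_rate(311, 46)  # 14.8
#' capture_rate(176, 47)  # 26.7
#' @export
capture_rate <- function(pens_with_cells, pens_with_target) {
  if (pens_with_cells <= 0) stopf("pens_with_cells must be positive")
  if (pens_with_target < 0 || pens_with_target > pens_with_cells)
    stopf("pens_with_target must lie in [0, pens_with_cells]")
  round(100 * pens_with_target / pens_with_cells, 1)
}

#' Relative improvement between two capture rates
#'
#' `100 * (rate_new - rate_baseline) / rate_baseline`, rounded to one
#' decimal. By default the inputs are first rounded to one decimal (the
#' scale at which capture rates are reported), so improvements quoted
#' from printed rates reproduce exactly; `rounded = FALSE` computes the
#' ratio on the unrounded inputs.
#'
#' @param rate_baseline,rate_new percents; baseline must be > 0.
#' @param rounded round inputs to one decimal first (default TRUE).
#' @return percent increase (negative for a decrease), one decimal.
#' @examples
#' capture_improvement(14.8, 26.7)  # 80.4
#' @export
capture_improvement <- function(rate_baseline, rate_new, rounded = TRUE) {
  if (rate_baseline <= 0) stopf("baseline rate must be positive")
  if (rounded) {
    rate_baseline <- round(rate_baseline, 1)
    rate_new <- round(rate_new, 1)
  }
  round(100 * (rate_new - rate_baseline) / rate_baseline, 1)
}
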