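# Marker-level binning (two-cluster K-means per channel) and subtype
# assignment from Epcam/Cd49f/Sca-1 level patterns.

# Marker level patterns defining the subpopulations of interest:
# Epcam (-/+), Cd49f (low/high), Sca-1 (low/high)
SUBTYPE_PATTERNS <- rbind(
  P5 = c(Epcam = "NEG", Cd49f = "HIGH", `Sca-1` = "LOW"),
  P6 = c(Epcam = "NEG", Cd49f = "LOW",  `Sca-1` = "LOW"),
  P7 = c(Epcam = "POS", Cd49f = "HIGH", `Sca-1` = "LOW"),
  P8 = c(Epcam = "POS", Cd49f = "HIGH", `Sca-1` = "HIGH"))

#' Map marker levels to subtypes
#'
#' Pure vectorized mapping of the binary Epcam/Cd49f/Sca-1 level pattern
#' to the P5, P6, P7, P8 vocabulary: P5 = NEG/HIGH/LOW, P6 = NEG/LOW/LOW,
#' P7 = POS/HIGH/LOW, P8 = POS/HIGH/HIGH. Any of the four remaining
#' combinations maps to `UNASSIGNED`.
#'
#' @param epcam character vector of `"NEG"`/`"POS"` levels.
#' @param cd49f,sca1 character vectors of `"LOW"`/`"HIGH"` levels.
#' @return factor with levels `P5, P6, P7, P8, UNASSIGNED`.
#' @export
subtype_from_levels <- function(epcam, cd49f, sca1) {
  key <- paste(epcam, cd49f, sca1)
  pat <- apply(SUBTYPE_PATTERNS, 1L, paste, collapse = " ")
  lab <- names(pat)[match(key, pat)]
  lab[is.na(lab)] <- "UNASSIGNED"
  factor(lab, levels = SUBTYPE_LEVELS)
}

# exact 1-D two-cluster K-means: the optimal k=2 partition of points on a
# line is a threshold split, found by scanning sorted split points
kmeans2_1d <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  csum <- cumsum(xs); csq <- cumsum(xs^2)
  wss <- function(lo_n) {
    s1 <- csum[lo_n]; q1 <- csq[lo_n]
    s2 <- csum[n] - s1; q2 <- csq[n] - q1
    (q1 - s1^2 / lo_n) + (q2 - s2^2 / (n - lo_n))
  }
  splits <- which(diff(xs) > 0)  # split after position i
  if (!length(splits)) return(NULL)
  w <- vapply(splits, wss, numeric(1))
  k <- splits[which.min(w)]
  centers <- c(csum[k] / k, (csum[n] - csum[k]) / (n - k))
  list(centers = centers, boundary = mean(c(xs[k], xs[k + 1L])),
       wss = min(w))
}

#' Fit a two-level marker intensity model
#'
#' Per channel, clusters the 1-D normalized intensities into two groups by
#' K-means (k = 2); the cluster with the larger center is labeled HIGH
#' (POS for Epcam), automating the low/high binning of marker expression
#' without a hand-picked threshold. The 1-D k = 2 problem is solved
#' exactly (the optimal partition is a threshold split, found by scanning
#' sorted split points), so the fit is deterministic and invariant to
#' cell order; `seed` and `n_restarts` are retained in the model record
#' for provenance.
#'
#' @param expr numeric matrix, cells x channels; column names must
#'   include the modeled channels.
#' @param channels channels to model (default Epcam, Cd49f, Sca-1).
#' @param seed,n_restarts recorded in the model (the exact solver needs
#'   neither).
#' @return object of class `marker_level_model`: per channel the
#'   ascending `centers`, decision `boundary`, and level `labels`
#'   (NEG/POS for Epcam, LOW/HIGH otherwise).
#' @section Errors: a channel whose values are all identical cannot be
#'   split and raises a degenerate-channel error naming the channel.
#' @export
fit_level_model <- function(expr, channels = c("Epcam", "Cd49f", "Sca-1"),
                            seed = 1L, n_restarts = 10L) {
  expr <- as.matrix(expr)
  missing <- setdiff(channels, colnames(expr))
  if (length(missing)) stopf("missing channels: %s", paste(missing, collapse = ", "))
  if (nrow(expr) < 2L) stopf("need >= 2 cells to fit a level model")
  fit <- lapply(channels, function(ch) {
    x <- expr[, ch]
    km <- kmeans2_1d(x)
    if (is.null(km)) stopf("degenerate channel '%s': all values identical", ch)
    labels <- if (ch == "Epcam") c("NEG", "POS") else c("LOW", "HIGH")
    list(centers = km$centers, boundary = km$boundary, labels = labels)
  })
  names(fit) <- channels
  structure(list(channels = fit, seed = seed, n_restarts = n_restarts,
                 method = "kmeans"),
            class = "marker_level_model")
}

#' @export
print.marker_level_model <- function(x, ...) {
  cat("<marker_level_model> two-level K-means binning\n")
  for (ch in names(x$channels)) {
    f <- x$channels[[ch]]
    cat(sprintf("  %-6s centers %.3f / %.3f  boundary %.3f  (%s/%s)\n",
                ch, f$centers[1], f$centers[2], f$boundary,
                f$labels[1], f$labels[2]))
  }
  invisible(x)
}

#' Predict marker levels for new intensities
#'
#' @param object a [fit_level_model()] result.
#' @param newdata cells x channels intensity matrix.
#' @param ... unused.
#' @return character matrix of levels, cells x channels.
#' @export
predict.marker_level_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- sapply(names(object$channels), function(ch) {
    f <- object$channels[[ch]]
    ifelse(newdata[, ch] > f$boundary, f$labels[2], f$labels[1])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(NULL, names(object$channels)))
  rownames(out) <- rownames(newdata)
  out
}

#' Assign subtypes to cells from a fitted level model
#'
#' Maps each cell's per-channel intensity to its binary level via the
#' model, then to the P5..P8 vocabulary via [subtype_from_levels()].
#' Cells whose level pattern matches no subtype are retained as
#' `UNASSIGNED` (they still occupy pens and must be accounted for in
#' growth stratification).
#'
#' @param expr cells x channels intensity matrix with rownames as cell
#'   ids.
#' @param model a [fit_level_model()].
#' @return data frame: `cell`, one level column per channel, `subtype`.
#' @export
assign_subtypes <- function(expr, model) {
  expr <- as.matrix(expr)
  missing <- setdiff(names(model$channels), colnames(expr))
  if (length(missing)) stopf("missing channels: %s", paste(missing, collapse = ", "))
  lv <- predict(model, expr)
  out <- data.frame(cell = rownames(expr) %||% as.character(seq_len(nrow(expr))),
                    stringsAsFactors = FALSE)
  for (ch in colnames(lv)) out[[ch]] <- lv[, ch]
  out$subtype <- subtype_from_levels(lv[, "Epcam"], lv[, "Cd49f"],
                                     lv[, "Sca-1"])
  out
}

#' Pivot expression records into a cells x markers intensity matrix
#'
#' Convenience bridge from [quantify_cells()] long records to the matrix
#' interface of [fit_level_model()], renaming imaging channels to marker
#' names.
#'
#' @param records long data frame with `cell`, `channel`, `normalized`.
#' @param marker_channels named map marker -> channel.
#' @return numeric matrix, cells x markers.
#' @export
expression_matrix <- function(records, marker_channels = DEFAULT_MARKER_CHANNELS) {
  cells <- unique(records$cell)
  out <- matrix(NA_real_, length(cells), length(marker_channels),
                dimnames = list(cells, names(marker_channels)))
  for (mk in names(marker_channels)) {
    sub <- records[records$channel == marker_channels[[mk]], ]
    out[match(sub$cell, cells), mk] <- sub$normalized
  }
  if (anyNA(out)) stopf("missing channel measurements for some cells")
  out
}

#' Agreement between two subtype label vectors
#'
#' Percent of cells whose labels agree, plus the full confusion matrix.
#' By default `UNASSIGNED` labels count as disagreement (unless both
#' vectors agree on `UNASSIGNED`); with `unassigned = "drop"`, pairs where
#' either label is `UNASSIGNED` are removed before computing agreement.
#'
#' @param truth,predicted equal-length subtype vectors.
#' @param unassigned `"disagree"` (default) or `"drop"`.
#' @return list: `agreement` (percent), `confusion` (truth x predicted
#'   table), `n`.
#' @export
binning_concordance <- function(truth, predicted,
                                unassigned = c("disagree", "drop")) {
  unassigned <- match.arg(unassigned)
  if (length(truth) != length(predicted))
    stopf("label vectors differ in length (%d vs %d)",
          length(truth), length(predicted))
  truth <- factor(as.character(truth), levels = SUBTYPE_LEVELS)
  predicted <- factor(as.character(predicted), levels = SUBTYPE_LEVELS)
  conf <- table(truth = truth, predicted = predicted)
  if (unassigned == "drop") {
    keep <- truth != "UNASSIGNED" & predicted != "UNASSIGNED"
    truth <- truth[keep]; predicted <- predicted[keep]
  }
  n <- length(truth)
  agree <- if (n) 100 * mean(as.character(truth) == as.character(predicted))
           else NA_real_
  list(agreement = agree, confusion = conf, n = n)
}
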