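# Single-cell RNA-seq quality control, scaled expression, and
# marker-threshold gating into the P5..P8 subtypes.

#' QC thresholds for single-cell count matrices
#'
#' Defaults follow the standard mouse mammary single-cell workflow:
#' features must be present in at least 15 cells; cells are kept when the
#' mitochondrial read percentage is strictly below 20, the number of
#' detected features strictly above 2,000, and the total molecule count
#' strictly below 45,000.
#'
#' @param mito_max_pct maximum percent of counts mapping to
#'   mitochondrial genes (exclusive).
#' @param nfeature_min minimum detected features per cell (exclusive).
#' @param ncount_max maximum total counts per cell (exclusive).
#' @param min_cells_per_feature feature must be detected in at least this
#'   many cells (inclusive).
#' @export
qc_params <- function(mito_max_pct = 20, nfeature_min = 2000,
                      ncount_max = 45000, min_cells_per_feature = 15) {
  if (any(c(mito_max_pct, nfeature_min, ncount_max,
            min_cells_per_feature) <= 0))
    stopf("all QC thresholds must be positive")
  structure(list(mito_max_pct = mito_max_pct, nfeature_min = nfeature_min,
                 ncount_max = ncount_max,
                 min_cells_per_feature = min_cells_per_feature),
            class = "qc_params")
}

#' Per-cell QC statistics
#'
#' @param counts genes x cells matrix (sparse or dense) with gene symbols
#'   as rownames.
#' @param mito_pattern regular expression identifying mitochondrial gene
#'   symbols (mouse convention `mt-`, case-insensitive).
#' @return data frame: `barcode`, `n_count`, `n_feature`, `pct_mito`.
#' @export
cell_qc_stats <- function(counts, mito_pattern = "^mt-") {
  if (is.null(rownames(counts))) stopf("counts must have gene symbols as rownames")
  mito <- grepl(mito_pattern, rownames(counts), ignore.case = TRUE)
  n_count <- Matrix::colSums(counts)
  n_feature <- Matrix::colSums(counts > 0)
  mito_count <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE])
                else rep(0, ncol(counts))
  pct <- ifelse(n_count > 0, 100 * mito_count / n_count, 0)
  data.frame(barcode = colnames(counts) %||% as.character(seq_len(ncol(counts))),
             n_count = as.numeric(n_count), n_feature = as.numeric(n_feature),
             pct_mito = as.numeric(pct), stringsAsFactors = FALSE)
}

#' Quality-control filter for a count matrix
#'
#' Two-step filter. Step 1 removes features detected in fewer than
#' `min_cells_per_feature` cells (applied first, as when constructing the
#' expression object). Step 2 computes per-cell statistics on the
#' feature-filtered matrix and keeps cells with
#' `pct_mito < mito_max_pct`, `n_feature > nfeature_min`, and
#' `n_count < ncount_max` (all strict). High mitochondrial content flags
#' dying cells; very few features flag empty droplets and debris; very
#' large counts flag multiplets.
#'
#' @param counts genes x cells matrix with gene symbols as rownames and
#'   barcodes as colnames.
#' @param params a [qc_params()].
#' @param mito_pattern see [cell_qc_stats()].
#' @return list: `counts` (filtered matrix; possibly zero cells — never
#'   an error), `report` (features/cells in and out, per-criterion
#'   removal counts, surviving barcodes, the per-cell statistics).
#' @export
qc_filter <- function(counts, params = qc_params(), mito_pattern = "^mt-") {
  if (is.null(rownames(counts))) stopf("counts must have gene symbols as rownames")
  n_cells_in <- ncol(counts); n_genes_in <- nrow(counts)
  feat_keep <- Matrix::rowSums(counts > 0) >= params$min_cells_per_feature
  m <- counts[feat_keep, , drop = FALSE]
  st <- cell_qc_stats(m, mito_pattern)
  fail_mito <- st$pct_mito >= params$mito_max_pct
  fail_nfeat <- st$n_feature <= params$nfeature_min
  fail_ncount <- st$n_count >= params$ncount_max
  keep <- !(fail_mito | fail_nfeat | fail_ncount)
  out <- m[, keep, drop = FALSE]
  report <- list(
    n_genes_in = n_genes_in, n_genes_out = nrow(out),
    n_features_removed = sum(!feat_keep),
    n_cells_in = n_cells_in, n_cells_out = ncol(out),
    removed_mito = sum(fail_mito), removed_nfeature = sum(fail_nfeat),
    removed_ncount = sum(fail_ncount),
    survivors = st$barcode[keep],
    cell_stats = st, params = params)
  list(counts = out, report = report)
}

#' Scaled expression: depth-normalize, log-transform, standardize
#'
#' Per cell, counts are normalized to `target_depth` total molecules and
#' log1p-transformed; per gene, values are standardized to zero mean and
#' unit variance across cells. Genes with zero variance scale to 0. The
#' result is the continuous "scaled expression" axis on which marker
#' gates are placed.
#'
#' @param counts filtered genes x cells matrix.
#' @param target_depth counts per cell after normalization.
#' @return dense numeric matrix, genes x cells, with attribute
#'   `scaling_method = "lognorm_zscore"`.
#' @section Errors: a zero-depth cell cannot be normalized; the error
#'   names its barcode.
#' @export
scale_expression <- function(counts, target_depth = 1e4) {
  depth <- Matrix::colSums(counts)
  if (any(depth == 0)) {
    bad <- colnames(counts)[depth == 0][1]
    stopf("zero-depth cell cannot be normalized: %s", bad %||% "<unnamed>")
  }
  m <- as.matrix(counts)
  m <- log1p(sweep(m, 2L, depth / target_depth, `/`))
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  m <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  m[sdv == 0, ] <- 0
  attr(m, "scaling_method") <- "lognorm_zscore"
  m
}

#' Gating configuration for marker-based subtyping
#'
#' @param markers named map marker protein -> gene symbol; all three of
#'   Epcam, Cd49f, Sca-1 must map to distinct genes.
#' @param threshold scaled-expression cutoff: a marker is POS/HIGH when
#'   its scaled value is strictly greater (default 0.3, the lower bound
#'   of the upper expression mode).
#' @export
gating_config <- function(markers = c(Epcam = "Epcam", Cd49f = "Itga6",
                                      `Sca-1` = "Ly6a"),
                          threshold = 0.3) {
  if (!setequal(names(markers), c("Epcam", "Cd49f", "Sca-1")))
    stopf("markers must be named Epcam, Cd49f, Sca-1")
  if (anyDuplicated(markers)) stopf("marker genes must be distinct")
  structure(list(markers = markers, threshold = threshold),
            class = "gating_config")
}

#' Gate cells into subtypes by scaled marker expression
#'
#' Per marker, the level is POS/HIGH iff the scaled value exceeds the
#' threshold; the binary pattern maps to P5..P8 via
#' [subtype_from_levels()]. The triple-positive subset (P8:
#' Epcam+ Itga6 high Ly6a high) is summarized as a count and percent of
#' all gated cells (two decimals).
#'
#' @param scaled a [scale_expression()] matrix.
#' @param config a [gating_config()].
#' @return object of class `gate_result`: `labels` (barcode, per-marker
#'   level, subtype), `counts` and `fractions` over the subtype
#'   vocabulary, `p8_count`, `p8_pct`, `threshold`, `scaling_method`.
#' @section Errors: a missing marker gene raises an error listing
#'   case-insensitive near-matches present in the matrix.
#' @export
gate_cells <- function(scaled, config = gating_config()) {
  mk <- config$markers
  absent <- mk[!mk %in% rownames(scaled)]
  if (length(absent)) {
    near <- unlist(lapply(absent, function(g)
      grep(g, rownames(scaled), ignore.case = TRUE, value = TRUE)))
    stopf("marker gene(s) not in matrix: %s%s",
          paste(absent, collapse = ", "),
          if (length(near)) paste0(" (near matches: ",
                                   paste(unique(near), collapse = ", "), ")")
          else "")
  }
  thr <- config$threshold
  lv <- function(gene, labs) ifelse(scaled[gene, ] > thr, labs[2], labs[1])
  epcam <- lv(mk[["Epcam"]], c("NEG", "POS"))
  cd49f <- lv(mk[["Cd49f"]], c("LOW", "HIGH"))
  sca1 <- lv(mk[["Sca-1"]], c("LOW", "HIGH"))
  subtype <- subtype_from_levels(epcam, cd49f, sca1)
  counts <- table(subtype)
  n <- ncol(scaled)
  labels <- data.frame(barcode = colnames(scaled) %||%
                         as.character(seq_len(n)),
                       Epcam = epcam, Cd49f = cd49f, `Sca-1` = sca1,
                       subtype = subtype, check.names = FALSE,
                       stringsAsFactors = FALSE)
  structure(list(labels = labels, counts = counts,
                 fractions = counts / max(1L, n),
                 p8_count = unname(counts["P8"]),
                 p8_pct = round(100 * unname(counts["P8"]) / max(1L, n), 2),
                 threshold = thr,
                 scaling_method = attr(scaled, "scaling_method") %||% NA),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("<gate_result> %d cells gated at scaled threshold %g\n",
              sum(x$counts), x$threshold))
  print(x$counts)
  cat(sprintf("triple-positive (P8): %d cells (%.2f%%)\n",
              x$p8_count, x$p8_pct))
  invisible(x)
}

#' Per-group composition of clusters
#'
#' For each cluster, counts per group and the group's percent of the
#' cluster total (two decimals) — the sample-of-origin breakdown used
#' when comparing merged datasets.
#'
#' @param clusters per-cell cluster labels.
#' @param groups per-cell group labels (same length).
#' @return data frame: `cluster`, `group`, `count`, `cluster_total`,
#'   `percent`.
#' @export
composition_summary <- function(clusters, groups) {
  if (length(clusters) != length(groups))
    stopf("clusters and groups differ in length")
  tab <- table(cluster = clusters, group = groups)
  tot <- rowSums(tab)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3L] <- "count"
  df$cluster_total <- as.numeric(tot[df$cluster])
  df$percent <- ifelse(df$cluster_total > 0,
                       round(100 * df$count / df$cluster_total, 2), 0)
  df[order(df$cluster, df$group), ]
}
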