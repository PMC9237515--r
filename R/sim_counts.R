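# Synthetic gene x cell count matrices with planted marker-positive
# subpopulations, mitochondrial content, and expression-breadth clusters;
# toy protein-interaction networks.

#' Specification for a synthetic count matrix
#'
#' Cells receive a planted subtype drawn from `subtype_mix` (the P5..P8
#' Epcam/Itga6/Ly6a patterns, plus `OTHER` = all markers off); a marker
#' gene that is POS/HIGH for the cell's subtype contributes exactly
#' `marker_count` raw counts, so gating ground truth is unambiguous.
#' Remaining depth is multinomial over a background profile. Per-cell
#' library depth is Gaussian (`depth_sd = 0` gives identical depths — the
#' noise-free configuration), and a per-cell mitochondrial fraction
#' routes background counts to `mt-` prefixed genes.
#'
#' `cluster_design` optionally partitions cells into expression-breadth
#' clusters for potency scoring: each element is
#' `list(frac = , active = )` where `active` is `"all"` (transcriptionally
#' promiscuous: background spread uniformly over all filler genes) or an
#' integer (specialized: background confined to that many genes).
#'
#' @param n_genes total genes including markers and mitochondrial genes.
#' @param n_cells cells.
#' @param subtype_mix proportions over P5, P6, P7, P8, OTHER (sum 1).
#' @param marker_count raw counts a positive marker contributes.
#' @param depth_mean,depth_sd per-cell library size distribution.
#' @param mito_frac_mean,mito_frac_sd per-cell mitochondrial fraction.
#' @param n_mito_genes number of `mt-` genes.
#' @param cluster_design optional named list, see Details.
#' @param seed integer seed.
#' @return object of class `sim_expr_spec`.
#' @export
sim_expr_spec <- function(n_genes = 300L, n_cells = 500L,
                          subtype_mix = c(P5 = 0.20, P6 = 0.25, P7 = 0.20,
                                          P8 = 0.10, OTHER = 0.25),
                          marker_count = 40L,
                          depth_mean = 5000, depth_sd = 1200,
                          mito_frac_mean = 0.05, mito_frac_sd = 0.03,
                          n_mito_genes = 10L,
                          cluster_design = NULL,
                          seed = 1L) {
  if (abs(sum(subtype_mix) - 1) > 1e-8) stopf("subtype_mix must sum to 1")
  if (!all(names(subtype_mix) %in% c("P5", "P6", "P7", "P8", "OTHER")))
    stopf("subtype_mix names must be in P5, P6, P7, P8, OTHER")
  if (n_genes < n_mito_genes + 13L)
    stopf("n_genes too small for markers + mitochondrial genes")
  if (!is.null(cluster_design)) {
    fr <- vapply(cluster_design, `[[`, numeric(1), "frac")
    if (abs(sum(fr) - 1) > 1e-8) stopf("cluster_design fracs must sum to 1")
  }
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 subtype_mix = subtype_mix, marker_count = as.integer(marker_count),
                 depth_mean = depth_mean, depth_sd = depth_sd,
                 mito_frac_mean = mito_frac_mean, mito_frac_sd = mito_frac_sd,
                 n_mito_genes = as.integer(n_mito_genes),
                 cluster_design = cluster_design, seed = as.integer(seed)),
            class = "sim_expr_spec")
}

# marker gene pattern per subtype on the RNA side (gene symbols)
MARKER_GENES <- c(Epcam = "Epcam", Cd49f = "Itga6", `Sca-1` = "Ly6a")

#' Simulate a gene x cell count matrix with planted ground truth
#'
#' @param spec a [sim_expr_spec()].
#' @return list: `counts` (sparse `dgCMatrix`, genes x cells), `cells`
#'   (barcode, subtype, cluster, depth, mito_frac), `genes` (gene,
#'   is_marker, is_mito), `spec`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_expr_spec"))
  with_seed(spec$seed, {
    markers <- unname(MARKER_GENES)
    mito <- sprintf("mt-g%02d", seq_len(spec$n_mito_genes))
    n_fill <- spec$n_genes - length(markers) - length(mito)
    fill <- sprintf("g%04d", seq_len(n_fill))
    genes <- c(markers, mito, fill)

    n <- spec$n_cells
    barcodes <- sprintf("cell%05d", seq_len(n))
    if (n == 0L) {
      counts <- Matrix::Matrix(0L, length(genes), 0L, sparse = TRUE,
                               dimnames = list(genes, NULL))
      return(list(counts = methods::as(counts, "CsparseMatrix"),
                  cells = data.frame(barcode = character(),
                                     subtype = character(),
                                     cluster = character(),
                                     depth = numeric(), mito_frac = numeric(),
                                     stringsAsFactors = FALSE),
                  genes = data.frame(gene = genes,
                                     is_marker = genes %in% markers,
                                     is_mito = genes %in% mito,
                                     stringsAsFactors = FALSE),
                  spec = spec))
    }
    subtype <- sample(names(spec$subtype_mix), n, replace = TRUE,
                      prob = spec$subtype_mix)
    if (is.null(spec$cluster_design)) {
      cluster <- rep("base", n)
      profiles <- list(base = stats::rlnorm(n_fill, 0, 1.2))
    } else {
      fr <- vapply(spec$cluster_design, `[[`, numeric(1), "frac")
      cluster <- sample(names(spec$cluster_design), n, replace = TRUE,
                        prob = fr)
      profiles <- lapply(spec$cluster_design, function(cd) {
        if (identical(cd$active, "all")) rep(1, n_fill)
        else c(rep(1, min(cd$active, n_fill)),
               rep(0, max(0L, n_fill - cd$active)))
      })
    }
    depth <- pmax(200, round(stats::rnorm(n, spec$depth_mean, spec$depth_sd)))
    mito_frac <- pmin(0.9, pmax(0, stats::rnorm(n, spec$mito_frac_mean,
                                                spec$mito_frac_sd)))
    # Epcam/Itga6/Ly6a positivity per the subtype pattern; OTHER = all off
    pos <- matrix(0L, 3L, n, dimnames = list(markers, barcodes))
    for (i in seq_len(n)) {
      if (subtype[i] == "OTHER") {
        # a pattern outside the P5..P8 vocabulary (Ly6a-only positive),
        # so planted OTHER cells gate to UNASSIGNED, not P6
        pos["Ly6a", i] <- spec$marker_count
      } else {
        lv <- SUBTYPE_PATTERNS[subtype[i], ]
        pos[, i] <- ifelse(lv %in% c("POS", "HIGH"), spec$marker_count, 0L)
      }
    }
    ii <- list(); jj <- list(); xx <- list()
    for (i in seq_len(n)) {
      mk <- pos[, i]
      bg <- max(0L, depth[i] - sum(mk))
      n_mt <- round(bg * mito_frac[i])
      n_bg <- bg - n_mt
      mt_counts <- if (n_mt > 0L)
        as.integer(stats::rmultinom(1L, n_mt, rep(1, length(mito)))) else
        integer(length(mito))
      pr <- profiles[[cluster[i]]]
      bg_counts <- if (n_bg > 0L && sum(pr) > 0)
        as.integer(stats::rmultinom(1L, n_bg, pr)) else integer(n_fill)
      v <- c(mk, mt_counts, bg_counts)
      nz <- which(v > 0L)
      ii[[i]] <- nz; jj[[i]] <- rep(i, length(nz)); xx[[i]] <- v[nz]
    }
    counts <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                   x = unlist(xx),
                                   dims = c(length(genes), n),
                                   dimnames = list(genes, barcodes))
    list(counts = counts,
         cells = data.frame(barcode = barcodes, subtype = subtype,
                            cluster = cluster, depth = depth,
                            mito_frac = mito_frac, stringsAsFactors = FALSE),
         genes = data.frame(gene = genes, is_marker = genes %in% markers,
                            is_mito = genes %in% mito,
                            stringsAsFactors = FALSE),
         spec = spec)
  })
}

#' Simulate a toy protein-interaction network over a gene set
#'
#' Connected, simple, undirected scale-free graph (preferential
#' attachment) with vertices named by the supplied genes. Stands in for a
#' real interactome in tests and examples; it is synthetic and carries no
#' biological interaction information.
#'
#' @param genes vertex names.
#' @param m edges attached per new vertex.
#' @param seed integer seed.
#' @return an `igraph` object.
#' @export
simulate_ppi <- function(genes, m = 2L, seed = 1L) {
  with_seed(seed, {
    g <- igraph::sample_pa(length(genes), m = m, directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- genes
    g
  })
}

#' Read / write an undirected edge list (two-column TSV of gene symbols)
#'
#' @param path TSV file without header.
#' @return data frame with columns `from`, `to`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stopf("edge list must have two columns")
  names(df)[1:2] <- c("from", "to")
  df[, 1:2]
}

#' @rdname read_edge_list
#' @param graph an `igraph` object or `from`/`to` data frame.
#' @export
write_edge_list <- function(graph, path) {
  df <- if (inherits(graph, "igraph"))
    as.data.frame(igraph::as_edgelist(graph), stringsAsFactors = FALSE)
  else graph[, 1:2]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write counts in MatrixMarket triplet format
#'
#' Reads `matrix.mtx` + `genes.tsv` + `barcodes.tsv` from a directory
#' (the conventional sparse gene x cell layout), or a dense CSV with gene
#' rownames.
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return sparse `dgCMatrix`, genes x cells.
#' @export
read_counts_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) stopf("matrix.mtx not found in %s", dir)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)[, 1L]
  cells <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)[, 1L]
  dimnames(m) <- list(genes, cells)
  m
}

#' @rdname read_counts_mtx
#' @param counts genes x cells matrix with dimnames.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname read_counts_mtx
#' @param path dense CSV (genes in the first column).
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  methods::as(as.matrix(df), "CsparseMatrix")
}
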