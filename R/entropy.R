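# Differentiation-potency estimation: Shannon entropy rate of an
# expression-weighted random walk on a protein-interaction network.

#' Parameters for entropy-based potency scoring
#'
#' @param knn_k neighbors for count smoothing (default 8; 0 disables).
#' @param target_depth per-cell depth after renormalization (default
#'   10,000 counts).
#' @param pseudo positive offset replacing zero expression on network
#'   nodes (zero expression would disconnect the walk); default
#'   `1e-6 x` the cell's mean nonzero network-restricted value.
#' @export
entropy_params <- function(knn_k = 8L, target_depth = 1e4, pseudo = NULL) {
  if (knn_k < 0L) stopf("knn_k must be >= 0")
  if (target_depth <= 0) stopf("target_depth must be positive")
  if (!is.null(pseudo) && pseudo <= 0) stopf("pseudo must be positive")
  structure(list(knn_k = as.integer(knn_k), target_depth = target_depth,
                 pseudo = pseudo),
            class = "entropy_params")
}

#' Prepare a protein-interaction network for scoring
#'
#' Builds an undirected, simple graph from a two-column edge list (or
#' takes an existing `igraph`), optionally intersects the vertex set with
#' a gene universe, and restricts to the largest connected component —
#' the entropy rate of a stationary walk is defined on a connected graph.
#'
#' @param edges two-column data frame of gene symbols, or an `igraph`.
#' @param genes optional gene universe to intersect with (e.g. rownames
#'   of the expression matrix).
#' @return an `igraph` with named vertices.
#' @export
ppi_network <- function(edges, genes = NULL) {
  g <- if (inherits(edges, "igraph")) edges
       else igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!is.null(genes)) {
    keep <- intersect(igraph::V(g)$name, genes)
    if (length(keep) < 2L)
      stopf("fewer than 2 network genes present in the expression matrix")
    g <- igraph::induced_subgraph(g, keep)
  }
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    big <- which.max(comp$csize)
    g <- igraph::induced_subgraph(g, which(comp$membership == big))
  }
  g
}

# largest adjacency eigenvalue (unweighted); dense for small graphs,
# power iteration otherwise
lambda_max <- function(graph) {
  n <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  if (n <= 2000L) {
    eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values[1]
  } else {
    v <- rep(1 / sqrt(n), n)
    lam <- 0
    for (i in seq_len(1000L)) {
      w <- as.numeric(A %*% v)
      nw <- sqrt(sum(w^2))
      if (nw == 0) return(0)
      w <- w / nw
      if (abs(nw - lam) < 1e-13) { lam <- nw; break }
      lam <- nw; v <- w
    }
    lam
  }
}

# core entropy-rate computation on precomputed undirected edge indices
entropy_rate_core <- function(x, ei, ej, n) {
  w <- x[ei] * x[ej]
  grp <- factor(c(ei, ej), levels = seq_len(n))
  s <- as.numeric(rowsum(c(w, w), grp))
  pi_ <- s / sum(s)
  p1 <- w / s[ei]; p2 <- w / s[ej]
  hterm <- rowsum(c(p1 * log(p1), p2 * log(p2)), grp)
  H <- -as.numeric(hterm)
  H[is.na(H)] <- 0
  sum(pi_ * H)
}

#' Entropy rate of an expression-weighted random walk
#'
#' Expression is superimposed on the network by mass-action edge weights
#' `w_ij = x_i x_j` for each interaction `(i, j)`. The walk's transition
#' probabilities are `p_ij = w_ij / sum_k w_ik`, its stationary
#' distribution is proportional to the weighted degree
#' (`pi_i ~ sum_j w_ij`, exact by detailed balance on a symmetric
#' weight), and the Shannon entropy rate is
#' `SR = -sum_i pi_i sum_j p_ij log p_ij` (nats). The normalized score
#' divides by `log(lambda_max)` of the unweighted adjacency — the maximal
#' entropy rate any walk on the graph can attain — giving a value in
#' `[0, 1]` comparable across networks. Transcriptionally promiscuous
#' (stem-like) profiles spread the walk and score high; specialized
#' profiles concentrate it and score low.
#'
#' @param x named expression vector covering the network's genes
#'   (non-negative; zeros are lifted by `pseudo`).
#' @param graph connected `igraph` from [ppi_network()].
#' @param pseudo see [entropy_params()].
#' @return list: `raw` (nats), `normalized` (in `[0, 1]`, `NA` with a
#'   warning when `log(lambda_max) <= 0`, e.g. a single-edge graph),
#'   `lambda_max`.
#' @export
entropy_rate <- function(x, graph, pseudo = NULL) {
  if (!igraph::is_connected(graph))
    stopf("network is disconnected; restrict to its largest connected component (see ppi_network)")
  nodes <- igraph::V(graph)$name
  if (!is.null(names(x))) {
    if (!all(nodes %in% names(x)))
      stopf("expression vector missing %d network genes",
            sum(!nodes %in% names(x)))
    x <- x[nodes]
  } else if (length(x) != length(nodes)) {
    stopf("unnamed expression vector must match vertex count")
  }
  if (any(x < 0)) stopf("expression must be non-negative")
  if (is.null(pseudo)) {
    nz <- x[x > 0]
    pseudo <- if (length(nz)) 1e-6 * mean(nz) else 1e-6
  }
  x[x <= 0] <- pseudo
  el <- igraph::as_edgelist(graph, names = FALSE)
  raw <- entropy_rate_core(x, el[, 1L], el[, 2L], length(nodes))
  lam <- lambda_max(graph)
  norm <- if (log(lam) <= 0) {
    warning("log(lambda_max) <= 0: normalized entropy undefined for this network")
    NA_real_
  } else {
    v <- raw / log(lam)
    if (v > 1 && v < 1 + 1e-8) v <- 1
    if (v < 0 && v > -1e-12) v <- 0
    v
  }
  list(raw = raw, normalized = norm, lambda_max = lam)
}

#' k-nearest-neighbor smoothing of raw counts
#'
#' Reduces dropout-induced technical variance before entropy scoring:
#' a neighbor graph is built on Euclidean distance between log1p
#' depth-normalized profiles, and each cell's smoothed profile is the sum
#' of raw counts over itself and its `k` nearest neighbors (output stays
#' integer-valued; renormalization follows separately). `k = 0` is the
#' identity.
#'
#' @param counts genes x cells raw counts (sparse or dense).
#' @param k neighbor count; must be `< ncol(counts)`.
#' @param target_depth depth used for the neighbor-space normalization.
#' @return matrix of the same type, genes x cells.
#' @export
knn_smooth <- function(counts, k = 8L, target_depth = 1e4) {
  n <- ncol(counts)
  if (k == 0L) return(counts)
  if (k >= n) stopf("k (%d) must be smaller than the number of cells (%d)", k, n)
  prof <- log1p(as.matrix(depth_normalize(counts, target_depth)))
  d <- as.matrix(stats::dist(t(prof)))
  idx <- integer(0); jdx <- integer(0)
  for (j in seq_len(n)) {
    nn <- order(d[, j], seq_len(n))[seq_len(k + 1L)]  # includes self (d=0)
    if (!j %in% nn) nn <- c(j, nn[seq_len(k)])
    idx <- c(idx, nn); jdx <- c(jdx, rep(j, length(nn)))
  }
  S <- Matrix::sparseMatrix(i = idx, j = jdx, x = 1, dims = c(n, n))
  out <- counts %*% S
  dimnames(out) <- dimnames(counts)
  out
}

#' Renormalize each cell to a fixed depth
#'
#' @param counts genes x cells matrix; no zero-depth cells.
#' @param target_depth column sum after normalization (default 10,000).
#' @return matrix with every column summing to `target_depth`.
#' @export
depth_normalize <- function(counts, target_depth = 1e4) {
  depth <- Matrix::colSums(counts)
  if (any(depth == 0)) {
    bad <- colnames(counts)[depth == 0][1]
    stopf("zero-depth cell cannot be normalized: %s", bad %||% "<unnamed>")
  }
  if (inherits(counts, "Matrix")) {
    counts %*% Matrix::Diagonal(x = target_depth / depth)
  } else {
    sweep(counts, 2L, depth / target_depth, `/`)
  }
}

#' Score cells for differentiation potency
#'
#' Full pipeline: kNN smoothing of raw counts ([knn_smooth()]), depth
#' renormalization ([depth_normalize()]), then per-cell [entropy_rate()]
#' on the network restricted to genes present in the matrix. Given
#' cluster labels, clusters are ranked by descending mean normalized
#' score (ties broken by label order).
#'
#' @param counts genes x cells raw counts.
#' @param graph `igraph` interactome (restricted/validated via
#'   [ppi_network()] against the matrix genes).
#' @param params an [entropy_params()].
#' @param clusters optional per-cell cluster labels.
#' @return object of class `entropy_scores`: `scores` (barcode, raw,
#'   normalized), `cluster_summary` (cluster, n, mean_score, rank),
#'   `lambda_max`, `n_network_genes`.
#' @export
score_cells <- function(counts, graph, params = entropy_params(),
                        clusters = NULL) {
  g <- ppi_network(graph, genes = rownames(counts))
  sm <- knn_smooth(counts, params$knn_k, params$target_depth)
  nm <- depth_normalize(sm, params$target_depth)
  nodes <- igraph::V(g)$name
  m <- as.matrix(nm[nodes, , drop = FALSE])
  el <- igraph::as_edgelist(g, names = FALSE)
  lam <- lambda_max(g)
  loglam <- log(lam)
  n_nodes <- length(nodes)
  raw <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    nz <- x[x > 0]
    ps <- params$pseudo %||% if (length(nz)) 1e-6 * mean(nz) else 1e-6
    x[x <= 0] <- ps
    entropy_rate_core(x, el[, 1L], el[, 2L], n_nodes)
  }, numeric(1))
  normalized <- if (loglam > 0) pmin(1, pmax(0, raw / loglam)) else
    rep(NA_real_, length(raw))
  scores <- data.frame(barcode = colnames(counts) %||%
                         as.character(seq_len(ncol(counts))),
                       raw = raw, normalized = normalized,
                       stringsAsFactors = FALSE)
  cs <- NULL
  if (!is.null(clusters)) {
    lab <- sort(unique(as.character(clusters)))
    mean_score <- vapply(lab, function(cl)
      mean(normalized[as.character(clusters) == cl]), numeric(1))
    o <- order(-mean_score)  # stable: ties keep label order
    rk <- integer(length(lab)); rk[o] <- seq_along(lab)
    cs <- data.frame(cluster = lab,
                     n = as.integer(table(factor(clusters, levels = lab))),
                     mean_score = mean_score, rank = rk,
                     stringsAsFactors = FALSE)
    cs <- cs[order(cs$rank), ]
  }
  structure(list(scores = scores, cluster_summary = cs, lambda_max = lam,
                 n_network_genes = n_nodes, params = params),
            class = "entropy_scores")
}

#' @export
print.entropy_scores <- function(x, ...) {
  cat(sprintf("<entropy_scores> %d cells on a %d-gene network (lambda_max %.3f)\n",
              nrow(x$scores), x$n_network_genes, x$lambda_max))
  cat(sprintf("  normalized score: median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$scores$normalized),
              min(x$scores$normalized), max(x$scores$normalized)))
  if (!is.null(x$cluster_summary)) {
    cat("  cluster ranking (descending mean score):\n")
    print(x$cluster_summary, row.names = FALSE)
  }
  invisible(x)
}

#' Boxplot of normalized entropy scores by cluster
#'
#' @param x an `entropy_scores` object scored with cluster labels.
#' @param clusters per-cell labels (required if not scored with them).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.entropy_scores <- function(x, clusters = NULL, ...) {
  if (is.null(clusters) && is.null(x$cluster_summary))
    stopf("no cluster labels available")
  if (is.null(clusters))
    stopf("supply the per-cell cluster labels used for scoring")
  graphics::boxplot(x$scores$normalized ~ clusters,
                    ylab = "normalized entropy score", xlab = "cluster", ...)
  invisible(x)
}

#' Gene-wise correlation with entropy scores
#'
#' Spearman correlation of each gene's unsmoothed, depth-normalized
#' expression with the per-cell entropy score, with
#' Benjamini-Hochberg adjustment across all tested genes. Genes with
#' positive correlation are overexpressed in stem-like (high-entropy)
#' cells; negative correlation marks differentiation-associated genes.
#' Constant genes have undefined correlation: they are reported with
#' `NA` and excluded from the adjustment's test count.
#'
#' @param norm_counts unsmoothed depth-normalized genes x cells matrix
#'   (see [depth_normalize()]).
#' @param scores an `entropy_scores` object or numeric vector aligned
#'   with the columns.
#' @return data frame: `gene`, `rho`, `p`, `q`.
#' @export
gene_entropy_correlation <- function(norm_counts, scores) {
  s <- if (inherits(scores, "entropy_scores")) scores$scores$normalized
       else as.numeric(scores)
  if (length(s) != ncol(norm_counts))
    stopf("scores not aligned with cells (%d vs %d)", length(s),
          ncol(norm_counts))
  m <- as.matrix(norm_counts)
  n <- ncol(m)
  rs <- rank(s)
  rho <- apply(m, 1L, function(g) {
    if (max(g) == min(g)) return(NA_real_)
    stats::cor(rank(g), rs)
  })
  tt <- rho * sqrt((n - 2) / pmax(1e-300, 1 - rho^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!is.na(rho) & abs(rho) >= 1] <- 0
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(gene = rownames(m) %||% as.character(seq_len(nrow(m))),
             rho = rho, p = p, q = q, row.names = NULL,
             stringsAsFactors = FALSE)
}
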