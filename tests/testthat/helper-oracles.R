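# Independent oracles and small fixture builders shared across tests.

# dense brute-force entropy rate: explicit transition matrix, stationary
# distribution from the eigen decomposition of t(P)
oracle_entropy_rate <- function(x, A) {
  W <- A * outer(x, x)
  diag(W) <- 0
  P <- W / rowSums(W)
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  pi_ <- v / sum(v)
  -sum(pi_ * rowSums(ifelse(P > 0, P * log(P), 0)))
}

# random connected simple graph on n named vertices
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up[runif(length(up)) < p]] <- 1
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    if (igraph::is_connected(g) && igraph::ecount(g) >= 2) {
      igraph::V(g)$name <- paste0("g", seq_len(n))
      return(list(graph = g, A = A))
    }
  }
}

# per-cell brute-force QC predicate, evaluated independently of qc_filter
brute_qc_survivors <- function(counts, params, mito_pattern = "^mt-") {
  m <- as.matrix(counts)
  keep_gene <- vapply(seq_len(nrow(m)),
                      function(i) sum(m[i, ] > 0) >= params$min_cells_per_feature,
                      logical(1))
  m <- m[keep_gene, , drop = FALSE]
  mito <- grepl(mito_pattern, rownames(m), ignore.case = TRUE)
  keep <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    nc <- sum(v); nf <- sum(v > 0)
    pm <- if (nc > 0) 100 * sum(v[mito]) / nc else 0
    pm < params$mito_max_pct && nf > params$nfeature_min && nc < params$ncount_max
  }, logical(1))
  colnames(m)[keep]
}

# small noise-free chip spec used by imaging tests
small_chip_spec <- function(n_fovs = 2L, fill = 0.7, seed = 7L,
                            noise_sd = 0, intensity_cv = 0, ...) {
  sim_chip_spec(n_fovs = n_fovs, pens_nrow = 4L, pens_ncol = 4L,
                pen_fill_prob = fill, timepoints = c(0, 96),
                noise_sd = noise_sd, intensity_cv = intensity_cv,
                seed = seed, ...)
}

# match detections to planted cells by nearest center; returns per-cell
# distances in both directions
match_detections <- function(det, truth) {
  d_to_truth <- vapply(seq_len(nrow(det)), function(i)
    min(sqrt((truth$r - det$r[i])^2 + (truth$c - det$c[i])^2)), numeric(1))
  t_to_det <- vapply(seq_len(nrow(truth)), function(i)
    min(sqrt((det$r - truth$r[i])^2 + (det$c - truth$c[i])^2)), numeric(1))
  list(det_err = d_to_truth, truth_err = t_to_det)
}

# detect + quantify + nearest-truth subtype labels for one simulated chip
run_imaging_pipeline <- function(sim, params = hough_params(r_min = 3L, r_max = 8L)) {
  recs <- list(); labs <- list(); dets <- list()
  for (fv in names(sim$layout$fovs)) {
    oep <- sim$images[[fv]][["t0"]][["OEP"]]
    det <- detect_cells(oep, sim$layout, fv, params, t_hours = 0)
    dets[[fv]] <- det
    if (!nrow(det)) next
    fluor <- sim$images[[fv]][["t0"]]
    fluor <- fluor[setdiff(names(fluor), "OEP")]
    recs[[fv]] <- quantify_cells(det, fluor, sim$layout, fv)
    tr <- sim$truth$cells[sim$truth$cells$fov == fv, ]
    idx <- vapply(seq_len(nrow(det)), function(i)
      which.min((tr$r - det$r[i])^2 + (tr$c - det$c[i])^2), integer(1))
    labs[[fv]] <- data.frame(cell = det$cell, truth = tr$subtype[idx],
                             stringsAsFactors = FALSE)
  }
  list(detections = do.call(rbind, dets),
       records = do.call(rbind, recs),
       truth_labels = do.call(rbind, labs))
}
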