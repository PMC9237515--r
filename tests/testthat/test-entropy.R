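# Entropy-rate potency scoring: smoothing, normalization, the walk itself.

test_that("kNN smoothing sums raw counts over self plus neighbors", {
  # identical cells: smoothed profile is (k+1) x the raw profile
  m <- matrix(rep(c(3, 1, 0, 2), 6), 4, 6,
              dimnames = list(letters[1:4], sprintf("c%d", 1:6)))
  sm <- knn_smooth(m, k = 2)
  expect_equal(as.matrix(sm), m * 3, ignore_attr = TRUE)
  # k = 0 is the identity
  expect_identical(knn_smooth(m, 0), m)
  expect_error(knn_smooth(m, 6), "smaller than")
})

test_that("kNN smoothing matches brute-force neighbor selection", {
  set.seed(13)
  m <- matrix(rpois(5 * 40, 4), 40, 5,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%d", 1:5)))
  k <- 2
  sm <- knn_smooth(m, k)
  prof <- log1p(sweep(m, 2, colSums(m) / 1e4, `/`))
  d <- as.matrix(dist(t(prof)))
  for (j in 1:5) {
    nn <- setdiff(order(d[, j]), j)[seq_len(k)]
    expect_equal(as.numeric(sm[, j]), rowSums(m[, c(j, nn), drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("depth normalization behaves like a projection", {
  m <- matrix(c(2, 2, 0, 16, 4, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  n <- depth_normalize(m, 1e4)
  expect_equal(unname(colSums(as.matrix(n))), c(1e4, 1e4))
  # a cell at double the target depth is exactly halved
  m2 <- matrix(c(1e4, 1e4), 2, 1, dimnames = list(c("a", "b"), "c1"))
  expect_equal(as.numeric(depth_normalize(m2, 1e4)), c(5e3, 5e3))
  # idempotence
  expect_equal(as.matrix(depth_normalize(n, 1e4)), as.matrix(n),
               tolerance = 1e-12)
  m0 <- m; m0[, 1] <- 0
  expect_error(depth_normalize(m0), "zero-depth")
})

test_that("entropy rate matches hand computations on canonical graphs", {
  # 3-node path, uniform expression: pi = (1/4, 1/2, 1/4), H = (0, ln2, 0)
  g3 <- igraph::graph_from_edgelist(cbind(c("a", "b"), c("b", "c")),
                                    directed = FALSE)
  e3 <- entropy_rate(c(a = 1, b = 1, c = 1), g3)
  expect_equal(e3$raw, 0.5 * log(2), tolerance = 1e-12)
  expect_equal(e3$lambda_max, sqrt(2), tolerance = 1e-12)
  expect_equal(e3$normalized, 1, tolerance = 1e-12)
  # single edge: the walk is deterministic, and normalization is undefined
  g2 <- igraph::graph_from_edgelist(cbind("a", "b"), directed = FALSE)
  expect_warning(e2 <- entropy_rate(c(a = 2, b = 5), g2), "undefined")
  expect_equal(e2$raw, 0)
  expect_true(is.na(e2$normalized))
  # complete graphs at uniform expression attain the maximal rate ln(n-1)
  for (n in c(4, 6)) {
    gk <- igraph::make_full_graph(n)
    igraph::V(gk)$name <- paste0("v", seq_len(n))
    ek <- entropy_rate(stats::setNames(rep(2, n), paste0("v", seq_len(n))), gk)
    expect_equal(ek$raw, log(n - 1), tolerance = 1e-12)
    expect_equal(ek$normalized, 1, tolerance = 1e-12)
  }
})

test_that("entropy rate agrees with the dense eigen oracle", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    gg <- random_connected_graph(n)
    x <- runif(n, 0.05, 5)
    names(x) <- igraph::V(gg$graph)$name
    r <- suppressWarnings(entropy_rate(x, gg$graph))
    expect_equal(r$raw, oracle_entropy_rate(x, gg$A), tolerance = 1e-9)
    if (!is.na(r$normalized)) {
      expect_gte(r$normalized, 0)
      expect_lte(r$normalized, 1)
    }
  }
})

test_that("disconnected networks are rejected, ppi_network repairs them", {
  el <- data.frame(from = c("a", "c"), to = c("b", "d"))
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  expect_error(entropy_rate(c(a = 1, b = 1, c = 1, d = 1), g),
               "largest connected component")
  g2 <- ppi_network(el)
  expect_lte(igraph::vcount(g2), 2L)
  expect_true(igraph::is_connected(g2))
})

test_that("scores are scale invariant and constant across identical cells", {
  set.seed(7)
  m <- matrix(rpois(30 * 12, 5) + 1, 30, 12,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:12)))
  g <- simulate_ppi(rownames(m), seed = 3)
  s1 <- score_cells(m, g, entropy_params(knn_k = 0))
  m2 <- m; m2[, 3] <- m2[, 3] * 7  # library size absorbed by normalization
  s2 <- score_cells(m2, g, entropy_params(knn_k = 0))
  expect_equal(s2$scores$raw, s1$scores$raw, tolerance = 1e-12)
  ident <- m[, rep(1, 10)]
  colnames(ident) <- sprintf("c%d", 1:10)
  s3 <- score_cells(ident, g, entropy_params(knn_k = 3),
                    clusters = rep(c("x", "y"), 5))
  expect_equal(diff(range(s3$scores$normalized)), 0, tolerance = 1e-12)
  # tied cluster means rank by label order
  expect_equal(s3$cluster_summary$cluster, c("x", "y"))
  expect_equal(s3$cluster_summary$rank, c(1L, 2L))
})

test_that("promiscuous expression scores above specialized expression", {
  spec <- sim_expr_spec(n_genes = 80, n_cells = 60, subtype_mix = c(OTHER = 1),
                        depth_mean = 3000, depth_sd = 300,
                        cluster_design = list(
                          promiscuous = list(frac = 0.5, active = "all"),
                          specialized = list(frac = 0.5, active = 8)),
                        seed = 11)
  sim <- simulate_counts(spec)
  g <- simulate_ppi(rownames(sim$counts), seed = 2)
  sc <- score_cells(sim$counts, g, clusters = sim$cells$cluster)
  cs <- sc$cluster_summary
  expect_equal(cs$cluster[cs$rank == 1], "promiscuous")
  expect_gt(cs$mean_score[cs$cluster == "promiscuous"],
            cs$mean_score[cs$cluster == "specialized"])
})

test_that("smoothing reduces score variance within a homogeneous cluster", {
  spec <- sim_expr_spec(n_genes = 80, n_cells = 50, subtype_mix = c(OTHER = 1),
                        depth_mean = 1500, depth_sd = 200, seed = 23)
  sim <- simulate_counts(spec)
  g <- simulate_ppi(rownames(sim$counts), seed = 4)
  v_raw <- var(score_cells(sim$counts, g,
                           entropy_params(knn_k = 0))$scores$normalized)
  v_sm <- var(score_cells(sim$counts, g,
                          entropy_params(knn_k = 8))$scores$normalized)
  expect_lt(v_sm, v_raw)
})

test_that("gene-entropy correlations follow Spearman + BH conventions", {
  set.seed(41)
  n <- 40
  s <- runif(n)
  m <- rbind(exact = s,                       # rho = 1 by construction
             noise = rnorm(n),
             konst = rep(2, n))               # undefined correlation
  colnames(m) <- sprintf("c%02d", seq_len(n))
  res <- gene_entropy_correlation(m, s)
  expect_equal(res$rho[res$gene == "exact"], 1)
  expect_equal(res$p[res$gene == "exact"], 0)
  expect_true(is.na(res$rho[res$gene == "konst"]))
  expect_true(is.na(res$q[res$gene == "konst"]))
  # cross-check rho and p against stats::cor.test
  ct <- suppressWarnings(cor.test(m["noise", ], s, method = "spearman",
                                  exact = FALSE))
  expect_equal(res$rho[res$gene == "noise"], unname(ct$estimate),
               tolerance = 1e-12)
  expect_equal(res$p[res$gene == "noise"], ct$p.value, tolerance = 1e-9)
  # BH: q >= p, monotone after sorting, constant genes excluded from m
  ok <- !is.na(res$p)
  expect_true(all(res$q[ok] >= res$p[ok] - 1e-15))
  o <- order(res$p[ok])
  expect_true(all(diff(res$q[ok][o]) >= -1e-15))
})

test_that("a gene active only in the promiscuous cluster correlates positively", {
  spec <- sim_expr_spec(n_genes = 80, n_cells = 60, subtype_mix = c(OTHER = 1),
                        depth_mean = 3000, depth_sd = 0,
                        cluster_design = list(
                          promiscuous = list(frac = 0.5, active = "all"),
                          specialized = list(frac = 0.5, active = 8)),
                        seed = 17)
  sim <- simulate_counts(spec)
  g <- simulate_ppi(rownames(sim$counts), seed = 2)
  sc <- score_cells(sim$counts, g, clusters = sim$cells$cluster)
  # filler genes outside the specialized cluster's active set are
  # expressed only by promiscuous cells
  res <- gene_entropy_correlation(depth_normalize(sim$counts), sc)
  marker <- "g0050"
  expect_gt(res$rho[res$gene == marker], 0)
})
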