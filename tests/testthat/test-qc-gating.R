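# scRNA-seq QC filtering, scaled expression, marker gating, composition.

toy_counts <- function() {
  # 8 genes x 6 cells, engineered per-cell stats; thresholds scaled down
  genes <- c("mt-a", "mt-b", "g1", "g2", "g3", "g4", "g5", "g6")
  m <- matrix(0, 8, 6, dimnames = list(genes, sprintf("c%d", 1:6)))
  m["g1", ] <- c(10, 10, 10, 10, 10, 10)
  m["g2", ] <- c(10, 10, 10, 10, 10, 0)    # c6 loses a feature
  m["g3", ] <- c(10, 10, 10, 10, 10, 10)
  m["g4", ] <- c(10, 10, 10, 200, 10, 0)   # c4 exceeds the count ceiling
  m["mt-a", ] <- c(2, 30, 2, 2, 2, 0)      # c2 exceeds the mito cap; c6
                                           # is left with only 2 features
  m
}

test_that("qc_filter matches a brute-force per-cell predicate", {
  m <- toy_counts()
  qp <- qc_params(mito_max_pct = 20, nfeature_min = 3, ncount_max = 100,
                  min_cells_per_feature = 2)
  res <- qc_filter(m, qp)
  expect_equal(sort(colnames(res$counts)),
               sort(brute_qc_survivors(m, qp)))
  # c2 (mito), c4 (ncount), c6 (nfeature after g2 drop? g2 kept; c6 has
  # features g1,g3,g4 = 3, not > 3) removed
  expect_equal(res$report$n_cells_out, 3L)
  expect_equal(res$report$removed_mito, 1L)
  expect_equal(res$report$removed_ncount, 1L)
  expect_equal(res$report$removed_nfeature, 1L)
})

test_that("qc_filter is the identity when every cell passes, and idempotent", {
  m <- toy_counts()[, c(1, 3, 5)]
  qp <- qc_params(mito_max_pct = 50, nfeature_min = 2, ncount_max = 500,
                  min_cells_per_feature = 1)
  res <- qc_filter(m, qp)
  expect_equal(as.matrix(res$counts), as.matrix(m[rowSums(m) > 0, ]))
  res2 <- qc_filter(res$counts, qp)
  expect_equal(as.matrix(res2$counts), as.matrix(res$counts))
  expect_equal(res2$report$n_cells_out, res$report$n_cells_out)
})

test_that("qc_filter survives an all-fail matrix without erroring", {
  m <- toy_counts()
  qp <- qc_params(mito_max_pct = 0.001, nfeature_min = 3, ncount_max = 100,
                  min_cells_per_feature = 1)
  res <- qc_filter(m, qp)
  expect_equal(ncol(res$counts), 0L)
})

test_that("strict inequalities hold exactly at the thresholds", {
  genes <- c(sprintf("g%03d", 1:60), "mt-x")
  # cell at exactly 20% mito, exactly nfeature_min features, exactly
  # ncount_max counts must be removed (strict <, >, <)
  m <- matrix(0, 61, 4, dimnames = list(genes, c("at_mito", "at_nf",
                                                 "at_nc", "pass")))
  m[1:50, "at_mito"] <- 1; m["mt-x", "at_mito"] <- 12.5  # 12.5/62.5 = 20%
  m[1:30, "at_nf"] <- 2                                  # exactly 30 features
  m[1:50, "at_nc"] <- 2                                  # exactly 100 counts
  m[1:40, "pass"] <- 2
  qp <- qc_params(mito_max_pct = 20, nfeature_min = 30, ncount_max = 100,
                  min_cells_per_feature = 1)
  res <- qc_filter(m, qp)
  expect_equal(colnames(res$counts), "pass")
})

test_that("scale_expression agrees with hand arithmetic on a 3x3 case", {
  m <- matrix(c(1, 2, 1,
                0, 4, 4,
                3, 2, 5), 3, 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c("c1", "c2", "c3")))
  s <- scale_expression(m, target_depth = 10)
  # oracle: per-cell depth to 10, log1p, per-gene z-score
  d <- colSums(m)
  ln <- log1p(sweep(m, 2, d / 10, `/`))
  z <- t(apply(ln, 1, function(v) (v - mean(v)) / sd(v)))
  expect_equal(unclass(s), z, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("constant genes scale to zero and zero-depth cells error", {
  m <- matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  # equal depths make gA constant after normalization
  m[2, ] <- c(1, 1, 1)
  s <- scale_expression(m)
  expect_equal(unname(s["gA", ]), c(0, 0, 0))
  m0 <- m; m0[, 2] <- 0
  expect_error(scale_expression(m0), "c2")
})

test_that("depth normalization leaves relative profiles unchanged", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  m2 <- m; m2[, 1] <- m2[, 1] * 2  # double one cell's library
  n1 <- depth_normalize(m); n2 <- depth_normalize(m2)
  expect_equal(n1, n2)
})

test_that("gating maps planted subtypes back exactly at zero noise", {
  spec <- sim_expr_spec(n_genes = 100, n_cells = 400, depth_mean = 3000,
                        depth_sd = 0, mito_frac_sd = 0, seed = 5)
  sim <- simulate_counts(spec)
  g <- gate_cells(scale_expression(sim$counts))
  truth <- ifelse(sim$cells$subtype == "OTHER", "UNASSIGNED",
                  sim$cells$subtype)
  expect_equal(as.character(g$labels$subtype), truth)
  expect_equal(sum(g$counts), ncol(sim$counts))
})

test_that("an all-negative scaled matrix yields zero triple positives", {
  s <- matrix(-1, 3, 10, dimnames = list(c("Epcam", "Itga6", "Ly6a"),
                                         sprintf("c%d", 1:10)))
  g <- gate_cells(s)
  expect_equal(unname(g$counts["P8"]), 0L)
  expect_equal(g$p8_pct, 0)
})

test_that("gating is monotone in the threshold", {
  set.seed(2)
  s <- matrix(rnorm(3 * 200), 3, 200,
              dimnames = list(c("Epcam", "Itga6", "Ly6a"), NULL))
  n_p8 <- vapply(c(-1, 0, 0.3, 0.8, 2), function(th)
    unname(gate_cells(s, gating_config(threshold = th))$counts["P8"]),
    integer(1))
  expect_true(all(diff(n_p8) <= 0))
})

test_that("a missing marker gene suggests near matches", {
  s <- matrix(0, 3, 5, dimnames = list(c("Epcam", "ITGA6x", "Ly6a"), NULL))
  expect_error(gate_cells(s), "Itga6")
})

test_that("triple-positive percent is reported to two decimals", {
  n <- 5195; k <- 116
  s <- matrix(-1, 3, n, dimnames = list(c("Epcam", "Itga6", "Ly6a"), NULL))
  s[, seq_len(k)] <- 1
  g <- gate_cells(s)
  expect_equal(unname(g$counts["P8"]), k)
  expect_equal(g$p8_pct, 2.23)
})

test_that("composition percents reproduce printed arithmetic", {
  cl <- rep("myo1", 1944)
  gr <- c(rep("C57BL/6", 362), rep("Comma-1D", 1582))
  cs <- composition_summary(cl, gr)
  expect_equal(cs$percent[cs$group == "C57BL/6"], 18.62)
  expect_equal(cs$percent[cs$group == "Comma-1D"], 81.38)
  cs2 <- composition_summary(rep("ductal", 2466),
                             c(rep("only", 102), rep("both", 2364)))
  expect_equal(cs2$percent[cs2$group == "only"], 4.14)
  cs3 <- composition_summary(c("a", "a"), factor(c("x", "x"),
                                                 levels = c("x", "y")))
  expect_equal(cs3$percent[cs3$group == "y"], 0)
})
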