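# Stage runner: file-based pipeline glue with resolved-config provenance.
# Each stage reads only files and writes only files, so runs are
# restartable per stage and byte-reproducible given config + seed.

#' Default run configuration
#'
#' Nested list of per-stage parameters mirroring the stage functions:
#' `simulate` ([sim_chip_spec()] arguments), `detect` ([hough_params()]),
#' `quantify` (normalization mode), `bin`, `growth`,
#' `simulate_counts` ([sim_expr_spec()]), `qc` ([qc_params()]),
#' `gate` ([gating_config()]), `entropy` ([entropy_params()]). Override
#' any entry via a YAML/JSON config file or the `overrides` argument of
#' [run_stage()].
#'
#' @param seed global seed; stage generators derive their seeds from it.
#' @param out_dir directory stage artifacts are written to.
#' @return nested configuration list.
#' @export
run_config <- function(seed = 1L, out_dir = "nanopheno_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(n_fovs = 4L, pens_nrow = 5L, pens_ncol = 5L,
                    pen_fill_prob = 0.5, noise_sd = 40, intensity_cv = 0.08,
                    timepoints = c(0, 96)),
    detect = list(r_min = 3L, r_max = 8L, rel_threshold = 0.5,
                  edge_rel = 0.25, peak_threshold = 65535,
                  peak_halfwidth = 2L, max_offset = 20L),
    quantify = list(mode = "fov_background"),
    bin = list(),
    growth = list(final_timepoint = NULL, dead_band = 0),
    simulate_counts = list(n_genes = 300L, n_cells = 400L),
    qc = list(mito_max_pct = 20, nfeature_min = 2000, ncount_max = 45000,
              min_cells_per_feature = 15),
    gate = list(threshold = 0.3),
    entropy = list(knn_k = 8L, target_depth = 1e4)
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Entries present in the file override [run_config()] defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(run_config(), user)
}

#' @noRd
merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(user[[k]]) && is.list(base[[k]]))
      merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

#' @noRd
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' @noRd
pkg_version <- function() {
  as.character(utils::packageVersion("nanopheno"))
}

# every artifact carries tool version + resolved-config hash in a header
write_stage_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nanopheno %s config_md5=%s", pkg_version(), hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname run_stage
#' @param path a stage CSV artifact.
#' @export
read_stage_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run one pipeline stage against files on disk
#'
#' Stages: `simulate` (render a synthetic chip), `detect` (cell
#' detection on every OEP image), `quantify` (t0 fluorescence per cell),
#' `bin` (level model + subtype assignment), `growth` (pen time series
#' and stratified summaries), `simulate_counts`, `qc`, `gate`, `entropy`.
#' Each stage reads its inputs from `config$out_dir` (or the paths in its
#' config section), writes its artifacts there with a header naming the
#' tool version and resolved-config hash, and returns the artifact paths.
#' The resolved configuration is written beside the outputs
#' (`config_resolved.json`) on every call.
#'
#' @param stage stage name.
#' @param config a [run_config()] list.
#' @param overrides named list merged over `config` before running.
#' @return invisibly, a named list of artifact paths.
#' @export
run_stage <- function(stage = c("simulate", "detect", "quantify", "bin",
                                "growth", "simulate_counts", "qc", "gate",
                                "entropy"),
                      config = run_config(), overrides = NULL) {
  stage <- match.arg(stage)
  if (!is.null(overrides)) config <- merge_config(config, overrides)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  jsonlite::write_json(config, file.path(config$out_dir,
                                         "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  t0 <- Sys.time()
  out <- switch(stage,
    simulate = stage_simulate(config),
    detect = stage_detect(config, hash),
    quantify = stage_quantify(config, hash),
    bin = stage_bin(config, hash),
    growth = stage_growth(config, hash),
    simulate_counts = stage_simulate_counts(config),
    qc = stage_qc(config, hash),
    gate = stage_gate(config, hash),
    entropy = stage_entropy(config, hash))
  message(sprintf("[nanopheno] stage %s done in %.1fs -> %s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  config$out_dir))
  invisible(out)
}

#' Run several stages in sequence
#'
#' @param stages character vector of stage names, executed in order.
#' @inheritParams run_stage
#' @export
run_pipeline <- function(stages, config = run_config(), overrides = NULL) {
  res <- lapply(stages, run_stage, config = config, overrides = overrides)
  names(res) <- stages
  invisible(res)
}

stage_simulate <- function(config) {
  args <- config$simulate
  args$seed <- args$seed %||% config$seed
  spec <- do.call(sim_chip_spec, args)
  sim <- simulate_chip(spec)
  img_dir <- file.path(config$out_dir, "images")
  write_chip_images(sim, img_dir)
  list(images = img_dir, layout = file.path(img_dir, "layout.json"))
}

stage_detect <- function(config, hash) {
  img_dir <- file.path(config$out_dir, "images")
  layout <- read_chip_layout(file.path(img_dir, "layout.json"))
  idx <- list_chip_images(img_dir)
  oep <- idx[idx$channel == "OEP", ]
  if (!nrow(oep)) stopf("no OEP images found in %s", img_dir)
  dc <- config$detect
  params <- hough_params(dc$r_min, dc$r_max, dc$rel_threshold,
                         dc$min_sep, dc$edge_rel, dc$peak_threshold,
                         dc$peak_halfwidth)
  dets <- lapply(seq_len(nrow(oep)), function(i) {
    img <- read_fov_image(oep$path[i])
    reg <- register_fov(img, layout, oep$fov[i],
                        max_offset = dc$max_offset %||% 20L)
    detect_cells(reg$image, layout, oep$fov[i], params,
                 t_hours = oep$t_hours[i])
  })
  det <- do.call(rbind, dets)
  path <- file.path(config$out_dir, "detections.csv")
  write_stage_csv(det, path, hash)
  list(detections = path)
}

stage_quantify <- function(config, hash) {
  img_dir <- file.path(config$out_dir, "images")
  layout <- read_chip_layout(file.path(img_dir, "layout.json"))
  det <- read_stage_csv(file.path(config$out_dir, "detections.csv"))
  det0 <- det[det$t_hours == min(det$t_hours), ]
  idx <- list_chip_images(img_dir)
  idx <- idx[idx$t_hours == min(det$t_hours) & idx$channel != "OEP", ]
  recs <- lapply(unique(det0$fov), function(fv) {
    sub <- idx[idx$fov == fv, ]
    imgs <- lapply(seq_len(nrow(sub)), function(i) read_fov_image(sub$path[i]))
    names(imgs) <- sub$channel
    quantify_cells(det0[det0$fov == fv, ], imgs, layout, fv,
                   mode = config$quantify$mode %||% "fov_background")
  })
  rec <- do.call(rbind, recs)
  path <- file.path(config$out_dir, "expression.csv")
  write_stage_csv(rec, path, hash)
  list(expression = path)
}

stage_bin <- function(config, hash) {
  rec <- read_stage_csv(file.path(config$out_dir, "expression.csv"))
  expr <- expression_matrix(rec)
  model <- fit_level_model(expr, seed = config$seed)
  labels <- assign_subtypes(expr, model)
  mpath <- file.path(config$out_dir, "level_model.json")
  jsonlite::write_json(
    list(version = pkg_version(), config_md5 = unname(config_hash(config)),
         channels = lapply(model$channels, function(f)
           list(centers = f$centers, boundary = f$boundary,
                labels = f$labels)),
         seed = model$seed),
    mpath, auto_unbox = TRUE, digits = NA)
  spath <- file.path(config$out_dir, "subtypes.csv")
  write_stage_csv(labels, spath, hash)
  list(model = mpath, subtypes = spath)
}

stage_growth <- function(config, hash) {
  det <- read_stage_csv(file.path(config$out_dir, "detections.csv"))
  sub_path <- file.path(config$out_dir, "subtypes.csv")
  if (file.exists(sub_path)) {
    subs <- read_stage_csv(sub_path)
    det$subtype <- subs$subtype[match(det$cell, subs$cell)]
  }
  series <- build_timeseries(det,
                             final_timepoint = config$growth$final_timepoint,
                             dead_band = config$growth$dead_band %||% 0)
  spath <- file.path(config$out_dir, "pen_series.csv")
  write_stage_csv(as.data.frame(series), spath, hash)
  gpath <- file.path(config$out_dir, "growth_summary.csv")
  summ <- rbind(cbind(stratify = "subtype",
                      summarize_growth(series, "subtype")),
                cbind(stratify = "t0_count",
                      summarize_growth(series, "t0_count")))
  write_stage_csv(summ, gpath, hash)
  list(series = spath, summary = gpath)
}

stage_simulate_counts <- function(config) {
  args <- config$simulate_counts
  args$seed <- args$seed %||% config$seed
  spec <- do.call(sim_expr_spec, args)
  sim <- simulate_counts(spec)
  dir <- file.path(config$out_dir, "counts")
  write_counts_mtx(sim$counts, dir)
  utils::write.csv(sim$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  list(counts = dir)
}

stage_qc <- function(config, hash) {
  counts <- read_counts_mtx(config$qc$counts_dir %||%
                              file.path(config$out_dir, "counts"))
  qp <- qc_params(config$qc$mito_max_pct, config$qc$nfeature_min,
                  config$qc$ncount_max, config$qc$min_cells_per_feature)
  res <- qc_filter(counts, qp)
  fdir <- file.path(config$out_dir, "counts_filtered")
  write_counts_mtx(res$counts, fdir)
  rpath <- file.path(config$out_dir, "qc_report.json")
  rep <- res$report
  rep$cell_stats <- NULL
  rep$params <- unclass(rep$params)
  rep$version <- pkg_version(); rep$config_md5 <- unname(config_hash(config))
  jsonlite::write_json(rep, rpath, auto_unbox = TRUE, digits = NA)
  list(filtered = fdir, report = rpath)
}

stage_gate <- function(config, hash) {
  counts <- read_counts_mtx(config$gate$counts_dir %||%
                              file.path(config$out_dir, "counts_filtered"))
  scaled <- scale_expression(counts)
  gc_ <- gating_config(threshold = config$gate$threshold %||% 0.3)
  res <- gate_cells(scaled, gc_)
  lpath <- file.path(config$out_dir, "gate_labels.csv")
  write_stage_csv(res$labels, lpath, hash)
  spath <- file.path(config$out_dir, "gate_summary.csv")
  write_stage_csv(data.frame(subtype = names(res$counts),
                             count = as.integer(res$counts),
                             fraction = as.numeric(res$fractions)),
                  spath, hash)
  list(labels = lpath, summary = spath)
}

stage_entropy <- function(config, hash) {
  counts <- read_counts_mtx(config$entropy$counts_dir %||%
                              file.path(config$out_dir, "counts"))
  edges_path <- config$entropy$edges
  graph <- if (!is.null(edges_path)) ppi_network(read_edge_list(edges_path))
           else simulate_ppi(rownames(counts), seed = config$seed)
  ep <- entropy_params(config$entropy$knn_k %||% 8L,
                       config$entropy$target_depth %||% 1e4)
  clusters <- NULL
  tc <- file.path(config$out_dir, "counts", "truth_cells.csv")
  if (file.exists(tc)) clusters <- utils::read.csv(tc)$cluster
  res <- score_cells(counts, graph, ep, clusters = clusters)
  spath <- file.path(config$out_dir, "entropy_scores.csv")
  write_stage_csv(res$scores, spath, hash)
  paths <- list(scores = spath)
  if (!is.null(res$cluster_summary)) {
    cpath <- file.path(config$out_dir, "entropy_cluster_ranking.csv")
    write_stage_csv(res$cluster_summary, cpath, hash)
    paths$ranking <- cpath
  }
  corr <- gene_entropy_correlation(depth_normalize(counts), res)
  gpath <- file.path(config$out_dir, "gene_entropy_correlation.csv")
  write_stage_csv(corr, gpath, hash)
  paths$correlations <- gpath
  invisible(paths)
}
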