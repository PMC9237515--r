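# File formats: 16-bit grayscale TIFF stacks, chip-layout JSON, ground
# truth / detection / expression CSV.

#' Read one FOV image from a 16-bit grayscale TIFF
#'
#' @param path TIFF file.
#' @return integer matrix of intensities in `[0, 65535]`.
#' @export
read_fov_image <- function(path) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * SATURATION)), nrow(m), ncol(m))
}

#' @rdname read_fov_image
#' @param img integer intensity matrix.
#' @export
write_fov_image <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img, 0), SATURATION) / SATURATION, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Write a simulated chip to disk
#'
#' Writes one TIFF per FOV/timepoint/channel using the naming pattern
#' `chip_{c}_fov_{f}_t{h}h_{channel}.tiff`, plus `layout.json` and the
#' ground-truth CSVs (`truth_cells.csv`, `truth_pen_counts.csv`).
#'
#' @param sim a [simulate_chip()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_chip_images <- function(sim, dir) {
  stopifnot(inherits(sim, "nanopen_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fov in names(sim$images)) {
    f <- as.integer(sub("fov", "", fov))
    for (tlab in names(sim$images[[fov]])) {
      h <- as.numeric(sub("t", "", tlab))
      for (ch in names(sim$images[[fov]][[tlab]])) {
        fn <- sprintf("chip_%s_fov_%02d_t%gh_%s.tiff", sim$chip_id, f, h, ch)
        write_fov_image(sim$images[[fov]][[tlab]][[ch]], file.path(dir, fn))
      }
    }
  }
  write_chip_layout(sim$layout, file.path(dir, "layout.json"))
  utils::write.csv(sim$truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth$pen_counts,
                   file.path(dir, "truth_pen_counts.csv"), row.names = FALSE)
  invisible(dir)
}

#' Serialize / read a chip layout as JSON
#'
#' Layout JSON schema: `dim`, `bit_depth`, and per FOV a `pens` object
#' (`pen_id -> [r0, c0, r1, c1]`, half-open 0-based rectangles) plus
#' `feature_points` (`[[r, c], ...]`).
#'
#' @param layout a `chip_layout`.
#' @param path JSON file.
#' @export
write_chip_layout <- function(layout, path) {
  stopifnot(inherits(layout, "chip_layout"))
  obj <- list(dim = layout$dim, bit_depth = layout$bit_depth,
              fovs = lapply(layout$fovs, function(f)
                list(pens = lapply(f$pens, unname),
                     feature_points = unname(apply(f$feature_points, 1L,
                                                   identity, simplify = FALSE)))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_chip_layout
#' @export
read_chip_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fovs <- lapply(obj$fovs, function(f) {
    pens <- lapply(f$pens, function(p) {
      p <- as.integer(p); names(p) <- c("r0", "c0", "r1", "c1"); p
    })
    fp <- f$feature_points
    if (is.list(fp)) fp <- do.call(rbind, fp)
    fp <- matrix(as.integer(fp), ncol = 2L,
                 dimnames = list(NULL, c("r", "c")))
    list(pens = pens, feature_points = fp)
  })
  structure(list(fovs = fovs, dim = as.integer(obj$dim),
                 bit_depth = as.integer(obj$bit_depth)),
            class = "chip_layout")
}

#' List chip image files in a directory by name pattern
#'
#' Parses filenames of the form `chip_{c}_fov_{f}_t{h}h_{channel}.tiff`.
#'
#' @param dir directory to scan.
#' @return data frame: path, chip, fov, t_hours, channel.
#' @export
list_chip_images <- function(dir) {
  files <- list.files(dir, pattern = "^chip_.*\\.tiff$", full.names = TRUE)
  if (!length(files))
    return(data.frame(path = character(), chip = character(),
                      fov = character(), t_hours = numeric(),
                      channel = character(), stringsAsFactors = FALSE))
  bn <- basename(files)
  m <- regmatches(bn, regexec("^chip_(.+)_fov_([0-9]+)_t([0-9.]+)h_([A-Za-z0-9]+)\\.tiff$", bn))
  ok <- lengths(m) == 5L
  m <- m[ok]; files <- files[ok]
  data.frame(path = files,
             chip = vapply(m, `[`, "", 2L),
             fov = sprintf("fov%02d", as.integer(vapply(m, `[`, "", 3L))),
             t_hours = as.numeric(vapply(m, `[`, "", 4L)),
             channel = vapply(m, `[`, "", 5L),
             stringsAsFactors = FALSE)
}
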