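# FOV registration, circular Hough transform cell detection, and per-cell
# fluorescence quantification against cell-free nanopen background.

#' Register a FOV image against its layout feature points
#'
#' Finds the integer-pixel translation that maximizes image intensity at
#' the layout's fiducial feature points (summed over a 3x3 neighborhood
#' around each point), searching offsets within `max_offset` pixels, and
#' applies it to the image. An image already aligned returns offset
#' `(0, 0)`; an image whose content was shifted by `(dr, dc)` returns the
#' inverse offset `(-dr, -dc)`.
#'
#' @param image integer intensity matrix (see [read_fov_image()]).
#' @param layout a `chip_layout`.
#' @param fov FOV id (name in `layout$fovs`).
#' @param max_offset maximum admissible offset magnitude per axis (px).
#' @return list: `image` (translated), `offset` `c(dr, dc)`, `magnitude`.
#' @section Errors: a featureless (constant-score) image, or a best match
#'   on the search boundary (true offset beyond `max_offset`), raises a
#'   registration-failure error.
#' @export
register_fov <- function(image, layout, fov, max_offset = 20L) {
  fp <- layout$fovs[[fov]]$feature_points
  if (is.null(fp) || nrow(fp) < 2L)
    stopf("layout must provide >= 2 feature points for %s", fov)
  offs <- -max_offset:max_offset
  score <- matrix(NA_real_, length(offs), length(offs))
  img <- image
  nr <- nrow(img); nc <- ncol(img)
  for (ii in seq_along(offs)) {
    for (jj in seq_along(offs)) {
      s <- 0
      for (k in seq_len(nrow(fp))) {
        # fiducial at fp appears at fp + shift; candidate offset t = -shift
        # scores the image at fp - t
        r <- fp[k, 1L] - offs[ii] + 1L
        c <- fp[k, 2L] - offs[jj] + 1L
        if (r < 2L || r > nr - 1L || c < 2L || c > nc - 1L) { s <- NA; break }
        s <- s + sum(img[(r - 1L):(r + 1L), (c - 1L):(c + 1L)])
      }
      score[ii, jj] <- s
    }
  }
  ok <- !is.na(score)
  if (!any(ok)) stopf("registration failure for %s: no admissible offset", fov)
  # a real fiducial match dominates the offset landscape; a featureless
  # image (uniform or noise-only) gives a flat score surface
  if (max(score[ok]) <= 0 ||
      max(score[ok]) < 1.2 * stats::median(score[ok]))
    stopf("registration failure for %s: featureless image", fov)
  score[!ok] <- -Inf
  best <- which(score == max(score[ok]), arr.ind = TRUE)
  if (nrow(best) > 1L) {
    mag <- abs(offs[best[, 1L]]) + abs(offs[best[, 2L]])
    best <- best[order(mag, best[, 1L], best[, 2L]), , drop = FALSE]
  }
  off <- c(offs[best[1L, 1L]], offs[best[1L, 2L]])
  if (any(abs(off) >= max_offset))
    stopf("registration failure for %s: offset beyond max_offset (%d px)",
          fov, max_offset)
  list(image = translate_image(image, off), offset = off,
       magnitude = sqrt(sum(off^2)))
}

#' @noRd
translate_image <- function(img, off) {
  if (all(off == 0L)) return(img)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(as.integer(round(stats::median(img))), nr, nc)
  sr <- seq_len(nr) - off[1L]; sc <- seq_len(nc) - off[2L]
  okr <- sr >= 1L & sr <= nr; okc <- sc >= 1L & sc <= nc
  out[okr, okc] <- img[sr[okr], sc[okc]]
  out
}

#' Detection parameters for the circular Hough transform
#'
#' @param r_min,r_max candidate circle radii in pixels.
#' @param rel_threshold accumulator score (fraction of a full circle of
#'   supporting edge pixels) required for a candidate.
#' @param min_sep minimum center separation in pixels (defaults to
#'   `r_min`); closer candidates are suppressed keeping the higher score.
#' @param edge_rel relative gradient-magnitude threshold for edge pixels.
#' @param peak_threshold intensity `T` a true positive must reach: the
#'   maximum over the peak neighborhood must satisfy `peak >= T`. Default
#'   is the 16-bit saturation value 65,535.
#' @param peak_halfwidth half-width `h` of the `(2h+1)^2` peak
#'   neighborhood.
#' @export
hough_params <- function(r_min = 3L, r_max = 15L, rel_threshold = 0.5,
                         min_sep = NULL, edge_rel = 0.25,
                         peak_threshold = 65535, peak_halfwidth = 2L) {
  if (r_max < r_min || r_min < 1L) stopf("empty or invalid radius range")
  structure(list(r_min = as.integer(r_min), r_max = as.integer(r_max),
                 rel_threshold = rel_threshold,
                 min_sep = as.integer(min_sep %||% r_min),
                 edge_rel = edge_rel, peak_threshold = peak_threshold,
                 peak_halfwidth = as.integer(peak_halfwidth)),
            class = "hough_params")
}

#' Circular Hough transform
#'
#' Classic vote-accumulation circle detector: gradient-magnitude edge
#' pixels vote for candidate centers at every integer offset on a circle
#' of each candidate radius; accumulator scores are normalized by the
#' circle circumference so a fully supported circle scores ~1. Candidates
#' above `rel_threshold` are deduplicated by greedy non-maximum
#' suppression at `min_sep`.
#'
#' @param img intensity matrix.
#' @param params a [hough_params()].
#' @return data frame: `r`, `c` (0-based center), `radius`, `score`.
#' @export
hough_circles <- function(img, params = hough_params()) {
  nr <- nrow(img); nc <- ncol(img)
  m <- matrix(as.numeric(img), nr, nc)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  g <- sqrt(gx^2 + gy^2)
  gmax <- max(g)
  empty <- data.frame(r = numeric(), c = numeric(), radius = integer(),
                      score = numeric())
  if (gmax <= 0) return(empty)
  idx <- which(g >= params$edge_rel * gmax)
  if (!length(idx)) return(empty)
  er <- ((idx - 1L) %% nr) + 1L
  ec <- ((idx - 1L) %/% nr) + 1L
  best_score <- matrix(0, nr, nc)
  best_r <- matrix(0L, nr, nc)
  for (rad in params$r_min:params$r_max) {
    k <- max(16L, ceiling(2 * pi * rad))
    ang <- 2 * pi * (seq_len(k) - 1L) / k
    off <- unique(cbind(round(rad * cos(ang)), round(rad * sin(ang))))
    votes_r <- rep(er, nrow(off)) + rep(off[, 1L], each = length(er))
    votes_c <- rep(ec, nrow(off)) + rep(off[, 2L], each = length(er))
    ok <- votes_r >= 1L & votes_r <= nr & votes_c >= 1L & votes_c <= nc
    acc <- tabulate((votes_c[ok] - 1L) * nr + votes_r[ok], nbins = nr * nc)
    score <- matrix(acc / nrow(off), nr, nc)
    upd <- score > best_score
    best_score[upd] <- score[upd]
    best_r[upd] <- rad
  }
  cand <- which(best_score >= params$rel_threshold)
  if (!length(cand)) return(empty)
  cr <- ((cand - 1L) %% nr) + 1L
  cc <- ((cand - 1L) %/% nr) + 1L
  sc <- best_score[cand]
  rd <- best_r[cand]
  o <- order(-sc, cr, cc)
  cr <- cr[o]; cc <- cc[o]; sc <- sc[o]; rd <- rd[o]
  # greedy NMS: two distinct cells cannot sit closer than their disks
  # allow, so a candidate is suppressed when it overlaps a kept circle
  # (separation below 0.7 x the radius sum), with min_sep as a floor
  keep <- logical(length(cr))
  kr <- numeric(0); kc <- numeric(0); krad <- numeric(0)
  for (i in seq_along(cr)) {
    sep2 <- pmax(params$min_sep, 0.7 * (krad + rd[i]))^2
    if (!length(kr) || all((kr - cr[i])^2 + (kc - cc[i])^2 >= sep2)) {
      keep[i] <- TRUE
      kr <- c(kr, cr[i]); kc <- c(kc, cc[i]); krad <- c(krad, rd[i])
    }
  }
  data.frame(r = cr[keep] - 1L, c = cc[keep] - 1L, radius = rd[keep],
             score = sc[keep])
}

#' @noRd
pen_of_point <- function(pens, r, c) {
  for (pid in names(pens)) {
    p <- pens[[pid]]
    if (r >= p["r0"] && r < p["r1"] && c >= p["c0"] && c < p["c1"])
      return(pid)
  }
  NA_character_
}

#' Detect cells in a registered OEP brightfield image
#'
#' Runs [hough_circles()] within the FOV, removes candidate centers that
#' fall outside every nanopen ROI (false-positive filter), and removes
#' candidates whose peak intensity (maximum over the `(2h+1)^2`
#' neighborhood of the center) fails `peak >= peak_threshold` — the
#' saturation-reach criterion that separates true cells from background
#' in the brightfield channel. Survivors are assigned to their containing
#' pen; ROI rectangles are disjoint so the assignment is unique.
#'
#' @param oep registered OEP intensity matrix.
#' @param layout a `chip_layout`.
#' @param fov FOV id.
#' @param params a [hough_params()].
#' @param t_hours timepoint annotation carried into the output.
#' @return data frame of cell detections: `cell`, `fov`, `pen`, `r`, `c`
#'   (0-based center), `radius`, `score`, `peak_oep`, `t_hours`.
#' @export
detect_cells <- function(oep, layout, fov, params = hough_params(),
                         t_hours = 0) {
  pens <- layout$fovs[[fov]]$pens
  pen_size <- min(vapply(pens, function(p) min(p["r1"] - p["r0"],
                                               p["c1"] - p["c0"]), numeric(1)))
  if (params$r_max > pen_size)
    stopf("r_max (%d) exceeds pen size (%d)", params$r_max, pen_size)
  cand <- hough_circles(oep, params)
  empty <- data.frame(cell = character(), fov = character(),
                      pen = character(), r = numeric(), c = numeric(),
                      radius = integer(), score = numeric(),
                      peak_oep = numeric(), t_hours = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(cand)) return(empty)
  cand$pen <- vapply(seq_len(nrow(cand)),
                     function(i) pen_of_point(pens, cand$r[i], cand$c[i]),
                     character(1))
  cand <- cand[!is.na(cand$pen), , drop = FALSE]
  if (!nrow(cand)) return(empty)
  h <- params$peak_halfwidth
  nr <- nrow(oep); nc <- ncol(oep)
  cand$peak_oep <- vapply(seq_len(nrow(cand)), function(i) {
    rs <- max(1L, cand$r[i] + 1L - h):min(nr, cand$r[i] + 1L + h)
    cs <- max(1L, cand$c[i] + 1L - h):min(nc, cand$c[i] + 1L + h)
    max(oep[rs, cs])
  }, numeric(1))
  cand <- cand[cand$peak_oep >= params$peak_threshold, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(cand$pen, cand$r, cand$c), , drop = FALSE]
  data.frame(cell = sprintf("%s_t%g_d%03d", fov, t_hours, seq_len(nrow(cand))),
             fov = fov, pen = cand$pen, r = cand$r, c = cand$c,
             radius = cand$radius, score = cand$score,
             peak_oep = cand$peak_oep, t_hours = t_hours,
             stringsAsFactors = FALSE)
}

#' @noRd
disk_pixels <- function(nr, nc, r0, c0, radius) {
  rr <- max(0L, r0 - radius):min(nr - 1L, r0 + radius)
  cc <- max(0L, c0 - radius):min(nc - 1L, c0 + radius)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  inside <- which(d2 <= radius^2, arr.ind = TRUE)
  cbind(rr[inside[, 1L]] + 1L, cc[inside[, 2L]] + 1L)
}

#' @noRd
roi_mean <- function(img, p) {
  mean(img[(p["r0"] + 1L):p["r1"], (p["c0"] + 1L):p["c1"]])
}

#' Quantify per-cell fluorescence, normalized to cell-free background
#'
#' For each detected cell and each channel, `raw` is the mean intensity
#' over the detected disk. The normalized intensity divides `raw` by a
#' background denominator: under the default `fov_background` mode, the
#' mean intensity over all cell-free pen ROIs of the FOV in that channel
#' (which makes the ratio invariant to global illumination differences
#' between FOVs and chips); under `own_roi`, the mean intensity of the
#' cell's own pen ROI.
#'
#' @param detections output of [detect_cells()] for one FOV/timepoint.
#' @param images named list `channel -> intensity matrix`, registered and
#'   sharing the detections' FOV/timepoint.
#' @param layout a `chip_layout`.
#' @param fov FOV id.
#' @param mode normalization denominator, see Details.
#' @return data frame: `cell`, `fov`, `pen`, `t_hours`, `channel`, `raw`,
#'   `normalized`.
#' @section Errors: `fov_background` mode with no cell-free pen in the
#'   FOV raises an error suggesting `mode = "own_roi"`.
#' @export
quantify_cells <- function(detections, images, layout, fov,
                           mode = c("fov_background", "own_roi")) {
  mode <- match.arg(mode)
  pens <- layout$fovs[[fov]]$pens
  occupied <- unique(detections$pen)
  cellfree <- setdiff(names(pens), occupied)
  if (mode == "fov_background" && !length(cellfree))
    stopf(paste("no cell-free pens in %s for fov_background normalization;",
                "use mode = 'own_roi'"), fov)
  out <- list()
  for (ch in names(images)) {
    img <- images[[ch]]
    denom_fov <- if (mode == "fov_background")
      mean(vapply(cellfree, function(pid) roi_mean(img, pens[[pid]]),
                  numeric(1)))
    for (i in seq_len(nrow(detections))) {
      px <- disk_pixels(nrow(img), ncol(img), detections$r[i],
                        detections$c[i], detections$radius[i])
      raw <- mean(img[px])
      denom <- if (mode == "fov_background") denom_fov
               else roi_mean(img, pens[[detections$pen[i]]])
      if (!is.finite(denom) || denom <= 0)
        stopf("normalization denominator is not positive in channel %s", ch)
      out[[length(out) + 1L]] <- data.frame(
        cell = detections$cell[i], fov = fov, pen = detections$pen[i],
        t_hours = detections$t_hours[i], channel = ch, raw = raw,
        normalized = raw / denom, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cell = character(), fov = character(),
                      pen = character(), t_hours = numeric(),
                      channel = character(), raw = numeric(),
                      normalized = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-FOV per-channel background baseline from cell-free pens
#'
#' Mean and sd of intensity over cell-free pen ROIs, exported for QC and
#' for baseline subtraction of expression readings.
#'
#' @param images named list `channel -> intensity matrix` for one FOV.
#' @param layout a `chip_layout`.
#' @param fov FOV id.
#' @param occupied_pens pen ids with detected cells at this timepoint
#'   (empty vector = all pens cell-free).
#' @return data frame: `fov`, `channel`, `mean`, `sd`, `n_pens`.
#' @export
background_baseline <- function(images, layout, fov,
                                occupied_pens = character()) {
  pens <- layout$fovs[[fov]]$pens
  cellfree <- setdiff(names(pens), occupied_pens)
  do.call(rbind, lapply(names(images), function(ch) {
    img <- images[[ch]]
    px <- unlist(lapply(cellfree, function(pid) {
      p <- pens[[pid]]
      as.vector(img[(p["r0"] + 1L):p["r1"], (p["c0"] + 1L):p["c1"]])
    }))
    data.frame(fov = fov, channel = ch,
               mean = if (length(px)) mean(px) else NA_real_,
               sd = if (length(px) > 1L) stats::sd(px) else 0,
               n_pens = length(cellfree), stringsAsFactors = FALSE)
  }))
}
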