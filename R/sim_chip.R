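# Synthetic nanopen chip generator: pen-grid layouts, multi-channel 16-bit
# image stacks with planted cells, and pen-level growth ground truth.

#' Specification for a synthetic nanopen chip
#'
#' Describes a chip to be rendered by [simulate_chip()]: the pen grid per
#' field of view (FOV), cell placement and radii, per-channel intensity
#' levels, background variability between FOVs and chips, and per-subtype
#' clonal growth rates. Defaults model a full Beacon-style chip: 22 imaging
#' FOVs tiling a nanopen array (the physical chip holds 3,500 pens; the
#' simulator uses a regular 16 x 10 grid per FOV), 16-bit imaging with
#' saturation at 65,535, brightfield (OEP) plus DAPI/FITC/TRED/CY5
#' fluorescence, and time-lapse capture every 12 h for 96 h.
#'
#' Cells are rendered as hard disks with a Gaussian-tapered edge
#' (`taper_sigma` = 1 px) so that gradient-based circle detection sees
#' realistic edges. In the OEP channel the disk plateau sits at
#' `cell_peak_intensity` (default: the 16-bit saturation value, matching
#' the saturation-reach criterion used to confirm true positives).
#' Fluorescence plateaus are set multiplicatively relative to the FOV
#' background so that a cell's normalized intensity approximates
#' `norm_high` for HIGH/POS marker levels and `norm_low` for LOW/NEG,
#' following the Epcam/Cd49f/Sca-1 subtype patterns (see
#' [subtype_from_levels()]).
#'
#' @param n_fovs number of fields of view.
#' @param pens_nrow,pens_ncol pen grid within each FOV.
#' @param pen_size pen side length in pixels (square pens).
#' @param gap inter-pen channel width in pixels.
#' @param margin border around the pen grid in pixels (fiducials live here).
#' @param cell_radius_range integer `c(r_min, r_max)` cell radii in pixels.
#' @param channels imaging channel names; the first must be `"OEP"`.
#' @param marker_channels named map from marker protein to fluorescence
#'   channel.
#' @param background_level `c(mean, sd)` of the per-FOV background intensity.
#' @param chip_factor_sd sd of the log-normal multiplicative chip-to-chip
#'   illumination factor.
#' @param cell_peak_intensity OEP disk plateau intensity (default 65,535).
#' @param noise_sd per-pixel Gaussian noise sd.
#' @param intensity_cv per-cell log-normal jitter on fluorescence plateaus
#'   (0 = noise-free fluorescence levels).
#' @param norm_high,norm_low,dapi_norm target normalized intensities for
#'   HIGH/POS, LOW/NEG marker levels and the DAPI nuclear stain.
#' @param subtype_mix proportions over P5, P6, P7, P8 (must sum to 1).
#' @param pen_fill_prob probability a pen receives cells at t0.
#' @param cells_per_pen_probs probabilities for 1..4 cells at t0 in a
#'   filled pen.
#' @param timepoints imaging timepoints in hours (must include 0).
#' @param growth_rates named per-subtype expected proliferation ratio over
#'   the full culture (final/t0 count after the last timepoint).
#' @param growth_cap maximum renderable cells per pen (crowding capacity).
#' @param stray_cells_per_fov saturated disks planted in the inter-pen
#'   region of each FOV (outside every ROI), for detector-filter checks.
#' @param taper_sigma Gaussian edge taper sd in pixels.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return object of class `sim_chip_spec`.
#' @seealso [simulate_chip()], [chip_layout_grid()]
#' @export
sim_chip_spec <- function(n_fovs = 22L,
                          pens_nrow = 16L, pens_ncol = 10L,
                          pen_size = 40L, gap = 6L, margin = 16L,
                          cell_radius_range = c(4L, 6L),
                          channels = c("OEP", "DAPI", "FITC", "TRED", "CY5"),
                          marker_channels = DEFAULT_MARKER_CHANNELS,
                          background_level = c(mean = 1200, sd = 120),
                          chip_factor_sd = 0.08,
                          cell_peak_intensity = 65535,
                          noise_sd = 40,
                          intensity_cv = 0.08,
                          norm_high = 3.0, norm_low = 1.3, dapi_norm = 2.0,
                          subtype_mix = c(P5 = 0.30, P6 = 0.30,
                                          P7 = 0.25, P8 = 0.15),
                          pen_fill_prob = 0.09,
                          cells_per_pen_probs = c(0.55, 0.25, 0.13, 0.07),
                          timepoints = seq(0, 96, by = 12),
                          growth_rates = c(P5 = 1.5, P6 = 1.5,
                                           P7 = 1.5, P8 = 1.5),
                          growth_cap = 9L,
                          stray_cells_per_fov = 0L,
                          taper_sigma = 1,
                          seed = 1L) {
  r <- as.integer(cell_radius_range)
  if (length(r) != 2L || r[1] > r[2]) stopf("cell_radius_range must be c(r_min, r_max)")
  if (r[1] < 2L) stopf("r_min must be >= 2 px")
  if (pen_size < 2L * r[2] + 6L)
    stopf("cell radius range too large for pen size (need pen_size >= 2*r_max + 6)")
  if (abs(sum(subtype_mix) - 1) > 1e-8) stopf("subtype_mix must sum to 1")
  if (!setequal(names(subtype_mix), c("P5", "P6", "P7", "P8")))
    stopf("subtype_mix must be named over P5..P8")
  if (cell_peak_intensity < 0 || cell_peak_intensity > SATURATION)
    stopf("cell_peak_intensity must lie in [0, %d]", SATURATION)
  if (channels[1] != "OEP") stopf("the first channel must be OEP")
  if (!all(marker_channels %in% channels)) stopf("marker_channels must be a subset of channels")
  if (!0 %in% timepoints) stopf("timepoints must include 0 (t0)")
  if (!setequal(names(growth_rates), c("P5", "P6", "P7", "P8")))
    stopf("growth_rates must be named over P5..P8")
  if (abs(sum(cells_per_pen_probs) - 1) > 1e-8) stopf("cells_per_pen_probs must sum to 1")
  spec <- list(n_fovs = as.integer(n_fovs),
               pens_nrow = as.integer(pens_nrow), pens_ncol = as.integer(pens_ncol),
               pen_size = as.integer(pen_size), gap = as.integer(gap),
               margin = as.integer(margin),
               cell_radius_range = r, channels = channels,
               marker_channels = marker_channels,
               background_level = background_level,
               chip_factor_sd = chip_factor_sd,
               cell_peak_intensity = cell_peak_intensity,
               noise_sd = noise_sd, intensity_cv = intensity_cv,
               norm_high = norm_high, norm_low = norm_low, dapi_norm = dapi_norm,
               subtype_mix = subtype_mix[c("P5", "P6", "P7", "P8")],
               pen_fill_prob = pen_fill_prob,
               cells_per_pen_probs = cells_per_pen_probs,
               timepoints = sort(unique(timepoints)),
               growth_rates = growth_rates,
               growth_cap = as.integer(growth_cap),
               stray_cells_per_fov = as.integer(stray_cells_per_fov),
               taper_sigma = taper_sigma,
               seed = as.integer(seed))
  class(spec) <- "sim_chip_spec"
  spec
}

#' Build a regular-grid chip layout
#'
#' Pens are half-open pixel rectangles `[r0, r1) x [c0, c1)` in 0-based
#' coordinates, pairwise disjoint within a FOV, with chip-wide unique pen
#' ids. Each FOV carries two fiducial feature points in opposite margin
#' corners, used for registration.
#'
#' @inheritParams sim_chip_spec
#' @return object of class `chip_layout` with elements `fovs` (per FOV: a
#'   `pens` named list of rectangles and a `feature_points` matrix),
#'   `dim`, and `bit_depth`.
#' @export
chip_layout_grid <- function(n_fovs = 4L, pens_nrow = 5L, pens_ncol = 5L,
                             pen_size = 40L, gap = 6L, margin = 16L) {
  nr <- 2L * margin + pens_nrow * pen_size + (pens_nrow - 1L) * gap
  nc <- 2L * margin + pens_ncol * pen_size + (pens_ncol - 1L) * gap
  pens_per_fov <- pens_nrow * pens_ncol
  fovs <- vector("list", n_fovs)
  names(fovs) <- sprintf("fov%02d", seq_len(n_fovs))
  for (f in seq_len(n_fovs)) {
    pens <- vector("list", pens_per_fov)
    k <- 0L
    for (i in seq_len(pens_nrow)) {
      for (j in seq_len(pens_ncol)) {
        k <- k + 1L
        r0 <- margin + (i - 1L) * (pen_size + gap)
        c0 <- margin + (j - 1L) * (pen_size + gap)
        pens[[k]] <- c(r0 = r0, c0 = c0, r1 = r0 + pen_size, c1 = c0 + pen_size)
      }
    }
    names(pens) <- sprintf("p%05d", (f - 1L) * pens_per_fov + seq_len(pens_per_fov))
    fp <- rbind(as.integer(c(floor(margin / 2), floor(margin / 2))),
                as.integer(c(nr - 1L - floor(margin / 2),
                             nc - 1L - floor(margin / 2))))
    colnames(fp) <- c("r", "c")
    fovs[[f]] <- list(pens = pens, feature_points = fp)
  }
  structure(list(fovs = fovs, dim = c(nr, nc), bit_depth = 16L),
            class = "chip_layout")
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("<chip_layout> %d FOVs x %d pens, image %d x %d px, %d-bit\n",
              length(x$fovs), length(x$fovs[[1]]$pens), x$dim[1], x$dim[2],
              x$bit_depth))
  invisible(x)
}

# disk with plateau at `value` for d <= radius - 2 and a Gaussian edge taper;
# composited by pixelwise max so saturated plateaus stay exact
render_disk <- function(img, ctr, radius, value, sigma = 1) {
  ext <- radius + ceiling(3 * sigma)
  rr <- max(0L, ctr[1] - ext):min(nrow(img) - 1L, ctr[1] + ext)
  cc <- max(0L, ctr[2] - ext):min(ncol(img) - 1L, ctr[2] + ext)
  d <- sqrt(outer((rr - ctr[1])^2, (cc - ctr[2])^2, `+`))
  edge <- pmax(d - (radius - 2), 0)
  f <- exp(-edge^2 / (2 * sigma^2))
  patch <- img[rr + 1L, cc + 1L, drop = FALSE]
  img[rr + 1L, cc + 1L] <- pmax(patch, round(value * f))
  img
}

render_cross <- function(img, ctr, arm = 3L, value = SATURATION) {
  r <- ctr[1] + 1L; c <- ctr[2] + 1L
  rs <- pmax(1L, r - arm):pmin(nrow(img), r + arm)
  cs <- pmax(1L, c - arm):pmin(ncol(img), c + arm)
  img[rs, c] <- value
  img[r, cs] <- value
  # solid 3x3 core so the fiducial localizes in both axes
  rb <- pmax(1L, r - 1L):pmin(nrow(img), r + 1L)
  cb <- pmax(1L, c - 1L):pmin(ncol(img), c + 1L)
  img[rb, cb] <- value
  img
}

# candidate anchor positions inside a pen; corners for <= 4 cells, a 3x3
# grid (with radii clamped to r_min) when crowding forces more
pen_anchors <- function(pen, n, r_max) {
  size <- pen["r1"] - pen["r0"]
  inset <- r_max + 2L
  p1 <- inset; p2 <- size - 1L - inset; pm <- floor((size - 1L) / 2L)
  if (n <= 4L) {
    pts <- rbind(c(p1, p1), c(p1, p2), c(p2, p1), c(p2, p2))
  } else {
    pts <- as.matrix(expand.grid(c(p1, pm, p2), c(p1, pm, p2)))
  }
  if (n > nrow(pts)) stopf("cannot place %d cells in one pen", n)
  idx <- sample.int(nrow(pts), n)
  pts <- pts[idx, , drop = FALSE] +
    matrix(sample(-1:1, 2L * n, replace = TRUE), ncol = 2L)
  sweep(pts, 2L, c(pen["r0"], pen["c0"]), `+`)
}

# one step of a Poisson branching process per subtype-count vector
branch_step <- function(counts, mult, cap) {
  nxt <- vapply(seq_along(counts), function(i) {
    if (counts[i] == 0L) 0L else as.integer(rpois(1L, counts[i] * mult[i]))
  }, integer(1))
  total <- sum(nxt)
  if (total > cap) {
    # crowding capacity: trim proportionally, largest counts first
    while (sum(nxt) > cap) {
      j <- which.max(nxt)
      nxt[j] <- nxt[j] - 1L
    }
  }
  nxt
}

#' Render a synthetic chip with planted ground truth
#'
#' Generates a [chip_layout_grid()] layout plus per-FOV, per-timepoint,
#' per-channel 16-bit image stacks. Cells are planted at t0 per
#' `spec$pen_fill_prob` and `spec$cells_per_pen_probs`, each with a subtype
#' drawn from `spec$subtype_mix`; fluorescence plateaus follow the
#' subtype's Epcam/Cd49f/Sca-1 level pattern. Pen occupancy evolves over
#' `spec$timepoints` by a per-subtype Poisson branching process whose
#' per-step multiplier is `rate^(dt/T)` (so the expected final/t0 ratio is
#' the subtype's `growth_rates` entry), truncated at `growth_cap` cells
#' per pen. Fluorescence channels are rendered at t0 only; the OEP
#' brightfield is rendered at every timepoint for growth tracking.
#'
#' All randomness derives from `spec$seed`: the same spec yields
#' bit-identical stacks.
#'
#' @param spec a [sim_chip_spec()].
#' @param chip_id integer chip identifier (used in file naming).
#' @return object of class `nanopen_sim`: `layout`, `images` (nested list
#'   `fov -> "t{h}" -> channel` of integer matrices), `truth` (data frames
#'   `cells`, `pen_counts`, `strays`, `fov_background`), `spec`, `chip_id`.
#' @export
simulate_chip <- function(spec, chip_id = 1L) {
  stopifnot(inherits(spec, "sim_chip_spec"))
  with_seed(spec$seed, {
    layout <- chip_layout_grid(spec$n_fovs, spec$pens_nrow, spec$pens_ncol,
                               spec$pen_size, spec$gap, spec$margin)
    chip_factor <- exp(rnorm(1L, 0, spec$chip_factor_sd))
    nfov <- spec$n_fovs
    fov_bg <- pmax(50, rnorm(nfov, spec$background_level[["mean"]],
                             spec$background_level[["sd"]]) * chip_factor)
    tps <- spec$timepoints
    t_final <- max(tps)
    n_steps <- length(tps) - 1L
    # per-step branching multiplier so that rate compounds to growth_rates
    step_mult <- if (n_steps > 0L) spec$growth_rates^(1 / n_steps) else spec$growth_rates
    r_rng <- spec$cell_radius_range
    patt <- SUBTYPE_PATTERNS

    cells <- list(); pen_counts <- list(); strays <- list()
    images <- vector("list", nfov); names(images) <- names(layout$fovs)
    cell_no <- 0L

    for (f in seq_len(nfov)) {
      fov_id <- names(layout$fovs)[f]
      fov <- layout$fovs[[f]]
      pens <- fov$pens
      filled <- names(pens)[runif(length(pens)) < spec$pen_fill_prob]
      # t0 planting
      fov_cells <- list()
      pen_sub_counts <- list()  # per pen: named int vector over subtypes
      for (pid in filled) {
        n0 <- sample(1:4, 1L, prob = spec$cells_per_pen_probs)
        subs <- sample(names(spec$subtype_mix), n0, replace = TRUE,
                       prob = spec$subtype_mix)
        pos <- pen_anchors(pens[[pid]], n0, r_rng[2])
        radii <- sample(r_rng[1]:r_rng[2], n0, replace = TRUE)
        jit <- if (spec$intensity_cv > 0)
          exp(rnorm(n0, 0, spec$intensity_cv)) else rep(1, n0)
        for (i in seq_len(n0)) {
          cell_no <- cell_no + 1L
          lv <- patt[subs[i], ]
          nm <- ifelse(lv %in% c("HIGH", "POS"), spec$norm_high, spec$norm_low)
          names(nm) <- names(lv)
          fov_cells[[length(fov_cells) + 1L]] <- data.frame(
            cell = sprintf("c%06d", cell_no), fov = fov_id, pen = pid,
            r = pos[i, 1], c = pos[i, 2], radius = radii[i],
            subtype = subs[i], t_hours = 0,
            norm_Epcam = nm[["Epcam"]] * jit[i],
            norm_Cd49f = nm[["Cd49f"]] * jit[i],
            norm_Sca1 = nm[["Sca-1"]] * jit[i],
            stringsAsFactors = FALSE)
        }
        sc <- table(factor(subs, levels = names(spec$subtype_mix)))
        pen_sub_counts[[pid]] <- as.integer(sc)
      }
      # growth trajectories (counts per pen per timepoint)
      traj <- list()
      for (pid in filled) {
        cnt <- pen_sub_counts[[pid]]
        series <- integer(length(tps)); series[1] <- sum(cnt)
        if (n_steps > 0L) for (s in seq_len(n_steps)) {
          cnt <- branch_step(cnt, step_mult, spec$growth_cap)
          series[s + 1L] <- sum(cnt)
        }
        traj[[pid]] <- series
      }
      for (pid in filled) {
        pen_counts[[length(pen_counts) + 1L]] <- data.frame(
          pen = pid, fov = fov_id, t_hours = tps, count = traj[[pid]],
          stringsAsFactors = FALSE)
      }
      fc <- if (length(fov_cells)) do.call(rbind, fov_cells) else NULL
      if (!is.null(fc)) cells[[length(cells) + 1L]] <- fc

      # stray disks in the inter-pen margin (outside every ROI)
      st <- NULL
      if (spec$stray_cells_per_fov > 0L) {
        sr <- layout$dim[1] - spec$margin + floor(spec$margin / 2) - 1L
        scol <- round(seq(spec$margin + 8L, layout$dim[2] - spec$margin - 8L,
                          length.out = spec$stray_cells_per_fov))
        st <- data.frame(fov = fov_id, r = rep(sr, spec$stray_cells_per_fov),
                         c = scol, radius = r_rng[1], stringsAsFactors = FALSE)
        strays[[length(strays) + 1L]] <- st
      }

      # render
      fimg <- list()
      for (ti in seq_along(tps)) {
        tlab <- sprintf("t%g", tps[ti])
        chans <- if (tps[ti] == 0) spec$channels else "OEP"
        fimg[[tlab]] <- list()
        for (ch in chans) {
          img <- matrix(fov_bg[f], layout$dim[1], layout$dim[2])
          if (spec$noise_sd > 0)
            img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                                nrow(img))
          if (ch == "OEP")
            for (k in seq_len(nrow(fov$feature_points)))
              img <- render_cross(img, fov$feature_points[k, ])
          if (tps[ti] == 0) {
            if (!is.null(fc)) for (i in seq_len(nrow(fc))) {
              val <- if (ch == "OEP") spec$cell_peak_intensity
                     else if (ch == "DAPI") spec$dapi_norm * fov_bg[f]
                     else {
                       mk <- names(spec$marker_channels)[spec$marker_channels == ch]
                       if (length(mk) == 0L) spec$norm_low * fov_bg[f]
                       else {
                         col <- c(Epcam = "norm_Epcam", Cd49f = "norm_Cd49f",
                                  `Sca-1` = "norm_Sca1")[[mk]]
                         fc[[col]][i] * fov_bg[f]
                       }
                     }
              img <- render_disk(img, c(fc$r[i], fc$c[i]), fc$radius[i], val,
                                 spec$taper_sigma)
            }
            if (ch == "OEP" && !is.null(st)) for (i in seq_len(nrow(st)))
              img <- render_disk(img, c(st$r[i], st$c[i]), st$radius[i],
                                 spec$cell_peak_intensity, spec$taper_sigma)
          } else {
            # later timepoints: re-render current occupancy (pen-level counts,
            # no cell-identity tracking)
            for (pid in filled) {
              n_t <- traj[[pid]][ti]
              if (n_t == 0L) next
              pos <- pen_anchors(pens[[pid]], n_t, r_rng[2])
              rad <- if (n_t > 4L) r_rng[1] else
                sample(r_rng[1]:r_rng[2], n_t, replace = TRUE)
              for (i in seq_len(n_t))
                img <- render_disk(img, pos[i, ], rad[min(i, length(rad))],
                                   spec$cell_peak_intensity, spec$taper_sigma)
            }
          }
          fimg[[tlab]][[ch]] <- clip16(img)
        }
      }
      images[[f]] <- fimg
    }

    empty_cells <- data.frame(cell = character(), fov = character(),
                              pen = character(), r = numeric(), c = numeric(),
                              radius = numeric(), subtype = character(),
                              t_hours = numeric(), norm_Epcam = numeric(),
                              norm_Cd49f = numeric(), norm_Sca1 = numeric(),
                              stringsAsFactors = FALSE)
    truth <- list(
      cells = if (length(cells)) do.call(rbind, cells) else empty_cells,
      pen_counts = if (length(pen_counts)) do.call(rbind, pen_counts) else
        data.frame(pen = character(), fov = character(), t_hours = numeric(),
                   count = integer(), stringsAsFactors = FALSE),
      strays = if (length(strays)) do.call(rbind, strays) else
        data.frame(fov = character(), r = numeric(), c = numeric(),
                   radius = numeric(), stringsAsFactors = FALSE),
      fov_background = data.frame(fov = names(layout$fovs), bg_mean = fov_bg,
                                  stringsAsFactors = FALSE),
      chip_factor = chip_factor)
    structure(list(layout = layout, images = images, truth = truth,
                   spec = spec, chip_id = chip_id),
              class = "nanopen_sim")
  })
}

#' @export
print.nanopen_sim <- function(x, ...) {
  cat(sprintf("<nanopen_sim> chip %s: %d FOVs, %d planted cells at t0, %d occupied pens\n",
              x$chip_id, length(x$images), nrow(x$truth$cells),
              length(unique(x$truth$pen_counts$pen))))
  invisible(x)
}

#' Simulate pen-level clonal growth without imaging
#'
#' Count-level counterpart of the growth component of [simulate_chip()]:
#' per-pen cell counts evolve over `timepoints` by a Poisson branching
#' process with per-subtype step multiplier `rate^(1/n_steps)`, so the
#' expected final/t0 proliferation ratio equals each subtype's entry in
#' `rates`. Pens are pure-subtype here (the sorted-import design). Used
#' for growth-kinetics parameter-recovery checks at larger pen counts than
#' image rendering permits.
#'
#' @param n_pens_per_subtype pens planted per subtype.
#' @param rates named expected proliferation ratios per subtype.
#' @param t0_count_probs probabilities for 1..4 starting cells per pen.
#' @param timepoints hours, must include 0.
#' @param cap per-pen crowding capacity (default unlimited).
#' @param seed integer seed.
#' @return list with `pens` (pen, subtype, t0_count, true_rate) and
#'   `detections` (one row per cell per timepoint: pen, t_hours, subtype),
#'   the latter shaped for [build_timeseries()].
#' @export
simulate_growth <- function(n_pens_per_subtype = 50L,
                            rates = c(P5 = 1.5, P6 = 1.5, P7 = 1.5, P8 = 1.5),
                            t0_count_probs = c(0.55, 0.25, 0.13, 0.07),
                            timepoints = seq(0, 96, by = 12),
                            cap = Inf, seed = 1L) {
  stopifnot(0 %in% timepoints)
  tps <- sort(unique(timepoints))
  n_steps <- length(tps) - 1L
  with_seed(seed, {
    pens <- list(); det <- list(); pno <- 0L
    for (s in names(rates)) {
      mult <- rates[[s]]^(1 / max(1L, n_steps))
      for (p in seq_len(n_pens_per_subtype)) {
        pno <- pno + 1L
        pid <- sprintf("g%05d", pno)
        n0 <- sample(1:4, 1L, prob = t0_count_probs)
        cnt <- n0
        series <- integer(length(tps)); series[1] <- n0
        if (n_steps > 0L) for (st in seq_len(n_steps)) {
          cnt <- branch_step(cnt, mult, cap)
          series[st + 1L] <- cnt
        }
        pens[[pno]] <- data.frame(pen = pid, subtype = s, t0_count = n0,
                                  true_rate = rates[[s]],
                                  final_count = series[length(series)],
                                  stringsAsFactors = FALSE)
        nz <- series > 0L
        if (any(nz))
          det[[length(det) + 1L]] <- data.frame(
            pen = pid, t_hours = rep(tps[nz], series[nz]), subtype = s,
            stringsAsFactors = FALSE)
      }
    }
    list(pens = do.call(rbind, pens), detections = do.call(rbind, det))
  })
}
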