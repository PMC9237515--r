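# Registration, circle detection, quantification, background baselines.

test_that("registration recovers identity and planted shifts", {
  spec <- small_chip_spec(n_fovs = 1, fill = 0, noise_sd = 10, seed = 3)
  sim <- simulate_chip(spec)
  img <- sim$images[[1]][["t0"]][["OEP"]]
  r0 <- register_fov(img, sim$layout, "fov01")
  expect_equal(r0$offset, c(0, 0))
  expect_identical(r0$image, img)
  sh <- nanopheno:::translate_image(img, c(3, -2))
  r1 <- register_fov(sh, sim$layout, "fov01")
  expect_equal(r1$offset, c(-3, 2))
  # idempotence: registering the registered image is the identity
  r2 <- register_fov(r1$image, sim$layout, "fov01")
  expect_equal(r2$offset, c(0, 0))
})

test_that("registration fails on featureless images", {
  lay <- chip_layout_grid(1, 3, 3)
  expect_error(register_fov(matrix(500L, lay$dim[1], lay$dim[2]), lay, "fov01"),
               "featureless")
})

test_that("detection returns nothing on a uniform background", {
  lay <- chip_layout_grid(1, 3, 3)
  img <- matrix(1000L, lay$dim[1], lay$dim[2])
  det <- detect_cells(img, lay, "fov01", hough_params(3, 8))
  expect_equal(nrow(det), 0L)
})

test_that("detection finds planted disks and drops out-of-ROI ones", {
  spec <- small_chip_spec(fill = 0.7, stray_cells_per_fov = 1, seed = 7)
  sim <- simulate_chip(spec)
  for (fv in names(sim$layout$fovs)) {
    det <- detect_cells(sim$images[[fv]][["t0"]][["OEP"]], sim$layout, fv,
                        hough_params(3, 8), 0)
    tr <- sim$truth$cells[sim$truth$cells$fov == fv, ]
    expect_equal(nrow(det), nrow(tr))
    mm <- match_detections(det, tr)
    expect_lte(max(mm$det_err), 2)
    expect_lte(max(mm$truth_err), 2)
    # strays were planted but must not appear (they sit outside all ROIs)
    st <- sim$truth$strays[sim$truth$strays$fov == fv, ]
    for (i in seq_len(nrow(st)))
      expect_gt(min(sqrt((det$r - st$r[i])^2 + (det$c - st$c[i])^2)), 5)
    # every detection is inside its assigned pen
    for (i in seq_len(nrow(det))) {
      p <- sim$layout$fovs[[fv]]$pens[[det$pen[i]]]
      expect_true(det$r[i] >= p["r0"] && det$r[i] < p["r1"])
      expect_true(det$c[i] >= p["c0"] && det$c[i] < p["c1"])
    }
  }
})

test_that("the peak threshold excludes at T-1 and includes at T", {
  lay <- chip_layout_grid(1, 2, 2)
  p <- lay$fovs[[1]]$pens[[1]]
  ctr <- c(p["r0"] + 20, p["c0"] + 20)
  for (peak in c(65534, 65535)) {
    img <- matrix(1000, lay$dim[1], lay$dim[2])
    img <- nanopheno:::render_disk(img, ctr, 5, peak)
    det <- detect_cells(matrix(as.integer(img), nrow(img)), lay, "fov01",
                        hough_params(3, 8, peak_threshold = 65535))
    expect_equal(nrow(det), if (peak == 65535) 1L else 0L)
  }
})

test_that("detection rejects radius ranges wider than a pen", {
  lay <- chip_layout_grid(1, 2, 2, pen_size = 20)
  img <- matrix(1000L, lay$dim[1], lay$dim[2])
  expect_error(detect_cells(img, lay, "fov01", hough_params(3, 30)), "pen size")
  expect_error(hough_params(5, 3), "radius range")
})

test_that("quantification is ratio-exact and illumination invariant", {
  lay <- chip_layout_grid(1, 2, 2)
  img <- matrix(1200, lay$dim[1], lay$dim[2])
  p <- lay$fovs[[1]]$pens[[1]]
  ctr <- c(p["r0"] + 20, p["c0"] + 20)
  px <- nanopheno:::disk_pixels(nrow(img), ncol(img), ctr[1], ctr[2], 5)
  img[px] <- 2400
  det <- data.frame(cell = "c1", fov = "fov01", pen = names(lay$fovs[[1]]$pens)[1],
                    r = ctr[1], c = ctr[2], radius = 5, t_hours = 0,
                    stringsAsFactors = FALSE)
  q <- quantify_cells(det, list(TRED = img), lay, "fov01")
  expect_equal(q$raw, 2400)
  expect_equal(q$normalized, 2.0)
  # disk mean equal to background mean gives exactly 1.0
  q1 <- quantify_cells(det, list(TRED = matrix(1200, nrow(img), ncol(img))),
                       lay, "fov01")
  expect_equal(q1$normalized, 1.0)
  # global multiplicative illumination cancels in the ratio
  q3 <- quantify_cells(det, list(TRED = img * 3), lay, "fov01")
  expect_equal(q3$normalized, q$normalized)
  # own-ROI mode uses the cell's pen as denominator
  qo <- quantify_cells(det, list(TRED = img), lay, "fov01", mode = "own_roi")
  expect_lt(qo$normalized, q$normalized)  # own pen contains the bright disk
})

test_that("fov_background mode demands a cell-free pen", {
  lay <- chip_layout_grid(1, 1, 1)
  img <- matrix(1000, lay$dim[1], lay$dim[2])
  det <- data.frame(cell = "c1", fov = "fov01",
                    pen = names(lay$fovs[[1]]$pens)[1],
                    r = 30, c = 30, radius = 4, t_hours = 0,
                    stringsAsFactors = FALSE)
  expect_error(quantify_cells(det, list(TRED = img), lay, "fov01"), "own_roi")
  expect_silent(quantify_cells(det, list(TRED = img), lay, "fov01",
                               mode = "own_roi"))
})

test_that("background baselines report per-FOV constants", {
  lay <- chip_layout_grid(2, 2, 2)
  b1 <- background_baseline(list(TRED = matrix(500, lay$dim[1], lay$dim[2])),
                            lay, "fov01")
  expect_equal(b1$mean, 500)
  expect_equal(b1$sd, 0)
  b2 <- background_baseline(list(TRED = matrix(900, lay$dim[1], lay$dim[2])),
                            lay, "fov02")
  expect_false(isTRUE(all.equal(b1$mean, b2$mean)))
})

test_that("baselines recover the simulator's background level", {
  spec <- small_chip_spec(n_fovs = 1, fill = 0, noise_sd = 25, seed = 12,
                          chip_factor_sd = 0)
  sim <- simulate_chip(spec)
  bl <- background_baseline(sim$images[[1]][["t0"]]["TRED"], sim$layout,
                            "fov01")
  expect_equal(bl$mean, sim$truth$fov_background$bg_mean[1], tolerance = 0.01)
  expect_equal(bl$sd, 25, tolerance = 0.15)
})

test_that("normalized intensities are invariant to per-FOV illumination", {
  spec <- small_chip_spec(n_fovs = 1, fill = 0.6, seed = 5)
  sim <- simulate_chip(spec)
  det <- detect_cells(sim$images[[1]][["t0"]][["OEP"]], sim$layout, "fov01",
                      hough_params(3, 8), 0)
  img <- sim$images[[1]][["t0"]][["TRED"]]
  q1 <- quantify_cells(det, list(TRED = img), sim$layout, "fov01")
  q2 <- quantify_cells(det, list(TRED = img * 2.5), sim$layout, "fov01")
  expect_equal(q2$normalized, q1$normalized, tolerance = 1e-12)
})
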