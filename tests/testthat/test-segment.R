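make_blob <- function(img, i0, j0, n_px) {
  # paint an n_px 4-connected blob starting at (i0, j0), filling row-major
  w <- 5
  k <- 0
  for (di in 0:(ceiling(n_px / w) - 1)) for (dj in 0:(w - 1)) {
    if (k < n_px) {
      img[i0 + di, j0 + dj] <- 1
      k <- k + 1
    }
  }
  img
}

test_that("blank images yield zero nuclei and vessels without error", {
  g <- pixel_grid(64, 64, 1)
  z <- matrix(0, 64, 64)
  expect_equal(max(detect_nuclei(z, g)$labels), 0)
  expect_equal(max(detect_vessels(z, g)$labels), 0)
})

test_that("nucleus area filter is strict: < 23 um^2 excluded, >= 23 kept", {
  g <- pixel_grid(96, 96, 1)
  img <- matrix(0, 96, 96)
  img <- make_blob(img, 10, 10, 20)   # below: dropped
  img <- make_blob(img, 10, 50, 23)   # boundary: kept
  img <- make_blob(img, 50, 10, 26)   # above: kept
  p <- segmentation_params(dapi_threshold = 0.5, smoothing_sigma_um = 0)
  nuc <- detect_nuclei(img, g, p)
  expect_equal(max(nuc$labels), 2)
  areas <- sort(tabulate(nuc$labels[nuc$labels > 0]))
  expect_equal(areas, c(23, 26))
})

test_that("vessel area filter is strict: <= 5 um^2 dropped, > 5 kept", {
  g <- pixel_grid(96, 96, 1)
  img <- matrix(0, 96, 96)
  img[10:11, 10:11] <- 1              # 4 px: dropped
  img[10:11, 50:52] <- 1; img[10, 53] <- 0; img[11, 52] <- 0  # 5 px
  img[50:51, 10:12] <- 1              # 6 px: kept
  expect_equal(sum(img == 1), 15)
  p <- segmentation_params(cd31_threshold = 0.5, smoothing_sigma_um = 0)
  ves <- detect_vessels(img, g, p)
  expect_equal(max(ves$labels), 1)
  expect_equal(sum(ves$labels > 0), 6)
})

test_that("well-separated blobs give one label each (component oracle)", {
  g <- pixel_grid(64, 64, 1)
  truth <- disk_mask(64, 64, 20, 20, 4) | disk_mask(64, 64, 20, 32, 4)
  img <- matrix(0, 64, 64); img[truth] <- 1
  p <- segmentation_params(dapi_threshold = 0.5, smoothing_sigma_um = 0)
  nuc <- detect_nuclei(img, g, p)
  oracle <- label_components4(truth)
  expect_equal(max(nuc$labels), max(oracle))
  expect_equal(max(nuc$labels), 2)
})

test_that("simulate_cells with zero dilation is the identity", {
  g <- pixel_grid(40, 40, 1)
  lab <- matrix(0L, 40, 40); lab[disk_mask(40, 40, 20, 20, 3)] <- 1L
  nuc <- label_map(g, lab)
  expect_identical(simulate_cells(nuc, 0)$labels, nuc$labels)
})

test_that("simulate_cells grows an isolated disk to the expected area", {
  g <- pixel_grid(50, 50, 1)
  lab <- matrix(0L, 50, 50)
  core <- disk_mask(50, 50, 25, 25, 3)
  lab[core] <- 1L
  cells <- simulate_cells(label_map(g, lab), 5)
  # oracle: brute-force pixel count of all pixels within 5 px of the core
  d <- bf_distance_map(core)
  expect_identical(cells$labels == 1L, d <= 5 + 1e-9)
  expect_lt(abs(sum(cells$labels == 1L) - pi * 64) / (pi * 64), 0.05)
})

test_that("contested dilation pixels follow the nearest-nucleus tie rule", {
  g <- pixel_grid(40, 40, 1)
  lab <- matrix(0L, 40, 40)
  lab[disk_mask(40, 40, 20, 14, 2.2)] <- 1L
  lab[disk_mask(40, 40, 20, 20, 2.2)] <- 2L   # 6 um apart
  cells <- simulate_cells(label_map(g, lab), 5)
  oracle <- bf_nearest_label(lab, 5)
  expect_identical(cells$labels, oracle)
  # cells never shrink: nucleus pixels keep their label
  expect_true(all(cells$labels[lab > 0L] == lab[lab > 0L]))
})

test_that("flag_perfused reflects overlap and catches shape mismatch", {
  g <- pixel_grid(30, 30, 1)
  lab <- matrix(0L, 30, 30)
  lab[5:8, 5:8] <- 1L; lab[20:23, 20:23] <- 2L
  ves <- label_map(g, lab)
  expect_equal(flag_perfused(ves, matrix(FALSE, 30, 30)), c(FALSE, FALSE))
  expect_equal(flag_perfused(ves, matrix(TRUE, 30, 30)), c(TRUE, TRUE))
  half <- matrix(FALSE, 30, 30); half[, 1:10] <- TRUE
  expect_equal(flag_perfused(ves, half), c(TRUE, FALSE))
  expect_error(flag_perfused(ves, matrix(FALSE, 10, 10)), "dimensions")
})

test_that("phantom vessels are detected and their perfusion flags recovered", {
  ph <- small_phantom()
  g <- ph$channels$grid
  ves <- detect_vessels(ph$channels$channels$CD31, g)
  expect_equal(max(ves$labels), nrow(ph$truth$vessels))
  # match labels to truth by centroid proximity, compare perfusion flags
  hoechst_mask <- ph$channels$channels$Hoechst > 60
  flags <- flag_perfused(ves, hoechst_mask)
  cent <- vesseldist:::label_centroids_um(ves)
  tv <- ph$truth$vessels
  for (k in seq_len(nrow(cent))) {
    d2 <- (tv$x_um - cent$x_um[k])^2 + (tv$y_um - cent$y_um[k])^2
    expect_equal(flags[k], tv$perfused[which.min(d2)])
  }
})

test_that("count_validation arithmetic and degenerate tiles", {
  g <- pixel_grid(400, 400, 1)
  lab <- matrix(0L, 400, 400)
  centers <- expand.grid(x = seq(30, 370, by = 40), y = seq(30, 370, by = 40))
  for (k in seq_len(nrow(centers)))
    lab[centers$y[k], centers$x[k]] <- k
  lm <- label_map(g, lab)
  truth <- data.frame(x_um = centers$x - 0.5, y_um = centers$y - 0.5)
  cv <- count_validation(lm, truth, n_tiles = 6, tile_um = 350, seed = 5)
  expect_equal(cv$mean_pct_error, 0)
  # remove one truth object per tile: |detected - truth| / truth * 100
  cv10 <- count_validation(lm, truth[-1, ], n_tiles = 6, tile_um = 350,
                           seed = 5)
  expect_true(all(cv10$tiles$pct_error ==
                    abs(cv10$tiles$n_detected - cv10$tiles$n_truth) /
                    cv10$tiles$n_truth * 100, na.rm = TRUE))
  # tiles with no truth objects are excluded from the mean
  cv0 <- count_validation(lm, data.frame(x_um = 1, y_um = 1),
                          n_tiles = 4, tile_um = 100, seed = 8)
  expect_true(all(is.na(cv0$tiles$pct_error) |
                    cv0$tiles$n_truth > 0))
})

test_that("nuclei recall and precision exceed 0.95 on the noise-free phantom", {
  ph <- small_phantom()
  g <- ph$channels$grid
  nuc <- detect_nuclei(ph$channels$channels$DAPI, g)
  cent <- vesseldist:::label_centroids_um(nuc)
  tc <- ph$truth$cells
  nearest <- function(ax, ay, bx, by) {
    vapply(seq_along(ax), function(k)
      min((bx - ax[k])^2 + (by - ay[k])^2), numeric(1))
  }
  precision <- mean(nearest(cent$x_um, cent$y_um, tc$x_um, tc$y_um) <= 25)
  recall <- mean(nearest(tc$x_um, tc$y_um, cent$x_um, cent$y_um) <= 25)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("cell maps partition the dilated union (no double counting)", {
  ph <- small_phantom()
  g <- ph$channels$grid
  nuc <- detect_nuclei(ph$channels$channels$DAPI, g)
  cells <- simulate_cells(nuc, 5)
  dsq <- vesseldist:::edt_sq(nuc$labels > 0L)
  in_union <- dsq <= 25 + 1e-9
  expect_equal(sum(cells$labels > 0L), sum(in_union))
  expect_true(all((cells$labels > 0L) == in_union))
})
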