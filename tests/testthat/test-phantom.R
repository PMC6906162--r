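test_that("place_vessels handles empty and single-vessel cases", {
  g <- pixel_grid(200, 200, 1)
  expect_equal(nrow(place_vessels(g, 0, seed = 1)), 0)
  v <- place_vessels(g, 1, perfused_fraction = 1, seed = 2)
  expect_true(v$perfused)
  expect_true(v$x_um > 0 && v$x_um < 200 && v$y_um > 0 && v$y_um < 200)
})

test_that("place_vessels respects pairwise spacing (exhaustive check)", {
  g <- pixel_grid(1000, 1000, 1)
  v <- place_vessels(g, 12, min_spacing_um = 120, perfused_fraction = 0.5,
                     seed = 7)
  expect_equal(nrow(v), 12)
  expect_equal(sum(v$perfused), 6)
  for (a in 1:11) for (b in (a + 1):12) {
    d <- sqrt((v$x_um[a] - v$x_um[b])^2 + (v$y_um[a] - v$y_um[b])^2)
    expect_gte(d, 120)
  }
  # deterministic per seed
  expect_identical(v, place_vessels(g, 12, min_spacing_um = 120,
                                    perfused_fraction = 0.5, seed = 7))
})

test_that("infeasible vessel packing raises an informative error", {
  g <- pixel_grid(100, 100, 1)
  expect_error(place_vessels(g, 30, min_spacing_um = 90, seed = 1,
                             max_attempts = 2000),
               "n=30.*min_spacing_um=90")
})

test_that("oxygen solver: no source gives zero field, no consumption gives p_v", {
  g <- pixel_grid(96, 96, 1)
  none <- place_vessels(g, 0, seed = 1)
  p0 <- solve_oxygen(g, none, oxygen_params())
  expect_true(all(p0 == 0))
  one <- data.frame(x_um = 48, y_um = 48, radius_um = 6, perfused = TRUE)
  # tiny consumption stands in for M = 0 (parameters must be positive);
  # harmonic solution with one Dirichlet value and no-flux boundary is flat
  p1 <- solve_oxygen(g, one, oxygen_params(M = 1e-8, tol = 1e-7))
  expect_lt(max(abs(p1 - 40)), 0.01)
})

test_that("oxygen field is bounded, monotone along rays, and converged", {
  g <- pixel_grid(256, 256, 1)
  v <- data.frame(x_um = 128, y_um = 128, radius_um = 10, perfused = TRUE)
  op <- oxygen_params()
  p <- solve_oxygen(g, v, op)
  expect_true(all(p >= 0) && all(p <= op$p_v))
  expect_equal(max(p[vessel_lumen_mask(g, v)]), op$p_v)
  # residual below tolerance at non-source pixels
  res <- oxygen_residual(p, g, v, op)
  expect_lt(max(abs(res)), op$tol)
  # azimuthally averaged profile decreases with radius
  r <- sqrt((row(p) - 128.5)^2 + (col(p) - 128.5)^2)
  prof <- tapply(as.vector(p), as.vector(floor(r)), mean)
  rr <- as.numeric(names(prof))
  sel <- rr > 10 & rr < 120
  expect_true(all(diff(prof[sel]) < 1e-6))
})

test_that("marker fields follow their response curves pointwise", {
  mp <- marker_params()
  p <- matrix(seq(0, 60, by = 1), 1)
  mk <- marker_fields(p, mp, p_nec = 0.5)
  # direct formula evaluation as oracle
  expect_equal(mk$ef5[p >= 0.5],
               (mp$ef5_amp * mp$K_h^2 / (mp$K_h^2 + p^2))[p >= 0.5])
  expect_equal(mk$edu_prob, mp$edu_max * p / (p + mp$K_p))
  # half-max at K_h, zero inside necrosis
  mkh <- marker_fields(matrix(mp$K_h), mp, p_nec = 0.5)
  expect_equal(as.numeric(mkh$ef5), mp$ef5_amp / 2)
  mk0 <- marker_fields(matrix(0), mp, p_nec = 0.5)
  expect_equal(as.numeric(mk0$ef5), 0)
  expect_true(mk0$necrosis[1])
  # monotonicity: ef5 non-increasing, edu_prob non-decreasing in p
  ok <- !mk$necrosis
  expect_true(all(diff(mk$ef5[ok]) <= 0))
  expect_true(all(diff(mk$edu_prob) >= 0))
  expect_true(all(mk$edu_prob >= 0 & mk$edu_prob <= mp$edu_max))
})

test_that("sample_cells respects exclusions and Bernoulli proliferation", {
  g <- pixel_grid(500, 500, 1)
  nec <- matrix(FALSE, 500, 500); nec[1:100, ] <- TRUE
  expect_equal(nrow(sample_cells(g, nec, 0, seed = 1)), 0)
  pr0 <- matrix(0, 500, 500)
  cells0 <- sample_cells(g, nec, 1000, 5, NULL, pr0, seed = 2)
  expect_false(any(cells0$is_proliferating))
  # no center in necrosis, spacing respected
  expect_true(all(cells0$y_um >= 100 - 1))
  # binomial oracle: constant probability 0.3
  pr <- matrix(0.3, 500, 500)
  cells <- sample_cells(g, matrix(FALSE, 500, 500), 8000, 2, NULL, pr,
                        seed = 3)
  n <- nrow(cells)
  expect_gte(n, 1000)
  frac <- mean(cells$is_proliferating)
  band <- 3 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(frac - 0.3), band)
  # determinism
  cells_b <- sample_cells(g, matrix(FALSE, 500, 500), 8000, 2, NULL, pr,
                          seed = 3)
  expect_identical(cells, cells_b)
})

test_that("render_phantom produces the documented channel structure", {
  g <- pixel_grid(64, 64, 1)
  mp <- marker_params(noise_sd = 0)
  op <- oxygen_params()
  empty_truth <- phantom_truth(
    vessels = data.frame(x_um = numeric(0), y_um = numeric(0),
                         radius_um = numeric(0), perfused = logical(0)),
    oxygen = matrix(0, 64, 64), necrosis_mask = matrix(FALSE, 64, 64),
    cells = data.frame(x_um = numeric(0), y_um = numeric(0),
                       edu_prob = numeric(0), is_proliferating = logical(0)),
    oxygen_par = op, marker_par = mp, seed = 1)
  ch <- render_phantom(g, empty_truth, mp)
  expect_setequal(names(ch$channels), c("DAPI", "Hoechst", "CD31", "EF5", "EdU"))
  for (m in ch$channels) expect_true(all(m == mp$background))

  # one nucleus: DAPI argmax at its center pixel
  one <- empty_truth
  one$cells <- data.frame(x_um = 31.5, y_um = 21.5, edu_prob = 0,
                          is_proliferating = FALSE)
  ch1 <- render_phantom(g, one, mp)
  peak <- arrayInd(which.max(ch1$channels$DAPI), c(64, 64))
  expect_equal(as.integer(peak), c(22L, 32L))  # row = y, col = x (1-based)
})

test_that("noise-free DAPI local maxima count the rendered nuclei", {
  ph <- small_phantom()
  mp <- ph$truth$marker_par
  n <- count_local_maxima(ph$channels$channels$DAPI,
                          mp$background + 0.5 * mp$dapi_amp)
  expect_equal(n, nrow(ph$truth$cells))
})

test_that("make_phantom is bit-reproducible and honors p_nec", {
  cfg <- default_config()
  cfg$grid <- list(width_px = 192L, height_px = 192L)
  cfg$vessels <- list(n_vessels = 2L, min_spacing_um = 60, perfused_fraction = 1,
                      radius_range_um = c(8, 12))
  ph1 <- make_phantom(cfg, seed = 9)
  ph2 <- make_phantom(cfg, seed = 9)
  for (nm in names(ph1$channels$channels))
    expect_identical(ph1$channels$channels[[nm]], ph2$channels$channels[[nm]])
  expect_identical(ph1$truth$cells, ph2$truth$cells)
  expect_identical(ph1$truth$oxygen, ph2$truth$oxygen)

  cfg$oxygen$p_nec <- 0
  ph0 <- make_phantom(cfg, seed = 9)
  expect_false(any(ph0$truth$necrosis_mask))
})

test_that("default phantom places anoxia 100-200 um from perfused lumens", {
  run <- default_noise_free_run()
  tr <- run$truth
  g <- run$channels$grid
  lumen <- vessel_lumen_mask(g, tr$vessels, perfused_only = TRUE)
  d <- distance_map(lumen, g)
  expect_true(any(tr$necrosis_mask))
  onset <- min(d[tr$necrosis_mask])
  expect_gte(onset, 100)
  expect_lte(onset, 200)
})
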