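test_that("fit_similarity recovers exact transforms analytically", {
  set.seed(1)
  src <- matrix(runif(20, 0, 100), 10, 2)
  id <- fit_similarity(src, src)
  expect_equal(id$scale, 1, tolerance = 1e-12)
  expect_equal(id$theta, 0, tolerance = 1e-12)
  expect_equal(c(id$tx, id$ty), c(0, 0), tolerance = 1e-12)
  expect_lt(id$rms, 1e-12)
  # 90-degree rotation about the origin
  rot <- cbind(-src[, 2], src[, 1])
  f <- fit_similarity(src, rot)
  expect_equal(f$theta, pi / 2, tolerance = 1e-9)
  expect_equal(f$scale, 1, tolerance = 1e-9)
  # noise-free general similarity recovered to 1e-9
  true <- list(scale = 1.3, theta = 0.4, tx = 12, ty = -7)
  a <- complex(modulus = true$scale, argument = true$theta)
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- a * z + complex(real = true$tx, imaginary = true$ty)
  g <- fit_similarity(src, cbind(Re(w), Im(w)))
  expect_equal(g$scale, true$scale, tolerance = 1e-9)
  expect_equal(g$theta, true$theta, tolerance = 1e-9)
  expect_equal(c(g$tx, g$ty), c(true$tx, true$ty), tolerance = 1e-9)
  expect_lt(g$rms, 1e-9)
})

test_that("fit_similarity is invariant to point order and rejects degeneracy", {
  set.seed(2)
  src <- matrix(runif(16, 0, 50), 8, 2)
  dst <- src * 1.1 + 3
  f1 <- fit_similarity(src, dst)
  ord <- sample(8)
  f2 <- fit_similarity(src[ord, ], dst[ord, ])
  expect_equal(f1[c("scale", "theta", "tx", "ty")],
               f2[c("scale", "theta", "tx", "ty")])
  expect_error(fit_similarity(src[1, , drop = FALSE], dst[1, , drop = FALSE]),
               "at least 2")
  same <- matrix(5, 4, 2)
  expect_error(fit_similarity(same, dst[1:4, ]), "coincident")
})

test_that("noisy similarity fit matches the brute-force grid minimizer", {
  set.seed(3)
  src <- matrix(runif(40, 0, 100), 20, 2)
  a <- complex(modulus = 1.3, argument = 0.4)
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- a * z + complex(real = 12, imaginary = -7)
  dst <- cbind(Re(w), Im(w)) + matrix(rnorm(40, 0, 0.5), 20, 2)
  f <- fit_similarity(src, dst)
  bf <- bf_fit_similarity(src, dst)
  expect_equal(f$scale, bf$scale, tolerance = 2 * bf$resolution["scale"])
  expect_equal(f$theta, bf$theta, tolerance = 2 * bf$resolution["theta"])
})

test_that("apply_transform: identity and integer shifts are exact", {
  set.seed(4)
  img <- matrix(runif(400), 20, 20)
  id <- structure(list(scale = 1, theta = 0, tx = 0, ty = 0, rms = 0),
                  class = "similarity_transform")
  expect_identical(apply_transform(img, id, "nearest"), img)
  sh <- structure(list(scale = 1, theta = 0, tx = 3, ty = 0, rms = 0),
                  class = "similarity_transform")
  out <- apply_transform(img, sh, "nearest")
  expect_equal(out[, 4:20], img[, 1:17])
  expect_true(all(out[, 1:3] == 0))
})

test_that("warp then inverse-warp on a smooth ramp is nearly lossless", {
  img <- outer(1:40, 1:40, function(i, j) i + 0.5 * j)
  tf <- structure(list(scale = 1.05, theta = 0.1, tx = 2, ty = -1, rms = 0),
                  class = "similarity_transform")
  inv <- structure(list(scale = 1 / tf$scale, theta = -tf$theta,
                        tx = -(cos(-tf$theta) * tf$tx -
                                 sin(-tf$theta) * tf$ty) / tf$scale,
                        ty = -(sin(-tf$theta) * tf$tx +
                                 cos(-tf$theta) * tf$ty) / tf$scale,
                        rms = 0),
                  class = "similarity_transform")
  round_trip <- apply_transform(apply_transform(img, tf, "bilinear"),
                                inv, "bilinear")
  interior <- round_trip[10:30, 10:30]
  expect_lt(mean(abs(interior - img[10:30, 10:30])), 0.5)
})

test_that("invert_intensity is involutive and reverses the histogram", {
  set.seed(5)
  img <- matrix(sample(0:255, 400, replace = TRUE) + 0, 20, 20)
  inv <- invert_intensity(img, 255)
  expect_identical(invert_intensity(inv, 255), img)
  expect_true(all(invert_intensity(matrix(0, 4, 4), 255) == 255))
  h <- tabulate(img + 1, nbins = 256)
  h_inv <- tabulate(inv + 1, nbins = 256)
  expect_identical(h_inv, rev(h))
  expect_error(invert_intensity(img, 100), "outside")
})

test_that("TIFF round trips are lossless at each bit depth", {
  tmp <- withr::local_tempdir()
  i16 <- matrix(sample(0:65535, 256), 16, 16)
  f16 <- file.path(tmp, "a16.tif")
  write_image_tiff(i16, f16, bits = 16)
  expect_identical(read_image_tiff(f16), i16 + 0)
  i8 <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  f8 <- file.path(tmp, "a8.tif")
  write_image_tiff(i8, f8, bits = 8)
  expect_identical(read_image_tiff(f8), i8 + 0)
  fl <- matrix(runif(256, 0, 40), 16, 16)
  ffl <- file.path(tmp, "a32.tif")
  write_image_tiff(fl, ffl, bits = 32)
  back <- read_image_tiff(ffl)
  expect_lt(max(abs(back - fl) / pmax(fl, 1e-6)), 1e-6)
})

test_that("read_channels validates names and dimensions", {
  tmp <- withr::local_tempdir()
  a <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  b <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  fa <- file.path(tmp, "DAPI.tif"); fb <- file.path(tmp, "EF5.tif")
  write_image_tiff(a, fa, 16); write_image_tiff(b, fb, 16)
  expect_error(read_channels(c(DAPI = fa, EF5 = fb)), "differ")
  write_image_tiff(a, fb, 16)
  st <- read_channels(c(DAPI = fa, EF5 = fb), pixel_size_um = 2)
  expect_equal(st$grid$pixel_size_um, 2)
  expect_error(channel_stack(st$grid, list(Nope = a)), "unknown channel")
})

test_that("cell tables survive a CSV round trip to 6 significant digits", {
  tb <- scripted_cell_table(50)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(tb, tmp, row.names = FALSE)
  back <- read.csv(tmp)
  for (cn in c("mean_EF5", "mean_EdU", "dist_perfused_um"))
    expect_equal(signif(back[[cn]], 6), signif(tb[[cn]], 6))
})

test_that("configuration validation names the offending field", {
  cfg <- default_config()
  expect_silent(validate_config(cfg))
  bad <- cfg; bad$oxygen$p_nec <- 50
  expect_error(validate_config(bad), "p_nec")
  bad <- cfg; bad$classify$t1 <- 200
  expect_error(validate_config(bad), "t1 < t2 < t3")
  bad <- cfg; bad$pixel_size_um <- -1
  expect_error(validate_config(bad), "pixel_size_um")
  bad <- cfg; bad$vessels$perfused_fraction <- 1.5
  expect_error(validate_config(bad), "perfused_fraction")
  bad <- cfg; bad$marker$edu_max <- 2
  expect_error(validate_config(bad), "edu_max")
  # config files round-trip through YAML with overrides
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines("vessels:\n  n_vessels: 3\n", tmp)
  loaded <- load_config(tmp, overrides = list(cells = list(density_per_mm2 = 100)))
  expect_equal(loaded$vessels$n_vessels, 3)
  expect_equal(loaded$cells$density_per_mm2, 100)
  expect_error(load_config(tmp, overrides = list(nonsense = 1)),
               "unknown config field")
})
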