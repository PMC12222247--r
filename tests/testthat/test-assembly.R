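# Cube assembly, background correction and the two rendered views.

test_that("assembly merges 12 channels and drops U1r, in wavelength order", {
  sec <- small_section(650, seed = 3)
  ph <- sec$phantom
  acq <- render_filter_images(ph, seed = 4, visible_gain = 2)
  m12 <- assemble_multispectral(acq, visible_gain = 2, drop_u1r = FALSE)
  m11 <- assemble_multispectral(acq, visible_gain = 2)
  expect_equal(length(m12$channels), 12L)
  expect_equal(length(m11$channels), 11L)
  expect_identical(m12$channels, fluor_channels(drop_u1r = FALSE))
  expect_identical(m11$channels, fluor_channels())
  expect_false("U1r" %in% m11$channels)

  expect_error(assemble_multispectral(acq[c("U1", "U2", "BL")]), "missing filter")
  expect_error(assemble_multispectral(acq, visible_gain = 0), "positive")
})

test_that("assembly is linear: zero acquisitions and gain scaling", {
  ph <- flat_phantom()
  acq <- render_filter_images(ph, noise_sd = 0, seed = 1, visible_gain = 1,
                              u1r_reflection = 0)
  msi <- assemble_multispectral(acq)
  expect_true(all(msi$data == 0))

  # constant BLr plane of 100 assembled with gain 2 becomes 200
  acq$BL$rgb_planes[, , "R"] <- 100L
  g2 <- assemble_multispectral(acq, visible_gain = 2)
  expect_true(all(g2$data[, , "BLr"] == 200))
})

test_that("background estimation recovers the true offsets", {
  ph <- small_phantom(450, seed = 2)
  mk_images <- function(noise_sd, seeds) lapply(seeds, function(s) {
    assemble_multispectral(
      render_filter_images(ph, noise_sd = noise_sd, seed = s, visible_gain = 2),
      visible_gain = 2)
  })
  regions <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(image = i,
               row0 = c(2, 2, 180), row1 = c(21, 21, 190),
               col0 = c(2, 230, 2), col1 = c(21, 249, 21))
  }))

  # noise off: exact recovery of the assembled-scale background
  bg0 <- estimate_background(mk_images(0, 1:4), regions)
  expect_equal(unclass(bg0), ph$true_background[fluor_channels()],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(bg0, "n_regions_used"), 12L)

  # with noise: per-channel error within the CLT bound (gain doubles the
  # assembled-scale noise of the visible channels)
  n_px <- 12 * 20 * 20
  bg10 <- estimate_background(mk_images(10, 5:8), regions)
  err <- abs(unclass(bg10) - ph$true_background[fluor_channels()])
  sd_ch <- ifelse(fluor_channels() %in% c("BLb", "BLg", "BLr",
                                          "GRb", "GRg", "GRr"), 20, 10)
  expect_true(all(err < 3 * sd_ch / sqrt(n_px)))

  # a one-pixel region returns that pixel's values
  img <- mk_images(0, 1)[[1]]
  bg1 <- estimate_background(list(img),
                             data.frame(image = 1, row0 = 5, row1 = 5,
                                        col0 = 7, col1 = 7))
  expect_equal(as.numeric(bg1), as.numeric(img$data[5, 7, ]))

  expect_error(estimate_background(mk_images(0, 1), regions[0, ]),
               "at least one")
  expect_error(estimate_background(mk_images(0, 1),
                                   data.frame(image = 1, row0 = 0, row1 = 5,
                                              col0 = 1, col1 = 5)),
               "outside")
})

test_that("background subtraction clamps at zero and recovers the pure signal", {
  cube <- array(0, dim = c(1, 1, 11))
  cube[1, 1, ] <- c(50, 20, rep(100, 9))
  img <- multispectral_image(cube)
  bg <- stats::setNames(c(10, 30, rep(0, 9)), fluor_channels())
  out <- subtract_background(img, bg)
  expect_equal(as.numeric(out$data[1, 1, 1:2]), c(40, 0))

  # zero background is the identity
  same <- subtract_background(img, stats::setNames(rep(0, 11), fluor_channels()))
  expect_identical(same$data, img$data)

  expect_error(subtract_background(img, stats::setNames(rep(0, 11), rev(fluor_channels()))),
               "does not match")

  # noise-free rendered image minus the true background equals the linear
  # mixing term up to camera quantization (half a count)
  ph <- small_phantom(650, seed = 3)
  acq <- render_filter_images(ph, noise_sd = 0, seed = 1, visible_gain = 1)
  msi <- subtract_background(assemble_multispectral(acq),
                             true_background_vector(ph))
  sig <- phantom_expected_signal(ph)
  expect_lt(max(abs(msi$data - sig)), 0.5 + 1e-9)
})

test_that("sum-of-intensity image matches its definition", {
  cube <- array(1, dim = c(4, 5, 11))
  img <- multispectral_image(cube)
  expect_true(all(sum_intensity_image(img) == 255L))

  zero <- multispectral_image(array(0, dim = c(4, 5, 11)))
  expect_true(all(sum_intensity_image(zero) == 0L))

  # pixelwise equality with the brute-force oracle
  rnd <- random_msi(12, 9, seed = 2)
  s <- apply(rnd$data, c(1, 2), sum)
  oracle <- matrix(as.integer(floor(s / max(s) * 255 + 0.5)), 12, 9)
  expect_identical(sum_intensity_image(rnd), oracle)
})

test_that("composite RGB follows the clip-normalize-gamma transform", {
  mk <- function(v) multispectral_image(array(v, dim = c(2, 2, 11)))
  expect_true(all(composite_rgb(mk(11000)) == 255L))
  expect_true(all(composite_rgb(mk(2750)) == 128L))  # round(255 * 0.25^0.5)

  # gamma 1 on an 8-bit range is the identity
  img <- mk(0); img$data[] <- 137
  expect_true(all(composite_rgb(img, 0, 255, 1) == 137L))

  expect_error(composite_rgb(mk(1), 10, 10), "exceed")
  expect_error(composite_rgb(mk(1), gamma = 0), "positive")
})

test_that("composite planes are monotone in their contributing channels", {
  set.seed(9)
  img <- random_msi(6, 6, seed = 3, scale = 3000)
  base <- composite_rgb(img)
  up <- img
  up$data[, , "BLr"] <- up$data[, , "BLr"] + 500
  expect_true(all(composite_rgb(up)[, , "R"] >= base[, , "R"]))
})

test_that("noise-free baseline channels equal background before subtraction and zero after", {
  ph <- small_phantom(850, seed = 3)
  acq <- render_filter_images(ph, noise_sd = 0, seed = 1, visible_gain = 2)
  msi <- assemble_multispectral(acq, visible_gain = 2)
  for (ch in c("BLb", "GRb", "GRg")) {
    expect_true(all(msi$data[, , ch] == ph$true_background[[ch]]), info = ch)
  }
  sub <- subtract_background(msi, true_background_vector(ph))
  for (ch in c("BLb", "GRb", "GRg")) {
    expect_true(all(sub$data[, , ch] == 0), info = ch)
  }
})

test_that("multispectral TIFF round trip preserves channel order and counts", {
  ph <- flat_phantom(h = 8, w = 10,
                     abundances = list(lignin_like = matrix(7, 8, 10)))
  acq <- render_filter_images(ph, noise_sd = 0, seed = 1, visible_gain = 1,
                              u1r_reflection = 0)
  msi <- assemble_multispectral(acq, pixel_size = 10, provenance = "rt")
  f <- file.path(withr::local_tempdir(), "cube.tif")
  write_msi_tiff(msi, f)
  back <- read_msi_tiff(f)
  expect_identical(back$channels, msi$channels)
  expect_identical(dimnames(back$data), dimnames(msi$data))
  # 32-bit storage quantum is 2^14/2^32 counts
  expect_lt(max(abs(back$data - msi$data)), 1e-4)
  expect_equal(back$pixel_size, msi$pixel_size)
})

test_that("acquisition TIFF round trip is exact", {
  ph <- small_phantom(450, seed = 2)
  acq <- render_filter_images(ph, noise_sd = 3, seed = 9, visible_gain = 2)
  d <- withr::local_tempdir()
  p <- write_acquisition(acq, ph, d, "rt_section")
  back <- read_acquisition(p)
  for (f in names(acq)) {
    expect_identical(back[[f]]$rgb_planes[, , ], acq[[f]]$rgb_planes[, , ],
                     info = f)
  }
})
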