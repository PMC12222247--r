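# Synthetic phantom generator: geometry, stage trajectories, forward model.

test_that("phantom generation is deterministic and validates its inputs", {
  p1 <- generate_phantom(450, small_geometry(450), seed = 7)
  p2 <- generate_phantom(450, small_geometry(450), seed = 7)
  expect_identical(p1$label_map, p2$label_map)
  expect_identical(p1$abundance_maps, p2$abundance_maps)
  p3 <- generate_phantom(450, small_geometry(450), seed = 8)
  expect_false(identical(p1$label_map, p3$label_map))

  expect_error(generate_phantom(300), "invalid stage")
  big <- phantom_geometry(450, width = 64, height = 48,
                          pixel_size = 1.44 * 3500 / 512)
  expect_error(generate_phantom(450, big, seed = 1), "exceeds image grid")
})

test_that("label maps follow the stage design", {
  codes <- tissue_codes()
  p250 <- small_phantom(250, seed = 2)
  p450 <- small_phantom(450, seed = 2)
  p850 <- small_phantom(850, seed = 2)

  # aleurone differentiates only from 450 degree-days onward
  expect_false(any(p250$label_map == codes[["aleurone"]]))
  expect_true(any(p450$label_map == codes[["aleurone"]]))

  # the section is a single connected region
  lab <- EBImage::bwlabel(phantom_section_mask(p450))
  expect_equal(max(lab), 1)

  # abundances are nonnegative and cover the grid
  for (a in p450$abundance_maps) {
    expect_identical(dim(a), dim(p450$label_map))
    expect_true(all(a >= 0))
  }

  # lignin-like: absent at 250, dots at 450, near-ubiquitous over the
  # pericarp-side outer layers at 850
  expect_equal(max(p250$abundance_maps$lignin_like), 0)
  dots450 <- sum(p450$label_map == codes[["dot_feature"]])
  expect_gt(dots450, 0)
  ll <- lignin_layer_mask(p850)
  expect_gte(mean(p850$abundance_maps$lignin_like[ll] > 0), 0.99)
})

test_that("chlorophyll-like endocarp abundance is non-increasing in stage and maximal at 250", {
  codes <- tissue_codes()
  means <- vapply(c(250, 450, 650, 850), function(s) {
    p <- small_phantom(s, seed = 2)
    mean(p$abundance_maps$chlorophyll_like[p$label_map == codes[["endocarp"]]])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_equal(which.max(means), 1L)
})

test_that("same-stage phantoms share stage-level abundance means within 10%", {
  codes <- tissue_codes()
  for (f in c("chlorophyll_like", "hydroxycinnamate_like")) {
    m <- vapply(c(5, 6), function(seed) {
      p <- generate_phantom(650, small_geometry(650), seed = seed)
      mean(p$abundance_maps[[f]][p$label_map == codes[["endocarp"]]])
    }, numeric(1))
    expect_lt(abs(m[1] - m[2]) / m[1], 0.10)
  }
})

test_that("renderer reproduces background exactly in the zero-signal, noise-free case", {
  ph <- flat_phantom(background = c(120, 110, 100, 100, 95, 90,
                                    40, 46, 50, 36, 30, 28))
  acq <- render_filter_images(ph, noise_sd = 0, seed = 1, visible_gain = 2,
                              u1r_reflection = 0)
  for (f in names(acq)) {
    for (p in c("R", "G", "B")) {
      ch <- paste0(f, tolower(p))
      div <- if (f %in% c("BL", "GR")) 2 else 1
      expect_true(all(acq[[f]]$rgb_planes[, , p] ==
                        ph$true_background[[ch]] / div),
                  info = ch)
    }
  }
})

test_that("a single-pixel abundance renders the endmember weights exactly", {
  # abundance 100 with zero background and no noise: the pixel's channel
  # values are exactly 100 x the endmember weights (integers on this grid)
  ab <- matrix(0, 24, 32); ab[10, 12] <- 100
  ph <- flat_phantom(abundances = list(chlorophyll_like = ab))
  acq <- render_filter_images(ph, noise_sd = 0, seed = 1, visible_gain = 1,
                              u1r_reflection = 0)
  w <- default_endmembers()$chlorophyll_like$channel_weights
  for (ch in fluor_channels()) {
    f <- substr(ch, 1, 2); p <- toupper(substring(ch, 3))
    expect_equal(unname(acq[[f]]$rgb_planes[10, 12, p]),
                 as.integer(round(100 * w[[ch]])), info = ch)
  }
})

test_that("forward model is linear: doubling one abundance doubles its signal", {
  ab <- matrix(50, 24, 32)
  s1 <- phantom_expected_signal(flat_phantom(abundances = list(lignin_like = ab)))
  s2 <- phantom_expected_signal(flat_phantom(abundances = list(lignin_like = 2 * ab)))
  expect_equal(s2, 2 * s1)
})

test_that("baseline channels carry background and noise only", {
  sec <- small_section(850, seed = 3)
  sig <- phantom_expected_signal(sec$phantom)
  for (ch in c("BLb", "GRb", "GRg")) expect_equal(max(sig[, , ch]), 0, info = ch)
})

test_that("replicate noise draws agree in the mean within the CLT bound", {
  ph <- small_phantom(250, seed = 2)
  n <- sum(phantom_section_mask(ph))
  a1 <- render_filter_images(ph, noise_sd = 10, seed = 1, visible_gain = 1)
  a2 <- render_filter_images(ph, noise_sd = 10, seed = 2, visible_gain = 1)
  for (f in names(a1)) {
    m1 <- apply(a1[[f]]$rgb_planes, 3, function(pl) mean(pl[phantom_section_mask(ph)]))
    m2 <- apply(a2[[f]]$rgb_planes, 3, function(pl) mean(pl[phantom_section_mask(ph)]))
    # the difference of two independent means has sd sqrt(2) * sigma / sqrt(n)
    expect_true(all(abs(m1 - m2) < 3 * sqrt(2) * 10 / sqrt(n)), info = f)
  }
})

test_that("renderer rejects invalid arguments", {
  ph <- flat_phantom()
  expect_error(render_filter_images(ph, noise_sd = -1), "nonnegative")
  bad <- default_endmembers()
  bad$chlorophyll_like$channel_weights <- bad$chlorophyll_like$channel_weights[1:5]
  expect_error(render_filter_images(ph, endmembers = bad), "length 11")
  expect_error(endmember("x", c(BLb = 1)), "baseline")
  expect_error(endmember("x", c(U1b = -1)), "nonnegative")
})

test_that("series manifests follow the study design and are reproducible", {
  m <- generate_series(seed = 5)
  expect_equal(nrow(m), 40L)
  expect_equal(unname(table(m$stage)), rep(10L, 4), ignore_attr = TRUE)
  m2 <- generate_series(seed = 5)
  expect_identical(as.data.frame(m), as.data.frame(m2))

  single <- generate_series(design = c(`250` = 1L), seed = 5)
  expect_equal(nrow(single), 1L)
  expect_error(generate_series(design = integer(0)), "at least one section")
})
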