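# Shared fixtures, built lazily and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# half-resolution geometry: same physical section, quarter the pixels
small_geometry <- function(stage) {
  phantom_geometry(stage, width = 256L, height = 192L,
                   pixel_size = 1.44 * 3500 / 256)
}

small_phantom <- function(stage = 650, seed = 3) {
  memo(sprintf("phantom_%d_%d", stage, seed),
       generate_phantom(stage, small_geometry(stage), seed = seed))
}

# a background-subtracted cube + ground truth for segmentation tests
small_section <- function(stage = 650, seed = 3) {
  memo(sprintf("section_%d_%d", stage, seed), {
    ph <- small_phantom(stage, seed)
    acq <- render_filter_images(ph, seed = seed + 1, visible_gain = 2)
    msi <- assemble_multispectral(acq, visible_gain = 2,
                                  pixel_size = ph$pixel_size,
                                  provenance = "small_section")
    bg <- true_background_vector(ph)
    list(phantom = ph, msi = subtract_background(msi, bg))
  })
}

true_background_vector <- function(phantom) {
  structure(phantom$true_background[fluor_channels()],
            class = "background_vector")
}

# flat phantom on a tiny grid with fully controlled abundances
flat_phantom <- function(h = 24, w = 32, stage = 250,
                         background = rep(0, 12), abundances = NULL) {
  lab <- matrix(tissue_codes()[["starchy_endosperm"]], h, w)
  zero <- matrix(0, h, w)
  ab <- list(chlorophyll_like = zero, hydroxycinnamate_like = zero,
             lignin_like = zero)
  if (!is.null(abundances)) ab[names(abundances)] <- abundances
  bg <- stats::setNames(background, fluor_channels(drop_u1r = FALSE))
  section_phantom(lab, stage, ab, pixel_size = 10, true_background = bg)
}

# two-section-per-stage pipeline run used by the pipeline tests
small_run <- function() {
  memo("small_run", {
    cfg <- default_run_config(seed = 11,
                              design = c(`250` = 2L, `450` = 2L,
                                         `650` = 2L, `850` = 2L))
    run_pipeline(cfg, verbose = FALSE)
  })
}

# the full study-design fixture (4 stages x 10 sections); shared by the
# acceptance blocks
full_run <- function() {
  memo("full_run", run_pipeline(default_run_config(seed = 1), verbose = FALSE))
}

# random multispectral image for oracle checks
random_msi <- function(h, w, seed = 1, scale = 100) {
  set.seed(seed)
  cube <- array(stats::rexp(h * w * 11) * scale, dim = c(h, w, 11))
  multispectral_image(cube, fluor_channels(), pixel_size = 10,
                      provenance = sprintf("rand%d", seed))
}

full_mask <- function(h, w) roi_mask(matrix(TRUE, h, w), "whole_section")

# independent binning oracle: direct interval counting on the raw values,
# [e_i, e_{i+1}) with the last bin closed
bin_frequencies_oracle <- function(x, bins) {
  e <- bins$edges
  nb <- length(e) - 1
  counts <- vapply(seq_len(nb), function(i) {
    if (i < nb) sum(x >= e[i] & x < e[i + 1]) else sum(x >= e[i] & x <= e[i + 1])
  }, numeric(1))
  counts[1] <- counts[1] + sum(x < e[1])
  counts[nb] <- counts[nb] + sum(x > e[nb + 1])
  counts / length(x)
}
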