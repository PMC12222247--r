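# Synthetic grain-section phantoms.
#
# The study design this generator emulates: four developmental stages (250,
# 450, 650, 850 cumulative degree-days after flowering), ten transverse
# sections per stage, each acquired as four RGB fluorescence images.
# Phantoms provide ground-truthed stand-ins for real acquisitions: a ring
# geometry of outer tissues around a starchy endosperm with a ventral
# crease, per-tissue abundances of three fluorophore classes following the
# stage trajectories typical of the developing caryopsis (red-emitting
# chlorophyll fading with maturity; UV-excited blue emission rising then
# falling; blue-excited green emission absent early, patchy dots mid-way,
# homogeneous over the outer layers at the last stage).

phantom_stages <- function() c(250L, 450L, 650L, 850L)

#' Tissue label codes of a section phantom
#' @return named integer vector mapping tissue names to label-map codes.
#' @export
tissue_codes <- function() {
  c(background = 0L, outer_pericarp = 1L, endocarp = 2L, testa_line = 3L,
    aleurone = 4L, starchy_endosperm = 5L, crease_complex = 6L,
    dot_feature = 7L)
}

# Mean per-stage section areas (mm^2) the geometry is calibrated to
# reproduce: 4.64, 6.56, 7.11, 6.11 for stages 250..850.
stage_target_area_mm2 <- function(stage) {
  c(`250` = 4.64, `450` = 6.56, `650` = 7.11, `850` = 6.11)[as.character(stage)]
}

#' Default phantom geometry
#'
#' The working grid is 512 x 384 pixels; the pixel size is enlarged in
#' proportion (1.44 um x 3500/512 = 9.84 um) so that grain dimensions and
#' section areas stay on the real scale while the full series runs in
#' minutes. Morphological parameters elsewhere scale by the same ratio.
#'
#' @param stage developmental stage in degree-days after flowering (one of
#'   250, 450, 650, 850); sets the target section area.
#' @param width,height grid size in pixels.
#' @param pixel_size pixel edge in micrometers.
#' @param axis_ratio minor/major semi-axis ratio of the section ellipse.
#' @param crease_depth fractional radial depth of the ventral crease infold.
#' @param crease_width angular half-width (radians) of the crease.
#' @param target_area_mm2 section area to calibrate the radii to; defaults
#'   to the per-stage mean of the study design.
#' @return geometry parameter list.
#' @export
phantom_geometry <- function(stage = 450, width = 512L, height = 384L,
                             pixel_size = 1.44 * 3500 / 512,
                             axis_ratio = 0.72,
                             crease_depth = 0.28, crease_width = 0.35,
                             target_area_mm2 = stage_target_area_mm2(stage)) {
  stopifnot(width >= 32, height >= 32, pixel_size > 0,
            axis_ratio > 0, axis_ratio <= 1,
            crease_depth >= 0, crease_depth < 1, crease_width > 0)
  list(width = as.integer(width), height = as.integer(height),
       pixel_size = pixel_size, axis_ratio = axis_ratio,
       crease_depth = crease_depth, crease_width = crease_width,
       crease_angle = pi / 2, target_area_mm2 = unname(target_area_mm2))
}

# radial profile of the dented ellipse for unit major semi-axis
.radial_profile <- function(theta, axis_ratio, depth, width, angle) {
  b <- axis_ratio
  r_ell <- b / sqrt((b * cos(theta))^2 + sin(theta)^2)
  dth <- atan2(sin(theta - angle), cos(theta - angle))
  r_ell * (1 - depth * exp(-(dth / width)^2))
}

# major semi-axis (pixels) such that the dented-ellipse area matches the
# target; the unit-radius area is integrated numerically
.solve_semi_axis <- function(geom) {
  th <- seq(-pi, pi, length.out = 4096L)
  r1 <- .radial_profile(th, geom$axis_ratio, geom$crease_depth,
                        geom$crease_width, geom$crease_angle)
  area_unit <- 0.5 * sum(r1^2) * diff(th[1:2])
  area_px <- geom$target_area_mm2 * 1e6 / geom$pixel_size^2
  sqrt(area_px / area_unit)
}

# per-tissue abundance means by stage, one matrix per fluorophore
.stage_abundance <- function(stage) {
  s <- as.character(stage)
  chl <- list(`250` = c(op = 350, ec = 500, cc = 300),
              `450` = c(op = 180, ec = 300, cc = 180),
              `650` = c(op = 60,  ec = 130, cc = 80),
              `850` = c(op = 5,   ec = 15,  cc = 10))[[s]]
  hc <- list(`250` = c(op = 220, ec = 160, tl = 250, al = 0,   cc = 280, se = 35),
             `450` = c(op = 280, ec = 220, tl = 330, al = 320, cc = 320, se = 35),
             `650` = c(op = 330, ec = 260, tl = 380, al = 380, cc = 360, se = 35),
             `850` = c(op = 260, ec = 210, tl = 320, al = 330, cc = 320, se = 35))[[s]]
  lig <- list(`250` = c(dot = 0),
              `450` = c(dot = 600),
              `650` = c(dot = 650),
              `850` = c(op = 150, ec = 150, tl = 150, cc = 120))[[s]]
  list(chlorophyll_like = chl, hydroxycinnamate_like = hc, lignin_like = lig)
}

# expand sparse per-tissue means (op/ec/tl/al/se/cc/dot keys) to a vector
# indexed by tissue code 0..7
.tissue_mean_vector <- function(means) {
  key <- c(op = "outer_pericarp", ec = "endocarp", tl = "testa_line",
           al = "aleurone", se = "starchy_endosperm", cc = "crease_complex",
           dot = "dot_feature")
  v <- stats::setNames(numeric(length(tissue_codes())), names(tissue_codes()))
  v[key[names(means)]] <- means
  # dots sit in the endocarp: unless given their own level, they inherit it
  if (!("dot" %in% names(means)) && ("ec" %in% names(means))) {
    v["dot_feature"] <- means[["ec"]]
  }
  v
}

default_true_background <- function() {
  c(U1b = 120, U1g = 110, U1r = 100, U2b = 100, U2g = 95, U2r = 90,
    BLb = 40, BLg = 46, BLr = 50, GRb = 36, GRg = 30, GRr = 28)
}

#' Construct a section phantom from explicit components
#'
#' Low-level constructor used by [generate_phantom()] and by tests that need
#' fully controlled inputs (e.g. single-pixel abundances).
#'
#' @param label_map integer matrix of [tissue_codes()] values.
#' @param stage developmental stage (degree-days after flowering).
#' @param abundance_maps named list of nonnegative matrices, one per
#'   fluorophore, same size as `label_map`.
#' @param pixel_size micrometers per pixel.
#' @param true_background named additive offset per 12-channel layout
#'   (assembled-cube scale, counts).
#' @param geometry optional geometry record.
#' @return object of class `section_phantom`.
#' @export
section_phantom <- function(label_map, stage, abundance_maps, pixel_size,
                            true_background = default_true_background(),
                            geometry = NULL) {
  if (!stage %in% phantom_stages()) {
    stop("invalid stage: must be one of ", paste(phantom_stages(), collapse = ", "))
  }
  stopifnot(is.matrix(label_map))
  for (a in abundance_maps) {
    stopifnot(identical(dim(a), dim(label_map)))
    if (any(a < 0)) stop("abundance maps must be nonnegative")
  }
  ch12 <- fluor_channels(drop_u1r = FALSE)
  if (!all(ch12 %in% names(true_background))) {
    stop("true_background must name all 12 pre-exclusion channels")
  }
  structure(list(label_map = label_map, stage = as.integer(stage),
                 abundance_maps = abundance_maps, pixel_size = pixel_size,
                 true_background = true_background[ch12],
                 geometry = geometry),
            class = "section_phantom")
}

#' Generate a ground-truthed grain-section phantom
#'
#' Builds the tissue label map (outer pericarp, endocarp, testa line,
#' aleurone, starchy endosperm, crease complex, dot features) and per-
#' fluorophore abundance maps for one section at one developmental stage.
#' Deterministic for a fixed seed. The aleurone ring differentiates only
#' from stage 450 onward; chlorophyll-like abundance in the endocarp is
#' maximal at 250 and decreases with stage; lignin-like abundance is absent
#' at 250, confined to dot features at 450-650, and homogeneous over the
#' pericarp-side outer layers at 850.
#'
#' @param stage one of 250, 450, 650, 850 (degree-days after flowering).
#' @param geometry from [phantom_geometry()]; defaults to the stage default.
#' @param seed integer seed controlling geometry jitter, abundance jitter
#'   and dot placement.
#' @return a `section_phantom`.
#' @export
generate_phantom <- function(stage, geometry = NULL, seed = 1L) {
  if (!stage %in% phantom_stages()) {
    stop("invalid stage: must be one of ", paste(phantom_stages(), collapse = ", "))
  }
  geom <- if (is.null(geometry)) phantom_geometry(stage) else geometry
  codes <- tissue_codes()
  set.seed(seed)

  a0 <- .solve_semi_axis(geom)
  scale_jit <- stats::runif(1, 0.96, 1.04)
  a <- a0 * scale_jit
  b <- a * geom$axis_ratio
  jit <- stats::runif(2, -6, 6)
  cx <- geom$width / 2 + jit[1]
  cy <- geom$height / 2 + jit[2]
  cang <- geom$crease_angle + stats::runif(1, -0.08, 0.08)
  mult <- stats::setNames(stats::runif(3, 0.97, 1.03),
                          c("chlorophyll_like", "hydroxycinnamate_like",
                            "lignin_like"))

  if (cx - a < 2 || cx + a > geom$width - 1 ||
      cy - b < 2 || cy + b > geom$height - 1) {
    stop("geometry exceeds image grid")
  }

  h <- geom$height; w <- geom$width
  col <- matrix(rep(seq_len(w), each = h), h, w)
  row <- matrix(rep(seq_len(h), times = w), h, w)
  dx <- (col - cx) / a
  dy <- (row - cy) / a
  theta <- atan2(dy, dx)
  rho <- sqrt(dx^2 + dy^2)
  rmax <- .radial_profile(theta, geom$axis_ratio, geom$crease_depth,
                          geom$crease_width, cang)
  u <- rho / rmax

  lab <- matrix(codes[["background"]], h, w)
  inside <- u <= 1
  lab[inside & u > 0.93] <- codes[["outer_pericarp"]]
  lab[inside & u <= 0.93 & u > 0.86] <- codes[["endocarp"]]
  lab[inside & u <= 0.86 & u > 0.84] <- codes[["testa_line"]]
  band_al <- inside & u <= 0.84 & u > 0.79
  if (stage >= 450) {
    lab[band_al] <- codes[["aleurone"]]
  } else {
    lab[band_al] <- codes[["starchy_endosperm"]]
  }
  lab[inside & u <= 0.79] <- codes[["starchy_endosperm"]]

  dth <- atan2(sin(theta - cang), cos(theta - cang))
  crease <- inside & abs(dth) < 0.6 * geom$crease_width & u > 0.55 & u <= 0.97
  lab[crease] <- codes[["crease_complex"]]

  # lignin dot features: endocarp at 450, endocarp + outer pericarp at 650
  if (stage %in% c(450L, 650L)) {
    elig_codes <- if (stage == 450L) codes[["endocarp"]] else
      c(codes[["endocarp"]], codes[["outer_pericarp"]])
    elig <- which(lab %in% elig_codes)
    density <- if (stage == 450L) 0.005 else 0.0065
    n_dots <- max(1L, round(length(elig) * density))
    centers <- sample(elig, min(n_dots, length(elig)))
    cc <- arrayInd(centers, dim(lab))
    for (k in seq_len(nrow(cc))) {
      rr <- pmax(1L, cc[k, 1] - 2L):pmin(h, cc[k, 1] + 2L)
      cl <- pmax(1L, cc[k, 2] - 2L):pmin(w, cc[k, 2] + 2L)
      sub <- expand.grid(r = rr, c = cl)
      keep <- (sub$r - cc[k, 1])^2 + (sub$c - cc[k, 2])^2 <= 4 &
        lab[cbind(sub$r, sub$c)] != codes[["background"]]
      lab[cbind(sub$r[keep], sub$c[keep])] <- codes[["dot_feature"]]
    }
  }

  means <- .stage_abundance(stage)
  abund <- lapply(names(means), function(f) {
    mv <- .tissue_mean_vector(means[[f]]) * mult[[f]]
    base <- matrix(mv[lab + 1L], h, w)
    tex <- matrix(exp(stats::rnorm(h * w, 0, 0.1)), h, w)
    base * tex
  })
  names(abund) <- names(means)

  section_phantom(
    label_map = lab, stage = stage, abundance_maps = abund,
    pixel_size = geom$pixel_size,
    geometry = c(geom, list(semi_major = a, semi_minor = b,
                            center = c(cx, cy), crease_angle = cang,
                            seed = seed)))
}

#' Ground-truth masks of a phantom
#'
#' `phantom_section_mask()` is every non-background pixel.
#' `phantom_outer_mask()` is the outer-tissue set used to score the
#' outer-tissue segmentation (pericarp, endocarp, testa, aleurone, dots and
#' crease complex). `lignin_layer_mask()` is the pericarp-side layer set
#' (outer pericarp, endocarp, testa, dots) carrying the lignin-like
#' trajectory, excluding the aleurone.
#'
#' @param phantom a `section_phantom`.
#' @return logical matrix.
#' @export
phantom_section_mask <- function(phantom) {
  phantom$label_map != tissue_codes()[["background"]]
}

#' @rdname phantom_section_mask
#' @param include_aleurone,include_crease include those tissues in the mask.
#' @export
phantom_outer_mask <- function(phantom, include_aleurone = TRUE,
                               include_crease = TRUE) {
  codes <- tissue_codes()
  keep <- codes[c("outer_pericarp", "endocarp", "testa_line", "dot_feature")]
  if (include_aleurone) keep <- c(keep, codes[["aleurone"]])
  if (include_crease) keep <- c(keep, codes[["crease_complex"]])
  matrix(phantom$label_map %in% keep, nrow(phantom$label_map))
}

#' @rdname phantom_section_mask
#' @export
lignin_layer_mask <- function(phantom) {
  codes <- tissue_codes()
  keep <- codes[c("outer_pericarp", "endocarp", "testa_line", "dot_feature")]
  matrix(phantom$label_map %in% keep, nrow(phantom$label_map))
}

#' Noise-free expected channel signal of a phantom
#'
#' The linear mixing term of the forward model: for each retained channel,
#' the abundance-weighted sum of endmember weights, excluding background and
#' noise. Useful as ground truth for background-subtraction tests.
#'
#' @param phantom a `section_phantom`.
#' @param endmembers endmember library matching the abundance map names.
#' @return array height x width x 11 with channel dimnames.
#' @export
phantom_expected_signal <- function(phantom, endmembers = default_endmembers()) {
  ch <- fluor_channels()
  h <- nrow(phantom$label_map); w <- ncol(phantom$label_map)
  sig <- array(0, dim = c(h, w, length(ch)), dimnames = list(NULL, NULL, ch))
  wmat <- endmember_matrix(endmembers)
  for (f in names(phantom$abundance_maps)) {
    if (!f %in% rownames(wmat)) stop("no endmember named ", f)
    for (k in seq_along(ch)) {
      wk <- wmat[f, ch[k]]
      if (wk != 0) sig[, , k] <- sig[, , k] + phantom$abundance_maps[[f]] * wk
    }
  }
  sig
}

#' Render the four RGB filter acquisitions of a phantom
#'
#' Forward model: expected channel value = linear mixing of endmember
#' spectra weighted by the abundance maps, plus the per-channel additive
#' background, plus additive Gaussian noise, quantized and clipped to the
#' 14-bit camera range. The `U1r` plane carries a flat reflection artefact
#' over the section instead of fluorescence (it is discarded during
#' assembly). Planes of the two visible filters (BL, GR) are attenuated by
#' `1/visible_gain`, emulating the weaker visible-excitation fluorescence
#' that the assembly step compensates with a multiplicative gain.
#'
#' @param phantom a `section_phantom`.
#' @param endmembers endmember library.
#' @param noise_sd Gaussian noise standard deviation (camera counts).
#' @param seed integer noise seed.
#' @param visible_gain attenuation factor of the visible filters (>= 1).
#' @param u1r_reflection flat reflection amplitude on `U1r` over the section.
#' @return named list (`U1`, `U2`, `BL`, `GR`) of `raw_filter_image`
#'   objects, each holding integer `rgb_planes` (height x width x R,G,B).
#' @export
render_filter_images <- function(phantom, endmembers = default_endmembers(),
                                 noise_sd = 3, seed = 1L, visible_gain = 2,
                                 u1r_reflection = 400) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (visible_gain <= 0) stop("visible_gain must be positive")
  for (e in endmembers) {
    if (length(e$channel_weights) != length(fluor_channels())) {
      stop("endmember weight vectors must have length 11")
    }
  }
  sig <- phantom_expected_signal(phantom, endmembers)
  h <- nrow(phantom$label_map); w <- ncol(phantom$label_map)
  refl <- matrix(0, h, w)
  refl[phantom_section_mask(phantom)] <- u1r_reflection
  bg <- phantom$true_background
  set.seed(seed)

  out <- list()
  for (f in filter_names()) {
    div <- if (f %in% visible_filters()) visible_gain else 1
    planes <- array(0L, dim = c(h, w, 3), dimnames = list(NULL, NULL, c("R", "G", "B")))
    for (p in c("R", "G", "B")) {
      ch <- paste0(f, tolower(p))
      chan_sig <- if (ch == "U1r") refl else sig[, , ch]
      cam <- (chan_sig + bg[[ch]]) / div
      if (noise_sd > 0) cam <- cam + stats::rnorm(h * w, 0, noise_sd)
      planes[, , p] <- matrix(pmin.int(pmax.int(as.integer(round(cam)), 0L),
                                       max_count()), h, w)
    }
    out[[f]] <- structure(list(filter = f, rgb_planes = planes,
                               exposure_gain = 1 / div),
                          class = "raw_filter_image")
  }
  out
}

#' Generate the acquisition manifest of a synthetic series
#'
#' The default design reproduces the study layout: four stages, ten sections
#' per stage (five grains contributing two sections each), i.e. 40
#' acquisitions. The manifest records per-section stage, grain, and the
#' seeds from which phantom and rendering are deterministically
#' regenerated; acquisitions are materialized lazily via
#' [load_acquisition()] (or written to `dir` as TIFF files).
#'
#' @param design named integer vector: sections per stage, names in
#'   `c("250","450","650","850")`.
#' @param seed master seed; all per-section seeds derive from it.
#' @param noise_sd,visible_gain forwarded to [render_filter_images()].
#' @param dir optional directory: if given, every acquisition is written as
#'   four 16-bit multi-page TIFFs plus a label-map TIFF and JSON sidecar,
#'   and the manifest as `manifest.csv`.
#' @return data.frame of class `acquisition_manifest` with one row per
#'   section (`section_id`, `stage`, `grain_id`, `phantom_seed`,
#'   `render_seed`).
#' @export
generate_series <- function(design = c(`250` = 10L, `450` = 10L,
                                       `650` = 10L, `850` = 10L),
                            seed = 1L, noise_sd = 3, visible_gain = 2,
                            dir = NULL) {
  if (length(design) == 0 || sum(design) < 1) {
    stop("design must request at least one section")
  }
  stages <- as.integer(names(design))
  if (any(!stages %in% phantom_stages())) stop("unknown stage in design")

  rows <- list()
  idx <- 0L
  for (si in seq_along(design)) {
    st <- stages[si]
    for (k in seq_len(design[si])) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        section_id = sprintf("st%d_s%02d", st, k),
        stage = st,
        grain_id = sprintf("st%d_g%02d", st, (k + 1L) %/% 2L),
        phantom_seed = (abs(seed) * 10007 + 131 * idx) %% 2147483647,
        render_seed = (abs(seed) * 10007 + 131 * idx + 7) %% 2147483647,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "noise_sd") <- noise_sd
  attr(manifest, "visible_gain") <- visible_gain
  attr(manifest, "seed") <- seed
  class(manifest) <- c("acquisition_manifest", "data.frame")

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      ph <- load_phantom(manifest, i)
      acq <- render_filter_images(ph, noise_sd = noise_sd,
                                  seed = manifest$render_seed[i],
                                  visible_gain = visible_gain)
      paths[i] <- write_acquisition(acq, ph, dir, manifest$section_id[i])
    }
    manifest$path <- paths
    manifest$noise_sd <- noise_sd
    manifest$visible_gain <- visible_gain
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  manifest
}

#' Rebuild the phantom or acquisition for one manifest row
#'
#' Phantoms and acquisitions are regenerated deterministically from the
#' seeds stored in the manifest, so a series never needs to be held in
#' memory at once.
#'
#' @param manifest an `acquisition_manifest`.
#' @param i row index.
#' @return [load_phantom()]: a `section_phantom`; [load_acquisition()]: a
#'   list of four `raw_filter_image`.
#' @export
load_phantom <- function(manifest, i) {
  generate_phantom(manifest$stage[i], seed = manifest$phantom_seed[i])
}

#' @rdname load_phantom
#' @export
load_acquisition <- function(manifest, i) {
  if (!is.null(manifest$path) && dir.exists(manifest$path[i])) {
    return(read_acquisition(manifest$path[i]))
  }
  ph <- load_phantom(manifest, i)
  render_filter_images(ph, noise_sd = attr(manifest, "noise_sd"),
                       seed = manifest$render_seed[i],
                       visible_gain = attr(manifest, "visible_gain"))
}
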