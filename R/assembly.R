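# Cube assembly and preprocessing: merge the four RGB filter acquisitions
# into the multispectral cube, estimate and subtract per-channel additive
# backgrounds, and render the two standard views (sum-of-intensity gray
# image, RGB composite).

#' Construct a multispectral image
#'
#' @param data numeric array height x width x channels, nonnegative counts.
#' @param channels channel names matching `dim(data)[3]`.
#' @param pixel_size micrometers per pixel.
#' @param provenance source acquisition identifier.
#' @return object of class `multispectral_image`.
#' @export
multispectral_image <- function(data, channels = fluor_channels(),
                                pixel_size = NA_real_, provenance = NA_character_) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(channels))
  dimnames(data)[[3]] <- channels
  structure(list(data = data, channels = channels, pixel_size = pixel_size,
                 provenance = provenance),
            class = "multispectral_image")
}

#' Assemble the multispectral cube from four filter acquisitions
#'
#' Merges the blue, green and red planes of the U1, U2, BL and GR filter
#' images into a 12-channel intermediate ordered from high to low emission
#' wavelength, applies the multiplicative gain compensating the weaker
#' visible-excitation fluorescence to the BL and GR planes, and drops the
#' reflection-contaminated `U1r` channel, leaving the 11-channel cube.
#'
#' @param acquisition named list with elements `U1`, `U2`, `BL`, `GR` of
#'   class `raw_filter_image`, identical grids.
#' @param visible_gain multiplicative factor applied to all BL and GR
#'   planes before merging (> 0). Default 1; synthetic acquisitions carry
#'   the gain actually used in their manifest.
#' @param drop_u1r drop channel `U1r` (default); set `FALSE` to obtain the
#'   12-channel pre-exclusion intermediate.
#' @param pixel_size,provenance metadata forwarded to the result.
#' @return a `multispectral_image` with 11 (or 12) channels.
#' @export
assemble_multispectral <- function(acquisition, visible_gain = 1,
                                   drop_u1r = TRUE, pixel_size = NA_real_,
                                   provenance = NA_character_) {
  if (visible_gain <= 0) stop("visible_gain must be positive")
  missing <- setdiff(filter_names(), names(acquisition))
  if (length(missing)) stop("missing filter(s): ", paste(missing, collapse = ", "))
  dims <- lapply(acquisition[filter_names()], function(a) dim(a$rgb_planes)[1:2])
  if (length(unique(dims)) != 1) stop("filter images have mismatching shapes")

  ch <- fluor_channels(drop_u1r = FALSE)
  h <- dims[[1]][1]; w <- dims[[1]][2]
  cube <- array(0, dim = c(h, w, length(ch)), dimnames = list(NULL, NULL, ch))
  for (k in seq_along(ch)) {
    f <- filter_of_channel(ch[k])
    p <- toupper(plane_of_channel(ch[k]))
    plane <- acquisition[[f]]$rgb_planes[, , p] * 1.0
    if (f %in% visible_filters()) plane <- plane * visible_gain
    cube[, , k] <- plane
  }
  if (drop_u1r) cube <- cube[, , fluor_channels(), drop = FALSE]
  multispectral_image(cube, dimnames(cube)[[3]], pixel_size, provenance)
}

#' Estimate the per-channel additive background
#'
#' Averages the intensities over signal-free rectangular regions selected
#' on a few assembled images of the series (the default protocol takes
#' three regions on each of four images). The offset per channel is the mean over
#' the union of all supplied region pixels.
#'
#' @param images list of `multispectral_image` sharing one channel list.
#' @param regions data.frame with columns `image` (index into `images`),
#'   `row0`, `row1`, `col0`, `col1` (inclusive pixel bounds).
#' @return named numeric vector of class `background_vector` with attribute
#'   `n_regions_used`.
#' @export
estimate_background <- function(images, regions) {
  if (NROW(regions) == 0) stop("at least one background region is required")
  ch <- images[[1]]$channels
  acc <- numeric(length(ch)); n <- 0
  for (r in seq_len(nrow(regions))) {
    img <- images[[regions$image[r]]]
    d <- dim(img$data)
    if (regions$row0[r] < 1 || regions$row1[r] > d[1] ||
        regions$col0[r] < 1 || regions$col1[r] > d[2]) {
      stop("background region ", r, " lies outside the image grid")
    }
    if (!identical(img$channels, ch)) stop("channel lists differ across images")
    block <- img$data[regions$row0[r]:regions$row1[r],
                      regions$col0[r]:regions$col1[r], , drop = FALSE]
    acc <- acc + apply(block, 3, sum)
    n <- n + prod(dim(block)[1:2])
  }
  structure(stats::setNames(acc / n, ch), n_regions_used = nrow(regions),
            class = "background_vector")
}

#' Subtract a background vector from a multispectral image
#'
#' Per-channel subtraction, clamped at zero: fluorescence counts are
#' nonnegative and the downstream sum images and Otsu thresholds assume it.
#'
#' @param image a `multispectral_image`.
#' @param bg a `background_vector` (or named numeric) over the same channels.
#' @return the corrected `multispectral_image`.
#' @export
subtract_background <- function(image, bg) {
  if (!identical(image$channels, names(bg))) {
    stop("background channel list does not match the image")
  }
  for (k in seq_along(image$channels)) {
    image$data[, , k] <- pmax(image$data[, , k] - bg[[k]], 0)
  }
  image
}

#' Sum-of-fluorescence-intensity image
#'
#' Per-pixel sum over the 11 channels, rescaled linearly from `[0, max]`
#' (max over the image) to 256 gray levels. This is the segmentation view
#' on which the whole-section threshold operates.
#'
#' @param image a background-subtracted `multispectral_image`.
#' @return integer matrix with values in 0..255.
#' @export
sum_intensity_image <- function(image) {
  if (prod(dim(image$data)[1:2]) == 0) stop("empty image")
  s <- apply(image$data, c(1, 2), sum)
  m <- max(s)
  if (m <= 0) return(matrix(0L, nrow(s), ncol(s)))
  matrix(as.integer(floor(s / m * 255 + 0.5)), nrow(s), ncol(s))
}

#' RGB composite rendering of a multispectral image
#'
#' Averages the retained red channels (U2r, BLr, GRr) into the red plane,
#' the green channels (U1g, U2g, BLg) into green, and the UV blue channels
#' (U1b, U2b) into blue (the three signal-free baseline channels are
#' excluded), then maps each plane by clip to `[min_val, max_val]`,
#' normalize to `[0, 1]`, gamma power, and scale to 0..255. The defaults (0,
#' 11000 counts, gamma 0.5) are the series-wide rendering used to compare
#' sections on a common scale.
#'
#' @param image a background-subtracted `multispectral_image`.
#' @param min_val,max_val common count bounds (`max_val > min_val`).
#' @param gamma gamma coefficient (> 0); 0.5 enhances low intensities.
#' @return integer array height x width x 3 (R, G, B), values 0..255.
#' @export
composite_rgb <- function(image, min_val = 0, max_val = 11000, gamma = 0.5) {
  if (max_val <= min_val) stop("max_val must exceed min_val")
  if (gamma <= 0) stop("gamma must be positive")
  groups <- list(R = c("U2r", "BLr", "GRr"),
                 G = c("U1g", "U2g", "BLg"),
                 B = c("U1b", "U2b"))
  d <- dim(image$data)
  out <- array(0L, dim = c(d[1], d[2], 3),
               dimnames = list(NULL, NULL, names(groups)))
  for (g in names(groups)) {
    chans <- groups[[g]]
    plane <- apply(image$data[, , chans, drop = FALSE], c(1, 2), mean)
    v <- pmin(pmax((plane - min_val) / (max_val - min_val), 0), 1)^gamma
    out[, , g] <- matrix(as.integer(floor(v * 255 + 0.5)), d[1], d[2])
  }
  out
}
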