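# Regions of interest: the whole grain section (fixed gray-level threshold
# on the sum-of-intensity image, then square opening/closing) and the outer
# tissues (two Otsu thresholds restricted to section pixels, merged, then
# disk opening / dilation / opening and largest-component selection).
# Morphological sizes are given on the reference full-resolution grid
# (width 3500 px) and scale with the working grid width; "size" means side
# length for squares and radius for disks.

morph_scale <- function(width, reference_width = 3500) width / reference_width

odd_box <- function(size) {
  s <- max(1L, as.integer(round(size)))
  if (s %% 2L == 0L) s <- s + 1L
  s
}

#' New ROI mask object
#' @param mask logical matrix.
#' @param kind `"whole_section"` or `"outer_tissues"`.
#' @param params_used record of thresholds and morphological sizes.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(mask, kind, params_used = list()) {
  structure(list(mask = mask, kind = kind, params_used = params_used),
            class = "roi_mask")
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  lab == which.max(tab)
}

#' Segment the whole grain section
#'
#' Thresholds the 8-bit sum-of-intensity image at a common gray level
#' (default 2), then applies a morphological opening and closing with
#' square structuring elements (reference sizes 51 and 150 px, scaled to
#' the working grid) and keeps the largest connected region. The threshold
#' can be overridden per section where the common value is inappropriate.
#'
#' @param sum8 integer matrix from [sum_intensity_image()] (values 0..255).
#' @param threshold gray-level threshold; pixels strictly above it are kept.
#' @param open_size,close_size square structuring element side lengths in
#'   working-grid pixels; defaults scale 51 and 150 by
#'   `ncol(sum8)/reference_width`.
#' @param reference_width width of the reference grid the stated sizes
#'   refer to.
#' @param select_largest keep only the largest connected region.
#' @return a `roi_mask` of kind `"whole_section"`.
#' @export
segment_section <- function(sum8, threshold = 2, open_size = NULL,
                            close_size = NULL, reference_width = 3500,
                            select_largest = TRUE) {
  if (!is.matrix(sum8) || min(sum8) < 0 || max(sum8) > 255) {
    stop("sum8 must be an 8-bit (0..255) matrix")
  }
  sf <- morph_scale(ncol(sum8), reference_width)
  if (is.null(open_size)) open_size <- odd_box(51 * sf)
  if (is.null(close_size)) close_size <- odd_box(150 * sf)
  if (open_size < 1 || close_size < 1) stop("structuring sizes must be >= 1")

  m <- sum8 > threshold
  if (any(m)) {
    m <- EBImage::opening(m, EBImage::makeBrush(odd_box(open_size), "box")) > 0
    m <- EBImage::closing(m, EBImage::makeBrush(odd_box(close_size), "box")) > 0
    if (select_largest) m <- largest_component(m)
  }
  roi_mask(m, "whole_section",
           list(threshold = threshold, open_size = open_size,
                close_size = close_size))
}

# Otsu threshold from gray-level values (0..levels-1): maximizes the
# between-class variance of the histogram. Operates on an arbitrary pixel
# subset, which EBImage::otsu does not support; cross-checked against it in
# the tests. Returns the threshold t such that the foreground is v > t.
otsu_gray <- function(values, levels = 256L) {
  counts <- tabulate(as.integer(values) + 1L, nbins = levels)
  n <- sum(counts)
  if (sum(counts > 0) < 2) stop("degenerate input: Otsu threshold undefined on a constant image")
  g <- seq_len(levels) - 1
  w1 <- cumsum(counts)
  mu <- cumsum(counts * g)
  mu_t <- mu[levels]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  m1 <- mu / w1
  m2 <- (mu_t - mu) / w2
  bcv <- ifelse(valid, w1 * w2 * (m1 - m2)^2, -Inf)
  g[which.max(bcv)]
}

# rescale values to 0..255 over the masked pixels
rescale8_masked <- function(values, mask) {
  v <- values[mask]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("degenerate input: image is constant over the section")
  out <- matrix(0L, nrow(values), ncol(values))
  out[mask] <- as.integer(floor((v - lo) / (hi - lo) * 255 + 0.5))
  out
}

#' Segment the grain outer tissues
#'
#' Two Otsu thresholds are computed on the pixels of the whole-section ROI:
#' one on the sum of all 11 channels and one on the sum of the UV-weighted
#' channels (U1b, U1g, U2b, U2g, BLg), avoiding red emission. The two
#' supra-threshold regions are merged, post-processed with disk structuring
#' elements (opening radius 1 to remove noise, dilation radius 8 to enlarge,
#' opening radius 12 to smooth contours, reference-grid sizes scaled to the
#' working grid), and the largest connected region is retained. Thresholds
#' and sizes can be overridden, supporting the per-image manual
#' adjustments such series typically need.
#'
#' @param image a background-subtracted `multispectral_image`.
#' @param section `roi_mask` of the whole section (nonempty).
#' @param t1,t2 optional gray-level (0..255) overrides of the two Otsu
#'   thresholds.
#' @param open1,dilation,open2 disk radii on the reference grid (defaults
#'   1, 8, 12), scaled by `ncol/reference_width` with a floor of 1.
#' @param reference_width reference grid width for size scaling.
#' @return a `roi_mask` of kind `"outer_tissues"`.
#' @export
segment_outer_tissues <- function(image, section, t1 = NULL, t2 = NULL,
                                  open1 = 1, dilation = 8, open2 = 12,
                                  reference_width = 3500) {
  sec <- section$mask
  if (!any(sec)) stop("section mask is empty")
  s11 <- apply(image$data, c(1, 2), sum)
  suv <- apply(image$data[, , uv_sum_channels(), drop = FALSE], c(1, 2), sum)

  v1 <- rescale8_masked(s11, sec)
  v2 <- rescale8_masked(suv, sec)
  if (is.null(t1)) t1 <- otsu_gray(v1[sec])
  if (is.null(t2)) t2 <- otsu_gray(v2[sec])
  raw <- (sec & v1 > t1) | (sec & v2 > t2)

  sf <- morph_scale(ncol(sec), reference_width)
  radii <- pmax(1L, as.integer(round(c(open1, dilation, open2) * sf)))
  disks <- lapply(radii, function(r) EBImage::makeBrush(2L * r + 1L, "disc"))
  m <- EBImage::opening(raw, disks[[1]]) > 0
  m <- EBImage::dilate(m, disks[[2]]) > 0
  m <- EBImage::opening(m, disks[[3]]) > 0
  m <- largest_component(m)
  roi_mask(m, "outer_tissues",
           list(t1 = t1, t2 = t2, open1 = radii[1], dilation = radii[2],
                open2 = radii[3]))
}

#' Surface area of a mask
#'
#' @param mask a `roi_mask` or logical matrix.
#' @param pixel_size pixel edge in micrometers (> 0).
#' @return area in mm^2 (`count * pixel_size^2 * 1e-6`).
#' @export
section_area <- function(mask, pixel_size) {
  if (pixel_size <= 0) stop("pixel_size must be positive")
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  sum(m) * pixel_size^2 * 1e-6
}

#' Jaccard index of two masks
#' @param a,b logical matrices or `roi_mask` objects.
#' @return intersection-over-union in `[0, 1]` (1 if both empty).
#' @export
jaccard_index <- function(a, b) {
  ma <- if (inherits(a, "roi_mask")) a$mask else a
  mb <- if (inherits(b, "roi_mask")) b$mask else b
  u <- sum(ma | mb)
  if (u == 0) return(1)
  sum(ma & mb) / u
}
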