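# File formats: 16-bit multi-page TIFF for raw filter acquisitions (pages
# R, G, B), 32-bit float multi-page TIFF for assembled cubes (one page per
# channel, values scaled by 2^14) with a JSON sidecar, 8-bit TIFF for label
# maps and masks, PNG for renderings, CSV for tables, JSON for models.

RAW_SCALE <- 65535  # 16-bit TIFF stores k/65535 exactly for integer k
MSI_SCALE <- 16384  # power of two: integer counts stay exact in float32

#' Write / read one synthetic acquisition
#'
#' Writes the four filter images as `<sectionID>_<filter>.tif` (16-bit,
#' three pages R, G, B), the phantom label map as an 8-bit TIFF and the
#' metadata sidecar (stage, pixel size, true background, seed) as JSON,
#' in a per-section subdirectory.
#'
#' @param acquisition named list of `raw_filter_image` (U1, U2, BL, GR).
#' @param phantom the `section_phantom` ground truth (may be `NULL`).
#' @param dir parent output directory.
#' @param section_id section identifier used in filenames.
#' @return the per-section directory path.
#' @export
write_acquisition <- function(acquisition, phantom, dir, section_id) {
  sdir <- file.path(dir, section_id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  for (f in names(acquisition)) {
    planes <- acquisition[[f]]$rgb_planes
    pages <- lapply(c("R", "G", "B"), function(p) planes[, , p] / RAW_SCALE)
    tiff::writeTIFF(pages, file.path(sdir, sprintf("%s_%s.tif", section_id, f)),
                    bits.per.sample = 16L)
  }
  if (!is.null(phantom)) {
    tiff::writeTIFF(phantom$label_map / 255,
                    file.path(sdir, sprintf("%s_labels.tif", section_id)),
                    bits.per.sample = 8L)
    meta <- list(section_id = section_id, stage = phantom$stage,
                 pixel_size = phantom$pixel_size,
                 true_background = as.list(phantom$true_background),
                 seed = phantom$geometry$seed)
    jsonlite::write_json(meta, file.path(sdir, sprintf("%s_meta.json", section_id)),
                         auto_unbox = TRUE, digits = NA)
  }
  sdir
}

#' @rdname write_acquisition
#' @param path per-section directory written by [write_acquisition()].
#' @export
read_acquisition <- function(path) {
  section_id <- basename(path)
  out <- list()
  for (f in filter_names()) {
    pages <- tiff::readTIFF(file.path(path, sprintf("%s_%s.tif", section_id, f)),
                            all = TRUE)
    planes <- array(0L, dim = c(dim(pages[[1]]), 3),
                    dimnames = list(NULL, NULL, c("R", "G", "B")))
    for (k in 1:3) planes[, , k] <- as.integer(round(pages[[k]] * RAW_SCALE))
    out[[f]] <- structure(list(filter = f, rgb_planes = planes,
                               exposure_gain = NA_real_),
                          class = "raw_filter_image")
  }
  out
}

#' Write / read a multispectral image as multi-page 32-bit TIFF
#'
#' One 32-bit page per channel, counts scaled by 2^14 onto the TIFF unit
#' range; the storage quantum is 2^14/2^32 ~ 4e-6 counts, negligible
#' against photon noise. A JSON sidecar records channel names, pixel size
#' and provenance.
#'
#' @param image a `multispectral_image`.
#' @param path output `.tif` path (sidecar at `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_msi_tiff <- function(image, path) {
  pages <- lapply(seq_along(image$channels), function(k) image$data[, , k] / MSI_SCALE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(channels = image$channels,
                            pixel_size = image$pixel_size,
                            provenance = image$provenance,
                            scale = MSI_SCALE),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_msi_tiff
#' @export
read_msi_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  cube <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) cube[, , k] <- pages[[k]] * meta$scale
  multispectral_image(cube, meta$channels, meta$pixel_size, meta$provenance)
}

#' Write a binary mask as 8-bit TIFF with a JSON parameter sidecar
#' @param mask a `roi_mask`.
#' @param path output `.tif` path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask$mask * 255) / 255, path, bits.per.sample = 8L)
  jsonlite::write_json(list(kind = mask$kind, params_used = mask$params_used),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an 8-bit gray matrix or RGB array as PNG
#' @param img integer matrix (0..255) or height x width x 3 array.
#' @param path output `.png` path.
#' @export
write_png8 <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Serialize / read a PCA model as JSON
#' @param model a `pca_model`.
#' @param path JSON path.
#' @export
write_pca_json <- function(model, path) {
  jsonlite::write_json(
    list(channels = model$channels,
         mean = as.numeric(model$mean),
         eigenvalues = model$eigenvalues,
         loadings = as.numeric(t(model$loadings)),  # row-major
         explained = model$explained,
         n_pixels = model$n_pixels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- matrix(j$loadings, nrow = length(j$channels), byrow = TRUE)
  rownames(L) <- j$channels
  structure(list(mean = stats::setNames(j$mean, j$channels),
                 eigenvalues = j$eigenvalues, loadings = L,
                 explained = j$explained, n_pixels = j$n_pixels,
                 channels = j$channels),
            class = "pca_model")
}
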