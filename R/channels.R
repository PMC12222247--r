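# Canonical channel layout of the multispectral cube.
#
# Four excitation filter cubes (two UV: U1, U2; two visible: Blue BL, Green
# GR) each yield one RGB acquisition. Merging the blue/green/red planes in
# order of decreasing wavelength per filter gives 12 channels; channel U1r
# carries Rayleigh-band reflection and is dropped, leaving the 11-channel
# cube whose per-pixel rows are the "pseudo-spectra".

#' Channel names of the assembled multispectral cube
#'
#' @param drop_u1r if `TRUE` (default) return the 11 channels retained for
#'   analysis; if `FALSE`, the 12-channel pre-exclusion layout including the
#'   reflection-contaminated `U1r`.
#' @return character vector of channel names, ordered filter-wise from high
#'   to low emission wavelength (blue, green, red planes of U1, U2, BL, GR).
#' @export
fluor_channels <- function(drop_u1r = TRUE) {
  ch12 <- c("U1b", "U1g", "U1r",
            "U2b", "U2g", "U2r",
            "BLb", "BLg", "BLr",
            "GRb", "GRg", "GRr")
  if (drop_u1r) setdiff(ch12, "U1r") else ch12
}

# Channels with no autofluorescence signal, kept as a baseline in the
# pseudo-spectra: blue emission under blue/green excitation and green
# emission under green excitation.
baseline_channels <- function() c("BLb", "GRb", "GRg")

# Channels entering the second (UV-weighted) Otsu sum, avoiding red emission.
uv_sum_channels <- function() c("U1b", "U1g", "U2b", "U2g", "BLg")

filter_names <- function() c("U1", "U2", "BL", "GR")
visible_filters <- function() c("BL", "GR")

# 14-bit camera ceiling.
max_count <- function() 16383L

filter_of_channel <- function(ch) substr(ch, 1, 2)
plane_of_channel <- function(ch) substring(ch, 3)
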