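#' Construct a fluorophore endmember spectrum
#'
#' An endmember is a nonnegative weight per retained emission channel,
#' describing how one fluorophore class distributes its emission over the
#' 11-channel layout. The three signal-free baseline channels (`BLb`,
#' `GRb`, `GRg`) must carry zero weight.
#'
#' @param name fluorophore label.
#' @param weights named numeric vector; names must cover exactly
#'   [fluor_channels()] (missing channels default to 0).
#' @return an object of class `endmember`.
#' @export
endmember <- function(name, weights) {
  ch <- fluor_channels()
  w <- stats::setNames(numeric(length(ch)), ch)
  if (is.null(names(weights)) || !all(names(weights) %in% ch)) {
    stop("endmember weights must be named with retained channel names")
  }
  w[names(weights)] <- weights
  if (any(w < 0)) stop("endmember weights must be nonnegative")
  if (any(w[baseline_channels()] != 0)) {
    stop("baseline channels (", paste(baseline_channels(), collapse = ", "),
         ") must have zero weight")
  }
  structure(list(name = name, channel_weights = w), class = "endmember")
}

#' Default endmember library
#'
#' Three canonical fluorophore classes spanning the spectral contrasts of a
#' developing grain section:
#' * `chlorophyll_like` — red emission under blue/green excitation, with a
#'   weak red tail under UV2;
#' * `hydroxycinnamate_like` — blue (and some green) emission under the two
#'   UV excitations, typical of cell-wall phenolics;
#' * `lignin_like` — green emission under blue excitation plus a broad
#'   low-level contribution across UV channels.
#'
#' The weights are phenomenological contrasts, not measured spectra.
#'
#' @return named list of [endmember] objects.
#' @export
default_endmembers <- function() {
  list(
    chlorophyll_like = endmember("chlorophyll_like", c(
      U2r = 0.25, BLr = 1.0, GRr = 1.0)),
    hydroxycinnamate_like = endmember("hydroxycinnamate_like", c(
      U1b = 1.0, U1g = 0.40, U2b = 0.80, U2g = 0.35)),
    lignin_like = endmember("lignin_like", c(
      BLg = 1.0, U1b = 0.15, U1g = 0.30, U2b = 0.10, U2g = 0.30,
      BLr = 0.10, GRr = 0.05))
  )
}

# weights matrix (n_fluor x 11) in canonical channel order
endmember_matrix <- function(endmembers) {
  w <- t(vapply(endmembers, function(e) e$channel_weights,
                numeric(length(fluor_channels()))))
  rownames(w) <- vapply(endmembers, `[[`, character(1), "name")
  w
}
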