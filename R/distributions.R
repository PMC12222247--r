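# Score distributions on shared percentile bins, and their similarity map.
#
# For one component, the scores of all ROI pixels of all images are first
# pooled into a fine histogram (10,000 linear bins a priori, so the series
# never needs to be held in memory). Percentiles of that global
# distribution (0 to 100, step 1%) define ~100 variable-width bins common
# to the series; the observed distribution of each image is its per-bin
# relative frequency on those shared edges. By construction, the pooled
# pixel-weighted distribution is ~1% per bin; differences between images
# reveal where the pixels singled out by a component are found. A standard
# PCA of the stacked distributions gives per-image coordinates: the
# similarity map of developmental stages.

#' Global fine histogram of a component's scores
#'
#' @param scores numeric vector of all pooled ROI-pixel scores (all images).
#' @param n_bins number of linear bins (default 10000).
#' @param component optional component label carried along.
#' @return object of class `global_histogram`: `edges` (n_bins + 1),
#'   `counts` (n_bins, summing to the pooled pixel count), `n`,
#'   `component`. A degenerate pool (all scores equal) yields a single
#'   zero-width bin.
#' @export
global_histogram <- function(scores, n_bins = 10000L, component = NA_integer_) {
  if (length(scores) == 0) stop("empty score stream")
  if (n_bins < 2) stop("n_bins must be at least 2")
  lo <- min(scores); hi <- max(scores)
  if (hi <= lo) {
    return(structure(list(edges = c(lo, lo), counts = length(scores),
                          n = length(scores), component = component),
                     class = "global_histogram"))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  idx <- findInterval(scores, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(edges = edges, counts = counts, n = length(scores),
                 component = component),
            class = "global_histogram")
}

#' Percentile bin edges from a global histogram
#'
#' Percentile positions (0 to 100 by `step_percent`) are estimated from
#' the fine histogram by linear interpolation within bins; first and last
#' edges are the global minimum and maximum. Duplicate edges produced by
#' massive ties are merged, so the bin count may fall below
#' `100 / step_percent`.
#'
#' @param hist a `global_histogram`.
#' @param step_percent percentile step in percent (0 < step <= 50).
#' @return object of class `percentile_bins`: `edges` (non-decreasing,
#'   deduplicated), `n_bins`, `step_percent`, `component`.
#' @export
percentile_edges <- function(hist, step_percent = 1) {
  if (step_percent <= 0 || step_percent > 50) {
    stop("step_percent must be in (0, 50]")
  }
  if (length(hist$counts) == 1L) {
    return(structure(list(edges = hist$edges[c(1, 1)], n_bins = 1L,
                          step_percent = step_percent,
                          component = hist$component),
                     class = "percentile_bins"))
  }
  probs <- seq(0, 100, by = step_percent)
  if (probs[length(probs)] < 100) probs <- c(probs, 100)
  cum <- c(0, cumsum(hist$counts))
  targets <- probs / 100 * hist$n
  edges <- vapply(targets, function(t) {
    j <- findInterval(t, cum, rightmost.closed = TRUE, all.inside = TRUE)
    if (hist$counts[j] == 0) return(hist$edges[j + 1])
    hist$edges[j] + (t - cum[j]) / hist$counts[j] *
      (hist$edges[j + 1] - hist$edges[j])
  }, numeric(1))
  edges[1] <- hist$edges[1]
  edges[length(edges)] <- hist$edges[length(hist$edges)]
  edges <- unique(edges)
  structure(list(edges = edges, n_bins = length(edges) - 1L,
                 step_percent = step_percent, component = hist$component),
            class = "percentile_bins")
}

# per-bin counts on percentile edges; intervals are [e_i, e_{i+1}) with the
# last bin closed; values are clamped into the global span
bin_counts <- function(values, bins) {
  if (bins$n_bins == 1L && bins$edges[1] == bins$edges[2]) {
    return(length(values))
  }
  idx <- findInterval(values, bins$edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tabulate(idx, nbins = bins$n_bins)
}

#' Observed score distribution of one image
#'
#' Relative frequency of the image's ROI pixels per shared percentile bin.
#'
#' @param score a `score_image` (or numeric vector of score values).
#' @param mask ROI mask restricting the quantification (the outer-tissue
#'   ROI in the standard workflow); ignored when `score` is a vector.
#' @param bins a `percentile_bins` from the same component's global pass.
#' @param stage optional stage label carried along.
#' @param image_id optional identifier (defaults to the score image's).
#' @return object of class `score_distribution`: `frequencies`
#'   (nonnegative, summing to 1), `image_id`, `component`, `stage`.
#' @export
observed_distribution <- function(score, mask = NULL, bins, stage = NA,
                                  image_id = NULL) {
  if (inherits(score, "score_image")) {
    m <- if (inherits(mask, "roi_mask")) mask$mask else mask
    values <- if (is.null(m)) score$values[!is.na(score$values)] else
      score$values[m & !is.na(score$values)]
    comp <- score$component
    if (is.null(image_id)) image_id <- score$image_id
  } else {
    values <- score
    comp <- bins$component
  }
  if (length(values) == 0) stop("empty ROI")
  counts <- bin_counts(values, bins)
  structure(list(frequencies = counts / length(values),
                 image_id = image_id, component = comp, stage = stage,
                 n_pixels = length(values)),
            class = "score_distribution")
}

#' Average observed distributions by developmental stage
#'
#' Unweighted mean of the frequency vectors of each stage's sections
#' (sections from the same grain are not reweighted).
#'
#' @param distributions list of `score_distribution` objects, each with a
#'   stage label.
#' @return matrix, one row per stage (sorted), rows summing to 1.
#' @export
average_by_stage <- function(distributions) {
  stages <- vapply(distributions, function(d) as.character(d$stage), character(1))
  if (any(is.na(stages) | stages == "NA")) stop("unknown stage label")
  freq <- do.call(rbind, lapply(distributions, `[[`, "frequencies"))
  out <- t(vapply(sort(unique(stages)), function(s) {
    colMeans(freq[stages == s, , drop = FALSE])
  }, numeric(ncol(freq))))
  out
}

#' Similarity map: PCA of the score distributions
#'
#' Column-centered (covariance) PCA of the images-by-bins frequency
#' matrix; the per-image coordinates on the first components place similar
#' distributions close together, so developmental stages can be compared
#' at a glance.
#'
#' @param freq_matrix numeric matrix, images x bins (or a list of
#'   `score_distribution` objects).
#' @param n_components number of axes to keep.
#' @param stages optional per-image stage labels for plotting.
#' @return object of class `similarity_map`: `coordinates` (images x
#'   n_components, column means ~ 0), `explained` (percent per kept axis),
#'   `stages`, `rotation`, `center`.
#' @export
meta_pca <- function(freq_matrix, n_components = 2, stages = NULL) {
  if (is.list(freq_matrix) && !is.matrix(freq_matrix)) {
    if (is.null(stages)) {
      stages <- vapply(freq_matrix, function(d) as.character(d$stage), character(1))
    }
    freq_matrix <- do.call(rbind, lapply(freq_matrix, `[[`, "frequencies"))
  }
  if (nrow(freq_matrix) < 2) stop("at least two images are required")
  if (ncol(freq_matrix) < 2) stop("at least two bins are required")
  n_components <- min(n_components, nrow(freq_matrix) - 1, ncol(freq_matrix))
  pc <- stats::prcomp(freq_matrix, center = TRUE, scale. = FALSE)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coordinates = pc$x[, seq_len(n_components), drop = FALSE],
                 explained = expl[seq_len(n_components)],
                 stages = stages,
                 rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
                 center = pc$center),
            class = "similarity_map")
}
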