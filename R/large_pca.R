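# "Large PCA": one principal component analysis over all ROI pixels of a
# whole image series, fitted without ever concatenating the series. Each
# image is unfolded into its pixel-by-channel table X_i and contributes
# three accumulable statistics: its pixel count, the sum of its
# pseudo-spectra (contribution to the global mean), and its cross-product
# matrix X_i'X_i (contribution to the global variance-covariance matrix).
# The eigendecomposition of the accumulated covariance yields eigenvalues
# and loadings common to every image in the series; scores are obtained by
# re-visiting each image, centering by the global mean, projecting, and
# refolding to the pixel grid.

#' Per-image accumulated statistics
#'
#' Unfolds the ROI pixels of one multispectral image and computes its local
#' contribution to the series statistics.
#'
#' @param image a `multispectral_image`.
#' @param mask a `roi_mask` (or logical matrix) selecting contributing
#'   pixels; the analysis ROI is the whole-section mask.
#' @return object of class `accumulated_stats` with fields `n_pixels`,
#'   `sum_vector`, `crossprod`, `n_images`, `channels`.
#' @export
pixel_stats <- function(image, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!any(m)) stop("mask selects no pixels")
  X <- unfold_pixels(image, m)
  structure(list(n_pixels = nrow(X),
                 sum_vector = colSums(X),
                 crossprod = crossprod(X),
                 n_images = 1L,
                 channels = image$channels),
            class = "accumulated_stats")
}

#' Unfold ROI pixels into a pixel-by-channel table
#' @param image a `multispectral_image`.
#' @param mask logical matrix (or `roi_mask`).
#' @return numeric matrix, one row per ROI pixel (its pseudo-spectrum),
#'   columns named by channel.
#' @export
unfold_pixels <- function(image, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  idx <- which(m)
  X <- matrix(0, length(idx), length(image$channels),
              dimnames = list(NULL, image$channels))
  for (k in seq_along(image$channels)) X[, k] <- image$data[, , k][idx]
  X
}

#' Merge two accumulated statistics
#'
#' Element-wise addition; merging is associative and commutative, so the
#' accumulated series statistics are independent of image order.
#'
#' @param a,b `accumulated_stats` over identical channel lists.
#' @return merged `accumulated_stats`.
#' @export
merge_stats <- function(a, b) {
  if (!identical(a$channels, b$channels)) stop("channel lists differ")
  structure(list(n_pixels = a$n_pixels + b$n_pixels,
                 sum_vector = a$sum_vector + b$sum_vector,
                 crossprod = a$crossprod + b$crossprod,
                 n_images = a$n_images + b$n_images,
                 channels = a$channels),
            class = "accumulated_stats")
}

# pairwise reduction limits floating-point drift for long series
.pairwise_reduce <- function(items, f) {
  while (length(items) > 1) {
    n <- length(items)
    items <- lapply(seq_len(ceiling(n / 2)), function(i) {
      if (2 * i <= n) f(items[[2 * i - 1]], items[[2 * i]]) else items[[2 * i - 1]]
    })
  }
  items[[1]]
}

#' Accumulate series statistics over (image, mask) pairs
#'
#' Single streaming pass; per-image contributions are combined by pairwise
#' summation.
#'
#' @param series list of `list(image =, mask =)` pairs, or a list of
#'   already-computed `accumulated_stats`.
#' @return an `accumulated_stats` for the whole series.
#' @export
accumulate_statistics <- function(series) {
  if (length(series) == 0) stop("empty series")
  parts <- lapply(series, function(s) {
    if (inherits(s, "accumulated_stats")) s else pixel_stats(s$image, s$mask)
  })
  .pairwise_reduce(parts, merge_stats)
}

#' Finalize the PCA model from accumulated statistics
#'
#' Computes the global mean pseudo-spectrum `m = sum/N`, the centered
#' covariance `C = (crossprod - N m m') / (N - 1)`, and its
#' eigendecomposition, with eigenvalues sorted descending. Loading signs
#' are canonicalized by flipping each column so that its largest-magnitude
#' element is negative (so the intensity component, whose loading weighs
#' every channel with a common sign, comes out all-negative, matching the
#' usual presentation).
#'
#' @param stats an `accumulated_stats` with `n_pixels >= 2`.
#' @return object of class `pca_model`: fields `mean`, `eigenvalues`,
#'   `loadings` (channels x components, orthonormal), `explained`
#'   (percentages summing to 100), `n_pixels`, `channels`.
#' @export
finalize_pca <- function(stats) {
  N <- stats$n_pixels
  if (N < 2) stop("at least two pixels are required")
  if (!all(is.finite(stats$sum_vector)) || !all(is.finite(stats$crossprod))) {
    stop("non-finite accumulated statistics")
  }
  m <- stats$sum_vector / N
  C <- (stats$crossprod - N * tcrossprod(m)) / (N - 1)
  C <- (C + t(C)) / 2
  ee <- eigen(C, symmetric = TRUE)
  lambda <- pmax(ee$values, 0)
  L <- ee$vectors
  for (k in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, k])), k] > 0) L[, k] <- -L[, k]
  }
  rownames(L) <- stats$channels
  structure(list(mean = stats::setNames(m, stats$channels),
                 eigenvalues = lambda,
                 loadings = L,
                 explained = 100 * lambda / sum(lambda),
                 n_pixels = N,
                 channels = stats$channels),
            class = "pca_model")
}

#' Project one image onto a principal component
#'
#' Scores are the centered pseudo-spectra projected onto the common
#' loading, refolded to the image grid; pixels outside the ROI are `NA`.
#'
#' @param image a `multispectral_image`.
#' @param mask ROI mask (scores are defined on its pixels).
#' @param model a `pca_model` over the same channels.
#' @param component component index k.
#' @return object of class `score_image`: fields `component`, `values`
#'   (matrix, `NA` outside the ROI), `image_id`.
#' @export
project_scores <- function(image, mask, model, component) {
  if (component < 1 || component > ncol(model$loadings)) {
    stop("component out of range")
  }
  if (!identical(image$channels, model$channels)) {
    stop("model channels do not match the image")
  }
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  X <- unfold_pixels(image, m)
  s <- (X - rep(model$mean, each = nrow(X))) %*% model$loadings[, component]
  values <- matrix(NA_real_, nrow(m), ncol(m))
  values[which(m)] <- s
  structure(list(component = as.integer(component), values = values,
                 image_id = image$provenance),
            class = "score_image")
}

#' Score values of several components at once
#'
#' Matrix version of [project_scores()] for streaming pipelines: returns
#' the ROI-pixel score matrix without refolding.
#'
#' @param image,mask,model as in [project_scores()].
#' @param components integer vector of component indices.
#' @return numeric matrix, ROI pixels x components.
#' @export
project_score_values <- function(image, mask, model, components) {
  if (any(components < 1 | components > ncol(model$loadings))) {
    stop("component out of range")
  }
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  X <- unfold_pixels(image, m)
  (X - rep(model$mean, each = nrow(X))) %*%
    model$loadings[, components, drop = FALSE]
}

#' Render a score image on the common 8-bit scale
#'
#' The gray bounds are derived from the model eigenvalues as
#' `+/- spread * sqrt(lambda_k)` and are therefore identical for every
#' image of the series on a given component, making score images directly
#' comparable. Scores are clipped to the bounds and mapped linearly to
#' 0..255 (zero score maps to mid-gray 128); pixels outside the ROI render
#' as 0.
#'
#' @param score a `score_image`.
#' @param model the `pca_model` the score was projected with.
#' @param spread bound multiplier in score standard deviations (default 3,
#'   covering ~99.7% of a Gaussian score spread).
#' @return integer matrix 0..255 with attribute `bounds = c(lo, hi)`.
#' @export
score_to_8bit <- function(score, model, spread = 3) {
  if (spread <= 0) stop("spread must be positive")
  lam <- model$eigenvalues[score$component]
  if (lam == 0) {
    if (any(score$values != 0, na.rm = TRUE)) {
      stop("zero eigenvalue with nonzero scores")
    }
    b <- 1
  } else {
    b <- spread * sqrt(lam)
  }
  v <- pmin(pmax(score$values, -b), b)
  g <- floor((v + b) / (2 * b) * 255 + 0.5)
  g[is.na(g)] <- 0
  structure(matrix(as.integer(g), nrow(g), ncol(g)), bounds = c(-b, b))
}
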