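# Standard figures of the workflow: loadings per component, average score
# distributions per stage, and the similarity map.

#' Plot the loading of one or more components
#' @param model a `pca_model`.
#' @param components component indices.
#' @return a ggplot object.
#' @export
plot_loadings <- function(model, components = 1:5) {
  df <- do.call(rbind, lapply(components, function(k) {
    data.frame(channel = factor(model$channels, levels = model$channels),
               loading = model$loadings[, k],
               component = sprintf("PC%d (%.2f%%)", k, model$explained[k]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "loading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot the stage-averaged score distributions of one component
#' @param stage_avg matrix from [average_by_stage()].
#' @param bins the matching `percentile_bins`.
#' @return a ggplot object.
#' @export
plot_stage_distributions <- function(stage_avg, bins) {
  mids <- (bins$edges[-1] + bins$edges[-length(bins$edges)]) / 2
  df <- do.call(rbind, lapply(rownames(stage_avg), function(s) {
    data.frame(stage = s, score = mids, frequency = stage_avg[s, ])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$frequency,
                                   colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "score (bin midpoint)", y = "mean relative frequency",
                  colour = "stage (°DAF)") +
    ggplot2::theme_minimal()
}

#' Plot a similarity map
#' @param sim a `similarity_map`.
#' @return a ggplot object.
#' @export
plot_similarity_map <- function(sim) {
  df <- data.frame(axis1 = sim$coordinates[, 1],
                   axis2 = if (ncol(sim$coordinates) > 1)
                     sim$coordinates[, 2] else 0,
                   stage = if (is.null(sim$stages)) "all" else
                     as.character(sim$stages))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                   colour = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("axis 1 (%.1f%%)", sim$explained[1]),
      y = if (length(sim$explained) > 1)
        sprintf("axis 2 (%.1f%%)", sim$explained[2]) else "axis 2",
      colour = "stage (°DAF)") +
    ggplot2::theme_minimal()
}
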