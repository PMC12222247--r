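#!/usr/bin/env Rscript
# Similarity maps: PCA of the stacked score distributions, per component.
# Stages should order along axis 1 for the component tracking the fading
# red emission, and cluster by stage where the stage effect dominates.

library(grainspectra)

run <- if (file.exists("scratch/pipeline_run.rds")) {
  readRDS("scratch/pipeline_run.rds")
} else {
  run_pipeline(default_run_config(seed = 1L))
}

rows <- list()
for (nm in names(run$similarity)) {
  sm <- run$similarity[[nm]]
  if (is.null(sm)) next
  rows[[nm]] <- data.frame(component = nm,
                           section_id = run$manifest$section_id,
                           stage = run$manifest$stage,
                           axis1 = sm$coordinates[, 1],
                           axis2 = sm$coordinates[, 2],
                           axis1_explained_pct = sm$explained[1],
                           axis2_explained_pct = sm$explained[2])
}
coords <- do.call(rbind, rows)
write.csv(coords, "results/similarity_map.csv", row.names = FALSE)

sm1 <- run$similarity$comp1
cent <- tapply(sm1$coordinates[, 1], run$manifest$stage,
               mean)[as.character(c(250, 450, 650, 850))]
cat("component-1 similarity map: stage centroids on axis 1\n")
print(round(cent, 3))
cat("monotone in stage:", all(diff(cent) > 0) || all(diff(cent) < 0), "\n")
cat(sprintf("axis 1 / axis 2 explained: %.1f%% / %.1f%%\n",
            sm1$explained[1], sm1$explained[2]))

dir.create("results/figures", showWarnings = FALSE)
for (nm in names(run$similarity)) {
  if (is.null(run$similarity[[nm]])) next
  ggplot2::ggsave(sprintf("results/figures/similarity_%s.png", nm),
                  plot_similarity_map(run$similarity[[nm]]),
                  width = 6, height = 4.5, dpi = 150)
}
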