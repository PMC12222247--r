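# End-to-end orchestration: simulate (or ingest) the acquisition series,
# assemble and background-correct each cube, segment the two ROIs, fit the
# series-wide large PCA on the whole-section pixels, project scores, build
# percentile-binned score distributions on the outer-tissue ROI, average by
# stage and compute per-component similarity maps. Sections are processed
# one at a time; only masks and outer-ROI score vectors are retained
# between passes, so memory stays flat in the series length.

#' Default pipeline configuration
#'
#' @param seed master seed for the synthetic series.
#' @param design sections per stage (named integer vector).
#' @param noise_sd,visible_gain synthetic acquisition parameters.
#' @param components components to score and quantify (default first 5,
#'   which carry essentially all variance).
#' @param n_bins fine-histogram bin count for the global score pass.
#' @param step_percent percentile step defining the shared bins.
#' @param spread 8-bit rendering bound multiplier.
#' @param section_thresholds named list of per-section gray-level threshold
#'   overrides for the whole-section segmentation.
#' @param input_dir optional directory of acquisitions written by
#'   [generate_series()] (`dir` mode); `NULL` regenerates synthetically.
#' @param out_dir optional output directory for tables, models and
#'   renderings.
#' @param write_images also write per-section TIFF/PNG renderings (slower).
#' @return configuration list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L,
                               design = c(`250` = 10L, `450` = 10L,
                                          `650` = 10L, `850` = 10L),
                               noise_sd = 3, visible_gain = 2,
                               components = 1:5, n_bins = 10000L,
                               step_percent = 1, spread = 3,
                               section_thresholds = list(),
                               input_dir = NULL, out_dir = NULL,
                               write_images = FALSE) {
  structure(list(seed = seed, design = design, noise_sd = noise_sd,
                 visible_gain = visible_gain, components = components,
                 n_bins = n_bins, step_percent = step_percent,
                 spread = spread, section_thresholds = section_thresholds,
                 input_dir = input_dir, out_dir = out_dir,
                 write_images = write_images),
            class = "run_config")
}

# corner rectangles free of signal, on a few images spread over the stages
.auto_background_regions <- function(h, w, image_indices) {
  s <- max(8L, as.integer(round(w * 0.08)))
  rect <- rbind(c(3, 2 + s, 3, 2 + s),
                c(3, 2 + s, w - 1 - s, w - 2),
                c(h - 1 - s, h - 2, 3, 2 + s))
  do.call(rbind, lapply(seq_along(image_indices), function(i) {
    data.frame(image = i, row0 = rect[, 1], row1 = rect[, 2],
               col0 = rect[, 3], col1 = rect[, 4])
  }))
}

.assemble_section <- function(manifest, i, config) {
  acq <- load_acquisition(manifest, i)
  ph_ps <- if (is.null(manifest$pixel_size)) 1.44 * 3500 / 512 else manifest$pixel_size[i]
  assemble_multispectral(acq, visible_gain = attr(manifest, "visible_gain"),
                         pixel_size = ph_ps,
                         provenance = manifest$section_id[i])
}

#' Run the full analysis pipeline
#'
#' @param config a `run_config` from [default_run_config()].
#' @param verbose log stage progress via `message()`.
#' @return list of class `pipeline_run` with elements `manifest`,
#'   `background`, `masks` (per-section whole-section and outer-tissue
#'   ROIs), `areas` (section area table, mm^2), `area_by_stage`
#'   (mean +/- sd), `pca` (the series `pca_model`), `histograms`, `bins`,
#'   `distributions` (per component, list of `score_distribution`),
#'   `stage_averages`, `similarity` (per component `similarity_map`),
#'   `score_summary` (per-section, per-component mean and sd of the
#'   outer-ROI scores), `config`.
#' @export
run_pipeline <- function(config = default_run_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  manifest <- if (!is.null(config$input_dir)) {
    read_series_manifest(config$input_dir)
  } else {
    generate_series(config$design, seed = config$seed,
                    noise_sd = config$noise_sd,
                    visible_gain = config$visible_gain)
  }
  n <- nrow(manifest)
  say("series: ", n, " section(s), stages ",
      paste(unique(manifest$stage), collapse = "/"))

  # -- background from three corner regions on one section per stage
  bg_idx <- match(unique(manifest$stage), manifest$stage)
  bg_images <- lapply(bg_idx, function(i) .assemble_section(manifest, i, config))
  d <- dim(bg_images[[1]]$data)
  regions <- .auto_background_regions(d[1], d[2], bg_idx)
  background <- estimate_background(bg_images, regions)
  say("background estimated from ", nrow(regions), " regions on ",
      length(bg_idx), " image(s)")

  # -- pass 1: segment, measure, accumulate PCA statistics
  masks <- vector("list", n)
  areas <- numeric(n)
  stats <- NULL
  for (i in seq_len(n)) {
    sid <- manifest$section_id[i]
    res <- tryCatch({
      msi <- subtract_background(.assemble_section(manifest, i, config),
                                 background)
      sum8 <- sum_intensity_image(msi)
      thr <- config$section_thresholds[[sid]]
      sec <- segment_section(sum8, threshold = if (is.null(thr)) 2 else thr)
      outer <- segment_outer_tissues(msi, sec)
      list(sec = sec, outer = outer,
           area = section_area(sec, msi$pixel_size),
           stats = pixel_stats(msi, sec))
    }, error = function(e) stop("section ", sid, ": ", conditionMessage(e),
                                call. = FALSE))
    masks[[i]] <- list(section = res$sec, outer = res$outer)
    areas[i] <- res$area
    stats <- if (is.null(stats)) res$stats else merge_stats(stats, res$stats)
    say("  [", i, "/", n, "] ", sid, ": area ", round(res$area, 2), " mm^2")
  }
  area_table <- data.frame(section_id = manifest$section_id,
                           stage = manifest$stage, area_mm2 = areas)
  area_by_stage <- do.call(rbind, lapply(split(areas, manifest$stage), function(a) {
    data.frame(mean_mm2 = mean(a), sd_mm2 = stats::sd(a), n = length(a))
  }))
  area_by_stage$stage <- as.integer(rownames(area_by_stage))

  pca <- finalize_pca(stats)
  say("large PCA: ", pca$n_pixels, " pixels; explained (top 5): ",
      paste(round(pca$explained[1:min(5, length(pca$explained))], 2),
            collapse = " / "), " %")

  # -- pass 2: outer-ROI scores per section for the requested components
  comps <- config$components
  scores <- vector("list", n)
  for (i in seq_len(n)) {
    msi <- subtract_background(.assemble_section(manifest, i, config),
                               background)
    scores[[i]] <- project_score_values(msi, masks[[i]]$outer, pca, comps)
    if (!is.null(config$out_dir) && config$write_images) {
      .write_section_outputs(msi, masks[[i]], pca, comps, config,
                             manifest$section_id[i])
    }
  }

  # per-section, per-component score summary over the outer-tissue ROI
  score_summary <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(section_id = manifest$section_id[i], stage = manifest$stage[i],
               component = comps,
               mean_score = colMeans(scores[[i]]),
               sd_score = apply(scores[[i]], 2, stats::sd))
  }))

  # -- distributions and similarity maps per component
  histograms <- list(); bins <- list(); dists <- list()
  stage_avgs <- list(); sims <- list()
  for (j in seq_along(comps)) {
    k <- comps[j]
    pooled <- unlist(lapply(scores, function(s) s[, j]), use.names = FALSE)
    histograms[[j]] <- global_histogram(pooled, n_bins = config$n_bins,
                                        component = k)
    bins[[j]] <- percentile_edges(histograms[[j]],
                                  step_percent = config$step_percent)
    dists[[j]] <- lapply(seq_len(n), function(i) {
      observed_distribution(scores[[i]][, j], bins = bins[[j]],
                            stage = manifest$stage[i],
                            image_id = manifest$section_id[i])
    })
    stage_avgs[[j]] <- average_by_stage(dists[[j]])
    if (n >= 2) {
      sims[[j]] <- meta_pca(dists[[j]])
    } else {
      say("similarity map skipped for component ", k,
          ": needs at least two images")
      sims[j] <- list(NULL)
    }
  }
  names(histograms) <- names(bins) <- names(dists) <-
    names(stage_avgs) <- names(sims) <- paste0("comp", comps)

  run <- structure(list(manifest = manifest, background = background,
                        masks = masks, areas = area_table,
                        area_by_stage = area_by_stage, pca = pca,
                        histograms = histograms, bins = bins,
                        distributions = dists, stage_averages = stage_avgs,
                        similarity = sims, score_summary = score_summary,
                        config = config),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) write_run_outputs(run)
  run
}

.write_section_outputs <- function(msi, mask_pair, pca, comps, config, sid) {
  sdir <- file.path(config$out_dir, "sections", sid)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  write_msi_tiff(msi, file.path(sdir, paste0(sid, "_cube.tif")))
  write_png8(composite_rgb(msi), file.path(sdir, paste0(sid, "_composite.png")))
  write_mask_tiff(mask_pair$section, file.path(sdir, paste0(sid, "_section.tif")))
  write_mask_tiff(mask_pair$outer, file.path(sdir, paste0(sid, "_outer.tif")))
  for (k in comps) {
    sc <- project_scores(msi, mask_pair$section, pca, k)
    write_png8(score_to_8bit(sc, pca, config$spread),
               file.path(sdir, sprintf("%s_score%d.png", sid, k)))
  }
}

#' Write the run's tables and models to its output directory
#' @param run a `pipeline_run` whose config names an `out_dir`.
#' @return the output directory, invisibly.
#' @export
write_run_outputs <- function(run) {
  od <- run$config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$areas, file.path(od, "section_areas.csv"),
                   row.names = FALSE)
  utils::write.csv(run$area_by_stage, file.path(od, "area_by_stage.csv"),
                   row.names = FALSE)
  write_pca_json(run$pca, file.path(od, "pca_model.json"))
  utils::write.csv(distribution_table(run), file.path(od, "score_distributions.csv"),
                   row.names = FALSE)
  sim_rows <- list()
  for (nm in names(run$similarity)) {
    sm <- run$similarity[[nm]]
    if (is.null(sm)) next
    sim_rows[[nm]] <- data.frame(component = nm,
                                 section_id = run$manifest$section_id,
                                 stage = run$manifest$stage,
                                 axis1 = sm$coordinates[, 1],
                                 axis2 = if (ncol(sm$coordinates) > 1)
                                   sm$coordinates[, 2] else NA_real_)
  }
  if (length(sim_rows)) {
    utils::write.csv(do.call(rbind, sim_rows),
                     file.path(od, "similarity_map.csv"), row.names = FALSE)
  }
  manifest_info <- list(
    seed = attr(run$manifest, "seed"),
    noise_sd = attr(run$manifest, "noise_sd"),
    visible_gain = attr(run$manifest, "visible_gain"),
    n_sections = nrow(run$manifest),
    package_version = as.character(utils::packageVersion("grainspectra")),
    area_by_stage = run$area_by_stage)
  jsonlite::write_json(manifest_info, file.path(od, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(od)
}

#' Long-format table of all observed score distributions
#' @param run a `pipeline_run`.
#' @return data.frame: `section_id`, `stage`, `component`, `bin_index`,
#'   `lower_edge`, `upper_edge`, `frequency`.
#' @export
distribution_table <- function(run) {
  rows <- list()
  for (nm in names(run$distributions)) {
    b <- run$bins[[nm]]
    for (d in run$distributions[[nm]]) {
      nb <- length(d$frequencies)
      rows[[length(rows) + 1]] <- data.frame(
        section_id = d$image_id, stage = d$stage, component = d$component,
        bin_index = seq_len(nb),
        lower_edge = b$edges[seq_len(nb)],
        upper_edge = b$edges[seq_len(nb) + 1],
        frequency = d$frequencies)
    }
  }
  do.call(rbind, rows)
}

#' Read back a series manifest written by [generate_series()]
#' @param dir directory containing `manifest.csv`.
#' @return an `acquisition_manifest`.
#' @export
read_series_manifest <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  manifest$path <- file.path(dir, basename(manifest$path))
  attr(manifest, "noise_sd") <-
    if (!is.null(manifest$noise_sd)) manifest$noise_sd[1] else 3
  attr(manifest, "visible_gain") <-
    if (!is.null(manifest$visible_gain)) manifest$visible_gain[1] else 2
  class(manifest) <- c("acquisition_manifest", "data.frame")
  manifest
}
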