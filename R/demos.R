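#' Subsample a population into organ-specific event cohorts
#'
#' Emulates ex vivo organ analysis: each organ draws events from the
#' simulated population with class-specific weights, so organs can share
#' clones while differing in relative composition.
#'
#' @param population data frame from \code{\link{simulate_population}}.
#' @param organ_weights named list: per organ, a named numeric vector of
#'   sampling weights over color classes (classes absent from the vector get
#'   weight 0 for that organ; \code{"negative"} may be weighted too).
#' @param n_per_organ events drawn per organ (with replacement).
#' @param seed integer seed.
#' @return The sampled population rows with an \code{organ} column.
#' @export
sample_organs <- function(population, organ_weights, n_per_organ = 2000,
                          seed = 1L) {
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (organ in names(organ_weights)) {
      w <- organ_weights[[organ]]
      pw <- w[population$color_class]
      pw[is.na(pw)] <- 0
      if (sum(pw) <= 0)
        stop("organ '", organ, "' has zero total sampling weight")
      idx <- sample(nrow(population), n_per_organ, replace = TRUE, prob = pw)
      sub <- population[idx, , drop = FALSE]
      sub$organ <- organ
      out[[organ]] <- sub
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

#' End-to-end confocal demo: simulate, render, segment, classify, report
#'
#' Reproduces the imaging workflow on synthetic data: simulate genotypes,
#' render a multichannel field, run the detection pipeline, derive
#' thresholds from the measured cells, classify them, aggregate the clonal
#' composition, and score everything against the renderer's ground truth.
#' All intermediates are written to \code{out_dir}.
#'
#' @param out_dir artifact directory.
#' @param config a run config (see \code{\link{read_run_config}}).
#' @param seed global seed override.
#' @param plot also write the pseudo-color and composition images.
#' @return Invisibly, a list with the pipeline result, the evaluation
#'   (object F1, intensity error), the classification accuracy against
#'   ground truth, and the composition table.
#' @export
demo_confocal <- function(out_dir, config = read_run_config(), seed = NULL,
                          plot = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  # imaging demo defaults: a sorted, fully transduced population so most
  # cells are visible (as in cultured transduced material), imaged after
  # transient Cre-GFP expression has decayed — a uniform viral pedestal on
  # every cell would otherwise be absorbed into the adaptive green
  # threshold and mask nuclear nGFP
  if (is.null(config$recombination$transduction_efficiency))
    config$recombination$transduction_efficiency <- 1
  if (is.null(config$scene$viral_transient_level))
    config$scene$viral_transient_level <- 0
  p <- config_params(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pop <- simulate_population(p$scene$n_cells, p$recombination)
  write_population(pop, file.path(out_dir, "population.csv"))
  scene <- render_scene(p$scene, pop)
  write_stack(scene$stack, file.path(out_dir, "stack.tif"))
  write.csv(scene$truth$cells, file.path(out_dir, "ground_truth.csv"),
            row.names = FALSE)
  write_label_mask(scene$truth$label_mask,
                   file.path(out_dir, "truth_labels.tif"))

  res <- run_pipeline(scene$stack, p$segmentation)
  write.csv(res$cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  write_label_mask(res$labels, file.path(out_dir, "labels.tif"))
  jsonlite::write_json(res$qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  if (plot) write_pseudocolor(res$labels, file.path(out_dir, "pseudocolor.png"))

  eval <- evaluate_segmentation(res, scene$truth, p$scene)

  events <- res$cells
  names(events)[match(paste0("mean_", CHANNELS), names(events))] <- CHANNELS
  thr <- derive_thresholds(events)
  write_thresholds(thr, file.path(out_dir, "thresholds.json"))
  classified <- classify_table(events, thr)
  write.csv(classified, file.path(out_dir, "classified.csv"),
            row.names = FALSE)

  # accuracy on matched cells against the expected confocal class
  expected <- expected_confocal_class(scene$truth$cells, p$scene)
  m <- eval$matches
  pred <- classified$color_class[match(m$detected_label, classified$label)]
  accuracy <- if (nrow(m) > 0)
    mean(pred == expected[m$truth_label]) else NA_real_

  ct <- compose_classes(classified)
  write_report(ct, out_dir, qc = res$qc, plot = plot)
  log_msg("info", sprintf(
    "confocal demo: F1 %.3f, intensity relerr %.4f, accuracy %.3f",
    eval$f1, eval$mean_intensity_relerr, accuracy))
  invisible(list(pipeline = res, evaluation = eval, accuracy = accuracy,
                 composition = ct, truth = scene$truth))
}

#' End-to-end flow demo: simulate events per organ, classify, report
#'
#' Reproduces the ex vivo flow workflow: simulate a recombined population,
#' draw organ cohorts with organ-specific class weights, add measurement
#' noise, classify against data-derived thresholds, and report per-organ
#' clonal composition with pairwise overlap summaries.
#'
#' @param out_dir artifact directory.
#' @param config a run config.
#' @param organ_weights per-organ class sampling weights (default: four
#'   organs sharing clones with different relative distributions).
#' @param n_population population size to simulate.
#' @param n_per_organ events per organ.
#' @param seed global seed override.
#' @param plot write the composition PNG.
#' @return Invisibly, a list with the classified events, the composition
#'   table and pairwise \code{compare_groups} summaries.
#' @export
demo_flow <- function(out_dir, config = read_run_config(),
                      organ_weights = NULL, n_population = 20000,
                      n_per_organ = 2000, seed = NULL, plot = FALSE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  p <- config_params(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pop <- simulate_population(n_population, p$recombination)
  if (is.null(organ_weights)) {
    lv <- color_class_levels()
    organ_weights <- list(
      bone_marrow = setNames(rep(1, 11), c(lv, "negative")),
      spleen = setNames(c(seq(2, 0.5, length.out = 10), 1),
                        c(lv, "negative")),
      blood = setNames(c(seq(0.5, 2, length.out = 10), 1),
                       c(lv, "negative")),
      thymus = setNames(c(rep(2, 4), rep(0.3, 6), 1), c(lv, "negative"))
    )
  }
  cohort <- sample_organs(pop, organ_weights, n_per_organ,
                          seed = config$seed + 2L)
  cls_cfg <- p$classification
  ev <- simulate_events(
    cohort,
    signal = cls_cfg$signal %||% 1000,
    background = cls_cfg$background %||% 500,
    noise_sd = cls_cfg$noise_sd %||% 100,
    gfp_hi_level = cls_cfg$gfp_hi_level,
    seed = config$seed + 3L)
  ev$organ <- cohort$organ
  truth_class <- ev$color_class
  ev$color_class <- NULL; ev$gfp_hi <- NULL

  if (nrow(ev) == 0) {
    ct <- compose_classes(data.frame(organ = character(0),
                                     color_class = character(0)), "organ")
    write_report(ct, out_dir)
    return(invisible(list(classified = ev, composition = ct,
                          comparisons = list())))
  }
  thr <- derive_thresholds(ev, gfp_hi = isTRUE(cls_cfg$gfp_hi))
  write_thresholds(thr, file.path(out_dir, "thresholds.json"))
  classified <- classify_table(ev, thr)
  classified$true_class <- truth_class
  write.csv(classified, file.path(out_dir, "classified.csv"),
            row.names = FALSE)

  ct <- compose_classes(classified, "organ")
  organs <- ct$summary$organ
  comparisons <- list()
  if (length(organs) > 1) {
    for (i in seq_len(length(organs) - 1)) {
      for (j in (i + 1):length(organs)) {
        nm <- paste(organs[i], organs[j], sep = "_vs_")
        comparisons[[nm]] <- compare_groups(ct, organs[i], organs[j])
      }
    }
  }
  write_report(ct, out_dir, qc = list(comparisons = comparisons), plot = plot)
  acc <- mean(classified$color_class == truth_class)
  log_msg("info", sprintf("flow demo: %d organs, accuracy %.4f",
                          length(organs), acc))
  invisible(list(classified = classified, composition = ct,
                 comparisons = comparisons, accuracy = acc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
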