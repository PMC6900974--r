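#' Match detected objects to ground-truth cells and score recovery
#'
#' Matches each visible ground-truth cell (a cell with at least one
#' fluorescent signal; unlabeled cells are invisible to the detector) to at
#' most one detected object whose centroid lies within the cell radius,
#' greedily by distance. Reports object-level precision/recall/F1 and, on
#' matched cells, the per-channel relative error between the measured mean
#' intensity and the noise-free mean over the same segmented mask (the
#' geometry oracle), which isolates intensity quantification from boundary
#' placement (already scored by F1).
#'
#' @param result \code{\link{run_pipeline}} output (needs \code{labels} and
#'   \code{cells}).
#' @param truth ground truth from \code{\link{render_scene}}.
#' @param spec the \code{\link{scene_spec}} used to render the scene (for
#'   the noise-free reference rendering).
#' @return List with \code{n_truth_visible}, \code{tp}, \code{fp},
#'   \code{fn}, \code{precision}, \code{recall}, \code{f1},
#'   \code{matches} (data frame truth label vs detected label),
#'   \code{mean_intensity_relerr} (average over matched cells and signal
#'   channels) and \code{max_intensity_relerr}.
#' @export
evaluate_segmentation <- function(result, truth, spec) {
  cells <- truth$cells
  viral_glow <- (cells$viral_marker == "transient" &
                   spec$viral_transient_level > 0) |
    (cells$viral_marker == "integrated" & spec$viral_integrated_level > 0)
  visible <- which(cells$color_class != "negative" | viral_glow)
  det <- result$cells
  n_det <- nrow(det)
  matched_truth <- integer(0)
  matched_det <- integer(0)
  if (n_det > 0 && length(visible) > 0) {
    # greedy nearest-centroid matching within the truth radius
    d <- outer(cells$row[visible], det$centroid_row, "-")^2 +
      outer(cells$col[visible], det$centroid_col, "-")^2
    cand <- which(d <= matrix(cells$radius[visible]^2, length(visible),
                              n_det), arr.ind = TRUE)
    if (length(cand) > 0) {
      ord <- order(d[cand])
      cand <- cand[ord, , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        ti <- cand[k, 1]; di <- cand[k, 2]
        if (!(ti %in% matched_truth) && !(di %in% matched_det)) {
          matched_truth <- c(matched_truth, ti)
          matched_det <- c(matched_det, di)
        }
      }
    }
  }
  tp <- length(matched_truth)
  fp <- n_det - tp
  fn <- length(visible) - tp
  precision <- if (n_det > 0) tp / n_det else NA_real_
  recall <- if (length(visible) > 0) tp / length(visible) else NA_real_
  f1 <- if (tp > 0) 2 * precision * recall / (precision + recall) else 0

  relerr <- numeric(0)
  if (tp > 0) {
    ref <- render_from_truth(truth, spec)$channels
    for (k in seq_len(tp)) {
      lab <- det$label[matched_det[k]]
      sel <- result$labels == lab
      for (cn in CHANNELS) {
        truth_mean <- mean(ref[[cn]][sel])
        if (truth_mean > spec$background_level + 1e-9) {
          meas <- det[[paste0("mean_", cn)]][matched_det[k]]
          relerr <- c(relerr, abs(meas - truth_mean) / truth_mean)
        }
      }
    }
  }
  list(n_truth_visible = length(visible), tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1,
       matches = data.frame(truth_label = cells$label[visible[matched_truth]],
                            detected_label = det$label[matched_det]),
       mean_intensity_relerr = if (length(relerr)) mean(relerr) else NA_real_,
       max_intensity_relerr = if (length(relerr)) max(relerr) else NA_real_)
}

#' Expected confocal class of a ground-truth cell
#'
#' In confocal images cassette nGFP and viral Cre-GFP share the green
#' channel, so a visible viral marker makes the green channel positive. The
#' expected classifier output is the class of positive channels, or
#' \code{"unresolved"} when three channels are positive (the classifier's
#' purity rule).
#'
#' @param truth_cells the \code{cells} data frame of a rendered scene.
#' @param spec the \code{\link{scene_spec}} (to know whether transient viral
#'   green is visible).
#' @return Character vector of expected class names.
#' @export
expected_confocal_class <- function(truth_cells, spec) {
  vapply(seq_len(nrow(truth_cells)), function(i) {
    colors <- class_colors(truth_cells$color_class[i])
    vm <- truth_cells$viral_marker[i]
    viral_visible <- (vm == "transient" && spec$viral_transient_level > 0) ||
      (vm == "integrated" && spec$viral_integrated_level > 0)
    channels <- unique(c(COLOR_CHANNEL[colors],
                         if (viral_visible) "GREEN"))
    if (length(channels) > 2) "unresolved"
    else color_class_name(CHANNEL_COLOR[channels])
  }, "")
}
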