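#' Segmentation pipeline configuration
#'
#' Parameters of the automated cell-detection pipeline: per-channel contrast
#' stretch and smoothing, composite merge, background-peak thresholding,
#' erosion-based separation with constrained expansion, and object filters.
#'
#' @param stretch_low,stretch_high percentiles mapped to 0 and 1 by the
#'   contrast stretch (defaults 1 and 99). Note the upper anchor lands in
#'   the background noise tail for a channel whose foreground covers less
#'   than 1\% of the field (sparse nuclear or membrane structures), which
#'   amplifies that channel's noise in the composite; raising
#'   \code{stretch_high} helps such channels but widens the smoothing halo
#'   around objects, which in turn hampers the separation of touching cells.
#' @param smooth_sigma Gaussian smoothing sigma in px ("slightly smoothed";
#'   default 1; 0 disables smoothing).
#' @param merge composite operator over the four stretched channels:
#'   \code{"max"} (default; preserves single-channel cells at full contrast)
#'   or \code{"sum"} (clipped at 1).
#' @param threshold_offset_k threshold = background mode + k x robust
#'   background spread ("just above the background peak"; default 3).
#' @param erosion_cycles erosion repetitions with a 3x3 box element used to
#'   disconnect touching cells. The default of 5 suits cells of radius 8-12
#'   px with 1-2 px overlaps: their binary necks are ~8-12 px wide, which 3
#'   cycles cannot disconnect, while nuclear seeds (>= 4 px radius) still
#'   survive 5 cycles.
#' @param connectivity pixel connectivity for component labeling, 4 or 8
#'   (default 8); expansion fronts always advance 4-connected.
#' @param min_object_px objects smaller than this are discarded as debris
#'   (default 30).
#' @param exclude_border drop objects touching the image border (default
#'   TRUE).
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(stretch_low = 1, stretch_high = 99,
                            smooth_sigma = 1,
                            merge = c("max", "sum"),
                            threshold_offset_k = 3,
                            erosion_cycles = 5,
                            connectivity = 8,
                            min_object_px = 30,
                            exclude_border = TRUE) {
  merge <- match.arg(merge)
  if (stretch_low < 0 || stretch_high > 100 || stretch_low >= stretch_high)
    stop("need 0 <= stretch_low < stretch_high <= 100")
  if (erosion_cycles < 1) stop("erosion_cycles must be >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (min_object_px < 1) stop("min_object_px must be >= 1")
  structure(
    list(stretch_low = stretch_low, stretch_high = stretch_high,
         smooth_sigma = smooth_sigma, merge = merge,
         threshold_offset_k = threshold_offset_k,
         erosion_cycles = as.integer(erosion_cycles),
         connectivity = as.integer(connectivity),
         min_object_px = as.integer(min_object_px),
         exclude_border = isTRUE(exclude_border)),
    class = "pipeline_config"
  )
}

#' Contrast-stretch and smooth one channel
#'
#' Linear rescale mapping the \code{stretch_low}/\code{stretch_high}
#' percentiles to 0/1 with clipping, followed by Gaussian smoothing.
#' A constant image maps to all zeros (degenerate contract, no error).
#'
#' @param channel 2D numeric matrix.
#' @param cfg a \code{\link{pipeline_config}}.
#' @return Matrix with values in [0, 1].
#' @export
stretch_and_smooth <- function(channel, cfg = pipeline_config()) {
  if (length(channel) == 0) stop("empty image")
  q <- quantile(channel, c(cfg$stretch_low, cfg$stretch_high) / 100,
                names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(channel), ncol(channel)))
  y <- pmin(pmax((channel - q[1]) / (q[2] - q[1]), 0), 1)
  if (cfg$smooth_sigma > 0) {
    y <- EBImage::gblur(y, sigma = cfg$smooth_sigma, boundary = "replicate")
    y <- pmin(pmax(y, 0), 1)
  }
  matrix(y, nrow(channel), ncol(channel))
}

#' Merge stretched channels into a composite gray-value image
#'
#' Pixelwise maximum (default) or clipped sum over the four stretched XFP
#' channels. The composite is monotone: increasing any input pixel never
#' decreases the composite.
#'
#' @param stack list of four stretched channel matrices in [0, 1].
#' @param merge \code{"max"} or \code{"sum"}.
#' @return 2D matrix in [0, 1].
#' @export
composite_image <- function(stack, merge = c("max", "sum")) {
  merge <- match.arg(merge)
  dims <- vapply(stack, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1) stop("channel shapes differ")
  if (merge == "max") Reduce(pmax, stack)
  else pmin(Reduce(`+`, stack), 1)
}

#' Threshold just above the background peak
#'
#' Locates the background mode on a 256-bin histogram of the composite and
#' returns mode + k x robust background spread, where the spread is the RMS
#' deviation of the sub-mode half of the distribution reflected about the
#' mode. With two well-separated modes the result lies strictly between
#' them; \code{k = 0} returns the mode itself.
#'
#' @param gray composite matrix (>= 2 distinct values).
#' @param cfg a \code{\link{pipeline_config}} supplying
#'   \code{threshold_offset_k}.
#' @return Scalar threshold.
#' @export
background_threshold <- function(gray, cfg = pipeline_config()) {
  v <- as.numeric(gray)
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant image: no background peak separable")
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = 256)
  mode_bin <- which.max(h)
  mode_val <- (breaks[mode_bin] + breaks[mode_bin + 1]) / 2
  below <- v[v <= mode_val]
  spread <- if (length(below) == 0) 0 else
    sqrt(mean((mode_val - below)^2))
  # floor at one bin width so a clipped-to-zero background still yields a
  # strictly positive offset
  spread <- max(spread, diff(breaks[1:2]))
  mode_val + cfg$threshold_offset_k * spread
}

# n cycles of 3x3 box binary erosion (EBImage)
erode_mask <- function(mask, cycles) {
  brush <- EBImage::makeBrush(3, shape = "box")
  m <- mask
  for (i in seq_len(cycles)) m <- EBImage::erode(m, brush)
  m
}

#' Separate touching cells by erosion and constrained expansion
#'
#' Erodes the binary mask \code{erosion_cycles} times to disconnect touching
#' cells, labels the surviving components, then regrows every label by
#' geodesic dilation constrained to the original mask: all fronts advance one
#' pixel per iteration until nothing changes, contested pixels go to the
#' lowest label, and labels never merge. Mask pixels unreachable from any
#' eroded seed stay background; objects erased by the erosion yield no label.
#'
#' @param binary logical or 0/1 matrix.
#' @param cfg a \code{\link{pipeline_config}}.
#' @return Integer label matrix (consecutive labels from 1).
#' @export
separate_and_label <- function(binary, cfg = pipeline_config()) {
  mask <- matrix(as.integer(binary != 0), nrow(binary), ncol(binary))
  if (sum(mask) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  eroded <- erode_mask(mask, cfg$erosion_cycles)
  eroded <- matrix(as.integer(eroded != 0), nrow(mask), ncol(mask))
  seeds <- label_components_cpp(eroded, cfg$connectivity)
  # expansion fronts advance 4-connected for clean, deterministic boundaries
  geodesic_expand_cpp(seeds, mask, 4L)
}

#' Remove small and border-touching objects
#'
#' Drops every object with area below \code{min_object_px} (cell debris,
#' dead cells) and, when \code{exclude_border}, every object with a pixel on
#' the image border. Survivors are relabeled consecutively preserving
#' relative order.
#'
#' @param labels integer label matrix.
#' @param cfg a \code{\link{pipeline_config}}.
#' @return Filtered, consecutively relabeled matrix.
#' @export
filter_objects <- function(labels, cfg = pipeline_config()) {
  if (max(labels) == 0) return(labels)
  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- areas >= cfg$min_object_px
  if (cfg$exclude_border) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    keep[border[border > 0]] <- FALSE
  }
  keep[areas == 0] <- FALSE
  remap <- integer(max(labels))
  remap[which(keep)] <- seq_len(sum(keep))
  out <- labels
  out[labels > 0] <- remap[labels[labels > 0]]
  out
}

#' Measure per-cell intensities
#'
#' For every label: area, centroid (0-based row/col) and the per-channel
#' mean of the ORIGINAL (unstretched) intensities, plus relative channel
#' contributions: channel mean minus the estimated channel background
#' (median of non-object pixels), floored at 0 and normalized to sum 1
#' (all-zero when nothing exceeds background).
#'
#' @param labels integer label matrix.
#' @param stack the original \code{\link{channel_stack}}.
#' @return Data frame with one row per label: \code{label}, \code{area},
#'   \code{centroid_row}, \code{centroid_col}, \code{mean_<CH>} and
#'   \code{rel_<CH>} for each channel.
#' @export
measure_cells <- function(labels, stack) {
  if (!all(dim(labels) == dim(stack$CFP)))
    stop("label image and stack dimensions differ")
  n <- max(labels)
  cols <- c("label", "area", "centroid_row", "centroid_col",
            paste0("mean_", CHANNELS), paste0("rel_", CHANNELS))
  if (n == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  bg <- vapply(CHANNELS, function(cn) median(stack[[cn]][labels == 0]), 0)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- (idx - 1) %% nrow(labels)       # 0-based
  colsix <- (idx - 1) %/% nrow(labels)
  area <- tabulate(lab, nbins = n)
  f <- factor(lab, levels = seq_len(n))  # keep numeric label order
  cr <- tapply(rows, f, mean)
  cc <- tapply(colsix, f, mean)
  means <- vapply(CHANNELS, function(cn)
    as.numeric(tapply(stack[[cn]][idx], f, mean)), numeric(n))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1,
                                           dimnames = list(NULL, CHANNELS))
  excess <- sweep(means, 2, bg)
  excess[excess < 0] <- 0
  tot <- rowSums(excess)
  rel <- excess / ifelse(tot > 0, tot, 1)
  rel[tot == 0, ] <- 0
  out <- data.frame(label = seq_len(n), area = area,
                    centroid_row = as.numeric(cr),
                    centroid_col = as.numeric(cc))
  for (i in seq_along(CHANNELS)) out[[paste0("mean_", CHANNELS[i])]] <- means[, i]
  for (i in seq_along(CHANNELS)) out[[paste0("rel_", CHANNELS[i])]] <- rel[, i]
  out
}

#' Run the full detection pipeline
#'
#' Chains stretch/smooth, composite merge, background-peak thresholding,
#' erosion + constrained expansion, object filtering, and per-cell
#' measurement. Deterministic: identical inputs give identical outputs.
#'
#' @param stack a \code{\link{channel_stack}} of original intensities.
#' @param cfg a \code{\link{pipeline_config}}.
#' @return List with \code{labels} (filtered label image), \code{cells}
#'   (measurement data frame) and \code{qc} (threshold, object counts per
#'   stage, effective parameters).
#' @export
run_pipeline <- function(stack, cfg = pipeline_config()) {
  stretched <- lapply(unclass(stack), stretch_and_smooth, cfg = cfg)
  comp <- composite_image(stretched, merge = cfg$merge)
  thr <- background_threshold(comp, cfg)
  binary <- comp > thr
  labels0 <- separate_and_label(binary, cfg)
  labels <- filter_objects(labels0, cfg)
  cells <- measure_cells(labels, stack)
  qc <- list(threshold = thr,
             n_mask_px = sum(binary),
             n_objects_separated = max(labels0),
             n_objects_final = max(labels),
             config = unclass(cfg))
  list(labels = labels, cells = cells, qc = qc)
}
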