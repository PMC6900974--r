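#' Write / read a multichannel stack as TIFF
#'
#' The primary dialect is a single multi-page 16-bit TIFF with pages in the
#' fixed channel order CFP, GREEN, YFP, RED; the channel order is also
#' recorded in a JSON sidecar (\code{<path>.json}). The per-channel dialect
#' writes one single-page TIFF per channel. Reading inverts writing exactly:
#' \code{read_stack(write_stack(x))} reproduces the pixel values bit for bit
#' (intensities are clipped to the 16-bit range on write).
#'
#' @param stack a \code{\link{channel_stack}}.
#' @param path output path for the multi-page dialect, or (for
#'   \code{dialect = "per-channel"}) a path template whose channel files are
#'   \code{<stem>_<CHANNEL>.tif}.
#' @param dialect \code{"multipage"} (default) or \code{"per-channel"}.
#' @return \code{write_stack} invisibly returns the written path(s);
#'   \code{read_stack} returns a \code{channel_stack}.
#' @export
write_stack <- function(stack, path, dialect = c("multipage", "per-channel")) {
  dialect <- match.arg(dialect)
  if (!inherits(stack, "channel_stack")) stop("not a channel_stack")
  norm <- lapply(stack, function(m) pmin(pmax(m, 0), DTYPE_MAX) / DTYPE_MAX)
  if (dialect == "multipage") {
    tiff::writeTIFF(unclass(norm), path, bits.per.sample = 16)
    jsonlite::write_json(list(channels = names(stack)),
                         paste0(path, ".json"), auto_unbox = FALSE)
    invisible(path)
  } else {
    stem <- sub("\\.tiff?$", "", path)
    paths <- paste0(stem, "_", names(stack), ".tif")
    for (i in seq_along(paths))
      tiff::writeTIFF(norm[[i]], paths[i], bits.per.sample = 16)
    invisible(paths)
  }
}

#' @rdname write_stack
#' @param paths one multi-page TIFF path, or a character vector of four
#'   per-channel TIFF paths named or suffixed by channel id.
#' @export
read_stack <- function(paths) {
  if (length(paths) == 1) {
    pages <- tiff::readTIFF(paths, all = TRUE)
    if (length(pages) != length(CHANNELS))
      stop("expected ", length(CHANNELS), "-page TIFF, found ",
           length(pages), " page(s)")
    order <- CHANNELS
    sidecar <- paste0(paths, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      if (!setequal(meta$channels, CHANNELS))
        stop("sidecar channel metadata does not name the four channels")
      order <- meta$channels
    }
    ch <- setNames(lapply(pages, function(p) round(p * DTYPE_MAX)), order)
  } else {
    if (length(paths) != length(CHANNELS))
      stop("per-channel dialect needs exactly ", length(CHANNELS), " files")
    ids <- names(paths)
    if (is.null(ids) || any(!nzchar(ids))) {
      ids <- vapply(CHANNELS, function(cn)
        paths[grepl(paste0("_", cn, "\\.tiff?$"), paths)][1], "")
      if (any(is.na(ids))) stop("cannot infer channel ids from file names")
      paths <- ids
      ids <- CHANNELS
      names(paths) <- ids
    }
    if (!setequal(ids, CHANNELS))
      stop("per-channel paths must cover channels: ",
           paste(CHANNELS, collapse = ", "))
    ch <- lapply(paths[CHANNELS], function(p)
      round(tiff::readTIFF(p) * DTYPE_MAX))
  }
  channel_stack(ch$CFP, ch$GREEN, ch$YFP, ch$RED)
}

#' Write / read an integer label mask as 16-bit TIFF
#'
#' @param labels integer matrix (0 = background); labels must be < 65536.
#' @param path file path.
#' @export
write_label_mask <- function(labels, path) {
  if (max(labels) >= DTYPE_MAX) stop("too many labels for 16-bit storage")
  tiff::writeTIFF(labels / DTYPE_MAX, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- round(tiff::readTIFF(path) * DTYPE_MAX)
  storage.mode(m) <- "integer"
  m
}

#' Pseudo-color rendering of a label image
#'
#' Assigns each label a distinct deterministic color (background black) and
#' writes a PNG, emulating the pseudo-colored review image of the original
#' workflow.
#'
#' @param labels integer label matrix.
#' @param path PNG output path.
#' @return Invisibly, the RGB array written.
#' @export
write_pseudocolor <- function(labels, path) {
  n <- max(labels)
  # fixed golden-angle hue walk: distinct, deterministic, label-stable
  hues <- (0.618033988749895 * seq_len(max(n, 1))) %% 1
  cols <- grDevices::hsv(hues, s = 0.85, v = 1)
  rgbm <- grDevices::col2rgb(cols) / 255
  arr <- array(0, c(nrow(labels), ncol(labels), 3))
  for (k in seq_len(n)) {
    sel <- labels == k
    for (d in 1:3) {
      plane <- arr[, , d]
      plane[sel] <- rgbm[d, k]
      arr[, , d] <- plane
    }
  }
  png::writePNG(arr, path)
  invisible(arr)
}
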