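#' Derive per-channel positivity thresholds from measured intensities
#'
#' Formalizes visual threshold reading as valley detection on a log-like
#' (log1p) scale: per channel the events are sorted and the lowest clear
#' gap — an empty log-intensity interval at least \code{clear_gap_width}
#' wide (0.5, about a 1.6-fold intensity jump) with at least a fraction
#' \code{min_side_frac} of the events on each side — becomes the cutoff
#' (its midpoint, mapped back to the original scale). Taking the lowest
#' clear valley rather than the widest keeps the cutoff just above the
#' negative population even when a brighter GFP-hi tier creates a second,
#' wider gap higher up. When no clear valley exists — membrane signal in
#' particular tends to lack a crisp threshold — the method falls back to
#' the two-class variance-minimizing (Otsu-style) split on the log scale;
#' the method used is recorded per channel.
#'
#' Optionally a second, higher cutoff on the green channel separates GFP-hi
#' events (stably integrated Cre-GFP provirus) from cassette nGFP; it is
#' disabled by default because the GFP-hi population is not always present.
#'
#' @param events data frame with intensity columns \code{CFP}, \code{GREEN},
#'   \code{YFP}, \code{RED} (>= 20 rows).
#' @param gfp_hi logical; also derive a GFP-hi cutoff on the green channel.
#' @param min_side_frac minimum fraction of events required on each side of
#'   a candidate gap (a fraction, not a count, so thresholds are invariant
#'   to duplicating the whole table; it also sets the smallest GFP-hi tier
#'   that can be resolved).
#' @param clear_gap_width a gap counts as a clear valley when it is at
#'   least this wide on the log1p scale (0.5 corresponds to roughly a
#'   1.6-fold intensity ratio between the populations it separates).
#' @return Object of class \code{channel_thresholds}: per-channel
#'   \code{cutoff}, \code{method} ("gap" or "variance"), and optional
#'   \code{gfp_hi_cutoff}.
#' @export
derive_thresholds <- function(events, gfp_hi = FALSE, min_side_frac = 0.05,
                              clear_gap_width = 0.5) {
  check_event_table(events)
  if (nrow(events) < 20) stop("need at least 20 events, got ", nrow(events))
  cutoff <- setNames(numeric(length(CHANNELS)), CHANNELS)
  method <- setNames(character(length(CHANNELS)), CHANNELS)
  for (cn in CHANNELS) {
    sp <- split_channel(events[[cn]], min_side_frac, clear_gap_width)
    if (is.null(sp)) stop("channel ", cn, " has no intensity variation")
    cutoff[cn] <- sp$cutoff
    method[cn] <- sp$method
  }
  ghc <- NA_real_
  if (gfp_hi) {
    pos <- events$GREEN[events$GREEN > cutoff["GREEN"]]
    if (length(pos) >= 10) {
      sp <- split_channel(pos, min_side_frac, clear_gap_width)
      # only accept a clear valley: without a distinct GFP-hi population the
      # cutoff stays unset
      if (!is.null(sp) && sp$method == "gap") ghc <- sp$cutoff
    }
    if (!is.na(ghc) && ghc <= cutoff["GREEN"]) ghc <- NA_real_
  }
  structure(list(cutoff = cutoff, method = method, gfp_hi_cutoff = ghc),
            class = "channel_thresholds")
}

# split one channel's intensities into negative/positive; returns NULL for
# constant data
split_channel <- function(x, min_side_frac, clear_gap_width) {
  v <- sort(log1p(x))
  n <- length(v)
  if (v[n] - v[1] == 0) return(NULL)
  lo <- max(ceiling(min_side_frac * n), 1)
  cand <- lo:(n - lo)                      # split after index k
  gaps <- v[cand + 1] - v[cand]
  clear <- which(gaps >= clear_gap_width)
  if (length(clear) > 0) {
    # lowest clear valley: the boundary just above the negative population
    # (the widest gap could instead separate positives from a GFP-hi tier)
    k <- cand[clear[1]]
    return(list(cutoff = expm1((v[k] + v[k + 1]) / 2), method = "gap"))
  }
  # fallback: exhaustive two-class variance-minimizing split on the log scale
  css <- cumsum(v); css2 <- cumsum(v^2)
  within <- vapply(cand, function(k) {
    s1 <- css[k]; s2 <- css2[k]
    w1 <- s2 - s1^2 / k
    w2 <- (css2[n] - s2) - (css[n] - s1)^2 / (n - k)
    w1 + w2
  }, 0)
  k <- cand[which.min(within)]
  list(cutoff = expm1((v[k] + v[k + 1]) / 2), method = "variance")
}

check_event_table <- function(events) {
  miss <- setdiff(CHANNELS, names(events))
  if (length(miss) > 0)
    stop("event table lacks channel column(s): ", paste(miss, collapse = ", "))
  for (cn in CHANNELS)
    if (any(events[[cn]] < 0)) stop("negative intensities in channel ", cn)
  invisible(TRUE)
}

#' Classify one event into a Confetti color class
#'
#' A channel is positive when its intensity exceeds the cutoff; the class is
#' the set of positive XFP channels. Mirroring exclusion gating, an event
#' positive in more than two XFP channels is assigned the explicit
#' \code{"unresolved"} category rather than forced into a class. When a
#' GFP-hi cutoff is set and the green intensity exceeds it, the green signal
#' is attributed to the viral marker (not nGFP) and the event is flagged
#' \code{gfp_hi}.
#'
#' @param event named numeric vector or one-row data frame with the four
#'   channel intensities.
#' @param thresholds a \code{\link{derive_thresholds}} result.
#' @return List with \code{class} (class name, \code{"negative"} or
#'   \code{"unresolved"}) and \code{gfp_hi} (logical).
#' @export
classify_event <- function(event, thresholds) {
  if (is.data.frame(event)) event <- unlist(event[1, CHANNELS])
  miss <- setdiff(CHANNELS, names(event))
  if (length(miss) > 0)
    stop("event lacks channel(s): ", paste(miss, collapse = ", "))
  pos <- vapply(CHANNELS, function(cn)
    event[[cn]] > thresholds$cutoff[[cn]], NA)
  hi <- FALSE
  ghc <- thresholds$gfp_hi_cutoff
  if (!is.null(ghc) && !is.na(ghc) && event[["GREEN"]] > ghc) {
    hi <- TRUE
    pos["GREEN"] <- FALSE  # green now attributed to viral GFP, not nGFP
  }
  colors <- CHANNEL_COLOR[CHANNELS[pos]]
  cls <- if (length(colors) > 2) "unresolved" else color_class_name(colors)
  list(class = cls, gfp_hi = hi)
}

#' Classify a whole event table
#'
#' Row-wise application of \code{\link{classify_event}}; metadata columns are
#' preserved and \code{color_class} / \code{gfp_hi} columns appended.
#'
#' @param events event data frame.
#' @param thresholds a \code{\link{derive_thresholds}} result.
#' @return The input with \code{color_class} and \code{gfp_hi} columns.
#' @export
classify_table <- function(events, thresholds) {
  if (nrow(events) == 0) {
    events$color_class <- character(0)
    events$gfp_hi <- logical(0)
    return(events)
  }
  check_event_table(events)
  cut <- thresholds$cutoff
  pos <- vapply(CHANNELS, function(cn) events[[cn]] > cut[[cn]],
                logical(nrow(events)))
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1,
                                       dimnames = list(NULL, CHANNELS))
  hi <- rep(FALSE, nrow(events))
  ghc <- thresholds$gfp_hi_cutoff
  if (!is.null(ghc) && !is.na(ghc)) {
    hi <- events$GREEN > ghc
    pos[hi, "GREEN"] <- FALSE
  }
  cls <- apply(pos, 1, function(p) {
    colors <- CHANNEL_COLOR[CHANNELS[p]]
    if (length(colors) > 2) "unresolved" else color_class_name(colors)
  })
  events$color_class <- cls
  events$gfp_hi <- hi
  events
}

#' Simulate per-event channel intensities from genotypes
#'
#' Builds a flow-style event table: each expressed fluorophore adds
#' \code{signal} to its detection channel over \code{background}, with
#' optional Gaussian measurement noise (clipped at 0). By default the viral
#' marker contributes nothing — transient Cre-GFP expression is lost within
#' days — but setting \code{gfp_hi_level} adds bright green to cells with an
#' integrated provirus, reproducing the GFP-hi population.
#'
#' @param genotypes population data frame (from
#'   \code{\link{simulate_population}}).
#' @param signal,background intensity levels.
#' @param noise_sd Gaussian noise SD (the signal-to-noise ratio is
#'   \code{signal / noise_sd}).
#' @param gfp_hi_level optional green intensity of integrated-provirus
#'   events.
#' @param seed integer seed for the noise generator.
#' @return Event data frame with \code{cell_id}, the four channel columns
#'   and the generating \code{color_class} / \code{gfp_hi} annotations.
#' @export
simulate_events <- function(genotypes, signal = 1000, background = 500,
                            noise_sd = 0, gfp_hi_level = NULL, seed = 1L) {
  n <- nrow(genotypes)
  ev <- data.frame(cell_id = genotypes$cell_id)
  member <- lapply(strsplit(genotypes$color_class, "+", fixed = TRUE),
                   intersect, x = XFP_NAMES)
  for (cn in CHANNELS) ev[[cn]] <- rep(background, n)
  for (col in XFP_NAMES) {
    has <- vapply(member, function(m) col %in% m, NA)
    cn <- COLOR_CHANNEL[[col]]
    ev[[cn]] <- ev[[cn]] + signal * has
  }
  if (!is.null(gfp_hi_level))
    ev$GREEN <- ev$GREEN +
      gfp_hi_level * (genotypes$viral_marker == "integrated")
  if (noise_sd > 0) {
    ev[CHANNELS] <- withr::with_seed(as.integer(seed), {
      ev[CHANNELS] + matrix(rnorm(4 * n, 0, noise_sd), n, 4)
    })
    ev[CHANNELS] <- lapply(ev[CHANNELS], pmax, 0)
  }
  ev$color_class <- genotypes$color_class
  ev$gfp_hi <- genotypes$gfp_hi
  ev
}

#' Write thresholds to JSON
#' @param thresholds a \code{channel_thresholds} object.
#' @param path output path.
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(
    list(cutoff = as.list(thresholds$cutoff),
         method = as.list(thresholds$method),
         gfp_hi_cutoff = thresholds$gfp_hi_cutoff),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
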