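DTYPE_MAX <- 65535  # 16-bit unsigned export range

#' Multichannel image stack
#'
#' Bundles co-registered 2D intensity images, one per detection channel, in
#' the fixed order CFP, GREEN, YFP, RED.
#'
#' @param cfp,green,yfp,red numeric matrices of identical dimensions with
#'   non-negative intensities.
#' @return An object of class \code{channel_stack}: a named list of matrices.
#' @export
channel_stack <- function(cfp, green, yfp, red) {
  ch <- list(CFP = cfp, GREEN = green, YFP = yfp, RED = red)
  dims <- lapply(ch, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("all channels must share identical dimensions")
  if (any(vapply(ch, function(m) any(m < 0), logical(1))))
    stop("intensities must be non-negative")
  structure(ch, class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$CFP)
  cat("channel_stack:", d[1], "x", d[2], "px, channels",
      paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Specification of a synthetic confocal field
#'
#' Describes a 2D field of round suspension cells. Geometry is in pixels
#' (no physical pixel size is assumed); intensities are in arbitrary
#' detector units on a 16-bit scale.
#'
#' @param field_size integer (rows, cols) of the field.
#' @param n_cells number of cells to place.
#' @param radius_range (min, max) cell radius in px; radii must be >= 3.
#' @param touching_pair_fraction fraction of cells placed as touching pairs
#'   (centers closer than the radius sum).
#' @param debris_count number of 1-4 px bright debris specks.
#' @param background_level additive background intensity per channel.
#' @param noise_sd Gaussian noise standard deviation.
#' @param signal_level fluorophore signal intensity above background.
#' @param viral_transient_level green-channel intensity added over the whole
#'   cell body by a transient Cre-GFP provirus.
#' @param viral_integrated_level green-channel intensity for an integrated
#'   (GFP-hi) provirus; higher than the transient level.
#' @param margin_px minimum gap between non-touching cells.
#' @param seed integer seed; rendering is deterministic given the seed.
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(field_size = c(512, 512),
                       n_cells = 50,
                       radius_range = c(8, 12),
                       touching_pair_fraction = 0.2,
                       debris_count = 10,
                       background_level = 1000,
                       noise_sd = 800,
                       signal_level = 10000,
                       viral_transient_level = 3000,
                       viral_integrated_level = 25000,
                       margin_px = 6,
                       seed = 1L) {
  if (length(field_size) != 2 || any(field_size < 16))
    stop("field_size must be two dimensions >= 16 px")
  if (any(radius_range < 3)) stop("cell radii must be >= 3 px")
  if (radius_range[1] > radius_range[2]) stop("radius_range must be ordered")
  if (touching_pair_fraction < 0 || touching_pair_fraction > 1)
    stop("touching_pair_fraction must lie in [0, 1]")
  lv <- c(background_level, noise_sd, signal_level,
          viral_transient_level, viral_integrated_level)
  if (any(lv < 0)) stop("intensities must be non-negative")
  if (2 * max(radius_range) + 4 > min(field_size))
    stop("field too small for the requested cell radii")
  structure(
    list(field_size = as.integer(field_size), n_cells = as.integer(n_cells),
         radius_range = radius_range,
         touching_pair_fraction = touching_pair_fraction,
         debris_count = as.integer(debris_count),
         background_level = background_level, noise_sd = noise_sd,
         signal_level = signal_level,
         viral_transient_level = viral_transient_level,
         viral_integrated_level = viral_integrated_level,
         margin_px = margin_px, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# place cells (touching pairs first, then singletons) by rejection sampling;
# returns data.frame(row, col, radius) in 1-based pixel coordinates
place_cells <- function(spec) {
  nr <- spec$field_size[1]; nc <- spec$field_size[2]
  n <- spec$n_cells
  n_pairs <- floor(n * spec$touching_pair_fraction / 2)
  rows <- cols <- radii <- numeric(0)
  partner_of <- integer(0)  # 0 = free-standing, else index of pair mate
  rmin <- spec$radius_range[1]; rmax <- spec$radius_range[2]

  fits <- function(r0, c0, rad, ignore = integer(0)) {
    if (r0 - rad < 2 || r0 + rad > nr - 1 || c0 - rad < 2 || c0 + rad > nc - 1)
      return(FALSE)
    if (length(rows) == 0) return(TRUE)
    keep <- setdiff(seq_along(rows), ignore)
    if (length(keep) == 0) return(TRUE)
    d2 <- (rows[keep] - r0)^2 + (cols[keep] - c0)^2
    all(d2 > (radii[keep] + rad + spec$margin_px)^2)
  }
  draw_radius <- function() runif(1, rmin, rmax)

  add_cell <- function(idx, paired_with = NULL) {
    for (try in seq_len(500)) {
      rad <- draw_radius()
      if (is.null(paired_with)) {
        r0 <- runif(1, rad + 2, nr - rad - 1)
        c0 <- runif(1, rad + 2, nc - rad - 1)
        ok <- fits(r0, c0, rad)
      } else {
        # touching mate: centers closer than the radius sum (1-2 px overlap)
        d <- radii[paired_with] + rad - runif(1, 1, 2)
        th <- runif(1, 0, 2 * pi)
        r0 <- rows[paired_with] + d * sin(th)
        c0 <- cols[paired_with] + d * cos(th)
        ok <- fits(r0, c0, rad, ignore = paired_with)
      }
      if (ok) {
        rows[idx] <<- r0; cols[idx] <<- c0; radii[idx] <<- rad
        partner_of[idx] <<- if (is.null(paired_with)) 0L else paired_with
        return(invisible(NULL))
      }
    }
    stop("field overcrowded: could not place cell ", idx,
         " after 500 attempts")
  }

  i <- 1L
  for (p in seq_len(n_pairs)) {
    add_cell(i); add_cell(i + 1L, paired_with = i)
    partner_of[i] <- i + 1L
    i <- i + 2L
  }
  while (i <= n) { add_cell(i); i <- i + 1L }
  data.frame(row = rows, col = cols, radius = radii,
             partner = partner_of)[seq_len(max(n, 0)), , drop = FALSE]
}

# squared distance of every pixel to a center (1-based grid)
pixel_dist2 <- function(nr, nc, r0, c0) {
  outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, "+")
}

# deterministic noise-free rendering from ground truth geometry + genotypes;
# also builds the label mask (cells 1..n, debris n+1..n+d)
render_from_truth <- function(truth, spec) {
  nr <- spec$field_size[1]; nc <- spec$field_size[2]
  ch <- setNames(lapply(CHANNELS, function(x) matrix(0, nr, nc)), CHANNELS)
  cells <- truth$cells
  n <- nrow(cells)
  label_mask <- matrix(0L, nr, nc)
  # distance-normalized ownership resolves overlap pixels of touching pairs
  owner_score <- matrix(Inf, nr, nc)

  for (i in seq_len(n)) {
    d2 <- pixel_dist2(nr, nc, cells$row[i] + 1, cells$col[i] + 1)
    rad <- cells$radius[i]
    disk <- d2 <= rad^2
    score <- sqrt(d2) / rad
    claim <- disk & (score < owner_score)
    owner_score[claim] <- score[claim]
    label_mask[claim] <- i

    nucleus <- d2 <= (rad / 2)^2
    membrane <- disk & (d2 > (rad - 2)^2)
    for (col in class_colors(cells$color_class[i])) {
      compartment <- switch(xfp_colors()$localization[match(col, XFP_NAMES)],
                            nuclear = nucleus,
                            cytoplasmic = disk,
                            membrane = membrane)
      cn <- COLOR_CHANNEL[[col]]
      ch[[cn]][compartment] <- ch[[cn]][compartment] + spec$signal_level
    }
    vlev <- switch(cells$viral_marker[i],
                   none = 0,
                   transient = spec$viral_transient_level,
                   integrated = spec$viral_integrated_level)
    if (vlev > 0) ch$GREEN[disk] <- ch$GREEN[disk] + vlev
  }

  if (!is.null(truth$debris) && nrow(truth$debris) > 0) {
    for (j in seq_len(nrow(truth$debris))) {
      db <- truth$debris[j, ]
      px <- matrix(as.integer(strsplit(db$pixels, ";")[[1]]), ncol = 2,
                   byrow = TRUE) + 1L  # stored 0-based
      idx <- cbind(px[, 1], px[, 2])
      label_mask[idx] <- n + j
      ch[[db$channel]][idx] <- ch[[db$channel]][idx] + db$level
    }
  }
  for (cn in CHANNELS) ch[[cn]] <- ch[[cn]] + spec$background_level
  list(channels = ch, label_mask = label_mask)
}

#' Render a synthetic multichannel confocal field
#'
#' Draws each cell as a disk with genotype-determined fluorescence:
#' cytoplasmic colors (eYFP, RFP) fill the disk, nuclear nGFP fills a
#' concentric disk of half the radius, membrane mCFP a 2 px annulus at the
#' rim. A viral Cre-GFP provirus adds green over the whole cell body
#' (integrated proviruses at a higher level). Debris specks of 1-4 bright
#' pixels and Gaussian background noise exercise downstream filtering.
#' Rendering is deterministic under a fixed \code{spec$seed}.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param genotypes data frame with \code{nrow(genotypes) == spec$n_cells}
#'   and columns \code{allele1}, \code{allele2}, \code{viral_marker} (e.g.
#'   from \code{\link{simulate_population}}).
#' @return List with \code{stack} (a \code{\link{channel_stack}} of rounded
#'   16-bit-range intensities) and \code{truth}: \code{cells} (0-based
#'   center \code{row}/\code{col}, \code{radius}, genotype columns,
#'   \code{color_class}, \code{gfp_hi}, \code{label}), \code{debris}, and
#'   \code{label_mask} (cells labeled 1..n, debris n+1..n+d).
#' @export
#' @examples
#' sp <- scene_spec(field_size = c(96, 96), n_cells = 2, debris_count = 1,
#'                  noise_sd = 0, seed = 3)
#' pop <- simulate_population(2, recombination_params(
#'   transduction_efficiency = 1, seed = 3))
#' sc <- render_scene(sp, pop)
#' range(sc$stack$RED)
render_scene <- function(spec, genotypes) {
  if (!inherits(spec, "scene_spec")) stop("spec must be a scene_spec")
  if (nrow(genotypes) != spec$n_cells)
    stop("need exactly ", spec$n_cells, " genotypes, got ", nrow(genotypes))
  nr <- spec$field_size[1]; nc <- spec$field_size[2]

  withr::with_seed(spec$seed, {
    placed <- if (spec$n_cells > 0) place_cells(spec) else
      data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
                 partner = integer(0))

    cells <- data.frame(
      label = seq_len(spec$n_cells),
      row = round(placed$row) - 1,   # exported coordinates are 0-based
      col = round(placed$col) - 1,
      radius = placed$radius,
      touching = placed$partner > 0,
      stringsAsFactors = FALSE
    )
    if (spec$n_cells > 0) {
      cells$allele1 <- genotypes$allele1
      cells$allele2 <- genotypes$allele2
      cells$viral_marker <- genotypes$viral_marker
      oc <- lapply(seq_len(spec$n_cells), function(i)
        observable_colors(cells$allele1[i], cells$allele2[i],
                          cells$viral_marker[i]))
      cells$color_class <- vapply(oc, `[[`, "", "class")
      cells$gfp_hi <- vapply(oc, `[[`, NA, "gfp_hi")
    }

    # debris: 1-4 px specks at 0.8 x signal in one random channel, placed
    # away from cells so ground-truth labels stay unambiguous
    debris <- data.frame(channel = character(0), level = numeric(0),
                         pixels = character(0), stringsAsFactors = FALSE)
    if (spec$debris_count > 0) {
      for (j in seq_len(spec$debris_count)) {
        placed_ok <- FALSE
        for (try in seq_len(500)) {
          r0 <- sample(3:(nr - 3), 1); c0 <- sample(3:(nc - 3), 1)
          if (spec$n_cells == 0) { placed_ok <- TRUE; break }
          d2 <- (placed$row - r0)^2 + (placed$col - c0)^2
          if (all(d2 > (placed$radius + spec$margin_px)^2)) {
            placed_ok <- TRUE; break
          }
        }
        if (!placed_ok)
          stop("field overcrowded: could not place debris speck ", j)
        npx <- sample(1:4, 1)
        offs <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))[seq_len(npx), ,
                                                          drop = FALSE]
        px <- cbind(r0 + offs[, 1], c0 + offs[, 2]) - 1L  # 0-based
        debris <- rbind(debris, data.frame(
          channel = sample(CHANNELS, 1), level = 0.8 * spec$signal_level,
          pixels = paste(t(px), collapse = ";"), stringsAsFactors = FALSE))
      }
    }

    truth <- list(cells = cells, debris = debris)
    rend <- render_from_truth(truth, spec)
    ch <- rend$channels
    if (spec$noise_sd > 0)
      for (cn in CHANNELS)
        ch[[cn]] <- ch[[cn]] + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    for (cn in CHANNELS)
      ch[[cn]] <- round(pmin(pmax(ch[[cn]], 0), DTYPE_MAX))
    truth$label_mask <- rend$label_mask
    list(stack = channel_stack(ch$CFP, ch$GREEN, ch$YFP, ch$RED),
         truth = truth)
  })
}
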