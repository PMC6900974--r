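#' The four Confetti cassette fluorophores
#'
#' Each Brainbow2.1/Confetti allele recombines stochastically to one of four
#' fluorescent outcomes with fixed subcellular localization: nuclear nGFP
#' (hrGFPnls), cytoplasmic eYFP, cytoplasmic RFP (tdimer2(12)) and
#' membrane-tethered mCFP (mCerulean). Each color is read out on its own
#' detection channel, except that nGFP shares the green channel with the
#' retroviral Cre-GFP marker.
#'
#' @return A data frame with one row per fluorophore and columns
#'   \code{name}, \code{localization} and \code{detection_channel}.
#' @export
#' @examples
#' xfp_colors()
xfp_colors <- function() {
  data.frame(
    name = c("nGFP", "eYFP", "RFP", "mCFP"),
    localization = c("nuclear", "cytoplasmic", "cytoplasmic", "membrane"),
    detection_channel = c("GREEN", "YFP", "RED", "CFP"),
    stringsAsFactors = FALSE
  )
}

# canonical color and channel orders used everywhere
XFP_NAMES <- c("nGFP", "eYFP", "RFP", "mCFP")
CHANNELS <- c("CFP", "GREEN", "YFP", "RED")
# channel -> color (the green channel is shared with viral GFP)
CHANNEL_COLOR <- c(CFP = "mCFP", GREEN = "nGFP", YFP = "eYFP", RED = "RFP")
COLOR_CHANNEL <- c(nGFP = "GREEN", eYFP = "YFP", RFP = "RED", mCFP = "CFP")

#' Canonical name of a color class
#'
#' A color class is a set of 0-2 expressed fluorophores. Classes are named by
#' joining the member colors with \code{"+"} in canonical order
#' (nGFP, eYFP, RFP, mCFP); the empty set is \code{"negative"}.
#'
#' @param colors character vector of fluorophore names (possibly empty).
#' @return A single class name string.
#' @export
#' @examples
#' color_class_name(c("mCFP", "RFP"))  # "RFP+mCFP"
color_class_name <- function(colors) {
  colors <- unique(colors)
  bad <- setdiff(colors, XFP_NAMES)
  if (length(bad) > 0)
    stop("unknown fluorophore name(s): ", paste(bad, collapse = ", "))
  if (length(colors) == 0) return("negative")
  paste(XFP_NAMES[XFP_NAMES %in% colors], collapse = "+")
}

#' Display order of the ten observable color classes
#'
#' The fixed report order: the four single-color classes in canonical color
#' order, then the six double-color classes in lexicographic order of their
#' (canonically ordered) member pairs.
#'
#' @return Character vector of length 10.
#' @export
color_class_levels <- function() {
  singles <- XFP_NAMES
  pairs <- utils::combn(XFP_NAMES, 2)
  doubles <- apply(pairs, 2, paste, collapse = "+")
  c(singles, doubles)
}

# split a class name back into member colors; "negative"/"unresolved" -> none
class_colors <- function(class_name) {
  if (class_name %in% c("negative", "unresolved")) return(character(0))
  strsplit(class_name, "+", fixed = TRUE)[[1]]
}
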