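ALLELE_STATES <- c("unrecombined", "nGFP", "eYFP", "RFP", "mCFP")
VIRAL_STATES <- c("none", "transient", "integrated")

#' Parameters for the recombination simulator
#'
#' @param allele_outcome_probs named numeric vector of probabilities over the
#'   five allele states (\code{unrecombined}, \code{nGFP}, \code{eYFP},
#'   \code{RFP}, \code{mCFP}); must sum to 1. The default puts mass
#'   \code{unrecombined_mass} on no recombination and splits the rest
#'   uniformly over the four colors. Empirical outcome distributions are
#'   non-uniform, so these are parameters, not constants.
#' @param unrecombined_mass probability that an allele in a transduced cell
#'   stays unrecombined (used only to build the default
#'   \code{allele_outcome_probs}).
#' @param transduction_efficiency fraction of cells hit by the Cre virus;
#'   titration in the source protocol aims at 15-20\%, default 0.175.
#' @param integration_fraction fraction of transduced cells with a stably
#'   integrated (GFP-hi) provirus rather than a transient one; about 1\% of
#'   transduced cells in vitro.
#' @param seed integer seed for the simulation's own random generator; the
#'   global RNG state is left untouched.
#' @return An object of class \code{recombination_params}.
#' @export
recombination_params <- function(allele_outcome_probs = NULL,
                                 unrecombined_mass = 0.2,
                                 transduction_efficiency = 0.175,
                                 integration_fraction = 0.01,
                                 seed = 1L) {
  if (is.null(allele_outcome_probs)) {
    allele_outcome_probs <- c(
      unrecombined = unrecombined_mass,
      setNames(rep((1 - unrecombined_mass) / 4, 4), XFP_NAMES)
    )
  }
  if (!all(ALLELE_STATES %in% names(allele_outcome_probs)))
    stop("allele_outcome_probs must be named with all of: ",
         paste(ALLELE_STATES, collapse = ", "))
  allele_outcome_probs <- allele_outcome_probs[ALLELE_STATES]
  if (any(allele_outcome_probs < 0) ||
      abs(sum(allele_outcome_probs) - 1) > 1e-8)
    stop("allele_outcome_probs must be non-negative and sum to 1")
  for (f in c(transduction_efficiency, integration_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  structure(
    list(allele_outcome_probs = allele_outcome_probs,
         transduction_efficiency = transduction_efficiency,
         integration_fraction = integration_fraction,
         seed = as.integer(seed)),
    class = "recombination_params"
  )
}

#' Enumerate the ten observable color classes
#'
#' A homozygous Confetti cell carries two independently recombined alleles,
#' each expressing one of four fluorophores (or nothing), so the observable
#' non-empty color combinations are the 4 single colors plus the 6 unordered
#' pairs: 10 classes in total. Computed by exhaustive enumeration of allele
#' outcome pairs collapsed to observable color sets, not hard-coded.
#'
#' @return Character vector of class names in the fixed display order.
#' @export
#' @examples
#' length(enumerate_color_classes())  # 10
enumerate_color_classes <- function() {
  classes <- character(0)
  for (a1 in ALLELE_STATES) {
    for (a2 in ALLELE_STATES) {
      cls <- observable_colors(a1, a2)$class
      if (cls != "negative") classes <- union(classes, cls)
    }
  }
  lv <- color_class_levels()
  lv[lv %in% classes]
}

#' Observable color class of a genotype
#'
#' Collapses the two allele outcomes to the set of distinct expressed
#' fluorophores: identical outcomes on both alleles show as one color,
#' unrecombined alleles contribute nothing. The viral marker never adds a
#' cassette color; a stably integrated provirus sets the GFP-hi flag.
#'
#' @param allele1,allele2 allele states (one of \code{unrecombined},
#'   \code{nGFP}, \code{eYFP}, \code{RFP}, \code{mCFP}).
#' @param viral_marker one of \code{none}, \code{transient},
#'   \code{integrated}.
#' @return List with \code{colors} (character vector, length 0-2),
#'   \code{class} (canonical class name) and \code{gfp_hi} (logical).
#' @export
#' @examples
#' observable_colors("RFP", "mCFP")$class  # "RFP+mCFP"
observable_colors <- function(allele1, allele2, viral_marker = "none") {
  if (!allele1 %in% ALLELE_STATES || !allele2 %in% ALLELE_STATES)
    stop("allele states must be one of: ", paste(ALLELE_STATES, collapse = ", "))
  if (!viral_marker %in% VIRAL_STATES)
    stop("viral_marker must be one of: ", paste(VIRAL_STATES, collapse = ", "))
  colors <- setdiff(unique(c(allele1, allele2)), "unrecombined")
  colors <- XFP_NAMES[XFP_NAMES %in% colors]
  list(colors = colors,
       class = color_class_name(colors),
       gfp_hi = identical(viral_marker, "integrated"))
}

#' Maximum number of distinct fluorescent signals per cell
#'
#' Exhaustively enumerates every genotype (both allele states, viral marker
#' present or absent) and returns the maximum number of distinct fluorescent
#' proteins a single cell can express. The viral Cre-GFP marker is a distinct
#' protein from cassette nGFP (they share only the detection channel), so it
#' counts as one additional signal when present. With the marker the bound is
#' 3; without it, 2.
#'
#' @param with_viral_marker logical; include the Cre-GFP marker in the
#'   enumeration.
#' @param require_equal_alleles logical; restrict the enumeration to
#'   genotypes with identical outcomes on both alleles.
#' @return Integer maximum signal count.
#' @export
#' @examples
#' max_distinct_signals(TRUE)   # 3
#' max_distinct_signals(FALSE)  # 2
max_distinct_signals <- function(with_viral_marker = TRUE,
                                 require_equal_alleles = FALSE) {
  viral <- if (with_viral_marker) VIRAL_STATES else "none"
  best <- 0L
  for (a1 in ALLELE_STATES) {
    for (a2 in ALLELE_STATES) {
      if (require_equal_alleles && a1 != a2) next
      for (v in viral) {
        n <- length(observable_colors(a1, a2, v)$colors) +
          as.integer(v != "none")
        if (n > best) best <- n
      }
    }
  }
  best
}

#' Simulate a recombined cell population
#'
#' Each cell is transduced with probability
#' \code{params$transduction_efficiency}; transduced cells draw each allele
#' outcome independently from \code{params$allele_outcome_probs} and carry an
#' integrated provirus with probability \code{params$integration_fraction}
#' (transient otherwise). Untransduced cells stay unrecombined with no
#' marker. The simulation uses its own seeded generator, so a fixed seed
#' gives an identical population without touching the session RNG.
#'
#' @param n_cells number of cells (> 0).
#' @param params a \code{\link{recombination_params}} object.
#' @return Data frame with columns \code{cell_id}, \code{allele1},
#'   \code{allele2}, \code{viral_marker}, \code{color_class}, \code{gfp_hi}.
#' @export
#' @examples
#' pop <- simulate_population(100, recombination_params(seed = 7))
#' table(pop$color_class)
simulate_population <- function(n_cells, params = recombination_params()) {
  if (!inherits(params, "recombination_params"))
    stop("params must be a recombination_params object")
  n_cells <- as.integer(n_cells)
  if (n_cells <= 0) stop("n_cells must be > 0")
  withr::with_seed(params$seed, {
    transduced <- runif(n_cells) < params$transduction_efficiency
    a1 <- a2 <- rep("unrecombined", n_cells)
    viral <- rep("none", n_cells)
    nt <- sum(transduced)
    if (nt > 0) {
      p <- params$allele_outcome_probs
      a1[transduced] <- sample(ALLELE_STATES, nt, replace = TRUE, prob = p)
      a2[transduced] <- sample(ALLELE_STATES, nt, replace = TRUE, prob = p)
      viral[transduced] <- ifelse(
        runif(nt) < params$integration_fraction, "integrated", "transient")
    }
    cls <- character(n_cells)
    hi <- logical(n_cells)
    for (i in seq_len(n_cells)) {
      oc <- observable_colors(a1[i], a2[i], viral[i])
      cls[i] <- oc$class
      hi[i] <- oc$gfp_hi
    }
    data.frame(cell_id = seq_len(n_cells), allele1 = a1, allele2 = a2,
               viral_marker = viral, color_class = cls, gfp_hi = hi,
               stringsAsFactors = FALSE)
  })
}

#' Closed-form class probabilities for two independent alleles
#'
#' Analytic distribution over observable color classes (plus
#' \code{negative}) implied by independent allele draws from
#' \code{allele_outcome_probs}: a single color c has probability
#' p(c)^2 + 2 p(c) p(unrec), a pair \{c1, c2\} probability 2 p(c1) p(c2),
#' and negative p(unrec)^2. Used as the parameter-recovery oracle for
#' \code{\link{simulate_population}}.
#'
#' @param allele_outcome_probs named probability vector over the five allele
#'   states.
#' @return Named numeric vector over \code{color_class_levels()} plus
#'   \code{negative}, summing to 1.
#' @export
class_probabilities <- function(allele_outcome_probs) {
  p <- allele_outcome_probs[ALLELE_STATES]
  out <- setNames(numeric(11), c(color_class_levels(), "negative"))
  for (a1 in ALLELE_STATES) {
    for (a2 in ALLELE_STATES) {
      cls <- observable_colors(a1, a2)$class
      out[cls] <- out[cls] + p[[a1]] * p[[a2]]
    }
  }
  out
}

#' Write / read a simulated population as CSV
#'
#' @param population data frame from \code{\link{simulate_population}}.
#' @param path file path.
#' @return \code{read_population} returns the population data frame.
#' @export
write_population <- function(population, path) {
  write.csv(population, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "allele1", "allele2", "viral_marker",
            "color_class", "gfp_hi")
  if (!all(need %in% names(pop)))
    stop("population file lacks columns: ",
         paste(setdiff(need, names(pop)), collapse = ", "))
  pop
}
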