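#' Clonal composition per group
#'
#' Counts classified events per group and color class. Class fractions are
#' computed among labeled events only; \code{unresolved} events are counted
#' separately (never silently dropped) and \code{negative} events enter the
#' totals. Labeling efficiency is the fraction of events expressing any
#' cassette color among all events of the group. Group order is
#' lexicographic, hence deterministic.
#'
#' @param classified data frame with a \code{color_class} column plus the
#'   grouping metadata columns.
#' @param group_by character vector of metadata column names (empty for one
#'   global group).
#' @return Object of class \code{composition_table}: list with
#'   \code{composition} (long data frame: group columns, \code{color_class},
#'   \code{count}, \code{fraction} — \code{NA} for negative/unresolved rows)
#'   and \code{summary} (per group: \code{total}, \code{labeled},
#'   \code{unresolved}, \code{negative}, \code{labeling_efficiency},
#'   \code{richness}).
#' @export
#' @examples
#' df <- data.frame(organ = "spleen", color_class = c("mCFP", "mCFP", "RFP"))
#' compose_classes(df, "organ")$summary
compose_classes <- function(classified, group_by = character(0)) {
  if (!"color_class" %in% names(classified))
    stop("classified table lacks a color_class column")
  miss <- setdiff(group_by, names(classified))
  if (length(miss) > 0)
    stop("missing group column(s): ", paste(miss, collapse = ", "))
  lv <- c(color_class_levels(), "unresolved", "negative")
  bad <- setdiff(unique(classified$color_class), lv)
  if (length(bad) > 0)
    stop("unknown color class value(s): ", paste(bad, collapse = ", "))

  if (length(group_by) == 0) {
    classified$.group <- "all"
    group_by <- ".group"
  }
  key <- do.call(paste, c(classified[group_by], sep = "\r"))
  groups <- sort(unique(key))

  comp <- list(); summ <- list()
  for (g in groups) {
    sub <- classified[key == g, , drop = FALSE]
    counts <- table(factor(sub$color_class, levels = lv))
    total <- nrow(sub)
    unres <- as.integer(counts[["unresolved"]])
    neg <- as.integer(counts[["negative"]])
    labeled <- total - neg
    class_counts <- counts[color_class_levels()]
    class_total <- sum(class_counts)
    frac <- if (class_total > 0) as.numeric(class_counts) / class_total
            else rep(NA_real_, length(class_counts))
    gvals <- sub[1, group_by, drop = FALSE]
    comp[[g]] <- data.frame(
      gvals, color_class = lv,
      count = as.integer(counts),
      fraction = c(frac, NA_real_, NA_real_),
      row.names = NULL, check.names = FALSE)
    summ[[g]] <- data.frame(
      gvals, total = total, labeled = labeled, unresolved = unres,
      negative = neg,
      labeling_efficiency = if (total > 0) labeled / total else NA_real_,
      richness = sum(class_counts > 0),
      row.names = NULL, check.names = FALSE)
  }
  structure(list(composition = do.call(rbind, comp),
                 summary = do.call(rbind, summ),
                 group_by = group_by),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("composition_table over", nrow(x$summary), "group(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# fraction vector over labeled classes for one group of a composition table
group_fractions <- function(ct, group) {
  comp <- ct$composition
  key <- do.call(paste, c(comp[ct$group_by], sep = "\r"))
  sel <- key == paste(group, collapse = "\r") &
    comp$color_class %in% color_class_levels()
  if (!any(sel)) stop("group not found: ", paste(group, collapse = "/"))
  setNames(comp$fraction[sel], comp$color_class[sel])
}

#' Compare the clonal composition of two groups
#'
#' Reports the color classes shared by and unique to each group, and the
#' total variation distance between their class fraction vectors (half the
#' L1 distance over the union of classes; 0 for identical compositions, 1
#' for disjoint ones).
#'
#' @param ct a \code{\link{compose_classes}} result.
#' @param group_a,group_b group key values (one value per grouping column).
#' @return List with \code{shared}, \code{unique_a}, \code{unique_b},
#'   \code{tvd}.
#' @export
compare_groups <- function(ct, group_a, group_b) {
  fa <- group_fractions(ct, group_a)
  fb <- group_fractions(ct, group_b)
  fa[is.na(fa)] <- 0; fb[is.na(fb)] <- 0
  present_a <- names(fa)[fa > 0]
  present_b <- names(fb)[fb > 0]
  list(shared = intersect(present_a, present_b),
       unique_a = setdiff(present_a, present_b),
       unique_b = setdiff(present_b, present_a),
       tvd = sum(abs(fa - fb)) / 2)
}

#' Write a composition report
#'
#' Writes the composition and summary tables as CSV, a combined JSON report
#' (optionally including pipeline QC), and an optional stacked-bar PNG of
#' class fractions per group. Output is deterministic given the input.
#'
#' @param ct a \code{\link{compose_classes}} result.
#' @param out_dir output directory (created if missing).
#' @param qc optional QC list to embed in the JSON.
#' @param plot write \code{composition.png}.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(ct, out_dir, qc = NULL, plot = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(composition = file.path(out_dir, "composition.csv"),
             summary = file.path(out_dir, "summary.csv"),
             json = file.path(out_dir, "report.json"))
  write.csv(ct$composition, paths["composition"], row.names = FALSE)
  write.csv(ct$summary, paths["summary"], row.names = FALSE)
  jsonlite::write_json(
    list(composition = ct$composition, summary = ct$summary,
         group_by = ct$group_by, qc = qc),
    paths["json"], auto_unbox = TRUE, digits = NA, na = "null")

  if (plot) {
    png_path <- file.path(out_dir, "composition.png")
    comp <- ct$composition[ct$composition$color_class %in%
                             color_class_levels(), ]
    key <- do.call(paste, c(comp[ct$group_by], sep = "/"))
    m <- tapply(comp$fraction, list(comp$color_class, key), identity)
    m <- m[color_class_levels(), , drop = FALSE]
    m[is.na(m)] <- 0
    grDevices::png(png_path, width = 720, height = 480)
    graphics::par(mar = c(5, 4, 2, 10), xpd = TRUE)
    cols <- grDevices::hsv((0.618 * seq_len(10)) %% 1, 0.7, 0.95)
    graphics::barplot(m, col = cols, ylab = "fraction of labeled events",
                      las = 2)
    graphics::legend("topright", inset = c(-0.35, 0),
                     legend = rev(rownames(m)), fill = rev(cols), cex = 0.8)
    grDevices::dev.off()
    paths <- c(paths, png = png_path)
  }
  invisible(paths)
}
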