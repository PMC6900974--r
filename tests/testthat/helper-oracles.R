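# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: the expansion reference works by
# whole-matrix neighbor shifts, the labeling reference by an explicit stack
# walk.

# matrix with element (r,c) = m[r - dr, c - dc], zero-padded
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

NBR4 <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
NBR8 <- c(NBR4, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))

# synchronized-front geodesic expansion, lowest label wins contested pixels
ref_geodesic_expand <- function(seeds, mask, connectivity = 4) {
  nbrs <- if (connectivity == 4) NBR4 else NBR8
  lab <- seeds
  repeat {
    cand <- matrix(Inf, nrow(lab), ncol(lab))
    for (s in nbrs) {
      v <- shift_mat(lab, s[1], s[2])
      v[v == 0] <- Inf
      cand <- pmin(cand, v)
    }
    sel <- lab == 0 & mask != 0 & is.finite(cand)
    if (!any(sel)) break
    lab[sel] <- as.integer(cand[sel])
  }
  storage.mode(lab) <- "integer"
  lab
}

# connected-component labeling by explicit stack walk, column-major seed order
ref_label <- function(mask, connectivity = 8) {
  nbrs <- if (connectivity == 4) NBR4 else NBR8
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (mask[r0, c0] == 0 || lab[r0, c0] != 0) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (s in nbrs) {
        r <- p[1] + s[1]; c <- p[2] + s[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] != 0 && lab[r, c] == 0) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# brute-force per-pixel composite maximum
ref_composite_max <- function(stack) {
  out <- matrix(0, nrow(stack[[1]]), ncol(stack[[1]]))
  for (r in seq_len(nrow(out))) for (c in seq_len(ncol(out)))
    out[r, c] <- max(vapply(stack, function(m) m[r, c], 0))
  out
}

# closed-form class distribution for two independent alleles (hand formula:
# singles p^2 + 2 p p0, doubles 2 p1 p2, negative p0^2)
hand_class_probs <- function(p) {
  cols <- c("nGFP", "eYFP", "RFP", "mCFP")
  out <- c()
  for (cn in cols) out[cn] <- p[[cn]]^2 + 2 * p[[cn]] * p[["unrecombined"]]
  pr <- utils::combn(cols, 2)
  for (k in seq_len(ncol(pr))) {
    nm <- paste(pr[, k], collapse = "+")
    out[nm] <- 2 * p[[pr[1, k]]] * p[[pr[2, k]]]
  }
  out["negative"] <- p[["unrecombined"]]^2
  out
}

# a filled disk mask on an nr x nc grid (1-based center)
disk_mask <- function(nr, nc, r0, c0, rad) {
  outer((seq_len(nr) - r0)^2, (seq_len(nc) - c0)^2, "+") <= rad^2
}

# small fully transduced population with explicit genotypes
fixed_population <- function(allele1, allele2, viral = "none") {
  n <- length(allele1)
  viral <- rep(viral, length.out = n)
  cls <- character(n); hi <- logical(n)
  for (i in seq_len(n)) {
    oc <- observable_colors(allele1[i], allele2[i], viral[i])
    cls[i] <- oc$class; hi[i] <- oc$gfp_hi
  }
  data.frame(cell_id = seq_len(n), allele1 = allele1, allele2 = allele2,
             viral_marker = viral, color_class = cls, gfp_hi = hi,
             stringsAsFactors = FALSE)
}

# random blob-like binary mask for expansion/labeling property tests
random_mask <- function(nr, nc, p = 0.45) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}
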