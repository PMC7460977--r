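# Bondi van der Waals radii, Angstrom
.vdw_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 S = 1.80, Cl = 1.75, P = 1.80, B = 1.92, Br = 1.85)

#' Classify intermolecular close contacts by element pair
#'
#' Distance-based proxy for surface-based contact analysis: every atom of a
#' central molecule within `r_vdW(A) + r_vdW(B) + tolerance` of an atom of a
#' different molecule (periodic images included) counts one reciprocal
#' contact of unordered type `A...B`. Contacts between conjugated heavy atoms
#' (C...C, C...N, N...N) are classed "conductive" (they can carry
#' frontier-orbital overlap); any contact involving hydrogen is "insulating".
#' Because this counts atom pairs rather than partitioning a molecular
#' surface, absolute fractions differ from Hirshfeld-surface area fractions;
#' trends across related crystals are the meaningful output.
#'
#' @param structure a `crystal_structure`; molecules are identified if
#'   needed.
#' @param tolerance distance allowance beyond the van der Waals radius sum,
#'   Angstrom (default 0.2).
#' @param supercell images per axis on each side (default 1, i.e. 3x3x3;
#'   fractions are converged at this size for ordinary molecular cells).
#' @return A `contact_table`: `counts` and `fractions` keyed by unordered
#'   element pair (e.g. `"C...N"`), and `conductive_fraction`.
#' @export
contact_fractions <- function(structure, tolerance = 0.2, supercell = 1L) {
  stopifnot(inherits(structure, "crystal_structure"), tolerance >= 0)
  if (is.null(structure$molecules)) structure <- identify_molecules(structure)
  mols <- structure$molecules
  M <- structure$cell$frac_to_cart
  n <- supercell
  grid <- as.matrix(expand.grid(-n:n, -n:n, -n:n))
  trans <- grid %*% t(M)

  counts <- new.env(parent = emptyenv())
  bump <- function(e1, e2, k = 1) {
    key <- paste(min(e1, e2), max(e1, e2), sep = "...")
    assign(key, (if (exists(key, counts)) get(key, counts) else 0) + k, counts)
  }
  total <- 0
  for (ia in seq_along(mols)) {
    A <- mols[[ia]]$coords; ea <- mols[[ia]]$elements
    ra <- .vdw_radius[ea]
    for (ib in seq_along(mols)) {
      B0 <- mols[[ib]]$coords; eb <- mols[[ib]]$elements
      rb <- .vdw_radius[eb]
      thr <- outer(ra, rb, "+") + tolerance
      for (g in seq_len(nrow(trans))) {
        if (ib == ia && all(grid[g, ] == 0)) next
        B <- sweep(B0, 2, trans[g, ], "+")
        d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
        hit <- which(d2 <= thr^2, arr.ind = TRUE)
        for (h in seq_len(nrow(hit))) {
          bump(ea[hit[h, 1]], eb[hit[h, 2]])
          total <- total + 1
        }
      }
    }
  }
  if (total == 0)
    warning("no intermolecular contacts within threshold: empty table")
  cnt <- unlist(as.list(counts))
  if (is.null(cnt)) cnt <- numeric(0)
  frac <- if (total > 0) cnt / total else cnt
  conductive <- c("C...C", "C...N", "N...N")
  structure(list(counts = cnt, fractions = frac,
                 conductive_fraction = sum(frac[names(frac) %in% conductive]),
                 tolerance = tolerance),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat("contact_table (distance/vdW proxy, not a surface partition):\n")
  if (length(x$fractions)) {
    ord <- order(-x$fractions)
    for (i in ord)
      cat(sprintf("  %-8s %6.1f%%  (%d)\n", names(x$fractions)[i],
                  100 * x$fractions[i], as.integer(x$counts[i])))
    cat(sprintf("  conductive (C...C + C...N + N...N): %.1f%%\n",
                100 * x$conductive_fraction))
  } else cat("  (empty)\n")
  invisible(x)
}
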