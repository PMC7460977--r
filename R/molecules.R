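# Covalent radii (Cordero), Angstrom. Bond criterion: d <= r1 + r2 + tol.
.covalent_radius <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                      F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20)

.rcov <- function(elements) {
  r <- .covalent_radius[elements]
  if (anyNA(r)) stop("no covalent radius for element(s): ",
                     paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Construct a molecule record
#'
#' @param elements character vector of element symbols.
#' @param coords n x 3 matrix of Cartesian coordinates, Angstrom.
#' @param bonds two-column integer matrix of bonded atom index pairs; derived
#'   from the covalent-radius criterion when `NULL`.
#' @param bond_tol tolerance added to the covalent-radius sum, Angstrom.
#' @return A `molecule`: list with `elements`, `coords`, `bonds` and the
#'   unweighted `centroid`.
#' @export
molecule <- function(elements, coords, bonds = NULL, bond_tol = 0.4) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(length(elements) == nrow(coords))
  if (is.null(bonds)) {
    rc <- .rcov(elements)
    bonds <- matrix(integer(0), ncol = 2)
    n <- length(elements)
    if (n > 1) {
      d <- as.matrix(stats::dist(coords))
      thr <- outer(rc, rc, "+") + bond_tol
      hit <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
      bonds <- unname(hit)
    }
  }
  structure(list(elements = elements, coords = coords,
                 bonds = bonds, centroid = colMeans(coords)),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule: %d atoms (%s), %d bonds\n", length(x$elements),
              paste(names(table(x$elements)), table(x$elements),
                    sep = "", collapse = " "),
              nrow(x$bonds)))
  invisible(x)
}

# expand asymmetric sites over all symmetry ops into one P1 cell; dedupe
# coincident images (special positions) on a Cartesian tolerance
.expand_p1 <- function(structure, tol = 0.05) {
  s <- structure$sites
  frac <- as.matrix(s[, c("fx", "fy", "fz")])
  out_el <- character(0); out_fr <- NULL
  for (op in structure$symmetry) {
    f <- apply_symop(op, frac) %% 1
    out_el <- c(out_el, s$element)
    out_fr <- rbind(out_fr, f)
  }
  cart <- frac_to_cart(structure$cell, out_fr)
  keep <- rep(TRUE, nrow(out_fr))
  for (i in seq_len(nrow(out_fr))) {
    if (!keep[i]) next
    if (i < nrow(out_fr)) {
      j <- (i + 1):nrow(out_fr)
      # minimum-image duplicate check
      df <- out_fr[j, , drop = FALSE]
      df <- sweep(df, 2, out_fr[i, ])
      df <- df - round(df)
      dc <- frac_to_cart(structure$cell, df)
      dup <- j[sqrt(rowSums(dc^2)) < tol & out_el[j] == out_el[i]]
      keep[dup] <- FALSE
    }
  }
  list(element = out_el[keep], frac = out_fr[keep, , drop = FALSE],
       cart = cart[keep, , drop = FALSE])
}

#' Identify whole molecules in a crystal
#'
#' Expands the asymmetric unit over all symmetry operations into one P1 cell,
#' then finds connected components under the covalent bond criterion
#' (distance <= covalent-radius sum + `bond_tol`), following bonds across
#' periodic boundaries so that molecules straddling the cell are reassembled
#' into contiguous Cartesian geometry.
#'
#' @param structure a `crystal_structure` from [read_cif()] or
#'   [make_stack_crystal()].
#' @param bond_tol bond detection tolerance in Angstrom (default 0.4).
#' @return The structure with `molecules` set: a list of [molecule()] records,
#'   one per molecule in the unit cell, in a consistent Cartesian frame.
#' @details A component that does not close under translation (an atom is
#'   reached through bonds with two different lattice offsets) is an infinite
#'   covalent network, not a molecular crystal, and raises an error.
#' @export
identify_molecules <- function(structure, bond_tol = 0.4) {
  stopifnot(inherits(structure, "crystal_structure"))
  p1 <- .expand_p1(structure)
  n <- length(p1$element)
  rc <- .rcov(p1$element)
  cell <- structure$cell

  unwrapped <- matrix(NA_real_, n, 3)  # fractional, unwrapped per component
  comp <- integer(n)
  bonds_all <- vector("list", n)
  ncomp <- 0L
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))

  for (seed_atom in seq_len(n)) {
    if (comp[seed_atom] != 0L) next
    ncomp <- ncomp + 1L
    comp[seed_atom] <- ncomp
    unwrapped[seed_atom, ] <- p1$frac[seed_atom, ]
    queue <- seed_atom
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      ui <- unwrapped[i, ]
      for (j in seq_len(n)) {
        base <- round(ui - p1$frac[j, ])
        cand <- sweep(shifts, 2, base, "+")
        fj <- sweep(cand, 2, p1$frac[j, ], "+")
        dc <- frac_to_cart(cell, sweep(fj, 2, ui))
        dd <- sqrt(rowSums(dc^2))
        thr <- rc[i] + rc[j] + bond_tol
        hit <- which(dd <= thr & dd > 1e-6)
        for (h in hit) {
          uj <- fj[h, ]
          if (comp[j] == 0L) {
            comp[j] <- ncomp
            unwrapped[j, ] <- uj
            queue <- c(queue, j)
            bonds_all[[i]] <- rbind(bonds_all[[i]], c(i, j))
          } else {
            if (max(abs(unwrapped[j, ] - uj)) > 1e-6) {
              if (j == i || comp[j] == ncomp)
                stop("infinite covalent network: component does not close ",
                     "under translation (not a molecular crystal)")
            } else if (j > i) {
              bonds_all[[i]] <- rbind(bonds_all[[i]], c(i, j))
            }
          }
        }
      }
    }
  }

  bonds <- do.call(rbind, bonds_all[!vapply(bonds_all, is.null, logical(1))])
  mols <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    idx <- which(comp == k)
    remap <- match(seq_len(n), idx)
    bk <- bonds[comp[bonds[, 1]] == k, , drop = FALSE]
    bk <- cbind(remap[bk[, 1]], remap[bk[, 2]])
    bk <- unique(t(apply(bk, 1, sort)))
    if (length(bk) == 0) bk <- matrix(integer(0), ncol = 2)
    mols[[k]] <- molecule(p1$element[idx],
                          frac_to_cart(cell, unwrapped[idx, , drop = FALSE]),
                          bonds = matrix(as.integer(bk), ncol = 2))
  }
  structure$molecules <- mols
  structure$p1_sites <- p1
  structure
}

# rigid transform of a molecule (rotation matrix R, then translation t)
.transform_molecule <- function(mol, R = diag(3), t = c(0, 0, 0)) {
  m <- mol
  m$coords <- sweep(mol$coords %*% t(R), 2, t, "+")
  m$centroid <- colMeans(m$coords)
  m
}
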