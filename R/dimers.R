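#' Enumerate neighbor dimers of a crystal
#'
#' For each molecule in the unit cell (the central molecule), collects every
#' periodic image of every cell molecule whose centroid lies within `cutoff`
#' of the central centroid, and groups the resulting pairs into
#' symmetry-unique dimers by a rigid-motion-invariant distance fingerprint.
#' The image search runs over a supercell that is automatically grown so the
#' cutoff sphere is fully covered (at least 3x3x3).
#'
#' @param structure a `crystal_structure`; [identify_molecules()] is applied
#'   if it has not been already.
#' @param cutoff centroid-to-centroid cutoff in Angstrom (default 10, which
#'   covers all nearest-neighbor shells of acene-sized crystals).
#' @param fingerprint_digits decimal digits used when rounding intermolecular
#'   heavy-atom distances for the fingerprint (default 3, i.e. 1e-3 Angstrom).
#' @return A list of `dimer_pair` records, each with `mol_a` (central),
#'   `mol_b` (neighbor image), centroid separation `r_vec` and `r` (Angstrom),
#'   `multiplicity` (symmetry-equivalent instances around one central
#'   molecule) and `fingerprint`.
#' @examples
#' cr <- make_stack_crystal(stack_spec(n_rings = 1, spacing = 3.5))
#' length(enumerate_dimers(cr, cutoff = 4))  # the cofacial stack contact
#' @export
enumerate_dimers <- function(structure, cutoff = 10,
                             fingerprint_digits = 3) {
  stopifnot(inherits(structure, "crystal_structure"), cutoff > 0)
  if (is.null(structure$molecules)) structure <- identify_molecules(structure)
  mols <- structure$molecules
  cell <- structure$cell
  M <- cell$frac_to_cart

  # perpendicular cell heights give the image count guaranteeing coverage
  av <- M[, 1]; bv <- M[, 2]; cv <- M[, 3]
  h <- c(cell$volume / sqrt(sum(.cross(bv, cv)^2)),
         cell$volume / sqrt(sum(.cross(av, cv)^2)),
         cell$volume / sqrt(sum(.cross(av, bv)^2)))
  nimg <- pmax(1L, ceiling((cutoff + 1e-9) / h))

  grid <- as.matrix(expand.grid(-nimg[1]:nimg[1],
                                -nimg[2]:nimg[2],
                                -nimg[3]:nimg[3]))
  trans <- grid %*% t(M)

  pairs <- list()
  for (ia in seq_along(mols)) {
    ca <- mols[[ia]]$centroid
    for (ib in seq_along(mols)) {
      cb <- sweep(trans, 2, mols[[ib]]$centroid, "+")
      rvec <- sweep(cb, 2, ca)
      r <- sqrt(rowSums(rvec^2))
      hit <- which(r <= cutoff & r > 1e-6)
      for (hidx in hit) {
        mb <- .transform_molecule(mols[[ib]], t = trans[hidx, ])
        pairs[[length(pairs) + 1L]] <- .dimer_pair(
          mols[[ia]], mb, digits = fingerprint_digits)
      }
    }
  }
  if (!length(pairs)) return(list())
  dd <- deduplicate_dimers(pairs)
  # instances were collected around every cell molecule; multiplicity is the
  # count around one central molecule
  for (k in seq_along(dd))
    dd[[k]]$multiplicity <- dd[[k]]$multiplicity / length(mols)
  dd
}

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.dimer_pair <- function(mol_a, mol_b, digits = 3) {
  rvec <- mol_b$centroid - mol_a$centroid
  structure(list(mol_a = mol_a, mol_b = mol_b,
                 r_vec = rvec, r = sqrt(sum(rvec^2)),
                 multiplicity = 1L,
                 fingerprint = dimer_fingerprint(mol_a, mol_b, digits)),
            class = "dimer_pair")
}

#' Rigid-motion-invariant dimer fingerprint
#'
#' The sorted list of intermolecular heavy-atom distances (element-pair
#' labelled, rounded), which is invariant under swapping the two molecules
#' and under rigid motions of the dimer.
#'
#' @param mol_a,mol_b [molecule()] records.
#' @param digits decimal digits for rounding distances.
#' @return A single string key.
#' @export
dimer_fingerprint <- function(mol_a, mol_b, digits = 3) {
  ha <- mol_a$elements != "H"; hb <- mol_b$elements != "H"
  A <- mol_a$coords[ha, , drop = FALSE]
  B <- mol_b$coords[hb, , drop = FALSE]
  ea <- mol_a$elements[ha]; eb <- mol_b$elements[hb]
  d <- sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B))
  lab <- outer(ea, eb, function(x, y)
    paste(pmin(x, y), pmax(x, y), sep = "-"))
  ent <- sprintf("%s:%.*f", lab, digits, round(d, digits))
  paste(sort(ent), collapse = "|")
}

#' Merge symmetry-equivalent dimer pairs
#'
#' Pairs with identical fingerprints are merged into one entry whose
#' multiplicity is the summed instance count; the representative geometry of
#' the first (smallest-r) instance is kept.
#'
#' @param pairs list of `dimer_pair` records from one structure.
#' @param digits re-round fingerprints at this precision before grouping
#'   (`NULL` keeps the stored fingerprints).
#' @return A list of unique `dimer_pair` records sorted by `r`.
#' @export
deduplicate_dimers <- function(pairs, digits = NULL) {
  if (!length(pairs)) return(list())
  fps <- vapply(pairs, function(p) {
    if (is.null(digits)) p$fingerprint
    else dimer_fingerprint(p$mol_a, p$mol_b, digits)
  }, character(1))
  out <- list()
  for (fp in unique(fps)) {
    idx <- which(fps == fp)
    rs <- vapply(pairs[idx], function(p) p$r, numeric(1))
    rep_pair <- pairs[[idx[which.min(rs)]]]
    rep_pair$multiplicity <- sum(vapply(pairs[idx], function(p)
      as.numeric(p$multiplicity), numeric(1)))
    out[[length(out) + 1L]] <- rep_pair
  }
  out[order(vapply(out, function(p) p$r, numeric(1)))]
}

#' Tabulate dimers
#'
#' @param pairs list of `dimer_pair` records.
#' @return data.frame with `r`, the components of `r_vec`, `multiplicity` and
#'   a short fingerprint hash, one row per unique dimer.
#' @export
dimer_table <- function(pairs) {
  if (!length(pairs))
    return(data.frame(r = numeric(0), rx = numeric(0), ry = numeric(0),
                      rz = numeric(0), multiplicity = numeric(0),
                      fingerprint = character(0)))
  data.frame(
    r = vapply(pairs, function(p) p$r, numeric(1)),
    rx = vapply(pairs, function(p) p$r_vec[1], numeric(1)),
    ry = vapply(pairs, function(p) p$r_vec[2], numeric(1)),
    rz = vapply(pairs, function(p) p$r_vec[3], numeric(1)),
    multiplicity = vapply(pairs, function(p) as.numeric(p$multiplicity),
                          numeric(1)),
    fingerprint = vapply(pairs, function(p)
      substr(.fp_hash(p$fingerprint), 1, 12), character(1)),
    stringsAsFactors = FALSE)
}

# small stable string hash (djb2) for compact fingerprint ids
.fp_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2^31
  sprintf("%08x%04d", h, length(v) %% 10000)
}
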