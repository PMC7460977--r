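#' Default tight-binding parameters
#'
#' On-site energies and hoppings of the toy pi-electron backend: one p-type
#' basis function per heavy atom (C, N), nearest-neighbor hopping `beta`
#' within a molecule, and a distance-decayed intermolecular hopping
#' `t(d) = t0 * exp(-eta * (d - d0))` for heavy-atom pairs up to `d_max`.
#' Magnitudes are literature-typical for pi systems and put intermolecular
#' couplings in the tens-of-meV range at van der Waals stacking distances;
#' they are fixtures of the toy model, not fitted quantities.
#'
#' @return Named list: `alpha_C`, `alpha_N`, `beta` (eV); `t0` (eV), `eta`
#'   (1/Angstrom), `d0`, `d_max` (Angstrom); `s0` overlap prefactor used only
#'   when an overlap model is requested.
#' @export
huckel_params <- function() {
  list(alpha_C = -6.55, alpha_N = -8.55, beta = -2.7,
       t0 = -0.3, eta = 1.0, d0 = 3.5, d_max = 6.0, s0 = 0.02)
}

.onsite <- function(elements, params) {
  a <- c(C = params$alpha_C, N = params$alpha_N)[elements]
  if (anyNA(a)) stop("tight-binding backend supports C and N heavy atoms only")
  unname(a)
}

.heavy <- function(mol) which(mol$elements != "H")

# monomer tight-binding Hamiltonian over heavy atoms
.huckel_h <- function(mol, params) {
  hv <- .heavy(mol)
  n <- length(hv)
  H <- diag(.onsite(mol$elements[hv], params), n)
  if (nrow(mol$bonds)) {
    remap <- match(seq_along(mol$elements), hv)
    for (r in seq_len(nrow(mol$bonds))) {
      i <- remap[mol$bonds[r, 1]]; j <- remap[mol$bonds[r, 2]]
      if (!is.na(i) && !is.na(j)) H[i, j] <- H[j, i] <- params$beta
    }
  }
  H
}

#' Electronic structure of a monomer in the tight-binding toy backend
#'
#' Solves the pi-system tight-binding problem with one basis function per
#' heavy atom (C or N); each heavy atom contributes one pi electron. A
#' lightweight, deterministic stand-in for an ab initio backend with the
#' same output contract.
#'
#' @param mol a [molecule()].
#' @param params parameter list, see [huckel_params()].
#' @param n_electrons override of the pi-electron count (default: one per
#'   heavy atom); an odd count is rejected as open shell, so ionized toys
#'   must supply an even override.
#' @return An `electronic_structure`: `orbital_energies` (ascending, eV),
#'   `mo_coefficients` (basis x orbitals), `overlap`, `n_electrons`,
#'   `homo_index`/`lumo_index` (1-based), `basis_labels`.
#' @examples
#' benz <- acene_template(1)            # benzene ring
#' es <- huckel_monomer(benz)
#' frontier_levels(es)
#' @export
huckel_monomer <- function(mol, params = huckel_params(),
                           n_electrons = NULL) {
  H <- .huckel_h(mol, params)
  n <- nrow(H)
  if (is.null(n_electrons)) n_electrons <- n
  if (n_electrons %% 2L != 0L)
    stop("odd pi-electron count (", n_electrons,
         "): open-shell systems are unsupported")
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  electronic_structure(
    orbital_energies = eig$values[ord],
    mo_coefficients = eig$vectors[, ord, drop = FALSE],
    overlap = diag(n),
    n_electrons = n_electrons,
    basis_labels = paste0(mol$elements[.heavy(mol)], .heavy(mol), ":pz"))
}

#' Construct/validate an electronic-structure result
#'
#' @param orbital_energies ascending orbital energies, eV.
#' @param mo_coefficients basis x orbitals coefficient matrix.
#' @param overlap basis overlap matrix.
#' @param n_electrons even electron count.
#' @param basis_labels optional per-basis-function labels.
#' @return An `electronic_structure` object; orthonormality (C' S C = I) and
#'   energy ordering are enforced at construction.
#' @export
electronic_structure <- function(orbital_energies, mo_coefficients, overlap,
                                 n_electrons, basis_labels = NULL) {
  C <- as.matrix(mo_coefficients); S <- as.matrix(overlap)
  if (is.unsorted(orbital_energies)) stop("orbital energies must be ascending")
  if (n_electrons %% 2L != 0L) stop("n_electrons must be even (closed shell)")
  G <- t(C) %*% S %*% C
  if (max(abs(G - diag(ncol(C)))) > 1e-8)
    stop("MO coefficients are not S-orthonormal (C'SC differs from identity)")
  homo <- n_electrons / 2
  structure(list(orbital_energies = orbital_energies,
                 mo_coefficients = C, overlap = S,
                 n_electrons = as.integer(n_electrons),
                 homo_index = as.integer(homo),
                 lumo_index = as.integer(homo + 1L),
                 basis_labels = basis_labels),
            class = "electronic_structure")
}

#' @export
print.electronic_structure <- function(x, ...) {
  lv <- frontier_levels(x)
  cat(sprintf("electronic_structure: %d basis fn, %d electrons; HOMO %.3f eV, LUMO %.3f eV, gap %.3f eV\n",
              nrow(x$mo_coefficients), x$n_electrons,
              lv["homo"], lv["lumo"], lv["gap"]))
  invisible(x)
}

#' Dimer Fock/overlap matrices in the tight-binding toy backend
#'
#' Assembles the block dimer Hamiltonian: diagonal blocks are the monomer
#' tight-binding Hamiltonians; off-diagonal elements couple heavy-atom pairs
#' across the dimer with `t(d) = t0 * exp(-eta * (d - d0))` for
#' `d <= d_max`. Overlap is the identity (orthogonal tight binding) unless
#' `overlap_model = TRUE`, which applies the same exponential decay with
#' prefactor `s0` to the intermolecular overlap block.
#'
#' @param mol_a,mol_b [molecule()] records in their crystal-frame positions.
#' @param params see [huckel_params()].
#' @param overlap_model logical; include an exponential intermolecular
#'   overlap block.
#' @return A `dimer_matrices`: `fock`, `overlap`, `block_sizes = c(n_a, n_b)`.
#' @export
huckel_dimer <- function(mol_a, mol_b, params = huckel_params(),
                         overlap_model = FALSE) {
  Ha <- .huckel_h(mol_a, params); Hb <- .huckel_h(mol_b, params)
  na <- nrow(Ha); nb <- nrow(Hb)
  A <- mol_a$coords[.heavy(mol_a), , drop = FALSE]
  B <- mol_b$coords[.heavy(mol_b), , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 0.5))
    stop("overlapping atoms between the two molecules (d < 0.5 Angstrom)")
  Tblk <- ifelse(d <= params$d_max,
                 params$t0 * exp(-params$eta * (d - params$d0)), 0)
  F <- rbind(cbind(Ha, Tblk), cbind(t(Tblk), Hb))
  S <- diag(na + nb)
  if (overlap_model) {
    Sblk <- ifelse(d <= params$d_max,
                   params$s0 * exp(-params$eta * (d - params$d0)), 0)
    S[seq_len(na), na + seq_len(nb)] <- Sblk
    S[na + seq_len(nb), seq_len(na)] <- t(Sblk)
  }
  dimer_matrices(F, S, c(na, nb))
}

#' Construct/validate dimer Fock and overlap matrices
#'
#' @param fock symmetric Fock matrix, eV.
#' @param overlap symmetric positive-definite overlap matrix.
#' @param block_sizes integer 2-vector `c(n_a, n_b)` of monomer basis sizes.
#' @return A `dimer_matrices` object.
#' @export
dimer_matrices <- function(fock, overlap, block_sizes) {
  F <- as.matrix(fock); S <- as.matrix(overlap)
  block_sizes <- as.integer(block_sizes)
  n <- sum(block_sizes)
  if (!all(dim(F) == n) || !all(dim(S) == n))
    stop("matrix dimensions do not equal n_a + n_b = ", n)
  if (max(abs(F - t(F))) > 1e-10) stop("Fock matrix is not symmetric")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("overlap matrix is not positive definite")
  structure(list(fock = F, overlap = S, block_sizes = block_sizes),
            class = "dimer_matrices")
}
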