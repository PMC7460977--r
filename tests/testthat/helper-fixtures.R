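# shared fixtures: all built in code, no data files

rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-300)

# Symmetric planted dimer in which the off-diagonal block couples ONLY the
# frontier orbital pair (strength t). For these systems the half-splitting
# estimate is exact, so DIPRO and splitting_in_dimer must agree to numerical
# precision.
planted_symmetric_dimer <- function(n = 6, t = 0.05,
                                    carrier = "hole", seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  H <- (A + t(A)) / 2
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  C <- eig$vectors[, ord]
  ne <- 2 * floor(n / 2)
  mon <- electronic_structure(eig$values[ord], C, diag(n), ne)
  fidx <- if (carrier == "hole") mon$homo_index else mon$lumo_index
  cf <- C[, fidx]
  Tblk <- t * (cf %o% cf)
  dm <- dimer_matrices(rbind(cbind(H, Tblk), cbind(t(Tblk), H)),
                       diag(2 * n), c(n, n))
  list(dimer = dm, mon = mon, t = t, carrier = carrier)
}

# brute-force O(N^2) dimer scan over an explicit supercell: the oracle for
# enumerate_dimers
brute_force_dimers <- function(structure, cutoff, nimg = 1) {
  structure <- identify_molecules(structure)
  mols <- structure$molecules
  M <- structure$cell$frac_to_cart
  grid <- as.matrix(expand.grid(-nimg:nimg, -nimg:nimg, -nimg:nimg))
  fps <- character(0)
  for (ia in seq_along(mols)) {
    for (ib in seq_along(mols)) {
      for (g in seq_len(nrow(grid))) {
        if (ia == ib && all(grid[g, ] == 0)) next
        tvec <- drop(M %*% grid[g, ])
        mb <- mols[[ib]]
        mb$coords <- sweep(mb$coords, 2, tvec, "+")
        mb$centroid <- colMeans(mb$coords)
        r <- sqrt(sum((mb$centroid - mols[[ia]]$centroid)^2))
        if (r <= cutoff && r > 1e-6)
          fps <- c(fps, dimer_fingerprint(mols[[ia]], mb))
      }
    }
  }
  fps
}

# benzene in a large cube, built as a crystal structure
benzene_crystal <- function(edge = 20, center_frac = c(0.5, 0.5, 0.5)) {
  mol <- acene_template(1)
  cell <- unit_cell(edge, edge, edge)
  cart <- sweep(mol$coords, 2, drop(cell$frac_to_cart %*% center_frac), "+")
  frac <- cart %*% t(cell$cart_to_frac)
  sites <- data.frame(element = mol$elements,
                      fx = frac[, 1] %% 1, fy = frac[, 2] %% 1,
                      fz = frac[, 3] %% 1,
                      x = cart[, 1], y = cart[, 2], z = cart[, 3])
  structure(list(cell = cell, symmetry = list(parse_symop("x, y, z")),
                 sites = sites, molecules = NULL, name = "benzene_box"),
            class = "crystal_structure")
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
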