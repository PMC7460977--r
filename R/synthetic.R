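# Synthetic inputs: toy crystals, displaced-harmonic molecules and planted
# hop networks. Everything here is deterministic given (spec, seed) and
# carries its ground truth, so the physics modules can be tested without any
# external electronic-structure data.

#' Planar acene-like molecule template
#'
#' Builds an idealized linear polycyclic molecule of fused hexagons
#' (C-C bond 1.40 Angstrom, C-H 1.09 Angstrom) in the xy-plane, optionally
#' replacing peripheral CH units by N (aza substitution, hydrogen removed).
#' Default nitrogen patterns are centro-symmetric, mimicking the substitution
#' patterns of crystallographically known azaacenes.
#'
#' @param n_rings number of fused rings (1 = one hexagon).
#' @param n_nitrogens even number of CH units to replace by N.
#' @param pattern optional integer indices into the peripheral CH list
#'   (ordered by x, then y) overriding the default centro-symmetric choice.
#' @return A [molecule()] centered at the origin, long axis along x.
#' @examples
#' acene_template(3)            # anthracene-like
#' acene_template(3, n_nitrogens = 2)
#' @export
acene_template <- function(n_rings, n_nitrogens = 0, pattern = NULL) {
  stopifnot(n_rings >= 1, n_nitrogens %% 2 == 0)
  s <- sqrt(3) / 2 * 1.40  # 1.2124: half hexagon width
  centers <- (seq_len(n_rings) - (n_rings + 1) / 2) * 2 * s
  verts <- NULL
  for (cx in centers)
    verts <- rbind(verts,
                   cbind(cx + c(s, 0, -s, -s, 0, s),
                         c(0.70, 1.40, 0.70, -0.70, -1.40, -0.70)))
  verts <- verts[!duplicated(round(verts, 6)), ]
  nC <- nrow(verts)
  d <- as.matrix(stats::dist(verts))
  adj <- d < 1.45 & d > 0.1
  deg <- rowSums(adj)

  per <- which(deg == 2)  # peripheral CH positions
  per <- per[order(round(verts[per, 1], 6), round(verts[per, 2], 6))]
  if (n_nitrogens > length(per))
    stop("substitution pattern exceeds available peripheral positions")
  if (is.null(pattern)) {
    if (n_nitrogens > 0) {
      # centro-symmetric default: pick upper-half sites nearest the center,
      # then their inversion images
      upper <- per[verts[per, 2] > 0]
      upper <- upper[order(abs(verts[upper, 1]))]
      picks <- upper[seq_len(n_nitrogens / 2)]
      inv <- vapply(picks, function(i) {
        j <- which(colSums(abs(t(verts[per, ]) + verts[i, ])) < 1e-6)
        per[j]
      }, integer(1))
      pattern <- c(picks, inv)
    } else pattern <- integer(0)
  } else {
    pattern <- per[pattern]
  }
  if (anyDuplicated(pattern)) stop("invalid substitution pattern")

  elements <- rep("C", nC)
  elements[pattern] <- "N"
  coords <- cbind(verts, 0)
  # hydrogens on remaining CH sites, pointing away from the two neighbors
  for (i in setdiff(per, pattern)) {
    nb <- which(adj[i, ])
    u <- verts[i, ] - colMeans(verts[nb, , drop = FALSE])
    u <- u / sqrt(sum(u^2))
    elements <- c(elements, "H")
    coords <- rbind(coords, c(verts[i, ] + 1.09 * u, 0))
  }
  coords <- sweep(coords, 2, colMeans(coords))
  molecule(elements, coords)
}

#' Specification of a toy stacked crystal
#'
#' @param n_rings,n_nitrogens,pattern molecule template, see
#'   [acene_template()].
#' @param spacing stacking-axis separation, Angstrom (> 2.8; default 3.5,
#'   a van der Waals pi-stacking distance).
#' @param slip long-axis (x) slip between adjacent layers, Angstrom >= 0.
#' @param padding half-gap between neighboring molecules in the non-stacking
#'   directions, Angstrom. The default 1.2 puts peripheral hydrogens of
#'   adjacent stacks at ~2.4 Angstrom, i.e. in van der Waals contact, as in
#'   a real close-packed molecular crystal; large values isolate the stack.
#' @param herringbone build a two-molecule cell with alternating molecular
#'   tilt instead of a translational stack.
#' @param tilt full tilt angle between the two molecular planes of the
#'   herringbone motif, degrees.
#' @return A `stack_spec` list, input for [make_stack_crystal()].
#' @export
stack_spec <- function(n_rings = 3, n_nitrogens = 0, pattern = NULL,
                       spacing = 3.5, slip = 0, padding = 1.2,
                       herringbone = FALSE, tilt = 50) {
  stopifnot(spacing > 2.8, slip >= 0, padding > 0)
  structure(list(n_rings = n_rings, n_nitrogens = n_nitrogens,
                 pattern = pattern, spacing = spacing, slip = slip,
                 padding = padding, herringbone = herringbone, tilt = tilt),
            class = "stack_spec")
}

#' Build a toy stacked (or herringbone) crystal
#'
#' Face-to-face stack: one molecule per P1 cell, molecular plane xy, stacking
#' along the c axis with optional long-axis slip (a monoclinic cell carries
#' the slip). Herringbone variant: two molecules per cell stacked along c
#' with alternating tilt about the long axis, giving one tilted-contact dimer
#' class and one parallel translation class.
#'
#' @param spec a [stack_spec()].
#' @return A `crystal_structure` with molecules identified; deterministic
#'   given the spec.
#' @examples
#' cr <- make_stack_crystal(stack_spec(n_rings = 2, spacing = 3.5))
#' dimer_table(enumerate_dimers(cr, cutoff = 4))
#' @export
make_stack_crystal <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  mol <- acene_template(spec$n_rings, spec$n_nitrogens, spec$pattern)
  ext <- apply(mol$coords, 2, function(v) diff(range(v)))
  a_len <- ext[1] + 2 * spec$padding
  b_len <- ext[2] + 2 * spec$padding

  if (!spec$herringbone) {
    c_len <- sqrt(spec$slip^2 + spec$spacing^2)
    beta <- acos(spec$slip / c_len) * 180 / pi
    cell <- unit_cell(a_len, b_len, c_len, 90, beta, 90)
    mols <- list(mol)
  } else {
    cell <- unit_cell(a_len, b_len, 2 * spec$spacing, 90, 90, 90)
    th <- spec$tilt / 2 * pi / 180
    rotx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t),
                                 0, sin(t), cos(t)), 3, byrow = TRUE)
    mols <- list(.transform_molecule(mol, rotx(th)),
                 .transform_molecule(mol, rotx(-th),
                                     t = c(0, 0, spec$spacing)))
  }
  center <- drop(cell$frac_to_cart %*% c(0.5, 0.5, 0))
  sites_el <- character(0); sites_cart <- NULL
  for (m in mols) {
    sites_el <- c(sites_el, m$elements)
    sites_cart <- rbind(sites_cart, sweep(m$coords, 2, center, "+"))
  }
  d2 <- as.matrix(stats::dist(sites_cart))
  if (any(d2[upper.tri(d2)] < 0.8))
    stop("stack spec produces clashing atoms")
  frac <- cart_to_frac(cell, sites_cart)
  sites <- data.frame(element = sites_el,
                      fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                      x = sites_cart[, 1], y = sites_cart[, 2],
                      z = sites_cart[, 3], stringsAsFactors = FALSE)
  cr <- structure(list(cell = cell, symmetry = list(parse_symop("x, y, z")),
                       sites = sites, molecules = NULL,
                       name = sprintf("toy_stack_%dring_%dN%s",
                                      spec$n_rings, spec$n_nitrogens,
                                      if (spec$herringbone) "_hb" else "")),
                  class = "crystal_structure")
  identify_molecules(cr)
}

#' Displaced-harmonic molecular model with known reorganization energy
#'
#' Generates a synthetic molecule whose neutral and charged geometries differ
#' by a planted displacement along orthonormal, rigid-body-free normal modes,
#' together with consistent four-point energies and the mode set. Ground
#' truth: `lambda_true = sum(0.5 * k_f * delta^2)` with the planted per-mode
#' contributions attached; the four-point record splits `lambda_true` equally
#' between its two relaxation components (the equal-curvature convention), so
#' [lambda_four_point()] and the summed [normal_mode_decomposition()] both
#' recover `lambda_true` exactly.
#'
#' @param n_modes number of displaced modes.
#' @param force_constants per-mode force constants, eV/Angstrom^2 (recycled).
#' @param displacements per-mode displacements, Angstrom (recycled).
#' @param mass atom mass, amu (one value; default 12, carbon-like).
#' @param seed integer seed controlling the random reference geometry and
#'   mode directions.
#' @return List: `fourpoint` ([four_point_energies()]), `modes`
#'   ([normal_mode_set()]), `neutral_geom`, `charged_geom` (n x 3 matrices),
#'   `lambda_true` (eV), `lambda_i_true` (per mode, eV).
#' @export
make_displaced_harmonic <- function(n_modes = 2, force_constants = 1,
                                    displacements = 0.5, mass = 12,
                                    seed = 1) {
  stopifnot(n_modes >= 1, all(force_constants > 0))
  kf <- rep_len(force_constants, n_modes)
  dd <- rep_len(displacements, n_modes)
  n_atoms <- max(4L, ceiling((n_modes + 6) / 3) + 1L)
  masses <- rep(mass, n_atoms)

  set.seed(seed)
  x0 <- matrix(stats::rnorm(3 * n_atoms, sd = 2.0), ncol = 3)
  x0 <- .eckart_shift(x0, masses)

  rigid <- .rigid_body_basis(x0, masses)
  raw <- matrix(stats::rnorm(3 * n_atoms * n_modes), ncol = n_modes)
  raw <- raw - rigid %*% (t(rigid) %*% raw)
  L <- qr.Q(qr(raw))[, seq_len(n_modes), drop = FALSE]

  # mode curvature kappa = k_f / mass  ->  wavenumber
  omega <- .kappa_to_wavenumber(kf / mass)
  modes <- normal_mode_set(omega, L, masses)

  dq <- sqrt(mass) * dd                       # planted mass-weighted shifts
  disp_mw <- L %*% dq
  disp_cart <- matrix(disp_mw / rep(sqrt(masses), each = 3),
                      ncol = 3, byrow = TRUE)
  x1 <- x0 + disp_cart

  lambda_i <- 0.5 * kf * dd^2
  lambda_true <- sum(lambda_i)
  fp <- four_point_energies(E_N = 0, E_N_star = lambda_true / 2,
                            E_C = 5.0, E_C_star = 5.0 + lambda_true / 2)
  list(fourpoint = fp, modes = modes,
       neutral_geom = x0, charged_geom = x1,
       lambda_true = lambda_true, lambda_i_true = lambda_i)
}

# orthonormal mass-weighted rigid-body basis (3 translations + rotations)
.rigid_body_basis <- function(x0, masses) {
  n <- nrow(x0)
  ms <- rep(sqrt(masses), each = 3)
  B <- matrix(0, 3 * n, 6)
  for (k in 1:3) B[seq(k, 3 * n, by = 3), k] <- sqrt(masses)
  com <- colSums(x0 * masses) / sum(masses)
  xc <- sweep(x0, 2, com)
  axes <- diag(3)
  for (k in 1:3) {
    g <- t(apply(xc, 1, function(r) .cross(axes[k, ], r)))
    B[, 3 + k] <- as.vector(t(g)) * ms
  }
  Q <- qr(B)
  qr.Q(Q)[, seq_len(Q$rank), drop = FALSE]
}

#' Planted hop-network specifications
#'
#' `planted_chain()` gives the two opposite nearest neighbors of a 1D stack;
#' `planted_cubic()` the six neighbors of a simple cubic lattice;
#' `planted_anisotropic()` a quasi-one-dimensional network: a strong stack
#' channel plus weak side channels (default side coupling 20 meV, the regime
#' where transport is quasi- rather than strictly one-dimensional);
#' `planted_random()` draws a random direction set for stress tests.
#'
#' @param r hop distance, Angstrom.
#' @param J,J_stack,J_side transfer integrals, eV.
#' @param lambda reorganization energy, eV.
#' @param T temperature, K.
#' @param delta_e site-energy difference, eV.
#' @param n_dirs,seed direction count and seed for the random network.
#' @return A `planted_network` list: `hops` data.frame (rx, ry, rz, J,
#'   delta_e), `lambda`, `T`.
#' @name planted_networks
NULL

.planted <- function(hops, lambda, T) {
  structure(list(hops = hops, lambda = lambda, T = T),
            class = "planted_network")
}

#' @rdname planted_networks
#' @export
planted_chain <- function(r = 4, J = 0.05, lambda = 0.2, T = 300,
                          delta_e = 0) {
  .planted(data.frame(rx = 0, ry = 0, rz = c(r, -r), J = J,
                      delta_e = delta_e), lambda, T)
}

#' @rdname planted_networks
#' @export
planted_cubic <- function(r = 4, J = 0.05, lambda = 0.2, T = 300) {
  d <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)) * r
  .planted(data.frame(rx = d[, 1], ry = d[, 2], rz = d[, 3], J = J,
                      delta_e = 0), lambda, T)
}

#' @rdname planted_networks
#' @export
planted_anisotropic <- function(r = 3.5, J_stack = 0.1, J_side = 0.020,
                                lambda = 0.2, T = 300) {
  d <- rbind(c(0, 0, r), c(0, 0, -r),
             c(r, 0, 0), c(-r, 0, 0), c(0, r, 0), c(0, -r, 0))
  .planted(data.frame(rx = d[, 1], ry = d[, 2], rz = d[, 3],
                      J = c(J_stack, J_stack, rep(J_side, 4)),
                      delta_e = 0), lambda, T)
}

#' @rdname planted_networks
#' @export
planted_random <- function(n_dirs = 6, seed = 1, lambda = 0.2, T = 300) {
  set.seed(seed)
  # symmetric direction set (+/- pairs) with random lengths and couplings
  n <- ceiling(n_dirs / 2)
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * stats::runif(n, 3, 8)
  J <- stats::runif(n, 0.005, 0.12)
  d <- rbind(u, -u)
  .planted(data.frame(rx = d[, 1], ry = d[, 2], rz = d[, 3],
                      J = rep(J, 2), delta_e = 0), lambda, T)
}

#' Build hop specifications from a planted network
#'
#' @param spec a `planted_network` from one of the [planted_networks]
#'   constructors, or an equivalent list.
#' @return List of [hop_spec()], one per planted direction
#'   (multiplicity 1 each: directions are explicit).
#' @export
make_planted_network <- function(spec) {
  stopifnot(!is.null(spec$hops), !is.null(spec$lambda), !is.null(spec$T))
  h <- spec$hops
  lapply(seq_len(nrow(h)), function(i)
    hop_spec(J = h$J[i], lambda = spec$lambda,
             delta_e = if (is.null(h$delta_e)) 0 else h$delta_e[i],
             T = spec$T, r_vec = c(h$rx[i], h$ry[i], h$rz[i])))
}
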