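test_that("a single carbon gives one orbital at alpha_C", {
  m <- molecule("C", matrix(0, 1, 3))
  # one pi electron is open shell; the ionized (empty) system carries the
  # same one-orbital spectrum
  expect_error(huckel_monomer(m), "open-shell")
  es <- huckel_monomer(m, n_electrons = 0)
  expect_equal(es$orbital_energies, huckel_params()$alpha_C)
})

test_that("the benzene ring reproduces the closed-form ring spectrum", {
  p <- huckel_params()
  es <- huckel_monomer(acene_template(1))
  # beta < 0: levels alpha + 2beta, alpha + beta (x2), alpha - beta (x2),
  # alpha - 2beta
  want <- sort(p$alpha_C + p$beta * c(2, 1, 1, -1, -1, -2))
  expect_equal(es$orbital_energies, want, tolerance = 1e-12)
  lv <- frontier_levels(es)
  expect_equal(unname(lv["gap"]), 2 * abs(p$beta), tolerance = 1e-12)
})

test_that("odd pi-electron counts are rejected as open shell", {
  m <- molecule(c("C", "C", "C"),
                rbind(c(0, 0, 0), c(1.4, 0, 0), c(2.8, 0, 0)))
  expect_error(huckel_monomer(m), "open-shell")
})

test_that("nitrogen substitution lowers the LUMO", {
  lumo <- vapply(c(0, 2, 4), function(nn)
    frontier_levels(huckel_monomer(acene_template(3, nn)))["lumo"],
    numeric(1))
  expect_true(all(diff(lumo) < 0))
})

test_that("the monomer spectrum is invariant under rigid motion", {
  m <- acene_template(2, 2)
  e0 <- huckel_monomer(m)$orbital_energies
  for (seed in 1:3) {
    R <- random_rotation(seed)
    m2 <- m
    m2$coords <- sweep(m$coords %*% t(R), 2, c(1, 2, 3), "+")
    expect_equal(huckel_monomer(m2)$orbital_energies, e0, tolerance = 1e-9)
  }
})

test_that("the intermolecular hopping follows the exponential decay law", {
  p <- huckel_params()
  atom <- function(z) molecule("C", matrix(c(0, 0, z), 1))
  # two single-atom molecules at d0: coupling is exactly t0
  dm <- huckel_dimer(atom(0), atom(p$d0))
  expect_equal(dm$fock[1, 2], p$t0, tolerance = 1e-14)
  # t halves every ln(2)/eta Angstrom
  half <- log(2) / p$eta
  d1 <- huckel_dimer(atom(0), atom(p$d0 + half))$fock[1, 2]
  expect_equal(d1, p$t0 / 2, tolerance = 1e-12)
  # direct formula evaluation over a grid
  for (d in seq(3.0, 5.5, by = 0.5))
    expect_equal(huckel_dimer(atom(0), atom(d))$fock[1, 2],
                 p$t0 * exp(-p$eta * (d - p$d0)), tolerance = 1e-12)
  # beyond d_max: zero
  expect_equal(huckel_dimer(atom(0), atom(p$d_max + 0.1))$fock[1, 2], 0)
  # far-apart monomers: whole off-diagonal block zero
  cr <- make_stack_crystal(stack_spec(n_rings = 1, padding = 8))
  m <- identify_molecules(cr)$molecules[[1]]
  far <- m
  far$coords <- sweep(m$coords, 2, c(0, 0, 100), "+")
  dmf <- huckel_dimer(m, far)
  n <- dmf$block_sizes[1]
  expect_true(all(dmf$fock[seq_len(n), n + seq_len(n)] == 0))
  # clashing atoms rejected
  expect_error(huckel_dimer(atom(0), atom(0.2)), "overlap")
})

test_that("orbitals satisfy the generalized eigenproblem FC = SCe", {
  cr <- make_stack_crystal(stack_spec(n_rings = 2, n_nitrogens = 2))
  p <- enumerate_dimers(cr, cutoff = 4)[[1]]
  for (ov in c(FALSE, TRUE)) {
    dm <- huckel_dimer(p$mol_a, p$mol_b, overlap_model = ov)
    es <- eigen(dm$overlap, symmetric = TRUE)
    Sm12 <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
    eg <- eigen(Sm12 %*% dm$fock %*% Sm12, symmetric = TRUE)
    C <- Sm12 %*% eg$vectors
    resid <- dm$fock %*% C - dm$overlap %*% C %*% diag(eg$values)
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("adapter files round-trip and validate", {
  # hand-written 2x2 dimer file
  tf <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("#kind fock", "#dim 2 2", "#blocks 1 1",
               "-6.0 0.05", "0.05 -6.0",
               "#kind overlap", "#dim 2 2", "1 0", "0 1"), tf)
  dm <- load_external_matrices(tf)
  expect_s3_class(dm, "dimer_matrices")
  expect_equal(dm$fock[1, 2], 0.05)

  # writer round trip: dimer matrices
  cr <- make_stack_crystal(stack_spec(n_rings = 1))
  p <- enumerate_dimers(cr, cutoff = 4)[[1]]
  dm0 <- huckel_dimer(p$mol_a, p$mol_b)
  tf2 <- withr::local_tempfile(fileext = ".dat")
  write_external_matrices(dm0, tf2)
  dm1 <- load_external_matrices(tf2)
  expect_equal(dm1$fock, dm0$fock, tolerance = 1e-14)
  expect_equal(dm1$block_sizes, dm0$block_sizes)

  # writer round trip: four-point energies and monomer result
  fp0 <- four_point_energies(-100.0, -99.75, -95.5, -95.3)
  tf3 <- withr::local_tempfile(fileext = ".dat")
  write_external_matrices(fp0, tf3)
  fp1 <- load_external_matrices(tf3)
  expect_equal(fp1$E_C_star, fp0$E_C_star, tolerance = 1e-14)

  es0 <- huckel_monomer(acene_template(1))
  tf4 <- withr::local_tempfile(fileext = ".dat")
  write_external_matrices(es0, tf4)
  es1 <- load_external_matrices(tf4)
  expect_equal(es1$orbital_energies, es0$orbital_energies, tolerance = 1e-14)
  expect_equal(es1$homo_index, es0$homo_index)
})

test_that("corrupted adapter input fails with a validation error", {
  tf <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("#kind fock", "#dim 3 3", "#blocks 1 1",
               "-6.0 0.05", "0.05 -6.0"), tf)   # wrong dimension header
  expect_error(load_external_matrices(tf), "dim")

  tf2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("#kind fock", "#dim 2 2", "#blocks 1 1",
               "-6.0 0.5", "0.05 -6.0",          # asymmetric
               "#kind overlap", "#dim 2 2", "1 0", "0 1"), tf2)
  expect_error(load_external_matrices(tf2), "symmetric")

  tf3 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("#kind fock", "#dim 2 2", "#blocks 1 1",
               "-6.0 0.05", "0.05 -6.0",
               "#kind overlap", "#dim 2 2", "1 2", "2 1"), tf3)
  expect_error(load_external_matrices(tf3), "positive definite")
})

test_that("a Cartesian Hessian yields a valid normal-mode set", {
  # two uncoupled unit-mass-like oscillators along x embedded in 3N space
  n_at <- 4
  masses <- c(12, 12, 1, 1)
  k <- c(4, 9)
  H <- matrix(0, 3 * n_at, 3 * n_at)
  H[1, 1] <- k[1]; H[4, 4] <- k[2]
  tf <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("#kind hessian",
               sprintf("#dim %d %d", 3 * n_at, 3 * n_at),
               apply(H, 1, function(r) paste(sprintf("%.17g", r),
                                             collapse = " ")),
               "#kind masses", sprintf("#dim 1 %d", n_at),
               paste(masses, collapse = " ")), tf)
  nm <- load_external_matrices(tf)
  expect_s3_class(nm, "normal_mode_set")
  expect_length(nm$frequencies, 2L)
  # frequencies scale as sqrt(k/m): ratio sqrt(9/4) = 1.5
  expect_equal(nm$frequencies[2] / nm$frequencies[1], 1.5, tolerance = 1e-9)
})
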