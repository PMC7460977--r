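test_that("a one-atom P1 CIF parses to the expected Cartesian site", {
  tf <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_onesite",
               "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
               "_cell_angle_alpha 90", "_cell_angle_beta 90",
               "_cell_angle_gamma 90",
               "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
               "C1 C 0.5 0.5 0.5"), tf)
  cr <- read_cif(tf)
  expect_equal(nrow(cr$sites), 1L)
  expect_equal(unname(unlist(cr$sites[1, c("x", "y", "z")])), c(5, 5, 5),
               tolerance = 1e-12)
})

test_that("CIF writer round-trips cells and coordinates to 1e-6 A", {
  for (spec in list(stack_spec(n_rings = 2),
                    stack_spec(n_rings = 2, spacing = 3.6, slip = 1.5))) {
    cr <- make_stack_crystal(spec)
    tf <- withr::local_tempfile(fileext = ".cif")
    write_cif(cr, tf)
    rt <- read_cif(tf)
    expect_lt(max(abs(c(rt$cell$a - cr$cell$a, rt$cell$b - cr$cell$b,
                        rt$cell$c - cr$cell$c,
                        rt$cell$beta - cr$cell$beta))), 1e-6)
    expect_lt(max(abs(as.matrix(rt$sites[, c("x", "y", "z")]) -
                      as.matrix(cr$sites[, c("x", "y", "z")]))), 1e-6)
  }
})

test_that("symmetry operation strings parse to the correct affine maps", {
  op <- parse_symop("-x, y+1/2, -z+1/2")
  expect_equal(unname(op$rotation), diag(c(-1, 1, -1)))
  expect_equal(unname(op$translation), c(0, 0.5, 0.5))
  # string-parse oracle: apply the op to test points and compare with the
  # literal arithmetic of the expression
  pts <- rbind(c(0.1, 0.2, 0.3), c(-0.4, 0.9, 0.05))
  got <- apply_literal <- cbind(-pts[, 1], pts[, 2] + 0.5, -pts[, 3] + 0.5)
  expect_equal(unname(apply_symop(op, pts)), got, tolerance = 1e-12)
  expect_error(parse_symop("x, y"), "three")
  expect_error(parse_symop("x, y, q"), "unparseable|object")
})

test_that("missing cell block and disorder are rejected", {
  tf <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_bad", "loop_", "_atom_site_fract_x", "0.5"), tf)
  expect_error(read_cif(tf), "cell")
  tf2 <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_dis",
               "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
               "loop_", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y",
               "_atom_site_fract_z", "_atom_site_occupancy",
               "C 0.5 0.5 0.5 0.5", "N 0.5 0.5 0.5 0.5"), tf2)
  expect_error(read_cif(tf2), "occupanc|disorder")
  expect_equal(nrow(read_cif(tf2, keep_partial_occupancy = TRUE)$sites), 2L)
})

test_that("isolated atoms become one molecule each", {
  cell <- unit_cell(30, 30, 30)
  cart <- rbind(c(5, 5, 5), c(15, 15, 15), c(25, 25, 25))
  frac <- cart %*% t(cell$cart_to_frac)
  cr <- structure(list(cell = cell, symmetry = list(parse_symop("x, y, z")),
                       sites = data.frame(element = c("C", "C", "N"),
                                          fx = frac[, 1], fy = frac[, 2],
                                          fz = frac[, 3], x = cart[, 1],
                                          y = cart[, 2], z = cart[, 3]),
                       molecules = NULL, name = "atoms"),
                  class = "crystal_structure")
  cr <- identify_molecules(cr)
  expect_length(cr$molecules, 3L)
  expect_true(all(vapply(cr$molecules, function(m) length(m$elements),
                         integer(1)) == 1L))
})

test_that("benzene in a 20 A box is one molecule with 12 atoms and 12 bonds", {
  cr <- identify_molecules(benzene_crystal())
  expect_length(cr$molecules, 1L)
  m <- cr$molecules[[1]]
  expect_length(m$elements, 12L)
  expect_equal(nrow(m$bonds), 12L)
})

test_that("a molecule wrapped across the cell boundary is reassembled", {
  cr <- identify_molecules(benzene_crystal(edge = 8, center_frac = c(0, 0, 0)))
  expect_length(cr$molecules, 1L)
  m <- cr$molecules[[1]]
  bl <- apply(m$bonds, 1, function(b)
    sqrt(sum((m$coords[b[1], ] - m$coords[b[2], ])^2)))
  expect_lt(max(bl), 1.8)
})

test_that("dimer enumeration matches construction and the brute-force scan", {
  # isolated molecule: no dimers
  iso <- benzene_crystal(edge = 50)
  expect_length(enumerate_dimers(iso, cutoff = 10), 0L)

  # 1D stack, spacing 4, cutoff 5: one unique dimer, multiplicity 2, r = 4
  cr <- make_stack_crystal(stack_spec(n_rings = 2, spacing = 4,
                                      padding = 8))
  dd <- enumerate_dimers(cr, cutoff = 5)
  expect_length(dd, 1L)
  expect_equal(dd[[1]]$multiplicity, 2)
  expect_equal(dd[[1]]$r, 4, tolerance = 1e-9)

  # brute-force O(N^2) supercell oracle agrees on classes and counts
  for (spec in list(stack_spec(n_rings = 2),
                    stack_spec(n_rings = 2, slip = 1.5),
                    stack_spec(n_rings = 1, spacing = 4,
                               herringbone = TRUE))) {
    cr <- make_stack_crystal(spec)
    cutoff <- 8
    dd <- enumerate_dimers(cr, cutoff = cutoff)
    fps <- brute_force_dimers(cr, cutoff, nimg = 3)
    expect_setequal(vapply(dd, function(p) p$fingerprint, character(1)),
                    unique(fps))
    got <- sort(vapply(dd, function(p)
      as.numeric(p$multiplicity), numeric(1)) *
        length(cr$molecules))
    expect_equal(got, sort(as.numeric(table(fps))), ignore_attr = TRUE)
  }
})

test_that("herringbone toy yields two distinct contact classes", {
  hb <- make_stack_crystal(stack_spec(n_rings = 2, spacing = 4,
                                      herringbone = TRUE, padding = 8))
  dd <- enumerate_dimers(hb, cutoff = 8.5)
  expect_length(dd, 2L)
})

test_that("fingerprints are invariant under swap and rigid motion", {
  cr <- make_stack_crystal(stack_spec(n_rings = 2, slip = 1.0))
  p <- enumerate_dimers(cr, cutoff = 4.5)[[1]]
  expect_identical(dimer_fingerprint(p$mol_a, p$mol_b),
                   dimer_fingerprint(p$mol_b, p$mol_a))
  for (seed in 1:5) {
    R <- random_rotation(seed)
    t <- c(seed, -2 * seed, 0.5)
    ma <- p$mol_a; mb <- p$mol_b
    ma$coords <- sweep(ma$coords %*% t(R), 2, t, "+")
    mb$coords <- sweep(mb$coords %*% t(R), 2, t, "+")
    expect_identical(dimer_fingerprint(ma, mb), p$fingerprint)
  }
})

test_that("translation-equivalent pairs merge with summed multiplicity", {
  cr <- make_stack_crystal(stack_spec(n_rings = 1, padding = 8))
  cr <- identify_molecules(cr)
  m <- cr$molecules[[1]]
  up <- m; up$coords <- sweep(m$coords, 2, c(0, 0, 3.5), "+")
  up$centroid <- colMeans(up$coords)
  dn <- m; dn$coords <- sweep(m$coords, 2, c(0, 0, -3.5), "+")
  dn$centroid <- colMeans(dn$coords)
  pairs <- list(hopcrystal:::.dimer_pair(m, up),
                hopcrystal:::.dimer_pair(m, dn))
  merged <- deduplicate_dimers(pairs)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$multiplicity, 2)
})
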