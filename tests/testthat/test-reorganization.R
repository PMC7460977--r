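test_that("identical geometries give zero reorganization energy", {
  fp <- four_point_energies(0, 0, 5, 5)
  expect_equal(lambda_four_point(fp, "hole")$lambda_total, 0)
  fx <- make_displaced_harmonic(n_modes = 2, displacements = 0, seed = 2)
  expect_equal(fx$lambda_true, 0)
  mc <- normal_mode_decomposition(fx$neutral_geom, fx$charged_geom, fx$modes)
  expect_equal(attr(mc, "lambda_total"), 0, tolerance = 1e-14)
})

test_that("the four-point scheme adds the two relaxation components", {
  # minima displaced by delta on two equal-curvature parabolas: each
  # component is k*delta^2/2, the total k*delta^2
  k <- 2.0; delta <- 0.3
  fp <- four_point_energies(E_N = 0, E_N_star = k * delta^2 / 2,
                            E_C = 5, E_C_star = 5 + k * delta^2 / 2)
  lam <- lambda_four_point(fp, "electron")
  expect_equal(lam$lambda_total, k * delta^2, tolerance = 1e-14)
  expect_equal(unname(lam$components),
               rep(k * delta^2 / 2, 2), tolerance = 1e-14)
  # an out-of-order input (geometry not optimal for its state) is rejected
  expect_error(four_point_energies(0, -0.1, 5, 5.2), "optimum")
})

test_that("the displaced-harmonic fixture is exactly recovered", {
  # frozen single-mode example: k_f = 1 eV/A^2, delta = 0.5 A
  fx <- make_displaced_harmonic(n_modes = 1, force_constants = 1,
                                displacements = 0.5, seed = 11)
  expect_equal(fx$lambda_true, 0.125)
  expect_equal(lambda_four_point(fx$fourpoint, "hole")$lambda_total, 0.125,
               tolerance = 1e-14)
  mc <- normal_mode_decomposition(fx$neutral_geom, fx$charged_geom, fx$modes)
  expect_equal(attr(mc, "lambda_total"), 0.125, tolerance = 1e-10)

  # plant-and-recover on multi-mode random specs
  for (seed in 1:5) {
    set.seed(seed + 100)
    nm <- sample(2:5, 1)
    kf <- runif(nm, 0.5, 4)
    dd <- runif(nm, 0.05, 0.6)
    fx <- make_displaced_harmonic(nm, kf, dd, seed = seed)
    expect_equal(sum(fx$lambda_i_true), fx$lambda_true, tolerance = 1e-12)
    mc <- normal_mode_decomposition(fx$neutral_geom, fx$charged_geom,
                                    fx$modes)
    expect_equal(sort(mc$lambda), sort(fx$lambda_i_true),
                 tolerance = 1e-10)
    expect_lt(rel_diff(attr(mc, "lambda_total"),
                       lambda_four_point(fx$fourpoint, "hole")$lambda_total),
              1e-8)
  }
})

test_that("lambda is invariant under rigid motion of either geometry", {
  fx <- make_displaced_harmonic(3, c(1, 2, 0.7), c(0.3, 0.1, 0.4), seed = 4)
  lam0 <- attr(normal_mode_decomposition(fx$neutral_geom, fx$charged_geom,
                                         fx$modes), "lambda_total")
  for (seed in 1:4) {
    R <- random_rotation(seed)
    shift <- c(seed, -seed, 2)
    xC <- sweep(fx$charged_geom %*% t(R), 2, shift, "+")
    lam <- attr(normal_mode_decomposition(fx$neutral_geom, xC, fx$modes),
                "lambda_total")
    expect_equal(lam, lam0, tolerance = 1e-9)
  }
})

test_that("alignment is enforced when disabled", {
  fx <- make_displaced_harmonic(2, 1, 0.3, seed = 5)
  xC <- sweep(fx$charged_geom, 2, c(1, 0, 0), "+")  # net translation
  expect_error(normal_mode_decomposition(fx$neutral_geom, xC, fx$modes,
                                         align = FALSE), "alignment|Eckart")
  expect_error(normal_mode_decomposition(fx$neutral_geom,
                                         fx$charged_geom[-1, ], fx$modes),
               "mismatch")
})

test_that("Huang-Rhys factors obey the wavenumber conversion identity", {
  fx <- make_displaced_harmonic(2, c(1, 3), c(0.2, 0.4), seed = 6)
  mc <- normal_mode_decomposition(fx$neutral_geom, fx$charged_geom, fx$modes)
  hc_eVcm <- 1.239841984e-4
  expect_equal(mc$huang_rhys, mc$lambda / (hc_eVcm * mc$omega),
               tolerance = 1e-12)
  # independent arithmetic: a mode at 1000 cm^-1 with S = 1 carries
  # lambda = hbar*omega ~ 124 meV
  conv <- 0.5 * (2 * pi * 2.99792458e10)^2 * 1.66053906660e-27 * 1e-20 /
    1.602176634e-19
  dq_s1 <- sqrt(hc_eVcm * 1000 / (conv * 1000^2))
  masses <- rep(1, 4)
  L <- matrix(0, 12, 1); L[1, 1] <- 1
  nm <- normal_mode_set(1000, L, masses)
  x0 <- matrix(rnorm(12), ncol = 3)
  x1 <- x0
  x1[1, 1] <- x1[1, 1] + dq_s1
  mc1 <- normal_mode_decomposition(x0, x1, nm, align = FALSE,
                                   eckart_tol = Inf)
  expect_equal(mc1$lambda, hc_eVcm * 1000, tolerance = 1e-6)
  expect_equal(mc1$huang_rhys, 1, tolerance = 1e-6)
})

test_that("the Raman I/omega proxy report behaves as planted", {
  fx <- make_displaced_harmonic(6, seq(0.5, 3, length.out = 6),
                                c(0.3, 0.5, 0.1, 0.25, 0.05, 0.4), seed = 7)
  mc <- normal_mode_decomposition(fx$neutral_geom, fx$charged_geom, fx$modes)
  # intensities proportional to lambda_i * omega_i -> proxy = lambda_i
  rl <- raman_lines(mc$omega, 7.5 * mc$lambda * mc$omega)
  rep1 <- raman_proxy_report(mc, rl)
  expect_equal(rep1$rank_correlation, 1)
  expect_equal(nrow(rep1$table), 6L)

  # the two largest-lambda modes also carry the largest I/omega
  top_lambda <- order(-rep1$table$lambda)[1:2]
  top_proxy <- order(-rep1$table$proxy)[1:2]
  expect_setequal(top_lambda, top_proxy)

  # random intensities: near-zero mean correlation over seeds
  cors <- vapply(1:40, function(s) {
    set.seed(s)
    rr <- raman_proxy_report(mc, raman_lines(mc$omega, runif(6)))
    rr$rank_correlation
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.25)

  # unmatched lines are reported, not dropped
  rl2 <- raman_lines(c(mc$omega[-1], max(mc$omega) + 500),
                     rep(1, length(mc$omega)))
  rep2 <- raman_proxy_report(mc, rl2)
  expect_length(rep2$unmatched_modes, 1L)
  expect_length(rep2$unmatched_lines, 1L)
})
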