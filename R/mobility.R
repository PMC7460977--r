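#' Hop specification
#'
#' One directed charge-transfer channel from a central molecule to a
#' neighbor: electronic coupling, reorganization energy, site-energy
#' difference, temperature, hop vector and symmetry multiplicity.
#'
#' @param J transfer integral, eV.
#' @param lambda reorganization energy, eV, > 0.
#' @param delta_e site-energy difference `E_initial - E_final`, eV (0 for
#'   identical molecules); positive (downhill) values accelerate hopping.
#' @param T temperature, K, > 0.
#' @param r_vec hop vector (centroid to centroid), Angstrom.
#' @param multiplicity number of symmetry-equivalent channels with this
#'   geometry around one central molecule.
#' @return A `hop_spec` object.
#' @export
hop_spec <- function(J, lambda, delta_e = 0, T = 300,
                     r_vec = c(0, 0, 0), multiplicity = 1L) {
  stopifnot(lambda > 0, T > 0, multiplicity >= 1, length(r_vec) == 3)
  structure(list(J = J, lambda = lambda, delta_e = delta_e, T = T,
                 r_vec = as.numeric(r_vec),
                 multiplicity = as.integer(multiplicity)),
            class = "hop_spec")
}

#' Marcus charge-hop rate
#'
#' Semiclassical nonadiabatic hop rate
#' `k = (2 pi / hbar) J^2 (4 pi lambda k_B T)^(-1/2)
#'      exp(-(delta_e - lambda)^2 / (4 lambda k_B T))`,
#' with `delta_e = E_initial - E_final`, so the forward/backward ratio obeys
#' detailed balance `k(delta_e)/k(-delta_e) = exp(delta_e / k_B T)` and the
#' rate is maximal at `delta_e = lambda`.
#'
#' @param spec a [hop_spec()]; alternatively pass `J`, `lambda`, `delta_e`,
#'   `T` directly.
#' @param J,lambda,delta_e,T scalar shortcut arguments (eV, eV, eV, K) used
#'   when `spec` is missing; `J` and `lambda` may be vectors.
#' @return Hop rate(s) in 1/s.
#' @examples
#' marcus_rate(J = 0.1, lambda = 0.2, delta_e = 0, T = 300)  # ~5.4e13 /s
#' @export
marcus_rate <- function(spec, J, lambda, delta_e = 0, T = 300) {
  if (!missing(spec) && inherits(spec, "hop_spec")) {
    J <- spec$J; lambda <- spec$lambda; delta_e <- spec$delta_e; T <- spec$T
  } else if (!missing(spec) && missing(J)) {
    stop("pass a hop_spec or named J/lambda/delta_e/T arguments")
  }
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(T <= 0)) stop("temperature must be > 0")
  kbt <- .const$kB_eVK * T
  (2 * pi / .const$hbar_eVs) * J^2 / sqrt(4 * pi * lambda * kbt) *
    exp(-(delta_e - lambda)^2 / (4 * lambda * kbt))
}

#' Diffusion tensor and mobility from a hop network
#'
#' Assembles the charge diffusion coefficient by summation over all transport
#' directions around one central molecule. Default `"msd"` convention is the
#' exact mean-square-displacement tensor of the Markovian hop process,
#' `D = 1/2 sum_i m_i k_i (r_i (x) r_i)` (validated against the kinetic
#' Monte Carlo oracle, [simulate_random_walk()]); the literature-common
#' `"rate-weighted"` option reports the isotropic
#' `D = 1/6 sum_i m_i r_i^2 k_i P_i` with `P_i = k_i / sum_j m_j k_j`.
#' Mobility follows from the Einstein-Smoluchowski relation via
#' [einstein_mobility()].
#'
#' @param hops list of [hop_spec()] sharing one temperature; each entry's
#'   `multiplicity` expands it into its symmetry-equivalent directions.
#' @param convention `"msd"` (default) or `"rate-weighted"`.
#' @param carrier label recorded in the report.
#' @return A `mobility_report`: `per_direction` table (r_vec, r in Angstrom,
#'   J in meV, k in 1/s, P), `D_tensor` (3x3, cm^2/s), `D_iso` (cm^2/s),
#'   `mu` (cm^2/V/s), `temperature`, `carrier`, `convention`.
#' @examples
#' ch <- make_planted_network(planted_chain(r = 4, J = 0.05))
#' hopping_diffusion(ch)$D_iso
#' @export
hopping_diffusion <- function(hops, convention = c("msd", "rate-weighted"),
                              carrier = "hole") {
  convention <- match.arg(convention)
  if (!length(hops)) {
    warning("empty hop list: D = 0")
    return(.mobility_report(data.frame(), matrix(0, 3, 3), 0, 300,
                            carrier, convention))
  }
  stopifnot(all(vapply(hops, inherits, logical(1), "hop_spec")))
  Tset <- unique(vapply(hops, function(h) h$T, numeric(1)))
  if (length(Tset) != 1L) stop("hops carry mixed temperatures")
  T <- Tset

  k <- vapply(hops, marcus_rate, numeric(1))
  m <- vapply(hops, function(h) as.numeric(h$multiplicity), numeric(1))
  R <- t(vapply(hops, function(h) h$r_vec, numeric(3)))
  r2 <- rowSums(R^2)
  ktot <- sum(m * k)
  P <- if (ktot > 0) m * k / ktot else rep(0, length(k))

  A2_to_cm2 <- 1e-16
  D_tensor <- matrix(0, 3, 3)
  for (i in seq_along(hops))
    D_tensor <- D_tensor + 0.5 * m[i] * k[i] * (R[i, ] %o% R[i, ])
  D_tensor <- D_tensor * A2_to_cm2
  # rate-weighted: per-channel hop probability is k_i/ktot; a dimer class
  # with multiplicity m contributes m such channels
  D_iso <- switch(convention,
    "msd" = sum(diag(D_tensor)) / 3,
    "rate-weighted" = if (ktot > 0)
      (1 / 6) * sum(m * r2 * k * k / ktot) * A2_to_cm2 else 0)

  per_dir <- data.frame(
    rx = R[, 1], ry = R[, 2], rz = R[, 3], r = sqrt(r2),
    J_meV = 1000 * vapply(hops, function(h) h$J, numeric(1)),
    multiplicity = m, k = k, P = P)
  .mobility_report(per_dir, D_tensor, D_iso, T, carrier, convention)
}

.mobility_report <- function(per_dir, D_tensor, D_iso, T, carrier,
                             convention) {
  structure(list(per_direction = per_dir,
                 D_tensor = D_tensor, D_iso = D_iso,
                 mu = einstein_mobility(D_iso, T),
                 temperature = T, carrier = carrier,
                 convention = convention),
            class = "mobility_report")
}

#' @export
print.mobility_report <- function(x, ...) {
  cat(sprintf("mobility_report (%s, %s convention, %g K): D_iso = %.4g cm^2/s, mu = %.4g cm^2/V/s\n",
              x$carrier, x$convention, x$temperature, x$D_iso, x$mu))
  if (nrow(x$per_direction)) {
    top <- x$per_direction[order(-abs(x$per_direction$J_meV)), ]
    top <- utils::head(top, 3)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  r = %.3f A  J = %.2f meV  k = %.3e /s  P = %.3f\n",
                  top$r[i], top$J_meV[i], top$k[i], top$P[i]))
  }
  invisible(x)
}

#' Einstein-Smoluchowski mobility
#'
#' `mu = e D / (k_B T) = D / (k_B T / e)` with the thermal voltage
#' `k_B T / e` in volts.
#'
#' @param D diffusion coefficient, cm^2/s, >= 0.
#' @param T temperature, K, > 0.
#' @return Mobility in cm^2/V/s.
#' @examples
#' einstein_mobility(1e-3, 300)  # ~0.039
#' @export
einstein_mobility <- function(D, T = 300) {
  if (any(T <= 0)) stop("temperature must be > 0")
  if (any(D < 0)) stop("diffusion coefficient must be >= 0")
  D / (.const$kB_eVK * T)
}

#' Frontier orbital levels
#'
#' @param result an [electronic_structure()].
#' @return Named numeric vector: `homo`, `lumo` (eV) and `gap = lumo - homo`;
#'   a warning is issued for a vanishing gap.
#' @export
frontier_levels <- function(result) {
  stopifnot(inherits(result, "electronic_structure"))
  e <- result$orbital_energies
  if (result$lumo_index > length(e))
    stop("system has no unoccupied orbital: LUMO undefined")
  homo <- e[result$homo_index]; lumo <- e[result$lumo_index]
  if (lumo - homo < 1e-9)
    warning("zero HOMO-LUMO gap (metallic toy input)")
  c(homo = homo, lumo = lumo, gap = lumo - homo)
}
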