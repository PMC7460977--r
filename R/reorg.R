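#' Four-point adiabatic-potential energies
#'
#' Container for the four total energies defining the inner-sphere
#' reorganization energy: the neutral state at its optimal geometry (`E_N`),
#' the neutral state at the charged-state geometry (`E_N_star`), the charged
#' state at its optimal geometry (`E_C`) and the charged state at the neutral
#' geometry (`E_C_star`). Each geometry must be the optimum of its own state,
#' so `E_N_star >= E_N` and `E_C_star >= E_C`.
#'
#' @param E_N,E_N_star,E_C,E_C_star total energies, eV.
#' @return A `four_point_energies` object.
#' @export
four_point_energies <- function(E_N, E_N_star, E_C, E_C_star) {
  v <- c(E_N, E_N_star, E_C, E_C_star)
  stopifnot(length(v) == 4, all(is.finite(v)))
  if (E_N_star < E_N - 1e-6 || E_C_star < E_C - 1e-6)
    stop("inconsistent four-point energies: each geometry must be the ",
         "optimum of its own state (E_N* >= E_N, E_C* >= E_C)")
  structure(list(E_N = E_N, E_N_star = E_N_star,
                 E_C = E_C, E_C_star = E_C_star),
            class = "four_point_energies")
}

#' Reorganization energy by the four-point scheme
#'
#' `lambda = (E_N* - E_N) + (E_C* - E_C)` on the common (adiabatic) potential
#' energy surfaces; the two relaxation components are stored separately.
#' Inner-sphere only: no outer-sphere/polarization term is added.
#'
#' @param energies a [four_point_energies()].
#' @param carrier `"hole"` or `"electron"` (label carried into the result).
#' @return A `reorg_energies`: `lambda_total` (eV, >= 0), `components`
#'   (neutral-surface and charged-surface relaxation energies), `carrier`.
#' @examples
#' fp <- four_point_energies(0, 0.125, 1, 1.125)
#' lambda_four_point(fp, "hole")$lambda_total  # 0.25 eV
#' @export
lambda_four_point <- function(energies, carrier = c("hole", "electron")) {
  carrier <- match.arg(carrier)
  stopifnot(inherits(energies, "four_point_energies"))
  comp <- c(neutral_surface = energies$E_N_star - energies$E_N,
            charged_surface = energies$E_C_star - energies$E_C)
  if (any(comp < -1e-6))
    stop("inconsistent input: a relaxation component is negative (geometry ",
         "not optimal for its state)")
  structure(list(lambda_total = sum(comp), components = comp,
                 carrier = carrier),
            class = "reorg_energies")
}

#' @export
print.reorg_energies <- function(x, ...) {
  cat(sprintf("reorganization energy (%s): %.1f meV (neutral surface %.1f + charged surface %.1f)\n",
              x$carrier, 1000 * x$lambda_total,
              1000 * x$components[1], 1000 * x$components[2]))
  invisible(x)
}

#' Construct/validate a normal-mode set
#'
#' @param frequencies mode wavenumbers, cm^-1, all > 0 (rigid-body modes
#'   must already be projected out).
#' @param displacement_vectors 3N x n_modes matrix of mass-weighted mode
#'   vectors, orthonormal columns.
#' @param masses per-atom masses, amu.
#' @return A `normal_mode_set`.
#' @export
normal_mode_set <- function(frequencies, displacement_vectors, masses) {
  L <- as.matrix(displacement_vectors)
  stopifnot(length(frequencies) == ncol(L), all(frequencies > 0),
            nrow(L) == 3 * length(masses))
  G <- t(L) %*% L
  if (max(abs(G - diag(ncol(L)))) > 1e-8)
    stop("mode vectors are not orthonormal in the mass-weighted metric")
  structure(list(frequencies = as.numeric(frequencies),
                 displacement_vectors = L, masses = as.numeric(masses)),
            class = "normal_mode_set")
}

#' Normal-mode decomposition of the reorganization energy
#'
#' Projects the mass-weighted displacement between the neutral-state and
#' charged-state geometries onto each normal mode:
#' `dq_i = L_i . M^(1/2) (x_C - x_N)` (amu^(1/2) Angstrom), giving the mode
#' contribution `lambda_i = 1/2 omega_i^2 dq_i^2` (converted to eV) and the
#' Huang-Rhys factor `S_i = lambda_i / (hbar omega_i)`. Both geometries are
#' Eckart-aligned first (mass-weighted centroid removed, optimal rotation by
#' the Kabsch algorithm), so the result is invariant under rigid motion of
#' either input.
#'
#' @param neutral_geom,charged_geom n x 3 Cartesian coordinate matrices,
#'   Angstrom, same atom ordering (a [molecule()] is also accepted).
#' @param modes a [normal_mode_set()] computed at the neutral-state minimum.
#' @param align apply Eckart alignment (default `TRUE`); with `FALSE` the
#'   raw displacement is projected and an Eckart residual above `eckart_tol`
#'   raises an error.
#' @param eckart_tol residual net translation/rotation tolerance
#'   (amu^(1/2) Angstrom) when `align = FALSE`.
#' @return data.frame of class `mode_contributions`, ordered by frequency:
#'   `omega` (cm^-1), `dq` (amu^(1/2) Angstrom), `lambda` (eV),
#'   `huang_rhys`; total reorganization energy in attribute `lambda_total`.
#' @export
normal_mode_decomposition <- function(neutral_geom, charged_geom, modes,
                                      align = TRUE, eckart_tol = 1e-6) {
  stopifnot(inherits(modes, "normal_mode_set"))
  xN <- .coords_of(neutral_geom); xC <- .coords_of(charged_geom)
  if (!all(dim(xN) == dim(xC)) || nrow(xN) != length(modes$masses))
    stop("geometry/mode dimension mismatch")
  m <- modes$masses
  if (align) {
    xN <- .eckart_shift(xN, m)
    xC <- .eckart_shift(xC, m)
    R <- .kabsch(xC, xN, m)
    xC <- xC %*% t(R)
  }
  disp <- xC - xN
  q <- as.vector(t(disp)) * rep(sqrt(m), each = 3)
  if (!align) {
    res <- .eckart_residual(xN, disp, m)
    if (res > eckart_tol)
      stop("alignment error: Eckart residual ", format(res),
           " exceeds tolerance; net translation/rotation not removed")
  }
  dq <- drop(t(modes$displacement_vectors) %*% q)
  lambda_i <- .lambda_conv * modes$frequencies^2 * dq^2
  hbar_omega <- .const$hc_eVcm * modes$frequencies
  out <- data.frame(omega = modes$frequencies, dq = dq,
                    lambda = lambda_i, huang_rhys = lambda_i / hbar_omega)
  out <- out[order(out$omega), ]
  rownames(out) <- NULL
  attr(out, "lambda_total") <- sum(lambda_i)
  class(out) <- c("mode_contributions", "data.frame")
  out
}

.coords_of <- function(x) {
  if (inherits(x, "molecule")) x$coords else matrix(as.numeric(x), ncol = 3)
}

.eckart_shift <- function(x, m) sweep(x, 2, colSums(x * m) / sum(m))

# weighted Kabsch: rotation R minimizing sum m |R x - y|^2
.kabsch <- function(x, y, m) {
  A <- t(y * m) %*% x
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# residual mass-weighted net translation + angular momentum of a displacement
.eckart_residual <- function(x0, disp, m) {
  tr <- colSums(disp * m) / sqrt(sum(m))
  rot <- colSums(m * t(apply(cbind(x0, disp), 1, function(r)
    .cross(r[1:3], r[4:6]))))
  sqrt(sum(tr^2) + sum(rot^2))
}

#' Raman line records
#'
#' @param omega line positions, cm^-1.
#' @param intensity Raman intensities, arbitrary units, >= 0.
#' @return data.frame with `omega`, `intensity` and the `proxy = I/omega`
#'   column used as an experimental stand-in for mode reorganization
#'   contributions.
#' @export
raman_lines <- function(omega, intensity) {
  stopifnot(length(omega) == length(intensity), all(intensity >= 0),
            all(omega > 0))
  data.frame(omega = omega, intensity = intensity,
             proxy = intensity / omega)
}

#' Compare mode reorganization contributions with the Raman I/omega proxy
#'
#' Matches Raman lines to normal modes by frequency (nearest line within
#' `window`), tabulates `(omega_i, lambda_i, I_i/omega_i)` and reports the
#' Spearman rank correlation between the two columns plus the spectrally
#' integrated proxy. Purely descriptive: the proxy is a reported empirical
#' correlate, not a causal model. Unmatched modes and lines are listed, never
#' silently dropped.
#'
#' @param contribs a `mode_contributions` table from
#'   [normal_mode_decomposition()].
#' @param raman a [raman_lines()] table.
#' @param window matching window, cm^-1 (default 10).
#' @return A `raman_proxy_report`: `table` (matched modes), `rank_correlation`
#'   (Spearman, NA if fewer than 3 matches), `integrated_proxy`,
#'   `unmatched_modes`, `unmatched_lines`.
#' @export
raman_proxy_report <- function(contribs, raman, window = 10) {
  stopifnot(inherits(contribs, "data.frame"), inherits(raman, "data.frame"))
  mi <- integer(0); li <- integer(0)
  taken <- rep(FALSE, nrow(raman))
  for (i in seq_len(nrow(contribs))) {
    d <- abs(raman$omega - contribs$omega[i])
    d[taken] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= window) {
      mi <- c(mi, i); li <- c(li, j); taken[j] <- TRUE
    }
  }
  tab <- data.frame(omega = contribs$omega[mi],
                    lambda = contribs$lambda[mi],
                    proxy = raman$proxy[li])
  rc <- if (nrow(tab) >= 3 && stats::sd(tab$lambda) > 0 &&
            stats::sd(tab$proxy) > 0)
    stats::cor(tab$lambda, tab$proxy, method = "spearman") else NA_real_
  structure(list(table = tab,
                 rank_correlation = rc,
                 integrated_proxy = sum(raman$proxy),
                 unmatched_modes = contribs$omega[setdiff(seq_len(nrow(contribs)), mi)],
                 unmatched_lines = raman$omega[!taken]),
            class = "raman_proxy_report")
}

#' @export
print.raman_proxy_report <- function(x, ...) {
  cat(sprintf("raman_proxy_report: %d matched mode(s), rank correlation %s, integrated I/omega %.4g\n",
              nrow(x$table),
              ifelse(is.na(x$rank_correlation), "NA",
                     sprintf("%.3f", x$rank_correlation)),
              x$integrated_proxy))
  if (length(x$unmatched_modes))
    cat("  unmatched modes (cm^-1):",
        paste(sprintf("%.1f", x$unmatched_modes), collapse = ", "), "\n")
  if (length(x$unmatched_lines))
    cat("  unmatched lines (cm^-1):",
        paste(sprintf("%.1f", x$unmatched_lines), collapse = ", "), "\n")
  invisible(x)
}
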