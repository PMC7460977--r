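#' Kinetic Monte Carlo random walk on a hop network
#'
#' Brute-force oracle for the analytic diffusion summation: a residence-time
#' (Gillespie) random walk with site-independent rates. Waiting times are
#' exponential with the total escape rate, directions drawn with probability
#' proportional to `multiplicity * k_i`. The diffusion tensor is estimated
#' per trajectory by zero-intercept regression of the displacement product
#' `r_a(t) r_b(t) / 2` against time over the second half of the trajectory
#' (the first half is discarded as a guard against transients; for Markovian
#' hops the estimate is unbiased either way), then averaged over
#' trajectories with a standard error.
#'
#' @param hops list of [hop_spec()] (one hop network; shared temperature).
#' @param n_traj number of independent trajectories.
#' @param n_hops hops per trajectory.
#' @param seed integer RNG seed; results are reproducible given it.
#' @return A `kmc_result`: `D_tensor_est` (3x3, cm^2/s), `stderr` (3x3
#'   per-component standard errors), `D_iso_est`, `D_iso_stderr`,
#'   `n_trajectories`, `n_hops`, `seed`.
#' @examples
#' net <- make_planted_network(planted_chain(r = 4, J = 0.05))
#' simulate_random_walk(net, n_traj = 50, n_hops = 500, seed = 7)$D_iso_est
#' @export
simulate_random_walk <- function(hops, n_traj = 200, n_hops = 2000,
                                 seed = 1) {
  stopifnot(length(hops) >= 1, n_traj >= 1, n_hops >= 1)
  stopifnot(all(vapply(hops, inherits, logical(1), "hop_spec")))
  k <- vapply(hops, marcus_rate, numeric(1))
  m <- vapply(hops, function(h) as.numeric(h$multiplicity), numeric(1))
  R <- t(vapply(hops, function(h) h$r_vec, numeric(3)))
  w <- m * k
  ktot <- sum(w)
  if (ktot <= 0) stop("degenerate network: all hop rates are zero")

  set.seed(seed)
  ntot <- n_traj * n_hops
  idx <- sample.int(length(hops), ntot, replace = TRUE, prob = w / ktot)
  dt <- matrix(stats::rexp(ntot, rate = ktot), nrow = n_hops)
  steps <- R[idx, , drop = FALSE]

  half <- (n_hops %/% 2 + 1):n_hops
  est <- matrix(NA_real_, n_traj, 9)
  for (tr in seq_len(n_traj)) {
    rows <- ((tr - 1) * n_hops + 1):(tr * n_hops)
    pos <- apply(steps[rows, , drop = FALSE], 2, cumsum)
    tt <- cumsum(dt[, tr])
    th <- tt[half]
    st2 <- sum(th^2)
    for (a in 1:3) for (b in a:3) {
      y <- pos[half, a] * pos[half, b] / 2
      est[tr, (a - 1) * 3 + b] <- sum(th * y) / st2
    }
  }
  D <- matrix(0, 3, 3); SE <- matrix(0, 3, 3)
  for (a in 1:3) for (b in a:3) {
    v <- est[, (a - 1) * 3 + b] * 1e-16  # A^2/s -> cm^2/s
    D[a, b] <- D[b, a] <- mean(v)
    SE[a, b] <- SE[b, a] <- stats::sd(v) / sqrt(n_traj)
  }
  iso <- (est[, 1] + est[, 5] + est[, 9]) / 3 * 1e-16
  structure(list(D_tensor_est = D, stderr = SE,
                 D_iso_est = mean(iso),
                 D_iso_stderr = stats::sd(iso) / sqrt(n_traj),
                 n_trajectories = as.integer(n_traj),
                 n_hops = as.integer(n_hops), seed = as.integer(seed)),
            class = "kmc_result")
}

#' @export
print.kmc_result <- function(x, ...) {
  cat(sprintf("kmc_result: %d trajectories x %d hops (seed %d)\n",
              x$n_trajectories, x$n_hops, x$seed))
  cat(sprintf("  D_iso = %.4g +/- %.2g cm^2/s\n", x$D_iso_est, x$D_iso_stderr))
  invisible(x)
}
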