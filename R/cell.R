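#' Construct a unit cell
#'
#' Builds a `unit_cell` object from lattice lengths and angles and derives the
#' fractional-to-Cartesian matrix in the standard crystallographic convention
#' (a along x, b in the xy-plane).
#'
#' @param a,b,c lattice lengths in Angstrom.
#' @param alpha,beta,gamma lattice angles in degrees.
#' @return An object of class `unit_cell` with fields `a, b, c, alpha, beta,
#'   gamma`, the 3x3 `frac_to_cart` matrix, its inverse `cart_to_frac`, and
#'   the cell `volume` in Angstrom^3.
#' @examples
#' cl <- unit_cell(10, 10, 10)
#' cl$frac_to_cart %*% c(1, 0, 0)  # the a vector, length 10
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0)
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("cell angles do not define a positive cell volume")
  v <- sqrt(v2)
  m <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * v / sg
  ), nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 frac_to_cart = m, cart_to_frac = solve(m),
                 volume = a * b * c * v),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f A, alpha=%.2f beta=%.2f gamma=%.2f deg, V=%.2f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

frac_to_cart <- function(cell, frac) {
  frac <- matrix(frac, ncol = 3)
  t(cell$frac_to_cart %*% t(frac))
}

cart_to_frac <- function(cell, cart) {
  cart <- matrix(cart, ncol = 3)
  t(cell$cart_to_frac %*% t(cart))
}

#' Parse a symmetry operation string
#'
#' Converts a CIF-style symmetry operation such as `"-x, y+1/2, -z+1/2"` into
#' a rotation matrix and a fractional translation vector. Translations are
#' reduced to `[0, 1)`.
#'
#' @param s operation string with three comma-separated components in x, y, z.
#' @return A `symmetry_op`: list with an integer-entry 3x3 `rotation` and a
#'   fractional 3-vector `translation`.
#' @examples
#' op <- parse_symop("-x, y+1/2, -z+1/2")
#' op$rotation
#' @export
parse_symop <- function(s) {
  parts <- strsplit(s, ",")[[1]]
  if (length(parts) != 3L)
    stop("symmetry operation must have three comma-separated components: ", s)
  if (grepl("[^xyzXYZ0-9+*/., \t-]", s))
    stop("unparseable symmetry operation string: ", s)
  ev <- function(expr, x, y, z) {
    env <- list2env(list(x = x, y = y, z = z, X = x, Y = y, Z = z))
    vapply(expr, function(e) eval(parse(text = e), envir = env), numeric(1))
  }
  t0 <- ev(parts, 0, 0, 0)
  rot <- cbind(ev(parts, 1, 0, 0) - t0,
               ev(parts, 0, 1, 0) - t0,
               ev(parts, 0, 0, 1) - t0)
  if (max(abs(rot - round(rot))) > 1e-8)
    stop("symmetry rotation has non-integer entries: ", s)
  rot <- round(rot)
  if (abs(abs(det(rot)) - 1) > 1e-8)
    stop("symmetry rotation is not unimodular: ", s)
  structure(list(rotation = rot, translation = t0 %% 1), class = "symmetry_op")
}

#' Apply a symmetry operation to fractional coordinates
#'
#' @param op a `symmetry_op` from [parse_symop()].
#' @param frac fractional coordinates (3-vector or n x 3 matrix).
#' @return Transformed fractional coordinates, n x 3 (not reduced mod 1).
#' @export
apply_symop <- function(op, frac) {
  frac <- matrix(frac, ncol = 3)
  sweep(t(op$rotation %*% t(frac)), 2, op$translation, "+")
}
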