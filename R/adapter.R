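# Plain-text adapter for externally computed electronic-structure results
# (DFT or otherwise). Ab initio execution is outside this package; the
# adapter only ingests and validates its outputs.
#
# File format, one or more sections:
#   #kind fock|overlap|coeffs|energies|hessian|fourpoint|masses
#   #dim n [m]
#   #blocks n_a n_b        (dimer matrices only)
#   #nelec k               (monomer results only)
#   <whitespace-separated rows, full precision>

#' Load externally computed matrices from an adapter file
#'
#' Reads the plain-text adapter format and assembles the strongest object the
#' sections support: a `fourpoint` section yields [four_point_energies()];
#' `fock` + `overlap` with a `#blocks` header yield [dimer_matrices()];
#' `energies` + `coeffs` + `overlap` with `#nelec` yield
#' [electronic_structure()]; `hessian` + `masses` yield a
#' [normal_mode_set()] (mass-weighting, rigid-body modes dropped). All type
#' invariants are enforced at load time, so malformed input fails with an
#' error naming the offending matrix.
#'
#' @param path adapter file path.
#' @return One of `four_point_energies`, `dimer_matrices`,
#'   `electronic_structure`, `normal_mode_set`.
#' @export
load_external_matrices <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  secs <- .read_adapter_sections(path)
  kinds <- names(secs)

  if ("fourpoint" %in% kinds) {
    v <- secs$fourpoint$data
    if (length(v) != 4)
      stop("fourpoint section must hold exactly 4 energies (E_N E_N* E_C E_C*)")
    return(four_point_energies(v[1], v[2], v[3], v[4]))
  }
  if ("hessian" %in% kinds) {
    if (!"masses" %in% kinds)
      stop("hessian section requires a masses section")
    H <- secs$hessian$mat
    if (is.null(H) || nrow(H) != ncol(H))
      stop("hessian: expected a square matrix matching its #dim header")
    return(normal_modes_from_hessian(H, secs$masses$data))
  }
  if (all(c("energies", "coeffs", "overlap") %in% kinds)) {
    ne <- secs$coeffs$nelec
    if (is.null(ne)) stop("coeffs section requires a #nelec header")
    return(electronic_structure(secs$energies$data, secs$coeffs$mat,
                                secs$overlap$mat, ne))
  }
  if (all(c("fock", "overlap") %in% kinds)) {
    bl <- secs$fock$blocks
    if (is.null(bl))
      stop("fock: dimer matrices require a #blocks n_a n_b header")
    return(dimer_matrices(secs$fock$mat, secs$overlap$mat, bl))
  }
  stop("adapter file holds no recognized section combination: ",
       paste(kinds, collapse = ", "))
}

.read_adapter_sections <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^#kind\\b", lines)
  if (!length(starts)) stop("not an adapter file (no #kind header): ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  secs <- list()
  for (s in seq_along(starts)) {
    block <- lines[starts[s]:ends[s]]
    kind <- strsplit(trimws(block[1]), "[ \t]+")[[1]][2]
    hdr <- grep("^#", block, value = TRUE)
    rows <- grep("^#", block, value = TRUE, invert = TRUE)
    geth <- function(tag) {
      h <- grep(paste0("^#", tag, "\\b"), hdr, value = TRUE)
      if (!length(h)) return(NULL)
      as.numeric(strsplit(trimws(h[1]), "[ \t]+")[[1]][-1])
    }
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(rows), "[ \t]+"))))
    if (anyNA(vals)) stop("non-numeric data in adapter section '", kind, "'")
    dim_h <- geth("dim")
    mat <- NULL
    if (!is.null(dim_h)) {
      nr <- dim_h[1]; nc <- if (length(dim_h) > 1) dim_h[2] else dim_h[1]
      if (length(vals) != nr * nc)
        stop("adapter section '", kind, "': #dim ", nr, " ", nc,
             " does not match ", length(vals), " values")
      mat <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
    }
    secs[[kind]] <- list(data = vals, mat = mat,
                         blocks = geth("blocks"), nelec = geth("nelec"))
  }
  secs
}

#' Write an object to the adapter format
#'
#' Round-trips through [load_external_matrices()]; values are written with 17
#' significant digits.
#'
#' @param x a `four_point_energies`, `dimer_matrices` or
#'   `electronic_structure` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_external_matrices <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  fmt_row <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  wmat <- function(kind, m, extra = NULL) {
    w("#kind %s", kind)
    w("#dim %d %d", nrow(m), ncol(m))
    if (!is.null(extra)) writeLines(extra, con)
    for (i in seq_len(nrow(m))) writeLines(fmt_row(m[i, ]), con)
  }
  if (inherits(x, "four_point_energies")) {
    w("#kind fourpoint")
    w("#dim 1 4")
    writeLines(fmt_row(c(x$E_N, x$E_N_star, x$E_C, x$E_C_star)), con)
  } else if (inherits(x, "dimer_matrices")) {
    wmat("fock", x$fock,
         sprintf("#blocks %d %d", x$block_sizes[1], x$block_sizes[2]))
    wmat("overlap", x$overlap)
  } else if (inherits(x, "electronic_structure")) {
    w("#kind energies")
    w("#dim 1 %d", length(x$orbital_energies))
    writeLines(fmt_row(x$orbital_energies), con)
    wmat("coeffs", x$mo_coefficients,
         sprintf("#nelec %d", x$n_electrons))
    wmat("overlap", x$overlap)
  } else {
    stop("no adapter writer for class: ", paste(class(x), collapse = "/"))
  }
  invisible(path)
}

#' Normal modes from a Cartesian Hessian
#'
#' Mass-weights a Cartesian Hessian (eV/Angstrom^2), diagonalizes it, drops
#' rigid-body modes (near-zero curvature) and converts the remaining
#' curvatures to wavenumbers.
#'
#' @param hessian 3N x 3N symmetric Cartesian Hessian, eV/Angstrom^2.
#' @param masses per-atom masses, amu (length N).
#' @param rigid_tol curvature threshold (eV/(amu Angstrom^2)) below which a
#'   mode is treated as rigid-body and dropped.
#' @return A [normal_mode_set()].
#' @export
normal_modes_from_hessian <- function(hessian, masses, rigid_tol = 1e-6) {
  H <- as.matrix(hessian)
  n3 <- nrow(H)
  if (n3 %% 3L != 0L || length(masses) != n3 / 3L)
    stop("hessian dimension does not match 3 x number of masses")
  if (max(abs(H - t(H))) > 1e-8) stop("hessian is not symmetric")
  msqrt <- rep(sqrt(masses), each = 3L)
  Hmw <- H / outer(msqrt, msqrt)
  eig <- eigen((Hmw + t(Hmw)) / 2, symmetric = TRUE)
  keep <- eig$values > rigid_tol
  if (!any(keep)) stop("hessian has no positive-curvature modes")
  ord <- order(eig$values[keep])
  kappa <- eig$values[keep][ord]
  L <- eig$vectors[, keep, drop = FALSE][, ord, drop = FALSE]
  normal_mode_set(.kappa_to_wavenumber(kappa), L, masses)
}
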