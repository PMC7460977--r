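#' Read a crystal structure from CIF
#'
#' Parses the core-dictionary subset used for molecular crystals: cell
#' parameters (`_cell_length_*`, `_cell_angle_*`), symmetry operation strings
#' (`_symmetry_equiv_pos_as_xyz` or `_space_group_symop_operation_xyz`; if
#' absent, P1 is assumed) and fractional atom sites (`_atom_site_fract_*` with
#' `_atom_site_type_symbol` or `_atom_site_label`). Fractional coordinates are
#' converted once to Cartesian Angstrom; all downstream geometry is Cartesian.
#'
#' @param path path to a CIF file.
#' @param keep_partial_occupancy sites with occupancy < 1 are rejected with an
#'   error by default (molecular crystals of interest are ordered); set `TRUE`
#'   to keep the highest-occupancy alternative per label.
#' @return A `crystal_structure`: list with `cell` ([unit_cell()]), `symmetry`
#'   (list of `symmetry_op`), `sites` (data.frame: element, fractional and
#'   Cartesian coordinates), `molecules` (`NULL` until
#'   [identify_molecules()] is run) and `name`.
#' @seealso [write_cif()], [identify_molecules()], [enumerate_dimers()]
#' @export
read_cif <- function(path, keep_partial_occupancy = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  grab_num <- function(tag) {
    hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(NA_real_)
    val <- trimws(sub(paste0("^", tag), "", hit[1]))
    as.numeric(sub("\\(.*\\)", "", val))  # strip esd in parentheses
  }
  cell_par <- c(a = grab_num("_cell_length_a"),
                b = grab_num("_cell_length_b"),
                c = grab_num("_cell_length_c"),
                alpha = grab_num("_cell_angle_alpha"),
                beta  = grab_num("_cell_angle_beta"),
                gamma = grab_num("_cell_angle_gamma"))
  if (anyNA(cell_par[1:3]))
    stop("CIF format error: missing _cell_length_* block in ", path)
  if (anyNA(cell_par[4:6])) cell_par[4:6][is.na(cell_par[4:6])] <- 90
  cell <- unit_cell(cell_par["a"], cell_par["b"], cell_par["c"],
                    cell_par["alpha"], cell_par["beta"], cell_par["gamma"])

  loops <- .cif_loops(lines)

  sym_tags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  symops <- NULL
  for (lp in loops) {
    j <- which(tolower(lp$tags) %in% sym_tags)
    if (length(j)) {
      symops <- lapply(lp$rows[[j[1]]], parse_symop)
      break
    }
  }
  if (is.null(symops)) symops <- list(parse_symop("x, y, z"))

  site_loop <- NULL
  for (lp in loops) {
    if (any(tolower(lp$tags) == "_atom_site_fract_x")) { site_loop <- lp; break }
  }
  if (is.null(site_loop))
    stop("CIF format error: no _atom_site_fract_* loop in ", path)
  tg <- tolower(site_loop$tags)
  col <- function(tag) {
    j <- which(tg == tag)
    if (length(j)) site_loop$rows[[j[1]]] else NULL
  }
  num <- function(x) as.numeric(sub("\\(.*\\)", "", x))
  fx <- num(col("_atom_site_fract_x"))
  fy <- num(col("_atom_site_fract_y"))
  fz <- num(col("_atom_site_fract_z"))
  elem <- col("_atom_site_type_symbol")
  if (is.null(elem)) elem <- col("_atom_site_label")
  if (is.null(elem)) stop("CIF format error: atom sites carry no element symbol")
  elem <- sub("^([A-Za-z]{1,2}).*$", "\\1", elem)
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, nchar(elem))))
  occ <- col("_atom_site_occupancy")
  occ <- if (is.null(occ)) rep(1, length(fx)) else num(occ)
  if (any(occ < 1 - 1e-6)) {
    if (!keep_partial_occupancy)
      stop("CIF contains partially occupied (disordered) sites; ",
           "set keep_partial_occupancy = TRUE to keep the majority alternative")
    keep <- occ >= 0.5
    fx <- fx[keep]; fy <- fy[keep]; fz <- fz[keep]
    elem <- elem[keep]; occ <- occ[keep]
  }
  frac <- cbind(fx, fy, fz)
  cart <- frac_to_cart(cell, frac)
  sites <- data.frame(element = elem,
                      fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
                      x = cart[, 1], y = cart[, 2], z = cart[, 3],
                      stringsAsFactors = FALSE)
  name <- grep("^data_", lines, value = TRUE)
  name <- if (length(name)) sub("^data_", "", name[1]) else basename(path)
  structure(list(cell = cell, symmetry = symops, sites = sites,
                 molecules = NULL, name = name),
            class = "crystal_structure")
}

# minimal CIF loop_ tokenizer (quoted values honoured; no multi-line ; blocks)
.cif_loops <- function(lines) {
  loops <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (tolower(lines[i]) == "loop_") {
      i <- i + 1L
      tags <- character()
      while (i <= n && startsWith(lines[i], "_")) {
        tags <- c(tags, strsplit(lines[i], "[ \t]+")[[1]][1])
        i <- i + 1L
      }
      vals <- character()
      while (i <= n && !startsWith(lines[i], "_") &&
             tolower(lines[i]) != "loop_" && !startsWith(lines[i], "data_")) {
        vals <- c(vals, .cif_tokens(lines[i]))
        i <- i + 1L
      }
      if (length(tags) && length(vals) %% length(tags) == 0 && length(vals)) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        loops[[length(loops) + 1L]] <-
          list(tags = tags, rows = lapply(seq_along(tags), function(j) m[, j]))
      }
    } else i <- i + 1L
  }
  loops
}

.cif_tokens <- function(line) {
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|[^ \t]+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

#' Write a crystal structure to CIF (P1)
#'
#' Emits a parseable P1 CIF that round-trips through [read_cif()] to within
#' 1e-6 Angstrom. Symmetry is written as the identity: whatever sites the
#' structure holds are written as-is in fractional coordinates.
#'
#' @param structure a `crystal_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path) {
  stopifnot(inherits(structure, "crystal_structure"))
  s <- structure$sites
  if (is.null(s) || nrow(s) == 0L) stop("cannot write CIF: structure has no sites")
  cl <- structure$cell
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("data_%s", gsub("[^A-Za-z0-9_-]", "_", structure$name))
  w("_cell_length_a    %.10f", cl$a)
  w("_cell_length_b    %.10f", cl$b)
  w("_cell_length_c    %.10f", cl$c)
  w("_cell_angle_alpha %.10f", cl$alpha)
  w("_cell_angle_beta  %.10f", cl$beta)
  w("_cell_angle_gamma %.10f", cl$gamma)
  w("loop_")
  w("_symmetry_equiv_pos_as_xyz")
  w("'x, y, z'")
  w("loop_")
  w("_atom_site_label")
  w("_atom_site_type_symbol")
  w("_atom_site_fract_x")
  w("_atom_site_fract_y")
  w("_atom_site_fract_z")
  for (i in seq_len(nrow(s)))
    w("%s%d %s %.12f %.12f %.12f", s$element[i], i, s$element[i],
      s$fx[i], s$fy[i], s$fz[i])
  invisible(path)
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal_structure '%s': %d site(s) in asymmetric record, %d symmetry op(s)\n",
              x$name, nrow(x$sites), length(x$symmetry)))
  print(x$cell)
  if (!is.null(x$molecules))
    cat(sprintf("  %d molecule(s) identified in the unit cell\n",
                length(x$molecules)))
  invisible(x)
}
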