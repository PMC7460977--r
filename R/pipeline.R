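#' Run configuration for the end-to-end pipeline
#'
#' @param input a CIF path, a `crystal_structure`, a [stack_spec()] or (with
#'   `backend = "planted"`) a `planted_network`.
#' @param backend `"huckel"` (tight-binding toy), `"planted"` (hop network
#'   given directly) or `"adapter"` (externally computed dimer matrices;
#'   supply `adapter_files`).
#' @param carriers character subset of `c("hole", "electron")`.
#' @param temperature K.
#' @param cutoff dimer centroid cutoff, Angstrom.
#' @param convention diffusion convention, see [hopping_diffusion()].
#' @param lambda reorganization energy input: a single eV value, a named list
#'   `list(hole =, electron =)` of eV values or adapter file paths (a path is
#'   read with [load_external_matrices()] and must yield four-point
#'   energies).
#' @param adapter_files for `backend = "adapter"`: character vector of dimer
#'   adapter files, one per transport direction, with attributes handled by
#'   `run_pipeline`'s `dimer_geometry` table (r_vec per file).
#' @param dimer_geometry for `backend = "adapter"`: data.frame with columns
#'   rx, ry, rz, multiplicity, one row per adapter file.
#' @param output_dir optional directory for machine-readable artifacts.
#' @param seed integer recorded in the provenance block (the analytic
#'   pipeline itself is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(input, backend = c("huckel", "planted", "adapter"),
                       carriers = c("hole", "electron"),
                       temperature = 300, cutoff = 10,
                       convention = c("msd", "rate-weighted"),
                       lambda = 0.2, adapter_files = NULL,
                       dimer_geometry = NULL, output_dir = NULL, seed = 1) {
  backend <- match.arg(backend)
  convention <- match.arg(convention)
  stopifnot(temperature > 0, cutoff > 0,
            all(carriers %in% c("hole", "electron")))
  structure(list(input = input, backend = backend, carriers = carriers,
                 temperature = temperature, cutoff = cutoff,
                 convention = convention, lambda = lambda,
                 adapter_files = adapter_files,
                 dimer_geometry = dimer_geometry,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

.lambda_for <- function(lambda, carrier) {
  lam <- if (is.list(lambda)) lambda[[carrier]] else lambda
  if (is.null(lam)) stop("no reorganization energy configured for ", carrier)
  if (is.character(lam)) {
    fp <- load_external_matrices(lam)
    if (!inherits(fp, "four_point_energies"))
      stop("lambda adapter file does not hold four-point energies: ", lam)
    lam <- lambda_four_point(fp, carrier)$lambda_total
  }
  stopifnot(is.numeric(lam), lam > 0)
  lam
}

#' Run the full hopping-transport pipeline
#'
#' Composes the stages structure -> molecules -> dimers -> electronic
#' backend -> transfer integrals -> Marcus rates -> diffusion -> mobility,
#' plus the contact classification, from one configuration. Each stage
#' failure aborts with the failing stage named.
#'
#' @param config a [run_config()], or a YAML path accepted by
#'   [read_run_config()].
#' @return A `pipeline_result`: `j_table` (per unique dimer and carrier),
#'   `mobility` (named list of [hopping_diffusion()] reports per carrier),
#'   `contacts` ([contact_fractions()] table or `NULL` for planted input),
#'   `dimers`, `provenance`. When `output_dir` is set, writes
#'   `j_table.csv`, `mobility_<carrier>.json`, `contacts.csv` and
#'   `provenance.json` there.
#' @examples
#' cfg <- run_config(stack_spec(n_rings = 2), backend = "huckel",
#'                   cutoff = 4, lambda = 0.2)
#' run_pipeline(cfg)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dimers <- NULL; contacts <- NULL; structure_in <- NULL
  if (config$backend == "planted") {
    hops_per_carrier <- stage("planted-network", {
      net <- config$input
      out <- list()
      for (cr in config$carriers) {
        hops <- make_planted_network(net)
        out[[cr]] <- lapply(hops, function(h) {
          h$T <- config$temperature
          h$lambda <- .lambda_for(config$lambda, cr)
          h
        })
      }
      out
    })
    j_tab <- do.call(rbind, lapply(config$carriers, function(cr) {
      h <- hops_per_carrier[[cr]]
      data.frame(carrier = cr,
                 r = vapply(h, function(x) sqrt(sum(x$r_vec^2)), numeric(1)),
                 J_meV = vapply(h, function(x) 1000 * x$J, numeric(1)))
    }))
  } else {
    # the adapter backend may run without a structure: its dimer geometry
    # comes with the external matrices
    if (!(config$backend == "adapter" && is.null(config$input))) {
      structure_in <- stage("structure", {
        x <- config$input
        if (is.character(x)) x <- read_cif(x)
        if (inherits(x, "stack_spec")) x <- make_stack_crystal(x)
        stopifnot(inherits(x, "crystal_structure"))
        x
      })
      structure_in <- stage("molecules", identify_molecules(structure_in))
      dimers <- stage("dimers", enumerate_dimers(structure_in, config$cutoff))
      contacts <- stage("contacts",
                        suppressWarnings(contact_fractions(structure_in)))
    }

    couplings <- stage("transfer-integrals", {
      if (config$backend == "huckel") {
        lapply(dimers, function(p) {
          ma <- huckel_monomer(p$mol_a); mb <- huckel_monomer(p$mol_b)
          dm <- huckel_dimer(p$mol_a, p$mol_b)
          lapply(stats::setNames(config$carriers, config$carriers),
                 function(cr) dipro_coupling(dm, ma, mb, cr))
        })
      } else {  # adapter
        if (is.null(config$adapter_files) || is.null(config$dimer_geometry))
          stop("adapter backend needs adapter_files and dimer_geometry")
        lapply(seq_along(config$adapter_files), function(i) {
          dm <- load_external_matrices(config$adapter_files[i])
          if (!inherits(dm, "dimer_matrices"))
            stop("adapter file is not a dimer matrix set: ",
                 config$adapter_files[i])
          es <- .monomer_from_dimer(dm)
          lapply(stats::setNames(config$carriers, config$carriers),
                 function(cr) dipro_coupling(dm, es$a, es$b, cr))
        })
      }
    })
    geom <- if (config$backend == "huckel") {
      data.frame(rx = vapply(dimers, function(p) p$r_vec[1], numeric(1)),
                 ry = vapply(dimers, function(p) p$r_vec[2], numeric(1)),
                 rz = vapply(dimers, function(p) p$r_vec[3], numeric(1)),
                 multiplicity = vapply(dimers, function(p)
                   as.numeric(p$multiplicity), numeric(1)))
    } else config$dimer_geometry

    hops_per_carrier <- stage("rates", {
      out <- list()
      for (cr in config$carriers) {
        lam <- .lambda_for(config$lambda, cr)
        out[[cr]] <- lapply(seq_along(couplings), function(i) {
          tj <- couplings[[i]][[cr]]
          hop_spec(J = abs(tj$J_eff), lambda = lam, delta_e = tj$delta_e,
                   T = config$temperature,
                   r_vec = as.numeric(geom[i, c("rx", "ry", "rz")]),
                   multiplicity = max(1L, round(geom$multiplicity[i])))
        })
      }
      out
    })
    j_tab <- do.call(rbind, lapply(config$carriers, function(cr)
      do.call(rbind, lapply(seq_along(couplings), function(i) {
        tj <- couplings[[i]][[cr]]
        data.frame(carrier = cr,
                   r = sqrt(sum(as.numeric(geom[i, c("rx", "ry", "rz")])^2)),
                   multiplicity = geom$multiplicity[i],
                   J_raw_meV = 1000 * tj$J_raw, s_ab = tj$s_ab,
                   e_a = tj$e_a, e_b = tj$e_b,
                   J_meV = 1000 * abs(tj$J_eff))
      }))))
  }

  mobility <- stage("mobility", {
    out <- list()
    for (cr in config$carriers)
      out[[cr]] <- hopping_diffusion(hops_per_carrier[[cr]],
                                     convention = config$convention,
                                     carrier = cr)
    out
  })

  prov <- list(backend = config$backend, carriers = config$carriers,
               temperature = config$temperature, cutoff = config$cutoff,
               convention = config$convention, seed = config$seed,
               lambda = config$lambda,
               package_version = as.character(utils::packageVersion("hopcrystal")))

  res <- structure(list(j_table = j_tab, mobility = mobility,
                        contacts = contacts, dimers = dimers,
                        provenance = prov),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) .write_artifacts(res, config$output_dir)
  res
}

# monomer electronic structures implied by a dimer's diagonal blocks
.monomer_from_dimer <- function(dm) {
  na <- dm$block_sizes[1]; nb <- dm$block_sizes[2]
  solve_block <- function(F, S) {
    es <- eigen(S, symmetric = TRUE)
    Sm12 <- es$vectors %*% diag(1 / sqrt(es$values), nrow(S)) %*% t(es$vectors)
    eg <- eigen(Sm12 %*% F %*% Sm12, symmetric = TRUE)
    ord <- order(eg$values)
    electronic_structure(eg$values[ord],
                         Sm12 %*% eg$vectors[, ord, drop = FALSE], S,
                         n_electrons = 2 * floor(nrow(F) / 2))
  }
  list(a = solve_block(dm$fock[seq_len(na), seq_len(na), drop = FALSE],
                       dm$overlap[seq_len(na), seq_len(na), drop = FALSE]),
       b = solve_block(dm$fock[na + seq_len(nb), na + seq_len(nb), drop = FALSE],
                       dm$overlap[na + seq_len(nb), na + seq_len(nb),
                                  drop = FALSE]))
}

.write_artifacts <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$j_table, file.path(dir, "j_table.csv"),
                   row.names = FALSE)
  for (cr in names(res$mobility)) {
    m <- res$mobility[[cr]]
    jsonlite::write_json(
      list(carrier = cr, convention = m$convention,
           temperature = m$temperature, D_iso = m$D_iso,
           D_tensor = m$D_tensor, mu = m$mu,
           per_direction = m$per_direction),
      file.path(dir, paste0("mobility_", cr, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$contacts)) {
    ct <- res$contacts
    utils::write.csv(
      data.frame(pair = names(ct$fractions),
                 count = as.integer(ct$counts),
                 fraction = as.numeric(ct$fractions)),
      file.path(dir, "contacts.csv"), row.names = FALSE)
  }
  jsonlite::write_json(res$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (cr in names(x$mobility)) {
    m <- x$mobility[[cr]]
    cat(sprintf("  %s: mu = %.4g cm^2/V/s (D_iso %.4g cm^2/s, %s convention)\n",
                cr, m$mu, m$D_iso, m$convention))
  }
  if (!is.null(x$contacts))
    cat(sprintf("  conductive contact fraction: %.1f%%\n",
                100 * x$contacts$conductive_fraction))
  invisible(x)
}
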