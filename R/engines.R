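HARTREE_TO_KCAL <- 627.5094740631

# covalent radii (Angstrom) used for bond perception, matching the backend
covalent_radius <- function(z) {
  radii <- c(`1` = 0.32, `5` = 0.85, `6` = 0.75, `7` = 0.71, `8` = 0.63,
             `9` = 0.64, `14` = 1.16, `15` = 1.11, `16` = 1.03, `17` = 0.99,
             `35` = 1.14, `46` = 1.20, `53` = 1.33)
  out <- radii[as.character(z)]
  out[is.na(out)] <- 0.75
  unname(out)
}

#' Define an energy engine
#'
#' Engines provide geometry optimization and/or single-point energies behind
#' a common contract. Available engines:
#'
#' * `"mock"` — deterministic test engine; the energy is the sum of inverse
#'   pairwise interatomic distances (in 1/Angstrom, reported as kcal/mol), or
#'   a fixed value per reaction site when `energy_map` is supplied. Supports
#'   optimize (a no-op on coordinates) and singlepoint.
#' * `"forcefield"` — UFF via the RDKit backend (UFF carries a generic Pd
#'   type; MMFF is not parameterized for transition metals). Supports
#'   optimize and singlepoint.
#' * `"xtb"` — external GFN1-xTB binary with the ALPB implicit solvent,
#'   discovered on PATH or via `options(regiopd.xtb = ...)`. Supports
#'   optimize and singlepoint.
#' * `"orca"` — external ORCA binary for r2SCAN-3c single points (CPCM
#'   solvent); singlepoint only.
#' * `"mock_sp"` — deterministic single-point-only engine (same energy rule
#'   as `"mock"`), standing at the refinement level in offline tests;
#'   singlepoint only.
#'
#' @param name one of `"mock"`, `"forcefield"`, `"xtb"`, `"orca"`,
#'   `"mock_sp"`.
#' @param solvent implicit solvent label passed to engines that support one
#'   (default `"ch2cl2"`).
#' @param energy_map optional named numeric vector mapping site atom indices
#'   (as names) to fixed energies in kcal/mol; honoured by the mock engines.
#' @param binary optional explicit path to the external binary.
#' @return an object of class `engine_spec` with fields `name`, `level`,
#'   `solvent`, `capabilities`.
#' @export
engine_spec <- function(name = c("mock", "forcefield", "xtb", "orca",
                                 "mock_sp"),
                        solvent = "ch2cl2", energy_map = NULL,
                        binary = NULL) {
  name <- match.arg(name)
  level <- switch(name,
                  mock = "mock", mock_sp = "dft_singlepoint",
                  forcefield = "forcefield", xtb = "tightbinding",
                  orca = "dft_singlepoint")
  caps <- switch(name,
                 mock = c("optimize", "singlepoint"),
                 forcefield = c("optimize", "singlepoint"),
                 xtb = c("optimize", "singlepoint"),
                 orca = "singlepoint",
                 mock_sp = "singlepoint")
  structure(list(name = name, level = level, solvent = solvent,
                 capabilities = caps, energy_map = energy_map,
                 binary = binary),
            class = "engine_spec")
}

#' @export
print.engine_spec <- function(x, ...) {
  cat("<engine_spec> ", x$name, " (level: ", x$level, "; ",
      paste(x$capabilities, collapse = "/"), "; solvent: ", x$solvent,
      ")\n", sep = "")
  invisible(x)
}

mock_energy <- function(engine, cx, coords) {
  if (!is.null(engine$energy_map)) {
    site <- as.character(cx$pair$site_atom)
    val <- engine$energy_map[site]
    return(if (is.na(val)) 0 else unname(val))
  }
  d <- as.matrix(stats::dist(coords))
  sum(1 / d[upper.tri(d)])
}

external_binary <- function(engine) {
  bin <- engine$binary %||% getOption(paste0("regiopd.", engine$name))
  if (is.null(bin)) {
    hit <- Sys.which(engine$name)
    bin <- if (nzchar(hit)) unname(hit) else NULL
  }
  if (is.null(bin) || !nzchar(bin) || !file.exists(bin)) {
    abort(paste0("external engine '", engine$name,
                 "' is not installed (binary not found); set options(regiopd.",
                 engine$name, " = \"/path/to/binary\")"),
          class = "regiopd_config_error")
  }
  bin
}

write_xyz_file <- function(path, symbols, coords, comment = "") {
  lines <- c(length(symbols), comment,
             sprintf("%-3s %14.8f %14.8f %14.8f", symbols,
                     coords[, 1], coords[, 2], coords[, 3]))
  writeLines(lines, path)
}

run_xtb <- function(engine, cx, coords, optimize = TRUE) {
  bin <- external_binary(engine)
  dir <- tempfile("xtb")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  xyz <- file.path(dir, "input.xyz")
  write_xyz_file(xyz, cx$symbols, coords)
  args <- c(shQuote(xyz), "--gfn", "1", "--alpb", engine$solvent,
            "--chrg", cx$net_charge, "--uhf", "0")
  if (optimize) args <- c(args, "--opt")
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE)
  out <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = TRUE))
  eline <- grep("TOTAL ENERGY", out, value = TRUE)
  if (!length(eline)) {
    return(list(energy_kcal = NA_real_, coords = coords, converged = FALSE))
  }
  eh <- as.numeric(regmatches(eline[length(eline)],
                              regexpr("-?[0-9]+\\.[0-9]+", eline[length(eline)])))
  final <- coords
  optfile <- file.path(dir, "xtbopt.xyz")
  if (optimize && file.exists(optfile)) {
    lines <- readLines(optfile)
    n <- as.integer(lines[1])
    parts <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
    final <- do.call(rbind, lapply(parts, function(p) as.numeric(p[2:4])))
  }
  converged <- !optimize || any(grepl("GEOMETRY OPTIMIZATION CONVERGED", out))
  list(energy_kcal = eh * HARTREE_TO_KCAL, coords = final,
       converged = converged)
}

run_orca <- function(engine, cx, coords) {
  bin <- external_binary(engine)
  dir <- tempfile("orca")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  inp <- file.path(dir, "sp.inp")
  xyzlines <- sprintf("%-3s %14.8f %14.8f %14.8f", cx$symbols,
                      coords[, 1], coords[, 2], coords[, 3])
  writeLines(c("! r2SCAN-3c CPCM(CH2Cl2)",
               sprintf("* xyz %d %d", cx$net_charge, cx$spin),
               xyzlines, "*"), inp)
  out <- suppressWarnings(system2(bin, shQuote(inp), stdout = TRUE,
                                  stderr = TRUE))
  eline <- grep("FINAL SINGLE POINT ENERGY", out, value = TRUE)
  if (!length(eline)) {
    abort("ORCA run produced no final energy",
          class = "regiopd_backend_error")
  }
  eh <- as.numeric(regmatches(eline[1], regexpr("-?[0-9]+\\.[0-9]+",
                                                eline[1])))
  list(energy_kcal = eh * HARTREE_TO_KCAL, coords = coords, converged = TRUE)
}

engine_dispatch <- function(engine, cx, coords, optimize) {
  switch(engine$name,
         mock = ,
         mock_sp = list(energy_kcal = mock_energy(engine, cx, coords),
                        coords = coords, converged = TRUE),
         forcefield = {
           r <- chem_backend("uff", smiles = cx$smiles,
                             site = cx$pair$site_atom, dg = cx$pair$dg_atom,
                             coords = apply(coords, 1, as.list,
                                            simplify = FALSE),
                             optimize = optimize)
           list(energy_kcal = r$energy_kcal, coords = coords_matrix(r$coords),
                converged = isTRUE(r$converged))
         },
         xtb = run_xtb(engine, cx, coords, optimize = optimize),
         orca = run_orca(engine, cx, coords))
}

require_capability <- function(engine, cap) {
  stopifnot(inherits(engine, "engine_spec"))
  if (!cap %in% engine$capabilities) {
    abort(paste0("engine '", engine$name, "' does not support ", cap),
          class = "regiopd_capability_error")
  }
}

#' Optimize one conformer and validate the resulting geometry
#'
#' Runs the engine's optimizer from the given coordinates, then applies the
#' two geometry checks that gate entry into the ranking: connectivity away
#' from the metal must be unchanged ([check_connectivity()]) and the four Pd
#' coordination partners must be coplanar with Pd ([check_planarity()]).
#'
#' @param engine an [engine_spec()] supporting `optimize`.
#' @param cx a [build_complex()] object.
#' @param coords starting n_atoms x 3 coordinate matrix.
#' @return a list: `coordinates`, `energy_kcal`, `converged`,
#'   `valid_connectivity`, `valid_planarity`, `planarity_angle_deg`, `valid`.
#' @export
optimize_geometry <- function(engine, cx, coords) {
  require_capability(engine, "optimize")
  res <- engine_dispatch(engine, cx, coords, optimize = TRUE)
  validate_geometry(cx, coords, res)
}

validate_geometry <- function(cx, before, res) {
  ix <- cx$index_map
  conn <- check_connectivity(cx, before, res$coords)
  plan <- tryCatch(
    check_planarity(res$coords, ix$pd, ix$site, ix$dg, ix$o1, ix$o2),
    error = function(e) list(angle_deg = NA_real_, ok = FALSE)
  )
  list(coordinates = res$coords,
       energy_kcal = res$energy_kcal,
       converged = res$converged,
       valid_connectivity = conn,
       valid_planarity = plan$ok,
       planarity_angle_deg = plan$angle_deg,
       valid = res$converged && conn && plan$ok)
}

#' Single-point energy at a fixed geometry
#'
#' @param engine an [engine_spec()] supporting `singlepoint`.
#' @param cx a [build_complex()] object.
#' @param coords n_atoms x 3 coordinate matrix.
#' @return energy in kcal/mol.
#' @export
single_point <- function(engine, cx, coords) {
  require_capability(engine, "singlepoint")
  engine_dispatch(engine, cx, coords, optimize = FALSE)$energy_kcal
}

perceive_bonds <- function(z, coords, scale = 1.25) {
  n <- length(z)
  r <- covalent_radius(z)
  d <- as.matrix(stats::dist(coords))
  thr <- outer(r, r, "+") * scale
  hits <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  sprintf("%d_%d", hits[, 1] - 1L, hits[, 2] - 1L)
}

#' Check that connectivity away from the metal is preserved
#'
#' Bonds are perceived from both geometries with the covalent-radius
#' criterion (bonded iff distance <= 1.25 x sum of covalent radii); any bond
#' involving Pd is ignored, since bond perception at the metal is unreliable.
#' Returns TRUE iff the two perceived bond sets are identical.
#'
#' @param cx a [build_complex()] object (supplies atomic numbers and the Pd
#'   index).
#' @param before,after n_atoms x 3 coordinate matrices.
#' @return logical.
#' @export
check_connectivity <- function(cx, before, after) {
  stopifnot(nrow(before) == cx$n_atoms, nrow(after) == cx$n_atoms)
  pd <- cx$index_map$pd
  drop_pd <- function(keys) {
    ij <- do.call(rbind, strsplit(keys, "_"))
    keys[ij[, 1] != as.character(pd) & ij[, 2] != as.character(pd)]
  }
  b <- drop_pd(perceive_bonds(cx$z, before))
  a <- drop_pd(perceive_bonds(cx$z, after))
  setequal(a, b)
}

#' Check coplanarity of the Pd coordination sphere
#'
#' Computes the angle between the normal of the plane spanned by (Pd, site
#' carbon, directing heteroatom) and the normal of the plane spanned by (Pd,
#' acetate O1, acetate O2), folded into \[0, 90\] degrees because plane
#' normals carry a sign ambiguity. The square-planar intermediate passes when
#' this angle is strictly below `max_angle_deg`.
#'
#' @param coords n_atoms x 3 coordinate matrix.
#' @param pd,site_c,dg_x,o1,o2 0-based atom indices of the labelled atoms.
#' @param max_angle_deg pass threshold in degrees (default 5, strict).
#' @return a list with `angle_deg` and `ok`.
#' @export
check_planarity <- function(coords, pd, site_c, dg_x, o1, o2,
                            max_angle_deg = 5) {
  at <- function(i) coords[i + 1L, ]
  n1 <- cross3(at(site_c) - at(pd), at(dg_x) - at(pd))
  n2 <- cross3(at(o1) - at(pd), at(o2) - at(pd))
  if (sqrt(sum(n1^2)) < 1e-8 || sqrt(sum(n2^2)) < 1e-8) {
    abort("degenerate (collinear) atom triple in planarity check",
          class = "regiopd_geometry_error")
  }
  cosang <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  ang <- acos(pmin(1, pmax(-1, abs(cosang)))) * 180 / pi
  list(angle_deg = ang, ok = ang < max_angle_deg)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
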