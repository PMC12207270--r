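#' Build a substrate-Pd(OAc) palladacycle intermediate
#'
#' Constructs the molecular graph of the palladacycle intermediate for one
#' candidate pair: the substrate with the site hydrogen removed, a Pd centre
#' sigma-bonded to the site carbon, the directing heteroatom coordinated to
#' Pd, and a kappa-2 acetate (both oxygens bound to Pd). The complex carries
#' the substrate's net charge (Pd(II) + acetate(-1) + aryl(-1) cancel) and a
#' singlet spin state.
#'
#' @param sub a [parse_substrate()] object.
#' @param pair a one-row tibble (or list) with `site_atom` and `dg_atom`.
#' @return an object of class `palladacycle`.
#' @export
build_complex <- function(sub, pair) {
  stopifnot(inherits(sub, "substrate"))
  site <- as.integer(pair$site_atom)
  dg <- as.integer(pair$dg_atom)
  resp <- chem_backend("complex", smiles = sub$smiles_input,
                       site = site, dg = dg)
  structure(
    list(
      smiles = sub$smiles_input,
      pair = tibble(site_atom = site, dg_atom = dg),
      symbols = unlist(resp$symbols),
      z = as.integer(unlist(resp$z)),
      bonds = bind_rows(lapply(resp$bonds, as_tibble)),
      index_map = lapply(resp$index_map, as.integer),
      net_charge = resp$net_charge,
      spin = 1L,
      n_atoms = resp$n_atoms,
      n_rot_substrate = resp$n_rot_substrate,
      molblock = resp$molblock
    ),
    class = "palladacycle"
  )
}

#' @export
print.palladacycle <- function(x, ...) {
  cat("<palladacycle> ", x$smiles, "\n", sep = "")
  cat("  site C: ", x$pair$site_atom, "  DG atom: ", x$pair$dg_atom,
      "  atoms: ", x$n_atoms, "  charge: ", x$net_charge,
      " (singlet)\n", sep = "")
  invisible(x)
}

#' Generate a distance-geometry conformer ensemble
#'
#' Requests `3 * N_rot + 3` ETKDG embeddings of the complex, where `N_rot` is
#' the number of rotatable bonds of the substrate alone (the Pd-ligand
#' framework does not count). Pd-ligand distance bounds are set from covalent
#' radii with 15% slack before embedding, since distance geometry is not
#' metal-aware. Failed embeddings are dropped without retry.
#'
#' @param cx a [build_complex()] object.
#' @param seed integer embedding seed; fixed seed gives identical coordinates.
#' @return an object of class `conformer_ensemble` with elements `complex`,
#'   `coords` (list of n_atoms x 3 matrices), `n_requested`, and (after
#'   [cluster_conformers()]) `cluster` / `representatives`.
#' @export
generate_conformers <- function(cx, seed = 1) {
  stopifnot(inherits(cx, "palladacycle"))
  n_req <- 3L * cx$n_rot_substrate + 3L
  resp <- chem_backend("conformers", smiles = cx$smiles,
                       site = cx$pair$site_atom, dg = cx$pair$dg_atom,
                       n = n_req, seed = as.integer(seed))
  coords <- lapply(resp$coords, coords_matrix)
  if (!length(coords)) {
    warn(paste0("all ", n_req, " embeddings failed for pair (",
                cx$pair$site_atom, ", ", cx$pair$dg_atom,
                "); complex excluded"))
  }
  structure(
    list(complex = cx, coords = coords, n_requested = n_req,
         cluster = NULL, representatives = NULL),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", length(x$coords), "/", x$n_requested,
      " conformers", sep = "")
  if (!is.null(x$representatives)) {
    cat("; ", length(x$representatives), " cluster representatives",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

# Kabsch-aligned RMSD between two coordinate matrices (rows = atoms)
aligned_rmsd <- function(a, b) {
  bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
}

rmsd_matrix <- function(coords) {
  n <- length(coords)
  d <- matrix(0, n, n)
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- aligned_rmsd(coords[[i]], coords[[j]])
    }
  }
  d
}

# Butina-style clustering on a distance matrix; representative = medoid.
# Returns list(cluster = assignment vector, representatives = one index per
# cluster, in cluster-id order).
cluster_by_distance <- function(d, cutoff) {
  n <- nrow(d)
  d[is.na(d)] <- Inf      # failed alignments count as infinitely distant
  assign <- rep(NA_integer_, n)
  cl <- 0L
  while (anyNA(assign)) {
    open <- which(is.na(assign))
    counts <- vapply(open, function(i) sum(d[i, open] <= cutoff), numeric(1))
    leader <- open[which.max(counts)]
    members <- open[d[leader, open] <= cutoff]
    cl <- cl + 1L
    assign[members] <- cl
  }
  reps <- vapply(seq_len(cl), function(k) {
    members <- which(assign == k)
    if (length(members) == 1L) return(members)
    tot <- vapply(members, function(i) sum(d[i, members]), numeric(1))
    members[which.min(tot)]
  }, integer(1))
  list(cluster = assign, representatives = reps)
}

#' Cluster a conformer ensemble by heavy-atom RMSD
#'
#' Conformers are clustered on pairwise Kabsch-aligned heavy-atom RMSD with
#' the given cutoff (Butina neighbour-count clustering; no graph-automorphism
#' symmetry correction). Within each cluster the retained representative is
#' the medoid, the member minimizing total RMSD to the other members.
#'
#' @param ens a [generate_conformers()] ensemble.
#' @param cutoff_angstrom RMSD cutoff in Angstrom (default 1.0).
#' @return the ensemble with `cluster` (assignment per conformer) and
#'   `representatives` (conformer indices) filled in.
#' @export
cluster_conformers <- function(ens, cutoff_angstrom = 1.0) {
  stopifnot(inherits(ens, "conformer_ensemble"))
  if (!length(ens$coords)) {
    ens$cluster <- integer(0)
    ens$representatives <- integer(0)
    return(ens)
  }
  heavy <- ens$complex$z > 1L
  d <- rmsd_matrix(lapply(ens$coords, function(m) m[heavy, , drop = FALSE]))
  res <- cluster_by_distance(d, cutoff_angstrom)
  ens$cluster <- res$cluster
  ens$representatives <- res$representatives
  ens
}
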