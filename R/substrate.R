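#' Parse a substrate SMILES
#'
#' Parses a SMILES string into an immutable substrate object holding the atom
#' and bond tables used throughout the workflow. Atom indices are 0-based and
#' follow the input SMILES atom order; they are stable for the lifetime of the
#' object and are the indices used in every downstream table and report.
#'
#' Two derived per-atom flags drive site/DG enumeration:
#' * `sp2_ch` — sp2-hybridized carbon carrying at least one hydrogen, i.e. a
#'   potential C-H activation site;
#' * `dg_donor` — N, O or S bearing at least one available lone pair (the
#'   pyrrole-type aromatic nitrogen, whose lone pair is part of the aromatic
#'   sextet, does not qualify; quaternary/protonated nitrogens do not either).
#'   Phosphorus donors can be admitted with `options(regiopd.donor_elements =
#'   c("N","O","S","P"))`.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `substrate`: a list with elements `smiles`
#'   (canonical), `smiles_input`, `atoms` (tibble), `bonds` (tibble),
#'   `net_charge` and `n_rot` (rotatable bonds of the substrate).
#' @examples
#' \dontrun{
#' sub <- parse_substrate("c1ccc(-c2ccccn2)cc1")
#' sub$atoms
#' }
#' @export
parse_substrate <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  donors <- getOption("regiopd.donor_elements", c("N", "O", "S"))
  resp <- chem_backend("parse", smiles = smiles,
                       donor_elements = as.list(donors))
  atoms <- bind_rows(lapply(resp$atoms, as_tibble))
  bonds <- bind_rows(lapply(resp$bonds, as_tibble))
  structure(
    list(
      smiles = resp$canonical_smiles,
      smiles_input = smiles,
      atoms = atoms,
      bonds = bonds,
      net_charge = resp$net_charge,
      n_rot = resp$n_rot
    ),
    class = "substrate"
  )
}

#' @export
print.substrate <- function(x, ...) {
  cat("<substrate> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", nrow(x$atoms),
      "  (sp2 C-H sites: ", sum(x$atoms$sp2_ch),
      ", DG donors: ", sum(x$atoms$dg_donor), ")\n", sep = "")
  cat("  bonds: ", nrow(x$bonds),
      "  net charge: ", x$net_charge,
      "  rotatable bonds: ", x$n_rot, "\n", sep = "")
  invisible(x)
}

# bond graph as an igraph object (atom ids stored as 0-based names)
substrate_graph <- function(sub) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(sub$bonds$i), to = as.character(sub$bonds$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(sub$atoms$atom))
  )
}

classes_from_marks <- function(atoms, marks) {
  ids <- match(marks, unique(marks))
  tibble(atom = as.integer(atoms), class_id = as.integer(ids),
         mark_smiles = as.character(marks))
}

#' Symmetry classes of candidate C-H sites
#'
#' Two sites are symmetry-equivalent when attaching one explicit, labelled
#' hydrogen at each of them yields the same canonical SMILES. Equivalent sites
#' give rise to identical palladacycle intermediates, so only one per class is
#' carried through the workflow.
#'
#' @param sub a [parse_substrate()] object.
#' @param sites integer vector of candidate site atom indices (0-based);
#'   defaults to every sp2 C-H atom.
#' @return a tibble with columns `atom`, `class_id`, `mark_smiles`. Class ids
#'   are 1-based in first-appearance order of `sites`.
#' @export
site_symmetry_classes <- function(sub, sites = NULL) {
  stopifnot(inherits(sub, "substrate"))
  if (is.null(sites)) sites <- sub$atoms$atom[sub$atoms$sp2_ch]
  sites <- as.integer(sites)
  if (length(sites) == 0L) {
    return(tibble(atom = integer(), class_id = integer(),
                  mark_smiles = character()))
  }
  bad <- sites[sub$atoms$n_h[match(sites, sub$atoms$atom)] < 1]
  if (length(bad)) {
    abort(paste0("site atom(s) without hydrogen: ",
                 paste(bad, collapse = ", ")),
          class = "regiopd_precondition_error")
  }
  marks <- chem_backend("site_marks", smiles = sub$smiles_input,
                        sites = as.list(sites))$marks
  classes_from_marks(sites, unlist(marks))
}

#' Symmetry classes of directing heteroatoms
#'
#' Two heteroatoms are symmetry-equivalent when coordinating a dummy atom to
#' each of them yields the same canonical SMILES (the dummy is attached with a
#' dative bond so aromatic systems are unperturbed).
#'
#' @param sub a [parse_substrate()] object.
#' @param heteroatoms integer vector of donor atom indices (0-based); defaults
#'   to every qualifying lone-pair N/O/S.
#' @return a tibble with columns `atom`, `class_id`, `mark_smiles`.
#' @export
dg_symmetry_classes <- function(sub, heteroatoms = NULL) {
  stopifnot(inherits(sub, "substrate"))
  if (is.null(heteroatoms)) heteroatoms <- sub$atoms$atom[sub$atoms$dg_donor]
  heteroatoms <- as.integer(heteroatoms)
  if (length(heteroatoms) == 0L) {
    return(tibble(atom = integer(), class_id = integer(),
                  mark_smiles = character()))
  }
  marks <- chem_backend("dg_marks", smiles = sub$smiles_input,
                        atoms = as.list(heteroatoms))$marks
  classes_from_marks(heteroatoms, unlist(marks))
}

#' Randomly renumbered writings of a SMILES
#'
#' Utility for invariance testing: returns `n` SMILES strings for the same
#' molecule written in randomly permuted atom orders, together with the
#' permutation (`perm[new_index + 1] = old_index`, 0-based values).
#'
#' @param smiles a SMILES string.
#' @param n number of renumberings.
#' @param seed integer seed.
#' @return a tibble with columns `smiles` and `perm` (list-column).
#' @export
renumber_smiles <- function(smiles, n = 10, seed = 1) {
  resp <- chem_backend("renumber", smiles = smiles, n = n, seed = seed)
  tibble(
    smiles = map_chr(resp$renumbered, "smiles"),
    perm = map(resp$renumbered, ~ as.integer(unlist(.x$perm)))
  )
}
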