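#' Enumerate all (C-H site, heteroatom) pairs for remote directing groups
#'
#' For meta-, para- and remote-directed activation the ortho path-length rule
#' does not apply. Instead, the symmetry-unique sp2 C-H sites and the
#' symmetry-unique donor heteroatoms are combined as a Cartesian product with
#' no path-length restriction; geometric feasibility is judged afterwards by
#' [strain_screen()].
#'
#' @param sub a [parse_substrate()] object.
#' @return a tibble of candidate pairs (`provenance = "remote_cartesian"`).
#' @export
enumerate_all_pairs <- function(sub) {
  stopifnot(inherits(sub, "substrate"))
  sc <- site_symmetry_classes(sub)
  dc <- dg_symmetry_classes(sub)
  if (!nrow(sc) || !nrow(dc)) return(empty_pairs())
  sites <- summarise(group_by(sc, .data$class_id),
                     atom = min(.data$atom), .groups = "drop")$atom
  donors <- summarise(group_by(dc, .data$class_id),
                      atom = min(.data$atom), .groups = "drop")$atom
  g <- substrate_graph(sub)
  d <- igraph::distances(g, v = as.character(sites), to = as.character(donors))
  out <- tibble(
    site_atom = rep(as.integer(sites), times = length(donors)),
    dg_atom = rep(as.integer(donors), each = length(sites)),
    path_bonds = as.integer(as.vector(d))
  )
  out <- filter(out, .data$site_atom != .data$dg_atom)
  out <- mutate(out, ring_size = .data$path_bonds + 2L,
                provenance = "remote_cartesian")
  arrange(out, .data$site_atom, .data$dg_atom)
}

#' Force-field ring-strain screen for candidate pairs
#'
#' Probes whether a pair can close a geometrically reasonable palladacycle
#' without involving the metal: the site hydrogen is removed and a CCl2
#' fragment is bridged between the site carbon and the heteroatom, mimicking
#' the Pd(OAc)2 unit with a force-field-parameterizable dummy. The dummy ring
#' is embedded with distance geometry (ETKDG) and optimized with MMFF94s; the
#' strain score is the sum of the out-of-plane angle and torsion terms of the
#' optimized structure. Pairs are kept when embedding succeeds and the strain
#' is at or below `threshold_kcal`.
#'
#' @param sub a [parse_substrate()] object.
#' @param pairs candidate pairs, typically from [enumerate_all_pairs()].
#' @param threshold_kcal strain threshold in kcal/mol (default 10).
#' @param seed embedding seed (default 0xC0FFEE).
#' @param attempts embedding attempts before declaring failure (default 10).
#' @return `pairs` with added columns `embed_ok`, `strain_kcal`, `kept` and
#'   `reason` (for rejected pairs).
#' @export
strain_screen <- function(sub, pairs, threshold_kcal = 10,
                          seed = 0xC0FFEE, attempts = 10) {
  stopifnot(inherits(sub, "substrate"))
  if (!nrow(pairs)) {
    return(mutate(pairs, embed_ok = logical(0), strain_kcal = numeric(0),
                  kept = logical(0), reason = character(0)))
  }
  resp <- chem_backend("strain", smiles = sub$smiles_input,
                       pairs = pmap(list(site = pairs$site_atom,
                                         dg = pairs$dg_atom), list),
                       seed = seed, attempts = attempts)
  res <- map(resp$results, function(r) {
    if (!isTRUE(r$embed_ok)) {
      return(list(embed_ok = FALSE, strain = NA_real_, kept = FALSE,
                  reason = r$reason %||% "embedding failed"))
    }
    if (!isTRUE(r$param_ok)) {
      return(list(embed_ok = TRUE, strain = NA_real_, kept = FALSE,
                  reason = r$reason %||% "force field unparameterized"))
    }
    list(embed_ok = TRUE, strain = r$strain_kcal,
         kept = r$strain_kcal <= threshold_kcal, reason = NA_character_)
  })
  mutate(pairs,
         embed_ok = map_lgl(res, "embed_ok"),
         strain_kcal = map_dbl(res, "strain"),
         kept = map_lgl(res, "kept"),
         reason = map_chr(res, "reason"))
}
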