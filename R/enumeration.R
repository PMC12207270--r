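#' Ideal internal angle of a planar ring
#'
#' Internal angle of a regular polygon with `n_atoms` vertices,
#' `(n_atoms - 2) * 180 / n_atoms` degrees. Used as the reference when
#' screening candidate palladacycle rings in a 2D embedding.
#'
#' @param n_atoms ring size (>= 3), vectorized.
#' @return angle in degrees.
#' @examples
#' ideal_ring_angle(4:6) # 90, 108, 120
#' @export
ideal_ring_angle <- function(n_atoms) {
  if (any(n_atoms < 3)) {
    abort("a ring needs at least 3 atoms", class = "regiopd_precondition_error")
  }
  (n_atoms - 2) * 180 / n_atoms
}

#' Enumerate ortho-directed (C-H site, heteroatom) pairs
#'
#' All combinations of an sp2 C-H carbon and a lone-pair directing heteroatom
#' whose shortest topological path is 2-5 bonds. These are the candidates for
#' small (4- to 7-membered) palladacycle intermediates; geometric filtering
#' and symmetry deduplication happen downstream.
#'
#' @param sub a [parse_substrate()] object.
#' @return a tibble of candidate pairs: `site_atom`, `dg_atom`, `path_bonds`,
#'   `ring_size` (= path_bonds + 2, counting Pd), `provenance`.
#' @export
find_ortho_pairs <- function(sub) {
  stopifnot(inherits(sub, "substrate"))
  sites <- sub$atoms$atom[sub$atoms$sp2_ch]
  donors <- sub$atoms$atom[sub$atoms$dg_donor]
  if (!length(sites) || !length(donors)) return(empty_pairs())
  g <- substrate_graph(sub)
  d <- igraph::distances(g,
                         v = as.character(sites),
                         to = as.character(donors))
  out <- tibble(
    site_atom = rep(sites, times = length(donors)),
    dg_atom = rep(donors, each = length(sites)),
    path_bonds = as.integer(as.vector(d))
  )
  out <- filter(out, .data$path_bonds >= 2L, .data$path_bonds <= 5L)
  out <- mutate(out,
                ring_size = .data$path_bonds + 2L,
                provenance = "ortho_smarts")
  arrange(out, .data$site_atom, .data$dg_atom)
}

empty_pairs <- function() {
  tibble(site_atom = integer(), dg_atom = integer(), path_bonds = integer(),
         ring_size = integer(), provenance = character())
}

# internal angles (degrees) at each vertex of a closed polygon given as an
# n x 2 (or n x 3) coordinate matrix in ring order
ring_internal_angles <- function(coords) {
  n <- nrow(coords)
  vapply(seq_len(n), function(k) {
    b <- coords[k, ]
    v1 <- coords[if (k == 1) n else k - 1, ] - b
    v2 <- coords[if (k == n) 1 else k + 1, ] - b
    cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
    acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }, numeric(1))
}

#' 2D ring-angle filter for candidate palladacycles
#'
#' For each candidate pair, the substrate plus a Pd placeholder closing the
#' ring through the site carbon and the heteroatom is laid out in a single
#' plane (2D coordinates). Each internal angle of that ring is compared with
#' the ideal planar angle for its ring size; a pair fails when any angle
#' deviates relatively by more than `tolerance` (the boundary is inclusive:
#' a deviation of exactly `tolerance` passes). Pairs whose 2D embedding fails
#' are rejected with a warning.
#'
#' @param sub a [parse_substrate()] object.
#' @param pairs tibble from [find_ortho_pairs()].
#' @param tolerance maximum relative deviation (default 0.10).
#' @param include_pd_angle also test the internal angle at the Pd placeholder
#'   (default TRUE).
#' @return `pairs` with added columns `max_rel_dev` and `angle_ok`.
#' @export
passes_angle_filter <- function(sub, pairs, tolerance = 0.10,
                                include_pd_angle = TRUE) {
  stopifnot(inherits(sub, "substrate"))
  if (!nrow(pairs)) {
    return(mutate(pairs, max_rel_dev = numeric(0), angle_ok = logical(0)))
  }
  resp <- chem_backend("ring2d", smiles = sub$smiles_input,
                       pairs = pmap(list(site = pairs$site_atom,
                                         dg = pairs$dg_atom), list))
  res <- pmap(list(pairs$site_atom, pairs$dg_atom, pairs$ring_size,
                   resp$results),
              function(site, dg, ring_size, r) {
    if (!isTRUE(r$embed_ok)) {
      warn(paste0("2D embedding failed for pair (", site, ", ", dg, "): ",
                  r$reason %||% "unknown"))
      return(c(dev = NA_real_, ok = 0))
    }
    coords <- coords_matrix(r$coords)
    ang <- ring_internal_angles(coords)
    if (!include_pd_angle) ang <- ang[-length(ang)]
    dev <- max(abs(ang - ideal_ring_angle(ring_size)) /
                 ideal_ring_angle(ring_size))
    c(dev = dev, ok = as.numeric(dev <= tolerance))
  })
  mutate(pairs,
         max_rel_dev = map_dbl(res, "dev"),
         angle_ok = map_dbl(res, "ok") == 1)
}

# resonance-equivalent donor oxygens: nitro and carboxylate groups
resonance_groups <- function(sub) {
  pats <- c("[NX3](=[OX1])[OX1]", "[N+](=[OX1])[O-]", "[CX3](=[OX1])[O-]")
  m <- chem_backend("smarts", smiles = sub$smiles_input,
                    patterns = as.list(pats))$matches
  if (!length(m)) return(tibble(atom = integer(), res_group = integer()))
  rows <- imap(m, function(x, k) {
    atoms <- as.integer(unlist(x$atoms))
    z <- as.integer(unlist(x$z))
    tibble(atom = atoms[z == 8L], key = paste0(sort(atoms), collapse = "_"))
  })
  out <- distinct(bind_rows(rows))
  mutate(out, res_group = match(.data$key, unique(.data$key)))[
    c("atom", "res_group")]
}

#' Remove symmetry- and resonance-duplicate candidate pairs
#'
#' Pairs are grouped by the cross product of site symmetry class and directing
#' heteroatom symmetry class; donor atoms that are the two oxygens of a nitro
#' or carboxylate group are additionally merged (equivalent resonance forms).
#' One representative pair per group is kept (lowest `site_atom`, then
#' `dg_atom`). The operation is idempotent.
#'
#' @param sub a [parse_substrate()] object.
#' @param pairs tibble of candidate pairs from the same substrate.
#' @return the deduplicated pairs tibble with added `site_class` and
#'   `dg_class` columns.
#' @export
dedup_pairs <- function(sub, pairs) {
  stopifnot(inherits(sub, "substrate"))
  if (!nrow(pairs)) {
    return(mutate(pairs, site_class = integer(), dg_class = integer()))
  }
  sc <- site_symmetry_classes(sub, unique(pairs$site_atom))
  dc <- dg_symmetry_classes(sub, unique(pairs$dg_atom))
  res <- resonance_groups(sub)
  pairs$site_class <- NULL
  pairs$dg_class <- NULL
  out <- left_join(pairs, rename(sc[c("atom", "class_id")],
                                 site_class = "class_id"),
                   by = c(site_atom = "atom"))
  out <- left_join(out, rename(dc[c("atom", "class_id")],
                               dg_class = "class_id"),
                   by = c(dg_atom = "atom"))
  out <- left_join(out, res, by = c(dg_atom = "atom"))
  out <- mutate(out, .dg_key = ifelse(is.na(.data$res_group),
                                      paste0("c", .data$dg_class),
                                      paste0("r", .data$res_group)))
  out <- arrange(out, .data$site_atom, .data$dg_atom)
  out <- group_by(out, .data$site_class, .data$.dg_key)
  out <- ungroup(filter(out, row_number() == 1L))
  arrange(select(out, -".dg_key", -"res_group"),
          .data$site_atom, .data$dg_atom)
}
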