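#' Load a SMARTS directing-group strength table
#'
#' The lookup-table predictor works from a TSV with columns `smarts` (the
#' first SMARTS atom must be the reactive aromatic CH, `[cH1]`) and
#' `dg_strength_kcal` (relative palladacycle energy for that directing
#' environment; more negative = stronger directing). A table with the
#' directing groups printed in the original hierarchy publication is bundled
#' as `system.file("extdata", "tomberg_patterns.tsv", package = "regiopd")`;
#' users supply the full table in the same format.
#'
#' @param path path to the TSV file.
#' @return a tibble with columns `smarts`, `dg_strength_kcal`.
#' @export
load_pattern_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    smarts = readr::col_character(),
    dg_strength_kcal = readr::col_double()
  ))
  if (!nrow(tab)) {
    warn(paste0("pattern table is empty: ", path))
    return(tab)
  }
  dup <- tab$smarts[duplicated(tab$smarts)]
  if (length(dup)) {
    abort(paste0("duplicate SMARTS in pattern table: ",
                 paste(unique(dup), collapse = ", ")),
          class = "regiopd_input_error")
  }
  for (k in seq_len(nrow(tab))) {
    ok <- tryCatch({
      chem_backend("smarts", smiles = "c1ccccc1",
                   patterns = list(tab$smarts[k]))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      abort(paste0("row ", k, ": malformed SMARTS '", tab$smarts[k], "'"),
            class = "regiopd_input_error")
    }
  }
  tab
}

# stable three-key sort: most heavy atoms first, then highest atomic-number
# sum, then lowest (most negative) DG strength; equal keys keep input order
three_key_order <- function(n_heavy, z_sum, dg_strength) {
  order(-n_heavy, -z_sum, dg_strength)
}

#' Match directing-group SMARTS patterns onto a substrate
#'
#' Every substructure match of every table pattern is recorded against the
#' site atom it fires on (the `[cH1]` atom, first in the SMARTS). Per site,
#' matches are ranked by the three-key priority: number of heavy atoms
#' matched (descending, most specific pattern first), then sum of atomic
#' numbers of the matched heavy atoms (descending, heteroatom matches beat
#' carbon), then DG strength (ascending, strongest directing first). Generic
#' SMARTS atoms (`A`, `[C,c]`) contribute the atomic number of the atom they
#' actually matched.
#'
#' @param smiles substrate SMILES.
#' @param table a [load_pattern_table()] tibble.
#' @return a tibble of match records: `site_atom`, `smarts`,
#'   `dg_strength_kcal`, `n_heavy`, `z_sum`, `rank_at_site`, sorted by site
#'   then rank. Empty when nothing matches.
#' @export
match_patterns <- function(smiles, table) {
  empty <- tibble(site_atom = integer(), smarts = character(),
                  dg_strength_kcal = numeric(), n_heavy = integer(),
                  z_sum = integer(), rank_at_site = integer())
  if (!nrow(table)) return(empty)
  resp <- chem_backend("smarts", smiles = smiles,
                       patterns = as.list(table$smarts))
  if (!length(resp$matches)) return(empty)
  rec <- bind_rows(lapply(resp$matches, function(m) {
    z <- as.integer(unlist(m$z))
    tibble(site_atom = as.integer(m$atoms[[1]]),
           pattern = as.integer(m$pattern) + 1L,
           n_heavy = sum(z > 1L), z_sum = sum(z[z > 1L]))
  }))
  rec$smarts <- table$smarts[rec$pattern]
  rec$dg_strength_kcal <- table$dg_strength_kcal[rec$pattern]
  parts <- lapply(split(rec, rec$site_atom), function(df) {
    df <- df[three_key_order(df$n_heavy, df$z_sum, df$dg_strength_kcal), ]
    df$rank_at_site <- seq_len(nrow(df))
    df
  })
  out <- bind_rows(parts)
  out <- arrange(out, .data$site_atom, .data$rank_at_site)
  select(out, "site_atom", "smarts", "dg_strength_kcal", "n_heavy",
         "z_sum", "rank_at_site")
}

#' Predict the reaction site from the pattern table
#'
#' Each matched site is assigned the DG strength of its top-ranked pattern;
#' the predicted reaction sites are those achieving the minimum (strongest)
#' assigned strength, with ties all reported. Symmetry-equivalent sites are
#' listed individually, as in the program's visual output.
#'
#' @param smiles substrate SMILES.
#' @param table a [load_pattern_table()] tibble.
#' @return an object of class `pattern_prediction`: list with
#'   `predicted_sites` (atom indices), `report` (per-site tibble with the
#'   assigned strength) and `matches` (the full [match_patterns()] table).
#'   When no pattern matches, `predicted_sites` is `NULL` and the object's
#'   `no_prediction` flag is TRUE ("no prediction possible", as opposed to an
#'   empty prediction).
#' @export
predict_site_from_patterns <- function(smiles, table) {
  m <- match_patterns(smiles, table)
  if (!nrow(m)) {
    return(structure(list(smiles = smiles, predicted_sites = NULL,
                          report = m, matches = m, no_prediction = TRUE),
                     class = "pattern_prediction"))
  }
  top <- filter(m, .data$rank_at_site == 1L)
  report <- select(top, "site_atom", assigned_strength_kcal =
                     "dg_strength_kcal", "smarts", "n_heavy", "z_sum")
  best <- min(report$assigned_strength_kcal)
  structure(
    list(smiles = smiles,
         predicted_sites =
           report$site_atom[report$assigned_strength_kcal == best],
         report = report, matches = m, no_prediction = FALSE),
    class = "pattern_prediction"
  )
}

#' @export
print.pattern_prediction <- function(x, ...) {
  cat("<pattern_prediction> ", x$smiles, "\n", sep = "")
  if (x$no_prediction) {
    cat("  no pattern matched: no prediction possible\n")
  } else {
    cat("  predicted site atom(s): ",
        paste(x$predicted_sites, collapse = ", "), "\n", sep = "")
    print(x$report)
  }
  invisible(x)
}

#' @method tidy pattern_prediction
#' @export
tidy.pattern_prediction <- function(x, ...) x$matches

#' @method glance pattern_prediction
#' @export
glance.pattern_prediction <- function(x, ...) {
  tibble(n_sites_matched = length(unique(x$matches$site_atom)),
         n_predicted = length(x$predicted_sites %||% integer()),
         no_prediction = x$no_prediction)
}

#' @method autoplot pattern_prediction
#' @export
autoplot.pattern_prediction <- function(object, ...) {
  if (object$no_prediction) {
    abort("nothing to plot: no pattern matched",
          class = "regiopd_input_error")
  }
  df <- object$report
  df$site <- factor(df$site_atom)
  df$predicted <- df$site_atom %in% object$predicted_sites
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site,
                                   y = .data$assigned_strength_kcal,
                                   fill = .data$predicted)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d62828",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = "matched site (atom index)",
                  y = "assigned DG strength [kcal/mol]",
                  title = "Lookup-table site prediction")
}
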