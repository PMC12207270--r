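#' Rank reaction sites by palladacycle intermediate energy
#'
#' Takes one row per surviving complex with the energy of its best valid
#' conformer, computes relative energies against the global minimum, and
#' collects every site whose complex lies within `threshold_kcal` of that
#' minimum as a predicted reaction site. The global-minimum site is always
#' predicted; with `threshold_kcal = 0` only exact ties join it. Site order
#' in the predicted set follows relative energy, ties broken by site atom
#' index.
#'
#' @param results a tibble with columns `site_atom`, `dg_atom`, `site_class`,
#'   `energy_kcal` (best valid conformer energy per complex, kcal/mol);
#'   optional list-columns `complex` and `coords` are carried along and are
#'   needed by [refine()].
#' @param threshold_kcal energy window in kcal/mol (default 1.0).
#' @param drop_log optional tibble describing complexes excluded upstream
#'   (attached to the prediction for diagnostics).
#' @return an object of class `ch_prediction`.
#' @export
rank_sites <- function(results, threshold_kcal = 1.0, drop_log = NULL) {
  stopifnot(is.data.frame(results), threshold_kcal >= 0)
  if (!nrow(results) || all(is.na(results$energy_kcal))) {
    abort(paste0("no complex produced a valid optimized conformer; ",
                 "cannot rank sites",
                 if (!is.null(drop_log) && nrow(drop_log))
                   paste0(" (dropped: ",
                          paste(sprintf("pair (%s,%s): %s",
                                        drop_log$site_atom,
                                        drop_log$dg_atom,
                                        drop_log$reason),
                                collapse = "; "), ")")),
          class = "regiopd_prediction_error")
  }
  per <- filter(results, !is.na(.data$energy_kcal))
  per <- mutate(per,
                relative_energy_kcal = .data$energy_kcal -
                  min(.data$energy_kcal),
                within_threshold = .data$relative_energy_kcal <=
                  threshold_kcal)
  per <- arrange(per, .data$relative_energy_kcal, .data$site_atom)
  hit <- filter(per, .data$within_threshold)
  structure(
    list(per_complex = per,
         predicted_sites = unique(hit$site_class),
         predicted_atoms = unique(hit$site_atom),
         threshold_kcal = threshold_kcal,
         refined = FALSE,
         drop_log = drop_log),
    class = "ch_prediction"
  )
}

#' @export
print.ch_prediction <- function(x, ...) {
  cat("<ch_prediction> ", nrow(x$per_complex), " complexes, threshold ",
      x$threshold_kcal, " kcal/mol",
      if (x$refined) " (refined)", "\n", sep = "")
  cat("  predicted site atom(s): ",
      paste(x$predicted_atoms, collapse = ", "),
      "  [class ", paste(x$predicted_sites, collapse = ", "), "]\n",
      sep = "")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy ch_prediction
#' @export
tidy.ch_prediction <- function(x, ...) {
  keep <- !vapply(x$per_complex, is.list, logical(1))
  x$per_complex[, keep, drop = FALSE]
}

#' @method glance ch_prediction
#' @export
glance.ch_prediction <- function(x, ...) {
  tibble(n_complexes = nrow(x$per_complex),
         n_predicted_sites = length(x$predicted_sites),
         threshold_kcal = x$threshold_kcal,
         refined = x$refined,
         min_energy_kcal = min(x$per_complex$energy_kcal))
}

#' @method autoplot ch_prediction
#' @export
autoplot.ch_prediction <- function(object, ...) {
  df <- tidy(object)
  df$site <- factor(df$site_atom)
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$site,
                               y = .data$relative_energy_kcal,
                               fill = .data$within_threshold)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold_kcal,
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2a9d8f",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = "reaction site (atom index)",
                  y = "relative intermediate energy [kcal/mol]",
                  title = "Palladacycle intermediate energies")
}

#' Refine a prediction with single-point energies
#'
#' When two or more distinct sites fall inside the energy window, the best
#' conformer of each within-threshold complex is re-evaluated with a
#' single-point engine (typically a DFT composite method) and the threshold
#' is re-applied on the refined energies. With fewer than two distinct
#' predicted sites the call is a no-op. Complexes on which the engine fails
#' keep their rank by unrefined energy, with a warning.
#'
#' @param prediction a [rank_sites()] object whose `per_complex` carries
#'   `complex` and `coords` list-columns.
#' @param engine an [engine_spec()] supporting `singlepoint`.
#' @return a `ch_prediction` with `refined = TRUE`.
#' @export
refine <- function(prediction, engine) {
  stopifnot(inherits(prediction, "ch_prediction"))
  if (length(prediction$predicted_sites) < 2L) return(prediction)
  require_capability(engine, "singlepoint")
  per <- prediction$per_complex
  if (is.null(per$complex) || is.null(per$coords)) {
    abort("refine() needs 'complex' and 'coords' list-columns in per_complex",
          class = "regiopd_precondition_error")
  }
  hit <- which(per$within_threshold)
  refined <- map_dbl(hit, function(i) {
    tryCatch(single_point(engine, per$complex[[i]], per$coords[[i]]),
             error = function(e) {
               warn(paste0("single-point failed for pair (",
                           per$site_atom[i], ", ", per$dg_atom[i],
                           "); keeping unrefined rank: ",
                           conditionMessage(e)))
               NA_real_
             })
  })
  if (all(is.na(refined))) {
    warn("single-point engine failed on every complex; prediction unchanged")
    return(prediction)
  }
  sub <- per[hit, ]
  # failures fall back to the unrefined relative ordering on the same scale
  scale_shift <- min(refined, na.rm = TRUE)
  sub$energy_refined_kcal <- ifelse(
    is.na(refined), sub$relative_energy_kcal + scale_shift, refined)
  sub$relative_energy_kcal <- sub$energy_refined_kcal -
    min(sub$energy_refined_kcal)
  sub$within_threshold <- sub$relative_energy_kcal <=
    prediction$threshold_kcal
  sub <- arrange(sub, .data$relative_energy_kcal, .data$site_atom)
  win <- filter(sub, .data$within_threshold)
  structure(
    list(per_complex = sub,
         predicted_sites = unique(win$site_class),
         predicted_atoms = unique(win$site_atom),
         threshold_kcal = prediction$threshold_kcal,
         refined = TRUE,
         drop_log = prediction$drop_log),
    class = "ch_prediction"
  )
}

#' Evaluate a prediction against the observed reaction site
#'
#' Three-way classification: `"correct"` when the observed site is the unique
#' predicted site, `"semi_correct"` when it is among several predicted sites
#' (the method cannot distinguish sites within chemical accuracy), and
#' `"incorrect"` when it is not predicted at all.
#'
#' @param prediction a `ch_prediction`.
#' @param observed_site_class symmetry-class id of the experimentally
#'   observed site (map an atom index with [site_symmetry_classes()]).
#' @return one of `"correct"`, `"semi_correct"`, `"incorrect"`.
#' @export
evaluate_prediction <- function(prediction, observed_site_class) {
  stopifnot(inherits(prediction, "ch_prediction"))
  if (!observed_site_class %in% prediction$per_complex$site_class) {
    abort("observed site is not among the candidate reaction sites",
          class = "regiopd_validation_error")
  }
  pred <- prediction$predicted_sites
  if (observed_site_class %in% pred) {
    if (length(pred) == 1L) "correct" else "semi_correct"
  } else {
    "incorrect"
  }
}

#' Random-guess null model for site prediction
#'
#' A model that guesses one of the k potential reaction sites of each
#' molecule uniformly at random is correct with probability 1/k, so the
#' expected number of correct predictions over a set of molecules is the sum
#' of 1/k_i. The 95% interval of the total is available both exactly (the
#' total is Poisson-binomial; computed by convolution) and by Monte-Carlo
#' simulation.
#'
#' @param site_counts integer vector, number of potential sites per molecule
#'   (each >= 2).
#' @param n_sim simulation draws (default 1e5).
#' @param seed RNG seed for the simulation.
#' @param method `"exact"`, `"simulation"`, or `"both"` (default).
#' @return a tibble with columns `method`, `expected_correct`, `ci95_lo`,
#'   `ci95_hi`.
#' @export
null_model <- function(site_counts, n_sim = 1e5, seed = 1,
                       method = c("both", "exact", "simulation")) {
  method <- match.arg(method)
  stopifnot(all(site_counts >= 2))
  p <- 1 / site_counts
  expected <- sum(p)
  rows <- list()
  if (method %in% c("both", "exact")) {
    pmf <- c(1)
    for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
    cdf <- cumsum(pmf)
    lo <- which(cdf >= 0.025)[1] - 1L
    hi <- which(cdf >= 0.975)[1] - 1L
    rows$exact <- tibble(method = "exact", expected_correct = expected,
                         ci95_lo = lo, ci95_hi = hi)
  }
  if (method %in% c("both", "simulation")) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    draws <- vapply(seq_len(n_sim),
                    function(i) sum(stats::runif(length(p)) < p),
                    numeric(1))
    q <- unname(quantile(draws, c(0.025, 0.975), type = 1))
    rows$sim <- tibble(method = "simulation", expected_correct = mean(draws),
                       ci95_lo = q[1], ci95_hi = q[2])
  }
  bind_rows(rows)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
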