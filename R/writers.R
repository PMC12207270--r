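#' Write an XYZ file
#'
#' Plain-text Cartesian coordinates (element symbols, Angstrom).
#'
#' @param symbols character vector of element symbols.
#' @param coords n_atoms x 3 matrix.
#' @param path output file.
#' @param comment second-line comment.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(symbols, coords, path, comment = "") {
  write_xyz_file(path, symbols, coords, comment)
  invisible(path)
}

#' Write a palladacycle complex as SDF
#'
#' V2000 molblock (via the RDKit backend) with the candidate-pair metadata
#' and the total charge attached as SDF data fields.
#'
#' @param cx a [build_complex()] object.
#' @param coords n_atoms x 3 coordinate matrix for the conformer to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complex_sdf <- function(cx, coords, path) {
  mb <- chem_backend("molblock", smiles = cx$smiles,
                     site = cx$pair$site_atom, dg = cx$pair$dg_atom,
                     coords = apply(coords, 1, as.list, simplify = FALSE)
  )$molblock
  props <- c(
    sprintf(">  <substrate_smiles>\n%s\n", cx$smiles),
    sprintf(">  <site_atom>\n%d\n", cx$pair$site_atom),
    sprintf(">  <dg_atom>\n%d\n", cx$pair$dg_atom),
    sprintf(">  <net_charge>\n%d\n", cx$net_charge),
    sprintf(">  <spin>\n%d\n", cx$spin),
    "$$$$"
  )
  writeLines(c(sub("\n$", "", mb), props), path)
  invisible(path)
}

prediction_document <- function(pred) {
  per <- tidy(pred)
  list(
    substrate_smiles = pred$substrate$smiles,
    substrate_smiles_input = pred$substrate$smiles_input,
    atom_indexing = "0-based, input SMILES atom order",
    mode = pred$mode,
    engine_level = pred$engine_level,
    threshold_kcal = pred$threshold_kcal,
    refined = pred$refined,
    seed = pred$seed,
    per_complex = per,
    predicted_site_atoms = pred$predicted_atoms,
    predicted_site_classes = pred$predicted_sites,
    observed_site_class = pred$observed_site_class,
    label = pred$label,
    dropped = pred$drop_log
  )
}

#' Write the JSON results document and run manifest for a prediction
#'
#' @param pred a `ch_prediction` from [run_prediction()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(pred, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(prediction_document(pred),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  per <- pred$per_complex
  if (!is.null(per$complex)) {
    for (k in seq_len(nrow(per))) {
      write_complex_sdf(per$complex[[k]], per$coords[[k]],
                        file.path(dir, sprintf("complex_site%d_dg%d.sdf",
                                               per$site_atom[k],
                                               per$dg_atom[k])))
    }
  }
  manifest <- list(
    package = "regiopd",
    version = as.character(utils::packageVersion("regiopd")),
    r_version = R.version.string,
    seed = pred$seed,
    mode = pred$mode,
    engine_level = pred$engine_level,
    threshold_kcal = pred$threshold_kcal
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
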