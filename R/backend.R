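#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn hash %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows desc filter group_by left_join mutate
#'   n rename row_number select summarise ungroup distinct
#' @importFrom purrr map map_dbl map_chr map_int map_lgl pmap imap keep
#' @importFrom stats quantile setNames
NULL

# in-session response cache: backend calls are pure given the request
the <- new.env(parent = emptyenv())
the$cache <- new.env(parent = emptyenv())

backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "regiopd")
  if (!nzchar(path) || !file.exists(path)) {
    abort("chem_backend.py not found; is regiopd installed correctly?",
          class = "regiopd_config_error")
  }
  path
}

python_binary <- function() {
  opt <- getOption("regiopd.python")
  if (!is.null(opt)) return(opt)
  for (cand in c("python", "python3")) {
    hit <- Sys.which(cand)
    if (nzchar(hit)) return(unname(hit))
  }
  abort("no python interpreter found on PATH (needed for the RDKit backend)",
        class = "regiopd_config_error")
}

#' Call the RDKit backend
#'
#' Low-level bridge to the bundled Python/RDKit helper. One JSON request in,
#' one JSON response out; responses are cached for the R session since every
#' backend operation is deterministic in its inputs.
#'
#' @param op backend operation name.
#' @param ... operation arguments, serialized as JSON.
#' @return the parsed response list (with `ok` stripped).
#' @keywords internal
chem_backend <- function(op, ...) {
  req <- list(op = op, ...)
  key <- rlang::hash(req)
  hit <- the$cache[[key]]
  if (!is.null(hit)) return(hit)
  js <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(
    system2(python_binary(), shQuote(backend_script()),
            input = js, stdout = TRUE, stderr = FALSE)
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0L || length(out) == 0L) {
    abort(paste0("RDKit backend failed (op = ", op, ", exit ", status, ")"),
          class = "regiopd_backend_error")
  }
  resp <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  if (!isTRUE(resp$ok)) {
    abort(paste0("RDKit backend error: ", resp$error %||% "unknown"),
          class = if (grepl("unparsable", resp$error %||% ""))
            "regiopd_input_error" else "regiopd_backend_error")
  }
  resp$ok <- NULL
  the$cache[[key]] <- resp
  resp
}

# list-of-xyz-lists -> n_atoms x 3 numeric matrix
coords_matrix <- function(x) {
  do.call(rbind, lapply(x, function(r) as.numeric(unlist(r))))
}
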