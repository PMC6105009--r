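LEARNING_VARIANTS <- c("2HGF", "2HGFprecfb", "3HGF", "3HGFprecfb")
RESPONSE_VARIANTS <- c("BL", "RelPE", "IrrelBias", "RelPE+IrrelBias")

#' The full model space
#'
#' All combinations of the four learning variants (2- or 3-level hierarchical
#' Gaussian filter, with or without precision feedback) and the four response
#' models (baseline, relevance-weighted prediction error, irrelevance-weighted
#' bias, or both).
#'
#' @param learning,response character vectors of variants to combine; defaults
#'   give the full 16-model space in canonical order (learning varies slowest).
#' @return character vector of model ids such as `"2HGF-RelPE+IrrelBias"`.
#' @export
#' @examples
#' model_space()
#' model_space(learning = "2HGF")
model_space <- function(learning = LEARNING_VARIANTS,
                        response = RESPONSE_VARIANTS) {
  learning <- match.arg(learning, LEARNING_VARIANTS, several.ok = TRUE)
  response <- match.arg(response, RESPONSE_VARIANTS, several.ok = TRUE)
  as.vector(t(outer(learning, response, paste, sep = "-")))
}

#' Parse a model id into its learning and response components
#'
#' @param model_id string like `"3HGFprecfb-IrrelBias"`.
#' @return list with elements `learning`, `response`, `n_levels`, `precfb`,
#'   `relpe`, `irrelbias`.
#' @export
parse_model_id <- function(model_id) {
  stopifnot(is.character(model_id), length(model_id) == 1)
  parts <- strsplit(model_id, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% LEARNING_VARIANTS ||
      !parts[2] %in% RESPONSE_VARIANTS) {
    abort(paste0(
      "invalid model id '", model_id, "': expected <learning>-<response> ",
      "with learning in {", paste(LEARNING_VARIANTS, collapse = ", "),
      "} and response in {", paste(RESPONSE_VARIANTS, collapse = ", "), "}"))
  }
  list(
    learning = parts[1], response = parts[2],
    n_levels = if (grepl("^3", parts[1])) 3L else 2L,
    precfb = grepl("precfb", parts[1], fixed = TRUE),
    relpe = parts[2] %in% c("RelPE", "RelPE+IrrelBias"),
    irrelbias = parts[2] %in% c("IrrelBias", "RelPE+IrrelBias"))
}
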