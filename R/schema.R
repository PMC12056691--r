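#' Construct a variable schema
#'
#' @param contextVars character vector of context variable names.
#' @param candidateVars non-empty character vector of candidate cause
#'   variable names.
#' @param outcomeVar name of the real-valued outcome column.
#' @param unitNote free-text unit annotation.
#' @return a [VariableSchema-class].
#' @examples
#' variableSchema(contextVars = c("Protein_ID", "Concentration_of_Molecule"),
#'                candidateVars = "Small_Molecule", outcomeVar = "log2FC")
#' @export
variableSchema <- function(contextVars = character(),
                           candidateVars,
                           outcomeVar,
                           unitNote = NA_character_) {
  new("VariableSchema",
      contextVars = as.character(contextVars),
      candidateVars = as.character(candidateVars),
      outcomeVar = as.character(outcomeVar),
      unitNote = as.character(unitNote))
}

#' The default corona schema
#'
#' Context variables `Protein_ID` and `Concentration_of_Molecule`, candidate
#' variable `Small_Molecule`, outcome `log2FC`.  Concentration is a context
#' variable by default (counterfactual worlds hold protein and concentration
#' fixed while the molecule varies); promote it to a candidate with
#' [variableSchema()] if treatment concentration itself should be tested as
#' a cause.
#'
#' @return a [VariableSchema-class].
#' @export
defaultSchema <- function() {
  variableSchema(
    contextVars = c("Protein_ID", "Concentration_of_Molecule"),
    candidateVars = "Small_Molecule",
    outcomeVar = "log2FC",
    unitNote = "Concentration_of_Molecule in ug/mL")
}

# all non-outcome variables, in schema order
.schemaVars <- function(schema) c(schema@contextVars, schema@candidateVars)

setMethod("show", "VariableSchema", function(object) {
  cat("VariableSchema\n")
  cat("  context:  ", paste(object@contextVars, collapse = ", "), "\n")
  cat("  candidate:", paste(object@candidateVars, collapse = ", "), "\n")
  cat("  outcome:  ", object@outcomeVar, "\n")
  if (!is.na(object@unitNote)) cat("  units:    ", object@unitNote, "\n")
})
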