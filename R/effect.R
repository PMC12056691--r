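#' Construct the dual-threshold effect predicate
#'
#' The effect phi of interest is a shift in corona composition measured on
#' log2 fold change, judged differently by protein abundance class.  With
#' the default `"depletion_enrichment"` orientation:
#' \deqn{\phi = (\mathrm{abundant} \wedge \mathrm{log2FC} \le \theta_a) \vee
#'       (\neg\mathrm{abundant} \wedge \mathrm{log2FC} > \theta_r)}
#' i.e. highly abundant proteins count when depleted at or below
#' `thetaAbundant`, all other proteins when enriched strictly above
#' `thetaRest`.  The `"enrichment_only"` orientation uses `>=`/`<=` with the
#' class roles swapped (abundant enriched, rest depleted).
#'
#' @param thetaAbundant threshold for the abundant class (default 0.1).
#' @param thetaRest threshold for the remaining proteins (default 0.1).
#' @param abundantIds accessions in the abundant class; defaults to the
#'   packaged 25-protein plasma list ([abundantProteins()]).  Pass
#'   `character(0)` to disable class logic (every record is "rest").
#' @param orientation `"depletion_enrichment"` (default) or
#'   `"enrichment_only"`.
#' @param idVar column holding protein accessions (default `"Protein_ID"`).
#' @return an [EffectPredicate-class].
#' @examples
#' phi <- effectPredicate(thetaAbundant = 0.1, thetaRest = 0.1)
#' @export
effectPredicate <- function(thetaAbundant = 0.1, thetaRest = 0.1,
                            abundantIds = abundantProteins(),
                            orientation = c("depletion_enrichment",
                                            "enrichment_only"),
                            idVar = "Protein_ID") {
  orientation <- match.arg(orientation)
  new("EffectPredicate",
      thetaAbundant = as.numeric(thetaAbundant),
      thetaRest = as.numeric(thetaRest),
      abundantIds = as.character(abundantIds),
      orientation = orientation,
      idVar = idVar)
}

setMethod("show", "EffectPredicate", function(object) {
  cat("EffectPredicate (", object@orientation, ")\n", sep = "")
  cat(sprintf("  thetaAbundant = %g, thetaRest = %g\n",
              object@thetaAbundant, object@thetaRest))
  cat(sprintf("  abundant class: %d id(s) via column '%s'\n",
              length(object@abundantIds), object@idVar))
})

# phi on a vector of outcomes + abundance flags; pure and vectorized
.phi <- function(fc, abundant, predicate) {
  switch(predicate@orientation,
    depletion_enrichment =
      ifelse(abundant, fc <= predicate@thetaAbundant,
                       fc >  predicate@thetaRest),
    enrichment_only =
      ifelse(abundant, fc >= predicate@thetaAbundant,
                       fc <= predicate@thetaRest))
}

.abundantFlag <- function(rec, predicate) {
  if (predicate@idVar %in% names(rec) && length(predicate@abundantIds))
    rec[[predicate@idVar]] %in% predicate@abundantIds
  else
    rep(FALSE, nrow(rec))
}

#' Evaluate the effect predicate
#'
#' Pure, deterministic evaluation of phi.  The `CausalModel` method returns
#' one logical per record; the `data.frame` method evaluates arbitrary
#' record rows (and is the single-record entry point), rejecting rows whose
#' outcome is missing or non-finite.
#'
#' @param x a [CausalModel-class] or a data.frame of records.
#' @param predicate an [EffectPredicate-class].
#' @param ... unused.
#' @param outcomeVar outcome column name for the data.frame method
#'   (default `"log2FC"`).
#' @return logical vector, one element per record.
#' @examples
#' phi <- effectPredicate(thetaAbundant = 0.1, abundantIds = "P02768")
#' evaluateEffect(data.frame(Protein_ID = "P02768", log2FC = -0.5), phi)
#' @name evaluateEffect
NULL

#' @rdname evaluateEffect
setMethod("evaluateEffect", "CausalModel", function(x, predicate, ...) {
  stopifnot(is(predicate, "EffectPredicate"))
  rec <- x@records
  .phi(rec[[x@schema@outcomeVar]], .abundantFlag(rec, predicate), predicate)
})

#' @rdname evaluateEffect
setMethod("evaluateEffect", "data.frame",
          function(x, predicate, ..., outcomeVar = "log2FC") {
  stopifnot(is(predicate, "EffectPredicate"))
  if (!outcomeVar %in% names(x))
    stop("record lacks outcome column '", outcomeVar, "'")
  fc <- x[[outcomeVar]]
  if (!is.numeric(fc)) fc <- suppressWarnings(as.numeric(fc))
  bad <- which(!is.finite(fc))
  if (length(bad))
    stop("record(s) rejected: missing or non-finite outcome at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  .phi(fc, .abundantFlag(x, predicate), predicate)
})

#' The packaged highly-abundant plasma protein list
#'
#' The 25 plasma proteins with the highest mean normalized intensity
#' (albumin first), used as the default abundant class of the effect
#' predicate.  Shipped as a plain-text two-column fixture.
#'
#' @param withNames if `TRUE`, return accessions named by protein name.
#' @return character vector of 25 accessions, in abundance-rank order.
#' @examples
#' head(abundantProteins())
#' @export
abundantProteins <- function(withNames = FALSE) {
  path <- system.file("extdata", "highly_abundant_proteins.tsv",
                      package = "CoronaCausality", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- tab$accession
  if (anyDuplicated(ids)) stop("fixture contains duplicated accessions")
  if (withNames) names(ids) <- tab$protein_name
  ids
}
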