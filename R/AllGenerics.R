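#' Accessors for CoronaCausality objects
#'
#' Standard accessor generics: `records()` returns the observation table of
#' a [CausalModel-class], `causalSchema()` its [VariableSchema-class],
#' `domains()` the realized value sets, `modelMetadata()` its metadata list,
#' `resultTable()` the full per-assignment table of a
#' [CauseResults-class], `causes()` the subset of assignments identified as
#' actual causes (in rank order), and `sweepCells()` the long-format cell
#' table of a [SweepGrid-class].
#'
#' @param x the object.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases records causalSchema domains modelMetadata resultTable causes
#'   sweepCells
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("causalSchema", function(x) standardGeneric("causalSchema"))

#' @rdname accessors
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname accessors
#' @export
setGeneric("modelMetadata", function(x) standardGeneric("modelMetadata"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

#' @rdname accessors
#' @export
setGeneric("causes", function(x) standardGeneric("causes"))

#' @rdname accessors
#' @export
setGeneric("sweepCells", function(x) standardGeneric("sweepCells"))

#' @rdname evaluateEffect
#' @export
setGeneric("evaluateEffect",
  function(x, predicate, ...) standardGeneric("evaluateEffect"))
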