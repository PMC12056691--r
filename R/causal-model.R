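#' Construct an empirical causal model from a long-format table
#'
#' Validates a data.frame against a schema and builds a
#' [CausalModel-class]: context/candidate columns are coerced to character,
#' the outcome must be finite numeric, extra columns are dropped, row order
#' is preserved, and empirical domains are computed from the realized
#' values.
#'
#' @param data data.frame containing at least the schema's columns.
#' @param schema a [VariableSchema-class]; defaults to [defaultSchema()].
#' @param metadata optional list of free-form metadata.
#' @return a [CausalModel-class].
#' @examples
#' df <- data.frame(Protein_ID = c("P1", "P1", "P2", "P2"),
#'                  Small_Molecule = c("a", "b", "a", "b"),
#'                  Concentration_of_Molecule = "10",
#'                  log2FC = c(1.2, -0.3, 0.4, 0.0))
#' causalModel(df)
#' @export
causalModel <- function(data, schema = defaultSchema(), metadata = list()) {
  stopifnot(is.data.frame(data))
  vars <- c(.schemaVars(schema), schema@outcomeVar)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("data lacks required column(s): ", paste(miss, collapse = ", "))
  rec <- data[vars]
  rownames(rec) <- NULL
  for (v in .schemaVars(schema)) rec[[v]] <- as.character(rec[[v]])
  out <- rec[[schema@outcomeVar]]
  if (!is.numeric(out))
    stop("outcome column '", schema@outcomeVar, "' must be numeric")
  bad <- which(!is.finite(out))
  if (length(bad))
    stop("outcome column '", schema@outcomeVar,
         "' has missing/non-finite values at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  doms <- .computeDomains(rec, schema)
  new("CausalModel", records = rec, schema = schema, domains = doms,
      metadata = metadata)
}

.computeDomains <- function(rec, schema) {
  doms <- lapply(.schemaVars(schema),
                 function(v) sort(unique(rec[[v]]), method = "radix"))
  names(doms) <- .schemaVars(schema)
  doms[[schema@outcomeVar]] <- sort(unique(rec[[schema@outcomeVar]]))
  doms
}

#' @rdname accessors
setMethod("records", "CausalModel", function(x) x@records)

#' @rdname accessors
setMethod("causalSchema", "CausalModel", function(x) x@schema)

#' @rdname accessors
setMethod("domains", "CausalModel", function(x) x@domains)

#' @rdname accessors
setMethod("modelMetadata", "CausalModel", function(x) x@metadata)

setMethod("show", "CausalModel", function(object) {
  sch <- object@schema
  cat("CausalModel with", nrow(object@records), "records\n")
  for (v in .schemaVars(sch))
    cat(sprintf("  %s: %d value(s)\n", v, length(object@domains[[v]])))
  rng <- range(object@records[[sch@outcomeVar]])
  cat(sprintf("  %s (outcome): range [%.4g, %.4g]\n",
              sch@outcomeVar, rng[1], rng[2]))
})

#' Enumerate candidate assignments of a variable
#'
#' One `X <- x` [Assignment-class] per distinct observed value of the
#' candidate variable, in deterministic sorted order.
#'
#' @param table a [CausalModel-class].
#' @param variable a candidate variable of its schema.
#' @return list of [Assignment-class] objects.
#' @export
candidateAssignments <- function(table, variable) {
  stopifnot(is(table, "CausalModel"))
  if (!variable %in% table@schema@candidateVars)
    stop("'", variable, "' is not a candidate variable of the schema")
  lapply(table@domains[[variable]],
         function(v) new("Assignment", variable = variable, value = v))
}

setMethod("show", "Assignment", function(object) {
  cat(sprintf("Assignment: %s <- %s\n", object@variable, object@value))
})
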