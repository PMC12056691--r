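#' @import methods
NULL

#' VariableSchema: roles of the columns of an empirical causal model
#'
#' Declares which columns of a long-format table act as context variables
#' (held fixed when building counterfactual worlds), which are candidate
#' cause variables (eligible for `X <- x` assignments), and which single
#' real-valued column is the outcome the effect predicate reads.
#'
#' @slot contextVars character vector of context variable names.
#' @slot candidateVars character vector of candidate cause variable names
#'   (non-empty, disjoint from `contextVars`).
#' @slot outcomeVar single name of the real-valued outcome column.
#' @slot unitNote free-text unit annotation carried as metadata (for the
#'   corona design, the concentration unit).
#'
#' @seealso [variableSchema()], [defaultSchema()]
#' @exportClass VariableSchema
setClass("VariableSchema",
  representation(
    contextVars = "character",
    candidateVars = "character",
    outcomeVar = "character",
    unitNote = "character"
  )
)

setValidity("VariableSchema", function(object) {
  msg <- character()
  if (length(object@candidateVars) == 0)
    msg <- c(msg, "candidateVars must be non-empty")
  if (length(object@outcomeVar) != 1)
    msg <- c(msg, "outcomeVar must be a single column name")
  if (any(object@outcomeVar %in% c(object@contextVars, object@candidateVars)))
    msg <- c(msg, "outcomeVar must not be a context or candidate variable")
  if (any(object@contextVars %in% object@candidateVars))
    msg <- c(msg, "contextVars and candidateVars must be disjoint")
  if (anyDuplicated(c(object@contextVars, object@candidateVars)))
    msg <- c(msg, "variable names must be unique")
  if (length(msg)) msg else TRUE
})

#' CausalModel: an empirical causal model over observed records
#'
#' The package's central container: a validated long-format table together
#' with its [VariableSchema-class] and the empirical domain (set of realized
#' values) of every variable.  The empirical domains stand in for the value
#' mapping functions of a basic causal model: the analysis only ever reasons
#' over worlds that were actually observed.
#'
#' @slot records data.frame with one row per observation; context and
#'   candidate columns are character, the outcome column is finite numeric.
#' @slot schema the [VariableSchema-class].
#' @slot domains named list mapping each schema variable to its sorted set
#'   of realized values.
#' @slot metadata free-form list (e.g. abundant protein ids and the
#'   generating configuration for simulated tables).
#'
#' @seealso [causalModel()], [readCoronaTable()], [simulateCorona()]
#' @exportClass CausalModel
setClass("CausalModel",
  representation(
    records = "data.frame",
    schema = "VariableSchema",
    domains = "list",
    metadata = "list"
  )
)

setValidity("CausalModel", function(object) {
  sch <- object@schema
  rec <- object@records
  vars <- c(sch@contextVars, sch@candidateVars, sch@outcomeVar)
  msg <- character()
  miss <- setdiff(vars, names(rec))
  if (length(miss))
    return(sprintf("records lack schema column(s): %s",
                   paste(miss, collapse = ", ")))
  if (nrow(rec) == 0)
    msg <- c(msg, "records must contain at least one row")
  out <- rec[[sch@outcomeVar]]
  if (!is.numeric(out) || any(!is.finite(out)))
    msg <- c(msg, "outcome column must be finite numeric")
  for (v in c(sch@contextVars, sch@candidateVars)) {
    if (!is.character(rec[[v]]))
      msg <- c(msg, sprintf("variable '%s' must be stored as character", v))
    dom <- sort(unique(rec[[v]]), method = "radix")
    if (!identical(object@domains[[v]], dom))
      msg <- c(msg, sprintf("domain of '%s' does not match realized values", v))
  }
  if (length(msg)) msg else TRUE
})

#' Assignment: a candidate cause `X <- x`
#'
#' A single value assignment to a candidate variable, the unit hypothesis
#' the actual-cause search tests.
#'
#' @slot variable name of a candidate variable.
#' @slot value one of its observed values (as character).
#'
#' @seealso [candidateAssignments()]
#' @exportClass Assignment
setClass("Assignment",
  representation(variable = "character", value = "character")
)

setValidity("Assignment", function(object) {
  if (length(object@variable) != 1 || length(object@value) != 1)
    "variable and value must both be single strings"
  else TRUE
})

#' EffectPredicate: the dual-threshold corona effect
#'
#' Encodes the effect phi as a threshold rule on log2 fold change that is
#' conditioned on protein abundance class.  In the default
#' `"depletion_enrichment"` orientation the desirable effect is depletion of
#' highly abundant proteins (`log2FC <= thetaAbundant`) or enrichment of the
#' remaining proteins (`log2FC > thetaRest`).  The `"enrichment_only"`
#' orientation flips both comparisons (`>=` for abundant, `<=` for the
#' rest), the literal reading of the alternative rule in the source study's
#' worked example; both are kept because the two stated rules disagree.
#'
#' @slot thetaAbundant threshold applied to abundant proteins.
#' @slot thetaRest threshold applied to all other proteins.
#' @slot abundantIds protein accessions in the highly abundant class; may be
#'   empty, in which case every record is treated as "rest" (useful for
#'   generic tables with a binary-coded outcome).
#' @slot orientation `"depletion_enrichment"` or `"enrichment_only"`.
#' @slot idVar name of the column holding protein accessions; a table
#'   without that column has no abundant class.
#'
#' @seealso [effectPredicate()], [evaluateEffect()]
#' @exportClass EffectPredicate
setClass("EffectPredicate",
  representation(
    thetaAbundant = "numeric",
    thetaRest = "numeric",
    abundantIds = "character",
    orientation = "character",
    idVar = "character"
  )
)

setValidity("EffectPredicate", function(object) {
  msg <- character()
  if (length(object@thetaAbundant) != 1 || !is.finite(object@thetaAbundant))
    msg <- c(msg, "thetaAbundant must be a single finite number")
  if (length(object@thetaRest) != 1 || !is.finite(object@thetaRest))
    msg <- c(msg, "thetaRest must be a single finite number")
  if (!object@orientation %in% c("depletion_enrichment", "enrichment_only"))
    msg <- c(msg, "orientation must be 'depletion_enrichment' or 'enrichment_only'")
  if (length(object@idVar) != 1)
    msg <- c(msg, "idVar must be a single column name")
  if (length(msg)) msg else TRUE
})

#' CauseResults: verdicts and probabilities for every candidate assignment
#'
#' Holds one row per candidate assignment with its AC1/PC2/AC3 verdicts,
#' actual and counterfactual probabilities (exact integer ratios carried in
#' `*_num`/`*_den` columns), conditional probability, support counts, and the
#' rank among identified causes.  Rows are ordered causes-first by rank.
#'
#' @slot results the per-assignment data.frame (see [resultTable()]).
#' @slot mode counterfactual aggregation mode used, `"standardized"` or
#'   `"pooled"`.
#' @slot k number of top causes flagged.
#' @slot predicate the [EffectPredicate-class] that defined the effect.
#' @slot variables candidate variables searched.
#'
#' @seealso [findCauses()], [causes()], [writeCauseResults()]
#' @exportClass CauseResults
setClass("CauseResults",
  representation(
    results = "data.frame",
    mode = "character",
    k = "integer",
    predicate = "EffectPredicate",
    variables = "character"
  )
)

#' SweepGrid: ranked causes over a 2-D grid of effect thresholds
#'
#' Result of sweeping the cause search over pairs of thresholds
#' (one for abundant proteins, one for the rest).  `cells` is a long-format
#' data.frame with one row per (cell, rank) for which a cause was found;
#' cells absent at a rank had no cause there ("None").
#'
#' @slot thetaAbundantAxis strictly monotone numeric axis for the
#'   abundant-protein threshold.
#' @slot thetaRestAxis strictly monotone numeric axis for the rest-protein
#'   threshold.
#' @slot cells data.frame with columns ia, ir, theta_abundant, theta_rest,
#'   rank, variable, value, probability.
#' @slot k maximum number of ranks kept per cell.
#' @slot mode counterfactual aggregation mode.
#' @slot nCells total number of grid cells.
#'
#' @seealso [runSweep()], [frequencyTable()], [top3MembershipRate()]
#' @exportClass SweepGrid
setClass("SweepGrid",
  representation(
    thetaAbundantAxis = "numeric",
    thetaRestAxis = "numeric",
    cells = "data.frame",
    k = "integer",
    mode = "character",
    nCells = "integer"
  )
)

setValidity("SweepGrid", function(object) {
  msg <- character()
  if (length(object@thetaAbundantAxis) < 1 ||
      is.unsorted(object@thetaAbundantAxis, strictly = TRUE))
    msg <- c(msg, "thetaAbundantAxis must be strictly increasing")
  if (length(object@thetaRestAxis) < 1 ||
      is.unsorted(object@thetaRestAxis, strictly = TRUE))
    msg <- c(msg, "thetaRestAxis must be strictly increasing")
  if (object@nCells !=
      length(object@thetaAbundantAxis) * length(object@thetaRestAxis))
    msg <- c(msg, "nCells must equal the product of the axis lengths")
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: generative parameters for corona-like tables
#'
#' Parameters of the synthetic-data generator used to emulate the study
#' design: one log2FC value per (protein x molecule x concentration) cell,
#' with one optional planted causal molecule that depletes abundant proteins
#' and enriches the rest, molecule-level nuisance shifts, and per-record
#' Gaussian noise.
#'
#' @slot nProteins number of synthetic proteins.
#' @slot nAbundant number flagged highly abundant (the first `nAbundant`
#'   ids).
#' @slot molecules candidate molecule labels.
#' @slot concentrations concentration levels (defaults to 10/100/1000).
#' @slot plantedCause molecule label of the planted cause, or `character(0)`
#'   for a null table.
#' @slot depletionShift log2FC shift the planted cause applies to abundant
#'   proteins.
#' @slot enrichmentShift shift applied to non-abundant proteins.
#' @slot nullShiftSd sd of molecule-level nuisance shifts for null
#'   molecules.
#' @slot noiseSd sd of per-record noise.
#' @slot concentrationGain per-concentration multiplier on shifts (named by
#'   concentration, or a single value recycled).
#' @slot seed RNG seed.
#'
#' @seealso [coronaSimConfig()], [simulateCorona()]
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nProteins = "integer",
    nAbundant = "integer",
    molecules = "character",
    concentrations = "numeric",
    plantedCause = "character",
    depletionShift = "numeric",
    enrichmentShift = "numeric",
    nullShiftSd = "numeric",
    noiseSd = "numeric",
    concentrationGain = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nProteins < 1) msg <- c(msg, "nProteins must be >= 1")
  if (object@nAbundant < 0 || object@nAbundant > object@nProteins)
    msg <- c(msg, "nAbundant must lie in [0, nProteins]")
  if (length(object@molecules) < 1 || anyDuplicated(object@molecules))
    msg <- c(msg, "molecules must be a non-empty set of unique labels")
  if (length(object@plantedCause) > 1)
    msg <- c(msg, "plantedCause must be a single label or absent")
  if (length(object@plantedCause) == 1 &&
      !object@plantedCause %in% object@molecules)
    msg <- c(msg, "plantedCause must be one of molecules")
  if (any(object@nullShiftSd < 0, object@noiseSd < 0))
    msg <- c(msg, "standard deviations must be non-negative")
  if (!length(object@concentrationGain) %in%
      c(1L, length(object@concentrations)))
    msg <- c(msg, "concentrationGain must have length 1 or one per concentration")
  if (length(msg)) msg else TRUE
})

#' TableReadReport: validation summary from reading a corona table
#'
#' @slot nRowsRead total data rows encountered in the file.
#' @slot nRowsRejected rows dropped (missing or non-finite outcome).
#' @slot rejectedReasons named integer vector of counts per rejection
#'   reason.
#' @slot domainsSummary named integer vector: cardinality of each schema
#'   variable among accepted rows.
#'
#' @seealso [readCoronaTable()]
#' @exportClass TableReadReport
setClass("TableReadReport",
  representation(
    nRowsRead = "integer",
    nRowsRejected = "integer",
    rejectedReasons = "integer",
    domainsSummary = "integer"
  )
)

setValidity("TableReadReport", function(object) {
  if (sum(object@rejectedReasons) != object@nRowsRejected)
    "rejectedReasons must sum to nRowsRejected"
  else TRUE
})
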