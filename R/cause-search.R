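# Singleton actual-cause search: AC1 (cause and effect co-occur), PC2
# (probability raising against contingency-matched counterfactual worlds),
# AC3 (automatic for singleton assignments).  All probabilities are exact
# ratios of record counts; PC2 is decided by cross-multiplication, never by
# floating-point comparison.

# context key for a candidate variable: every non-outcome variable except
# the one under test (other candidate variables are part of the contingency)
.contextKey <- function(model, variable) {
  vars <- setdiff(.schemaVars(model@schema), variable)
  rec <- model@records
  if (!length(vars)) return(factor(rep("", nrow(rec))))
  key <- do.call(paste, c(rec[vars], sep = "\r"))
  factor(key)
}

# Assess every observed value of `variable` against phi in one pass.
# Contexts are tabulated once; per value we read off actual-world counts,
# matched counterfactual counts, and the exact probabilities.
.assessVariable <- function(model, phi, variable, mode) {
  rec <- model@records
  vals <- model@domains[[variable]]
  x <- factor(rec[[variable]], levels = vals)
  f <- .contextKey(model, variable)
  n_tab <- table(f, x)               # context x value record counts
  e_tab <- table(f[phi], x[phi])     # same, restricted to phi records
  tot_n <- rowSums(n_tab)
  tot_e <- rowSums(e_tab)
  lapply(vals, function(val) {
    n_c <- n_tab[, val]              # actual records per context
    e_c <- e_tab[, val]
    n_act <- sum(n_c)
    n_eff <- sum(e_c)
    m_c <- tot_n - n_c               # counterfactual records per context
    k_c <- tot_e - e_c
    use <- n_c > 0 & m_c > 0         # contexts realized in the actual world
                                     # that have a counterfactual counterpart
    p_act <- .frac(n_eff, n_act)
    if (!any(use)) {
      p_cf <- NULL
      pc2 <- FALSE
      n_cf <- 0
    } else {
      if (mode == "pooled") {
        p_cf <- .frac(sum(k_c[use]), sum(m_c[use]))
      } else {
        # context-standardized: weight each context's counterfactual rate by
        # its share of actual records among usable contexts
        acc <- c(0, 1)
        for (i in which(use))
          acc <- .frac_add(acc, .frac(n_c[i] * k_c[i], m_c[i]))
        p_cf <- .frac(acc[1], acc[2] * sum(n_c[use]))
      }
      pc2 <- .frac_gt(p_act, p_cf)
      n_cf <- sum(m_c[use])
    }
    list(variable = variable, value = val,
         ac1 = n_eff >= 1, pc2 = pc2,
         p_act = p_act, p_cf = p_cf,
         n_actual = n_act, n_counterfactual = n_cf)
  })
}

.asAssignment <- function(model, assignment) {
  stopifnot(is(assignment, "Assignment"))
  v <- assignment@variable
  if (!v %in% model@schema@candidateVars)
    stop("'", v, "' is not a candidate variable of the schema")
  if (!assignment@value %in% model@domains[[v]])
    stop("value '", assignment@value, "' is never observed for '", v, "'")
  assignment
}

.assessOne <- function(table, assignment, predicate, mode) {
  a <- .asAssignment(table, assignment)
  phi <- evaluateEffect(table, predicate)
  res <- .assessVariable(table, phi, a@variable, mode)
  res[[match(a@value, table@domains[[a@variable]])]]
}

#' Does AC1 hold for an assignment?
#'
#' AC1 requires the candidate assignment and the effect to happen together:
#' at least one record carries the assignment's value and satisfies phi.
#'
#' @param table a [CausalModel-class].
#' @param assignment an [Assignment-class].
#' @param predicate an [EffectPredicate-class].
#' @return logical.
#' @export
ac1Holds <- function(table, assignment, predicate) {
  .assessOne(table, assignment, predicate, "pooled")$ac1
}

#' Split records into actual and contingency-matched counterfactual worlds
#'
#' The actual world for `X <- x` is every record with `X = x`.  Each
#' counterfactual world keeps every other variable at its actual-world
#' value and lets only `X` differ: records with `X != x` that share the
#' exact context (all non-outcome variables except `X`) of some
#' actual-world record.  Contexts realized only outside the actual world do
#' not appear on either side.
#'
#' @inheritParams ac1Holds
#' @return list with `actual` (data.frame of actual-world records) and
#'   `counterfactual` (named list, one data.frame per actual-world context;
#'   empty data.frames mark contexts with no counterfactual counterpart).
#' @export
contingencySplit <- function(table, assignment) {
  a <- .asAssignment(table, assignment)
  rec <- table@records
  vars <- setdiff(.schemaVars(table@schema), a@variable)
  sel <- rec[[a@variable]] == a@value
  key <- if (length(vars)) do.call(paste, c(rec[vars], sep = "|"))
         else rep("", nrow(rec))
  ctxs <- sort(unique(key[sel]), method = "radix")
  cf <- lapply(ctxs, function(ctx) {
    out <- rec[!sel & key == ctx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(cf) <- ctxs
  actual <- rec[sel, , drop = FALSE]
  rownames(actual) <- NULL
  list(actual = actual, counterfactual = cf)
}

#' Does PC2 (probability raising) hold for an assignment?
#'
#' Compares the probability of the effect in the actual world (records with
#' `X = x`) with its probability in the contingency-matched counterfactual
#' worlds (records with `X != x`, same context).  `"pooled"` merges all
#' matched counterfactual records into one pool; `"standardized"` averages
#' per-context counterfactual rates weighted by each context's share of
#' actual-world records, which is immune to Simpson-type reversal when the
#' design is unbalanced.  PC2 requires strict raising; if no counterfactual
#' world exists the comparison is undefined and PC2 is false.
#'
#' @inheritParams ac1Holds
#' @param mode `"standardized"` (default) or `"pooled"`.
#' @return list with `holds` (logical), `pActual`, `pCounterfactual`
#'   (numeric; `pCounterfactual` is `NA` when undefined), and the exact
#'   ratios `pActualFrac`, `pCounterfactualFrac` as `c(num, den)`.
#' @export
pc2Holds <- function(table, assignment, predicate,
                     mode = c("standardized", "pooled")) {
  mode <- match.arg(mode)
  r <- .assessOne(table, assignment, predicate, mode)
  list(holds = r$pc2,
       pActual = .frac_num(r$p_act),
       pCounterfactual = if (is.null(r$p_cf)) NA_real_ else .frac_num(r$p_cf),
       pActualFrac = r$p_act,
       pCounterfactualFrac = r$p_cf)
}

#' Conditional probability of the effect given an assignment
#'
#' `count(X = x and phi) / count(X = x)`, as an exact ratio.  Used only to
#' rank assignments already identified as causes, never to establish
#' causation.
#'
#' @inheritParams ac1Holds
#' @return numeric probability with the exact ratio in attribute `"frac"`.
#' @export
conditionalProbability <- function(table, assignment, predicate) {
  r <- .assessOne(table, assignment, predicate, "pooled")
  if (r$n_actual == 0)
    stop("assignment value never occurs; conditional probability undefined")
  structure(.frac_num(r$p_act), frac = r$p_act)
}

# deterministic ordering: conditional probability desc (exact values are
# safely compared as doubles for ordering only; counts here keep rationals
# far wider apart than double epsilon), then larger actual support, then
# variable, then value lexicographically
.rankOrder <- function(df) {
  order(-df$conditional_probability, -df$n_actual, df$variable, df$value,
        method = "radix")
}

.resultsDataFrame <- function(rows) {
  df <- data.frame(
    variable = vapply(rows, `[[`, "", "variable"),
    value = vapply(rows, `[[`, "", "value"),
    ac1 = vapply(rows, `[[`, NA, "ac1"),
    pc2 = vapply(rows, `[[`, NA, "pc2"),
    ac3 = TRUE,
    is_cause = NA,
    rank = NA_integer_,
    p_actual = vapply(rows, function(r) .frac_num(r$p_act), 0),
    p_actual_num = vapply(rows, function(r) r$p_act[1], 0),
    p_actual_den = vapply(rows, function(r) r$p_act[2], 0),
    p_counterfactual = vapply(rows, function(r)
      if (is.null(r$p_cf)) NA_real_ else .frac_num(r$p_cf), 0),
    p_counterfactual_num = vapply(rows, function(r)
      if (is.null(r$p_cf)) NA_real_ else r$p_cf[1], 0),
    p_counterfactual_den = vapply(rows, function(r)
      if (is.null(r$p_cf)) NA_real_ else r$p_cf[2], 0),
    n_actual = vapply(rows, `[[`, 0, "n_actual"),
    n_counterfactual = vapply(rows, `[[`, 0, "n_counterfactual"),
    stringsAsFactors = FALSE)
  # the ranking statistic equals p_actual by definition; kept as its own
  # column because it plays a different role (ranking, not causation)
  df$conditional_probability <- df$p_actual
  df$is_cause <- df$ac1 & df$pc2 & df$ac3
  ord <- .rankOrder(df)
  df <- df[c(ord[df$is_cause[ord]], ord[!df$is_cause[ord]]), , drop = FALSE]
  rownames(df) <- NULL
  ncause <- sum(df$is_cause)
  if (ncause) df$rank[seq_len(ncause)] <- seq_len(ncause)
  df
}

#' Search for singleton actual causes
#'
#' Evaluates every candidate assignment of the requested variables: AC1
#' (assignment and effect co-occur), PC2 (strict probability raising over
#' contingency-matched counterfactual worlds), AC3 (automatic, since only
#' singleton assignments are searched).  An assignment is an actual cause
#' iff all three hold.  All assignments are returned; causes are ranked by
#' conditional probability of the effect (ties: larger actual-world support,
#' then lexicographic order) and the top `k` flagged.
#'
#' @param table a [CausalModel-class].
#' @param predicate an [EffectPredicate-class].
#' @param variables candidate variables to search (default: all in the
#'   schema).
#' @param k number of top causes to flag (default 3).
#' @param mode counterfactual aggregation, `"standardized"` (default) or
#'   `"pooled"`; see [pc2Holds()].
#' @return a [CauseResults-class].
#' @examples
#' m <- simulateCorona(coronaSimConfig(noiseSd = 0, nullShiftSd = 0))
#' phi <- effectPredicate(abundantIds = modelMetadata(m)$abundant_ids)
#' causes(findCauses(m, phi))
#' @export
findCauses <- function(table, predicate,
                       variables = causalSchema(table)@candidateVars,
                       k = 3, mode = c("standardized", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(is(table, "CausalModel"), is(predicate, "EffectPredicate"),
            k >= 1)
  bad <- setdiff(variables, table@schema@candidateVars)
  if (length(bad))
    stop("not candidate variable(s): ", paste(bad, collapse = ", "))
  phi <- evaluateEffect(table, predicate)
  rows <- list()
  for (v in variables)
    rows <- c(rows, .assessVariable(table, phi, v, mode))
  df <- .resultsDataFrame(rows)
  new("CauseResults", results = df, mode = mode, k = as.integer(k),
      predicate = predicate, variables = as.character(variables))
}

#' @rdname accessors
setMethod("resultTable", "CauseResults", function(x) x@results)

#' @rdname accessors
setMethod("causes", "CauseResults",
          function(x) x@results[x@results$is_cause, , drop = FALSE])

setMethod("show", "CauseResults", function(object) {
  df <- object@results
  nc <- sum(df$is_cause)
  cat(sprintf("CauseResults: %d assignment(s), %d cause(s) [mode=%s]\n",
              nrow(df), nc, object@mode))
  if (nc) {
    top <- df[seq_len(min(nc, object@k)), ]
    for (i in seq_len(nrow(top)))
      cat(sprintf("  #%d %s <- %s  P(phi|cause) = %.0f/%.0f = %.4f\n",
                  top$rank[i], top$variable[i], top$value[i],
                  top$p_actual_num[i], top$p_actual_den[i],
                  top$conditional_probability[i]))
  } else {
    cat("  None: no assignment satisfies AC1 and PC2\n")
  }
})
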