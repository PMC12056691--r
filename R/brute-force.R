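#' Brute-force actual-cause oracle
#'
#' Recomputes every [findCauses()] result by literal set construction:
#' nested loops over records, explicit per-context record lists, no
#' tabulation.  Intended as an independent correctness oracle for small
#' tables; output must agree with [findCauses()] field for field, including
#' the exact rational probabilities and the ranking.
#'
#' @inheritParams findCauses
#' @return a [CauseResults-class].
#' @export
bruteForceCauses <- function(table, predicate,
                             variables = causalSchema(table)@candidateVars,
                             k = 3, mode = c("standardized", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(is(table, "CausalModel"), is(predicate, "EffectPredicate"))
  rec <- table@records
  n <- nrow(rec)
  # effect evaluated one record at a time
  phi <- logical(n)
  for (i in seq_len(n))
    phi[i] <- evaluateEffect(rec[i, , drop = FALSE], predicate,
                             outcomeVar = table@schema@outcomeVar)
  rows <- list()
  for (v in variables) {
    others <- setdiff(.schemaVars(table@schema), v)
    vals <- sort(unique(as.character(rec[[v]])), method = "radix")
    for (val in vals) {
      actual <- integer(0)
      for (i in seq_len(n)) if (rec[i, v] == val) actual <- c(actual, i)
      n_act <- length(actual)
      n_eff <- 0
      for (i in actual) if (phi[i]) n_eff <- n_eff + 1
      # unique contexts realized among actual-world records
      proj <- function(i) paste(unlist(rec[i, others]), collapse = "\r")
      ctxs <- character(0)
      for (i in actual) {
        p <- proj(i)
        if (!p %in% ctxs) ctxs <- c(ctxs, p)
      }
      # per-context actual/counterfactual membership
      use_n <- use_m <- use_k <- numeric(0)
      pool_m <- pool_k <- 0
      for (ctx in ctxs) {
        nc <- mc <- kc <- 0
        for (i in seq_len(n)) {
          if (proj(i) != ctx) next
          if (rec[i, v] == val) {
            nc <- nc + 1
          } else {
            mc <- mc + 1
            if (phi[i]) kc <- kc + 1
          }
        }
        if (mc > 0) {
          use_n <- c(use_n, nc)
          use_m <- c(use_m, mc)
          use_k <- c(use_k, kc)
          pool_m <- pool_m + mc
          pool_k <- pool_k + kc
        }
      }
      p_act <- .frac(n_eff, n_act)
      if (pool_m == 0) {
        p_cf <- NULL
        pc2 <- FALSE
        n_cf <- 0
      } else {
        if (mode == "pooled") {
          p_cf <- .frac(pool_k, pool_m)
        } else {
          acc <- c(0, 1)
          for (j in seq_along(use_m))
            acc <- .frac_add(acc, .frac(use_n[j] * use_k[j], use_m[j]))
          p_cf <- .frac(acc[1], acc[2] * sum(use_n))
        }
        pc2 <- .frac_gt(p_act, p_cf)
        n_cf <- pool_m
      }
      rows[[length(rows) + 1]] <- list(
        variable = v, value = val, ac1 = n_eff >= 1, pc2 = pc2,
        p_act = p_act, p_cf = p_cf,
        n_actual = n_act, n_counterfactual = n_cf)
    }
  }
  df <- .bruteRank(rows)
  new("CauseResults", results = df, mode = mode, k = as.integer(k),
      predicate = predicate, variables = as.character(variables))
}

# independent re-statement of the deterministic ranking contract
.bruteRank <- function(rows) {
  df <- data.frame(
    variable = vapply(rows, `[[`, "", "variable"),
    value = vapply(rows, `[[`, "", "value"),
    ac1 = vapply(rows, `[[`, NA, "ac1"),
    pc2 = vapply(rows, `[[`, NA, "pc2"),
    ac3 = TRUE,
    is_cause = NA,
    rank = NA_integer_,
    p_actual = vapply(rows, function(r) r$p_act[1] / r$p_act[2], 0),
    p_actual_num = vapply(rows, function(r) r$p_act[1], 0),
    p_actual_den = vapply(rows, function(r) r$p_act[2], 0),
    p_counterfactual = vapply(rows, function(r)
      if (is.null(r$p_cf)) NA_real_ else r$p_cf[1] / r$p_cf[2], 0),
    p_counterfactual_num = vapply(rows, function(r)
      if (is.null(r$p_cf)) NA_real_ else r$p_cf[1], 0),
    p_counterfactual_den = vapply(rows, function(r)
      if (is.null(r$p_cf)) NA_real_ else r$p_cf[2], 0),
    n_actual = vapply(rows, `[[`, 0, "n_actual"),
    n_counterfactual = vapply(rows, `[[`, 0, "n_counterfactual"),
    stringsAsFactors = FALSE)
  df$conditional_probability <- df$p_actual
  df$is_cause <- df$ac1 & df$pc2 & df$ac3
  ord <- order(-df$conditional_probability, -df$n_actual,
               df$variable, df$value, method = "radix")
  df <- df[c(ord[df$is_cause[ord]], ord[!df$is_cause[ord]]), , drop = FALSE]
  rownames(df) <- NULL
  ncause <- sum(df$is_cause)
  if (ncause) df$rank[seq_len(ncause)] <- seq_len(ncause)
  df
}
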