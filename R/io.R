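# Readers and writers for the delimited tables the pipeline touches.
# Numeric fields are serialized at 12 significant digits; "None" cells in
# sweep maps use that literal token.

.sniffSep <- function(path) {
  header <- readLines(path, n = 1)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read a long-format corona table
#'
#' Reads a comma- or tab-delimited table (delimiter auto-detected from the
#' header line), validates it against the schema, and returns the model
#' together with a validation report.  Rows whose outcome is missing,
#' non-numeric, or non-finite are dropped and counted by reason; extra
#' columns are ignored and row order is preserved.
#'
#' @param path path to a delimited text file with a header.
#' @param schema a [VariableSchema-class]; defaults to [defaultSchema()].
#' @param columnMap optional named character vector mapping schema variable
#'   names to the file's column names, for inputs whose headers differ from
#'   the canonical ones.
#' @return list with `model` (a [CausalModel-class]) and `report`
#'   (a [TableReadReport-class]).
#' @export
readCoronaTable <- function(path, schema = defaultSchema(),
                            columnMap = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .sniffSep(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (!is.null(columnMap)) {
    for (v in names(columnMap)) {
      if (!columnMap[[v]] %in% names(df))
        stop("mapped column '", columnMap[[v]], "' not found in ", path)
      names(df)[names(df) == columnMap[[v]]] <- v
    }
  }
  need <- c(.schemaVars(schema), schema@outcomeVar)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("required column(s) missing from ", path, ": ",
         paste(miss, collapse = ", "))
  nread <- nrow(df)
  raw <- df[[schema@outcomeVar]]
  num <- if (is.numeric(raw)) raw else suppressWarnings(as.numeric(raw))
  missing_out <- is.na(raw) | (is.character(raw) & !nzchar(trimws(raw)))
  nonnum_out <- !missing_out & is.na(num)
  nonfin_out <- !missing_out & !nonnum_out & !is.finite(num)
  keep <- !(missing_out | nonnum_out | nonfin_out)
  reasons <- c(missing_outcome = sum(missing_out),
               non_numeric_outcome = sum(nonnum_out),
               non_finite_outcome = sum(nonfin_out))
  reasons <- reasons[reasons > 0]
  if (!any(keep))
    stop("no usable rows in ", path, " (all outcomes missing/invalid)")
  acc <- df[keep, , drop = FALSE]
  acc[[schema@outcomeVar]] <- num[keep]
  model <- causalModel(acc, schema)
  dom <- domains(model)
  report <- new("TableReadReport",
                nRowsRead = as.integer(nread),
                nRowsRejected = as.integer(nread - sum(keep)),
                rejectedReasons =
                  stats::setNames(as.integer(reasons), names(reasons)),
                domainsSummary = stats::setNames(
                  vapply(need, function(v) length(dom[[v]]), 0L), need))
  list(model = model, report = report)
}

setMethod("show", "TableReadReport", function(object) {
  cat(sprintf("TableReadReport: %d row(s) read, %d rejected\n",
              object@nRowsRead, object@nRowsRejected))
  for (r in names(object@rejectedReasons))
    cat(sprintf("  %s: %d\n", r, object@rejectedReasons[[r]]))
  cat("  domains:",
      paste(sprintf("%s=%d", names(object@domainsSummary),
                    object@domainsSummary), collapse = ", "), "\n")
})

.fmt12 <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- NA
  out
}

#' Write ranked cause results to a TSV file
#'
#' Columns: rank, variable, value, p_actual, p_counterfactual,
#' conditional_probability, n_support, verdict.  Causes come first in rank
#' order, then non-causes in the same deterministic order; numbers carry 12
#' significant digits, an undefined counterfactual probability is `NA`.
#'
#' @param results a [CauseResults-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCauseResults <- function(results, path) {
  stopifnot(is(results, "CauseResults"))
  df <- results@results
  out <- data.frame(
    rank = df$rank,
    variable = df$variable,
    value = df$value,
    p_actual = .fmt12(df$p_actual),
    p_counterfactual = .fmt12(df$p_counterfactual),
    conditional_probability = .fmt12(df$conditional_probability),
    n_support = df$n_actual,
    verdict = ifelse(df$is_cause, "cause", "no_cause"),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Re-read a cause-result TSV written by [writeCauseResults()]
#'
#' @param path file written by [writeCauseResults()].
#' @return data.frame with numeric probability columns.
#' @export
readCauseResults <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(rank = "integer", variable = "character",
                                   value = "character"))
}

#' Write sweep maps and the rank-frequency table
#'
#' Emits one long-format TSV per rank (`rank_1.tsv`, ...) with columns
#' `theta_abundant`, `theta_rest`, `cause_value`, `probability`; cells with
#' no cause at that rank carry the literal token `None` and an `NA`
#' probability.  Also writes `frequency.tsv` (value x rank percentages) and
#' `frequency_counts.tsv` (raw cell counts) so either denominator
#' convention can be recovered.
#'
#' @param grid a [SweepGrid-class].
#' @param freq output of [frequencyTable()] for `grid` (recomputed when
#'   omitted).
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
writeSweepOutputs <- function(grid, freq = frequencyTable(grid), dir) {
  stopifnot(is(grid, "SweepGrid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  full <- expand.grid(ir = seq_along(grid@thetaRestAxis),
                      ia = seq_along(grid@thetaAbundantAxis))
  full <- full[order(full$ia, full$ir), c("ia", "ir")]
  key <- paste(full$ia, full$ir)
  for (r in seq_len(grid@k)) {
    sub <- grid@cells[grid@cells$rank == r, , drop = FALSE]
    idx <- match(key, paste(sub$ia, sub$ir))
    out <- data.frame(
      theta_abundant = .fmt12(grid@thetaAbundantAxis[full$ia]),
      theta_rest = .fmt12(grid@thetaRestAxis[full$ir]),
      cause_value = ifelse(is.na(idx), "None", sub$value[idx]),
      probability = .fmt12(sub$probability[idx]),
      stringsAsFactors = FALSE)
    p <- file.path(dir, sprintf("rank_%d.tsv", r))
    utils::write.table(out, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    paths <- c(paths, p)
  }
  vals <- sort(unique(freq$value), method = "radix")
  vals <- c(setdiff(vals, "None"), "None")
  wide <- function(col, fmt = identity) {
    m <- data.frame(value = vals, stringsAsFactors = FALSE)
    for (r in seq_len(grid@k)) {
      sub <- freq[freq$rank == r, ]
      m[[sprintf("rank_%d", r)]] <-
        fmt(ifelse(is.na(match(vals, sub$value)), 0,
                   sub[[col]][match(vals, sub$value)]))
    }
    m
  }
  p <- file.path(dir, "frequency.tsv")
  utils::write.table(wide("percent", .fmt12), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "frequency_counts.tsv")
  utils::write.table(wide("count"), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Write a causal model back to the canonical long-format CSV
#'
#' @param model a [CausalModel-class].
#' @param path output file (`.csv` comma-delimited, anything else
#'   tab-delimited).
#' @return the path, invisibly.
#' @export
writeCoronaTable <- function(model, path) {
  stopifnot(is(model, "CausalModel"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  rec <- model@records
  rec[[model@schema@outcomeVar]] <- .fmt12(rec[[model@schema@outcomeVar]])
  utils::write.table(rec, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
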