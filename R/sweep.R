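#' Build the threshold axes for a sweep
#'
#' The observed log2FC range is split at a pivot (0.1 by default, the
#' point below which abundant-protein depletion is considered desirable):
#' the abundant-protein axis spans `[min log2FC, pivot]` and the
#' rest-protein axis `[pivot, max log2FC]`, endpoints included.  Spacing is
#' linear by default; `"quantile"` places the interior points at empirical
#' quantiles of the observed log2FC values within each segment.
#'
#' @param table a [CausalModel-class].
#' @param nAbundantSteps,nRestSteps number of grid points per axis
#'   (each >= 2; defaults 20 and 21).
#' @param pivot split point between the two segments (default 0.1).
#' @param spacing `"linear"` (default) or `"quantile"`.
#' @return list with numeric `thetaAbundant` and `thetaRest` axes.
#' @export
buildGrid <- function(table, nAbundantSteps = 20, nRestSteps = 21,
                      pivot = 0.1, spacing = c("linear", "quantile")) {
  spacing <- match.arg(spacing)
  stopifnot(is(table, "CausalModel"), nAbundantSteps >= 2, nRestSteps >= 2)
  fc <- table@records[[table@schema@outcomeVar]]
  lo <- min(fc)
  hi <- max(fc)
  if (lo >= pivot || hi <= pivot)
    stop("degenerate threshold range: observed log2FC [", signif(lo, 4),
         ", ", signif(hi, 4), "] does not straddle the pivot ", pivot)
  axis <- function(a, b, n, seg) {
    if (spacing == "linear") return(seq(a, b, length.out = n))
    q <- stats::quantile(seg, probs = seq(0, 1, length.out = n),
                         names = FALSE, type = 7)
    q[1] <- a
    q[n] <- b
    unique(q)  # collapses ties; axes must stay strictly monotone
  }
  list(thetaAbundant = axis(lo, pivot, nAbundantSteps, fc[fc <= pivot]),
       thetaRest = axis(pivot, hi, nRestSteps, fc[fc >= pivot]))
}

#' Run the cause search over a grid of threshold pairs
#'
#' For every `(thetaAbundant, thetaRest)` pair, instantiates the effect
#' predicate from the template (keeping its abundant class and orientation),
#' runs [findCauses()], and records the top-`k` causes.  Cells are
#' independent; the result is a pure function of its inputs.
#'
#' @param table a [CausalModel-class].
#' @param predicateTemplate an [EffectPredicate-class] supplying the
#'   abundant class, orientation, and id column; its thresholds are
#'   overridden per cell.
#' @param axes axis list from [buildGrid()].
#' @param k causes kept per cell (default 3).
#' @param mode counterfactual aggregation; see [pc2Holds()].
#' @param variables candidate variables to search.
#' @return a [SweepGrid-class].
#' @examples
#' m <- simulateCorona(coronaSimConfig(noiseSd = 0, nullShiftSd = 0))
#' tpl <- effectPredicate(abundantIds = modelMetadata(m)$abundant_ids)
#' g <- runSweep(m, tpl, buildGrid(m, 4, 4))
#' frequencyTable(g)
#' @export
runSweep <- function(table, predicateTemplate, axes, k = 3,
                     mode = c("standardized", "pooled"),
                     variables = causalSchema(table)@candidateVars) {
  mode <- match.arg(mode)
  stopifnot(is(table, "CausalModel"),
            is(predicateTemplate, "EffectPredicate"))
  ta <- axes$thetaAbundant
  tr <- axes$thetaRest
  out <- vector("list", length(ta) * length(tr))
  cell <- 0L
  for (ia in seq_along(ta)) {
    for (ir in seq_along(tr)) {
      cell <- cell + 1L
      p <- predicateTemplate
      p@thetaAbundant <- ta[ia]
      p@thetaRest <- tr[ir]
      res <- findCauses(table, p, variables = variables, k = k, mode = mode)
      top <- causes(res)
      top <- top[top$rank <= k, , drop = FALSE]
      if (nrow(top))
        out[[cell]] <- data.frame(
          ia = ia, ir = ir,
          theta_abundant = ta[ia], theta_rest = tr[ir],
          rank = top$rank, variable = top$variable, value = top$value,
          probability = top$conditional_probability,
          stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, out[!vapply(out, is.null, NA)])
  if (is.null(cells))
    cells <- data.frame(ia = integer(), ir = integer(),
                        theta_abundant = numeric(), theta_rest = numeric(),
                        rank = integer(), variable = character(),
                        value = character(), probability = numeric(),
                        stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  new("SweepGrid", thetaAbundantAxis = ta, thetaRestAxis = tr,
      cells = cells, k = as.integer(k), mode = mode,
      nCells = length(ta) * length(tr))
}

#' @rdname accessors
setMethod("sweepCells", "SweepGrid", function(x) x@cells)

setMethod("show", "SweepGrid", function(object) {
  cat(sprintf("SweepGrid: %d x %d cells (k = %d, mode = %s)\n",
              length(object@thetaAbundantAxis),
              length(object@thetaRestAxis), object@k, object@mode))
  n1 <- sum(object@cells$rank == 1)
  cat(sprintf("  cells with a rank-1 cause: %d / %d\n", n1, object@nCells))
})

#' Rank-frequency summary of a sweep
#'
#' For each rank up to `k`, the number and percentage of grid cells where
#' each cause value holds that rank; cells with no cause at that rank are
#' tallied under `"None"`.  Percentages use the total cell count as the
#' denominator, so each rank's percentages sum to 100.
#'
#' @param grid a [SweepGrid-class].
#' @return data.frame with columns `rank`, `value`, `count`, `percent`.
#' @export
frequencyTable <- function(grid) {
  stopifnot(is(grid, "SweepGrid"))
  res <- list()
  for (r in seq_len(grid@k)) {
    sub <- grid@cells[grid@cells$rank == r, , drop = FALSE]
    tab <- table(sub$value)
    vals <- if (length(tab)) sort(names(tab), method = "radix")
            else character(0)
    df <- data.frame(rank = r,
                     value = c(vals, "None"),
                     count = c(as.integer(tab[vals]),
                               grid@nCells - nrow(sub)),
                     stringsAsFactors = FALSE)
    res[[r]] <- df
  }
  out <- do.call(rbind, res)
  out$percent <- out$count * 100 / grid@nCells
  rownames(out) <- NULL
  out
}

#' Percentage of cells where a value is among the top three causes
#'
#' @param grid a [SweepGrid-class] built with `k >= 3` (smaller `k` uses
#'   the available ranks).
#' @param value a cause value (e.g. a molecule label).
#' @return percentage of grid cells in which `value` holds rank 1, 2 or 3.
#' @export
top3MembershipRate <- function(grid, value) {
  stopifnot(is(grid, "SweepGrid"))
  sub <- grid@cells[grid@cells$value == value &
                    grid@cells$rank <= min(3L, grid@k), , drop = FALSE]
  # a value can hold at most one rank per cell, but guard via unique cells
  ncell <- nrow(unique(sub[c("ia", "ir")]))
  ncell * 100 / grid@nCells
}
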