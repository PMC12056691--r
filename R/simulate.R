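#' Configure the corona-table simulator
#'
#' Defaults emulate a desk-scale version of the study design: 20 proteins
#' of which the first 5 are highly abundant, 8 candidate molecules with one
#' planted cause, one record per (protein x molecule x concentration) at
#' 10/100/1000, planted shifts of -1 / +1 log2 units (depletion of abundant
#' proteins, enrichment of the rest), molecule-level nuisance shifts and
#' per-record noise of 0.2 log2 units, and a concentration gain of 1 so the
#' planted effect is concentration-independent.
#'
#' @param nProteins,nAbundant protein counts (abundant = first
#'   `nAbundant` ids).
#' @param molecules candidate molecule labels.
#' @param concentrations concentration levels.
#' @param plantedCause planted causal molecule, or `NULL` for a null table.
#' @param depletionShift,enrichmentShift planted log2FC shifts by protein
#'   class.
#' @param nullShiftSd sd of per-molecule nuisance shifts (null molecules).
#' @param noiseSd sd of per-record Gaussian noise.
#' @param concentrationGain multiplier on shifts per concentration (length
#'   1 or one per concentration).
#' @param seed RNG seed.
#' @return a [SyntheticConfig-class].
#' @export
coronaSimConfig <- function(nProteins = 20, nAbundant = 5,
                            molecules = sprintf("M%02d", 1:8),
                            concentrations = c(10, 100, 1000),
                            plantedCause = molecules[1],
                            depletionShift = -1.0, enrichmentShift = 1.0,
                            nullShiftSd = 0.2, noiseSd = 0.2,
                            concentrationGain = 1, seed = 1) {
  new("SyntheticConfig",
      nProteins = as.integer(nProteins),
      nAbundant = as.integer(nAbundant),
      molecules = as.character(molecules),
      concentrations = as.numeric(concentrations),
      plantedCause = if (is.null(plantedCause)) character(0)
                     else as.character(plantedCause),
      depletionShift = as.numeric(depletionShift),
      enrichmentShift = as.numeric(enrichmentShift),
      nullShiftSd = as.numeric(nullShiftSd),
      noiseSd = as.numeric(noiseSd),
      concentrationGain = as.numeric(concentrationGain),
      seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat(sprintf("  %d proteins (%d abundant), %d molecules, %d concentrations\n",
              object@nProteins, object@nAbundant, length(object@molecules),
              length(object@concentrations)))
  cat(sprintf("  planted cause: %s (shifts %+g / %+g)\n",
              if (length(object@plantedCause)) object@plantedCause
              else "none",
              object@depletionShift, object@enrichmentShift))
  cat(sprintf("  nullShiftSd = %g, noiseSd = %g, seed = %d\n",
              object@nullShiftSd, object@noiseSd, object@seed))
})

#' Generate a corona-like table with known causal structure
#'
#' One record per (protein x molecule x concentration) with
#' \deqn{\mathrm{log2FC}(p, m, c) = g(c)\,s(m, \mathrm{class}(p)) +
#'   \varepsilon,\quad \varepsilon \sim N(0, \sigma^2)}
#' where the planted cause's shift is `depletionShift` for abundant
#' proteins and `enrichmentShift` for the rest, and each null molecule
#' draws one shared shift from `N(0, nullShiftSd^2)`.  Protein ids are
#' synthesized as `SYN0001...`; the abundant ids are returned in the
#' model's metadata (`modelMetadata(x)$abundant_ids`) together with the
#' configuration.  Identical seeds give identical tables.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [CausalModel-class].
#' @examples
#' m <- simulateCorona(coronaSimConfig(seed = 7))
#' m
#' @export
simulateCorona <- function(config = coronaSimConfig()) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  set.seed(config@seed)
  prot <- sprintf("SYN%04d", seq_len(config@nProteins))
  abundant <- prot[seq_len(config@nAbundant)]
  mols <- config@molecules
  # one nuisance shift per molecule, drawn in label order for determinism;
  # the planted molecule's draw is discarded
  nullShift <- stats::setNames(
    stats::rnorm(length(mols), 0, config@nullShiftSd), mols)
  gain <- config@concentrationGain
  if (length(gain) == 1) gain <- rep(gain, length(config@concentrations))
  gain <- stats::setNames(gain, as.character(config@concentrations))
  df <- expand.grid(Protein_ID = prot, Small_Molecule = mols,
                    Concentration_of_Molecule =
                      as.character(config@concentrations),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  isAb <- df$Protein_ID %in% abundant
  planted <- if (length(config@plantedCause) == 1)
    df$Small_Molecule == config@plantedCause else rep(FALSE, nrow(df))
  shift <- ifelse(planted,
                  ifelse(isAb, config@depletionShift, config@enrichmentShift),
                  nullShift[df$Small_Molecule])
  eps <- stats::rnorm(nrow(df), 0, config@noiseSd)
  df$log2FC <- gain[df$Concentration_of_Molecule] * shift + eps
  causalModel(df, defaultSchema(),
              metadata = list(abundant_ids = abundant, config = config))
}

#' Generate the confounded toy table (season / ice cream)
#'
#' A six-record table in which the outcome depends only on the season:
#' during summer the binary outcome is always 1, during winter always 0,
#' while ice-cream consumption is merely more frequent in summer.  Sized so
#' that pooled counterfactual aggregation is fooled into calling
#' `IceCream <- hi` a cause while context-standardized aggregation rejects
#' it; `Season <- summer` is a cause under both.  Both variables are
#' candidates so either can be put under test (the other then serves as
#' the contingency context).  The seed only permutes row order, to which
#' all results are invariant.
#'
#' @param seed integer; permutes record order.
#' @return a [CausalModel-class] with outcome column `Outcome` (0/1);
#'   pair it with `effectPredicate(thetaRest = 0.5,
#'   abundantIds = character(0))` so phi is `Outcome > 0.5`.
#' @export
simulateConfounded <- function(seed = 1) {
  df <- data.frame(
    Season = c("summer", "summer", "summer", "winter", "winter", "winter"),
    IceCream = c("hi", "hi", "lo", "hi", "lo", "lo"),
    Outcome = c(1, 1, 1, 0, 0, 0),
    stringsAsFactors = FALSE)
  set.seed(seed)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  sch <- variableSchema(contextVars = character(),
                        candidateVars = c("IceCream", "Season"),
                        outcomeVar = "Outcome")
  causalModel(df, sch)
}
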