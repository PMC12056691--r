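# Hand-checkable worlds and random-table generators shared across tests.

# T1: balanced 2x2 world where M <- a is the unique cause.
#   (M=a, C=1, phi=1), (a, 2, 1), (b, 1, 0), (b, 2, 1)
toyT1 <- function() {
  causalModel(
    data.frame(M = c("a", "a", "b", "b"),
               C = c("1", "2", "1", "2"),
               Outcome = c(1, 1, 0, 1),
               stringsAsFactors = FALSE),
    variableSchema(contextVars = "C", candidateVars = "M",
                   outcomeVar = "Outcome"))
}

# phi for binary-coded outcomes: Outcome > 0.5, no abundance class
binaryPhi <- function() {
  effectPredicate(thetaRest = 0.5, abundantIds = character(0))
}

# random small tables for oracle-equivalence checks: 5 proteins x 3
# molecules x 2 concentrations, with random row dropout so designs are
# unbalanced and some contexts lack counterfactual counterparts
randomTable <- function(seed, flavor = c("binary", "corona")) {
  flavor <- match.arg(flavor)
  set.seed(seed)
  abundant <- c("SYN0001", "SYN0002")
  df <- expand.grid(Protein_ID = sprintf("SYN%04d", 1:5),
                    Small_Molecule = c("a", "b", "c"),
                    Concentration_of_Molecule = c("10", "100"),
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  df <- df[stats::runif(nrow(df)) < 0.85, , drop = FALSE]
  if (flavor == "binary") {
    df$log2FC <- sample(0:1, nrow(df), replace = TRUE)
    pred <- effectPredicate(thetaRest = 0.5, abundantIds = character(0))
  } else {
    df$log2FC <- stats::runif(nrow(df), -2, 2)
    pred <- effectPredicate(0.1, 0.1, abundantIds = abundant)
  }
  list(model = causalModel(df), predicate = pred)
}

expect_same_results <- function(a, b) {
  expect_equal(resultTable(a), resultTable(b))
}
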