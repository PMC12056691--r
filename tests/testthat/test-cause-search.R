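test_that("candidate assignments enumerate observed values in sorted order", {
  t1 <- toyT1()
  a <- candidateAssignments(t1, "M")
  expect_length(a, 2)
  expect_identical(vapply(a, function(x) x@value, ""), c("a", "b"))
  expect_error(candidateAssignments(t1, "C"), "candidate")
  m <- simulateCorona(coronaSimConfig(seed = 2))
  vals <- vapply(candidateAssignments(m, "Small_Molecule"),
                 function(x) x@value, "")
  expect_identical(vals, sort(sprintf("M%02d", 1:8)))
})

test_that("AC1 holds iff the assignment and effect co-occur", {
  t1 <- toyT1()
  phi <- binaryPhi()
  expect_true(ac1Holds(t1, new("Assignment", variable = "M", value = "a"),
                       phi))
  # effect nowhere: AC1 fails for every assignment
  allzero <- causalModel(
    data.frame(M = c("a", "b"), C = c("1", "1"), Outcome = c(0, 0)),
    variableSchema("C", "M", "Outcome"))
  for (a in candidateAssignments(allzero, "M"))
    expect_false(ac1Holds(allzero, a, phi))
  # a value never observed is rejected at the assignment level
  expect_error(ac1Holds(t1, new("Assignment", variable = "M", value = "z"),
                        phi), "never observed")
})

test_that("contingency split matches actual-world contexts exactly", {
  t1 <- toyT1()
  sp <- contingencySplit(t1, new("Assignment", variable = "M", value = "a"))
  expect_equal(nrow(sp$actual), 2)
  expect_length(sp$counterfactual, 2)
  expect_equal(vapply(sp$counterfactual, nrow, 0L), c(`1` = 1L, `2` = 1L))
  expect_identical(sp$counterfactual[["1"]]$M, "b")
  expect_identical(sp$counterfactual[["1"]]$Outcome, 0)
  # single-valued variable: all counterfactual lists are empty
  solo <- causalModel(
    data.frame(M = c("a", "a"), C = c("1", "2"), Outcome = c(1, 0)),
    variableSchema("C", "M", "Outcome"))
  sp2 <- contingencySplit(solo, new("Assignment", variable = "M",
                                    value = "a"))
  expect_true(all(vapply(sp2$counterfactual, nrow, 0L) == 0))
  # a context realized only outside the actual world enters neither side
  t1b <- causalModel(
    data.frame(M = c("a", "a", "b", "b", "b"),
               C = c("1", "2", "1", "2", "3"),
               Outcome = c(1, 1, 0, 1, 1)),
    variableSchema("C", "M", "Outcome"))
  sp3 <- contingencySplit(t1b, new("Assignment", variable = "M",
                                   value = "a"))
  expect_false("3" %in% names(sp3$counterfactual))
})

test_that("PC2 compares exact probabilities on the toy worlds", {
  t1 <- toyT1()
  phi <- binaryPhi()
  a <- new("Assignment", variable = "M", value = "a")
  b <- new("Assignment", variable = "M", value = "b")
  for (mode in c("pooled", "standardized")) {
    ra <- pc2Holds(t1, a, phi, mode)
    expect_true(ra$holds)
    expect_identical(ra$pActualFrac, c(1, 1))
    expect_identical(ra$pCounterfactualFrac, c(1, 2))
    rb <- pc2Holds(t1, b, phi, mode)
    expect_false(rb$holds)
    expect_identical(rb$pActualFrac, c(1, 2))
    expect_identical(rb$pCounterfactualFrac, c(1, 1))
  }
})

test_that("the confounder toy separates pooled from standardized PC2", {
  t2 <- simulateConfounded(1)
  phi <- binaryPhi()
  ice <- new("Assignment", variable = "IceCream", value = "hi")
  pooled <- pc2Holds(t2, ice, phi, "pooled")
  expect_true(pooled$holds)               # fooled by the confound
  expect_identical(pooled$pActualFrac, c(2, 3))
  expect_identical(pooled$pCounterfactualFrac, c(1, 3))
  std <- pc2Holds(t2, ice, phi, "standardized")
  expect_false(std$holds)                 # (2/3)*1 + (1/3)*0 = p_actual
  expect_identical(std$pCounterfactualFrac, c(2, 3))
  season <- new("Assignment", variable = "Season", value = "summer")
  for (mode in c("pooled", "standardized"))
    expect_true(pc2Holds(t2, season, phi, mode)$holds)
})

test_that("a single-valued variable yields an undefined counterfactual", {
  solo <- causalModel(
    data.frame(M = c("a", "a"), C = c("1", "2"), Outcome = c(1, 1)),
    variableSchema("C", "M", "Outcome"))
  r <- pc2Holds(solo, new("Assignment", variable = "M", value = "a"),
                binaryPhi())
  expect_false(r$holds)
  expect_true(is.na(r$pCounterfactual))
  res <- resultTable(findCauses(solo, binaryPhi()))
  expect_false(res$is_cause[1])
  expect_true(is.na(res$p_counterfactual[1]))
})

test_that("conditional probability is the exact co-occurrence ratio", {
  t1 <- toyT1()
  phi <- binaryPhi()
  pa <- conditionalProbability(t1, new("Assignment", variable = "M",
                                       value = "a"), phi)
  expect_equal(as.numeric(pa), 1)
  pb <- conditionalProbability(t1, new("Assignment", variable = "M",
                                       value = "b"), phi)
  expect_equal(as.numeric(pb), 0.5)
  expect_identical(attr(pb, "frac"), c(1, 2))
})

test_that("findCauses identifies exactly {M <- a} on T1", {
  res <- findCauses(toyT1(), binaryPhi())
  cs <- causes(res)
  expect_equal(nrow(cs), 1)
  expect_identical(cs$value, "a")
  expect_identical(cs$rank, 1L)
  expect_equal(cs$conditional_probability, 1)
  # probabilities carried as exact integer ratios
  expect_identical(c(cs$p_actual_num, cs$p_actual_den), c(1, 1))
  expect_identical(c(cs$p_counterfactual_num, cs$p_counterfactual_den),
                   c(1, 2))
})

test_that("an everywhere-false effect yields an empty cause set", {
  m <- simulateCorona(coronaSimConfig(seed = 3))
  fc <- records(m)$log2FC
  vacuous <- effectPredicate(min(fc) - 1, max(fc) + 1,
                             modelMetadata(m)$abundant_ids)
  res <- findCauses(m, vacuous)
  expect_equal(nrow(causes(res)), 0)
  expect_false(any(resultTable(res)$ac1))
})

test_that("results are local: untouched assignments are unchanged", {
  t1 <- toyT1()
  phi <- binaryPhi()
  before <- resultTable(findCauses(t1, phi))
  # add a record for value b in a brand-new context: a's occurrences and
  # matched contexts are untouched, so a's result row must not change
  aug <- causalModel(
    rbind(records(t1),
          data.frame(M = "b", C = "9", Outcome = 1)),
    causalSchema(t1))
  after <- resultTable(findCauses(aug, phi))
  rowA <- function(df) {
    r <- df[df$value == "a",
            c("ac1", "pc2", "is_cause", "p_actual_num", "p_actual_den",
              "p_counterfactual_num", "p_counterfactual_den",
              "n_actual", "n_counterfactual")]
    rownames(r) <- NULL
    r
  }
  expect_equal(rowA(before), rowA(after))
})

test_that("pooled and standardized agree on balanced designs", {
  for (seed in 1:10) {
    set.seed(seed)
    df <- expand.grid(Protein_ID = sprintf("SYN%04d", 1:4),
                      Small_Molecule = c("a", "b", "c"),
                      Concentration_of_Molecule = c("10", "100"),
                      stringsAsFactors = FALSE)
    df$log2FC <- stats::runif(nrow(df), -2, 2)
    m <- causalModel(df)
    pred <- effectPredicate(0.1, 0.1, c("SYN0001", "SYN0002"))
    rp <- resultTable(findCauses(m, pred, mode = "pooled"))
    rs <- resultTable(findCauses(m, pred, mode = "standardized"))
    rp <- rp[order(rp$value), ]
    rs <- rs[order(rs$value), ]
    expect_equal(rp, rs, ignore_attr = TRUE)
  }
})

test_that("standardized PC2 rejects context-determined effects", {
  # outcome is a deterministic function of the context, so within every
  # context p_cf(ctx) = p_actual(ctx); no assignment may pass PC2
  for (seed in 1:10) {
    set.seed(seed)
    df <- expand.grid(Protein_ID = sprintf("SYN%04d", 1:5),
                      Small_Molecule = c("a", "b", "c"),
                      Concentration_of_Molecule = c("10", "100"),
                      stringsAsFactors = FALSE)
    ctx <- paste(df$Protein_ID, df$Concentration_of_Molecule)
    lvl <- unique(ctx)
    ctxOutcome <- stats::setNames(sample(0:1, length(lvl), TRUE), lvl)
    df$log2FC <- as.numeric(ctxOutcome[ctx])
    # unbalance by duplicating rows, so every context keeps counterfactual
    # counterparts while the value counts differ across contexts
    df <- rbind(df, df[sample.int(nrow(df), 10), ])
    m <- causalModel(df)
    res <- resultTable(findCauses(m, binaryPhi(), mode = "standardized"))
    expect_false(any(res$pc2))
  }
})

test_that("ranking is deterministic with the documented tie-breaks", {
  # two causes tied on conditional probability: larger support wins,
  # then lexicographic value
  df <- data.frame(
    M = c("a", "a", "c", "b", "b", "b", "b", "c"),
    C = c("1", "1", "1", "2", "2", "2", "2", "2"),
    Outcome = c(1, 1, 0, 1, 1, 1, 1, 0))
  m <- causalModel(df, variableSchema("C", "M", "Outcome"))
  res <- causes(findCauses(m, binaryPhi()))
  expect_identical(res$value, c("b", "a"))  # both P=1; b has support 4
  expect_identical(res$rank, c(1L, 2L))
})
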