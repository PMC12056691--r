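writeCsv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

cleanDf <- function() {
  data.frame(Protein_ID = c("P1", "P2", "P1", "P2"),
             Small_Molecule = c("a", "a", "b", "b"),
             Concentration_of_Molecule = c(10, 10, 100, 100),
             log2FC = c(1.5, -0.25, 0.125, 2),
             stringsAsFactors = FALSE)
}

test_that("clean tables read without rejections, preserving order", {
  rt <- readCoronaTable(writeCsv(cleanDf()))
  expect_equal(nrow(records(rt$model)), 4)
  expect_equal(rt$report@nRowsRejected, 0L)
  expect_equal(rt$report@nRowsRead, 4L)
  expect_identical(records(rt$model)$Protein_ID, cleanDf()$Protein_ID)
  expect_identical(domains(rt$model)$Concentration_of_Molecule,
                   c("10", "100"))
})

test_that("rows with missing outcome are dropped and counted by reason", {
  df <- cleanDf()
  df$log2FC <- as.character(df$log2FC)
  df$log2FC[2] <- ""
  rt <- readCoronaTable(writeCsv(df))
  expect_equal(nrow(records(rt$model)), 3)
  expect_equal(rt$report@nRowsRejected, 1L)
  expect_equal(rt$report@rejectedReasons[["missing_outcome"]], 1L)
  expect_equal(rt$report@nRowsRead,
               nrow(records(rt$model)) + rt$report@nRowsRejected)
})

test_that("schema errors name the missing column; empty tables error", {
  df <- cleanDf()
  names(df)[names(df) == "Small_Molecule"] <- "Molecule"
  p <- writeCsv(df)
  expect_error(readCoronaTable(p), "Small_Molecule")
  # ... unless a column mapping supplies it
  rt <- readCoronaTable(p, columnMap = c(Small_Molecule = "Molecule"))
  expect_equal(nrow(records(rt$model)), 4)
  df2 <- cleanDf()
  df2$log2FC <- NA
  expect_error(readCoronaTable(writeCsv(df2)), "no usable rows")
})

test_that("tab-delimited input is auto-detected and re-reading is idempotent", {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(cleanDf(), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  rt <- readCoronaTable(path)
  expect_equal(nrow(records(rt$model)), 4)
  # write -> read round trip reproduces the in-memory table
  out <- tempfile(fileext = ".csv")
  writeCoronaTable(rt$model, out)
  rt2 <- readCoronaTable(out)
  expect_equal(records(rt2$model), records(rt$model), tolerance = 1e-12)
})

test_that("cause results round-trip through TSV at 12 significant digits", {
  m <- simulateCorona(coronaSimConfig(seed = 11))
  res <- findCauses(m, effectPredicate(
    abundantIds = modelMetadata(m)$abundant_ids))
  path <- tempfile(fileext = ".tsv")
  writeCauseResults(res, path)
  back <- readCauseResults(path)
  df <- resultTable(res)
  expect_equal(nrow(back), nrow(df))
  expect_identical(back$value, df$value)
  expect_identical(back$verdict,
                   ifelse(df$is_cause, "cause", "no_cause"))
  expect_equal(back$p_actual, df$p_actual, tolerance = 1e-11)
  expect_equal(back$conditional_probability, df$conditional_probability,
               tolerance = 1e-11)
  expect_equal(back$n_support, df$n_actual)
  # empty and single-row outputs
  empty <- findCauses(toyT1(), effectPredicate(
    thetaRest = 2, abundantIds = character(0)))  # phi nowhere
  p2 <- tempfile(fileext = ".tsv")
  writeCauseResults(empty, p2)
  expect_equal(nrow(readCauseResults(p2)), 2)  # all assignments reported
})

test_that("sweep outputs carry the None token and consistent frequencies", {
  m <- simulateCorona(coronaSimConfig(noiseSd = 0, nullShiftSd = 0))
  tpl <- effectPredicate(abundantIds = modelMetadata(m)$abundant_ids)
  grid <- runSweep(m, tpl, buildGrid(m, 2, 2))
  dir <- tempfile()
  paths <- writeSweepOutputs(grid, frequencyTable(grid), dir)
  r1 <- utils::read.delim(file.path(dir, "rank_1.tsv"),
                          stringsAsFactors = FALSE)
  expect_equal(nrow(r1), 4)      # 2x2 grid -> 4 data rows per rank file
  r3 <- utils::read.delim(file.path(dir, "rank_3.tsv"),
                          stringsAsFactors = FALSE)
  # zero-noise table has a unique cause, so rank 3 is None everywhere
  expect_true(all(r3$cause_value == "None"))
  freq <- frequencyTable(grid)
  # per rank: percentages (None included) must sum to exactly 100
  for (r in 1:3)
    expect_equal(sum(freq$percent[freq$rank == r]), 100)
  # recompute a percentage from raw cell counts
  n1 <- sum(sweepCells(grid)$rank == 1 & sweepCells(grid)$value == "M01")
  expect_equal(freq$percent[freq$rank == 1 & freq$value == "M01"],
               n1 * 100 / grid@nCells)
})

test_that("a causeless single-cell sweep writes one None row", {
  # thresholds that keep phi empty in the only cell
  df <- data.frame(Protein_ID = c("A1", "R1"),
                   Small_Molecule = c("a", "b"),
                   Concentration_of_Molecule = "10",
                   log2FC = c(-1, 1))
  m <- causalModel(df)
  tpl <- effectPredicate(abundantIds = "A1")
  grid <- runSweep(m, tpl, list(thetaAbundant = -2, thetaRest = 2))
  dir <- tempfile()
  writeSweepOutputs(grid, frequencyTable(grid), dir)
  r1 <- utils::read.delim(file.path(dir, "rank_1.tsv"),
                          stringsAsFactors = FALSE)
  expect_equal(nrow(r1), 1)
  expect_identical(r1$cause_value, "None")
})
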