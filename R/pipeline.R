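#' Run a full pipeline stage from a configuration
#'
#' Config-driven entry point wiring the stages together; the thin
#' command-line wrapper shipped under `inst/cli/` is a front end to this
#' function.  `config` is a list (or path to a YAML file) with a `task`
#' field — `"simulate"`, `"find_causes"`, `"sweep"`, or `"reproduce"` — plus
#' the settings below.  The resolved configuration is echoed to
#' `config_used.yaml` in the output directory for provenance; identical
#' config and inputs give identical outputs.
#'
#' Common fields: `out_dir` (default `"."`), `seed`.
#' Effect fields (`find_causes`/`sweep`/`reproduce`): `theta_abundant`,
#' `theta_rest` (defaults 0.1), `orientation`, `abundant_list` (path to a
#' two-column TSV, default the packaged fixture; `"none"` disables the
#' class), `mode`, `top_k`, `candidate_vars`, and `column_map` (named list
#' mapping schema names to file columns).
#' Sweep fields: `steps_abundant` (20), `steps_rest` (21), `spacing`.
#' Simulate fields: any argument of [coronaSimConfig()] (snake_case).
#' Reproduce fields: `focal` (default `"PtdChos"`).
#'
#' @param config list or path to a YAML config file.
#' @return the stage's result object, invisibly (model, [CauseResults-class],
#'   [SweepGrid-class], or reproduction summary list).
#' @seealso [reproduceStudy()]
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  task <- config$task
  if (is.null(task) ||
      !task %in% c("simulate", "find_causes", "sweep", "reproduce"))
    stop("config$task must be one of simulate, find_causes, sweep, reproduce")
  cfg <- .resolveConfig(config)
  # validate inputs before creating any output
  if (task %in% c("find_causes", "sweep", "reproduce")) {
    if (is.null(cfg$input)) stop("config$input is required for task ", task)
    if (!file.exists(cfg$input)) stop("input file not found: ", cfg$input)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$out_dir, "config_used.yaml"))
  result <- switch(task,
    simulate = .taskSimulate(cfg),
    find_causes = .taskFindCauses(cfg),
    sweep = .taskSweep(cfg),
    reproduce = .taskReproduce(cfg))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolveConfig <- function(config) {
  defaults <- list(
    out_dir = ".", seed = 1,
    theta_abundant = 0.1, theta_rest = 0.1,
    orientation = "depletion_enrichment",
    abundant_list = "packaged", mode = "standardized", top_k = 3,
    candidate_vars = "Small_Molecule",
    steps_abundant = 20, steps_rest = 21, spacing = "linear",
    focal = "PtdChos")
  for (k in names(defaults))
    config[[k]] <- config[[k]] %||% defaults[[k]]
  config
}

.configAbundant <- function(cfg) {
  if (identical(cfg$abundant_list, "none")) return(character(0))
  if (identical(cfg$abundant_list, "packaged")) return(abundantProteins())
  if (!file.exists(cfg$abundant_list))
    stop("abundant_list file not found: ", cfg$abundant_list)
  utils::read.delim(cfg$abundant_list, stringsAsFactors = FALSE)[[1]]
}

.configPredicate <- function(cfg) {
  effectPredicate(thetaAbundant = cfg$theta_abundant,
                  thetaRest = cfg$theta_rest,
                  abundantIds = .configAbundant(cfg),
                  orientation = cfg$orientation)
}

.configColumnMap <- function(cfg) {
  if (is.null(cfg$column_map)) NULL else unlist(cfg$column_map)
}

.taskSimulate <- function(cfg) {
  args <- list(seed = cfg$seed)
  map <- c(n_proteins = "nProteins", n_abundant = "nAbundant",
           molecules = "molecules", concentrations = "concentrations",
           planted_cause = "plantedCause",
           depletion_shift = "depletionShift",
           enrichment_shift = "enrichmentShift",
           null_shift_sd = "nullShiftSd", noise_sd = "noiseSd",
           concentration_gain = "concentrationGain")
  for (k in names(map))
    if (!is.null(cfg[[k]])) args[[map[[k]]]] <- cfg[[k]]
  model <- simulateCorona(do.call(coronaSimConfig, args))
  writeCoronaTable(model, file.path(cfg$out_dir, "synthetic_corona.csv"))
  writeLines(modelMetadata(model)$abundant_ids,
             file.path(cfg$out_dir, "abundant_ids.txt"))
  message(sprintf("simulate: wrote %d records to %s",
                  nrow(records(model)), cfg$out_dir))
  model
}

.taskFindCauses <- function(cfg) {
  rt <- readCoronaTable(cfg$input, defaultSchema(), .configColumnMap(cfg))
  res <- findCauses(rt$model, .configPredicate(cfg),
                    variables = cfg$candidate_vars,
                    k = cfg$top_k, mode = cfg$mode)
  writeCauseResults(res, file.path(cfg$out_dir, "causes.tsv"))
  message(sprintf("find_causes: %d record(s), %d rejected, %d cause(s)",
                  rt$report@nRowsRead, rt$report@nRowsRejected,
                  sum(resultTable(res)$is_cause)))
  res
}

.taskSweep <- function(cfg) {
  rt <- readCoronaTable(cfg$input, defaultSchema(), .configColumnMap(cfg))
  axes <- buildGrid(rt$model, cfg$steps_abundant, cfg$steps_rest,
                    spacing = cfg$spacing)
  grid <- runSweep(rt$model, .configPredicate(cfg), axes,
                   k = cfg$top_k, mode = cfg$mode,
                   variables = cfg$candidate_vars)
  writeSweepOutputs(grid, frequencyTable(grid), cfg$out_dir)
  message(sprintf("sweep: %d cells, %d with a rank-1 cause",
                  grid@nCells, sum(sweepCells(grid)$rank == 1)))
  grid
}

.taskReproduce <- function(cfg) {
  rep <- reproduceStudy(cfg$input, focal = cfg$focal,
                        stepsAbundant = cfg$steps_abundant,
                        stepsRest = cfg$steps_rest,
                        k = cfg$top_k, mode = cfg$mode,
                        orientation = cfg$orientation,
                        abundantIds = .configAbundant(cfg),
                        columnMap = .configColumnMap(cfg))
  writeSweepOutputs(rep$grid, rep$frequency, cfg$out_dir)
  message(sprintf("reproduce: %s rank-1 in %.2f%% of cells, top-3 in %.2f%%",
                  rep$focal, rep$rank1Percent, rep$top3Percent))
  rep
}

#' Reproduce the study-style sweep analysis on a user-supplied table
#'
#' Runs the full analysis on an external long-format log2FC table: read and
#' validate, build the default 20 x 21 threshold grid, sweep the cause
#' search, and summarize.  Reports the percentage of grid cells in which
#' the focal molecule is the rank-1 cause, the percentage in which it is
#' among the top three, and the full rank-frequency table.
#'
#' @param input path to the long-format table (e.g. the source study's
#'   supplementary log2FC table).
#' @param focal molecule whose cell percentages are reported (default
#'   `"PtdChos"`).
#' @param stepsAbundant,stepsRest grid resolution (defaults 20 and 21).
#' @param k causes kept per cell.
#' @param mode counterfactual aggregation; see [pc2Holds()].
#' @param orientation effect orientation; see [effectPredicate()].
#' @param abundantIds abundant protein class (default the packaged list).
#' @param columnMap optional schema-to-file column mapping.
#' @return list with `grid`, `frequency`, `focal`, `rank1Percent`,
#'   `top3Percent`, and the read `report`.
#' @export
reproduceStudy <- function(input, focal = "PtdChos",
                           stepsAbundant = 20, stepsRest = 21, k = 3,
                           mode = "standardized",
                           orientation = "depletion_enrichment",
                           abundantIds = abundantProteins(),
                           columnMap = NULL) {
  rt <- readCoronaTable(input, defaultSchema(), columnMap)
  tpl <- effectPredicate(abundantIds = abundantIds,
                         orientation = orientation)
  axes <- buildGrid(rt$model, stepsAbundant, stepsRest)
  grid <- runSweep(rt$model, tpl, axes, k = k, mode = mode)
  freq <- frequencyTable(grid)
  r1 <- freq[freq$rank == 1 & freq$value == focal, "percent"]
  list(grid = grid,
       frequency = freq,
       focal = focal,
       rank1Percent = if (length(r1)) r1 else 0,
       top3Percent = top3MembershipRate(grid, focal),
       report = rt$report)
}
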