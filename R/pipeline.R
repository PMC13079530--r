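# Pipeline orchestration: simulate -> expose -> match -> fit -> infer,
# with CSV interchange between stages so every stage can be re-run from
# its persisted inputs with identical results.

.logMsg <- function(config, ...) {
  if (config@logLevel != "quiet") message(sprintf(...))
}

.writeCsv <- function(df, path) write.csv(df, path, row.names = FALSE)

.cancerDir <- function(config, cancer) {
  d <- file.path(config@outDir, cancer)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.failStage <- function(config, stage, err) {
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(stage, conditionMessage(err)),
             file.path(config@outDir, "FAILED"))
  stop(sprintf("[stage %s] %s", stage, conditionMessage(err)), call. = FALSE)
}

#' Validate facility and participant tables
#'
#' Reports coordinate-range violations, duplicate (facility, agent, year)
#' keys, negative hazards, unknown lifestyle categories, case rows without
#' a cancer type, and visit years whose lag windows fall partly or wholly
#' before the facility reporting span. Fatal issues raise an error;
#' warnings are returned.
#'
#' @param facilities,participants input tables.
#' @param fail raise an error on fatal issues (default TRUE).
#' @return data.frame of issues (severity, check, message, n), invisibly
#'   when empty.
#' @export
validateInputs <- function(facilities, participants, fail = TRUE) {
  issues <- list()
  add <- function(severity, check, message, n) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, check = check, message = message, n = n,
      stringsAsFactors = FALSE)
  }
  badCoord <- function(df) sum(!is.finite(df$lon) | !is.finite(df$lat) |
                                 abs(df$lon) > 180 | abs(df$lat) > 90)
  n <- badCoord(facilities)
  if (n) add("fatal", "facility_coordinates",
             "longitude/latitude outside valid range", n)
  n <- badCoord(participants)
  if (n) add("fatal", "participant_coordinates",
             "longitude/latitude outside valid range", n)
  n <- sum(duplicated(facilities[, c("facility_id", "agent", "year")]))
  if (n) add("fatal", "facility_key", "duplicate (facility_id, agent, year)", n)
  n <- sum(facilities$modeled_hazard < 0, na.rm = TRUE)
  if (n) add("fatal", "hazard_sign", "negative modeled hazard", n)
  n <- sum(duplicated(participants$participant_id))
  if (n) add("fatal", "participant_key", "duplicate participant_id", n)
  for (v in c("alcohol", "tobacco")) {
    n <- sum(!participants[[v]] %in% .LIFESTYLE_LEVELS)
    if (n) add("fatal", paste0(v, "_levels"),
               paste("levels outside current/past/never/unknown in", v), n)
  }
  n <- sum(participants$case == 1L & participants$cancer_type == "none")
  if (n) add("fatal", "case_cancer_type", "case rows with cancer_type 'none'", n)
  if (nrow(facilities)) {
    fy <- range(facilities$year)
    n <- sum(participants$visit_year < fy[1] + 1L)
    if (n) add("warning", "lag_window_empty",
               "visit year at or before first facility reporting year (empty lag windows)", n)
    n <- sum(participants$visit_year >= fy[1] + 1L &
               participants$visit_year < fy[1] + 5L)
    if (n) add("warning", "lag_window_partial",
               "5-year lag window extends before facility reporting span", n)
    n <- sum(participants$visit_year > fy[2] + 5L)
    if (n) add("warning", "visit_after_reporting",
               "visit year more than 5 years after last facility report", n)
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), check = character(0),
               message = character(0), n = integer(0))
  if (fail && any(out$severity == "fatal"))
    stop("input validation failed: ",
         paste(out$message[out$severity == "fatal"], collapse = "; "),
         call. = FALSE)
  if (nrow(out) == 0L) invisible(out) else out
}

# Restrict the cohort for one cancer analysis: cases of that cancer plus
# the cancer-free control pool; breast-cancer runs are female-only; the
# never-smoker sensitivity analysis restricts cases AND controls before
# matching.
.cohortFor <- function(participants, cancer, neverSmokerOnly) {
  keep <- (participants$case == 1L & participants$cancer_type == cancer) |
    participants$case == 0L
  cohort <- participants[keep, , drop = FALSE]
  if (cancer == "breast")
    cohort <- cohort[cohort$sex == "Female", , drop = FALSE]
  if (neverSmokerOnly)
    cohort <- cohort[cohort$tobacco == "never", , drop = FALSE]
  rownames(cohort) <- NULL
  cohort
}

#' Run the full analysis for one cancer type in memory
#'
#' Core of the pipeline without file I/O: restricts the cohort, computes
#' and dichotomizes the exposure grid, applies the prevalence filter,
#' builds the three matched datasets, fits conditional logistic regression
#' for every retained definition under each matching method, and applies
#' the per-agent Bonferroni adjustment, consensus rule, agent summary and
#' volcano exports.
#'
#' @param participants,facilities input tables.
#' @param cancer "breast" or "lung".
#' @param seed analysis seed (drives matching tie-break streams).
#' @param buffers,lags,idwExponent,minExposed exposure-grid parameters.
#' @param ratio,caliper,ageBinWidth matching parameters.
#' @param alpha adjusted-significance threshold.
#' @param neverSmokerOnly never-smoker sensitivity restriction.
#' @return list with \code{cohort}, \code{exposures}
#'   (\linkS4class{ExposureSet}), \code{matched} (list of three
#'   \linkS4class{MatchedData}), \code{balance}, \code{results},
#'   \code{adjusted}, \code{consensus}, \code{agentSummary},
#'   \code{volcano}.
#' @export
analyzeCancer <- function(participants, facilities, cancer, seed = 1L,
                          buffers = .BUFFERS_DEFAULT, lags = .LAGS_DEFAULT,
                          idwExponent = 1, minExposed = 10L, ratio = 4L,
                          caliper = NA_real_, ageBinWidth = 5,
                          alpha = 0.01, neverSmokerOnly = FALSE) {
  cohort <- .cohortFor(participants, cancer, neverSmokerOnly)
  stopIf(sum(cohort$case == 1L) == 0L, "no cases for cancer type ", cancer)
  stopIf(sum(cohort$case == 0L) == 0L, "no controls for cancer type ", cancer)
  defs <- enumerateGrid(sort(unique(facilities$agent)),
                        buffers = buffers, lags = lags)
  es <- exposureMatrix(cohort, facilities, defs, idwExponent = idwExponent)
  es <- dichotomize(es)
  es <- prevalenceFilter(es, minExposed = minExposed)
  matched <- list(); balance <- list(); results <- list()
  for (m in .MATCH_METHODS) {
    spec <- matchSpec(m, ratio = ratio, caliper = caliper,
                      ageBinWidth = ageBinWidth,
                      seed = subSeed(seed, paste0("match|", m, "|", cancer)))
    md <- withCallingHandlers(
      matchCaseControl(cohort, spec),
      warning = function(w) invokeRestart("muffleWarning"))
    matched[[m]] <- md
    balance[[m]] <- balanceReport(md, cohort)
    res <- fitAllExposures(es, md)
    res$cancer <- cancer
    results[[m]] <- res
  }
  allRes <- do.call(rbind, results)
  rownames(allRes) <- NULL
  adjusted <- adjustResults(allRes, alpha = alpha)
  volcano <- lapply(setNames(.MATCH_METHODS, .MATCH_METHODS),
                    function(m) volcanoExport(adjusted, m, alpha = alpha))
  list(cohort = cohort, exposures = es, matched = matched,
       balance = balance, results = allRes, adjusted = adjusted,
       consensus = consensusResults(adjusted, alpha = alpha),
       agentSummary = agentSummary(adjusted),
       volcano = volcano)
}

#' Pipeline stage: simulate
#'
#' Generates the synthetic facility and participant tables and writes
#' \code{facilities.csv}, \code{participants.csv} and \code{truth.json}
#' (config echo and true parameters) under the output directory.
#'
#' @param config a \linkS4class{RunConfig} in synthetic mode.
#' @return invisibly, the list from \code{\link{generateParticipants}}.
#' @export
stageSimulate <- function(config) {
  stopIf(is.null(config@simConfig), "stageSimulate requires synthetic mode")
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  sc <- config@simConfig
  .logMsg(config, "simulate: %d cases, %d controls, %d agents",
          sc@nCases, sc@nControls, length(sc@agents))
  fac <- generateFacilities(sc)
  gp <- generateParticipants(sc, fac)
  .writeCsv(fac, file.path(config@outDir, "facilities.csv"))
  .writeCsv(gp$participants, file.path(config@outDir, "participants.csv"))
  truth <- list(
    seed = sc@seed, region = sc@region, n_cases = sc@nCases,
    n_controls = sc@nControls, years = sc@years, agents = sc@agents,
    baseline_logit = sc@baselineLogit,
    true_log_or = as.list(sc@trueLogOR),
    confounder_log_or = as.list(sc@confounderLogOR))
  jsonlite::write_json(truth, file.path(config@outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(gp)
}

.readInputs <- function(config) {
  fdir <- if (nzchar(config@facilitiesFile)) config@facilitiesFile
          else file.path(config@outDir, "facilities.csv")
  pdir <- if (nzchar(config@participantsFile)) config@participantsFile
          else file.path(config@outDir, "participants.csv")
  stopIf(!file.exists(fdir), "I/O error: cannot read ", fdir)
  stopIf(!file.exists(pdir), "I/O error: cannot read ", pdir)
  list(facilities = read.csv(fdir, stringsAsFactors = FALSE),
       participants = read.csv(pdir, stringsAsFactors = FALSE))
}

#' Pipeline stage: expose
#'
#' Reads the persisted tables, computes the exposure grid for each
#' requested cancer cohort, and writes \code{exposures.csv} (raw, wide),
#' \code{exposures_binary.csv} (analysis codings, exact integers) and
#' \code{definitions.csv} (grid with coding status, exposed counts and
#' retention flags).
#'
#' @param config a \linkS4class{RunConfig}.
#' @return invisibly NULL.
#' @export
stageExpose <- function(config) {
  inp <- .readInputs(config)
  validateInputs(inp$facilities, inp$participants)
  for (cancer in config@cancers) {
    d <- .cancerDir(config, cancer)
    cohort <- .cohortFor(inp$participants, cancer, config@neverSmokerOnly)
    defs <- enumerateGrid(sort(unique(inp$facilities$agent)),
                          buffers = config@buffers, lags = config@lags)
    es <- prevalenceFilter(
      dichotomize(exposureMatrix(cohort, inp$facilities, defs,
                                 idwExponent = config@idwExponent)),
      minExposed = config@minExposed)
    .logMsg(config, "expose[%s]: %d definitions, %d retained", cancer,
            nrow(es), sum(rowData(es)$retained))
    raw <- t(assay(es, "raw"))
    .writeCsv(data.frame(participant_id = rownames(raw), raw,
                         check.names = FALSE),
              file.path(d, "exposures.csv"))
    bin <- t(assay(es, "binary"))
    .writeCsv(data.frame(participant_id = rownames(bin), bin,
                         check.names = FALSE),
              file.path(d, "exposures_binary.csv"))
    .writeCsv(definitions(es), file.path(d, "definitions.csv"))
  }
  invisible(NULL)
}

#' Pipeline stage: match
#'
#' Builds the three matched datasets per cancer cohort and writes
#' \code{matched_<method>.csv} (set_id, role, participant_id) and
#' \code{balance_<method>.csv}.
#'
#' @param config a \linkS4class{RunConfig}.
#' @return invisibly NULL.
#' @export
stageMatch <- function(config) {
  inp <- .readInputs(config)
  for (cancer in config@cancers) {
    d <- .cancerDir(config, cancer)
    cohort <- .cohortFor(inp$participants, cancer, config@neverSmokerOnly)
    for (m in .MATCH_METHODS) {
      spec <- matchSpec(m, ratio = config@ratio, caliper = config@caliper,
                        ageBinWidth = config@ageBinWidth,
                        seed = subSeed(config@seed,
                                       paste0("match|", m, "|", cancer)))
      md <- withCallingHandlers(
        matchCaseControl(cohort, spec),
        warning = function(w) invokeRestart("muffleWarning"))
      .logMsg(config, "match[%s,%s]: %d sets", cancer, m,
              length(unique(md@sets$set_id)))
      .writeCsv(md@sets[, c("set_id", "role", "participant_id")],
                file.path(d, paste0("matched_", m, ".csv")))
      .writeCsv(balanceReport(md, cohort, spec),
                file.path(d, paste0("balance_", m, ".csv")))
    }
  }
  invisible(NULL)
}

#' Pipeline stage: fit
#'
#' Reads the persisted binary codings, definitions and matched sets, fits
#' one conditional logistic regression per retained definition and
#' matching method, and writes \code{clr_results_<method>.csv}.
#'
#' @param config a \linkS4class{RunConfig}.
#' @return invisibly NULL.
#' @export
stageFit <- function(config) {
  inp <- .readInputs(config)
  for (cancer in config@cancers) {
    d <- .cancerDir(config, cancer)
    cohort <- .cohortFor(inp$participants, cancer, config@neverSmokerOnly)
    defs <- read.csv(file.path(d, "definitions.csv"),
                     stringsAsFactors = FALSE, check.names = FALSE)
    binW <- read.csv(file.path(d, "exposures_binary.csv"),
                     stringsAsFactors = FALSE, check.names = FALSE)
    bin <- t(as.matrix(binW[, -1, drop = FALSE]))
    colnames(bin) <- binW$participant_id
    se <- SummarizedExperiment(
      assays = list(raw = bin, binary = bin),
      rowData = DataFrame(defs, row.names = defs$definition_id),
      colData = DataFrame(cohort, row.names = cohort$participant_id))
    es <- new("ExposureSet", se)
    for (m in .MATCH_METHODS) {
      sets <- read.csv(file.path(d, paste0("matched_", m, ".csv")),
                       stringsAsFactors = FALSE)
      md <- new("MatchedData", sets = sets, method = m,
                spec = matchSpec(m, ratio = config@ratio),
                droppedCases = character(0), partialSets = character(0),
                totalDistance = NA_real_)
      res <- fitAllExposures(es, md)
      res$cancer <- cancer
      .logMsg(config, "fit[%s,%s]: %d models", cancer, m, nrow(res))
      .writeCsv(res, file.path(d, paste0("clr_results_", m, ".csv")))
    }
  }
  invisible(NULL)
}

#' Pipeline stage: infer
#'
#' Reads the per-method CLR results, applies the per-agent Bonferroni
#' adjustment and consensus rule, and writes \code{clr_adjusted.csv},
#' \code{consensus.csv}, \code{agent_summary.csv} and
#' \code{volcano_<method>.csv}.
#'
#' @param config a \linkS4class{RunConfig}.
#' @return invisibly NULL.
#' @export
stageInfer <- function(config) {
  for (cancer in config@cancers) {
    d <- .cancerDir(config, cancer)
    res <- do.call(rbind, lapply(.MATCH_METHODS, function(m)
      read.csv(file.path(d, paste0("clr_results_", m, ".csv")),
               stringsAsFactors = FALSE)))
    adjusted <- adjustResults(res, alpha = config@alpha)
    .writeCsv(adjusted, file.path(d, "clr_adjusted.csv"))
    .writeCsv(consensusResults(adjusted, alpha = config@alpha),
              file.path(d, "consensus.csv"))
    .writeCsv(agentSummary(adjusted), file.path(d, "agent_summary.csv"))
    for (m in .MATCH_METHODS)
      .writeCsv(volcanoExport(adjusted, m, alpha = config@alpha),
                file.path(d, paste0("volcano_", m, ".csv")))
    .logMsg(config, "infer[%s]: %d overall-significant definitions", cancer,
            sum(consensusResults(adjusted, alpha = config@alpha)$overall_significant))
  }
  invisible(NULL)
}

#' Run the full pipeline
#'
#' Executes simulate (synthetic mode) or input validation (file mode),
#' then expose, match, fit and infer for each requested cancer type, all
#' through the persisted CSV interchange files, and writes a
#' \code{manifest.json} (config echo, seeds, row counts, package version,
#' per-stage wall times). Identical configurations produce byte-identical
#' CSV outputs. Any stage failure aborts with a stage-tagged error and a
#' \code{FAILED} marker file alongside the partial outputs.
#'
#' @param config a \linkS4class{RunConfig}.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config) {
  validObject(config)
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(config@outDir, "FAILED"))
  stages <- list(
    simulate = function() if (!is.null(config@simConfig))
      stageSimulate(config) else {
        inp <- .readInputs(config)
        validateInputs(inp$facilities, inp$participants)
      },
    expose = function() stageExpose(config),
    match = function() stageMatch(config),
    fit = function() stageFit(config),
    infer = function() stageInfer(config))
  timings <- list()
  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    tryCatch(stages[[nm]](), error = function(e) .failStage(config, nm, e))
    timings[[nm]] <- round(proc.time()[["elapsed"]] - t0, 3)
  }
  inp <- .readInputs(config)
  counts <- list(facilities = nrow(inp$facilities),
                 participants = nrow(inp$participants))
  for (cancer in config@cancers) {
    cohort <- .cohortFor(inp$participants, cancer, config@neverSmokerOnly)
    counts[[paste0(cancer, "_cases")]] <- sum(cohort$case == 1L)
    counts[[paste0(cancer, "_controls")]] <- sum(cohort$case == 0L)
  }
  manifest <- list(
    package = "toxprox",
    version = as.character(packageVersion("toxprox")),
    r_version = as.character(getRversion()),
    seed = config@seed,
    mode = if (is.null(config@simConfig)) "files" else "synthetic",
    cancers = config@cancers,
    never_smoker_only = config@neverSmokerOnly,
    matching_ratio = config@ratio,
    buffers = config@buffers, lags = config@lags,
    idw_exponent = config@idwExponent,
    min_exposed = config@minExposed, alpha = config@alpha,
    counts = counts, stage_seconds = timings)
  jsonlite::write_json(manifest, file.path(config@outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{runConfig}} (snake
#' or camel case); a \code{sim_config} block holds
#' \code{\link{simConfig}} arguments for synthetic mode.
#'
#' @param path YAML file path.
#' @return a validated \linkS4class{RunConfig}.
#' @export
readRunConfig <- function(path) {
  stopIf(!file.exists(path), "I/O error: cannot read ", path)
  y <- yaml::read_yaml(path)
  camel <- function(nm) {
    nm <- gsub("_(\\w)", "\\U\\1", nm, perl = TRUE)
    sub("LogOr$", "LogOR", nm)
  }
  names(y) <- camel(names(y))
  if (!is.null(y$simConfig)) {
    sc <- y$simConfig
    names(sc) <- camel(names(sc))
    if (!is.null(sc$trueLogOR)) sc$trueLogOR <- unlist(sc$trueLogOR)
    if (!is.null(sc$confounderLogOR))
      sc$confounderLogOR <- unlist(sc$confounderLogOR)
    if (!is.null(sc$covariateFreqs))
      sc$covariateFreqs <- lapply(sc$covariateFreqs, unlist)
    y$simConfig <- do.call(simConfig, sc)
  }
  do.call(runConfig, y)
}
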