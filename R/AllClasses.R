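#' @title Core S4 classes
#' @name toxprox-classes
#' @description S4 containers used throughout the package: simulation
#'   configuration, exposure matrices, matching specifications and results,
#'   and conditional-logistic-regression designs and fits.
NULL

.AGENTS_DEFAULT <- c(
  "antimony", "arsenic", "benzene", "beryllium", "cadmium", "chromium",
  "cobalt", "ethylene_oxide", "formaldehyde", "hydrazine", "nickel"
)
.METRICS <- c("presence", "count", "idw_hazard")
.BUFFERS_DEFAULT <- c(2, 5, 10, 20)
.LAGS_DEFAULT <- 1:5
.LIFESTYLE_LEVELS <- c("current", "past", "never", "unknown")
.MATCH_METHODS <- c("nearest_neighbor", "exact", "optimal")
.CONTINUOUS_VARS <- c("age", "visit_year", "adi_std")

#' SimConfig: synthetic-study configuration
#'
#' Holds every knob of the synthetic data generator: the spatial region,
#' sample sizes, visit-year range, agents and facility process, covariate
#' category frequencies, and the case-generating logistic model (true
#' per-exposure log odds ratios, confounder effects and intercept).
#'
#' @slot seed master integer seed; all stage streams are derived from it.
#' @slot region bounding box in decimal degrees,
#'   \code{c(lonMin, lonMax, latMin, latMax)}.
#' @slot nCases,nControls target accrual counts.
#' @slot years inclusive visit-year range \code{c(first, last)}.
#' @slot agents agent names (default: the 11 carcinogenic agents tracked).
#' @slot facilitiesPerAgent facilities placed per agent.
#' @slot hazardLogMean,hazardLogSd lognormal parameters of the annual
#'   toxicity-modeled hazard score.
#' @slot facilityPersistence probability a facility reports in a given year.
#' @slot covariateFreqs named list of category probability vectors for
#'   sex, race, ethnicity, alcohol, tobacco.
#' @slot ageMeanCase,ageMeanControl,ageSd age model (years), drawn
#'   conditional on realized case status.
#' @slot adiRawMean,adiRawSd raw neighborhood-deprivation scale.
#' @slot trueLogOR named numeric: true log odds ratio per planted exposure
#'   definition id (\code{agent|metric|buffer|lag}); a bare agent name is
#'   shorthand for its \code{presence|10|3} definition.
#' @slot baselineLogit intercept of the case-generating model.
#' @slot confounderLogOR named numeric of covariate effects; names are
#'   \code{"var:level"} indicators or \code{"adi_std"} (per point, centered
#'   at 100).
#' @slot cancerTypes cancer types assigned to cases (subset of breast/lung).
#' @slot clusterFacilities,nClusters,clusterSdKm optional Gaussian-blob
#'   clustering of facility locations (industrial corridors).
#' @slot maxAttemptFactor accrual is abandoned with an error after
#'   \code{maxAttemptFactor * (nCases + nControls)} candidate draws.
#' @export
setClass("SimConfig", representation(
  seed = "integer", region = "numeric", nCases = "integer",
  nControls = "integer", years = "integer", agents = "character",
  facilitiesPerAgent = "integer", hazardLogMean = "numeric",
  hazardLogSd = "numeric", facilityPersistence = "numeric",
  covariateFreqs = "list", ageMeanCase = "numeric",
  ageMeanControl = "numeric", ageSd = "numeric", adiRawMean = "numeric",
  adiRawSd = "numeric", trueLogOR = "numeric", baselineLogit = "numeric",
  confounderLogOR = "numeric", cancerTypes = "character",
  clusterFacilities = "logical", nClusters = "integer",
  clusterSdKm = "numeric", maxAttemptFactor = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  r <- object@region
  if (length(r) != 4 || !all(is.finite(r)) || r[1] >= r[2] || r[3] >= r[4])
    msg <- c(msg, "region must be a non-degenerate c(lonMin, lonMax, latMin, latMax)")
  if (length(r) == 4 && all(is.finite(r)) &&
      (r[1] < -180 || r[2] > 180 || r[3] < -90 || r[4] > 90))
    msg <- c(msg, "region outside valid longitude/latitude bounds")
  if (object@nCases < 1L) msg <- c(msg, "nCases must be >= 1")
  if (object@nControls < object@nCases)
    msg <- c(msg, "nControls must be >= nCases")
  if (length(object@years) != 2 || object@years[1] > object@years[2])
    msg <- c(msg, "years must be an inclusive c(first, last) range")
  if (length(object@agents) == 0)
    msg <- c(msg, "at least one agent is required")
  if (anyDuplicated(object@agents))
    msg <- c(msg, "agent names must be unique")
  if (object@hazardLogSd <= 0) msg <- c(msg, "hazardLogSd must be > 0")
  if (object@facilityPersistence < 0 || object@facilityPersistence > 1)
    msg <- c(msg, "facilityPersistence must be in [0, 1]")
  for (v in names(object@covariateFreqs)) {
    p <- object@covariateFreqs[[v]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      msg <- c(msg, sprintf("covariateFreqs$%s must be named, nonnegative and sum to 1", v))
  }
  if (!all(c("sex", "race", "ethnicity", "alcohol", "tobacco") %in%
           names(object@covariateFreqs)))
    msg <- c(msg, "covariateFreqs needs sex, race, ethnicity, alcohol, tobacco")
  if (object@ageSd <= 0) msg <- c(msg, "ageSd must be > 0")
  if (object@adiRawSd <= 0) msg <- c(msg, "adiRawSd must be > 0")
  if (length(object@trueLogOR) && is.null(names(object@trueLogOR)))
    msg <- c(msg, "trueLogOR must be named by definition id or agent")
  if (length(object@confounderLogOR)) {
    nm <- names(object@confounderLogOR)
    ok <- nm == "adi_std" | grepl("^(sex|race|ethnicity|alcohol|tobacco):", nm)
    if (is.null(nm) || !all(ok))
      msg <- c(msg, "confounderLogOR names must be 'adi_std' or 'var:level'")
  }
  if (!all(object@cancerTypes %in% c("breast", "lung")) ||
      length(object@cancerTypes) == 0)
    msg <- c(msg, "cancerTypes must be a nonempty subset of breast/lung")
  if (object@maxAttemptFactor < 1)
    msg <- c(msg, "maxAttemptFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Build a synthetic-study configuration
#'
#' Defaults emulate the source study at reduced scale: a ~260 x 220 km
#' mid-Atlantic region, visit years 2010-2023 with facility reporting back to
#' five years before the first visit, 11 carcinogenic agents, covariate
#' category frequencies close to the control population of a large hospital
#' EHR, and a 1:4 case:control accrual target.
#'
#' @param seed master integer seed.
#' @param region,years,agents,cancerTypes see \linkS4class{SimConfig}.
#' @param nCases,nControls accrual targets.
#' @param facilitiesPerAgent,hazardLogMean,hazardLogSd,facilityPersistence
#'   facility process parameters.
#' @param covariateFreqs named list of category probabilities.
#' @param ageMeanCase,ageMeanControl,ageSd,adiRawMean,adiRawSd covariate
#'   models.
#' @param trueLogOR,baselineLogit,confounderLogOR case-generating model.
#' @param clusterFacilities,nClusters,clusterSdKm facility clustering.
#' @param maxAttemptFactor accrual attempt cap multiplier.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1, nCases = 50, nControls = 200,
#'                  agents = c("chromium", "benzene"))
#' @export
simConfig <- function(seed = 1L,
                      region = c(-79, -76, 36.5, 38.5),
                      nCases = 500L, nControls = 2000L,
                      years = c(2010L, 2023L),
                      agents = .AGENTS_DEFAULT,
                      facilitiesPerAgent = 25L,
                      hazardLogMean = 8, hazardLogSd = 2,
                      facilityPersistence = 0.8,
                      covariateFreqs = list(
                        sex = c(Female = 0.54, Male = 0.46),
                        race = c(White = 0.46, Black = 0.41, Asian = 0.03,
                                 Other = 0.10),
                        ethnicity = c("Not Hispanic" = 0.94,
                                      Hispanic = 0.04, Unknown = 0.02),
                        alcohol = c(current = 0.36, past = 0.06,
                                    never = 0.25, unknown = 0.33),
                        tobacco = c(current = 0.18, past = 0.14,
                                    never = 0.43, unknown = 0.25)
                      ),
                      ageMeanCase = 63, ageMeanControl = 45, ageSd = 15,
                      adiRawMean = 50, adiRawSd = 25,
                      trueLogOR = setNames(numeric(0), character(0)),
                      baselineLogit = -1.5,
                      confounderLogOR = c("tobacco:current" = 0.7,
                                          "tobacco:past" = 0.4,
                                          "alcohol:current" = 0.2,
                                          "adi_std" = 0.01),
                      cancerTypes = c("breast", "lung"),
                      clusterFacilities = FALSE, nClusters = 5L,
                      clusterSdKm = 15,
                      maxAttemptFactor = 50) {
  new("SimConfig", seed = as.integer(seed), region = as.numeric(region),
      nCases = as.integer(nCases), nControls = as.integer(nControls),
      years = as.integer(years), agents = as.character(agents),
      facilitiesPerAgent = as.integer(facilitiesPerAgent),
      hazardLogMean = hazardLogMean, hazardLogSd = hazardLogSd,
      facilityPersistence = facilityPersistence,
      covariateFreqs = covariateFreqs, ageMeanCase = ageMeanCase,
      ageMeanControl = ageMeanControl, ageSd = ageSd,
      adiRawMean = adiRawMean, adiRawSd = adiRawSd,
      trueLogOR = trueLogOR, baselineLogit = baselineLogit,
      confounderLogOR = confounderLogOR,
      cancerTypes = cancerTypes, clusterFacilities = clusterFacilities,
      nClusters = as.integer(nClusters), clusterSdKm = clusterSdKm,
      maxAttemptFactor = maxAttemptFactor)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat("  seed:", object@seed, " cases:", object@nCases,
      " controls:", object@nControls, "\n")
  cat("  years:", paste(object@years, collapse = "-"),
      " agents:", length(object@agents),
      " facilities/agent:", object@facilitiesPerAgent, "\n")
  cat("  planted effects:", length(object@trueLogOR), "\n")
})

#' MatchSpec: matching-method specification
#'
#' @slot method one of \code{nearest_neighbor}, \code{exact}, \code{optimal}.
#' @slot variables ordered matching covariates.
#' @slot ratio controls per case (k).
#' @slot caliper optional maximum admissible distance (NA for none;
#'   nearest-neighbor only).
#' @slot ageBinWidth age coarsening width in years (exact method).
#' @slot seed stream seed for stochastic tie-breaking (exact partitions).
#' @export
setClass("MatchSpec", representation(
  method = "character", variables = "character", ratio = "integer",
  caliper = "numeric", ageBinWidth = "numeric", seed = "integer"
))

setValidity("MatchSpec", function(object) {
  msg <- character(0)
  if (!object@method %in% .MATCH_METHODS)
    msg <- c(msg, paste("method must be one of",
                        paste(.MATCH_METHODS, collapse = ", ")))
  if (length(object@variables) == 0)
    msg <- c(msg, "variables must be nonempty")
  if (object@ratio < 1L) msg <- c(msg, "ratio (k) must be >= 1")
  if (object@ageBinWidth <= 0) msg <- c(msg, "ageBinWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' Build a matching specification
#'
#' Default variable sets follow the study design: nearest-neighbor and exact
#' matching on age, sex, race and visit year; optimal matching additionally
#' on alcohol, tobacco and the standardized deprivation index.
#'
#' @param method matching method.
#' @param variables matching covariates; sensible per-method default.
#' @param ratio controls per case (k), default 4.
#' @param caliper optional maximum distance (NA = none).
#' @param ageBinWidth exact-matching age bin width (years).
#' @param seed stream seed for seeded tie-breaking.
#' @return a \linkS4class{MatchSpec}.
#' @export
matchSpec <- function(method = c("nearest_neighbor", "exact", "optimal"),
                      variables = NULL, ratio = 4L, caliper = NA_real_,
                      ageBinWidth = 5, seed = 1L) {
  method <- match.arg(method)
  if (is.null(variables)) {
    variables <- c("age", "sex", "race", "visit_year")
    if (method == "optimal")
      variables <- c(variables, "alcohol", "tobacco", "adi_std")
  }
  new("MatchSpec", method = method, variables = variables,
      ratio = as.integer(ratio), caliper = as.numeric(caliper),
      ageBinWidth = as.numeric(ageBinWidth), seed = as.integer(seed))
}

setMethod("show", "MatchSpec", function(object) {
  cat("MatchSpec:", object@method, " k =", object@ratio, "\n")
  cat("  variables:", paste(object@variables, collapse = ", "), "\n")
})

#' ExposureSet: participants x exposure-definition matrix
#'
#' A \linkS4class{SummarizedExperiment} whose rows are exposure definitions
#' (agent, metric, buffer, lag) and whose columns are participants. The
#' \code{"raw"} assay holds raw metric values; \code{\link{dichotomize}}
#' adds a \code{"binary"} analysis coding and
#' \code{\link{prevalenceFilter}} adds exposed-case/control counts and
#' retention flags to \code{rowData}.
#'
#' @export
setClass("ExposureSet", contains = "SummarizedExperiment")

setValidity("ExposureSet", function(object) {
  msg <- character(0)
  if (!"raw" %in% assayNames(object))
    msg <- c(msg, "'raw' assay is required")
  need <- c("definition_id", "agent", "metric", "buffer_km", "lag_years")
  if (!all(need %in% colnames(rowData(object))))
    msg <- c(msg, paste("rowData needs columns:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' MatchedData: one matched case-control dataset
#'
#' @slot sets data.frame with columns \code{set_id}, \code{participant_id},
#'   \code{role} ("case"/"control"); exactly one case per set, each control
#'   used at most once (matching without replacement).
#' @slot method matching method that produced the dataset.
#' @slot spec the \linkS4class{MatchSpec} used.
#' @slot droppedCases ids of cases that could not be matched.
#' @slot partialSets set ids with fewer than k controls.
#' @slot totalDistance total matching distance over assigned pairs (NA for
#'   exact matching).
#' @export
setClass("MatchedData", representation(
  sets = "data.frame", method = "character", spec = "MatchSpec",
  droppedCases = "character", partialSets = "character",
  totalDistance = "numeric"
))

setValidity("MatchedData", function(object) {
  msg <- character(0)
  s <- object@sets
  if (nrow(s)) {
    if (!all(c("set_id", "participant_id", "role") %in% colnames(s)))
      msg <- c(msg, "sets needs set_id, participant_id, role")
    else {
      nCase <- tapply(s$role == "case", s$set_id, sum)
      if (any(nCase != 1L)) msg <- c(msg, "every set must have exactly one case")
      ctl <- s$participant_id[s$role == "control"]
      if (anyDuplicated(ctl))
        msg <- c(msg, "controls must not be reused (matching without replacement)")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MatchedData", function(object) {
  ns <- length(unique(object@sets$set_id))
  cat("MatchedData:", object@method, "\n")
  cat(sprintf("  %d sets (%d participants), %d unmatched cases, %d partial sets\n",
              ns, nrow(object@sets), length(object@droppedCases),
              length(object@partialSets)))
})

#' CLRDesign: conditional-logistic design matrix
#'
#' @slot X numeric model matrix (exposure column plus adjustment columns).
#' @slot y 0/1 case indicator, exactly one 1 per set.
#' @slot set integer set index per row.
#' @slot exposure name of the exposure column of \code{X}.
#' @slot dropped names of set-constant adjustment columns removed from the
#'   design (inestimable under the conditional likelihood).
#' @export
setClass("CLRDesign", representation(
  X = "matrix", y = "integer", set = "integer", exposure = "character",
  dropped = "character"
))

#' CLRFit: a conditional logistic regression fit
#'
#' @slot coef,se,vcov estimates, observed-information standard errors and
#'   covariance.
#' @slot loglik maximized conditional log-likelihood.
#' @slot iterations Newton-Raphson iterations used.
#' @slot converged convergence flag.
#' @slot status "ok", "non_evaluable", "separation" or "not_converged";
#'   anything but "ok" propagates a not-evaluable result.
#' @slot nSets,nInformative number of matched sets and of sets with
#'   within-set exposure variation.
#' @slot exposure name of the exposure coefficient.
#' @export
setClass("CLRFit", representation(
  coef = "numeric", se = "numeric", vcov = "matrix", loglik = "numeric",
  iterations = "integer", converged = "logical", status = "character",
  nSets = "integer", nInformative = "integer", exposure = "character"
))

setMethod("show", "CLRFit", function(object) {
  cat("CLRFit (", object@status, "): ", object@nSets, " sets, ",
      object@nInformative, " informative\n", sep = "")
  if (object@status == "ok") {
    b <- object@coef[object@exposure]
    s <- object@se[object@exposure]
    cat(sprintf("  %s: log OR = %.4f (SE %.4f), OR = %.3f\n",
                object@exposure, b, s, exp(b)))
  }
})

#' SimTruth: ground truth of a synthetic cohort
#'
#' @slot exposures raw exposure values (definitions x participants) for the
#'   full grid, computed with the same engine the analysis uses, so
#'   recomputation on the emitted tables reproduces them exactly.
#' @slot definitions the grid data.frame.
#' @slot eta linear predictor used for case assignment.
#' @slot case realized 0/1 labels.
#' @slot config the generating \linkS4class{SimConfig}.
#' @export
setClass("SimTruth", representation(
  exposures = "matrix", definitions = "data.frame", eta = "numeric",
  case = "integer", config = "SimConfig"
))

#' RunConfig: end-to-end pipeline configuration
#'
#' Synthetic mode (a \linkS4class{SimConfig}) and external-table mode
#' (facility/participant CSV paths) are mutually exclusive. The never-smoker
#' flag restricts cases and the control pool to \code{tobacco == "never"}
#' before matching.
#'
#' @slot simConfig a \linkS4class{SimConfig}, or NULL in file mode.
#' @slot facilitiesFile,participantsFile CSV paths (file mode).
#' @slot cancers cancer types to analyze.
#' @slot neverSmokerOnly sensitivity-analysis flag.
#' @slot outDir output directory.
#' @slot seed master analysis seed.
#' @slot ratio,caliper,ageBinWidth matching parameters shared by methods.
#' @slot buffers,lags exposure-grid overrides.
#' @slot idwExponent inverse-distance weight exponent.
#' @slot minExposed prevalence-filter threshold.
#' @slot alpha adjusted-significance threshold.
#' @slot logLevel "quiet" or "info".
#' @export
setClass("RunConfig", representation(
  simConfig = "ANY", facilitiesFile = "character",
  participantsFile = "character", cancers = "character",
  neverSmokerOnly = "logical", outDir = "character", seed = "integer",
  ratio = "integer", caliper = "numeric", ageBinWidth = "numeric",
  buffers = "numeric", lags = "integer", idwExponent = "numeric",
  minExposed = "integer", alpha = "numeric", logLevel = "character"
))

setValidity("RunConfig", function(object) {
  msg <- character(0)
  synth <- !is.null(object@simConfig)
  files <- nzchar(object@facilitiesFile) || nzchar(object@participantsFile)
  if (synth && files)
    msg <- c(msg, "synthetic mode and external-table mode are mutually exclusive")
  if (!synth && !(nzchar(object@facilitiesFile) && nzchar(object@participantsFile)))
    msg <- c(msg, "either simConfig or both input files are required")
  if (synth && !is(object@simConfig, "SimConfig"))
    msg <- c(msg, "simConfig must be a SimConfig")
  if (!all(object@cancers %in% c("breast", "lung")) || !length(object@cancers))
    msg <- c(msg, "cancers must be a nonempty subset of breast/lung")
  if (!all(object@lags %in% 1:5))
    msg <- c(msg, "lags must lie in 1..5")
  if (any(object@buffers <= 0)) msg <- c(msg, "buffers must be positive")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Build a pipeline configuration
#'
#' @param simConfig a \linkS4class{SimConfig} for synthetic mode (NULL in
#'   file mode).
#' @param facilitiesFile,participantsFile input CSVs for file mode.
#' @param cancers cancer types to analyze.
#' @param neverSmokerOnly restrict cases and control pool to never-smokers.
#' @param outDir output directory.
#' @param seed master analysis seed.
#' @param ratio,caliper,ageBinWidth matching parameters.
#' @param buffers,lags exposure-grid overrides.
#' @param idwExponent inverse-distance weight exponent (default 1).
#' @param minExposed prevalence-filter threshold (default 10).
#' @param alpha adjusted-significance threshold (default 0.01).
#' @param logLevel "quiet" or "info".
#' @return a validated \linkS4class{RunConfig}.
#' @export
runConfig <- function(simConfig = NULL, facilitiesFile = "",
                      participantsFile = "", cancers = c("breast", "lung"),
                      neverSmokerOnly = FALSE, outDir = "toxprox_out",
                      seed = 1L, ratio = 4L, caliper = NA_real_,
                      ageBinWidth = 5, buffers = .BUFFERS_DEFAULT,
                      lags = .LAGS_DEFAULT, idwExponent = 1,
                      minExposed = 10L, alpha = 0.01, logLevel = "info") {
  new("RunConfig", simConfig = simConfig,
      facilitiesFile = facilitiesFile, participantsFile = participantsFile,
      cancers = cancers, neverSmokerOnly = neverSmokerOnly, outDir = outDir,
      seed = as.integer(seed), ratio = as.integer(ratio),
      caliper = as.numeric(caliper), ageBinWidth = as.numeric(ageBinWidth),
      buffers = as.numeric(buffers), lags = as.integer(lags),
      idwExponent = idwExponent, minExposed = as.integer(minExposed),
      alpha = alpha, logLevel = logLevel)
}
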