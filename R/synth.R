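# Synthetic facility and participant generation with known ground truth.

#' Generate a synthetic facility-emissions table
#'
#' Places \code{facilitiesPerAgent} facilities per agent inside the region
#' (uniform by default, Gaussian clusters when
#' \code{clusterFacilities = TRUE}) and, for each calendar year from five
#' years before the first visit year through the last visit year, emits a
#' report with probability \code{facilityPersistence}; the annual
#' toxicity-modeled hazard is lognormal. Deterministic given the seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return data.frame with columns \code{facility_id}, \code{lon},
#'   \code{lat}, \code{agent}, \code{year}, \code{modeled_hazard};
#'   \code{(facility_id, agent, year)} is unique.
#' @examples
#' fac <- generateFacilities(simConfig(seed = 1, nCases = 10, nControls = 40,
#'                                     agents = "benzene",
#'                                     facilitiesPerAgent = 3L))
#' @export
generateFacilities <- function(config) {
  stopIf(!is(config, "SimConfig"), "config must be a SimConfig")
  validObject(config)
  r <- config@region
  reportYears <- (min(config@years) - 5L):max(config@years)
  nf <- config@facilitiesPerAgent
  if (nf == 0L)
    return(data.frame(facility_id = character(0), lon = numeric(0),
                      lat = numeric(0), agent = character(0),
                      year = integer(0), modeled_hazard = numeric(0)))
  withSeed(subSeed(config@seed, "facilities"), {
    out <- vector("list", length(config@agents))
    for (ai in seq_along(config@agents)) {
      ag <- config@agents[ai]
      if (config@clusterFacilities) {
        cl <- cbind(runif(config@nClusters, r[1], r[2]),
                    runif(config@nClusters, r[3], r[4]))
        which_cl <- sample.int(config@nClusters, nf, replace = TRUE)
        latSd <- config@clusterSdKm / 110.574
        lonSd <- config@clusterSdKm /
          (111.320 * cos(cl[which_cl, 2] * pi / 180))
        lon <- pmin(pmax(rnorm(nf, cl[which_cl, 1], lonSd), r[1]), r[2])
        lat <- pmin(pmax(rnorm(nf, cl[which_cl, 2], latSd), r[3]), r[4])
      } else {
        lon <- runif(nf, r[1], r[2])
        lat <- runif(nf, r[3], r[4])
      }
      ids <- sprintf("F_%s_%03d", ag, seq_len(nf))
      grid <- expand.grid(fi = seq_len(nf), year = reportYears,
                          KEEP.OUT.ATTRS = FALSE)
      grid <- grid[order(grid$fi, grid$year), , drop = FALSE]
      keep <- runif(nrow(grid)) < config@facilityPersistence
      grid <- grid[keep, , drop = FALSE]
      hz <- rlnorm(nrow(grid), config@hazardLogMean, config@hazardLogSd)
      out[[ai]] <- data.frame(
        facility_id = ids[grid$fi], lon = lon[grid$fi], lat = lat[grid$fi],
        agent = ag, year = as.integer(grid$year), modeled_hazard = hz,
        stringsAsFactors = FALSE)
    }
    fac <- do.call(rbind, out)
    rownames(fac) <- NULL
    fac
  })
}

#' Standardize a raw deprivation index to mean 100, SD 20
#'
#' Applies \code{100 + 20 * (x - mean(x)) / sd(x)} with the sample (n - 1)
#' standard deviation, the conventional scaling of the Area Deprivation
#' Index.
#'
#' @param raw numeric vector of at least two raw index values.
#' @return standardized values with mean exactly 100 and sample SD exactly
#'   20 (up to floating tolerance).
#' @examples
#' standardizeADI(c(80, 100, 120))  # already on the target scale
#' @export
standardizeADI <- function(raw) {
  stopIf(!is.numeric(raw) || length(raw) < 2,
         "raw must be a numeric vector with >= 2 values")
  stopIf(any(!is.finite(raw)), "raw values must be finite")
  s <- sd(raw)
  stopIf(s == 0, "degenerate scale: raw values are constant")
  100 + 20 * (raw - mean(raw)) / s
}

# Expand the names of trueLogOR into a definitions data.frame. A bare agent
# name is shorthand for that agent's presence|10|3 definition.
.plantedDefinitions <- function(config) {
  nm <- names(config@trueLogOR)
  if (!length(nm))
    return(list(defs = parseDefinitionId(character(0)), logOR = numeric(0)))
  full <- ifelse(grepl("|", nm, fixed = TRUE), nm,
                 paste(nm, "presence", "10", "3", sep = "|"))
  defs <- parseDefinitionId(full)
  bad <- !defs$agent %in% config@agents
  stopIf(any(bad), "trueLogOR references unknown agents: ",
         paste(unique(defs$agent[bad]), collapse = ", "))
  list(defs = defs, logOR = unname(config@trueLogOR))
}

# Confounder contribution to the linear predictor for a candidate table.
.confounderEta <- function(config, cand) {
  eta <- numeric(nrow(cand))
  cf <- config@confounderLogOR
  for (nm in names(cf)) {
    if (nm == "adi_std") {
      eta <- eta + cf[[nm]] * (cand$adi_std - 100)
    } else {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      eta <- eta + cf[[nm]] * (cand[[parts[1]]] == parts[2])
    }
  }
  eta
}

#' Generate a synthetic participant table with ground truth
#'
#' Samples candidate residences uniformly in the region, draws visit year
#' and categorical covariates, computes the planted exposures with the same
#' engine the analysis uses, and assigns case status from
#' \eqn{logit^{-1}(\beta_0 + \sum \beta_e z_e + \sum \gamma_c c)}, where
#' \eqn{z_e} is the any-in-buffer-facility indicator of each planted
#' definition. Accrual continues until exactly \code{nCases} cases and
#' \code{nControls} controls are collected; age is then drawn conditional on
#' the realized status, and female cases are assigned a cancer type among
#' \code{cancerTypes} (male cases can only be lung). Deterministic given the
#' seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param facilities facility table from
#'   \code{\link{generateFacilities}(config)}.
#' @param computeTruth when TRUE (default) the returned truth carries the
#'   full-grid raw exposures of the accrued cohort; FALSE skips that
#'   computation (the participant table is identical either way).
#' @return list with \code{participants} (data.frame) and \code{truth}
#'   (\linkS4class{SimTruth}; full-grid raw exposures of the accrued cohort,
#'   the case-model linear predictor, and realized labels).
#' @export
generateParticipants <- function(config, facilities, computeTruth = TRUE) {
  stopIf(!is(config, "SimConfig"), "config must be a SimConfig")
  validObject(config)
  r <- config@region
  planted <- .plantedDefinitions(config)
  onlyBreast <- identical(config@cancerTypes, "breast")
  freqs <- config@covariateFreqs
  target <- c(case = config@nCases, control = config@nControls)
  cap <- ceiling(config@maxAttemptFactor * sum(target))
  batch <- max(500L, sum(target))

  acc <- list(); accEta <- list()
  nAcc <- c(case = 0L, control = 0L); tried <- 0L
  withSeed(subSeed(config@seed, "participants"), {
    while (any(nAcc < target)) {
      stopIf(tried >= cap,
             "simulation error: accrual targets unreachable within attempt cap")
      m <- min(batch, cap - tried)
      tried <- tried + m
      cand <- data.frame(
        lon = runif(m, r[1], r[2]), lat = runif(m, r[3], r[4]),
        visit_year = sample(seq(config@years[1], config@years[2]), m,
                            replace = TRUE),
        stringsAsFactors = FALSE)
      for (v in c("sex", "race", "ethnicity", "alcohol", "tobacco"))
        cand[[v]] <- sample(names(freqs[[v]]), m, replace = TRUE,
                            prob = freqs[[v]])
      adiRaw <- rnorm(m, config@adiRawMean, config@adiRawSd)
      cand$adi_std <- 100 + 20 * (adiRaw - config@adiRawMean) / config@adiRawSd
      eta <- config@baselineLogit + .confounderEta(config, cand)
      if (nrow(planted$defs)) {
        raw <- .rawExposures(cand, facilities, planted$defs)
        eta <- eta + as.numeric(crossprod(raw > 0, planted$logOR))
      }
      isCase <- runif(m) < plogis(eta)
      if (onlyBreast) isCase <- isCase & cand$sex == "Female"
      cand$case <- as.integer(isCase)
      cand$.eta <- eta
      # sequential fill in candidate order: quota overflow is discarded
      keep <- (isCase & cumsum(isCase) <= target[["case"]] - nAcc[["case"]]) |
        (!isCase & cumsum(!isCase) <= target[["control"]] - nAcc[["control"]])
      nAcc[["case"]] <- nAcc[["case"]] + sum(keep & isCase)
      nAcc[["control"]] <- nAcc[["control"]] + sum(keep & !isCase)
      if (any(keep)) acc[[length(acc) + 1L]] <- cand[keep, , drop = FALSE]
    }
    parts <- do.call(rbind, acc)
    rownames(parts) <- NULL
    parts$participant_id <- sprintf("P%06d", seq_len(nrow(parts)))
    parts$age <- rnorm(nrow(parts),
                       ifelse(parts$case == 1L, config@ageMeanCase,
                              config@ageMeanControl),
                       config@ageSd)
    parts$cancer_type <- "none"
    ci <- which(parts$case == 1L)
    for (i in ci) {
      opts <- if (parts$sex[i] == "Female") config@cancerTypes else "lung"
      parts$cancer_type[i] <- if (length(opts) == 1L) opts else
        sample(opts, 1L)
    }
    eta <- parts$.eta
    parts$.eta <- NULL
    parts <- parts[, c("participant_id", "lon", "lat", "visit_year",
                       "cancer_type", "case", "age", "sex", "race",
                       "ethnicity", "alcohol", "tobacco", "adi_std")]
    grid <- if (computeTruth) enumerateGrid(config@agents) else
      parseDefinitionId(character(0))
    truth <- new("SimTruth",
                 exposures = .rawExposures(parts, facilities, grid),
                 definitions = grid, eta = eta,
                 case = parts$case, config = config)
    list(participants = parts, truth = truth)
  })
}

#' Simulate matched sets directly from the conditional model
#'
#' Generates \code{nSets} sets of one case and \code{k} controls in which
#' member exposures are iid Bernoulli(\code{pExposed}) and the case position
#' within each set is drawn with probability proportional to
#' \eqn{\exp(\beta x)} -- exactly the sampling model whose likelihood
#' conditional logistic regression maximizes. Used for calibration studies
#' of the fitter (bias, CI coverage) with a known true log odds ratio.
#'
#' @param nSets number of matched sets.
#' @param k controls per case.
#' @param logOR true log odds ratio \eqn{\beta}.
#' @param pExposed exposure prevalence among set members.
#' @param seed integer seed.
#' @return data.frame with columns \code{set_id}, \code{participant_id},
#'   \code{case}, \code{exposure}.
#' @examples
#' d <- simulateMatchedSets(100, 4, log(2), seed = 7)
#' @export
simulateMatchedSets <- function(nSets, k = 4L, logOR = 0, pExposed = 0.3,
                                seed = 1L) {
  stopIf(!isCount(nSets, 1L) || !isCount(k, 1L), "nSets and k must be counts")
  withSeed(seed, {
    size <- k + 1L
    x <- matrix(rbinom(nSets * size, 1L, pExposed), nrow = nSets)
    w <- exp(logOR * x)
    pos <- apply(w, 1L, function(wi) sample.int(size, 1L, prob = wi))
    data.frame(
      set_id = rep(seq_len(nSets), each = size),
      participant_id = sprintf("S%05d_%02d",
                               rep(seq_len(nSets), each = size),
                               rep(seq_len(size), nSets)),
      case = as.integer(rep(seq_len(size), nSets) == rep(pos, each = size)),
      exposure = as.integer(t(x)),
      stringsAsFactors = FALSE)
  })
}
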