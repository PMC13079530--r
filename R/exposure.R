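# Exposure assessment: great-circle buffers, cumulative reporting-year lags,
# the (metric x buffer x lag) definition grid, binary analysis codings and
# the exposed-case/control prevalence filter.

.EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorized with
#' recycling.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in WGS84 decimal degrees.
#' @return distance(s) in km; symmetric and nonnegative.
#' @examples
#' haversineKm(0, 0, 0, 0)        # 0
#' haversineKm(0, 0, 180, 0)      # half circumference, ~20015.1 km
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  stopIf(any(!is.finite(c(lon1, lat1, lon2, lat2))),
         "coordinates must be finite")
  stopIf(any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180),
         "coordinates outside valid longitude/latitude range")
  .haversineRaw(lon1, lat1, lon2, lat2)
}

# Unvalidated vectorized kernel shared by the engine.
.haversineRaw <- function(lon1, lat1, lon2, lat2) {
  d <- pi / 180
  dLat <- (lat2 - lat1) * d
  dLon <- (lon2 - lon1) * d
  a <- sin(dLat / 2)^2 + cos(lat1 * d) * cos(lat2 * d) * sin(dLon / 2)^2
  2 * .EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Cumulative lag window of reporting years
#'
#' The window covers the \code{lagYears} whole calendar years strictly
#' before the visit year (annual reporting; the visit year itself is
#' excluded).
#'
#' @param visitYear calendar visit year.
#' @param lagYears integer lag in 1..5.
#' @return inclusive integer year range
#'   \code{(visitYear - lagYears):(visitYear - 1)}.
#' @examples
#' lagWindow(2015, 1)  # 2014
#' lagWindow(2015, 5)  # 2010..2014
#' @export
lagWindow <- function(visitYear, lagYears) {
  stopIf(length(lagYears) != 1 || !lagYears %in% 1:5,
         "configuration error: lagYears must be an integer in 1..5")
  seq.int(visitYear - lagYears, visitYear - 1)
}

definitionId <- function(agent, metric, buffer_km, lag_years) {
  paste(agent, metric, buffer_km, lag_years, sep = "|")
}

#' Parse exposure-definition ids
#'
#' @param id character vector of ids of the form
#'   \code{agent|metric|buffer_km|lag_years}.
#' @return data.frame with columns \code{definition_id}, \code{agent},
#'   \code{metric}, \code{buffer_km}, \code{lag_years}.
#' @export
parseDefinitionId <- function(id) {
  if (length(id) == 0L)
    return(data.frame(definition_id = character(0), agent = character(0),
                      metric = character(0), buffer_km = numeric(0),
                      lag_years = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(id, "|", fixed = TRUE)
  stopIf(any(lengths(parts) != 4L),
         "definition ids must have the form agent|metric|buffer_km|lag_years")
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  data.frame(definition_id = id, agent = m[, 1], metric = m[, 2],
             buffer_km = as.numeric(m[, 3]), lag_years = as.integer(m[, 4]),
             stringsAsFactors = FALSE)
}

#' Enumerate the exposure-definition grid
#'
#' Full cross-product of metrics (presence, count, inverse-distance-weighted
#' hazard), buffer radii and cumulative lags per agent: 3 x 4 x 5 = 60
#' definitions per agent at the defaults. Deterministic order: agents
#' sorted, metrics in canonical order (presence, count, idw_hazard), then
#' buffer and lag ascending.
#'
#' @param agents nonempty vector of unique agent names.
#' @param metrics exposure metrics to include.
#' @param buffers buffer radii in km.
#' @param lags cumulative lags in years (subset of 1..5).
#' @return definitions data.frame (see \code{\link{parseDefinitionId}}).
#' @examples
#' nrow(enumerateGrid("benzene"))  # 60
#' @export
enumerateGrid <- function(agents, metrics = .METRICS,
                          buffers = .BUFFERS_DEFAULT, lags = .LAGS_DEFAULT) {
  if (length(agents) == 0L)
    stop("input error: at least one agent is required", call. = FALSE)
  stopIf(anyDuplicated(agents) > 0, "input error: duplicate agent names")
  stopIf(!all(metrics %in% .METRICS), "unknown metric")
  stopIf(any(buffers <= 0), "buffers must be positive")
  stopIf(!all(lags %in% 1:5), "configuration error: lags must lie in 1..5")
  agents <- sort(as.character(agents))
  metrics <- .METRICS[.METRICS %in% metrics]
  buffers <- sort(as.numeric(buffers))
  lags <- sort(as.integer(lags))
  g <- expand.grid(lag_years = lags, buffer_km = buffers, metric = metrics,
                   agent = agents, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, c("agent", "metric", "buffer_km", "lag_years")]
  g$definition_id <- definitionId(g$agent, g$metric, g$buffer_km, g$lag_years)
  rownames(g) <- NULL
  g[, c("definition_id", "agent", "metric", "buffer_km", "lag_years")]
}

#' Raw exposure of one participant under one definition
#'
#' Reference implementation of the exposure contract: select facility-year
#' records of the definition's agent whose reporting year falls in
#' \code{\link{lagWindow}} and whose facility lies within the buffer, then
#' return \code{presence} (any record), \code{count} (distinct facilities)
#' or \code{idw_hazard} (sum of modeled hazard divided by distance, floored
#' at \code{distanceFloorKm}, raised to \code{idwExponent}). An empty
#' selection yields 0 for every metric. The vectorized engine behind
#' \code{\link{exposureMatrix}} is tested to agree with this exactly.
#'
#' @param participant one-row data.frame (or list) with \code{lon},
#'   \code{lat}, \code{visit_year}.
#' @param defn one-row definitions data.frame (or list) with \code{agent},
#'   \code{metric}, \code{buffer_km}, \code{lag_years}.
#' @param facilities facility table.
#' @param idwExponent inverse-distance exponent (default 1).
#' @param distanceFloorKm lower distance bound for IDW weights (default
#'   0.1 km, bounding weights for co-located points).
#' @return the raw exposure value.
#' @export
computeExposure <- function(participant, defn, facilities,
                            idwExponent = 1, distanceFloorKm = 0.1) {
  years <- lagWindow(participant$visit_year, defn$lag_years)
  f <- facilities[facilities$agent == defn$agent &
                    facilities$year %in% years, , drop = FALSE]
  if (nrow(f) == 0L) return(0)
  dist <- haversineKm(participant$lon, participant$lat, f$lon, f$lat)
  inBuf <- dist <= defn$buffer_km
  f <- f[inBuf, , drop = FALSE]
  dist <- dist[inBuf]
  switch(defn$metric,
         presence = as.numeric(nrow(f) > 0),
         count = as.numeric(length(unique(f$facility_id))),
         idw_hazard = sum(f$modeled_hazard /
                            pmax(dist, distanceFloorKm)^idwExponent),
         stop("unknown metric: ", defn$metric))
}

# Engine: raw exposure matrix (definitions x participants), one compiled
# pass per agent. Facility coordinates are taken from each facility's
# first record (sites are fixed; validateInputs flags inconsistencies).
# Inverse-distance sums accumulate in record order with long-double
# carries, so output is bit-identical to computeExposure() row by row.
.rawExposures <- function(participants, facilities, definitions,
                          idwExponent = 1, distanceFloorKm = 0.1,
                          chunkSize = NULL) {
  nP <- nrow(participants)
  out <- matrix(0, nrow = nrow(definitions), ncol = nP,
                dimnames = list(definitions$definition_id,
                                participants$participant_id))
  if (nP == 0L || nrow(definitions) == 0L) return(out)
  metricCode <- c(presence = 0L, count = 1L, idw_hazard = 2L)
  for (ag in unique(definitions$agent)) {
    recs <- facilities[facilities$agent == ag, , drop = FALSE]
    dIdx <- which(definitions$agent == ag)
    if (nrow(recs) == 0L) next
    facIds <- unique(recs$facility_id)
    facRow <- match(facIds, recs$facility_id)
    fIdx <- match(recs$facility_id, facIds)
    buffers <- sort(unique(definitions$buffer_km[dIdx]))
    lags <- sort(unique(as.integer(definitions$lag_years[dIdx])))
    out[dIdx, ] <- .exposureKernel(
      as.numeric(participants$lon), as.numeric(participants$lat),
      as.integer(participants$visit_year),
      as.numeric(recs$lon[facRow]), as.numeric(recs$lat[facRow]),
      fIdx, as.integer(recs$year), as.numeric(recs$modeled_hazard),
      buffers, lags,
      metricCode[definitions$metric[dIdx]],
      match(definitions$buffer_km[dIdx], buffers),
      match(as.integer(definitions$lag_years[dIdx]), lags),
      distanceFloorKm, idwExponent)
  }
  out
}

#' Compute the exposure matrix for a cohort
#'
#' Evaluates every definition for every participant with the vectorized
#' engine and returns an \linkS4class{ExposureSet} (rows = definitions,
#' columns = participants) whose \code{"raw"} assay holds the raw metric
#' values; participant covariates go to \code{colData} and the definition
#' grid to \code{rowData}.
#'
#' @param participants participant table (needs \code{participant_id},
#'   \code{lon}, \code{lat}, \code{visit_year}; other columns are carried
#'   into \code{colData}).
#' @param facilities facility table.
#' @param definitions definitions data.frame, default the full grid over
#'   the agents present in \code{facilities}.
#' @param idwExponent,distanceFloorKm,chunkSize see
#'   \code{\link{computeExposure}}; \code{chunkSize} bounds memory.
#' @return an \linkS4class{ExposureSet}.
#' @export
exposureMatrix <- function(participants, facilities,
                           definitions = enumerateGrid(unique(facilities$agent)),
                           idwExponent = 1, distanceFloorKm = 0.1,
                           chunkSize = 1000L) {
  need <- c("participant_id", "lon", "lat", "visit_year")
  stopIf(!all(need %in% colnames(participants)),
         "participants needs columns: ", paste(need, collapse = ", "))
  raw <- .rawExposures(participants, facilities, definitions,
                       idwExponent, distanceFloorKm, chunkSize)
  se <- SummarizedExperiment(
    assays = list(raw = raw),
    rowData = DataFrame(definitions, row.names = definitions$definition_id),
    colData = DataFrame(participants,
                        row.names = participants$participant_id))
  es <- new("ExposureSet", se)
  metadata(es)$idwExponent <- idwExponent
  metadata(es)$distanceFloorKm <- distanceFloorKm
  es
}

#' Dichotomize raw exposures into binary analysis codings
#'
#' Adds a \code{"binary"} assay: presence columns are kept as is; a count
#' column becomes \code{count >= 2} when any participant has two or more
#' in-buffer facilities and is otherwise flagged redundant with presence;
#' an IDW column is cut at the median of its positive values over the whole
#' dataset (strictly greater is exposed; zeros and at-or-below-median
#' positives are the reference). All-zero columns are flagged
#' non-informative. Redundant and non-informative columns are excluded
#' before the prevalence filter.
#'
#' @param es an \linkS4class{ExposureSet} with a \code{"raw"} assay.
#' @return the \linkS4class{ExposureSet} with a \code{"binary"} assay and
#'   rowData columns \code{status} ("ok"/"redundant"/"non_informative") and
#'   \code{idw_cut}.
#' @export
dichotomize <- function(es) {
  stopIf(!is(es, "ExposureSet"), "es must be an ExposureSet")
  raw <- assay(es, "raw")
  defs <- rowData(es)
  bin <- matrix(0L, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  status <- rep("ok", nrow(raw))
  cut <- rep(NA_real_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    x <- raw[i, ]
    if (all(x == 0)) { status[i] <- "non_informative"; next }
    bin[i, ] <- switch(defs$metric[i],
      presence = as.integer(x > 0),
      count = {
        if (max(x) >= 2) as.integer(x >= 2)
        else { status[i] <- "redundant"; as.integer(x >= 1) }
      },
      idw_hazard = {
        cut[i] <- median(x[x > 0])
        as.integer(x > cut[i])
      })
  }
  assay(es, "binary") <- bin
  rowData(es)$status <- status
  rowData(es)$idw_cut <- cut
  es
}

#' Apply the minimum exposed-case/control prevalence filter
#'
#' A definition is retained when at least \code{minExposed} cases and at
#' least \code{minExposed} controls carry binary coding 1 (and its coding
#' status is "ok"). Invariant to participant ordering.
#'
#' @param es a dichotomized \linkS4class{ExposureSet} whose \code{colData}
#'   has a 0/1 \code{case} column.
#' @param minExposed threshold (default 10).
#' @return the \linkS4class{ExposureSet} with rowData columns
#'   \code{n_exposed_cases}, \code{n_exposed_controls} and \code{retained}.
#' @export
prevalenceFilter <- function(es, minExposed = 10L) {
  stopIf(!is(es, "ExposureSet"), "es must be an ExposureSet")
  stopIf(!"binary" %in% assayNames(es), "run dichotomize() first")
  stopIf(is.null(colData(es)$case), "colData(es)$case labels are required")
  bin <- assay(es, "binary")
  isCase <- colData(es)$case == 1L
  nec <- as.integer(bin %*% as.numeric(isCase))
  nectl <- as.integer(bin %*% as.numeric(!isCase))
  rowData(es)$n_exposed_cases <- nec
  rowData(es)$n_exposed_controls <- nectl
  rowData(es)$retained <- rowData(es)$status == "ok" &
    nec >= minExposed & nectl >= minExposed
  es
}

#' Definition table of an ExposureSet
#'
#' @param es an \linkS4class{ExposureSet}.
#' @return \code{rowData} as a plain data.frame (definition grid plus any
#'   coding-status, count and retention columns added downstream).
#' @export
definitions <- function(es) {
  as.data.frame(rowData(es), optional = TRUE)
}

#' Retained definitions after the prevalence filter
#'
#' @param es an \linkS4class{ExposureSet} that has been through
#'   \code{\link{prevalenceFilter}}.
#' @return the retained subset of \code{\link{definitions}}.
#' @export
retainedDefinitions <- function(es) {
  d <- definitions(es)
  stopIf(is.null(d$retained), "run prevalenceFilter() first")
  d[d$retained, , drop = FALSE]
}

#' Binary analysis codings
#'
#' @param es a dichotomized \linkS4class{ExposureSet}.
#' @return integer matrix of 0/1 codings (definitions x participants).
#' @export
binaryCoding <- function(es) {
  stopIf(!"binary" %in% assayNames(es), "run dichotomize() first")
  assay(es, "binary")
}
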