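# Independent oracles and small fixture builders used across the suite.

# Random toy facility table: consistent per-facility coordinates, annual
# records over reporting years with dropout, lognormal hazards.
toyFacilities <- function(agents, nFac, years = 2005:2018,
                          lonRange = c(-78, -77), latRange = c(37, 38),
                          keepProb = 0.7) {
  do.call(rbind, lapply(agents, function(ag) {
    ids <- sprintf("F_%s_%02d", ag, seq_len(nFac))
    lon <- runif(nFac, lonRange[1], lonRange[2])
    lat <- runif(nFac, latRange[1], latRange[2])
    g <- expand.grid(i = seq_len(nFac), year = years)
    g <- g[runif(nrow(g)) < keepProb, , drop = FALSE]
    data.frame(facility_id = ids[g$i], lon = lon[g$i], lat = lat[g$i],
               agent = ag, year = as.integer(g$year),
               modeled_hazard = rlnorm(nrow(g), 5, 2),
               stringsAsFactors = FALSE)
  }))
}

toyParticipants <- function(n, visitYears = 2010:2018,
                            lonRange = c(-78, -77), latRange = c(37, 38)) {
  data.frame(participant_id = sprintf("P%04d", seq_len(n)),
             lon = runif(n, lonRange[1], lonRange[2]),
             lat = runif(n, latRange[1], latRange[2]),
             visit_year = sample(visitYears, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Brute-force exposure oracle: plain double loop over facility records
# with explicit window and buffer checks. Selection logic is coded
# independently of the package engine; distances use the exported
# haversine (itself cross-checked against geosphere).
bruteExposure <- function(part, defn, facilities,
                          floorKm = 0.1, expo = 1) {
  terms <- numeric(0)
  ids <- character(0)
  for (r in seq_len(nrow(facilities))) {
    if (facilities$agent[r] != defn$agent) next
    delta <- part$visit_year - facilities$year[r]
    if (delta < 1 || delta > defn$lag_years) next
    d <- haversineKm(part$lon, part$lat, facilities$lon[r], facilities$lat[r])
    if (d > defn$buffer_km) next
    ids <- c(ids, facilities$facility_id[r])
    terms <- c(terms, facilities$modeled_hazard[r] / max(d, floorKm)^expo)
  }
  switch(defn$metric,
         presence = as.numeric(length(ids) > 0),
         count = as.numeric(length(unique(ids))),
         idw_hazard = sum(terms))
}

# Exhaustive-permutation minimum assignment cost (k = 1): every injective
# assignment of cases to controls.
bruteAssignmentCost <- function(D) {
  nr <- nrow(D); nc <- ncol(D)
  best <- Inf
  rec <- function(row, used, acc) {
    if (acc >= best) return()
    if (row > nr) { best <<- acc; return() }
    for (j in seq_len(nc)) if (!used[j]) {
      used[j] <- TRUE
      rec(row + 1L, used, acc + D[row, j])
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, nc), 0)
  best
}

# Independent conditional-likelihood maximizer for a single-coefficient
# model: direct per-set evaluation plus one-dimensional optimization.
bruteCLRBeta <- function(data) {
  ll <- function(b) {
    tot <- 0
    for (s in unique(data$set_id)) {
      rows <- data[data$set_id == s, ]
      num <- exp(b * rows$exposure[rows$case == 1])
      tot <- tot + log(num / sum(exp(b * rows$exposure)))
    }
    tot
  }
  optimize(ll, c(-10, 10), maximum = TRUE, tol = 1e-9)$maximum
}

# 1:1 pairs with n10 case-only-exposed, n01 control-only-exposed and
# nConc concordant-exposed pairs (closed-form OR = n10/n01).
discordantPairs <- function(n10, n01, nConc = 5) {
  n <- n10 + n01 + nConc
  data.frame(
    set_id = rep(seq_len(n), each = 2),
    case = rep(c(1L, 0L), n),
    exposure = c(rbind(c(rep(1, n10), rep(0, n01), rep(1, nConc)),
                       c(rep(0, n10), rep(1, n01), rep(1, nConc)))))
}

# Pooled case+control table with known covariate structure for matching
# tests.
toyCohort <- function(nCase, nControl, ageShift = 0, seed = 1) {
  set.seed(seed)
  n <- nCase + nControl
  data.frame(
    participant_id = sprintf("T%04d", seq_len(n)),
    case = rep(c(1L, 0L), c(nCase, nControl)),
    age = round(c(rnorm(nCase, 60 + ageShift, 8), rnorm(nControl, 60, 8)), 1),
    sex = sample(c("Female", "Male"), n, replace = TRUE),
    race = sample(c("White", "Black"), n, replace = TRUE),
    visit_year = sample(2015:2018, n, replace = TRUE),
    alcohol = sample(c("current", "never", "unknown"), n, replace = TRUE),
    tobacco = sample(c("current", "never", "unknown"), n, replace = TRUE),
    adi_std = rnorm(n, 100, 20),
    stringsAsFactors = FALSE)
}
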