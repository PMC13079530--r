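# Exposure assessment: geodesic distances, lag windows, the definition
# grid, raw metrics against an independent double loop, codings and the
# prevalence filter.

test_that("haversine distance matches an independent geodesic oracle", {
  expect_equal(haversineKm(-77.4, 37.5, -77.4, 37.5), 0)
  expect_equal(haversineKm(0, 0, 180, 0), pi * 6371.0088, tolerance = 1e-9)
  skip_if_not_installed("geosphere")
  set.seed(8)
  pts <- cbind(runif(20, -180, 180), runif(20, -85, 85))
  for (i in seq_len(10)) {
    a <- pts[2 * i - 1, ]; b <- pts[2 * i, ]
    ref <- geosphere::distHaversine(a, b, r = 6371008.8) / 1000
    expect_equal(haversineKm(a[1], a[2], b[1], b[2]), ref,
                 tolerance = 1e-9)
  }
  # one named check: ~1 degree of longitude at latitude 37.54
  d <- haversineKm(-77.4360, 37.5407, -76.4360, 37.5407)
  expect_equal(d, geosphere::distHaversine(c(-77.4360, 37.5407),
                                           c(-76.4360, 37.5407),
                                           r = 6371008.8) / 1000,
               tolerance = 1e-9)
  expect_error(haversineKm(NA, 0, 0, 0), "finite")
  expect_error(haversineKm(0, 95, 0, 0), "range")
})

test_that("lag windows cover whole years strictly before the visit", {
  expect_equal(lagWindow(2015, 1), 2014)
  expect_equal(lagWindow(2015, 5), 2010:2014)
  expect_equal(lagWindow(2010, 3), 2007:2009)
  expect_error(lagWindow(2015, 0), "configuration error")
  expect_error(lagWindow(2015, 6), "configuration error")
})

test_that("the definition grid enumerates 3 x 4 x 5 cells per agent", {
  g <- enumerateGrid("benzene")
  expect_equal(nrow(g), 60L)
  expect_equal(nrow(enumerateGrid(sprintf("ag%02d", 1:11))), 660L)
  expect_error(enumerateGrid(character(0)), "input error")
  expect_error(enumerateGrid(c("a", "a")), "duplicate")
  # deterministic order, round-trippable ids
  g2 <- enumerateGrid(c("zinc", "benzene"))
  expect_identical(g2, g2[order(g2$agent), ])
  expect_identical(parseDefinitionId(g2$definition_id)[, -1], g2[, -1])
})

test_that("raw metrics follow the contract on hand-built cases", {
  part <- list(lon = -77.5, lat = 37.5, visit_year = 2015)
  # facility at ~4 km due north reporting in two window years, hazard 8
  dlat <- 4 / 110.574
  fac <- data.frame(facility_id = "F1", lon = -77.5, lat = 37.5 + dlat,
                    agent = "x", year = c(2013L, 2014L),
                    modeled_hazard = 8, stringsAsFactors = FALSE)
  d <- haversineKm(-77.5, 37.5, -77.5, 37.5 + dlat)
  defn <- function(m, b, l) list(agent = "x", metric = m, buffer_km = b,
                                 lag_years = l)
  expect_equal(computeExposure(part, defn("presence", 5, 3), fac), 1)
  expect_equal(computeExposure(part, defn("count", 5, 3), fac), 1)
  expect_equal(computeExposure(part, defn("idw_hazard", 5, 3), fac),
               2 * 8 / d)
  # no facility in buffer
  expect_equal(computeExposure(part, defn("presence", 2, 3), fac), 0)
  expect_equal(computeExposure(part, defn("idw_hazard", 2, 3), fac), 0)
  # second facility beyond 10 km does not add to the count
  fac2 <- rbind(fac, data.frame(facility_id = "F2", lon = -77.5,
                                lat = 37.5 + 12 / 110.574, agent = "x",
                                year = 2014L, modeled_hazard = 3))
  expect_equal(computeExposure(part, defn("count", 10, 3), fac2), 1)
  expect_equal(computeExposure(part, defn("count", 20, 3), fac2), 2)
  # distance floor bounds the weight of a co-located facility
  fac3 <- data.frame(facility_id = "F3", lon = -77.5, lat = 37.5,
                     agent = "x", year = 2014L, modeled_hazard = 5)
  expect_equal(computeExposure(part, defn("idw_hazard", 2, 1), fac3),
               5 / 0.1)
})

test_that("the engine equals the brute-force double loop exactly", {
  set.seed(42)
  for (rep in 1:50) {
    fac <- toyFacilities(c("a", "b"), sample(2:10, 1))
    p <- toyParticipants(sample(10:50, 1))
    defs <- enumerateGrid(c("a", "b"))
    sub <- defs[sample(nrow(defs), 30), ]
    es <- exposureMatrix(p, fac, sub)
    raw <- SummarizedExperiment::assay(es, "raw")
    for (i in sample(nrow(sub), 6)) {
      for (j in sample(nrow(p), 4)) {
        expect_identical(unname(raw[i, j]),
                         bruteExposure(p[j, ], sub[i, ], fac))
      }
    }
  }
})

test_that("metrics are monotone in buffer and lag, and idw is additive", {
  set.seed(99)
  fac <- toyFacilities(c("a", "b"), 8)
  p <- toyParticipants(25)
  defs <- enumerateGrid(c("a", "b"))
  raw <- SummarizedExperiment::assay(exposureMatrix(p, fac, defs), "raw")
  d <- definitions(exposureMatrix(p, fac, defs))
  key <- function(agent, metric, b, l) paste(agent, metric, b, l, sep = "|")
  for (ag in c("a", "b")) for (m in c("presence", "count", "idw_hazard")) {
    for (l in 1:5) {  # nondecreasing across buffers
      vals <- sapply(c(2, 5, 10, 20), function(b) raw[key(ag, m, b, l), ])
      expect_true(all(diff(t(vals)) >= 0))
    }
    for (b in c(2, 5, 10, 20)) {  # nondecreasing across lags
      vals <- sapply(1:5, function(l) raw[key(ag, m, b, l), ])
      expect_true(all(diff(t(vals)) >= 0))
    }
  }
  # lag-5 idw equals the sum over the five disjoint single-year windows
  for (j in sample(nrow(p), 8)) {
    part <- p[j, ]
    defn <- list(agent = "a", metric = "idw_hazard", buffer_km = 10,
                 lag_years = 5)
    total <- raw[key("a", "idw_hazard", 10, 5), j]
    single <- sum(sapply(1:5, function(delta) {
      facYear <- fac[fac$year == part$visit_year - delta, , drop = FALSE]
      computeExposure(part, within(defn, lag_years <- delta), facYear)
    }))
    expect_equal(unname(total), single, tolerance = 1e-9)
  }
})

test_that("dichotomization follows the per-metric coding rules", {
  raw <- rbind(
    "a|presence|5|1" = c(0, 1, 1, 0, 1),
    "a|count|5|1" = c(0, 1, 3, 2, 1),
    "a|idw_hazard|5|1" = c(0, 0, 2, 4, 6),
    "b|count|5|1" = c(0, 1, 1, 0, 1),
    "b|idw_hazard|5|1" = c(0, 0, 0, 0, 0))
  defs <- parseDefinitionId(rownames(raw))
  p <- data.frame(participant_id = sprintf("P%d", 1:5),
                  lon = 0, lat = 0, visit_year = 2015,
                  case = c(1L, 1L, 0L, 0L, 1L))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = raw),
    rowData = S4Vectors::DataFrame(defs, row.names = defs$definition_id),
    colData = S4Vectors::DataFrame(p, row.names = p$participant_id))
  es <- dichotomize(new("ExposureSet", se))
  bin <- binaryCoding(es)
  d <- definitions(es)
  expect_equal(unname(bin["a|presence|5|1", ]), c(0, 1, 1, 0, 1))
  # counts cut at >= 2 when any participant has two or more facilities
  expect_equal(unname(bin["a|count|5|1", ]), c(0, 0, 1, 1, 0))
  expect_equal(d["a|count|5|1", "status"], "ok")
  # positives {2,4,6}: median 4, strictly-greater rule
  expect_equal(unname(bin["a|idw_hazard|5|1", ]), c(0, 0, 0, 0, 1))
  expect_equal(d["a|idw_hazard|5|1", "idw_cut"], 4)
  # max count 1: redundant with presence
  expect_equal(d["b|count|5|1", "status"], "redundant")
  # all-zero column: non-informative
  expect_equal(d["b|idw_hazard|5|1", "status"], "non_informative")
  # redundant/non-informative are never retained by the filter
  es <- prevalenceFilter(es, minExposed = 0L)
  d <- definitions(es)
  expect_false(d["b|count|5|1", "retained"])
  expect_false(d["b|idw_hazard|5|1", "retained"])
})

test_that("the prevalence filter requires 10 exposed cases AND controls", {
  mk <- function(nExpCase, nExpCtl) {
    n <- 600
    case <- rep(c(1L, 0L), c(100, 500))
    bin <- c(rep(1, nExpCase), rep(0, 100 - nExpCase),
             rep(1, nExpCtl), rep(0, 500 - nExpCtl))
    raw <- matrix(bin, nrow = 1,
                  dimnames = list("a|presence|5|1", sprintf("P%d", 1:n)))
    p <- data.frame(participant_id = sprintf("P%d", 1:n), lon = 0, lat = 0,
                    visit_year = 2015, case = case)
    defs <- parseDefinitionId("a|presence|5|1")
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(raw = raw),
      rowData = S4Vectors::DataFrame(defs, row.names = defs$definition_id),
      colData = S4Vectors::DataFrame(p, row.names = p$participant_id))
    prevalenceFilter(dichotomize(new("ExposureSet", se)))
  }
  expect_true(definitions(mk(10, 10))$retained)
  expect_false(definitions(mk(9, 500))$retained)
  expect_false(definitions(mk(90, 9))$retained)
  expect_false(definitions(mk(0, 0))$retained)
  # invariant to participant ordering
  set.seed(1)
  fac <- toyFacilities("a", 6)
  p <- toyParticipants(80)
  p$case <- rep(c(1L, 0L), 40)
  es1 <- prevalenceFilter(dichotomize(exposureMatrix(p, fac)), 5L)
  perm <- sample(nrow(p))
  es2 <- prevalenceFilter(dichotomize(exposureMatrix(p[perm, ], fac)), 5L)
  expect_equal(definitions(es1)$retained, definitions(es2)$retained)
})
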