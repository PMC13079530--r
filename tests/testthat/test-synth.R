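# Synthetic-data generator: facility process, ADI standardization,
# participant accrual and ground-truth round trip.

test_that("facility generation honors counts, persistence and the seed", {
  cfg <- simConfig(seed = 7, nCases = 10, nControls = 40,
                   agents = c("a", "b", "c"), facilitiesPerAgent = 4L,
                   facilityPersistence = 1, years = c(2014L, 2014L))
  fac <- generateFacilities(cfg)
  # 3 agents x 4 facilities x 6 report years (visit year plus 5 prior)
  expect_equal(nrow(fac), 3 * 4 * 6)
  expect_false(anyDuplicated(fac[, c("facility_id", "agent", "year")]) > 0)
  expect_true(all(fac$modeled_hazard > 0))
  r <- simConfig()@region
  expect_true(all(fac$lon >= r[1] & fac$lon <= r[2]))
  expect_identical(fac, generateFacilities(cfg))

  expect_equal(nrow(generateFacilities(
    simConfig(nCases = 1, nControls = 1, agents = "a",
              facilitiesPerAgent = 0L))), 0L)
  expect_error(simConfig(agents = character(0)), "agent")
})

test_that("clustered facility placement stays inside the region", {
  cfg <- simConfig(seed = 3, nCases = 5, nControls = 20, agents = "a",
                   facilitiesPerAgent = 40L, clusterFacilities = TRUE,
                   nClusters = 3L, clusterSdKm = 10)
  fac <- generateFacilities(cfg)
  r <- cfg@region
  expect_true(all(fac$lon >= r[1] & fac$lon <= r[2]))
  expect_true(all(fac$lat >= r[3] & fac$lat <= r[4]))
})

test_that("ADI standardization hits mean 100 / SD 20 with the n-1 SD", {
  expect_equal(standardizeADI(c(80, 100, 120)), c(80, 100, 120))
  expect_equal(standardizeADI(c(0, 10)),
               c(100 - 20 / sqrt(2), 100 + 20 / sqrt(2)))
  set.seed(1)
  for (n in c(2, 5, 100)) {
    x <- rnorm(n, 40, 13)
    z <- standardizeADI(x)
    expect_lt(abs(mean(z) - 100), 1e-9)
    expect_lt(abs(sd(z) - 20), 1e-9)
    # affine and order-preserving
    expect_equal(order(z), order(x))
    # idempotent up to tolerance
    expect_equal(standardizeADI(z), z, tolerance = 1e-12)
  }
  expect_error(standardizeADI(rep(5, 4)), "degenerate")
  expect_error(standardizeADI(3), ">= 2")
})

test_that("participant accrual is deterministic and hits exact targets", {
  cfg <- simConfig(seed = 11, nCases = 40, nControls = 160,
                   agents = "chromium", facilitiesPerAgent = 10L)
  fac <- generateFacilities(cfg)
  gp <- generateParticipants(cfg, fac)
  p <- gp$participants
  expect_equal(sum(p$case == 1L), 40L)
  expect_equal(sum(p$case == 0L), 160L)
  expect_true(all(p$cancer_type[p$case == 1L] != "none"))
  expect_true(all(p$cancer_type[p$case == 0L] == "none"))
  expect_true(all(p$cancer_type[p$sex == "Male" & p$case == 1L] == "lung"))
  expect_true(all(p$alcohol %in% c("current", "past", "never", "unknown")))
  gp2 <- generateParticipants(cfg, fac)
  expect_identical(p, gp2$participants)
})

test_that("ground-truth exposures equal the exposure module exactly", {
  cfg <- simConfig(seed = 5, nCases = 25, nControls = 100,
                   agents = c("chromium", "benzene"),
                   facilitiesPerAgent = 8L,
                   trueLogOR = c("chromium|presence|10|3" = log(2)))
  fac <- generateFacilities(cfg)
  gp <- generateParticipants(cfg, fac)
  es <- exposureMatrix(gp$participants, fac)
  expect_identical(SummarizedExperiment::assay(es, "raw"),
                   gp$truth@exposures)
})

test_that("null generator yields exchangeable case/control distributions", {
  cfg <- simConfig(seed = 17, nCases = 300, nControls = 1200,
                   agents = "chromium", facilitiesPerAgent = 25L,
                   trueLogOR = setNames(numeric(0), character(0)),
                   confounderLogOR = setNames(numeric(0), character(0)),
                   ageMeanCase = 50, ageMeanControl = 50)
  fac <- generateFacilities(cfg)
  p <- generateParticipants(cfg, fac, computeTruth = FALSE)$participants
  # generous alpha: these are sanity checks, not power studies
  expect_gt(ks.test(p$adi_std[p$case == 1], p$adi_std[p$case == 0])$p.value,
            1e-3)
  expect_gt(ks.test(p$age[p$case == 1], p$age[p$case == 0])$p.value, 1e-3)
  expect_gt(chisq.test(table(p$case, p$tobacco))$p.value, 1e-3)
  es <- prevalenceFilter(dichotomize(exposureMatrix(p, fac)))
  bin <- binaryCoding(es)["chromium|presence|20|3", ]
  expect_gt(chisq.test(table(bin, p$case))$p.value, 1e-3)
})

test_that("a planted odds ratio of 2 is visible in the exposed cross-tab", {
  cfg <- simConfig(seed = 23, nCases = 400, nControls = 1600,
                   agents = "chromium", facilitiesPerAgent = 40L,
                   trueLogOR = c("chromium|presence|20|3" = log(2)),
                   confounderLogOR = setNames(numeric(0), character(0)))
  fac <- generateFacilities(cfg)
  gp <- generateParticipants(cfg, fac, computeTruth = FALSE)
  p <- gp$participants
  raw <- toxprox:::.rawExposures(
    p, fac, parseDefinitionId("chromium|presence|20|3"))
  tab <- table(exposed = raw[1, ] > 0, case = p$case)
  orHat <- (tab[2, 2] * tab[1, 1]) / (tab[1, 2] * tab[2, 1])
  expect_lt(abs(log(orHat) - log(2)), 0.35)  # ~3 SEs at this size
})

test_that("an agent shorthand in trueLogOR expands to a presence definition", {
  cfg <- simConfig(seed = 1, nCases = 5, nControls = 20,
                   agents = "benzene", facilitiesPerAgent = 3L,
                   trueLogOR = c(benzene = 0.5))
  pl <- toxprox:::.plantedDefinitions(cfg)
  expect_equal(pl$defs$definition_id, "benzene|presence|10|3")
  expect_error(
    generateParticipants(
      simConfig(seed = 1, nCases = 5, nControls = 20, agents = "benzene",
                facilitiesPerAgent = 3L, trueLogOR = c(arsenic = 1)),
      generateFacilities(cfg)),
    "unknown agents")
})

test_that("unreachable accrual targets raise a simulation error", {
  cfg <- simConfig(seed = 2, nCases = 50, nControls = 50,
                   agents = "a", facilitiesPerAgent = 1L,
                   baselineLogit = -30, maxAttemptFactor = 2)
  fac <- generateFacilities(cfg)
  expect_error(generateParticipants(cfg, fac, computeTruth = FALSE),
               "simulation error")
})

test_that("the conditional-model set simulator has one case per set", {
  d <- simulateMatchedSets(50, 3, log(2), seed = 4)
  expect_equal(nrow(d), 50 * 4)
  expect_true(all(tapply(d$case, d$set_id, sum) == 1))
  expect_identical(d, simulateMatchedSets(50, 3, log(2), seed = 4))
})
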