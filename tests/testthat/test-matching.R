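# Matching: composite distance, greedy nearest-neighbor, exact strata,
# optimal assignment against the exhaustive oracle, and balance reporting.

test_that("match distance combines standardized gaps and category penalties", {
  spec <- matchSpec("nearest_neighbor")
  a <- list(age = 60, sex = "Female", race = "White", visit_year = 2015)
  expect_equal(matchDistance(a, a, spec), 0)
  b <- a; b$sex <- "Male"
  expect_equal(matchDistance(a, b, spec), 1000)
  c1 <- a; c1$age <- 68
  expect_equal(matchDistance(a, c1, spec, scales = c(age = 8)), 1)
  # symmetric; missing categoricals are their own category
  expect_equal(matchDistance(b, a, spec), matchDistance(a, b, spec))
  d1 <- a; d1$race <- NA
  d2 <- a; d2$race <- NA
  expect_equal(matchDistance(d1, d2, spec), 0)
})

test_that("greedy nearest-neighbor matching follows the stated order and ties", {
  # 1 case, 3 identical controls, k = 2: lowest two control ids win
  p <- data.frame(participant_id = c("C1", "K1", "K2", "K3"),
                  case = c(1L, 0L, 0L, 0L), age = 60, sex = "F",
                  race = "W", visit_year = 2015, stringsAsFactors = FALSE)
  spec <- matchSpec("nearest_neighbor", ratio = 2L)
  md <- nearestNeighborMatch(p, spec)
  s <- matchedSets(md)
  expect_equal(sort(s$participant_id[s$role == "control"]), c("K1", "K2"))
  # perfect copies match at distance zero
  p2 <- toyCohort(5, 5)
  p2[6:10, setdiff(names(p2), c("participant_id", "case"))] <-
    p2[1:5, setdiff(names(p2), c("participant_id", "case"))]
  md2 <- nearestNeighborMatch(p2, matchSpec("nearest_neighbor", ratio = 1L))
  expect_equal(md2@totalDistance, 0)
  expect_equal(length(unique(matchedSets(md2)$set_id)), 5L)
})

test_that("greedy assignment reproduces a hand-simulated toy instance", {
  # ages only; scales fixed to 1 so distances are |age gaps|
  p <- data.frame(
    participant_id = c("A", "B", "C", "u", "v", "w", "x", "y", "z"),
    case = c(1L, 1L, 1L, rep(0L, 6)),
    age = c(70, 60, 50, 71, 69, 61, 59, 49, 30),
    stringsAsFactors = FALSE)
  spec <- matchSpec("nearest_neighbor", variables = "age", ratio = 2L)
  md <- nearestNeighborMatch(p, spec, scales = c(age = 1))
  s <- matchedSets(md)
  got <- lapply(split(s, s$set_id), function(d)
    list(case = d$participant_id[d$role == "case"],
         controls = sort(d$participant_id[d$role == "control"])))
  got <- got[order(sapply(got, `[[`, "case"))]
  # hand simulation: A (oldest) takes u,v; B takes w,x; C takes y,z
  expect_equal(got[[1]], list(case = "A", controls = c("u", "v")))
  expect_equal(got[[2]], list(case = "B", controls = c("w", "x")))
  expect_equal(got[[3]], list(case = "C", controls = c("y", "z")))
})

test_that("a caliper drops cases without admissible controls", {
  p <- data.frame(participant_id = c("C1", "C2", "K1"),
                  case = c(1L, 1L, 0L), age = c(60, 90, 61),
                  stringsAsFactors = FALSE)
  spec <- matchSpec("nearest_neighbor", variables = "age", ratio = 1L,
                    caliper = 5)
  expect_warning(md <- nearestNeighborMatch(p, spec, scales = c(age = 1)),
                 "dropped")
  expect_equal(md@droppedCases, "C2")
  expect_equal(nrow(matchedSets(md)), 2L)
})

test_that("exact matching forms coarsened strata with one case per set", {
  p <- data.frame(participant_id = c("C1", "K1"), case = c(1L, 0L),
                  age = c(61, 63), sex = "F", race = "W",
                  visit_year = 2015, stringsAsFactors = FALSE)
  md <- exactMatch(p, matchSpec("exact", ratio = 1L))
  expect_equal(nrow(matchedSets(md)), 2L)
  # age bins are ageBinWidth wide: 61 and 66 do not share a stratum
  p2 <- p; p2$age <- c(61, 66)
  expect_error(exactMatch(p2, matchSpec("exact", ratio = 1L)),
               "matching failure")
  # a case in a stratum without controls is dropped and logged
  p3 <- rbind(p, data.frame(participant_id = "C9", case = 1L, age = 30,
                            sex = "M", race = "W", visit_year = 2015))
  expect_warning(md3 <- exactMatch(p3, matchSpec("exact", ratio = 1L)),
                 "dropped")
  expect_equal(md3@droppedCases, "C9")
})

test_that("exact matching partitions stratum controls among its cases", {
  p <- data.frame(participant_id = c("C1", "C2", "K1", "K2", "K3"),
                  case = c(1L, 1L, 0L, 0L, 0L),
                  age = 62, sex = "F", race = "W", visit_year = 2015,
                  stringsAsFactors = FALSE)
  for (seed in 1:5) {
    md <- exactMatch(p, matchSpec("exact", ratio = 2L, seed = seed))
    s <- matchedSets(md)
    sizes <- as.integer(sort(tapply(s$role == "control", s$set_id, sum)))
    expect_equal(sizes, c(1L, 2L))  # {2,1} or {1,2} by seed
    expect_setequal(s$participant_id[s$role == "control"],
                    c("K1", "K2", "K3"))
  }
  # deterministic for a fixed seed
  expect_identical(
    matchedSets(exactMatch(p, matchSpec("exact", ratio = 2L, seed = 3))),
    matchedSets(exactMatch(p, matchSpec("exact", ratio = 2L, seed = 3))))
})

test_that("optimal matching solves the toy diagonal instance", {
  # cost [[1,2],[2,1]] via ages with unit scale
  p <- data.frame(participant_id = c("C1", "C2", "K1", "K2"),
                  case = c(1L, 1L, 0L, 0L),
                  age = c(1, 2, 2, 1), stringsAsFactors = FALSE)
  spec <- matchSpec("optimal", variables = "age", ratio = 1L)
  md <- optimalMatch(p, spec, scales = c(age = 1))
  expect_equal(md@totalDistance, 0)  # diagonal pairing: |1-1| + |2-2|
  s <- matchedSets(md)
  pair <- function(k) s$participant_id[
    s$set_id == s$set_id[s$participant_id == k] & s$role == "control"]
  expect_equal(pair("C1"), "K2")
  expect_equal(pair("C2"), "K1")
})

test_that("optimal matching equals the exhaustive-permutation oracle", {
  set.seed(31)
  for (rep in 1:50) {
    nCa <- sample(2:6, 1)
    nCo <- nCa + sample(0:3, 1)
    p <- toyCohort(nCa, nCo, seed = 1000 + rep)
    specO <- matchSpec("optimal", ratio = 1L)
    specN <- matchSpec("nearest_neighbor", variables = specO@variables,
                       ratio = 1L)
    sc <- matchScales(p, specO@variables)
    mdO <- optimalMatch(p, specO)
    mdN <- nearestNeighborMatch(p, specN)
    cases <- p[p$case == 1L, ]
    controls <- p[p$case == 0L, ]
    controls <- controls[order(controls$participant_id), ]
    D <- outer(seq_len(nCa), seq_len(nCo), Vectorize(function(i, j)
      matchDistance(cases[i, ], controls[j, ], specO, sc)))
    expect_equal(mdO@totalDistance, bruteAssignmentCost(D),
                 tolerance = 1e-9)
    # global optimum never beaten by the greedy method
    expect_lte(mdO@totalDistance, mdN@totalDistance + 1e-9)
  }
})

test_that("infeasible ratios fall back to max-cardinality assignment", {
  p <- toyCohort(4, 6, seed = 9)
  expect_warning(md <- optimalMatch(p, matchSpec("optimal", ratio = 2L)),
                 "max-cardinality")
  s <- matchedSets(md)
  expect_equal(sum(s$role == "control"), 6L)  # every control used
  expect_equal(length(unique(s$set_id)), 4L)
})

test_that("matched datasets never reuse controls and are seed-stable", {
  p <- toyCohort(20, 100, ageShift = 5, seed = 77)
  for (m in c("nearest_neighbor", "exact", "optimal")) {
    spec <- matchSpec(m, ratio = 3L, seed = 5)
    md1 <- suppressWarnings(matchCaseControl(p, spec))
    md2 <- suppressWarnings(matchCaseControl(p, spec))
    expect_identical(matchedSets(md1), matchedSets(md2))
    ctl <- matchedSets(md1)$participant_id[matchedSets(md1)$role == "control"]
    expect_false(anyDuplicated(ctl) > 0)
  }
})

test_that("balance reports zero SMDs for copied controls and improvement otherwise", {
  p <- toyCohort(10, 10)
  p[11:20, setdiff(names(p), c("participant_id", "case"))] <-
    p[1:10, setdiff(names(p), c("participant_id", "case"))]
  md <- nearestNeighborMatch(p, matchSpec("nearest_neighbor", ratio = 1L))
  b <- balanceReport(md, p)
  expect_true(all(abs(b$after) < 1e-12))
  expect_true(all(b$balanced))
  # shifted ages: post-match |SMD| no worse than pre-match over seeds
  for (seed in 1:5) {
    p2 <- toyCohort(30, 150, ageShift = 6, seed = seed)
    md2 <- suppressWarnings(
      nearestNeighborMatch(p2, matchSpec("nearest_neighbor", ratio = 2L)))
    b2 <- balanceReport(md2, p2)
    age <- b2[b2$variable == "age", ]
    expect_lte(abs(age$after), abs(age$before) + 1e-9)
  }
})
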