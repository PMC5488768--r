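test_that("pedigree simulation is seeded, acyclic and structured as configured", {
  cfg <- simulationConfig(nFounders = 50, nGenerations = 2,
                          nMatings = 40, siresPerGen = 6)
  p1 <- simulatePedigree(cfg, seed = 71)
  p2 <- simulatePedigree(cfg, seed = 71)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- simulatePedigree(cfg, seed = 72)
  expect_false(identical(as.data.frame(p1), as.data.frame(p3)))
  ## zero generations: founders only
  p0 <- simulatePedigree(simulationConfig(nFounders = 30,
                                          nGenerations = 0), seed = 73)
  expect_equal(length(p0), 30)
  expect_true(all(is.na(p0@sire)))
  ## inbred loops create nonzero inbreeding
  pI <- simulatePedigree(simulationConfig(nFounders = 60,
                                          nGenerations = 3,
                                          nMatings = 80, siresPerGen = 6,
                                          inbredLoops = TRUE,
                                          inbredFraction = 0.5),
                         seed = 74)
  expect_gt(max(inbreeding(pI)), 0)
})

test_that("gene dropping reproduces the prescribed covariance structure", {
  cfg <- simulationConfig(nFounders = 40, nGenerations = 2,
                          nMatings = 30, siresPerGen = 5)
  ped <- simulatePedigree(cfg, seed = 75)
  ## zero G0 -> identically zero effects
  t0 <- dropGameticEffects(ped, matrix(0, 2, 2), seed = 76)
  expect_true(all(t0@aS == 0) && all(t0@aD == 0))
  ## founder sample covariance over many replicates approaches G0
  G0 <- matrix(c(1, 0.7, 0.7, 1.5), 2)
  R <- 4000
  f1 <- which(is.na(ped@sire))[1]
  sub <- pedIds(ped)[1:15]
  draws <- vapply(seq_len(R), function(r) {
    tr <- dropGameticEffects(ped, G0, seed = 1000 + r)
    c(tr@aS[f1], tr@aD[f1], unname(tr@aS[sub]))
  }, numeric(17))
  emp <- cov(t(draws[1:2, ]))
  mcse <- sqrt(2 / R) * max(G0)        # rough Wishart scale
  expect_lt(max(abs(emp - G0)), 3 * mcse)
  ## across a fixed pedigree, cov(aS) tracks sigma2s * A elementwise
  A <- relationshipBlock(ped, sub)
  empA <- cov(t(draws[-(1:2), ]))
  expect_lt(max(abs(empA - G0[1, 1] * A)), 3 * mcse)
})

test_that("phenotypes decompose into the generating variance components", {
  cfg <- simulationConfig(nFounders = 400, nGenerations = 1,
                          nMatings = 1500, siresPerGen = 120,
                          sdGroupEffect = 0, groupSize = 1500,
                          parityEffects = c(0, 0, 0),
                          birthTypeEffects = c(S = 0, T = 0),
                          ageCoef = c(0, 0, 0),
                          recordedSexes = c("M", "F"))
  d <- simulateDataset(cfg, seed = 77)
  tr <- attr(d$records, "recordTruth")
  ## all variances zero -> deterministic fixed part
  cfg0 <- simulationConfig(nFounders = 40, nGenerations = 1,
                           nMatings = 30, siresPerGen = 5,
                           sigma2s = 0, sigma2d = 0, sigmasd = 0,
                           sigma2e = 0, sdGroupEffect = 0,
                           recordedSexes = c("M", "F"))
  d0 <- simulateDataset(cfg0, seed = 78)
  tr0 <- attr(d0$records, "recordTruth")
  expect_equal(d0$records$value, tr0$fixedPart, tolerance = 1e-12)
  ## variance decomposition: var(y) ~ s2s + s2d + var(phi) + s2e with
  ## founder parents (F = 0), i.e. 2 * (s2s + s2d) + s2e
  G0 <- cfg$G0
  expFull <- 2 * (G0[1, 1] + G0[2, 2]) + cfg$sigma2e
  vy <- var(d$records$value)
  expect_lt(abs(vy - expFull) / expFull, 0.15)
  ## paternal half-sib covariance ~ sigma2s
  byS <- split(seq_len(nrow(d$records)), d$records$sire)
  prs <- do.call(rbind, lapply(byS, function(ix) {
    if (length(ix) < 2) return(NULL)
    t(combn(ix, 2))
  }))
  y <- d$records$value - mean(d$records$value)
  hs <- mean(y[prs[, 1]] * y[prs[, 2]])
  expect_lt(abs(hs - G0[1, 1]), 4 * G0[1, 1] / sqrt(nrow(prs) / 20))
})

test_that("binary simulation honours the link, the seed and the null rate", {
  cfg <- simulationConfig(nFounders = 60, nGenerations = 1,
                          nMatings = 400, siresPerGen = 10,
                          sigma2s = 0, sigma2d = 0, sigmasd = 0,
                          binaryIntercept = 0,
                          recordedSexes = c("M", "F"))
  d <- simulateDataset(cfg, seed = 79, binary = TRUE)
  ## eta = 0 everywhere -> class frequencies near 50/50
  expect_lt(abs(mean(d$records$class) - 0.5),
            3 * 0.5 / sqrt(nrow(d$records)))
  b1 <- simulateBinary(d$records, cfg, seed = 80)
  b2 <- simulateBinary(d$records, cfg, seed = 80)
  expect_identical(b1$class, b2$class)
  cfgT <- cfg
  cfgT$binaryLink <- "threshold"
  b3 <- simulateBinary(d$records, cfgT, seed = 80)
  expect_false(identical(b1$class, b3$class))
})
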