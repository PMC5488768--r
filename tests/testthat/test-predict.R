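vcP <- imprintingComponents(1, 1.2, 0.8, 4)

buildSystems <- function(ped, rec, vc) {
  ai <- buildAInverse(ped)
  list(
    imp = assembleMME("imprinting", buildDesign(rec, "imprinting", ped),
                      vc, ai),
    eqv = assembleMME("equivalent", buildDesign(rec, "equivalent", ped),
                      transformComponents(vc, "equivalent"), ai))
}

test_that("POE from the equivalent model equals the TA difference, and is relabelling-invariant", {
  cfg <- simulationConfig(nFounders = 80, nGenerations = 2,
                          nMatings = 80, siresPerGen = 10,
                          recordedSexes = c("M", "F"))
  d <- simulateDataset(cfg, seed = 51)
  sys <- buildSystems(d$ped, d$records, vcP)
  solI <- solveBlup(sys$imp)
  solE <- solveBlup(sys$eqv)
  iI <- poeEstimates(solI)
  iE <- poeEstimates(solE)
  expect_lt(max(abs(iE - iI[names(iE)])), 1e-8)
  ## the TA-as-sire vectors of the two models coincide as well
  expect_lt(max(abs(solVec(solI, "TA_as_sire") -
                    solVec(solE, "TA_as_sire"))), 1e-8)

  ## permuting the input record order permutes nothing in the keyed output
  set.seed(52)
  rec2 <- d$records[sample(nrow(d$records)), ]
  solI2 <- solveBlup(assembleMME("imprinting",
                                 buildDesign(rec2, "imprinting", d$ped),
                                 vcP, buildAInverse(d$ped)))
  expect_equal(poeEstimates(solI2), iI, tolerance = 1e-10)
})

test_that("the two PEV routes agree and no-information animals sit at the prior", {
  cfg <- simulationConfig(nFounders = 80, nGenerations = 2,
                          nMatings = 80, siresPerGen = 10,
                          recordedSexes = c("M", "F"))
  d <- simulateDataset(cfg, seed = 53)
  ## append an unconnected founder with no records
  df <- as.data.frame(d$ped)
  df <- rbind(df[, 1:5],
              data.frame(animal = "lone", sire = NA, dam = NA,
                         sex = "M", birthYear = 1970L))
  ped <- Pedigree(df$animal, df$sire, df$dam, sex = df$sex,
                  birthYear = df$birthYear)
  sys <- buildSystems(ped, d$records, vcP)
  solI <- computePEV(sys$imp)
  solE <- computePEV(sys$eqv)
  pI <- poePev(solI)
  pE <- poePev(solE)
  expect_lt(max(abs(pE - pI[names(pE)])), 1e-8)
  ## unconnected founder: PEV equals the prior variance of each effect
  expect_equal(unname(effectTable(solI, "TA_as_sire")$pev[
    effectTable(solI, "TA_as_sire")$level == "lone"]), vcP@sigma2s,
    tolerance = 1e-8)
  expect_equal(unname(pE["lone"]),
               transformComponents(vcP, "equivalent")@sigma2x,
               tolerance = 1e-8)
  ## reliabilities: no-information founder at 0; cross-model equality
  solI <- reliability(solI, vcP, ped)
  solE <- reliability(solE, transformComponents(vcP, "equivalent"), ped)
  tabE <- effectTable(solE, "imprinting_effect")
  expect_equal(tabE$reliability[tabE$level == "lone"], 0)
  rI <- 1 - pI / ((1 + inbreeding(ped)[names(pI)]) *
                  transformComponents(vcP, "equivalent")@sigma2x)
  expect_equal(setNames(tabE$reliability, tabE$level)[names(pI)],
               pmin(pmax(rI, 0), 1 - 1e-12), tolerance = 1e-8)
})

test_that("PEV shrinks when a sire gains phenotyped progeny", {
  ## focal sire s1 gains progeny; a contemporary sire s2 anchors the
  ## comparison group so information can reach s1 past the intercept
  nd <- 12
  ped <- Pedigree(c("s1", "s2", paste0("d", 1:nd), paste0("p", 1:nd)),
                  sire = c(NA, NA, rep(NA, nd),
                           c(rep("s1", 6), rep("s2", 6))),
                  dam = c(NA, NA, rep(NA, nd), paste0("d", 1:nd)))
  set.seed(54)
  yall <- rnorm(nd, 10)
  mk <- function(k) {
    ix <- c(seq_len(k), 7:12)          # k progeny of s1, all 6 of s2
    data.frame(progeny = paste0("p", ix), sire = c(rep("s1", k),
                                                   rep("s2", 6)),
               dam = paste0("d", ix), group = "g1", parity = 1,
               birthType = "S", age = 500, value = yall[ix],
               stringsAsFactors = FALSE)
  }
  ai <- buildAInverse(ped)
  pevAt <- function(k) {
    sys <- assembleMME("equivalent", buildDesign(mk(k), "equivalent", ped),
                       transformComponents(vcP, "equivalent"), ai)
    tab <- effectTable(computePEV(sys), "TA_as_sire")
    tab$pev[tab$level == "s1"]
  }
  pevs <- vapply(c(1, 3, 6), pevAt, numeric(1))
  expect_true(all(diff(pevs) < 0))
  expect_true(all(pevs < vcP@sigma2s))
})

test_that("genetic trends aggregate by birth year and stay linear in the effects", {
  cfg <- simulationConfig(nFounders = 60, nGenerations = 2,
                          nMatings = 60, siresPerGen = 8,
                          recordedSexes = c("M", "F"))
  d <- simulateDataset(cfg, seed = 55)
  sys <- buildSystems(d$ped, d$records, vcP)
  sol <- solveBlup(sys$eqv)
  tr <- geneticTrend(sol, d$ped)
  expect_true(all(tr$n > 0))
  expect_equal(tr$meanPoe, tr$meanAd - tr$meanAs, tolerance = 1e-12)
  ## single-animal years: mean equals that animal's estimate
  yr1 <- tr$year[tr$n == 1]
  if (length(yr1)) {
    ids <- pedIds(d$ped)[d$ped@birthYear == yr1[1]]
    aS <- solVec(sol, "TA_as_sire")
    expect_equal(tr$meanAs[tr$year == yr1[1]], unname(aS[ids]))
  }
  ## all-zero effects give an all-zero trend
  solZ <- sol
  solZ@estimates[] <- 0
  trZ <- geneticTrend(solZ, d$ped)
  expect_true(all(trZ$meanAs == 0 & trZ$meanPoe == 0))
})
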