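test_that("the parameterisation map is the stated linear bijection", {
  vc <- imprintingComponents(1, 1, 0.9, 4)
  ve <- transformComponents(vc, "equivalent")
  expect_equal(ve@sigma2x, 0.2)      # sigma2i = 1 + 1 - 2*0.9
  expect_equal(ve@sigmacov, -0.1)    # sigmasi = 0.9 - 1
  back <- transformComponents(ve, "imprinting")
  expect_equal(back@sigma2s, vc@sigma2s)
  expect_equal(back@sigma2x, vc@sigma2x)
  expect_equal(back@sigmacov, vc@sigmacov)

  ## (s - sd) + (d - sd) = sigma2i, i.e. the two (possibly negative)
  ## covariance-style contributions always add up to the imprinting
  ## variance, on random PSD G0
  set.seed(1)
  for (k in 1:20) {
    L <- matrix(rnorm(4), 2)
    G <- crossprod(L)
    vcr <- imprintingComponents(G[1, 1], G[2, 2], G[1, 2], 1)
    ver <- transformComponents(vcr, "equivalent")
    expect_equal((G[1, 1] - G[1, 2]) + (G[2, 2] - G[1, 2]), ver@sigma2x)
  }
})

test_that("derived parameters: identities, signs and scale invariance", {
  vc <- imprintingComponents(0.8, 1.3, 0.859, 11.45)
  d <- derivedGeneticParameters(vc)
  expect_equal(d$sigma2i, 0.8 + 1.3 - 2 * 0.859)
  expect_equal(d$sigma2a, 0.8 + 1.3 + 2 * 0.859)
  expect_equal(d$contribPaternal + d$contribMaternal, 100)
  ## sigma_sd > sigma2s -> negative paternal contribution (partial
  ## imprinting signature)
  expect_lt(d$contribPaternal, 0)
  ## no-imprinting limit
  d0 <- derivedGeneticParameters(imprintingComponents(1, 1, 1, 4))
  expect_equal(d0$sigma2i, 0)
  expect_equal(d0$relImprinting, 0)
  expect_true(is.na(d0$contribPaternal))
  ## ratios invariant under common rescaling
  for (c0 in c(0.3, 7)) {
    dc <- derivedGeneticParameters(
      imprintingComponents(0.8 * c0, 1.3 * c0, 0.859 * c0, 11.45 * c0))
    expect_equal(dc$relImprinting, d$relImprinting)
    expect_equal(dc$contribMaternal, d$contribMaternal)
    expect_equal(dc$h2, d$h2)
  }
})

test_that("design matrices have the documented incidence patterns", {
  ped <- Pedigree(c("s1", "d1", "p1"), sire = c(NA, NA, "s1"),
                  dam = c(NA, NA, "d1"))
  rec <- data.frame(progeny = "p1", sire = "s1", dam = "d1", group = "g1",
                    parity = 1, birthType = "S", age = 500, value = 1)
  ids <- pedIds(ped)
  ei <- function(id) as.numeric(ids == id)

  dI <- buildDesign(rec, "imprinting", ped)
  expect_equal(as.numeric(dI$Z$TA_as_sire[1, ]), ei("s1"))
  expect_equal(as.numeric(dI$Z$TA_as_dam[1, ]), ei("d1"))

  dE <- buildDesign(rec, "equivalent", ped)
  expect_equal(as.numeric(dE$Z$TA_as_sire[1, ]), ei("s1") + ei("d1"))
  expect_equal(as.numeric(dE$Z$imprinting_effect[1, ]), ei("d1"))

  dA <- buildDesign(rec, "animal", ped)
  expect_equal(as.numeric(dA$Z$TA[1, ]), ei("s1") + ei("d1"))

  ## cubic age regression is centred
  rec3 <- rec[rep(1, 3), ]
  rec3$age <- c(400, 500, 600)
  X <- buildDesign(rec3, "imprinting", ped)$X
  xc <- rec3$age - mean(rec3$age)
  expect_equal(unname(X[, "age1"]), xc)
  expect_equal(unname(X[, "age2"]), xc^2)
  expect_equal(unname(X[, "age3"]), xc^3)

  rec$sire <- "ghost"
  expect_error(buildDesign(rec, "imprinting", ped), "pedigree entry")
})

test_that("Mendelian weights follow the reduced-model residual inflation", {
  expect_equal(mendelianWeights(c(0, 0.5), c(0, 1),
                                imprintingComponents(0, 0, 0, 1)),
               c(1, 1))
  expect_equal(mendelianWeights(1, 1, imprintingComponents(2, 3, 1, 5)), 1)
  expect_equal(mendelianWeights(0, 0,
                                imprintingComponents(0.25, 0.25, 0.1, 1)),
               1.5)
  ## w >= 1 and F = 0 maximises w at fixed components
  set.seed(2)
  vc <- imprintingComponents(0.7, 1.1, 0.5, 2)
  Fs <- runif(20); Fd <- runif(20)
  w <- mendelianWeights(Fs, Fd, vc)
  expect_true(all(w >= 1))
  expect_true(all(w <= mendelianWeights(0, 0, vc)))
  expect_error(mendelianWeights(0, 0, imprintingComponents(1, 1, 0, 0)),
               "sigma2e")
})

test_that("assembled MME are symmetric and reproduce dense GLS", {
  rp <- randomPedigree(25, 21, pUnknown = 0)
  rec <- makeRecords(rp, 22)
  vc <- imprintingComponents(1, 1.2, 0.8, 4)
  ai <- buildAInverse(rp)
  for (kind in c("imprinting", "equivalent", "animal")) {
    vcK <- if (kind == "animal") animalComponents(0.9, 4)
           else transformComponents(vc, kind)
    des <- buildDesign(rec, kind, rp)
    sys <- assembleMME(kind, des, vcK, ai)
    expect_lt(max(abs(sys@coeff - Matrix::t(sys@coeff))), 1e-14)
    sol <- solveBlup(sys)
    orc <- glsOracle(rec, rp, vcK, kind)
    lay <- sol@layout
    expect_equal(sol@estimates[lay$eq[lay$kind == "fixed"]], orc$beta,
                 tolerance = 1e-10)
    for (k in unique(orc$uKinds)) {
      est <- solVec(sol, k)
      expect_equal(unname(est[orc$uNames[orc$uKinds == k]]),
                   orc$u[orc$uKinds == k], tolerance = 1e-10)
    }
  }
  expect_error(assembleMME("imprinting",
                           buildDesign(rec, "imprinting", rp),
                           imprintingComponents(1, 1, 1, 4), ai),
               "singular")
})

test_that("the animal null is the equal-components limit of the imprinting model", {
  rp <- randomPedigree(30, 23, pUnknown = 0)
  rec <- makeRecords(rp, 24)
  u <- 0.9; e <- 4
  llA <- remlLoglik(animalComponents(u, e), rec, rp, "animal")
  ## approach the singular constraint sd -> u from inside the PSD cone
  del <- c(1e-4, 1e-6)
  lls <- vapply(del, function(dd)
    remlLoglik(imprintingComponents(u, u, u - dd, e), rec, rp,
               "imprinting"), numeric(1))
  expect_lt(abs(lls[2] - llA), abs(lls[1] - llA) + 1e-9)
  expect_equal(lls[2], llA, tolerance = 1e-4)
})
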