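vcRef <- imprintingComponents(1, 1.2, 0.8, 4)

test_that("the sparse MME likelihood equals the dense textbook evaluation", {
  rp <- randomPedigree(28, 31, pUnknown = 0)
  rec <- makeRecords(rp, 32)
  for (kind in c("imprinting", "equivalent", "animal")) {
    vcK <- if (kind == "animal") animalComponents(0.9, 4)
           else transformComponents(vcRef, kind)
    expect_equal(remlLoglik(vcK, rec, rp, kind),
                 glsOracle(rec, rp, vcK, kind)$ll, tolerance = 1e-8)
  }
})

test_that("the likelihood is invariant to record order and parameterisation", {
  rp <- randomPedigree(40, 33, pUnknown = 0)
  rec <- makeRecords(rp, 34)
  ll <- remlLoglik(vcRef, rec, rp, "imprinting")
  set.seed(35)
  perm <- sample(nrow(rec))
  expect_equal(remlLoglik(vcRef, rec[perm, ], rp, "imprinting"), ll,
               tolerance = 1e-10)
  expect_equal(remlLoglik(transformComponents(vcRef, "equivalent"),
                          rec, rp, "equivalent"), ll, tolerance = 1e-8)
  expect_error(remlLoglik(imprintingComponents(0.1, 0.1, 0.5, 4),
                          rec, rp, "imprinting"), "positive semidefinite")
})

test_that("fitReml converges to a stationary point with a monotone EM path", {
  ## a deep, informative design so the optimum is interior
  cfg <- simulationConfig(nFounders = 300, nGenerations = 3,
                          nMatings = 350, siresPerGen = 25, sigma2e = 2,
                          recordedSexes = c("M", "F"))
  d <- simulateDataset(cfg, seed = 41)
  fit <- fitReml(d$records, d$ped, "imprinting")
  expect_true(fit@converged)
  expect_length(fit@boundary, 0)
  ## finite-difference REML score ~ 0 at the optimum, evaluated through
  ## the independent sparse-likelihood route
  p <- poeBLUP:::parFromVc("imprinting", fit@vc)
  g <- vapply(seq_along(p), function(j) {
    h <- 1e-5 * max(abs(p[j]), 1e-2)
    pp <- p; pm <- p
    pp[j] <- p[j] + h; pm[j] <- p[j] - h
    (remlLoglik(poeBLUP:::vcFromPar("imprinting", pp), d$records,
                d$ped, "imprinting") -
     remlLoglik(poeBLUP:::vcFromPar("imprinting", pm), d$records,
                d$ped, "imprinting")) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g)), 1e-2)
  ## dense engine and sparse likelihood agree at the fitted point
  expect_equal(fit@loglik,
               remlLoglik(fit@vc, d$records, d$ped, "imprinting"),
               tolerance = 1e-8)

  ## EM iterations never decrease the log-likelihood
  cfgS <- simulationConfig(nFounders = 120, nGenerations = 2,
                           nMatings = 120, siresPerGen = 12,
                           recordedSexes = c("M", "F"))
  dS <- simulateDataset(cfgS, seed = 42)
  fitEM <- fitReml(dS$records, dS$ped, "imprinting",
                   control = remlControl(algorithm = "EM", maxIter = 15L))
  expect_true(all(diff(fitEM@trajectory$loglik) >= -1e-10))
})

test_that("the animal null is the constrained imprinting fit", {
  cfgS <- simulationConfig(nFounders = 120, nGenerations = 2,
                           nMatings = 120, siresPerGen = 12,
                           recordedSexes = c("M", "F"))
  d <- simulateDataset(cfgS, seed = 47)
  fit0 <- fitReml(d$records, d$ped, "animal")
  u <- poeBLUP:::parFromVc("animal", fit0@vc)
  ## approach the singular constraint sd -> u from inside the PSD cone
  llA <- fit0@loglik
  lls <- vapply(c(1e-4, 1e-6), function(dd)
    remlLoglik(imprintingComponents(u[1], u[1], u[1] * (1 - dd), u[2]),
               d$records, d$ped, "imprinting"), numeric(1))
  expect_lt(abs(lls[2] - llA), abs(lls[1] - llA) + 1e-9)
  expect_equal(lls[2], llA, tolerance = 1e-4)
})

test_that("the RLRT uses the conservative 2-DF reference", {
  fitA <- new("RemlFit", vc = animalComponents(1, 1), kind = "animal",
              loglik = -100, aiCov = matrix(NA_real_, 2, 2),
              converged = TRUE, iterations = 1L,
              trajectory = data.frame(), boundary = character(0),
              dataHash = c(n = 10, sumY = 5))
  mkFull <- function(ll, hash = c(n = 10, sumY = 5))
    new("RemlFit", vc = vcRef, kind = "imprinting", loglik = ll,
        aiCov = matrix(NA_real_, 4, 4), converged = TRUE,
        iterations = 1L, trajectory = data.frame(),
        boundary = character(0), dataHash = hash)
  r0 <- rlrt(mkFull(-100), fitA)
  expect_equal(r0@statistic, 0)
  expect_equal(r0@pValue, 1)
  r1 <- rlrt(mkFull(-100 + 13.816 / 2), fitA)
  expect_equal(r1@statistic, 13.816)
  expect_equal(r1@pValue, 0.001, tolerance = 1e-3)
  expect_error(rlrt(mkFull(-90, hash = c(n = 11, sumY = 5)), fitA),
               "same records")
  expect_error(rlrt(fitA, fitA), "full fit")
})

test_that("delta-method SEs match the identity and sampling oracles", {
  ## a fit object with a known, well-conditioned asymptotic covariance:
  ## the delta machinery is checked against brute-force propagation
  p <- c(sigma2s = 0.8, sigmasd = 0.859, sigma2d = 1.3, sigma2e = 11.45)
  R <- matrix(c(1, 0.3, 0.2, 0.1,
                0.3, 1, 0.3, 0.1,
                0.2, 0.3, 1, 0.1,
                0.1, 0.1, 0.1, 1), 4, 4)
  sds <- c(0.02, 0.02, 0.03, 0.1)
  Sig <- diag(sds) %*% R %*% diag(sds)
  dimnames(Sig) <- list(names(p), names(p))
  fit <- new("RemlFit", vc = imprintingComponents(0.8, 1.3, 0.859, 11.45),
             kind = "imprinting", loglik = 0, aiCov = Sig,
             converged = TRUE, iterations = 1L, trajectory = data.frame(),
             boundary = character(0), dataHash = c(n = 1, sumY = 1))
  expect_equal(deltaSE(fit, "sigma2s"), sds[1])       # identity functional
  set.seed(44)
  dr <- sweep(matrix(rnorm(1e5 * 4), ncol = 4) %*% chol(Sig), 2, p, "+")
  relMc <- 100 * (dr[, 1] + dr[, 3] - 2 * dr[, 2]) /
    (dr[, 1] + dr[, 3] + 2 * dr[, 2])
  expect_lt(abs(deltaSE(fit, "relImprinting") - sd(relMc)) / sd(relMc),
            0.05)
  i <- p[1] + p[3] - 2 * p[2]
  cpMc <- 100 * (dr[, 1] - dr[, 2]) /
    (dr[, 1] + dr[, 3] - 2 * dr[, 2])
  expect_lt(abs(deltaSE(fit, "contribPaternal") - sd(cpMc)) / sd(cpMc),
            0.05)
})

test_that("rescaling the data rescales component SEs but not ratio SEs", {
  cfgS <- simulationConfig(nFounders = 150, nGenerations = 2,
                           nMatings = 180, siresPerGen = 15,
                           recordedSexes = c("M", "F"))
  d <- simulateDataset(cfgS, seed = 48)
  fit <- fitReml(d$records, d$ped, "imprinting")
  rec2 <- d$records
  rec2$value <- rec2$value * 3
  p <- poeBLUP:::parFromVc("imprinting", fit@vc)
  fit2 <- fitReml(rec2, d$ped, "imprinting",
                  start = poeBLUP:::vcFromPar("imprinting", 9 * p))
  expect_equal(deltaSE(fit2, "sigma2i"), 9 * deltaSE(fit, "sigma2i"),
               tolerance = 1e-3)
  expect_equal(deltaSE(fit2, "relImprinting"),
               deltaSE(fit, "relImprinting"), tolerance = 1e-3)
})
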