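## Gene-dropping simulator: multi-generation cattle-like pedigrees and
## phenotypes with exactly the covariance structure the imprinting models
## assume (two correlated transmitting abilities per animal with
## covariance G0 (x) A, Mendelian-sampling deviations absorbed into the
## residual of non-parent records, the standard fixed effects, and an
## optional binary trait).

#' Simulation configuration
#'
#' Defaults emulate a fattening-bull slaughter data set: overlapping
#' two-generation parent pools, strong paternal half-sib families, records
#' on non-parent bulls only, comparison groups of moderate size, a
#' maternally dominated imprinting variance of 10 percent of the total
#' additive genetic variance with a parental-effect correlation of about
#' 0.84, and a heritability of 0.25.
#'
#' @param nFounders number of founder animals
#' @param propMaleFounders proportion of male founders
#' @param nGenerations number of discrete generations after the founders
#' @param nMatings matings per generation
#' @param siresPerGen distinct sires drawn per generation (half-sib family
#'   structure)
#' @param twinRate probability that a mating produces twins
#' @param inbredLoops if \code{TRUE} a fraction of matings are
#'   sire-daughter, creating inbred loops
#' @param inbredFraction fraction of matings that are within-family when
#'   \code{inbredLoops}
#' @param sigma2s,sigma2d,sigmasd generating TA-scale covariance
#'   components (defaults give a relative imprinting variance of 10
#'   percent, maternally dominated)
#' @param sigma2e residual variance (default: heritability 0.25)
#' @param mu overall mean of the trait
#' @param groupSize comparison-group size (the tail group is smaller, so
#'   the minimum-size record filter is exercised)
#' @param sdGroupEffect standard deviation of comparison-group effects
#' @param parityEffects fixed effects of parity 1, 2, 3+
#' @param birthTypeEffects fixed effects of singleton and twin birth
#' @param ageRange slaughter-age range in days
#' @param ageCoef linear, quadratic and cubic age-regression coefficients
#' @param recordedSexes sexes that receive records (fattening bulls:
#'   \code{"M"}; use \code{c("M","F")} to enlarge data sets)
#' @param maxRecords optional cap on the number of records
#' @param binaryIntercept intercept of the binary linear predictor on the
#'   logit scale
#' @param binaryLink \code{"logit"} or \code{"threshold"}
#' @param binaryThreshold latent threshold for the threshold link
#' @return a configuration list of class \code{poeSimConfig}
#' @export
simulationConfig <- function(nFounders = 120L, propMaleFounders = 0.3,
                             nGenerations = 3L, nMatings = 120L,
                             siresPerGen = 20L, twinRate = 0.03,
                             inbredLoops = FALSE, inbredFraction = 0.15,
                             sigma2s = 0.8, sigma2d = 1.3,
                             sigmasd = 0.859, sigma2e = 11.45, mu = 100,
                             groupSize = 12L, sdGroupEffect = 2,
                             parityEffects = c(0, 0.4, 0.7),
                             birthTypeEffects = c(S = 0, T = -1.5),
                             ageRange = c(400L, 560L),
                             ageCoef = c(0.05, -4e-4, 1e-6),
                             recordedSexes = "M", maxRecords = NULL,
                             binaryIntercept = 0,
                             binaryLink = c("logit", "threshold"),
                             binaryThreshold = 0) {
  cfg <- list(nFounders = nFounders, propMaleFounders = propMaleFounders,
              nGenerations = nGenerations, nMatings = nMatings,
              siresPerGen = siresPerGen, twinRate = twinRate,
              inbredLoops = inbredLoops, inbredFraction = inbredFraction,
              G0 = matrix(c(sigma2s, sigmasd, sigmasd, sigma2d), 2L, 2L),
              sigma2e = sigma2e, mu = mu, groupSize = groupSize,
              sdGroupEffect = sdGroupEffect,
              parityEffects = parityEffects,
              birthTypeEffects = birthTypeEffects, ageRange = ageRange,
              ageCoef = ageCoef, recordedSexes = recordedSexes,
              maxRecords = maxRecords, binaryIntercept = binaryIntercept,
              binaryLink = match.arg(binaryLink),
              binaryThreshold = binaryThreshold)
  ev <- eigen(cfg$G0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("generating G0 must be positive semidefinite")
  class(cfg) <- "poeSimConfig"
  cfg
}

#' Simulate a multi-generation pedigree
#'
#' Discrete generations with overlapping parent pools (sires and dams are
#' drawn from the two preceding generations), repeated use of dams across
#' matings (parity), strong paternal half-sib families, and optional
#' sire-daughter matings that create inbred loops. Fully reproducible
#' given the seed.
#'
#' @param cfg a [simulationConfig()]
#' @param seed integer seed
#' @return a [Pedigree-class]
#' @export
simulatePedigree <- function(cfg = simulationConfig(), seed = 1L) {
  set.seed(seed)
  nm <- max(1L, round(cfg$nFounders * cfg$propMaleFounders))
  id <- sprintf("F%04d", seq_len(cfg$nFounders))
  sex <- c(rep("M", nm), rep("F", cfg$nFounders - nm))
  sire <- rep(NA_character_, cfg$nFounders)
  dam <- rep(NA_character_, cfg$nFounders)
  year <- rep(1970L, cfg$nFounders)
  gen <- rep(0L, cfg$nFounders)
  cnt <- 0L
  for (g in seq_len(cfg$nGenerations)) {
    poolIdx <- which(gen >= g - 2L & gen <= g - 1L)
    males <- id[poolIdx][sex[poolIdx] == "M"]
    females <- id[poolIdx][sex[poolIdx] == "F"]
    if (!length(males) || !length(females))
      stop("mating pool exhausted in generation ", g,
           "; increase founders or the sex ratio")
    sires <- sample(males, min(cfg$siresPerGen, length(males)))
    for (m in seq_len(cfg$nMatings)) {
      s <- sample(sires, 1L)
      d <- if (cfg$inbredLoops && g >= 2L &&
               runif(1) < cfg$inbredFraction) {
        daughters <- id[!is.na(sire) & sire == s & sex == "F" &
                          id %in% females]
        if (length(daughters)) sample(daughters, 1L)
        else sample(females, 1L)
      } else sample(females, 1L)
      nOff <- if (runif(1) < cfg$twinRate) 2L else 1L
      for (o in seq_len(nOff)) {
        cnt <- cnt + 1L
        id <- c(id, sprintf("G%d_%04d", g, cnt))
        sex <- c(sex, sample(c("M", "F"), 1L))
        sire <- c(sire, s)
        dam <- c(dam, d)
        year <- c(year, 1970L + 3L * g)
        gen <- c(gen, g)
      }
    }
  }
  Pedigree(id, sire, dam, sex = sex, birthYear = year)
}

## symmetric PSD square root
msqrt <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S)) %*% t(ev$vectors)
}

#' Drop gametic (transmitting-ability) effects through a pedigree
#'
#' Founder TA pairs are bivariate normal with covariance G0; a
#' non-founder's pair is the parental average plus a Mendelian-sampling
#' deviation with covariance \eqn{(\tfrac12 - \tfrac14(F_s + F_d))G_0}
#' (one-known-parent and founder cases use \eqn{\tfrac34 - \tfrac14 F}
#' and 1). The whole-gamete infinitesimal construction reproduces
#' \eqn{\mathrm{cov} = G_0 \otimes A} exactly.
#'
#' @param ped a [Pedigree-class]
#' @param G0 generating 2x2 TA covariance matrix
#' @param seed integer seed
#' @return a [SimulationTruth-class]
#' @export
dropGameticEffects <- function(ped, G0, seed = 1L) {
  ev <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("G0 must be positive semidefinite")
  set.seed(seed)
  n <- length(ped)
  L <- msqrt(G0)
  t2 <- matrix(0, 2L, n)
  F <- ped@inbreeding
  for (i in seq_len(n)) {
    s <- ped@sire[i]; d <- ped@dam[i]
    nk <- (!is.na(s)) + (!is.na(d))
    dms <- if (nk == 2L) 0.5 - 0.25 * (F[s] + F[d])
           else if (nk == 1L) 0.75 - 0.25 * F[if (is.na(s)) d else s]
           else 1
    m <- sqrt(dms) * (L %*% rnorm(2L))
    base <- 0
    if (!is.na(s)) base <- base + 0.5 * t2[, s]
    if (!is.na(d)) base <- base + 0.5 * t2[, d]
    t2[, i] <- base + m
  }
  new("SimulationTruth", aS = setNames(t2[1L, ], ped@id),
      aD = setNames(t2[2L, ], ped@id), G0 = G0, seed = as.numeric(seed))
}

#' Simulate phenotype records
#'
#' Records are generated for non-parent animals of the configured sexes
#' with both parents known:
#' \deqn{y = \mu + SD + PN + BT + b_1 x + b_2 x^2 + b_3 x^3 +
#'   a_s(\mathrm{sire}) + a_d(\mathrm{dam}) + \phi + e}
#' with the Mendelian-sampling deviation
#' \eqn{\phi \sim N(0, (1-F_s)\sigma^2_s + (1-F_d)\sigma^2_d)} absorbed
#' into the residual, exactly as the reduced model assumes. The true
#' per-record decomposition is attached as
#' \code{attr(records, "recordTruth")}.
#'
#' @param ped a [Pedigree-class]
#' @param truth a [SimulationTruth-class] generated on the same pedigree
#' @param cfg a [simulationConfig()]
#' @param seed integer seed
#' @return a trait-record data.frame (see [validateRecords()])
#' @export
simulatePhenotypes <- function(ped, truth, cfg = simulationConfig(),
                               seed = 1L) {
  set.seed(seed)
  isParent <- ped@id %in% c(ped@id[ped@sire[!is.na(ped@sire)]],
                            ped@id[ped@dam[!is.na(ped@dam)]])
  cand <- which(!isParent & ped@sex %in% cfg$recordedSexes &
                  !is.na(ped@sire) & !is.na(ped@dam) & !ped@phantom)
  if (!length(cand)) stop("no candidate animals to record")
  cand <- sample(cand)                      # shuffle before grouping
  if (!is.null(cfg$maxRecords)) cand <- head(cand, cfg$maxRecords)
  n <- length(cand)
  grp <- paste0("SD", sprintf("%03d", ceiling(seq_len(n) / cfg$groupSize)))
  grpEff <- rnorm(length(unique(grp)), 0, cfg$sdGroupEffect)
  names(grpEff) <- unique(grp)
  parity <- sample(seq_along(cfg$parityEffects), n, replace = TRUE,
                   prob = c(0.45, 0.3, 0.25)[seq_along(cfg$parityEffects)])
  bt <- ifelse(runif(n) < cfg$twinRate, "T", "S")
  age <- sample(seq(cfg$ageRange[1L], cfg$ageRange[2L]), n, replace = TRUE)
  sidx <- ped@sire[cand]; didx <- ped@dam[cand]
  Fs <- ped@inbreeding[sidx]; Fd <- ped@inbreeding[didx]
  phiVar <- (1 - Fs) * cfg$G0[1L, 1L] + (1 - Fd) * cfg$G0[2L, 2L]
  phi <- rnorm(n, 0, sqrt(phiVar))
  e <- rnorm(n, 0, sqrt(cfg$sigma2e))
  gS <- truth@aS[sidx]
  gD <- truth@aD[didx]
  fixedPart <- cfg$mu + grpEff[grp] + cfg$parityEffects[parity] +
    cfg$birthTypeEffects[bt] + cfg$ageCoef[1L] * age +
    cfg$ageCoef[2L] * age^2 + cfg$ageCoef[3L] * age^3
  y <- fixedPart + gS + gD + phi + e
  rec <- data.frame(progeny = ped@id[cand], sire = ped@id[sidx],
                    dam = ped@id[didx], group = grp, parity = parity,
                    birthType = bt, age = age, value = as.numeric(y),
                    stringsAsFactors = FALSE)
  attr(rec, "recordTruth") <- data.frame(
    progeny = rec$progeny, etaGenetic = as.numeric(gS + gD),
    phi = phi, e = e, fixedPart = as.numeric(fixedPart))
  rec
}

#' Draw a binary class for simulated records
#'
#' Logit link: the class-zero probability is
#' \eqn{p_0 = \mathrm{logit}^{-1}(b_0 + a_s(\mathrm{sire}) +
#' a_d(\mathrm{dam}))} and the class is Bernoulli. Threshold link: the
#' class is one when a Gaussian latent variable (genetic part plus
#' residual) exceeds the configured threshold.
#'
#' @param records output of [simulatePhenotypes()] (the per-record truth
#'   attribute is required)
#' @param cfg a [simulationConfig()]
#' @param seed integer seed
#' @return the records with a \code{class} column added
#' @export
simulateBinary <- function(records, cfg = simulationConfig(), seed = 1L) {
  tr <- attr(records, "recordTruth")
  if (is.null(tr))
    stop("records carry no simulation truth; use simulatePhenotypes()")
  set.seed(seed)
  n <- nrow(records)
  if (cfg$binaryLink == "logit") {
    p0 <- plogis(cfg$binaryIntercept + tr$etaGenetic)
    records$class <- 1 - rbinom(n, 1L, p0)
  } else {
    latent <- tr$etaGenetic + rnorm(n, 0, sqrt(cfg$sigma2e))
    records$class <- as.numeric(latent > cfg$binaryThreshold)
  }
  attr(records, "recordTruth") <- tr
  records
}

#' Simulate a complete analysis-ready data set
#'
#' Pedigree, gametic truth and phenotype records in one call, with
#' deterministic sub-seeds derived from \code{seed}.
#'
#' @param cfg a [simulationConfig()]
#' @param seed integer seed
#' @param binary also draw the binary class
#' @return list with elements \code{ped}, \code{truth}, \code{records}
#' @export
simulateDataset <- function(cfg = simulationConfig(), seed = 1L,
                            binary = FALSE) {
  ped <- simulatePedigree(cfg, seed)
  truth <- dropGameticEffects(ped, cfg$G0, seed + 1L)
  records <- simulatePhenotypes(ped, truth, cfg, seed + 2L)
  if (binary) records <- simulateBinary(records, cfg, seed + 3L)
  list(ped = ped, truth = truth, records = records)
}
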