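## Solving the MME at fixed components: BLUP estimates, exact PEVs,
## reliabilities and birth-year genetic trends.

#' Solve the mixed model equations
#'
#' Sparse symmetric solve of \eqn{C\theta = \mathrm{rhs}}.
#'
#' @param system a [MixedModelSystem-class]
#' @return a [SolutionSet-class] with estimates only (PEV and reliability
#'   slots are \code{NA} until [computePEV()] / [reliability()])
#' @export
solveBlup <- function(system) {
  ch <- tryCatch(Cholesky(forceSymmetric(system@coeff), LDL = FALSE,
                          perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch)) {
    fixedLv <- system@layout$level[system@layout$kind == "fixed"]
    stop("coefficient matrix is singular (confounded effects?); fixed ",
         "levels present: ", paste(head(fixedLv, 8L), collapse = ", "),
         if (length(fixedLv) > 8L) ", ...")
  }
  est <- as.numeric(solve(ch, system@rhs))
  m <- length(est)
  new("SolutionSet", estimates = est, layout = system@layout,
      kind = system@kind, pev = rep(NA_real_, m),
      reliability = rep(NA_real_, m), pecPoe = numeric(0))
}

#' Prediction error variances from the inverse coefficient matrix
#'
#' For the equivalent kind the PEV of each imprinting effect is read
#' directly from the diagonal of \eqn{C^{-1}} at the imprinting-effect
#' equation. For the imprinting kind the PEV of the parent-of-origin
#' effect additionally needs the off-diagonal prediction error covariance
#' between the TA-as-sire and TA-as-dam equations of the same animal:
#' \eqn{\mathrm{PEV}(\hat i_k) = \mathrm{PEV}(\hat a_{s,k}) +
#' \mathrm{PEV}(\hat a_{d,k}) - 2\,\mathrm{PEC}(\hat a_{s,k},
#' \hat a_{d,k})}; those covariances are returned in the \code{pecPoe}
#' slot. Both routes agree exactly.
#'
#' @param system a [MixedModelSystem-class]
#' @param solutions optional [SolutionSet-class] from [solveBlup()] (solved
#'   afresh when missing)
#' @param maxDense refuse to invert above this equation count; select a
#'   subset of animals or raise the guard deliberately
#' @return the [SolutionSet-class] with \code{pev} (and for the imprinting
#'   kind \code{pecPoe}) filled
#' @export
computePEV <- function(system, solutions = NULL, maxDense = 20000L) {
  m <- nrow(system@coeff)
  if (m > maxDense)
    stop(m, " equations exceed maxDense = ", maxDense,
         "; invert a subset or raise the guard")
  if (is.null(solutions)) solutions <- solveBlup(system)
  Ci <- as.matrix(solve(system@coeff))   # dense: vectorised extraction
  solutions@pev <- pmax(diag(Ci), 0)
  if (system@kind == "imprinting") {
    lay <- system@layout
    sEq <- lay$eq[lay$kind == "TA_as_sire"]
    dEq <- lay$eq[lay$kind == "TA_as_dam"]
    ids <- lay$level[lay$kind == "TA_as_sire"]
    solutions@pecPoe <- setNames(Ci[cbind(sEq, dEq)], ids)
  }
  solutions
}

#' PEV of the parent-of-origin effect per animal
#'
#' @param solutions a [SolutionSet-class] with PEVs computed
#' @return named vector: equivalent kind reads the imprinting-effect
#'   diagonal; imprinting kind combines the two TA PEVs with the stored
#'   prediction error covariance
#' @export
poePev <- function(solutions) {
  lay <- solutions@layout
  if (solutions@kind == "equivalent") {
    sel <- lay$kind == "imprinting_effect"
    return(setNames(solutions@pev[lay$eq[sel]], lay$level[sel]))
  }
  if (solutions@kind != "imprinting")
    stop("POE is undefined for the animal kind")
  if (!length(solutions@pecPoe))
    stop("run computePEV() first")
  sEq <- lay$eq[lay$kind == "TA_as_sire"]
  dEq <- lay$eq[lay$kind == "TA_as_dam"]
  ids <- lay$level[lay$kind == "TA_as_sire"]
  setNames(solutions@pev[sEq] + solutions@pev[dEq] -
           2 * solutions@pecPoe[ids], ids)
}

#' Parent-of-origin effect estimates per animal
#'
#' @param solutions a [SolutionSet-class]
#' @return named vector: \eqn{\hat i} directly (equivalent kind) or
#'   \eqn{\hat a_d - \hat a_s} (imprinting kind)
#' @export
poeEstimates <- function(solutions) {
  lay <- solutions@layout
  if (solutions@kind == "equivalent") {
    sel <- lay$kind == "imprinting_effect"
    return(setNames(solutions@estimates[lay$eq[sel]], lay$level[sel]))
  }
  if (solutions@kind != "imprinting")
    stop("POE is undefined for the animal kind")
  sEq <- lay$eq[lay$kind == "TA_as_sire"]
  dEq <- lay$eq[lay$kind == "TA_as_dam"]
  setNames(solutions@estimates[dEq] - solutions@estimates[sEq],
           lay$level[lay$kind == "TA_as_sire"])
}

#' Reliabilities from prediction error variances
#'
#' \eqn{r^2_k = 1 - \mathrm{PEV}_k / (a_{kk}\,\sigma^2_{\mathrm{effect}})}
#' with \eqn{a_{kk} = 1 + F_k} by default (the diagonal of the numerator
#' relationship matrix; switchable to 1), clipped to \eqn{[0, 1)}.
#'
#' @param solutions a [SolutionSet-class] with PEVs computed
#' @param vc the [VarianceComponents-class] the system was built with
#' @param ped the [Pedigree-class]
#' @param denominator \code{"1+F"} (default) or \code{"1"}
#' @return the [SolutionSet-class] with the \code{reliability} slot filled
#'   for every genetic-effect equation
#' @export
reliability <- function(solutions, vc, ped,
                        denominator = c("1+F", "1")) {
  denominator <- match.arg(denominator)
  if (all(is.na(solutions@pev))) stop("run computePEV() first")
  lay <- solutions@layout
  vcK <- if (solutions@kind == "animal")
    transformComponents(vc, "imprinting") else
    transformComponents(vc, solutions@kind)
  effVar <- switch(solutions@kind,
    imprinting = c(TA_as_sire = vcK@sigma2s, TA_as_dam = vcK@sigma2x),
    equivalent = c(TA_as_sire = vcK@sigma2s,
                   imprinting_effect = vcK@sigma2x),
    animal = c(TA = vcK@sigma2s))
  Fvec <- setNames(ped@inbreeding, ped@id)
  rel <- rep(NA_real_, length(solutions@estimates))
  for (k in names(effVar)) {
    sel <- lay$kind == k
    if (!any(sel)) next
    akk <- if (denominator == "1+F") 1 + Fvec[lay$level[sel]] else 1
    if (effVar[[k]] <= 0) next
    r2 <- 1 - solutions@pev[lay$eq[sel]] / (akk * effVar[[k]])
    rel[lay$eq[sel]] <- pmin(pmax(r2, 0), 1 - 1e-12)
  }
  solutions@reliability <- rel
  solutions
}

#' Genetic trends by birth year
#'
#' Mean TA-as-sire, TA-as-dam and parent-of-origin effect of the animals
#' born in each year. For the equivalent kind the TA-as-dam mean is
#' reconstructed as TA-as-sire + imprinting effect.
#'
#' @param solutions a [SolutionSet-class] of the imprinting or equivalent
#'   kind
#' @param ped the [Pedigree-class] (source of birth years)
#' @return data.frame with columns year, meanAs, meanAd, meanPoe, n;
#'   years without animals are omitted
#' @export
geneticTrend <- function(solutions, ped) {
  lay <- solutions@layout
  selS <- lay$kind == "TA_as_sire"
  ids <- lay$level[selS]
  aS <- solutions@estimates[lay$eq[selS]]
  if (solutions@kind == "equivalent") {
    poe <- solutions@estimates[lay$eq[lay$kind == "imprinting_effect"]]
    aD <- aS + poe
  } else if (solutions@kind == "imprinting") {
    aD <- solutions@estimates[lay$eq[lay$kind == "TA_as_dam"]]
    poe <- aD - aS
  } else stop("trend of POE needs an imprinting or equivalent fit")
  year <- ped@birthYear[match(ids, ped@id)]
  ok <- !is.na(year)
  if (!any(ok)) return(data.frame(year = integer(0), meanAs = numeric(0),
                                  meanAd = numeric(0), meanPoe = numeric(0),
                                  n = integer(0)))
  ag <- aggregate(cbind(meanAs = aS[ok], meanAd = aD[ok],
                        meanPoe = poe[ok]),
                  by = list(year = year[ok]), FUN = mean)
  cnt <- as.data.frame(table(year = year[ok]), stringsAsFactors = FALSE)
  ag$n <- cnt$Freq[match(ag$year, as.integer(cnt$year))]
  ag[order(ag$year), ]
}

#' Write a solutions file
#'
#' Delimited text with columns animal_id, effect_kind, estimate, PEV,
#' reliability.
#'
#' @param solutions a [SolutionSet-class]
#' @param path output file
#' @export
writeSolutions <- function(solutions, path) {
  lay <- solutions@layout
  sel <- !lay$kind %in% c("fixed")
  write.table(data.frame(animal_id = lay$level[sel],
                         effect_kind = lay$kind[sel],
                         estimate = solutions@estimates[lay$eq[sel]],
                         pev = solutions@pev[lay$eq[sel]],
                         reliability = solutions@reliability[lay$eq[sel]]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}
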