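#' @import methods
#' @import Matrix
#' @importFrom stats model.matrix rnorm runif rbinom rpois plogis qlogis var
#'   pchisq aggregate setNames qnorm sd cor
#' @importFrom utils read.table write.table
NULL

## ---------------------------------------------------------------------------
## Pedigree
## ---------------------------------------------------------------------------

#' Pedigree of a population
#'
#' An ordered pedigree: every parent precedes all of its offspring, parent
#' links are stored as integer positions (\code{NA} for unknown), and
#' inbreeding coefficients (Meuwissen--Luo) are cached at construction.
#' Phantom records are placeholders materialised for unknown parents when
#' genetic-group assignment is requested; they carry \code{phantom = TRUE}.
#'
#' @slot id animal identifiers (opaque strings), topologically ordered
#' @slot sire,dam integer positions of the parents within \code{id}
#'   (\code{NA} = unknown)
#' @slot sex \code{"M"}, \code{"F"} or \code{"U"}
#' @slot birthYear integer birth year, \code{NA} if missing
#' @slot phantom logical, \code{TRUE} for phantom-parent placeholders
#' @slot inbreeding inbreeding coefficient F per animal
#'
#' @seealso [readPedigree()], [computeInbreeding()], [buildAInverse()]
#' @export
setClass("Pedigree", representation(
  id = "character", sire = "integer", dam = "integer", sex = "character",
  birthYear = "integer", phantom = "logical", inbreeding = "numeric"
))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  lens <- c(length(object@sire), length(object@dam), length(object@sex),
            length(object@birthYear), length(object@phantom),
            length(object@inbreeding))
  if (any(lens != n)) return("slot lengths differ")
  if (anyDuplicated(object@id)) return("duplicate animal identifiers")
  if (n == 0L) return(TRUE)
  pa <- c(object@sire, object@dam)
  pa <- pa[!is.na(pa)]
  if (length(pa) && (min(pa) < 1L || max(pa) > n))
    return("parent index out of range")
  ## topological: parents strictly precede offspring (also rules out cycles
  ## and self-ancestry)
  bad <- which(!is.na(object@sire) & object@sire >= seq_len(n) |
               !is.na(object@dam) & object@dam >= seq_len(n))
  if (length(bad))
    return(sprintf("pedigree not parent-first ordered at animal '%s'",
                   object@id[bad[1L]]))
  if (!all(object@sex %in% c("M", "F", "U"))) return("sex must be M, F or U")
  both <- intersect(object@sire, object@dam)
  both <- both[!is.na(both)]
  if (length(both))
    return(sprintf("animal '%s' appears as both sire and dam",
                   object@id[both[1L]]))
  TRUE
})

#' @describeIn Pedigree number of animals (phantoms included)
#' @param x a \code{Pedigree}
#' @export
setMethod("length", "Pedigree", function(x) length(x@id))

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree with", length(object), "animals (",
      sum(object@phantom), "phantoms ),",
      sum(is.na(object@sire) & is.na(object@dam) & !object@phantom),
      "founders\n")
  cat("  max F =", format(max(c(0, object@inbreeding)), digits = 4), "\n")
})

#' @describeIn Pedigree pedigree as a data.frame with identifier parent
#'   columns
#' @export
setMethod("as.data.frame", "Pedigree", function(x, ...) {
  data.frame(animal = x@id,
             sire = ifelse(is.na(x@sire), NA_character_, x@id[x@sire]),
             dam = ifelse(is.na(x@dam), NA_character_, x@id[x@dam]),
             sex = x@sex, birthYear = x@birthYear, phantom = x@phantom,
             F = x@inbreeding, stringsAsFactors = FALSE)
})

#' @rdname pedigreeAccessors
#' @title Pedigree accessors
#' @description Extract identifiers or cached inbreeding coefficients.
#' @param ped a \code{Pedigree}
#' @return `pedIds()` the identifier vector; `inbreeding()` the named vector
#'   of inbreeding coefficients.
#' @export
pedIds <- function(ped) ped@id

#' @rdname pedigreeAccessors
#' @export
inbreeding <- function(ped) setNames(ped@inbreeding, ped@id)

## ---------------------------------------------------------------------------
## GroupAssignment
## ---------------------------------------------------------------------------

#' Phantom-parent genetic group assignment
#'
#' Maps every phantom parent to one genetic group defined by sex and a
#' birth-year bin (Westell--Van Vleck style cohort groups).
#'
#' @slot phantomId phantom identifiers
#' @slot group group label per phantom (parallel to \code{phantomId})
#' @slot levels ordered vector of all group labels (both sex sets)
#' @slot binning the binning configuration used (see [groupBinning()])
#' @export
setClass("GroupAssignment", representation(
  phantomId = "character", group = "character", levels = "character",
  binning = "list"
))

setValidity("GroupAssignment", function(object) {
  if (length(object@phantomId) != length(object@group))
    return("phantomId and group lengths differ")
  if (anyDuplicated(object@phantomId))
    return("a phantom may carry only one group")
  if (!all(object@group %in% object@levels))
    return("group label outside declared levels")
  TRUE
})

setMethod("show", "GroupAssignment", function(object) {
  cat("GroupAssignment:", length(object@phantomId), "phantoms in",
      length(unique(object@group)), "of", length(object@levels),
      "groups\n")
})

## ---------------------------------------------------------------------------
## RelationshipInverse
## ---------------------------------------------------------------------------

#' Sparse inverse numerator relationship matrix
#'
#' Holds A-inverse built by Henderson's rules with inbreeding, optionally
#' augmented with genetic-group rows (Quaas--Pollak/Westell). Row order is
#' animals (non-phantom when grouped) followed by group labels.
#'
#' @slot matrix sparse symmetric matrix
#' @slot ids row identifiers (animals then groups)
#' @slot groupLabels labels of the appended group rows (may be empty)
#' @slot logDetA log-determinant of A (animals only; \code{NA} when grouped
#'   rows are present and the determinant is not meaningful)
#' @export
setClass("RelationshipInverse", representation(
  matrix = "ANY", ids = "character", groupLabels = "character",
  logDetA = "numeric"
))

setValidity("RelationshipInverse", function(object) {
  if (!inherits(object@matrix, "Matrix"))
    return("matrix slot must be a sparse Matrix")
  TRUE
})

setMethod("show", "RelationshipInverse", function(object) {
  cat("RelationshipInverse:", length(object@ids), "rows (",
      length(object@groupLabels), "group rows ), nnz =",
      length(object@matrix@x), "\n")
})

## ---------------------------------------------------------------------------
## VarianceComponents
## ---------------------------------------------------------------------------

#' Variance components on the transmitting-ability scale
#'
#' Two parameterisations of the same 2x2 genetic covariance matrix G0 plus a
#' residual variance. In the \emph{imprinting} parameterisation G0 holds the
#' TA-as-sire variance, the sire--dam covariance and the TA-as-dam variance;
#' in the \emph{equivalent} parameterisation it holds the TA-as-sire
#' variance, the covariance between TA-as-sire and the imprinting effect,
#' and the imprinting-effect variance. [transformComponents()] maps between
#' the two exactly.
#'
#' @slot parameterisation \code{"imprinting"} or \code{"equivalent"}
#' @slot sigma2s TA-as-sire variance (shared by both parameterisations)
#' @slot sigma2x TA-as-dam variance (imprinting) or imprinting-effect
#'   variance (equivalent)
#' @slot sigmacov sire--dam covariance (imprinting) or sire--imprinting
#'   covariance (equivalent)
#' @slot sigma2e residual variance
#' @export
setClass("VarianceComponents", representation(
  parameterisation = "character", sigma2s = "numeric", sigma2x = "numeric",
  sigmacov = "numeric", sigma2e = "numeric"
))

setValidity("VarianceComponents", function(object) {
  if (!object@parameterisation %in% c("imprinting", "equivalent"))
    return("parameterisation must be 'imprinting' or 'equivalent'")
  v <- c(object@sigma2s, object@sigma2x, object@sigmacov, object@sigma2e)
  if (any(!is.finite(v))) return("components must be finite")
  if (object@sigma2s < 0 || object@sigma2e < 0)
    return("variances must be non-negative")
  ## the imprinting-effect "variance" of the equivalent parameterisation
  ## may be estimated negative when the unconstrained G0 is indefinite;
  ## the TA-as-dam variance of the imprinting parameterisation may not
  if (object@parameterisation == "imprinting" && object@sigma2x < 0)
    return("variances must be non-negative")
  TRUE
})

setMethod("show", "VarianceComponents", function(object) {
  if (object@parameterisation == "imprinting") {
    cat(sprintf(
      "VarianceComponents (imprinting): s2_s=%.4g s_sd=%.4g s2_d=%.4g s2_e=%.4g\n",
      object@sigma2s, object@sigmacov, object@sigma2x, object@sigma2e))
  } else {
    cat(sprintf(
      "VarianceComponents (equivalent): s2_s=%.4g s_si=%.4g s2_i=%.4g s2_e=%.4g\n",
      object@sigma2s, object@sigmacov, object@sigma2x, object@sigma2e))
  }
})

## ---------------------------------------------------------------------------
## MixedModelSystem
## ---------------------------------------------------------------------------

#' Assembled mixed model equations
#'
#' Sparse symmetric coefficient matrix, right-hand side and the map from
#' (effect kind, level) to equation number for one of the three model kinds.
#'
#' @slot coeff sparse symmetric coefficient matrix
#' @slot rhs right-hand side
#' @slot layout data.frame with columns \code{kind} (\code{"fixed"},
#'   \code{"group"}, \code{"TA_as_sire"}, \code{"TA_as_dam"},
#'   \code{"imprinting_effect"}, \code{"TA"}), \code{level}, \code{eq}
#' @slot kind model kind (\code{"imprinting"}, \code{"equivalent"},
#'   \code{"animal"})
#' @slot W diagonal Mendelian-sampling residual weights (one per record)
#' @slot vc the [VarianceComponents-class] used
#' @slot aux bookkeeping needed by the REML likelihood (n, p, log|R|,
#'   log|G|, y'R^-1 y, ...)
#' @export
setClass("MixedModelSystem", representation(
  coeff = "ANY", rhs = "numeric", layout = "data.frame", kind = "character",
  W = "numeric", vc = "VarianceComponents", aux = "list"
))

setValidity("MixedModelSystem", function(object) {
  if (!inherits(object@coeff, "Matrix"))
    return("C must be a sparse Matrix")
  if (nrow(object@coeff) != length(object@rhs))
    return("C and rhs dimensions differ")
  TRUE
})

setMethod("show", "MixedModelSystem", function(object) {
  cat("MixedModelSystem (", object@kind, "):", nrow(object@coeff),
      "equations,", object@aux$n, "records\n")
})

## ---------------------------------------------------------------------------
## SolutionSet
## ---------------------------------------------------------------------------

#' BLUP solutions with prediction error variances and reliabilities
#'
#' @slot estimates solution vector, one entry per equation
#' @slot layout equation map inherited from the [MixedModelSystem-class]
#' @slot kind model kind
#' @slot pev prediction error variance per equation (\code{NA} until
#'   [computePEV()] fills it)
#' @slot reliability reliability per equation (\code{NA} until
#'   [reliability()] fills it)
#' @slot pecPoe for the imprinting kind: per-animal prediction error
#'   covariance between the TA-as-sire and TA-as-dam estimates (named by
#'   animal id); empty otherwise
#' @export
setClass("SolutionSet", representation(
  estimates = "numeric", layout = "data.frame", kind = "character",
  pev = "numeric", reliability = "numeric", pecPoe = "numeric"
))

setMethod("show", "SolutionSet", function(object) {
  cat("SolutionSet (", object@kind, "):", length(object@estimates),
      "equations;", if (all(is.na(object@pev))) "PEV not computed"
      else "PEV available", "\n")
})

#' Extract one effect kind from a SolutionSet
#'
#' @param solutions a [SolutionSet-class]
#' @param kind effect kind as in the layout (e.g. \code{"TA_as_sire"},
#'   \code{"imprinting_effect"})
#' @return data.frame with level, estimate and (when computed) PEV and
#'   reliability
#' @export
effectTable <- function(solutions, kind) {
  sel <- solutions@layout$kind == kind
  data.frame(level = solutions@layout$level[sel],
             estimate = solutions@estimates[solutions@layout$eq[sel]],
             pev = solutions@pev[solutions@layout$eq[sel]],
             reliability = solutions@reliability[solutions@layout$eq[sel]],
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## RemlFit / RlrtResult
## ---------------------------------------------------------------------------

#' A converged (or diagnosed) REML fit
#'
#' @slot vc estimated [VarianceComponents-class]
#' @slot kind model kind
#' @slot loglik REML log-likelihood at the estimates
#' @slot aiCov asymptotic covariance of the component estimates from the
#'   final average-information matrix (named rows/columns)
#' @slot converged logical
#' @slot iterations iteration count
#' @slot trajectory per-iteration components and log-likelihood
#' @slot boundary names of components pinned at the boundary
#' @slot dataHash fingerprint of (n, sum of y) used to guard [rlrt()]
#' @export
setClass("RemlFit", representation(
  vc = "VarianceComponents", kind = "character", loglik = "numeric",
  aiCov = "matrix", converged = "logical", iterations = "integer",
  trajectory = "data.frame", boundary = "character", dataHash = "numeric"
))

setMethod("show", "RemlFit", function(object) {
  cat("RemlFit (", object@kind, "): logL =",
      format(object@loglik, digits = 8), "in", object@iterations,
      "iterations;", if (object@converged) "converged" else "NOT converged",
      "\n")
  show(object@vc)
})

#' REML likelihood-ratio test result
#'
#' @slot statistic 2 * (logL_full - logL_null), clipped at zero
#' @slot df degrees of freedom of the conservative chi-square reference (2)
#' @slot pValue upper-tail probability
#' @slot loglikFull,loglikNull the two log-likelihoods
#' @export
setClass("RlrtResult", representation(
  statistic = "numeric", df = "numeric", pValue = "numeric",
  loglikFull = "numeric", loglikNull = "numeric"
))

setMethod("show", "RlrtResult", function(object) {
  cat(sprintf("RLRT = %.4f on %g DF, P = %.4g\n", object@statistic,
              object@df, object@pValue))
})

## ---------------------------------------------------------------------------
## Simulation truth / PQL state
## ---------------------------------------------------------------------------

#' Generating truth of a gene-dropping simulation
#'
#' @slot aS,aD true transmitting abilities (as sire / as dam) per pedigree
#'   animal, named by id
#' @slot G0 the generating 2x2 TA covariance matrix
#' @slot seed the seed used
#' @export
setClass("SimulationTruth", representation(
  aS = "numeric", aD = "numeric", G0 = "matrix", seed = "numeric"
))

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth for", length(object@aS), "animals\n")
})

#' State of a converged penalised quasi-likelihood fit
#'
#' @slot eta linear predictor per record at convergence
#' @slot p class-zero probability per record
#' @slot working final working variable
#' @slot weights working weights p(1-p)
#' @slot innerFit the [RemlFit-class] on the working (logit) scale
#' @slot solutions BLUP solutions at the final components
#' @slot outerIterations outer iteration count
#' @slot converged logical
#' @slot kind model kind used for the genetic part
#' @export
setClass("PqlState", representation(
  eta = "numeric", p = "numeric", working = "numeric", weights = "numeric",
  innerFit = "RemlFit", solutions = "SolutionSet",
  outerIterations = "integer", converged = "logical", kind = "character"
))

setMethod("show", "PqlState", function(object) {
  cat("PqlState (", object@kind, "):", object@outerIterations,
      "outer iterations;", if (object@converged) "converged"
      else "NOT converged", "\n")
  show(object@innerFit@vc)
})
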