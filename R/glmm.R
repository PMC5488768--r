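## Binary carcass-grade analysis: logit-link penalised quasi-likelihood on
## top of the linear-model machinery.

#' Collapse ordered carcass categories to a binary class
#'
#' Conformation grades E, U and R (the better carcasses) map to class
#' zero, O and P to class one; fat scores 1 and 2 map to class zero,
#' 3--5 to class one. The mapping can be overridden.
#'
#' @param records trait records whose \code{value} column holds the
#'   categories (EUROP letters or fat scores)
#' @param trait \code{"conformation"} or \code{"fatness"}
#' @param mapping optional named vector category -> class (0/1)
#' @return the records with a \code{class} column added
#' @examples
#' r <- data.frame(progeny = "p", sire = "s", dam = "d", group = "g",
#'                 parity = 1, birthType = "S", age = 450, value = "R")
#' binarize(r, "conformation")$class
#' @export
binarize <- function(records, trait = c("conformation", "fatness"),
                     mapping = NULL) {
  trait <- match.arg(trait)
  if (is.null(mapping)) {
    mapping <- if (trait == "conformation")
      c(E = 0, U = 0, R = 0, O = 1, P = 1)
    else c("1" = 0, "2" = 0, "3" = 1, "4" = 1, "5" = 1)
  }
  v <- as.character(records$value)
  unknown <- setdiff(unique(v), names(mapping))
  if (length(unknown))
    stop("unknown category '", unknown[1L], "' for trait ", trait)
  records$class <- as.numeric(mapping[v])
  records
}

#' Class-zero probability under the logit link
#'
#' \eqn{p = 1/(1 + e^{-\eta})}: the probability that a record falls into
#' class zero given its linear predictor. Strictly monotone in \eqn{\eta}.
#'
#' @param eta linear predictor
#' @return probability in (0, 1)
#' @export
logitProbability <- function(eta) plogis(eta)

#' Penalised quasi-likelihood fit of the binary imprinting model
#'
#' Iterates the standard PQL loop for a logit-link animal model: from the
#' current linear predictor \eqn{\eta}, form \eqn{p = \mathrm{logit}^{-1}
#' (\eta)}, the working variable \eqn{\zeta = \eta + (t - p)/(p(1-p))}
#' (with \eqn{t = 1} for class-zero records) and the working weights
#' \eqn{p(1-p)}; fit the linear mixed model of the requested kind to
#' \eqn{\zeta} by REML with residual variance fixed at 1 and heterogeneous
#' residual weights \eqn{1/(p(1-p))} (no Mendelian-sampling inflation on
#' the quasi-likelihood scale); update \eqn{\eta} from the BLUP solutions
#' and repeat until the working variable stabilises. The returned
#' components live on the underlying logit scale.
#'
#' @param records trait records with a binary \code{class} column (see
#'   [binarize()])
#' @param ped a [Pedigree-class]
#' @param kind genetic model kind
#' @param start optional starting [VarianceComponents-class] on the logit
#'   scale
#' @param outerTol convergence tolerance on max |change| of the working
#'   variable
#' @param maxOuter maximum outer iterations
#' @param control inner REML control; the residual is always fixed at 1
#' @param etaGuard linear predictors beyond this magnitude raise a
#'   separation error naming the offending comparison-group cells
#' @return a [PqlState-class]
#' @export
pqlFit <- function(records, ped,
                   kind = c("imprinting", "equivalent", "animal"),
                   start = NULL, outerTol = 1e-6, maxOuter = 50L,
                   control = remlControl(tolLoglik = 1e-10,
                                         tolPar = 1e-8),
                   etaGuard = 15) {
  kind <- match.arg(kind)
  if (!"class" %in% names(records))
    stop("records need a binary 'class' column; see binarize()")
  if (!all(records$class %in% c(0, 1)))
    stop("class must be 0/1")
  records$.t <- as.numeric(records$class == 0)
  n <- nrow(records)
  control$fixResidual <- 1
  eta <- rep(qlogis((sum(records$.t) + 0.5) / (n + 1)), n)
  zeta <- NULL
  fit <- NULL
  startVc <- start
  converged <- FALSE
  it <- 0L
  ainv <- buildAInverse(ped)
  for (it in seq_len(maxOuter)) {
    if (any(abs(eta) > etaGuard)) {
      bad <- unique(records$group[abs(eta) > etaGuard])
      stop("separation: linear predictor pinned in comparison group(s) ",
           paste(head(bad, 5L), collapse = ", "))
    }
    p <- plogis(eta)
    p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
    v <- p * (1 - p)
    zetaNew <- eta + (records$.t - p) / v
    if (!is.null(zeta) && max(abs(zetaNew - zeta)) < outerTol) {
      converged <- TRUE
      break
    }
    zeta <- zetaNew
    records$.zeta <- zeta
    ctlIt <- control
    if (!is.null(startVc)) {
      ctlIt$algorithm <- "AI"                        # warm-started
      ## early working variables are provisional; polish only once the
      ## outer loop is close to its fixed point
      if (it <= 3L) ctlIt$maxIter <- 10L
    }
    fit <- fitReml(records, ped, kind, start = startVc, control = ctlIt,
                   response = ".zeta", weights = 1 / v, mendelian = FALSE)
    ## the solve step needs a positive-definite genetic covariance even
    ## when the unconstrained working-scale fit strays outside the cone
    ## (the animal kind has a scalar G0 and needs no projection)
    vcSolve <- if (kind == "animal") fit@vc else psdProjectVc(fit@vc)
    startVc <- vcSolve
    design <- buildDesign(records, kind, ped, response = ".zeta")
    sys <- assembleMME(kind, design, vcSolve, ainv, W = 1 / v)
    sol <- solveBlup(sys)
    lay <- sol@layout
    etaFix <- as.numeric(design$X %*%
                           sol@estimates[lay$eq[lay$kind == "fixed"]])
    etaGen <- numeric(n)
    for (k in names(design$Z)) {
      u <- sol@estimates[lay$eq[lay$kind == k]]
      ## map from ainv row order to pedigree order used by Z columns
      uPed <- u[match(design$ids, lay$level[lay$kind == k])]
      etaGen <- etaGen + as.numeric(design$Z[[k]] %*% uPed)
    }
    eta <- etaFix + etaGen
  }
  p <- plogis(eta)
  sol <- computePEV(sys, sol)
  sol <- reliability(sol, fit@vc, ped)
  new("PqlState", eta = eta, p = p, working = zeta,
      weights = p * (1 - p), innerFit = fit, solutions = sol,
      outerIterations = it, converged = converged, kind = kind)
}
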