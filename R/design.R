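## Variance-component parameterisations, design matrices and assembly of the
## mixed model equations for the three model kinds.

#' Variance-component constructors
#'
#' @param sigma2s TA-as-sire variance
#' @param sigma2d TA-as-dam variance
#' @param sigmasd covariance between TA-as-sire and TA-as-dam
#' @param sigma2e residual variance
#' @return a [VarianceComponents-class]
#' @examples
#' vc <- imprintingComponents(1, 1, 0.9, 4)
#' transformComponents(vc, "equivalent")
#' @export
imprintingComponents <- function(sigma2s, sigma2d, sigmasd, sigma2e) {
  new("VarianceComponents", parameterisation = "imprinting",
      sigma2s = sigma2s, sigma2x = sigma2d, sigmacov = sigmasd,
      sigma2e = sigma2e)
}

#' @rdname imprintingComponents
#' @param sigma2i imprinting-effect variance
#' @param sigmasi covariance between TA-as-sire and the imprinting effect
#' @export
equivalentComponents <- function(sigma2s, sigma2i, sigmasi, sigma2e) {
  new("VarianceComponents", parameterisation = "equivalent",
      sigma2s = sigma2s, sigma2x = sigma2i, sigmacov = sigmasi,
      sigma2e = sigma2e)
}

#' @rdname imprintingComponents
#' @param sigma2u TA variance of the animal-model null (TA as sire and as
#'   dam coincide)
#' @export
animalComponents <- function(sigma2u, sigma2e) {
  imprintingComponents(sigma2u, sigma2u, sigma2u, sigma2e)
}

#' The 2x2 genetic covariance matrix G0 of a parameterisation
#'
#' @param vc a [VarianceComponents-class]
#' @return symmetric 2x2 matrix (order: TA-as-sire, then TA-as-dam or the
#'   imprinting effect depending on the parameterisation)
#' @export
G0matrix <- function(vc) {
  matrix(c(vc@sigma2s, vc@sigmacov, vc@sigmacov, vc@sigma2x), 2L, 2L,
         dimnames = if (vc@parameterisation == "imprinting")
           list(c("s", "d"), c("s", "d")) else
           list(c("s", "i"), c("s", "i")))
}

#' Convert between the imprinting and equivalent parameterisations
#'
#' The map is linear and exact: the imprinting-effect variance is
#' \eqn{\sigma^2_i = \sigma^2_s + \sigma^2_d - 2\sigma_{sd}} and the
#' covariance between the TA as sire and the imprinting effect is
#' \eqn{\sigma_{si} = \sigma_{sd} - \sigma^2_s}; the TA-as-sire and
#' residual variances are unchanged. The inverse map recovers
#' \eqn{\sigma^2_d = \sigma^2_s + \sigma^2_i + 2\sigma_{si}} and
#' \eqn{\sigma_{sd} = \sigma^2_s + \sigma_{si}}. The round trip is the
#' identity.
#'
#' @param vc a [VarianceComponents-class]
#' @param to target parameterisation
#' @return a [VarianceComponents-class] in the target parameterisation
#' @export
transformComponents <- function(vc, to = c("equivalent", "imprinting")) {
  to <- match.arg(to)
  if (vc@parameterisation == to) return(vc)
  if (to == "equivalent") {
    equivalentComponents(
      sigma2s = vc@sigma2s,
      sigma2i = vc@sigma2s + vc@sigma2x - 2 * vc@sigmacov,
      sigmasi = vc@sigmacov - vc@sigma2s,
      sigma2e = vc@sigma2e)
  } else {
    imprintingComponents(
      sigma2s = vc@sigma2s,
      sigma2d = vc@sigma2s + vc@sigma2x + 2 * vc@sigmacov,
      sigmasd = vc@sigma2s + vc@sigmacov,
      sigma2e = vc@sigma2e)
  }
}

#' Derived genetic parameters of the imprinting model
#'
#' From the imprinting-parameterisation components: imprinting variance
#' \eqn{\sigma^2_i = \sigma^2_s + \sigma^2_d - 2\sigma_{sd}}, total
#' additive genetic variance \eqn{\sigma^2_a = \sigma^2_s + \sigma^2_d +
#' 2\sigma_{sd}}, correlation between parental effects, the relative
#' imprinting variance \eqn{100\,\sigma^2_i/\sigma^2_a} (percent), the
#' paternal and maternal gametic contributions
#' \eqn{100(\sigma^2_s-\sigma_{sd})/\sigma^2_i} and
#' \eqn{100(\sigma^2_d-\sigma_{sd})/\sigma^2_i} (which always sum to 100
#' and may individually be negative at partially imprinted loci), and the
#' heritability \eqn{h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)}.
#'
#' When G0 is indefinite beyond \code{psdTol}, it is projected to the
#' nearest positive semidefinite matrix before the ratios are formed, with
#' a warning.
#'
#' @param vc a [VarianceComponents-class]
#' @param psdTol tolerance for the PSD projection, relative to the largest
#'   eigenvalue
#' @return named list with elements \code{sigma2i}, \code{sigma2a},
#'   \code{rsd}, \code{relImprinting}, \code{contribPaternal},
#'   \code{contribMaternal}, \code{h2}. Contributions are \code{NA} when
#'   \eqn{\sigma^2_i = 0}.
#' @export
derivedGeneticParameters <- function(vc, psdTol = 1e-8) {
  vc <- transformComponents(vc, "imprinting")
  G0 <- G0matrix(vc)
  ev <- eigen(G0, symmetric = TRUE)
  if (min(ev$values) < -psdTol * max(abs(ev$values), 1)) {
    warning("G0 indefinite; projected to the nearest PSD matrix for ",
            "derived parameters")
    lam <- pmax(ev$values, 0)
    G0 <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
  }
  s2s <- G0[1, 1]; s2d <- G0[2, 2]; ssd <- G0[1, 2]
  sigma2i <- s2s + s2d - 2 * ssd
  sigma2a <- s2s + s2d + 2 * ssd
  rsd <- if (s2s > 0 && s2d > 0) ssd / sqrt(s2s * s2d) else NA_real_
  rel <- if (sigma2a > 0) 100 * sigma2i / sigma2a else NA_real_
  if (sigma2i > 0) {
    cp <- 100 * (s2s - ssd) / sigma2i
    cm <- 100 * (s2d - ssd) / sigma2i
  } else {
    cp <- NA_real_; cm <- NA_real_
  }
  h2 <- sigma2a / (sigma2a + vc@sigma2e)
  list(sigma2i = sigma2i, sigma2a = sigma2a, rsd = rsd,
       relImprinting = rel, contribPaternal = cp, contribMaternal = cm,
       h2 = h2)
}

## ---------------------------------------------------------------------------
## Trait records
## ---------------------------------------------------------------------------

recordColumns <- c("progeny", "sire", "dam", "group", "parity",
                   "birthType", "age", "value")

#' Validate a trait-record table
#'
#' Trait records are a plain data.frame with columns \code{progeny},
#' \code{sire}, \code{dam}, \code{group} (comparison group: fattening farm
#' by slaughter date), \code{parity}, \code{birthType}, \code{age}
#' (slaughter age in days), \code{value}, and optionally \code{class}
#' (binary 0/1).
#'
#' @param records data.frame
#' @return the records, invisibly, after checking
#' @export
validateRecords <- function(records) {
  miss <- setdiff(recordColumns, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$age) | records$age <= 0))
    stop("slaughter age must be finite and positive")
  same <- !is.na(records$sire) & !is.na(records$dam) &
    records$sire == records$dam
  if (any(same))
    stop("record with sire equal to dam for progeny '",
         records$progeny[which(same)[1L]], "'")
  invisible(records)
}

## ---------------------------------------------------------------------------
## Design matrices
## ---------------------------------------------------------------------------

#' Build design matrices for one model kind
#'
#' The fixed part is always comparison group + parity + birth type
#' (indicator columns, first level dropped) plus a centred cubic regression
#' on slaughter age. The genetic part depends on the kind:
#' \describe{
#'   \item{imprinting}{\code{Zs} one 1 per row in the sire column,
#'     \code{Zd} one 1 in the dam column;}
#'   \item{equivalent}{\code{Zs} ones in \emph{both} the sire and dam
#'     columns (TA-as-sire of both parents), \code{Zi} one 1 in the dam
#'     column (imprinting effect of the dam);}
#'   \item{animal}{a single TA effect with ones in the sire and dam
#'     columns.}
#' }
#'
#' @param records validated trait records (see [validateRecords()])
#' @param ped a [Pedigree-class] containing every sire and dam
#' @param kind model kind
#' @param response which column to use as y (default \code{"value"})
#' @return an internal design list (y, X, Z blocks, parent indices,
#'   parental inbreeding per record, the pedigree ids indexing Z columns)
#' @export
buildDesign <- function(records,
                        kind = c("imprinting", "equivalent", "animal"),
                        ped, response = "value") {
  kind <- match.arg(kind)
  validateRecords(records)
  sidx <- match(records$sire, ped@id)
  didx <- match(records$dam, ped@id)
  if (anyNA(sidx) || anyNA(didx)) {
    off <- records$progeny[which(is.na(sidx) | is.na(didx))[1L]]
    stop("record for progeny '", off,
         "' has a sire or dam without a pedigree entry")
  }
  n <- nrow(records)
  fixed <- list()
  for (f in c("group", "parity", "birthType")) {
    v <- factor(records[[f]])
    if (nlevels(v) >= 2L) fixed[[f]] <- v
  }
  X <- if (length(fixed)) {
    model.matrix(~ ., data = as.data.frame(fixed))
  } else {
    matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }
  xc <- records$age - mean(records$age)
  if (length(unique(records$age)) > 1L)   # constant age: no regression
    X <- cbind(X, age1 = xc, age2 = xc^2, age3 = xc^3)
  q <- length(ped)
  Zs1 <- sparseMatrix(i = seq_len(n), j = sidx, x = 1, dims = c(n, q))
  Zd1 <- sparseMatrix(i = seq_len(n), j = didx, x = 1, dims = c(n, q))
  Z <- switch(kind,
    imprinting = list(TA_as_sire = Zs1, TA_as_dam = Zd1),
    equivalent = list(TA_as_sire = Zs1 + Zd1, imprinting_effect = Zd1),
    animal = list(TA = Zs1 + Zd1))
  list(kind = kind, y = as.numeric(records[[response]]), X = X, Z = Z,
       sidx = sidx, didx = didx,
       Fs = ped@inbreeding[sidx], Fd = ped@inbreeding[didx],
       ids = ped@id, n = n, ageCenter = mean(records$age))
}

#' Mendelian-sampling residual weights
#'
#' In the reduced (parents-only) model the Mendelian-sampling deviation of
#' each slaughtered bull is absorbed into its residual, inflating the
#' residual variance of record k to
#' \eqn{\sigma^2_e + (1-F_{s(k)})\sigma^2_s + (1-F_{d(k)})\sigma^2_d}.
#' The diagonal weight returned is \eqn{w_k = 1 + [(1-F_{s(k)})\sigma^2_s +
#' (1-F_{d(k)})\sigma^2_d]/\sigma^2_e}, so that the residual covariance
#' used throughout is \eqn{R = \mathrm{diag}(w_k)\,\sigma^2_e}.
#'
#' @param Fs,Fd inbreeding coefficients of each record's sire and dam
#' @param vc a [VarianceComponents-class] in the imprinting
#'   parameterisation (TA scale)
#' @return numeric vector of weights, all \eqn{\ge 1}
#' @examples
#' mendelianWeights(0, 0, imprintingComponents(0.25, 0.25, 0.2, 1))
#' @export
mendelianWeights <- function(Fs, Fd, vc) {
  if (vc@parameterisation != "imprinting")
    stop("mendelianWeights expects the imprinting parameterisation; ",
         "use transformComponents() first")
  if (vc@sigma2e <= 0) stop("sigma2e must be positive")
  1 + ((1 - Fs) * vc@sigma2s + (1 - Fd) * vc@sigma2x) / vc@sigma2e
}

## project the genetic covariance of a parameterisation onto the PSD cone
## (tiny ridge), leaving the residual variance untouched
psdProjectVc <- function(vc, eps = 1e-8) {
  G0 <- G0matrix(vc)
  ev <- eigen(G0, symmetric = TRUE)
  if (min(ev$values) > eps * max(abs(ev$values), 1)) return(vc)
  lam <- pmax(ev$values, eps * max(abs(ev$values), 1))
  G <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
  if (vc@parameterisation == "imprinting")
    imprintingComponents(G[1, 1], G[2, 2], G[1, 2], vc@sigma2e)
  else equivalentComponents(G[1, 1], G[2, 2], G[1, 2], vc@sigma2e)
}

modelWeights <- function(design, vc) {
  mendelianWeights(design$Fs, design$Fd,
                   transformComponents(vc, "imprinting"))
}

## ---------------------------------------------------------------------------
## MME assembly
## ---------------------------------------------------------------------------

#' Assemble the mixed model equations
#'
#' Builds the sparse symmetric coefficient matrix
#' \deqn{C = \begin{pmatrix} X'R^{-1}X & X'R^{-1}Z \\ Z'R^{-1}X &
#'   Z'R^{-1}Z + G_0^{-1} \otimes A^{-1} \end{pmatrix}}
#' and right-hand side \eqn{(X'R^{-1}y;\; Z'R^{-1}y)} with
#' \eqn{R = \mathrm{diag}(w_k)\sigma^2_e}. For the animal kind the genetic
#' block is \eqn{Z'R^{-1}Z + A^{-1}/\sigma^2_u}. Genetic-group equations
#' are part of \code{ainv} when it was built with groups; the corresponding
#' Z columns are zero.
#'
#' @param kind model kind
#' @param design output of [buildDesign()] with a matching kind
#' @param vc a [VarianceComponents-class] whose parameterisation matches
#'   the kind (imprinting kind: imprinting; equivalent kind: equivalent;
#'   animal kind: equal sire/dam entries, see [animalComponents()])
#' @param ainv a [RelationshipInverse-class] over the same pedigree
#' @param W Mendelian-sampling weights (default recomputed from \code{vc})
#' @return a [MixedModelSystem-class]; \code{aux$lambda} holds the
#'   block of lambda coefficients (\eqn{\sigma^2_e G_0^{-1}}) that,
#'   Kronecker-multiplied with \eqn{A^{-1}}, penalises the genetic
#'   equations when the records are weighted by \eqn{W^{-1}}
#' @export
assembleMME <- function(kind = c("imprinting", "equivalent", "animal"),
                        design, vc, ainv, W = NULL) {
  kind <- match.arg(kind)
  if (design$kind != kind) stop("design was built for kind '", design$kind,
                                "', not '", kind, "'")
  grouped <- length(ainv@groupLabels) > 0L
  qa <- length(design$ids)                    # animals (incl. phantoms)
  if (kind == "animal") {
    if (vc@parameterisation != "imprinting" ||
        abs(vc@sigma2s - vc@sigma2x) > 1e-12 * max(vc@sigma2s, 1) ||
        abs(vc@sigma2s - vc@sigmacov) > 1e-12 * max(vc@sigma2s, 1))
      stop("animal kind needs equal sire/dam components; ",
           "use animalComponents()")
    G0 <- matrix(vc@sigma2s, 1L, 1L)
  } else {
    expect <- kind
    if (vc@parameterisation != expect)
      stop("variance components are in the '", vc@parameterisation,
           "' parameterisation but the model kind is '", kind, "'")
    G0 <- G0matrix(vc)
  }
  if (abs(det(G0)) < 1e-12 * max(diag(G0), 1)^nrow(G0))
    stop("G0 of the '", vc@parameterisation,
         "' parameterisation is singular; cannot assemble the MME")
  if (is.null(W)) W <- modelWeights(design, vc)
  if (any(W < 1 - 1e-12)) stop("Mendelian weights below 1")
  rinv <- 1 / (W * vc@sigma2e)
  y <- design$y
  X <- design$X
  p <- ncol(X)
  nEff <- length(design$Z)
  ## Z columns over the ainv row space (animal rows in ainv order, groups 0)
  mA <- length(ainv@ids)
  colMap <- match(design$ids, ainv@ids)      # NA for phantoms when grouped
  identityMap <- !anyNA(colMap) && mA == qa &&
    all(colMap == seq_len(qa))
  Zlist <- lapply(design$Z, function(Zq) {
    if (identityMap) return(Zq)
    keep <- which(!is.na(colMap))
    Zq[, keep, drop = FALSE] %*%
      sparseMatrix(i = seq_along(keep), j = colMap[keep], x = 1,
                   dims = c(length(keep), mA))
  })
  if (grouped) {
    ## phantom parents of recorded animals would need group columns in Z;
    ## records with phantom parents are rejected upstream, so Z rows only
    ## touch real animals.
    touched <- unique(c(design$sidx, design$didx))
    if (any(is.na(colMap[touched])))
      stop("a record's parent is a phantom; filter such records first")
  }
  Zbig <- do.call(cbind, Zlist)
  M <- cbind(Matrix(X, sparse = TRUE), Zbig)
  Ctop <- crossprod(M, rinv * M)
  G0i <- solve(G0)
  Lam <- kronecker(G0i, ainv@matrix)
  pad <- Diagonal(p, x = 0)
  Lfull <- bdiagPad(pad, Lam)
  C <- forceSymmetric(Ctop + Lfull)
  rhs <- as.numeric(crossprod(M, rinv * y))
  effKinds <- names(design$Z)
  nAnim <- mA - length(ainv@groupLabels)
  layout <- data.frame(
    kind = c(rep("fixed", p),
             unlist(lapply(effKinds, function(k)
               c(rep(k, nAnim), rep("group", length(ainv@groupLabels)))))),
    level = c(colnames(X), rep(ainv@ids, nEff)),
    eq = seq_len(p + nEff * mA),
    stringsAsFactors = FALSE)
  ## log|G| for the REML likelihood (ungrouped only; NA when G0 is
  ## indefinite and the likelihood undefined)
  dG0 <- det(G0)
  logDetG <- if (grouped || dG0 <= 0) NA_real_ else {
    nG <- nrow(G0)
    qa * log(dG0) + nG * ainv@logDetA
  }
  aux <- list(n = design$n, p = p, yRinvY = sum(rinv * y * y),
              logDetR = sum(log(W * vc@sigma2e)), logDetG = logDetG,
              grouped = grouped, nGenetic = nEff, mA = mA,
              ids = ainv@ids, y = y,
              ## the lambda coefficient block: C written with W^-1-scaled
              ## records carries lambda (x) A^-1 = sigma2e * G0^-1 (x) A^-1
              lambda = vc@sigma2e * G0i)
  new("MixedModelSystem", coeff = C, rhs = rhs, layout = layout, kind = kind,
      W = W, vc = vc, aux = aux)
}

## block-diagonal of a p x p zero pad and a sparse matrix
bdiagPad <- function(pad, Lam) {
  p <- nrow(pad); m <- nrow(Lam)
  Matrix::bdiag(pad, Lam)
}
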