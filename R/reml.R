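## REML: likelihood, AI/EM estimation, the imprinting RLRT and delta-method
## standard errors.
##
## Two computational routes coexist and are asserted equal in the test
## suite:
##  * remlLoglik() evaluates the likelihood through the sparse mixed model
##    equations (log|C| via CHOLMOD);
##  * fitReml() drives its iterations through a dense-V engine (V built by
##    indexing the tabular A over the parents carrying records), which
##    yields scores, the average-information matrix and the EM conditional
##    moments, including the dR/dtheta terms caused by the
##    component-dependent Mendelian-sampling weights.

parNames <- function(kind) switch(kind,
  imprinting = c("sigma2s", "sigmasd", "sigma2d", "sigma2e"),
  equivalent = c("sigma2s", "sigmasi", "sigma2i", "sigma2e"),
  animal = c("sigma2u", "sigma2e"))

vcFromPar <- function(kind, par) {
  par <- as.numeric(par)
  switch(kind,
    imprinting = imprintingComponents(par[1L], par[3L], par[2L], par[4L]),
    equivalent = equivalentComponents(par[1L], par[3L], par[2L], par[4L]),
    animal = animalComponents(par[1L], par[2L]))
}

parFromVc <- function(kind, vc) {
  if (kind == "animal") {
    vc <- transformComponents(vc, "imprinting")
    return(c(sigma2u = vc@sigma2s, sigma2e = vc@sigma2e))
  }
  vc <- transformComponents(vc, kind)
  setNames(c(vc@sigma2s, vc@sigmacov, vc@sigma2x, vc@sigma2e),
           parNames(kind))
}

#' REML iteration control
#'
#' @param maxIter maximum iterations
#' @param tolLoglik convergence tolerance on the log-likelihood change
#' @param tolPar convergence tolerance on the relative component change
#' @param algorithm \code{"AI"}, \code{"EM"} or \code{"EM-then-AI"}
#' @param emIter number of EM warm-up iterations for \code{"EM-then-AI"}
#' @param fixResidual fix the residual variance at this value instead of
#'   estimating it (used on the quasi-likelihood scale); \code{NA} =
#'   estimate
#' @param maxDense refuse to run the dense derivative engine above this
#'   record count
#' @param verbose print the iteration trajectory
#' @return a control list
#' @export
remlControl <- function(maxIter = 200L, tolLoglik = 1e-8, tolPar = 1e-6,
                        algorithm = c("EM-then-AI", "AI", "EM"),
                        emIter = 3L, fixResidual = NA_real_,
                        maxDense = 5000L, verbose = FALSE) {
  list(maxIter = as.integer(maxIter), tolLoglik = tolLoglik,
       tolPar = tolPar, algorithm = match.arg(algorithm),
       emIter = as.integer(emIter), fixResidual = fixResidual,
       maxDense = as.integer(maxDense), verbose = verbose)
}

## ---------------------------------------------------------------------------
## model context shared across likelihood evaluations
## ---------------------------------------------------------------------------

remlContext <- function(records, ped, kind, response = "value",
                        baseW = NULL, mendelian = TRUE) {
  design <- buildDesign(records, kind, ped, response = response)
  n <- design$n
  if (is.null(baseW)) baseW <- rep(1, n)
  activeIdx <- sort(unique(c(design$sidx, design$didx)))
  Aact <- relationshipBlock(ped, ped@id[activeIdx])
  sa <- match(design$sidx, activeIdx)
  da <- match(design$didx, activeIdx)
  ## parameter-free record-level blocks of A, cached across evaluations
  Ass <- Aact[sa, sa]; Add <- Aact[da, da]; Asd <- Aact[sa, da]
  list(design = design, kind = kind, n = n, y = design$y, X = design$X,
       p = ncol(design$X), baseW = baseW, mendelian = mendelian,
       Aact = Aact, sa = sa, da = da, qAct = length(activeIdx),
       qAll = length(ped), ped = ped,
       Ass = Ass, Add = Add, AsdSym = Asd + t(Asd))
}

## residual diagonal r_k and its derivatives wrt the genetic parameters
residualDiag <- function(ctx, par) {
  kind <- ctx$kind
  e <- par[length(par)]
  r <- ctx$baseW * e
  if (!ctx$mendelian)
    return(list(r = r, dr = c(rep(list(0), length(par) - 1L),
                              list(ctx$baseW))))
  onefs <- 1 - ctx$design$Fs
  onefd <- 1 - ctx$design$Fd
  if (kind == "imprinting") {
    r <- r + onefs * par[1L] + onefd * par[3L]
    dr <- list(onefs, 0, onefd, ctx$baseW)
  } else if (kind == "equivalent") {
    ## sigma2d = sigma2s + sigma2i + 2 sigmasi
    r <- r + onefs * par[1L] + onefd * (par[1L] + par[3L] + 2 * par[2L])
    dr <- list(onefs + onefd, 2 * onefd, onefd, ctx$baseW)
  } else {
    r <- r + (onefs + onefd) * par[1L]
    dr <- list(onefs + onefd, ctx$baseW)
  }
  list(r = r, dr = dr)
}

## dense V and the per-parameter derivative matrices
denseV <- function(ctx, par) {
  Ass <- ctx$Ass; Add <- ctx$Add; Sym <- ctx$AsdSym
  res <- residualDiag(ctx, par)
  n <- ctx$n
  D <- vector("list", length(par))
  if (ctx$kind == "imprinting") {
    D[[1L]] <- Ass
    D[[2L]] <- Sym
    D[[3L]] <- Add
  } else if (ctx$kind == "equivalent") {
    D[[1L]] <- Ass + Sym + Add
    D[[2L]] <- Sym + 2 * Add
    D[[3L]] <- Add
  } else {
    D[[1L]] <- Ass + Sym + Add
  }
  D[[length(par)]] <- NULL  # residual handled via dr
  V <- matrix(0, n, n)
  for (j in seq_along(D)) V <- V + par[j] * D[[j]]
  diag(V) <- diag(V) + res$r
  ## fold the residual derivative diagonals into full derivative matrices
  Dfull <- vector("list", length(par))
  for (j in seq_along(par)) {
    Dj <- if (j < length(par)) D[[j]] else matrix(0, n, n)
    dj <- res$dr[[j]]
    if (length(dj) > 1L || dj[1L] != 0) diag(Dj) <- diag(Dj) + dj
    Dfull[[j]] <- Dj
  }
  list(V = V, D = Dfull, r = res$r)
}

## loglik, scores, AI matrix and EM moments at one parameter point
remlEngine <- function(ctx, par, wantDeriv = TRUE) {
  vb <- denseV(ctx, par)
  n <- ctx$n; p <- ctx$p; X <- ctx$X; y <- ctx$y
  ch <- tryCatch(chol(vb$V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(NULL)
  XtViXi <- chol2inv(chX)
  P <- Vi - ViX %*% XtViXi %*% t(ViX)
  Py <- P %*% y
  yPy <- sum(y * Py)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy +
                (n - p) * log(2 * pi))
  out <- list(ll = ll, Py = as.numeric(Py))
  if (!wantDeriv) return(out)
  k <- length(par)
  score <- numeric(k)
  AI <- matrix(0, k, k)
  f <- vector("list", k)
  for (j in seq_len(k)) {
    Dj <- vb$D[[j]]
    score[j] <- -0.5 * (sum(P * Dj) - sum(Py * (Dj %*% Py)))
    f[[j]] <- Dj %*% Py
  }
  for (j in seq_len(k)) for (l in j:k) {
    AI[j, l] <- AI[l, j] <- 0.5 * sum(f[[j]] * (P %*% f[[l]]))
  }
  out$score <- score
  out$AI <- AI
  out$P <- P
  out$r <- vb$r
  out
}

## EM update of the genetic covariance block (and frozen-weight residual)
emUpdate <- function(ctx, par, eng) {
  kind <- ctx$kind
  n <- ctx$n; qAll <- ctx$qAll; qAct <- ctx$qAct
  Py <- eng$Py; P <- eng$P
  Ts <- sparseMatrix(i = seq_len(n), j = ctx$sa, x = 1,
                     dims = c(n, qAct))
  Td <- sparseMatrix(i = seq_len(n), j = ctx$da, x = 1,
                     dims = c(n, qAct))
  Tlist <- switch(kind,
    imprinting = list(Ts, Td),
    equivalent = list(Ts + Td, Td),
    animal = list(Ts + Td))
  nEff <- length(Tlist)
  v <- lapply(Tlist, function(T) as.numeric(crossprod(T, Py)))
  PT <- lapply(Tlist, function(T) as.matrix(P %*% T))
  S <- trSA <- vector("list", nEff * nEff)
  trS <- matrix(0, nEff, nEff)
  for (a in seq_len(nEff)) for (b in seq_len(nEff)) {
    Sab <- crossprod(Tlist[[a]], PT[[b]])
    trS[a, b] <- sum(as.matrix(Sab) * ctx$Aact)
  }
  G0 <- if (kind == "animal") matrix(par[1L], 1L, 1L) else
    matrix(c(par[1L], par[2L], par[2L], par[3L]), 2L, 2L)
  Gnew <- G0
  for (a in seq_len(nEff)) for (b in seq_len(nEff)) {
    va <- Reduce(`+`, lapply(seq_len(nEff),
                             function(k2) G0[a, k2] * v[[k2]]))
    vb2 <- Reduce(`+`, lapply(seq_len(nEff),
                              function(k2) G0[b, k2] * v[[k2]]))
    quad <- sum(va * (ctx$Aact %*% vb2))
    trTerm <- 0
    for (k2 in seq_len(nEff)) for (l2 in seq_len(nEff))
      trTerm <- trTerm + G0[a, k2] * G0[l2, b] * trS[k2, l2]
    Gnew[a, b] <- (quad + qAll * G0[a, b] - trTerm) / qAll
  }
  Gnew <- (Gnew + t(Gnew)) / 2
  e <- par[length(par)]
  w <- eng$r / e
  trPW <- sum(diag(P) * w)
  qfW <- sum(Py * (w * Py))
  eNew <- e + (e^2 / n) * (qfW - trPW)
  if (kind == "animal") c(Gnew[1L, 1L], eNew)
  else c(Gnew[1L, 1L], Gnew[1L, 2L], Gnew[2L, 2L], eNew)
}

## ---------------------------------------------------------------------------
## exported likelihood and fit
## ---------------------------------------------------------------------------

#' REML log-likelihood of a model at given components
#'
#' Evaluated through the sparse mixed model equations:
#' \deqn{\ell = -\tfrac12\left[\log|C| + \log|R| + \log|G| + y'Py +
#'   (n-p)\log 2\pi\right]}
#' with \eqn{y'Py = y'R^{-1}y - \hat\theta' \mathrm{rhs}}. Identical (to
#' numerical precision) for the imprinting and equivalent parameterisations
#' at components matched by [transformComponents()].
#'
#' @param vc a [VarianceComponents-class] matching the kind
#' @param records trait records
#' @param ped a [Pedigree-class]
#' @param kind model kind
#' @param response response column
#' @return scalar log-likelihood
#' @export
remlLoglik <- function(vc, records, ped,
                       kind = c("imprinting", "equivalent", "animal"),
                       response = "value") {
  kind <- match.arg(kind)
  G0 <- if (kind == "animal") {
    vcI <- transformComponents(vc, "imprinting")
    matrix(vcI@sigma2s, 1L, 1L)
  } else G0matrix(vc)
  if (min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) <=
      -1e-12 * max(abs(G0)))
    stop("G0 is not positive semidefinite; the REML likelihood is ",
         "undefined")
  design <- buildDesign(records, kind, ped, response = response)
  ainv <- buildAInverse(ped)
  sys <- assembleMME(kind, design, vc, ainv)
  remlLoglikSystem(sys)
}

remlLoglikSystem <- function(sys) {
  if (sys@aux$grouped)
    stop("the REML likelihood requires an ungrouped relationship inverse")
  if (is.na(sys@aux$logDetG))
    stop("G0 is not positive definite; the REML likelihood is undefined")
  ch <- tryCatch(Cholesky(forceSymmetric(sys@coeff), LDL = FALSE,
                          perm = TRUE),
                 error = function(e) NULL)
  if (is.null(ch))
    stop("coefficient matrix is not positive definite (rank-deficient ",
         "fixed effects?)")
  ldC <- 2 * as.numeric(determinant(ch, sqrt = TRUE)$modulus)
  sol <- as.numeric(solve(ch, sys@rhs))
  yPy <- sys@aux$yRinvY - sum(sol * sys@rhs)
  -0.5 * (ldC + sys@aux$logDetR + sys@aux$logDetG + yPy +
          (sys@aux$n - sys@aux$p) * log(2 * pi))
}

## linear maps between a kind's parameter vector and imprinting-scale
## coordinates (s, sd, d, e); used to clamp variance boundaries in one
## common coordinate system so all parameterisations share one feasible
## region (the covariance stays unconstrained)
parToImp <- function(kind, p) switch(kind,
  imprinting = p,
  equivalent = c(p[1L], p[1L] + p[2L], p[1L] + p[3L] + 2 * p[2L], p[4L]),
  animal = c(p[1L], p[1L], p[1L], p[2L]))

parFromImp <- function(kind, t) switch(kind,
  imprinting = t,
  equivalent = c(t[1L], t[2L] - t[1L], t[1L] + t[3L] - 2 * t[2L], t[4L]),
  animal = c(t[1L], t[4L]))

defaultStart <- function(kind, y) {
  vy <- var(y)
  switch(kind,
    imprinting = c(0.1 * vy, 0.09 * vy, 0.1 * vy, 0.8 * vy),
    equivalent = parFromVc("equivalent",
      imprintingComponents(0.1 * vy, 0.1 * vy, 0.09 * vy, 0.8 * vy)),
    animal = c(0.1 * vy, 0.8 * vy))
}

#' Fit variance components by REML
#'
#' Average-information REML with optional EM warm-up. The average
#' information matrix and the scores include the derivative of the
#' residual covariance with respect to the genetic components induced by
#' the Mendelian-sampling weights of the reduced model, so no fixed-W
#' approximation is involved in the AI steps; EM steps freeze the weights
#' within an iteration and refresh them afterwards, safeguarded by step
#' halving so the log-likelihood never decreases beyond tolerance.
#'
#' @param records trait records
#' @param ped a [Pedigree-class]
#' @param kind model kind (\code{"animal"} is the no-imprinting null)
#' @param start optional starting [VarianceComponents-class]; default
#'   0.1/0.09/0.1/0.8 of var(y) for the genetic block and residual
#' @param control see [remlControl()]
#' @param response response column
#' @param weights optional fixed heterogeneous base weights of the
#'   residual diagonal (used by the PQL working-scale fit)
#' @param mendelian include the Mendelian-sampling inflation (default
#'   \code{TRUE}; the PQL route sets \code{FALSE})
#' @return a [RemlFit-class]
#' @export
fitReml <- function(records, ped,
                    kind = c("imprinting", "equivalent", "animal"),
                    start = NULL, control = remlControl(),
                    response = "value", weights = NULL, mendelian = TRUE) {
  kind <- match.arg(kind)
  if (nrow(records) < 2L) stop("need at least 2 records")
  ctx <- remlContext(records, ped, kind, response = response,
                     baseW = weights, mendelian = mendelian)
  if (ctx$n > control$maxDense)
    stop("record count ", ctx$n, " exceeds control$maxDense (",
         control$maxDense, ") for the dense REML engine")
  par <- if (is.null(start)) defaultStart(kind, ctx$y)
         else parFromVc(kind, start)
  names(par) <- parNames(kind)
  fixE <- !is.na(control$fixResidual)
  if (fixE) par[length(par)] <- control$fixResidual
  free <- seq_along(par)
  if (fixE) free <- free[-length(par)]
  scale <- var(ctx$y)
  floorVar <- 1e-8 * scale
  ## boundary pinning acts on the physical TA variances (imprinting-scale
  ## coordinates) and the residual; the covariance is unconstrained, so
  ## the implied imprinting variance may go negative (indefinite G0)
  clamp <- function(p) {
    bd <- character(0)
    ti <- parToImp(kind, p)
    nmI <- c("sigma2s", "sigmasd", "sigma2d", "sigma2e")
    for (j in c(1L, 3L, 4L)) {
      if (j == 4L && fixE) next
      if (ti[j] < floorVar) {
        ti[j] <- floorVar
        bd <- c(bd, nmI[j])
      }
    }
    p <- parFromImp(kind, ti)
    names(p) <- parNames(kind)
    attr(p, "boundary") <- bd
    p
  }
  par <- clamp(par)
  eng <- remlEngine(ctx, par)
  if (is.null(eng)) stop("starting values give a non-positive-definite V")
  traj <- data.frame(iter = 0L, loglik = eng$ll,
                     as.list(setNames(par, names(par))), step = "start")
  converged <- FALSE
  boundary <- character(0)
  it <- 0L
  emLeft <- switch(control$algorithm, EM = control$maxIter,
                   `EM-then-AI` = control$emIter, AI = 0L)
  while (it < control$maxIter) {
    it <- it + 1L
    useEM <- emLeft > 0L
    if (useEM) emLeft <- emLeft - 1L
    parNew <- if (useEM) {
      pn <- emUpdate(ctx, par, eng)
      if (fixE) pn[length(pn)] <- par[length(par)]
      pn
    } else {
      delta <- tryCatch(solve(eng$AI[free, free, drop = FALSE],
                              eng$score[free]),
                        error = function(e) NULL)
      if (is.null(delta)) {
        pn <- emUpdate(ctx, par, eng)        # AI singular: EM fallback
        if (fixE) pn[length(pn)] <- par[length(par)]
        pn
      } else {
        pn <- par
        pn[free] <- par[free] + delta
        pn
      }
    }
    names(parNew) <- names(par)
    ## step-halving toward the current point until the likelihood is
    ## computable and not decreased (within tolerance)
    stepOK <- FALSE
    engNew <- NULL
    for (h in 0:12) {
      cand <- clamp(par + (parNew - par) / 2^h)
      engNew <- remlEngine(ctx, cand)
      if (!is.null(engNew) && engNew$ll >= eng$ll - 1e-10) {
        stepOK <- TRUE
        parNew <- cand
        break
      }
    }
    if (!stepOK) {
      converged <- TRUE    # no uphill step found: at a maximum
      break
    }
    dll <- engNew$ll - eng$ll
    dpar <- max(abs(parNew - par) / pmax(abs(par), 1e-3 * scale))
    boundary <- attr(parNew, "boundary")
    par <- parNew
    eng <- engNew
    traj <- rbind(traj, data.frame(iter = it, loglik = eng$ll,
                                   as.list(setNames(as.numeric(par),
                                                    names(par))),
                                   step = if (useEM) "EM" else "AI"))
    if (control$verbose)
      message(sprintf("it %d [%s] logL=%.8f", it,
                      if (useEM) "EM" else "AI", eng$ll))
    if (abs(dll) < control$tolLoglik && dpar < control$tolPar) {
      converged <- TRUE
      break
    }
  }
  aiCov <- tryCatch({
    s <- solve(eng$AI[free, free, drop = FALSE])
    dimnames(s) <- list(names(par)[free], names(par)[free])
    s
  }, error = function(e) {
    matrix(NA_real_, length(free), length(free),
           dimnames = list(names(par)[free], names(par)[free]))
  })
  if (length(boundary))
    message("component(s) pinned at the boundary: ",
            paste(boundary, collapse = ", "))
  new("RemlFit", vc = vcFromPar(kind, par), kind = kind, loglik = eng$ll,
      aiCov = aiCov, converged = converged, iterations = it,
      trajectory = traj, boundary = as.character(boundary),
      dataHash = c(n = ctx$n, sumY = sum(ctx$y)))
}

## ---------------------------------------------------------------------------
## RLRT
## ---------------------------------------------------------------------------

#' REML likelihood-ratio test for imprinting variance
#'
#' Compares the imprinting model against the animal-model null on the same
#' data. The statistic \eqn{2(\ell_{full} - \ell_{null})} is referred to a
#' conservative \eqn{\chi^2} distribution with 2 degrees of freedom (the
#' asymptotic distribution is a mixture of \eqn{\chi^2_1} and
#' \eqn{\chi^2_2} whose proportions are unknown with correlated data, so
#' the 2-DF reference errs on the conservative side).
#'
#' @param full imprinting-model (or equivalent-model) [RemlFit-class]
#' @param null animal-model [RemlFit-class] on the same records
#' @return an [RlrtResult-class]
#' @export
rlrt <- function(full, null) {
  if (null@kind != "animal")
    stop("the null fit must be of the animal kind")
  if (full@kind == "animal")
    stop("the full fit must include imprinting effects")
  if (any(abs(full@dataHash - null@dataHash) >
          1e-8 * pmax(abs(full@dataHash), 1)))
    stop("the two fits were not computed on the same records")
  stat <- 2 * (full@loglik - null@loglik)
  if (is.na(stat)) stop("non-finite log-likelihoods")
  statClip <- max(stat, 0)
  new("RlrtResult", statistic = statClip, df = 2,
      pValue = pchisq(statClip, df = 2, lower.tail = FALSE),
      loglikFull = full@loglik, loglikNull = null@loglik)
}

## ---------------------------------------------------------------------------
## delta-method standard errors
## ---------------------------------------------------------------------------

## gradient of a derived parameter wrt (sigma2s, sigmasd, sigma2d, sigma2e)
derivedGradient <- function(theta, functional) {
  s <- theta[1L]; c0 <- theta[2L]; d <- theta[3L]; e <- theta[4L]
  gi <- c(1, -2, 1, 0)
  ga <- c(1, 2, 1, 0)
  i <- s + d - 2 * c0
  a <- s + d + 2 * c0
  switch(functional,
    sigma2s = c(1, 0, 0, 0), sigmasd = c(0, 1, 0, 0),
    sigma2d = c(0, 0, 1, 0), sigma2e = c(0, 0, 0, 1),
    sigma2i = gi, sigma2a = ga,
    rsd = {
      r <- c0 / sqrt(s * d)
      c(-r / (2 * s), 1 / sqrt(s * d), -r / (2 * d), 0)
    },
    relImprinting = 100 * (a * gi - i * ga) / a^2,
    contribPaternal = {
      gsc <- c(1, -1, 0, 0)
      100 * (gsc * i - (s - c0) * gi) / i^2
    },
    contribMaternal = {
      gdc <- c(0, -1, 1, 0)
      100 * (gdc * i - (d - c0) * gi) / i^2
    },
    h2 = {
      ge <- c(0, 0, 0, 1)
      (ga * e - a * ge) / (a + e)^2
    },
    stop("unknown functional '", functional, "'"))
}

## Jacobian d(theta_imprinting)/d(theta_kind)
imprintingJacobian <- function(kind) {
  switch(kind,
    imprinting = diag(4),
    ## s_imp = s; sd = s + si; d = s + i + 2 si; e = e
    equivalent = matrix(c(1, 1, 1, 0,
                          0, 1, 2, 0,
                          0, 0, 1, 0,
                          0, 0, 0, 1), 4L, 4L),
    ## s_imp = u; sd = u; d = u; e = e
    animal = matrix(c(1, 1, 1, 0,
                      0, 0, 0, 1), 4L, 2L))
}

#' Delta-method standard error of a derived genetic parameter
#'
#' Propagates the asymptotic covariance of the variance-component
#' estimates (the inverse average-information matrix) through the analytic
#' gradient of the requested functional.
#'
#' @param fit a [RemlFit-class]
#' @param functional one of \code{"sigma2s"}, \code{"sigmasd"},
#'   \code{"sigma2d"}, \code{"sigma2e"}, \code{"sigma2i"},
#'   \code{"sigma2a"}, \code{"rsd"}, \code{"relImprinting"},
#'   \code{"contribPaternal"}, \code{"contribMaternal"}, \code{"h2"}
#' @return the standard error, or \code{NA} where the functional is
#'   undefined at the estimates (e.g. contributions at
#'   \eqn{\sigma^2_i = 0})
#' @export
deltaSE <- function(fit, functional) {
  if (any(is.na(fit@aiCov))) return(NA_real_)
  J <- imprintingJacobian(fit@kind)
  vcI <- transformComponents(fit@vc, "imprinting")
  theta <- c(vcI@sigma2s, vcI@sigmacov, vcI@sigma2x, vcI@sigma2e)
  if (functional %in% c("contribPaternal", "contribMaternal", "rsd")) {
    i <- theta[1L] + theta[3L] - 2 * theta[2L]
    if (functional != "rsd" && i <= 0) return(NA_real_)
    if (functional == "rsd" && (theta[1L] <= 0 || theta[3L] <= 0))
      return(NA_real_)
  }
  g <- derivedGradient(theta, functional)
  gKind <- as.numeric(t(J) %*% g)          # chain rule to the fit scale
  free <- match(rownames(fit@aiCov), parNames(fit@kind))
  gFree <- gKind[free]
  sqrt(max(as.numeric(t(gFree) %*% fit@aiCov %*% gFree), 0))
}

#' Report a REML fit as a data.frame
#'
#' Components, derived genetic parameters and their delta-method standard
#' errors in one table.
#'
#' @param fit a [RemlFit-class]
#' @return data.frame with columns parameter, estimate, se
#' @export
fitReport <- function(fit) {
  vcI <- transformComponents(fit@vc, "imprinting")
  dg <- derivedGeneticParameters(vcI)
  pars <- c(sigma2s = vcI@sigma2s, sigmasd = vcI@sigmacov,
            sigma2d = vcI@sigma2x, sigma2e = vcI@sigma2e,
            sigma2i = dg$sigma2i, sigma2a = dg$sigma2a, rsd = dg$rsd,
            relImprinting = dg$relImprinting,
            contribPaternal = dg$contribPaternal,
            contribMaternal = dg$contribMaternal, h2 = dg$h2)
  data.frame(parameter = names(pars), estimate = as.numeric(pars),
             se = vapply(names(pars), function(f) deltaSE(fit, f),
                         numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
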