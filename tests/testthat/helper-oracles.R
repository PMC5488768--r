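## Independent oracles and small generators used across the suite.
## Everything here is deliberately naive (dense base-R linear algebra,
## explicit recursions) so it cannot share a code path with the package's
## sparse/MME implementations.

## random pedigree with optional inbred loops, built with plain vectors
randomPedigree <- function(n, seed, pInbred = 0.3, pUnknown = 0.1) {
  set.seed(seed)
  id <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  nf <- max(4L, round(n / 5))
  sex[1:2] <- c("M", "F")
  for (i in (nf + 1L):n) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (!length(males) || !length(females)) next
    if (runif(1) < pInbred && length(males) > 2L && length(females) > 2L) {
      ## mate relatives: pick recent parents to create loops
      s <- males[length(males)]
      d <- females[length(females)]
    } else {
      s <- sample(males, 1L)
      d <- sample(females, 1L)
    }
    sire[i] <- id[s]
    dam[i] <- if (runif(1) < pUnknown) NA_character_ else id[d]
  }
  Pedigree(id, sire, dam, sex = sex,
           birthYear = 1970L + (seq_len(n) %/% 5L))
}

## dense GLS/BLUP oracle: beta-hat from V = ZGZ' + R, u-hat = G Z' V^-1 e,
## textbook REML log-likelihood; base R only
glsOracle <- function(records, ped, vc, kind) {
  vcI <- transformComponents(vc, "imprinting")
  ids <- pedIds(ped)
  q <- length(ids)
  A <- relationshipBlock(ped, ids)
  si <- match(records$sire, ids)
  di <- match(records$dam, ids)
  n <- nrow(records)
  Zs <- matrix(0, n, q); Zd <- matrix(0, n, q)
  Zs[cbind(seq_len(n), si)] <- 1
  Zd[cbind(seq_len(n), di)] <- 1
  s2s <- vcI@sigma2s; s2d <- vcI@sigma2x; ssd <- vcI@sigmacov
  s2e <- vcI@sigma2e
  Fv <- ped@inbreeding
  rdiag <- s2e + (1 - Fv[si]) * s2s + (1 - Fv[di]) * s2d
  if (kind == "animal") {
    Z <- Zs + Zd
    G <- s2s * A
    Zlist <- list(TA = Z)
  } else if (kind == "imprinting") {
    Z <- cbind(Zs, Zd)
    G <- rbind(cbind(s2s * A, ssd * A), cbind(ssd * A, s2d * A))
    Zlist <- list(TA_as_sire = Zs, TA_as_dam = Zd)
  } else { # equivalent
    vcE <- transformComponents(vc, "equivalent")
    Z <- cbind(Zs + Zd, Zd)
    G <- rbind(cbind(vcE@sigma2s * A, vcE@sigmacov * A),
               cbind(vcE@sigmacov * A, vcE@sigma2x * A))
    Zlist <- list(TA_as_sire = Zs + Zd, imprinting_effect = Zd)
  }
  X <- buildDesign(records, kind, ped)$X
  y <- records$value
  V <- Z %*% G %*% t(Z) + diag(rdiag)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  e <- y - X %*% beta
  u <- as.numeric(G %*% t(Z) %*% Vi %*% e)
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  ll <- -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                sum(y * (P %*% y)) + (n - ncol(X)) * log(2 * pi))
  nU <- length(Zlist) * q
  list(beta = as.numeric(beta), u = u, ll = as.numeric(ll),
       uNames = rep(ids, length(Zlist)),
       uKinds = rep(names(Zlist), each = q))
}

## simple records over an existing pedigree: phenotypes on the youngest
## animals with both parents known
makeRecords <- function(ped, seed, vc = imprintingComponents(1, 1.2, 0.8,
                                                             4),
                        nGroups = 3) {
  set.seed(seed)
  ok <- which(!is.na(ped@sire) & !is.na(ped@dam))
  n <- length(ok)
  si <- ped@sire[ok]; di <- ped@dam[ok]
  age <- sample(400:560, n, replace = TRUE)
  y <- 10 + 0.01 * age + rnorm(n, 0, sqrt(vc@sigma2e + vc@sigma2s +
                                            vc@sigma2x))
  data.frame(progeny = ped@id[ok], sire = ped@id[si], dam = ped@id[di],
             group = paste0("g", sample(seq_len(nGroups), n,
                                        replace = TRUE)),
             parity = sample(1:2, n, replace = TRUE),
             birthType = sample(c("S", "T"), n, replace = TRUE),
             age = age, value = y, stringsAsFactors = FALSE)
}

## solutions of a SolutionSet for one kind as a named vector
solVec <- function(sol, kind) {
  tab <- effectTable(sol, kind)
  setNames(tab$estimate, tab$level)
}
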