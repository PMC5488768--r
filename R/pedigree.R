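## Pedigree construction, inbreeding, relationship algebra, pruning and
## phantom-parent genetic groups.

topoOrder <- function(id, sireId, damId) {
  ## Kahn's algorithm on the parent -> offspring graph; errors with a cycle
  ## member when no topological order exists.
  n <- length(id)
  si <- match(sireId, id)
  di <- match(damId, id)
  indeg <- integer(n)
  kids <- vector("list", n)
  for (k in seq_len(n)) {
    for (p in c(si[k], di[k])) {
      if (!is.na(p)) {
        indeg[k] <- indeg[k] + 1L
        kids[[p]] <- c(kids[[p]], k)
      }
    }
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) < n) {
    member <- id[which(indeg > 0L)[1L]]
    stop("pedigree contains a cycle involving animal '", member, "'")
  }
  out
}

#' Construct a Pedigree from identifier vectors
#'
#' Closes the pedigree (parents that never appear as animals are added as
#' founders), checks sex consistency against parental usage, topologically
#' sorts it and computes inbreeding.
#'
#' @param id animal identifiers
#' @param sire,dam parent identifiers (\code{NA} = unknown)
#' @param sex optional \code{"M"/"F"/"U"} per animal; inferred from usage
#'   where missing
#' @param birthYear optional integer birth years
#' @param phantom optional logical flags for phantom placeholders
#' @return a [Pedigree-class]
#' @examples
#' ped <- Pedigree(c("o", "s", "d"), sire = c("s", NA, NA),
#'                 dam = c("d", NA, NA))
#' inbreeding(ped)
#' @export
Pedigree <- function(id, sire, dam, sex = NULL, birthYear = NULL,
                     phantom = NULL) {
  id <- as.character(id)
  sire <- as.character(sire); dam <- as.character(dam)
  if (anyDuplicated(id))
    stop("duplicate animal id '", id[duplicated(id)][1L], "'")
  same <- !is.na(sire) & !is.na(dam) & sire == dam
  if (any(same))
    stop("animal with sire equal to dam: '", id[which(same)[1L]], "'")
  ## close: add unlisted parents as founders
  missingPar <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(missingPar)) {
    id <- c(id, missingPar)
    sire <- c(sire, rep(NA_character_, length(missingPar)))
    dam <- c(dam, rep(NA_character_, length(missingPar)))
    if (!is.null(sex)) sex <- c(as.character(sex),
                                rep("U", length(missingPar)))
    if (!is.null(birthYear)) birthYear <- c(birthYear,
                                            rep(NA_integer_,
                                                length(missingPar)))
    if (!is.null(phantom)) phantom <- c(phantom,
                                        rep(FALSE, length(missingPar)))
  }
  n <- length(id)
  if (is.null(sex)) sex <- rep("U", n)
  sex <- as.character(sex); sex[is.na(sex)] <- "U"
  if (is.null(birthYear)) birthYear <- rep(NA_integer_, n)
  birthYear <- as.integer(birthYear)
  if (is.null(phantom)) phantom <- rep(FALSE, n)

  usedAsSire <- id %in% sire
  usedAsDam <- id %in% dam
  clash <- usedAsSire & usedAsDam
  if (any(clash))
    stop("animal '", id[clash][1L], "' is used as both a sire and a dam")
  badSex <- (usedAsSire & sex == "F") | (usedAsDam & sex == "M")
  if (any(badSex))
    stop("declared sex of animal '", id[badSex][1L],
         "' conflicts with its parental usage")
  sex[sex == "U" & usedAsSire] <- "M"
  sex[sex == "U" & usedAsDam] <- "F"

  ord <- topoOrder(id, sire, dam)
  id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
  sex <- sex[ord]; birthYear <- birthYear[ord]; phantom <- phantom[ord]
  ped <- new("Pedigree", id = id, sire = match(sire, id),
             dam = match(dam, id), sex = sex, birthYear = birthYear,
             phantom = phantom, inbreeding = numeric(length(id)))
  ped@inbreeding <- computeInbreeding(ped)
  ped
}

#' Read a pedigree file
#'
#' Delimited text with columns animal, sire, dam and optionally sex and
#' birth year (a header line naming the first column \code{animal} is
#' detected automatically). The separator is auto-detected among tab, comma
#' and whitespace unless given.
#'
#' @param path file path
#' @param unknownCode token marking an unknown parent (default \code{"0"})
#' @param sep field separator, or \code{NULL} to auto-detect
#' @param phantoms if \code{TRUE}, unknown parents are materialised as
#'   phantom placeholder animals (required for genetic-group assignment)
#' @return a [Pedigree-class]
#' @export
readPedigree <- function(path, unknownCode = "0", sep = NULL,
                         phantoms = FALSE) {
  first <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  }
  header <- grepl("animal", first, ignore.case = TRUE)
  d <- read.table(path, sep = sep, header = header,
                  colClasses = "character", strip.white = TRUE)
  if (ncol(d) < 3L)
    stop("pedigree file needs at least animal, sire and dam columns")
  names(d)[1:3] <- c("animal", "sire", "dam")
  if (anyDuplicated(d$animal))
    stop("duplicate animal id '", d$animal[duplicated(d$animal)][1L],
         "' in ", path)
  sire <- ifelse(d$sire == unknownCode | d$sire == "", NA_character_, d$sire)
  dam <- ifelse(d$dam == unknownCode | d$dam == "", NA_character_, d$dam)
  sex <- if (ncol(d) >= 4L) d[[4L]] else NULL
  if (!is.null(sex)) {
    sex <- toupper(substr(sex, 1L, 1L))
    sex[!sex %in% c("M", "F")] <- "U"
  }
  by <- if (ncol(d) >= 5L) suppressWarnings(as.integer(d[[5L]])) else NULL
  ped <- Pedigree(d$animal, sire, dam, sex = sex, birthYear = by)
  if (phantoms) ped <- addPhantomParents(ped)
  ped
}

#' Materialise phantom parents
#'
#' Replaces every unknown parent slot of a non-phantom animal with a new
#' phantom founder (one phantom per missing parent slot, Westell--Van Vleck
#' convention), so that genetic groups can be assigned.
#'
#' @param ped a [Pedigree-class]
#' @return a new [Pedigree-class] including phantom records
#' @export
addPhantomParents <- function(ped) {
  df <- as.data.frame(ped)
  needS <- which(is.na(df$sire) & !df$phantom)
  needD <- which(is.na(df$dam) & !df$phantom)
  if (!length(needS) && !length(needD)) return(ped)
  phS <- sprintf("ph_s_%s", df$animal[needS])
  phD <- sprintf("ph_d_%s", df$animal[needD])
  df$sire[needS] <- phS
  df$dam[needD] <- phD
  Pedigree(c(df$animal, phS, phD),
           c(df$sire, rep(NA, length(phS) + length(phD))),
           c(df$dam, rep(NA, length(phS) + length(phD))),
           sex = c(df$sex, rep("M", length(phS)), rep("F", length(phD))),
           birthYear = c(df$birthYear,
                         rep(NA_integer_, length(phS) + length(phD))),
           phantom = c(df$phantom, rep(TRUE, length(phS) + length(phD))))
}

#' Inbreeding coefficients by the Meuwissen--Luo algorithm
#'
#' Computes F for every animal of a sorted pedigree by accumulating the
#' diagonal of A = LDL' one animal at a time: the gene-flow row of L is
#' traced back through the ancestors and combined with the
#' Mendelian-sampling variances D. Unknown parents contribute no
#' relationship (F from the known side only).
#'
#' @param ped a [Pedigree-class] (parent-first ordered; the constructor
#'   guarantees this)
#' @return numeric vector of inbreeding coefficients, in pedigree order
#' @export
computeInbreeding <- function(ped) {
  n <- length(ped)
  si <- ped@sire; di <- ped@dam
  if (any(!is.na(si) & si >= seq_len(n)) ||
      any(!is.na(di) & di >= seq_len(n)))
    stop("pedigree must be sorted parent-first before computing inbreeding")
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    nk <- (!is.na(s)) + (!is.na(d))
    D[i] <- if (nk == 2L) 0.5 - 0.25 * (F[s] + F[d])
            else if (nk == 1L) 0.75 - 0.25 * F[if (is.na(s)) d else s]
            else 1
    if (nk < 2L) { F[i] <- 0; next }
    ## a_ii = sum_j L_ij^2 D_j accumulated by back-tracing from i
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in seq(i, 1L)) {
      lj <- L[j]
      if (lj == 0) next
      aii <- aii + lj * lj * D[j]
      sj <- si[j]; dj <- di[j]
      if (!is.na(sj)) L[sj] <- L[sj] + 0.5 * lj
      if (!is.na(dj)) L[dj] <- L[dj] + 0.5 * lj
    }
    F[i] <- aii - 1
  }
  F
}

#' Additive relationship submatrix by the tabular method
#'
#' Builds the numerator relationship matrix A over the whole pedigree by the
#' classical recursion and returns the block for the requested identifiers.
#'
#' @param ped a [Pedigree-class]
#' @param ids identifiers of the rows/columns wanted
#' @param maxAnimals guard against accidentally densifying a huge pedigree
#' @return dense symmetric matrix with dimnames \code{ids}
#' @export
relationshipBlock <- function(ped, ids, maxAnimals = 6000L) {
  idx <- match(ids, ped@id)
  if (anyNA(idx))
    stop("unknown animal id '", ids[which(is.na(idx))[1L]], "'")
  n <- length(ped)
  if (n > maxAnimals)
    stop("pedigree has ", n, " animals; raise maxAnimals to densify A")
  A <- matrix(0, n, n)
  si <- ped@sire; di <- ped@dam
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  out <- A[idx, idx, drop = FALSE]
  dimnames(out) <- list(ids, ids)
  out
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding. When a [GroupAssignment-class] is
#' supplied, phantom parents are replaced by their genetic-group columns
#' (Quaas--Pollak/Westell modification): group rows are appended after the
#' animal rows, phantom placeholder animals get no equations of their own,
#' and the Mendelian-sampling variance of an animal is driven by its known
#' (real) parents only. One reference group is pinned to zero to keep the
#' grouped system full-rank (see \code{referenceGroup}).
#'
#' @param ped a [Pedigree-class]
#' @param groups optional [GroupAssignment-class] covering every phantom
#' @param referenceGroup label of the group constrained to zero (dropped
#'   from the matrix); defaults to the last level. Ignored without groups.
#' @return a [RelationshipInverse-class]
#' @export
buildAInverse <- function(ped, groups = NULL, referenceGroup = NULL) {
  n <- length(ped)
  F <- ped@inbreeding
  si <- ped@sire; di <- ped@dam
  grouped <- !is.null(groups)
  if (grouped) {
    if (any(!groups@phantomId %in% ped@id[ped@phantom]))
      stop("group assignment references a non-phantom animal: '",
           setdiff(groups@phantomId, ped@id[ped@phantom])[1L], "'")
    phantomOf <- setNames(groups@group, groups@phantomId)
    if (!all(ped@id[ped@phantom] %in% groups@phantomId))
      stop("every phantom needs a group; missing for '",
           setdiff(ped@id[ped@phantom], groups@phantomId)[1L], "'")
    if (any(is.na(si[!ped@phantom]) | is.na(di[!ped@phantom])))
      stop("with genetic groups, materialise phantoms first ",
            "(readPedigree(..., phantoms = TRUE) or addPhantomParents())")
    keep <- which(!ped@phantom)
    usedLv <- unique(phantomOf)
    lv <- groups@levels[groups@levels %in% usedLv]
    if (is.null(referenceGroup)) referenceGroup <- lv[length(lv)]
    lv <- setdiff(lv, referenceGroup)
    animCol <- match(seq_len(n), keep)       # NA for phantoms
    grpCol <- function(ph) {
      g <- phantomOf[ped@id[ph]]
      if (g == referenceGroup) NA_integer_ else length(keep) + match(g, lv)
    }
    m <- length(keep) + length(lv)
    ids <- c(ped@id[keep], lv)
  } else {
    keep <- seq_len(n)
    animCol <- seq_len(n)
    m <- n
    ids <- ped@id
    lv <- character(0)
  }

  logDetA <- 0
  ## triplet accumulation via preallocated vectors for speed
  cap <- 9L * length(keep)
  ii <- integer(cap); jj <- integer(cap); xx <- numeric(cap)
  nt <- 0L
  push <- function(i, j, v) {
    nt <<- nt + 1L
    ii[nt] <<- i; jj[nt] <<- j; xx[nt] <<- v
  }
  for (a in keep) {
    s <- si[a]; d <- di[a]
    sReal <- !is.na(s) && !(grouped && ped@phantom[s])
    dReal <- !is.na(d) && !(grouped && ped@phantom[d])
    nk <- sReal + dReal
    dms <- if (nk == 2L) 0.5 - 0.25 * (F[s] + F[d])
           else if (nk == 1L) 0.75 - 0.25 * F[if (sReal) s else d]
           else 1
    logDetA <- logDetA + log(dms)
    alpha <- 1 / dms
    ca <- animCol[a]
    cols <- integer(0)
    if (!is.na(s)) {
      cs <- if (grouped && ped@phantom[s]) grpCol(s) else animCol[s]
      if (!is.na(cs)) cols <- c(cols, cs)
    }
    if (!is.na(d)) {
      cd <- if (grouped && ped@phantom[d]) grpCol(d) else animCol[d]
      if (!is.na(cd)) cols <- c(cols, cd)
    }
    push(ca, ca, alpha)
    for (cp in cols) {
      push(ca, cp, -alpha / 2); push(cp, ca, -alpha / 2)
    }
    for (c1 in cols) for (c2 in cols) push(c1, c2, alpha / 4)
  }
  M <- sparseMatrix(i = ii[seq_len(nt)], j = jj[seq_len(nt)],
                    x = xx[seq_len(nt)], dims = c(m, m),
                    dimnames = list(ids, ids))
  new("RelationshipInverse", matrix = forceSymmetric(M), ids = ids,
      groupLabels = lv, logDetA = if (grouped) NA_real_ else logDetA)
}

#' Prune a pedigree to the animals informative for an analysis
#'
#' Restricts the pedigree to the given animals plus all of their ancestors.
#' Equivalently: iteratively deletes every animal that has no phenotyped
#' progeny record attached and no retained offspring. No single-link
#' ancestors are absorbed, so the relationship matrix over the retained
#' animals is unchanged. Idempotent.
#'
#' @param ped a [Pedigree-class]
#' @param phenotyped identifiers to anchor the pruning (typically the
#'   recorded animals together with the sires and dams on their records)
#' @return the pruned [Pedigree-class] (possibly empty)
#' @export
prunePedigree <- function(ped, phenotyped) {
  keep <- logical(length(ped))
  keep[match(intersect(phenotyped, ped@id), ped@id)] <- TRUE
  ## reverse-topological sweep: a parent of any kept animal is kept
  for (i in rev(seq_len(length(ped)))) {
    if (keep[i]) {
      if (!is.na(ped@sire[i])) keep[ped@sire[i]] <- TRUE
      if (!is.na(ped@dam[i])) keep[ped@dam[i]] <- TRUE
    }
  }
  df <- as.data.frame(ped)[keep, , drop = FALSE]
  if (!nrow(df))
    return(new("Pedigree", id = character(0), sire = integer(0),
               dam = integer(0), sex = character(0),
               birthYear = integer(0), phantom = logical(0),
               inbreeding = numeric(0)))
  Pedigree(df$animal, df$sire, df$dam, sex = df$sex,
           birthYear = df$birthYear, phantom = df$phantom)
}

#' Birth-year binning for phantom-parent groups
#'
#' One open bin below \code{firstBoundary}, fixed-width interior bins, and
#' one open bin above \code{lastBoundary}; the whole layout is duplicated
#' for phantom sires and phantom dams.
#'
#' @param firstBoundary phantoms expected to be born before this year go to
#'   the first group (default 1974)
#' @param lastBoundary phantoms expected to be born after this year go to
#'   the last group (default 1996)
#' @param width interior bin width in years (default 3)
#' @param fallback label suffix of the bin used for phantoms with no dated
#'   offspring: \code{"first"} or \code{"last"}
#' @return a binning configuration list
#' @export
groupBinning <- function(firstBoundary = 1974, lastBoundary = 1996,
                         width = 3, fallback = "first") {
  stopifnot(lastBoundary > firstBoundary, width >= 1)
  nInterior <- as.integer(ceiling((lastBoundary - firstBoundary) / width))
  list(firstBoundary = firstBoundary, lastBoundary = lastBoundary,
       width = width, nInterior = nInterior,
       fallback = match.arg(fallback, c("first", "last")))
}

binLabels <- function(binning, sexTag) {
  lo <- binning$firstBoundary
  labs <- sprintf("%s:<%d", sexTag, lo)
  for (b in seq_len(binning$nInterior)) {
    a <- lo + (b - 1L) * binning$width
    z <- min(lo + b * binning$width - 1L, binning$lastBoundary)
    labs <- c(labs, sprintf("%s:%d-%d", sexTag, a, z))
  }
  c(labs, sprintf("%s:>%d", sexTag, binning$lastBoundary))
}

binOf <- function(year, binning) {
  if (year < binning$firstBoundary) return(1L)
  if (year > binning$lastBoundary) return(2L + binning$nInterior)
  1L + min(binning$nInterior,
           1L + (year - binning$firstBoundary) %/% binning$width)
}

#' Assign phantom parents to genetic groups
#'
#' The expected birth year of a phantom is the average over its dated
#' offspring of (offspring birth year minus the generation-interval offset
#' of the selection path). Offspring birth years missing in the pedigree
#' are themselves propagated from their own offspring. Phantoms whose
#' offspring carry no dated descendants fall into the configured fallback
#' bin.
#'
#' @param ped a [Pedigree-class] with phantoms materialised
#' @param binning see [groupBinning()]
#' @param offsets named generation-interval offsets in years for the four
#'   selection paths \code{sireOfMale}, \code{sireOfFemale},
#'   \code{damOfMale}, \code{damOfFemale}; a single unnamed number is
#'   recycled (default 6)
#' @return a [GroupAssignment-class]
#' @export
assignPhantomGroups <- function(ped, binning = groupBinning(),
                                offsets = 6) {
  if (length(offsets) == 1L && is.null(names(offsets)))
    offsets <- c(sireOfMale = offsets, sireOfFemale = offsets,
                 damOfMale = offsets, damOfFemale = offsets)
  need <- c("sireOfMale", "sireOfFemale", "damOfMale", "damOfFemale")
  if (!all(need %in% names(offsets)))
    stop("offsets must name all four selection paths")
  n <- length(ped)
  phIdx <- which(ped@phantom)
  if (!length(phIdx))
    return(new("GroupAssignment", phantomId = character(0),
               group = character(0),
               levels = c(binLabels(binning, "S"), binLabels(binning, "D")),
               binning = binning))
  ## expected year per animal: birth year, else mean over offspring of
  ## (offspring expected year - path offset); one reverse-topological sweep
  ey <- as.numeric(ped@birthYear)
  offSum <- numeric(n); offN <- integer(n)
  for (i in rev(seq_len(n))) {
    if (is.na(ey[i]) && offN[i] > 0L) ey[i] <- offSum[i] / offN[i]
    yi <- ey[i]
    if (is.na(yi)) next
    for (role in c("sire", "dam")) {
      p <- if (role == "sire") ped@sire[i] else ped@dam[i]
      if (is.na(p)) next
      path <- paste0(role, "Of", if (ped@sex[i] == "F") "Female" else "Male")
      offSum[p] <- offSum[p] + (yi - offsets[[path]])
      offN[p] <- offN[p] + 1L
    }
  }
  labsS <- binLabels(binning, "S"); labsD <- binLabels(binning, "D")
  fallbackBin <- if (binning$fallback == "first") 1L
                 else 2L + binning$nInterior
  grp <- character(length(phIdx))
  undated <- character(0)
  for (k in seq_along(phIdx)) {
    i <- phIdx[k]
    labs <- if (ped@sex[i] == "F") labsD else labsS
    if (offN[i] == 0L && is.na(ey[i])) {
      grp[k] <- labs[fallbackBin]
      undated <- c(undated, ped@id[i])
    } else {
      y <- if (!is.na(ey[i])) ey[i] else offSum[i] / offN[i]
      grp[k] <- labs[binOf(round(y), binning)]
    }
  }
  if (length(undated))
    message(length(undated),
            " phantom(s) without dated offspring assigned to the fallback ",
            "bin (first: '", undated[1L], "')")
  new("GroupAssignment", phantomId = ped@id[phIdx], group = grp,
      levels = c(labsS, labsD), binning = binning)
}

#' Write a group assignment to a two-column delimited file
#'
#' @param groups a [GroupAssignment-class]
#' @param path output file
#' @export
writeGroupAssignment <- function(groups, path) {
  write.table(data.frame(phantom_id = groups@phantomId,
                         group_label = groups@group),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}
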