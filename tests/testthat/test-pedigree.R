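test_that("reading preserves founders and reorders child-before-parent rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("animal,sire,dam", "a,0,0", "b,0,0", "c,0,0"), f)
  ped <- readPedigree(f)
  expect_identical(pedIds(ped), c("a", "b", "c"))
  expect_true(all(is.na(ped@sire)))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("animal\tsire\tdam", "kid\tpa\tma", "pa\t0\t0", "ma\t0\t0"),
             f2)
  ped2 <- readPedigree(f2)
  ki <- match("kid", pedIds(ped2))
  expect_true(ki > match("pa", pedIds(ped2)))
  expect_true(ki > match("ma", pedIds(ped2)))
})

test_that("sex conflicts, duplicates and cycles are rejected", {
  expect_error(Pedigree(c("o1", "o2", "x", "y", "z"),
                        sire = c("x", "y", NA, NA, NA),
                        dam = c("z", "x", NA, NA, NA)),
               "both a sire and a dam")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("animal,sire,dam", "a,0,0", "a,0,0"), f)
  expect_error(readPedigree(f), "duplicate")
  expect_error(Pedigree(c("a", "b"), sire = c("b", "a"),
                        dam = c(NA, NA)), "cycle")
})

test_that("inbreeding matches classical values and the tabular oracle", {
  ped <- Pedigree(c("x", "y", "o1", "o2", "z"),
                  sire = c(NA, NA, "x", "x", "o1"),
                  dam = c(NA, NA, "y", "y", "o2"))
  F <- inbreeding(ped)
  expect_equal(unname(F[c("x", "o1")]), c(0, 0))
  expect_equal(unname(F["z"]), 0.25)    # offspring of full sibs

  for (seed in 1:3) {
    rp <- randomPedigree(50, seed)
    A <- relationshipBlock(rp, pedIds(rp))
    expect_equal(computeInbreeding(rp), unname(diag(A) - 1),
                 tolerance = 1e-12)
  }
})

test_that("relationship blocks carry classical values and stay PSD", {
  ped <- Pedigree(c("s", "d", "o", "o2"), sire = c(NA, NA, "s", "s"),
                  dam = c(NA, NA, "d", "d"))
  A <- relationshipBlock(ped, c("s", "o", "o2"))
  expect_equal(A["s", "o"], 0.5)
  expect_equal(A["o", "o2"], 0.5)       # full sibs
  expect_error(relationshipBlock(ped, "nobody"), "unknown animal")
  for (seed in 4:6) {
    rp <- randomPedigree(60, seed)
    A <- relationshipBlock(rp, pedIds(rp))
    expect_gt(min(eigen(A, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-10)
  }
})

test_that("A-inverse inverts the tabular A, including inbred loops", {
  ped <- Pedigree(letters[1:4], sire = rep(NA, 4), dam = rep(NA, 4),
                  sex = c("M", "F", "M", "F"))
  expect_equal(as.matrix(buildAInverse(ped)@matrix),
               diag(4), ignore_attr = TRUE)
  for (seed in 7:9) {
    rp <- randomPedigree(100, seed, pInbred = 0.4)
    expect_gt(max(computeInbreeding(rp)), 0)  # loops present
    A <- relationshipBlock(rp, pedIds(rp))
    Ainv <- as.matrix(buildAInverse(rp)@matrix)
    expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-10)
  }
})

test_that("grouped A-inverse reproduces the ungrouped animal block", {
  ## the animal-by-animal block of the Westell grouped inverse must equal
  ## the ungrouped inverse built on the phantomless pedigree, because the
  ## Mendelian variance is driven by known real parents in both
  for (seed in 13:14) {
    rp <- randomPedigree(40, seed, pUnknown = 0.3)
    rp2 <- addPhantomParents(rp)
    g <- assignPhantomGroups(rp2)
    aiG <- buildAInverse(rp2, g)
    ai <- buildAInverse(rp)
    ids <- pedIds(rp)
    expect_equal(as.matrix(aiG@matrix)[ids, ids],
                 as.matrix(ai@matrix)[ids, ids], tolerance = 1e-12)
  }
  ped <- Pedigree(c("s", "d", "o"), sire = c(NA, NA, "s"),
                  dam = c(NA, NA, "d"), birthYear = c(1980, 1980, 1990))
  expect_error(buildAInverse(ped, new("GroupAssignment",
                                      phantomId = "s", group = "S:<1974",
                                      levels = "S:<1974",
                                      binning = list())),
               "non-phantom")
})

test_that("pruning keeps record parents and ancestors, drops leaves, and is idempotent", {
  ped <- Pedigree(c("gs", "gd", "s", "d", "rec", "leaf"),
                  sire = c(NA, NA, "gs", NA, "s", "s"),
                  dam = c(NA, NA, "gd", NA, "d", "d"))
  pr <- prunePedigree(ped, c("rec", "s", "d"))
  expect_true(all(c("s", "d", "gs", "gd", "rec") %in% pedIds(pr)))
  expect_false("leaf" %in% pedIds(pr))
  for (seed in 10:12) {
    rp <- randomPedigree(80, seed)
    keep <- sample(pedIds(rp), 20)
    p1 <- prunePedigree(rp, keep)
    p2 <- prunePedigree(p1, keep)
    expect_identical(sort(pedIds(p1)), sort(pedIds(p2)))
  }
})

test_that("phantom groups follow the year bins and the interior bin count", {
  ## phantom sire with expected year 1960 -> first sire group;
  ## phantom dam with expected year 2001 -> last dam group
  ped <- Pedigree(c("old", "young"), sire = c(NA, NA), dam = c(NA, NA),
                  sex = c("M", "F"), birthYear = c(1966L, 2007L))
  ped2 <- addPhantomParents(ped)
  g <- assignPhantomGroups(ped2, offsets = 6)
  gm <- setNames(g@group, g@phantomId)
  expect_identical(unname(gm["ph_s_old"]), "S:<1974")
  expect_identical(unname(gm["ph_d_young"]), "D:>1996")
  bn <- groupBinning(1974, 1996, 3)
  expect_equal(bn$nInterior, ceiling((1996 - 1974) / 3))
  expect_identical(sum(startsWith(g@levels, "S:")), bn$nInterior + 2L)
})
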