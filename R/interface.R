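## Run configuration, record filters, trait recodings, file IO and the
## end-to-end pipeline.

#' Run configuration
#'
#' Validates and completes a pipeline configuration. Unknown keys are
#' rejected. Thresholds default to the standard slaughter-data rules:
#' comparison groups need at least five records (four for the killing out
#' percentage, see \code{minGroupSize}).
#'
#' @param pedigreeFile path of the pedigree file (see [readPedigree()])
#' @param phenotypeFile path of the phenotype file (see [readRecords()])
#' @param trait label of the analysed trait (bookkeeping; with
#'   \code{"killingOut"} the group-size threshold defaults to 4)
#' @param modelKind kind of the full model (\code{"imprinting"};
#'   the equivalent model is always used for the POE/PEV stage)
#' @param minGroupSize minimum records per comparison group
#' @param recode \code{"none"}, \code{"conformationMonetary"} (EUROP
#'   letters to monetary values) or \code{"binary"}
#' @param binaryTrait when \code{recode = "binary"}:
#'   \code{"conformation"} or \code{"fatness"}
#' @param unknownCode unknown-parent token in the pedigree file
#' @param grouping \code{NULL} or a list with optional entries
#'   \code{binning} (see [groupBinning()]) and \code{offsets}
#' @param reml a [remlControl()] list
#' @param reliabilityDenominator \code{"1+F"} or \code{"1"}
#' @param outDir output directory (\code{NULL}: nothing written)
#' @param seed integer seed
#' @return validated configuration list of class \code{poeRunConfig}
#' @export
runConfig <- function(pedigreeFile = NULL, phenotypeFile = NULL,
                      trait = "trait", modelKind = "imprinting",
                      minGroupSize = NULL, recode = "none",
                      binaryTrait = "conformation", unknownCode = "0",
                      grouping = NULL, reml = remlControl(),
                      reliabilityDenominator = "1+F", outDir = NULL,
                      seed = 1L) {
  if (is.null(minGroupSize))
    minGroupSize <- if (identical(trait, "killingOut")) 4L else 5L
  cfg <- list(pedigreeFile = pedigreeFile, phenotypeFile = phenotypeFile,
              trait = trait, modelKind = modelKind,
              minGroupSize = as.integer(minGroupSize), recode = recode,
              binaryTrait = binaryTrait, unknownCode = unknownCode,
              grouping = grouping, reml = reml,
              reliabilityDenominator = reliabilityDenominator,
              outDir = outDir, seed = as.integer(seed))
  stopifnot(cfg$modelKind %in% c("imprinting", "equivalent"),
            cfg$recode %in% c("none", "conformationMonetary", "binary"),
            cfg$reliabilityDenominator %in% c("1+F", "1"),
            cfg$minGroupSize >= 1L)
  if (!is.null(grouping)) {
    extra <- setdiff(names(grouping), c("binning", "offsets",
                                        "referenceGroup"))
    if (length(extra))
      stop("unknown grouping key(s): ", paste(extra, collapse = ", "))
  }
  class(cfg) <- "poeRunConfig"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [runConfig()]; unknown keys are rejected.
#'
#' @param path YAML file
#' @return validated configuration
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  if (!is.null(raw$reml)) raw$reml <- do.call(remlControl, raw$reml)
  if (!is.null(raw$grouping) && !is.null(raw$grouping$binning))
    raw$grouping$binning <- do.call(groupBinning, raw$grouping$binning)
  do.call(runConfig, raw)
}

#' Read / write phenotype records
#'
#' Delimited text with a header naming at least the columns
#' \code{progeny}, \code{sire}, \code{dam}, \code{group}, \code{parity},
#' \code{birthType}, \code{age}, \code{value} (and optionally
#' \code{class}).
#'
#' @param path file path
#' @param sep separator (\code{NULL}: auto-detect tab/comma)
#' @return data.frame of trait records
#' @export
readRecords <- function(path, sep = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  d <- read.table(path, sep = sep, header = TRUE,
                  stringsAsFactors = FALSE)
  validateRecords(d)
  d
}

#' @rdname readRecords
#' @param records trait records
#' @export
writeRecords <- function(records, path) {
  keep <- !startsWith(names(records), ".")
  write.table(records[, keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Record filters of the slaughter-data pipeline
#'
#' First drops records whose sire or dam is missing (unknown code or
#' \code{NA}), then drops all records of comparison groups smaller than
#' the threshold; the group sizes counted are the post-missing-parent
#' counts. Returns the filtered records together with a per-rule report.
#'
#' @param records trait records
#' @param minGroupSize minimum number of records per comparison group
#'   (5 for most traits, 4 for the killing out percentage)
#' @param unknownCodes parent tokens treated as missing
#' @return list with \code{records} and \code{report} (named counts)
#' @export
applyRecordFilters <- function(records, minGroupSize = 5L,
                               unknownCodes = c("0", "")) {
  n0 <- nrow(records)
  missPar <- is.na(records$sire) | is.na(records$dam) |
    records$sire %in% unknownCodes | records$dam %in% unknownCodes
  records <- records[!missPar, , drop = FALSE]
  gs <- table(records$group)
  small <- records$group %in% names(gs)[gs < minGroupSize]
  records <- records[!small, , drop = FALSE]
  if (!nrow(records))
    stop("all records removed by the filters")
  list(records = records,
       report = c(input = n0, missingParent = sum(missPar),
                  smallGroup = sum(small), retained = nrow(records)))
}

#' Monetary recoding of EUROP conformation classes
#'
#' Replaces the EUROP letters (E best to P poorest) by the standard
#' monetary values 670, 655, 635, 585, 525, whose differences are stable
#' over time even though absolute prices move.
#'
#' @param grades character vector of EUROP letters
#' @return numeric monetary values
#' @examples
#' recodeConformation(c("E", "R", "P"))
#' @export
recodeConformation <- function(grades) {
  map <- c(E = 670, U = 655, R = 635, O = 585, P = 525)
  g <- as.character(grades)
  unknown <- setdiff(unique(g), names(map))
  if (length(unknown))
    stop("unknown EUROP grade '", unknown[1L], "'")
  as.numeric(map[g])
}

#' Run the full analysis pipeline
#'
#' read -> filter -> prune -> (group) -> fit null -> fit full -> RLRT ->
#' equivalent-model solve with PEV and reliability at the fitted
#' components -> genetic trend -> reports. Every stage logs record
#' counts; the run is reproducible given the seed.
#'
#' Variance components are estimated on the ungrouped pruned pedigree;
#' when grouping is configured, the equivalent-model solving stage uses
#' the grouped relationship inverse.
#'
#' @param cfg a [runConfig()]
#' @param pedigree,records optional in-memory inputs overriding the file
#'   paths in \code{cfg}
#' @return list with fits, the RLRT, the equivalent-model solutions,
#'   derived parameters, the trend table, the filter report and the paths
#'   of any files written
#' @export
runPipeline <- function(cfg, pedigree = NULL, records = NULL) {
  stopifnot(inherits(cfg, "poeRunConfig"))
  set.seed(cfg$seed)
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  ped <- stage("read_pedigree",
               if (!is.null(pedigree)) pedigree
               else readPedigree(cfg$pedigreeFile,
                                 unknownCode = cfg$unknownCode))
  recs <- stage("read_records",
                if (!is.null(records)) records
                else readRecords(cfg$phenotypeFile))
  if (cfg$recode == "conformationMonetary")
    recs$value <- stage("recode", recodeConformation(recs$value))
  binary <- cfg$recode == "binary"
  if (binary)
    recs <- stage("binarize", binarize(recs, cfg$binaryTrait))
  flt <- stage("filter", applyRecordFilters(recs, cfg$minGroupSize))
  recs <- flt$records
  log$filter <- flt$report
  message("filter: ", paste(names(flt$report), flt$report,
                            collapse = ", ", sep = "="))
  anchor <- unique(c(recs$progeny, recs$sire, recs$dam))
  ped <- stage("prune", prunePedigree(ped, anchor))
  message("prune: ", length(ped), " animals retained")
  groups <- NULL
  pedSolve <- ped
  if (!is.null(cfg$grouping)) {
    pedSolve <- stage("phantoms", addPhantomParents(ped))
    groups <- stage("groups", do.call(assignPhantomGroups, c(
      list(ped = pedSolve),
      cfg$grouping[intersect(names(cfg$grouping),
                             c("binning", "offsets"))])))
    message("groups: ", length(groups@phantomId), " phantoms in ",
            length(unique(groups@group)), " groups")
  }
  if (binary) {
    fitFull <- stage("fit_full",
                     pqlFit(recs, ped, cfg$modelKind,
                            control = cfg$reml))@innerFit
    fitNull <- NULL
    test <- NULL
  } else {
    fitNull <- stage("fit_null", fitReml(recs, ped, "animal",
                                         control = cfg$reml))
    fitFull <- stage("fit_full", fitReml(recs, ped, cfg$modelKind,
                                         control = cfg$reml))
    test <- stage("rlrt", rlrt(fitFull, fitNull))
    message(sprintf("RLRT = %.3f, P = %.4g", test@statistic,
                    test@pValue))
  }
  ## the solve stage needs a positive-definite G0 even when the
  ## unconstrained fit strayed outside the PSD cone
  vcEq <- psdProjectVc(transformComponents(fitFull@vc, "equivalent"))
  ## for a binary run the PQL state already holds its own solutions
  sol <- trend <- NULL
  if (!binary) {
    design <- stage("design_equivalent",
                    buildDesign(recs, "equivalent", pedSolve))
    ainv <- stage("a_inverse", buildAInverse(pedSolve, groups,
                                             referenceGroup =
                                               cfg$grouping$referenceGroup))
    sys <- stage("assemble", assembleMME("equivalent", design, vcEq, ainv))
    sol <- stage("solve", solveBlup(sys))
    sol <- stage("pev", computePEV(sys, sol))
    sol <- stage("reliability",
                 reliability(sol, vcEq, pedSolve,
                             denominator = cfg$reliabilityDenominator))
    trend <- stage("trend", geneticTrend(sol, pedSolve))
  }
  report <- fitReport(fitFull)
  files <- character(0)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(cfg$outDir, x)
    write.table(report, fp("fit_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- fp("fit_report.tsv")
    if (!is.null(test)) {
      write.table(data.frame(statistic = test@statistic, df = test@df,
                             p_value = test@pValue),
                  fp("rlrt.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, fp("rlrt.tsv"))
    }
    if (!is.null(sol)) {
      writeSolutions(sol, fp("solutions.tsv"))
      write.table(trend, fp("trend.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, fp("solutions.tsv"), fp("trend.tsv"))
    }
    if (!is.null(groups)) {
      writeGroupAssignment(groups, fp("groups.tsv"))
      files <- c(files, fp("groups.tsv"))
    }
  }
  list(fitNull = fitNull, fitFull = fitFull, rlrt = test,
       solutions = sol, trend = trend, report = report,
       filterReport = flt$report, groups = groups, files = files)
}
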