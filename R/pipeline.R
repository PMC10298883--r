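#' Read an expression TSV (gene column + one column per sample)
#'
#' @param path TSV whose first column holds gene symbols.
#' @param condition \code{"normal"} or \code{"tumor"}.
#' @param tissue tissue label.
#' @return an [ExpressionMatrix-class].
#' @export
readExpressionTsv <- function(path, condition, tissue = "") {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  ExpressionMatrix(m, condition, tissue)
}

#' Read a survival table (patient, time_months, event, gene columns)
#'
#' @param path TSV with header columns \code{patient},
#'   \code{time_months}, \code{event}, then one column per gene.
#' @return a [SurvivalCohort-class].
#' @export
readSurvivalTsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("patient", "time_months", "event") %in% names(d)))
  geneCols <- setdiff(names(d), c("patient", "time_months", "event"))
  expr <- t(as.matrix(d[, geneCols, drop = FALSE]))
  colnames(expr) <- d$patient
  SurvivalCohort(expr, d$time_months, d$event, d$patient)
}

#' Assemble a pipeline configuration
#'
#' @param edgeFiles character vector of interaction files (TSV edge
#'   lists and/or MITAB; dialect from extension, \code{.mitab} /
#'   \code{.txt} treated as MITAB only when named so).
#' @param rosterFile ORF roster, one symbol per line.
#' @param hallmarkFile hallmark-association list (optional; CH scoring
#'   skipped without it).
#' @param coexpr optional list(orf=, normalFile=, tumorFile=,
#'   tissueNormal=, tissueTumor=).
#' @param survival optional list(cohortFile=, genes=).
#' @param deFile optional long-format DE table.
#' @param thresholds overrides for chThreshold, minSize, maxSize, rThr,
#'   nearZero, pThr, fcThreshold, pCut, minCancers, alpha.
#' @param seed pipeline seed (stages are deterministic given inputs).
#' @param outDir optional directory for the report and stage tables.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(edgeFiles, rosterFile, hallmarkFile = NULL,
                           coexpr = NULL, survival = NULL, deFile = NULL,
                           thresholds = list(), seed = 20230615,
                           outDir = NULL) {
  thr <- utils::modifyList(
    list(chThreshold = 2, minSize = 7, maxSize = 100, rThr = 0.5,
         nearZero = 0.2, pThr = 0.05, fcThreshold = 2, pCut = 0.05,
         minCancers = 5, alpha = 0.05),
    thresholds)
  structure(list(edgeFiles = edgeFiles, rosterFile = rosterFile,
                 hallmarkFile = hallmarkFile, coexpr = coexpr,
                 survival = survival, deFile = deFile, thresholds = thr,
                 seed = seed, outDir = outDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipelineConfig()] arguments; relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return list of class \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(f) if (is.null(f)) NULL else
    ifelse(startsWith(f, "/"), f, file.path(base, f))
  if (!is.null(y$coexpr)) {
    y$coexpr$normalFile <- rel(y$coexpr$normalFile)
    y$coexpr$tumorFile <- rel(y$coexpr$tumorFile)
  }
  if (!is.null(y$survival)) y$survival$cohortFile <- rel(y$survival$cohortFile)
  pipelineConfig(
    edgeFiles = rel(unlist(y$edgeFiles)), rosterFile = rel(y$rosterFile),
    hallmarkFile = rel(y$hallmarkFile), coexpr = y$coexpr,
    survival = y$survival, deFile = rel(y$deFile),
    thresholds = y$thresholds %||% list(), seed = y$seed %||% 20230615,
    outDir = y$outDir)
}

#' Run the subinteractome analysis pipeline end to end
#'
#' Stages: aggregate interaction records and census the network;
#' extract subinteractomes, size-filter them and prioritize by
#' CH-score; optionally classify normal/tumor co-expression for one
#' ORF, evaluate a survival signature, and group/ordinate a DE matrix.
#' The report records, for every stage, its parameters, input file
#' hashes and the in/out/excluded bookkeeping of each filter, so every
#' count is auditable. Given identical inputs and seed the report is
#' identical.
#'
#' @param config a [pipelineConfig()] / [readPipelineConfig()] result.
#' @return the report (list); written as \code{report.json} when
#'   \code{config$outDir} is set.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(config$outDir))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds
  inputs <- c(config$edgeFiles, config$rosterFile, config$hallmarkFile,
              config$coexpr$normalFile, config$coexpr$tumorFile,
              config$survival$cohortFile, config$deFile)
  report <- list(
    parameters = thr, seed = config$seed,
    inputHashes = as.list(tools::md5sum(inputs)))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- aggregate ---------------------------------------------------
  net <- stage("aggregate", {
    roster <- readRoster(config$rosterFile)
    recs <- lapply(config$edgeFiles, function(f) {
      dialect <- if (grepl("\\.mitab", f, ignore.case = TRUE)) "mitab"
                 else "tsv_edges"
      parseInteractions(f, dialect)
    })
    aggregateNetwork(recs, roster)
  })
  cen <- partnerCensus(net)
  nRecords <- sum(vapply(config$edgeFiles, function(f) {
    dialect <- if (grepl("\\.mitab", f, ignore.case = TRUE)) "mitab"
               else "tsv_edges"
    nrow(suppressWarnings(parseInteractions(f, dialect)))
  }, 0L))
  report$network <- list(
    nRecordsIn = nRecords,
    nUniqueEdges = nrow(networkEdges(net)),
    nDuplicatesMerged = nRecords - nrow(networkEdges(net)) -
      net@nSelfLoopsDropped,
    nSelfLoopsDropped = net@nSelfLoopsDropped,
    nOrfOrfEdges = nrow(cen$orfOrfEdges),
    nSharedByTwo = length(cen$sharedByTwo),
    nSharedByThreePlus = length(cen$sharedByThreePlus),
    nRoster = length(orfRoster(net)),
    nOrphans = length(cen$orphanOrfs))

  # --- subinteractomes + CH-score ----------------------------------
  subs <- allSubinteractomes(net, connectedOnly = TRUE)
  hist <- sizeHistogram(subs)
  kept <- selectBySize(subs, thr$minSize, thr$maxSize)
  report$subinteractomes <- list(
    n = length(subs), sizeHistogram = as.list(hist),
    nSelected = length(kept),
    nExcludedBySize = length(subs) - length(kept))
  if (!is.null(config$hallmarkFile) && length(kept)) {
    prior <- stage("score", {
      ann <- readGeneList(config$hallmarkFile)
      prioritize(chScoreTable(kept, ann), thr$chThreshold)
    })
    report$chScore <- c(prior$summary,
                        list(nExcludedByScore =
                               prior$summary$n - prior$summary$nSelected,
                             prioritizedOrfs = prior$selected$orf))
    if (!is.null(config$outDir))
      writeChScoreTable(prior, file.path(config$outDir, "ch_scores.tsv"))
  }

  # --- co-expression classification --------------------------------
  if (!is.null(config$coexpr)) {
    report$coexpression <- stage("coexpr", {
      cx <- config$coexpr
      normal <- readExpressionTsv(cx$normalFile, "normal",
                                  cx$tissueNormal %||% "")
      tumor <- readExpressionTsv(cx$tumorFile, "tumor",
                                 cx$tissueTumor %||% "")
      orf <- normalizeSymbols(cx$orf)
      partners <- subPartners(subinteractome(net, orf))
      tab <- classifyPpi(coexprTable(orf, partners, normal, tumor),
                         thr$rThr, thr$nearZero, thr$pThr)
      if (!is.null(config$outDir))
        utils::write.table(tab, file.path(config$outDir, "coexpr.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      c(coexprSummary(tab),
        list(nPartnersRequested = length(partners),
             nSkipped = length(partners) - nrow(tab)))
    })
  }

  # --- survival signature ------------------------------------------
  if (!is.null(config$survival)) {
    report$survival <- stage("survive", {
      cohort <- readSurvivalTsv(config$survival$cohortFile)
      res <- evaluateSignature(cohort, config$survival$genes)
      list(genes = res$genes, hr = res$hr, hrCiLo = res$hrCi[1],
           hrCiHi = res$hrCi[2], logrankChi2 = res$logrankChi2,
           p = res$p, nLow = res$nLow, nHigh = res$nHigh,
           quantileSurvivalLow = res$quantileSurvivalLow,
           quantileSurvivalHigh = res$quantileSurvivalHigh)
    })
  }

  # --- DE grouping + PCA -------------------------------------------
  if (!is.null(config$deFile)) {
    report$expression <- stage("express", {
      dcm <- readDeTable(config$deFile, thr$fcThreshold, thr$pCut)
      pan <- panCancerGroup(dcm, thr$minCancers)
      pca <- pcaSvdImpute(encodeCalls(dcm))
      if (!is.null(config$outDir))
        utils::write.table(
          data.frame(cancer = rownames(pca$scores), pca$scores),
          file.path(config$outDir, "pca_scores.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      list(nGenes = length(deGenes(dcm)), nCancers = length(deCancers(dcm)),
           nPanCancer = nrow(pan),
           panCategories = as.list(table(pan$category)),
           pcVariance = pca$varianceExplained[1:2],
           nImputed = pca$nImputed, pcaConverged = pca$converged)
    })
  }

  if (!is.null(config$outDir))
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}
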