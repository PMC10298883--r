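#' Simulation configuration for the synthetic input generators
#'
#' Bundles every parameter the generators need, with defaults emulating
#' the study conditions of the analysis: a 219-member ORF roster of
#' which 177 have known partners, the reference subinteractome-size
#' distribution, 8 direct ORF-ORF interactions, 517 partners shared by
#' exactly two ORFs and roughly 768 interactions running through
#' partners shared by three or more; paired normal/tumor co-expression
#' with a strong normal correlation collapsing in the tumor;
#' proportional-hazards survival with a two-fold hazard in the
#' high-expression group and 20\% censoring; and a gene x cancer DE
#' matrix with two co-regulated cancer clusters, one cancer carrying an
#' exclusive 100-gene down-regulated block, and scattered pan-cancer
#' genes.
#'
#' @param seed master seed; every generator derives its own stream from
#'   it by a named sub-key, so adding one generator call never perturbs
#'   another.
#' @param nRoster roster size.
#' @param sizeDistribution data.frame(min, max, count) of partner-count
#'   ranges; counts sum to the number of connected ORFs.
#' @param nOrfOrfEdges planted direct ORF-ORF interactions.
#' @param nSharedByTwo partners bound to exactly two roster ORFs.
#' @param sharedThreePlusPpis edge budget through partners bound to
#'   three or more roster ORFs (each such partner gets 3-5 ORFs).
#' @param chPrevalence per-partner probability of a hallmark flag when
#'   no explicit targets are given.
#' @param rhoNormal,rhoTumor target Spearman correlations per condition.
#' @param nSamplesNormal,nSamplesTumor expression sample sizes.
#' @param baselineHazard events per month in the low group.
#' @param trueHr hazard multiplier of the high group.
#' @param censorFraction expected fraction censored (uniform
#'   administrative censoring).
#' @param nPatients cohort size.
#' @param signatureDelta mean expression shift of signature genes in the
#'   planted high group (z units).
#' @param nNoiseGenes uninformative genes added to the cohort.
#' @param deMissingFraction fraction of DE cells left unobserved.
#' @return list of class \code{SimulationConfig}.
#' @export
simConfig <- function(seed = 20230615,
                      nRoster = 219,
                      sizeDistribution = data.frame(
                        min = c(1, 7, 15, 30, 70, 101),
                        max = c(6, 14, 29, 69, 100, 150),
                        count = c(63, 30, 40, 27, 6, 11)),
                      nOrfOrfEdges = 8,
                      nSharedByTwo = 517,
                      sharedThreePlusPpis = 768,
                      chPrevalence = 0.28,
                      rhoNormal = 0.7, rhoTumor = -0.6,
                      nSamplesNormal = 200, nSamplesTumor = 200,
                      baselineHazard = 0.05, trueHr = 2,
                      censorFraction = 0.2, nPatients = 500,
                      signatureDelta = 3, nNoiseGenes = 20,
                      deMissingFraction = 0.1) {
  stopifnot(nRoster >= sum(sizeDistribution$count),
            all(sizeDistribution$count >= 0),
            all(sizeDistribution$min <= sizeDistribution$max),
            censorFraction >= 0, censorFraction < 1,
            abs(rhoNormal) < 1, abs(rhoTumor) < 1,
            baselineHazard > 0, trueHr > 0,
            chPrevalence >= 0, chPrevalence <= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

# deterministic sub-stream: run expr under a seed derived from
# (seed, key), restoring the caller's RNG state afterwards
withSubSeed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  codes <- utf8ToInt(key)
  sub <- (as.double(seed) %% 2147483647) * 48271 +
    sum(codes * seq_along(codes)) + 1
  set.seed(as.integer(sub %% 2147483647))
  force(expr)
}

#' Generate a PPI network with a planted partner structure
#'
#' Builds an aggregated network whose subinteractome-size histogram
#' matches \code{cfg$sizeDistribution} exactly. ORF-ORF edges, partners
#' shared by exactly two ORFs and partners shared by three or more are
#' planted first (consuming the affected ORFs' partner budgets), then
#' each ORF's remaining budget is filled with exclusive partners.
#' Roster members beyond the distribution's total stay orphans.
#'
#' @param cfg a [simConfig()].
#' @return list with \code{network} (an [AggregatedNetwork-class]) and
#'   \code{ledger} (planted sizes, ORF-ORF pairs, shared partners,
#'   orphans).
#' @export
genPpiNetwork <- function(cfg) {
  withSubSeed(cfg$seed, "ppi", {
    dist <- cfg$sizeDistribution
    nConnected <- sum(dist$count)
    roster <- sprintf("ORF%03d", seq_len(cfg$nRoster))
    connected <- sort(sample(roster, nConnected))
    orphans <- setdiff(roster, connected)
    sizes <- unlist(lapply(seq_len(nrow(dist)), function(i) {
      if (dist$count[i] == 0) return(integer())
      rng <- seq(dist$min[i], dist$max[i])
      rng[sample.int(length(rng), dist$count[i], replace = TRUE)]
    }))
    sizes <- as.integer(sizes)[sample.int(nConnected)]
    names(sizes) <- connected
    budget <- sizes
    drawOrfs <- function(k) {
      avail <- names(budget)[budget > 0]
      if (length(avail) < k)
        stop("infeasible size distribution: shared-partner demands ",
             "exceed the partner pool")
      sample(avail, k, prob = budget[avail])
    }
    edges <- list()
    addEdge <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
    # direct ORF-ORF interactions
    orfPairs <- matrix(character(), 0, 2)
    guard <- 0L
    while (nrow(orfPairs) < cfg$nOrfOrfEdges) {
      guard <- guard + 1L
      if (guard > 1000L * (cfg$nOrfOrfEdges + 1L))
        stop("infeasible size distribution: cannot place ORF-ORF edges")
      pr <- sort(drawOrfs(2L))
      if (any(orfPairs[, 1] == pr[1] & orfPairs[, 2] == pr[2])) next
      orfPairs <- rbind(orfPairs, pr)
      addEdge(pr[1], pr[2])
      budget[pr] <- budget[pr] - 1L
    }
    partnerId <- 0L
    newPartner <- function() {
      partnerId <<- partnerId + 1L
      sprintf("PRT%05d", partnerId)
    }
    sharedTwo <- character()
    if (cfg$nSharedByTwo > 0) for (i in seq_len(cfg$nSharedByTwo)) {
      orfs <- drawOrfs(2L)
      p <- newPartner()
      sharedTwo <- c(sharedTwo, p)
      for (o in orfs) addEdge(o, p)
      budget[orfs] <- budget[orfs] - 1L
    }
    sharedThree <- character()
    ppiLeft <- cfg$sharedThreePlusPpis
    while (ppiLeft >= 3) {
      deg <- min(sample(3:5, 1L), ppiLeft, sum(budget > 0))
      if (deg < 3) break
      orfs <- drawOrfs(deg)
      p <- newPartner()
      sharedThree <- c(sharedThree, p)
      for (o in orfs) addEdge(o, p)
      budget[orfs] <- budget[orfs] - 1L
      ppiLeft <- ppiLeft - deg
    }
    # exclusive partners absorb the remaining budget
    for (o in names(budget)) {
      if (budget[[o]] > 0) for (i in seq_len(budget[[o]]))
        addEdge(o, newPartner())
    }
    m <- do.call(rbind, edges)
    recs <- data.frame(geneA = m[, 1], geneB = m[, 2], source = "sim",
                       stringsAsFactors = FALSE)
    net <- aggregateNetwork(recs, roster)
    list(network = net,
         ledger = list(sizes = sizes,
                       orfOrfPairs = unname(orfPairs),
                       sharedByTwo = sort(sharedTwo),
                       sharedByThreePlus = sort(sharedThree),
                       sharedThreePlusPpisPlanted =
                         cfg$sharedThreePlusPpis - ppiLeft,
                       orphans = orphans))
  })
}

#' Plant a hallmark annotation achieving per-ORF CH-score targets
#'
#' With explicit targets, flags partners so that [chScore()] on the
#' generated annotation returns each requested target exactly. Only
#' partners bound to a single roster ORF are then flagged (shared
#' partners would couple the scores of several ORFs), and roster
#' symbols are never flagged, so the result is exact under either
#' \code{countSelf} setting. Without explicit targets, every non-roster
#' partner in the network is flagged independently with probability
#' \code{cfg$chPrevalence}, so each subinteractome's expected CH-score
#' is \code{10 * chPrevalence} regardless of partner sharing (the
#' default 0.28 emulates a score population with median near 2.8).
#'
#' @param net an [AggregatedNetwork-class] (typically from
#'   [genPpiNetwork()]).
#' @param targetScores named numeric vector of CH-score targets (names
#'   are roster symbols); each must equal \code{10 k / n} for an integer
#'   k within the ORF's exclusive-partner count. \code{NULL} for the
#'   prevalence-driven default.
#' @param cfg a [simConfig()] (seed and prevalence).
#' @return list with \code{annotation} (character vector of flagged
#'   symbols) and \code{ledger} (realized per-ORF scores).
#' @export
genHallmarkAnnotation <- function(net, targetScores = NULL, cfg = simConfig()) {
  withSubSeed(cfg$seed, "hallmark", {
    cen <- partnerCensus(net)
    if (is.null(targetScores)) {
      partners <- setdiff(networkNodes(net), net@orfRoster)
      flagged <- partners[stats::runif(length(partners)) < cfg$chPrevalence]
      connected <- setdiff(net@orfRoster, cen$orphanOrfs)
      realized <- vapply(connected, function(o)
        chScore(subinteractome(net, o), flagged, countSelf = FALSE)$score,
        0)
      return(list(annotation = sort(flagged),
                  ledger = list(scores = realized)))
    }
    exclusive <- cen$singleOrf
    flagged <- character()
    realized <- numeric()
    for (o in names(targetScores)) {
      sub <- subinteractome(net, o)
      n <- subSize(sub)
      if (n == 0)
        stop("ORF '", o, "' has no partners; any CH-score target is ",
             "unachievable")
      pool <- intersect(subPartners(sub), exclusive)
      target <- targetScores[[o]]
      k <- target * n / 10
      if (abs(k - round(k)) > 1e-9 || round(k) > length(pool))
        stop("CH-score target ", target, " unachievable for ORF '", o,
             "' (", n, " partners, ", length(pool), " exclusive)")
      k <- as.integer(round(k))
      if (k > 0) flagged <- c(flagged, sample(pool, k))
      realized[[o]] <- 10 * k / n
    }
    list(annotation = sort(unique(flagged)),
         ledger = list(scores = realized))
  })
}

# latent bivariate-normal correlation reproducing a target Spearman
latentRho <- function(rhoS) 2 * sin(pi * rhoS / 6)

#' Generate a matched normal/tumor expression pair with planted
#' co-expression
#'
#' Draws bivariate samples from a Gaussian copula with log-normal
#' marginals so that the ORF gene and each partner gene have the target
#' Spearman correlation in each condition. The latent Pearson
#' correlation is solved from the bivariate-normal identity
#' \code{rho_S = (6/pi) asin(rho/2)}, making targets exact in
#' expectation.
#'
#' @param cfg a [simConfig()]; uses \code{rhoNormal}, \code{rhoTumor},
#'   \code{nSamplesNormal}, \code{nSamplesTumor}.
#' @param orfGene,partnerGenes gene names to plant; \code{rhoNormal} and
#'   \code{rhoTumor} may be vectors along \code{partnerGenes}.
#' @param tissueNormal,tissueTumor labels for the two matrices.
#' @return list with \code{normal} and \code{tumor}
#'   ([ExpressionMatrix-class]) and \code{ledger} (targets used).
#' @export
genExpressionPair <- function(cfg, orfGene = "ORF001",
                              partnerGenes = "PRT00001",
                              tissueNormal = "normal tissue",
                              tissueTumor = "tumor") {
  withSubSeed(cfg$seed, "coexpr", {
    rhoN <- rep_len(cfg$rhoNormal, length(partnerGenes))
    rhoT <- rep_len(cfg$rhoTumor, length(partnerGenes))
    stopifnot(all(abs(rhoN) < 1), all(abs(rhoT) < 1),
              cfg$nSamplesNormal >= 10, cfg$nSamplesTumor >= 10)
    draw <- function(n, rhos) {
      z0 <- stats::rnorm(n)
      rows <- lapply(rhos, function(rs) {
        r <- latentRho(rs)
        z <- r * z0 + sqrt(1 - r^2) * stats::rnorm(n)
        exp(2 + 0.8 * z)  # log-normal marginal
      })
      m <- rbind(exp(2 + 0.8 * z0), do.call(rbind, rows))
      rownames(m) <- c(orfGene, partnerGenes)
      m
    }
    normal <- ExpressionMatrix(draw(cfg$nSamplesNormal, rhoN),
                               "normal", tissueNormal)
    tumor <- ExpressionMatrix(draw(cfg$nSamplesTumor, rhoT),
                              "tumor", tissueTumor)
    list(normal = normal, tumor = tumor,
         ledger = list(rhoNormal = rhoN, rhoTumor = rhoT))
  })
}

#' Generate a proportional-hazards survival cohort with a planted
#' signature
#'
#' Patients are split into equal planted low/high groups. Signature
#' genes are shifted by \code{cfg$signatureDelta} in the high group (so
#' a median split on the mean-z signature score recovers the planted
#' labels), noise genes are standard normal. Event times are
#' exponential with hazard \code{baselineHazard} (low) and
#' \code{baselineHazard * trueHr} (high); administrative censoring is
#' uniform on \code{[0, Tmax]} with Tmax solved numerically to hit
#' \code{censorFraction} in expectation.
#'
#' @param cfg a [simConfig()].
#' @param signatureGenes symbols of the planted signature genes.
#' @return list with \code{cohort} (a [SurvivalCohort-class]) and
#'   \code{ledger} (true group per patient, Tmax, parameters).
#' @export
genSurvivalCohort <- function(cfg, signatureGenes = c("SIG1", "SIG2", "SIG3")) {
  withSubSeed(cfg$seed, "survival", {
    n <- cfg$nPatients
    group <- rep(c(0L, 1L), length.out = n)[sample.int(n)]
    lambda <- cfg$baselineHazard * cfg$trueHr^group
    tEvent <- stats::rexp(n, lambda)
    if (cfg$censorFraction > 0) {
      pc <- function(tmax) {
        mean((1 - exp(-lambda * tmax)) / (lambda * tmax)) -
          cfg$censorFraction
      }
      tmax <- stats::uniroot(pc, c(1e-6, 1e6))$root
      cens <- stats::runif(n, 0, tmax)
      time <- pmin(tEvent, cens)
      event <- as.integer(tEvent <= cens)
    } else {
      tmax <- Inf
      time <- tEvent
      event <- rep(1L, n)
    }
    sig <- matrix(stats::rnorm(length(signatureGenes) * n), ncol = n) +
      rep(cfg$signatureDelta * group, each = length(signatureGenes))
    noise <- matrix(stats::rnorm(cfg$nNoiseGenes * n), ncol = n)
    expr <- rbind(sig, noise)
    rownames(expr) <- c(normalizeSymbols(signatureGenes),
                        sprintf("NOISE%03d", seq_len(cfg$nNoiseGenes)))
    colnames(expr) <- sprintf("P%04d", seq_len(n))
    cohort <- SurvivalCohort(expr, time, event)
    list(cohort = cohort,
         ledger = list(trueGroup = group, tmax = tmax,
                       baselineHazard = cfg$baselineHazard,
                       trueHr = cfg$trueHr))
  })
}

# the DE block plan emulated by default: two co-regulated cancers
# sharing an up block, one cancer with an exclusive 100-gene down
# block (plus a small non-exclusive down spillover), one up-only and
# one down-only cancer, and a handful of pan-cancer genes
defaultDeBlocks <- function() {
  list(
    list(cancers = c("DLBC", "THYM"), genes = 1:68, direction = "up"),
    list(cancers = "TGCT", genes = 69:168, direction = "down"),
    list(cancers = c("TGCT", "SKCM"), genes = 169:178, direction = "down"),
    list(cancers = "LAML", genes = 179:201, direction = "up"),
    list(cancers = c("UCEC", "OV", "COAD", "READ", "PAAD", "ESCA"),
         genes = 202:204, direction = "down"),
    list(cancers = c("BRCA", "LUAD", "LUSC", "KIRC", "GBM"),
         genes = 205:208, direction = "up"),
    list(cancers = c("KICH", "KIRP", "UCS"), genes = 209:212,
         direction = "up"),
    list(cancers = c("OV", "ESCA", "GBM"), genes = 209:212,
         direction = "down"))
}

#' Generate a sparse gene x cancer DE-call matrix with planted clusters
#'
#' Background cells are non-significant (small fold-changes, large
#' p-values); each planted block receives fold-changes beyond the
#' four-fold gate with small p-values in the stated direction. A
#' fraction of cells is then hidden (\code{NA}), never emptying a whole
#' row or column.
#'
#' @param cfg a [simConfig()].
#' @param genes gene symbols (default \code{ORF001..ORF219}, matching
#'   the roster naming).
#' @param cancers cancer codes.
#' @param blocks list of \code{list(cancers=, genes=, direction=)}
#'   (gene indices into \code{genes}).
#' @return list with \code{dcm} (a [DECallMatrix-class]) and
#'   \code{ledger} (the blocks and the hidden-cell mask).
#' @export
genDeMatrix <- function(cfg,
                        genes = sprintf("ORF%03d", 1:219),
                        cancers = c("TGCT", "LAML", "DLBC", "THYM",
                                    "SKCM", "LUSC", "LUAD", "GBM",
                                    "UCEC", "UCS", "OV", "BRCA", "KICH",
                                    "KIRC", "KIRP", "COAD", "READ",
                                    "PAAD", "ESCA"),
                        blocks = defaultDeBlocks()) {
  withSubSeed(cfg$seed, "dematrix", {
    G <- length(genes); K <- length(cancers)
    for (b in blocks)
      stopifnot(all(b$cancers %in% cancers), all(b$genes <= G),
                b$direction %in% c("up", "down"))
    fc <- matrix(stats::rnorm(G * K, 0, 0.3), G, K,
                 dimnames = list(genes, cancers))
    pm <- matrix(stats::runif(G * K, 0.2, 1), G, K,
                 dimnames = list(genes, cancers))
    for (b in blocks) {
      sgn <- if (b$direction == "up") 1 else -1
      for (ca in b$cancers) {
        idx <- b$genes
        fc[idx, ca] <- sgn * (2 + abs(stats::rnorm(length(idx), 1, 0.5)))
        pm[idx, ca] <- stats::runif(length(idx), 0, 0.049)
      }
    }
    mask <- matrix(stats::runif(G * K) < cfg$deMissingFraction, G, K)
    # never hide a whole row or column
    for (i in which(rowSums(!mask) == 0)) mask[i, sample.int(K, 1)] <- FALSE
    for (j in which(colSums(!mask) == 0)) mask[sample.int(G, 1), j] <- FALSE
    fc[mask] <- NA; pm[mask] <- NA
    list(dcm = deCallMatrix(fc, pm),
         ledger = list(blocks = blocks, hidden = mask))
  })
}

#' Write every simulated input as plain-text fixtures
#'
#' Emits the same formats the pipeline consumes: an edge-list TSV and a
#' roster file from the PPI generator, a hallmark list, normal/tumor
#' expression TSVs, a survival table and a long-format DE table, plus a
#' ledger JSON recording the planted ground truth.
#'
#' @param cfg a [simConfig()].
#' @param dir output directory (created if needed).
#' @return named list of the written paths, invisibly.
#' @export
writeSimulatedInputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  ppi <- genPpiNetwork(cfg)
  ed <- networkEdges(ppi$network)
  utils::write.table(ed[, c("geneA", "geneB", "sources")], p("edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  writeLines(orfRoster(ppi$network), p("roster.txt"))
  ann <- genHallmarkAnnotation(ppi$network, cfg = cfg)
  writeLines(ann$annotation, p("hallmarks.txt"))
  ex <- genExpressionPair(cfg)
  writeExpr <- function(em, f) {
    v <- exprValues(em)
    utils::write.table(data.frame(gene = rownames(v), v,
                                  check.names = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeExpr(ex$normal, p("expr_normal.tsv"))
  writeExpr(ex$tumor, p("expr_tumor.tsv"))
  sv <- genSurvivalCohort(cfg)
  sexpr <- t(exprValues(sv$cohort))
  utils::write.table(
    data.frame(patient = colnames(exprValues(sv$cohort)),
               time_months = survTime(sv$cohort),
               event = survEvent(sv$cohort), sexpr, check.names = FALSE),
    p("survival.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  de <- genDeMatrix(cfg)
  fc <- de$dcm@log2fc; pv <- de$dcm@p
  obs <- which(!is.na(fc), arr.ind = TRUE)
  utils::write.table(
    data.frame(gene = rownames(fc)[obs[, 1]],
               cancer = colnames(fc)[obs[, 2]],
               log2fc = fc[obs], p = pv[obs]),
    p("de.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed,
         orphans = ppi$ledger$orphans,
         nSharedByTwo = length(ppi$ledger$sharedByTwo),
         nSharedByThreePlus = length(ppi$ledger$sharedByThreePlus),
         trueHr = cfg$trueHr),
    p("ledger.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(edges = p("edges.tsv"), roster = p("roster.txt"),
                 hallmarks = p("hallmarks.txt"),
                 exprNormal = p("expr_normal.tsv"),
                 exprTumor = p("expr_tumor.tsv"),
                 survival = p("survival.tsv"), de = p("de.tsv"),
                 ledger = p("ledger.json")))
}
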