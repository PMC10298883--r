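#' Ternary differential-expression calls
#'
#' A gene in a cancer is called \code{up} when log2FC >= threshold and
#' p < cutoff, \code{down} when log2FC <= -threshold and p < cutoff,
#' \code{ns} otherwise; the boundary |log2FC| = threshold counts as
#' differentially expressed (the default threshold of 2 is the four-fold
#' change). Cells with a missing input stay \code{NA}.
#'
#' @param log2fc,p numeric matrices of equal shape (genes x cancers),
#'   \code{NA} allowed.
#' @param fcThreshold absolute log2 fold-change gate (default 2).
#' @param pCut p-value gate (default 0.05).
#' @return character matrix over \code{up}/\code{down}/\code{ns}/NA.
#' @export
deCall <- function(log2fc, p, fcThreshold = 2, pCut = 0.05) {
  if (!identical(dim(log2fc), dim(p)))
    stop("log2fc and p matrices must share shape")
  call <- matrix(NA_character_, nrow(log2fc), ncol(log2fc),
                 dimnames = dimnames(log2fc))
  obs <- !is.na(log2fc) & !is.na(p)
  call[obs] <- "ns"
  call[obs & log2fc >= fcThreshold & p < pCut] <- "up"
  call[obs & log2fc <= -fcThreshold & p < pCut] <- "down"
  call
}

#' Build a DECallMatrix from effect sizes and p-values
#'
#' @inheritParams deCall
#' @return a [DECallMatrix-class].
#' @export
deCallMatrix <- function(log2fc, p, fcThreshold = 2, pCut = 0.05) {
  log2fc <- as.matrix(log2fc); p <- as.matrix(p)
  rownames(log2fc) <- normalizeSymbols(rownames(log2fc))
  dimnames(p) <- dimnames(log2fc)
  new("DECallMatrix", log2fc = log2fc, p = p,
      call = deCall(log2fc, p, fcThreshold, pCut),
      fcThreshold = fcThreshold, pCut = pCut)
}

#' Read a long-format DE table (gene, cancer, log2fc, p)
#'
#' @param path TSV with header columns gene, cancer, log2fc, p.
#' @inheritParams deCall
#' @return a [DECallMatrix-class]; unobserved gene/cancer cells are NA.
#' @export
readDeTable <- function(path, fcThreshold = 2, pCut = 0.05) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "cancer", "log2fc", "p") %in% names(d)))
  genes <- unique(normalizeSymbols(d$gene))
  cancers <- unique(toupper(d$cancer))
  fc <- pm <- matrix(NA_real_, length(genes), length(cancers),
                     dimnames = list(genes, cancers))
  idx <- cbind(match(normalizeSymbols(d$gene), genes),
               match(toupper(d$cancer), cancers))
  fc[idx] <- d$log2fc
  pm[idx] <- d$p
  deCallMatrix(fc, pm, fcThreshold, pCut)
}

#' Genes differentially expressed in a single cancer only
#'
#' Returns the genes carrying the requested call in the named cancer
#' while being \code{ns} (or unobserved) in every other cancer — e.g.
#' a cancer-specific down-regulated expression signature.
#'
#' @param dcm a [DECallMatrix-class].
#' @param cancer cancer code present in the matrix.
#' @param direction \code{"down"} or \code{"up"}.
#' @return character vector of gene symbols.
#' @export
cancerSpecificGenes <- function(dcm, cancer, direction = c("down", "up")) {
  direction <- match.arg(direction)
  cancer <- toupper(cancer)
  if (!cancer %in% deCancers(dcm))
    stop("unknown cancer code: ", cancer)
  calls <- deCalls(dcm)
  inTarget <- !is.na(calls[, cancer]) & calls[, cancer] == direction
  others <- calls[, setdiff(colnames(calls), cancer), drop = FALSE]
  quietElsewhere <- apply(others, 1L, function(r)
    all(is.na(r) | r == "ns"))
  rownames(calls)[inTarget & quietElsewhere]
}

#' Pan-cancer grouping of differentially expressed genes
#'
#' Genes differentially expressed in at least \code{minCancers} cancers
#' form the pan-cancer group and are categorized by call direction:
#' \code{preferentially_up}/\code{preferentially_down} when one
#' direction accounts for more than 2/3 of the DE calls (all-one-way
#' included), \code{mixed} otherwise.
#'
#' @param dcm a [DECallMatrix-class].
#' @param minCancers membership threshold (default 5).
#' @return data.frame: gene, nUp, nDown, category.
#' @export
panCancerGroup <- function(dcm, minCancers = 5) {
  calls <- deCalls(dcm)
  nUp <- rowSums(calls == "up", na.rm = TRUE)
  nDown <- rowSums(calls == "down", na.rm = TRUE)
  nDe <- nUp + nDown
  keep <- nDe >= minCancers
  if (!any(keep))
    return(data.frame(gene = character(), nUp = integer(),
                      nDown = integer(), category = character()))
  nUp <- nUp[keep]; nDown <- nDown[keep]; nDe <- nDe[keep]
  category <- ifelse(nUp / nDe > 2 / 3, "preferentially_up",
              ifelse(nDown / nDe > 2 / 3, "preferentially_down", "mixed"))
  out <- data.frame(gene = rownames(deCalls(dcm))[keep],
                    nUp = as.integer(nUp), nDown = as.integer(nDown),
                    category = category, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Numeric encoding of DE calls for ordination
#'
#' \code{ternary}: up = +1, down = -1, ns = 0, missing = NA;
#' \code{log2fc}: the continuous fold-changes (ns cells kept, missing
#' NA). Rows of the returned matrix are cancers — the units ordinated by
#' [pcaSvdImpute()] — and columns are genes.
#'
#' @param dcm a [DECallMatrix-class].
#' @param encoding \code{"ternary"} (default) or \code{"log2fc"}.
#' @return numeric cancers x genes matrix.
#' @export
encodeCalls <- function(dcm, encoding = c("ternary", "log2fc")) {
  encoding <- match.arg(encoding)
  if (encoding == "ternary") {
    calls <- deCalls(dcm)
    m <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
    m[!is.na(calls) & calls == "ns"] <- 0
    m[!is.na(calls) & calls == "up"] <- 1
    m[!is.na(calls) & calls == "down"] <- -1
  } else {
    m <- dcm@log2fc
  }
  t(m)
}

#' Principal components by SVD with iterative imputation
#'
#' PCA of a matrix with missing cells: missing values are initialized at
#' their row means, then the matrix is repeatedly column-centered,
#' approximated by its rank-k truncated SVD, and the missing cells are
#' refilled from the reconstruction until the largest refill change
#' drops below \code{tol} (or \code{maxIter} is hit, flagged as
#' non-convergence). Scores come from the SVD of the completed,
#' column-centered matrix; no row scaling is applied. Variance fractions
#' are squared singular values over their total.
#'
#' @param x numeric matrix (observations x variables, e.g. cancers x
#'   genes), \code{NA} for missing; every row and column needs at least
#'   one observed cell.
#' @param nComponents rank of the imputation model and number of
#'   returned components (default 2).
#' @param maxIter,tol iteration controls.
#' @return list of class \code{PCAResult}: \code{scores} (observations x
#'   components), \code{loadings}, \code{varianceExplained} (all
#'   singular directions), \code{nImputed}, \code{converged},
#'   \code{iterations}, \code{completed} (the imputed matrix).
#' @export
pcaSvdImpute <- function(x, nComponents = 2, maxIter = 500, tol = 1e-6) {
  x <- as.matrix(x)
  miss <- is.na(x)
  if (any(rowSums(!miss) == 0)) stop("a row has no observed cell")
  if (any(colSums(!miss) == 0)) stop("a column has no observed cell")
  k <- min(nComponents, dim(x) - c(0, 0))
  filled <- x
  if (any(miss)) {
    rm <- rowMeans(x, na.rm = TRUE)
    filled[miss] <- rm[row(x)[miss]]
  }
  converged <- TRUE
  iter <- 0L
  if (any(miss)) {
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
      mu <- colMeans(filled)
      ctr <- sweep(filled, 2L, mu)
      sv <- svd(ctr, nu = k, nv = k)
      recon <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
      newVals <- sweep(recon, 2L, mu, `+`)[miss]
      delta <- max(abs(newVals - filled[miss]))
      filled[miss] <- newVals
      if (delta < tol) { converged <- TRUE; break }
    }
  }
  mu <- colMeans(filled)
  ctr <- sweep(filled, 2L, mu)
  sv <- svd(ctr)
  ve <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(
    list(scores = scores, loadings = loadings, varianceExplained = ve,
         nImputed = sum(miss), converged = converged, iterations = iter,
         completed = filled),
    class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  ve <- x$varianceExplained
  cat(sprintf("PCA (SVD with imputation): %d cells imputed%s\n",
              x$nImputed,
              if (x$converged) "" else " [did not converge]"))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of total variance\n",
              100 * ve[1], 100 * ifelse(length(ve) > 1, ve[2], 0)))
  invisible(x)
}
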