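#' Read a hallmark-association gene list
#'
#' One symbol per line, or a 2-column TSV (symbol, tag); lines starting
#' with \code{#} are ignored. The returned vector is the set of genes
#' annotated as cancer-hallmark-associated.
#'
#' @param path text file.
#' @return character vector of unique uppercased symbols, with the tag
#'   column (if any) kept in attribute \code{tags}.
#' @export
readGeneList <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- x[nzchar(trimws(x)) & !startsWith(trimws(x), "#")]
  fields <- strsplit(x, "\t", fixed = TRUE)
  syms <- normalizeSymbols(vapply(fields, `[[`, "", 1L))
  tags <- vapply(fields, function(f) if (length(f) > 1) f[[2]] else "", "")
  keep <- !duplicated(syms)
  out <- syms[keep]
  attr(out, "tags") <- tags[keep]
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields term, description, member
#' genes. Parsing is delegated to [fgsea::gmtPathways()]; member symbols
#' are uppercased for case-insensitive matching.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, normalizeSymbols)
}

#' Cancer-hallmark score of a subinteractome
#'
#' The CH-score is the relative frequency of cancer-hallmark-associated
#' proteins per 10 protein partners: \code{10 * nCh / nPartners}. A score
#' of 1 therefore means one hallmark-associated protein among 10
#' partners. With \code{countSelf = TRUE} (default) the target protein
#' itself contributes to the numerator when it is hallmark-associated,
#' while the denominator stays the partner count.
#'
#' @param sub a [Subinteractome-class] with at least one partner.
#' @param annotation character vector of hallmark-associated symbols
#'   (e.g. from [readGeneList()]).
#' @param countSelf should a hallmark-associated target count itself?
#' @return list of class \code{CHScoreReport}: \code{orf},
#'   \code{nPartners}, \code{nCh}, \code{score} and \code{core} (the
#'   hallmark-associated partners).
#' @examples
#' sub <- Subinteractome("C1ORF94", paste0("P", 1:10))
#' chScore(sub, annotation = "P1")$score  # exactly 1
#' @export
chScore <- function(sub, annotation, countSelf = TRUE) {
  n <- subSize(sub)
  if (n < 1)
    stop("CH-score undefined for an empty subinteractome (", subOrf(sub), ")")
  annotation <- normalizeSymbols(annotation)
  core <- intersect(subPartners(sub), annotation)
  nCh <- length(core) + as.integer(countSelf && subOrf(sub) %in% annotation)
  structure(
    list(orf = subOrf(sub), nPartners = n, nCh = nCh,
         score = 10 * nCh / n, core = core),
    class = "CHScoreReport")
}

#' @export
print.CHScoreReport <- function(x, ...) {
  cat(sprintf("CH-score of %s: %.2f (%d hallmark-associated / %d partners)\n",
              x$orf, x$score, x$nCh, x$nPartners))
  invisible(x)
}

#' CH-scores for a list of subinteractomes
#'
#' @param subs list of [Subinteractome-class] objects (sizes >= 1).
#' @inheritParams chScore
#' @return data.frame with columns orf, nPartners, nCh, score.
#' @export
chScoreTable <- function(subs, annotation, countSelf = TRUE) {
  rows <- lapply(subs, function(s) {
    r <- chScore(s, annotation, countSelf)
    data.frame(orf = r$orf, nPartners = r$nPartners, nCh = r$nCh,
               score = r$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prioritize subinteractomes by CH-score
#'
#' Keeps reports with \code{score >= threshold} and summarizes the score
#' distribution (median and 25th percentile by type-7 linear
#' interpolation, plus the selected fraction). The default threshold of 2
#' sits near the 25th percentile when the median score is around 2.8.
#'
#' @param reports data.frame from [chScoreTable()] (needs a \code{score}
#'   column), non-empty.
#' @param threshold minimum score, >= 0.
#' @return list with \code{selected} (data.frame, \code{selected} flag
#'   added to all rows in \code{scored}) and \code{summary} (median,
#'   p25, fractionSelected, nSelected, n).
#' @export
prioritize <- function(reports, threshold = 2) {
  if (!is.data.frame(reports) || !nrow(reports))
    stop("no CH-score reports to prioritize")
  stopifnot(threshold >= 0)
  sel <- reports$score >= threshold
  scored <- reports
  scored$selected <- sel
  list(
    selected = reports[sel, , drop = FALSE],
    scored = scored,
    summary = list(
      median = stats::median(reports$score),
      p25 = unname(stats::quantile(reports$score, 0.25, type = 7)),
      fractionSelected = mean(sel),
      nSelected = sum(sel),
      n = nrow(reports)))
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' drawing at least the observed overlap when \code{|query|} genes are
#' sampled from a universe of \code{background} genes of which
#' \code{termSize} belong to the set. Benjamini-Hochberg FDR is computed
#' across the retained terms (those with \code{termSize >= minTermSize}).
#' A term is called significant when its FDR is below \code{fdrCutoff}
#' and it covers more than \code{coverageCutoff} of the query (the
#' >10\%-of-subinteractome rule). Results are reported un-collapsed; no
#' redundancy reduction between overlapping terms is attempted.
#'
#' @param query character vector of gene symbols (the subinteractome).
#' @param geneSets named list of symbol vectors (e.g. [readGmt()]).
#' @param background universe: either a size (default 19467, the
#'   protein-coding reference) or a character vector of universe symbols.
#'   When a vector is given, query genes outside it are dropped with a
#'   warning and the universe size is its length.
#' @param minTermSize smallest term kept (default 4).
#' @param fdrCutoff significance level on BH-adjusted p (default 0.1).
#' @param coverageCutoff minimum covered query fraction, exclusive
#'   (default 0.10).
#' @return data.frame: termId, termSize, overlap, pValue, fdr, coverage,
#'   significant; ordered by pValue.
#' @export
ora <- function(query, geneSets, background = 19467, minTermSize = 4,
                fdrCutoff = 0.1, coverageCutoff = 0.10) {
  query <- unique(normalizeSymbols(query))
  if (!length(query)) stop("empty query")
  if (!length(geneSets)) stop("empty gene-set collection")
  if (is.character(background)) {
    universe <- unique(normalizeSymbols(background))
    out <- setdiff(query, universe)
    if (length(out)) {
      warning(length(out), " query gene(s) absent from the universe; ",
              "ignored: ", paste(utils::head(out, 5), collapse = ", "))
      query <- intersect(query, universe)
      if (!length(query)) stop("no query gene lies in the universe")
    }
    geneSets <- lapply(geneSets, intersect, universe)
    N <- length(universe)
  } else {
    N <- as.integer(background)
  }
  n <- length(query)
  if (N < n) stop("universe smaller than the query")
  sizes <- vapply(geneSets, function(s) length(unique(s)), 0L)
  keep <- sizes >= minTermSize
  geneSets <- geneSets[keep]
  sizes <- sizes[keep]
  if (!length(geneSets))
    return(data.frame(termId = character(), termSize = integer(),
                      overlap = integer(), pValue = numeric(),
                      fdr = numeric(), coverage = numeric(),
                      significant = logical()))
  ov <- vapply(geneSets, function(s) length(intersect(query, s)), 0L)
  p <- stats::phyper(ov - 1L, sizes, N - sizes, n, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  cov <- ov / n
  res <- data.frame(
    termId = names(geneSets), termSize = sizes, overlap = ov,
    pValue = p, fdr = fdr, coverage = cov,
    significant = fdr < fdrCutoff & cov > coverageCutoff,
    stringsAsFactors = FALSE)
  res <- res[order(res$pValue, res$termId), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a CH-score table with its selection flag
#'
#' @param prior result of [prioritize()].
#' @param path output TSV.
#' @export
writeChScoreTable <- function(prior, path) {
  utils::write.table(prior$scored, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(prior$scored)
}
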