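#' Spearman rank correlation with significance
#'
#' Rho is the Pearson correlation of mid-ranks (ties get average ranks).
#' The two-sided p-value uses the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on \code{n - 2} degrees
#' of freedom, adequate for the intended sample sizes (n >= 10); for
#' tiny samples (n <= 9) an exact permutation p-value is available.
#' Perfect monotone association (|rho| = 1) is reported with p = 0.
#'
#' @param x,y numeric vectors of equal length n >= 4, finite, neither
#'   constant.
#' @param method \code{"t"} (default) or \code{"exact"} (permutation
#'   enumeration, n <= 9 only).
#' @return list with \code{rho}, \code{p} and \code{n}.
#' @examples
#' spearmanTest(1:5, c(2, 4, 6, 8, 10))$rho  # 1
#' @export
spearmanTest <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 9) stop("exact permutation p only supported for n <= 9")
    perms <- permutationsOf(n)
    stat <- abs(apply(perms, 1L, function(pm) stats::cor(rx, ry[pm])))
    p <- mean(stat >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# all permutations of 1..n as an n!-row matrix (recursive; n <= 9)
permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsOf(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- ifelse(sub >= i, sub + 1L, sub)
  }
  out
}

#' Normal/tumor co-expression of one ORF against its partners
#'
#' For each partner present in both matrices, computes the Spearman
#' correlation of the ORF gene with the partner gene separately in the
#' normal-tissue and tumor matrices. Partners missing from either matrix
#' are skipped with a warning; a missing ORF gene is fatal.
#'
#' @param orf ORF gene symbol.
#' @param partners character vector of partner symbols.
#' @param normal,tumor [ExpressionMatrix-class] objects for the matched
#'   normal tissue and cancer cohort.
#' @return data.frame with one row per retained partner: orf, partner,
#'   tissueNormal, tissueTumor, rNormal, pNormal, nNormal, rTumor,
#'   pTumor, nTumor.
#' @export
coexprTable <- function(orf, partners, normal, tumor) {
  orf <- normalizeSymbols(orf)
  partners <- unique(normalizeSymbols(partners))
  stopifnot(exprCondition(normal) == "normal",
            exprCondition(tumor) == "tumor")
  vn <- exprValues(normal); vt <- exprValues(tumor)
  if (!orf %in% rownames(vn) || !orf %in% rownames(vt))
    stop("ORF gene '", orf, "' missing from an expression matrix")
  missing <- partners[!(partners %in% rownames(vn) &
                        partners %in% rownames(vt))]
  if (length(missing))
    warning("partner(s) absent from a matrix, skipped: ",
            paste(missing, collapse = ", "))
  partners <- setdiff(partners, missing)
  rows <- lapply(partners, function(p) {
    sn <- spearmanTest(vn[orf, ], vn[p, ])
    st <- spearmanTest(vt[orf, ], vt[p, ])
    data.frame(orf = orf, partner = p,
               tissueNormal = exprTissue(normal),
               tissueTumor = exprTissue(tumor),
               rNormal = sn$rho, pNormal = sn$p, nNormal = sn$n,
               rTumor = st$rho, pTumor = st$p, nTumor = st$n,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(orf = character(), partner = character(),
                      tissueNormal = character(), tissueTumor = character(),
                      rNormal = numeric(), pNormal = numeric(),
                      nNormal = integer(), rTumor = numeric(),
                      pTumor = numeric(), nTumor = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify interactions by their normal-to-tumor co-expression shift
#'
#' Labels each ORF-partner pair from the sign shift of its co-expression
#' between the matched normal tissue and the cancer cohort:
#' \describe{
#'   \item{cancer_dependent}{strong positive co-expression appears in the
#'     tumor only: \code{rTumor >= rThr} with \code{pTumor < pThr} while
#'     \code{rNormal < rThr}.}
#'   \item{perturbed_by_cancer}{strong positive co-expression in normal
#'     tissue (\code{rNormal >= rThr}, \code{pNormal < pThr}) collapses
#'     to negative or near-zero in the tumor
#'     (\code{rTumor <= nearZero}).}
#'   \item{concordant}{strong positive co-expression in both conditions.}
#'   \item{unclassified}{everything else.}
#' }
#' Additionally, \code{directHint} flags pairs whose co-expression
#' reaches r >= 0.85 in either condition — high enough to hint at a
#' direct physical interaction.
#'
#' @param tab data.frame from [coexprTable()] (columns rNormal, pNormal,
#'   rTumor, pTumor), or a one-row equivalent.
#' @param rThr strong-correlation threshold (default 0.5).
#' @param nearZero upper bound on a "collapsed" tumor correlation
#'   (default 0.2).
#' @param pThr significance gate (default 0.05).
#' @param directHintThr direct-interaction hint threshold (default 0.85).
#' @return the input with \code{label} and \code{directHint} columns
#'   appended.
#' @examples
#' tab <- data.frame(rNormal = c(-0.07, 0.87), pNormal = c(0.6, 1e-4),
#'                   rTumor = c(0.61, -0.66), pTumor = c(1e-3, 1e-3))
#' classifyPpi(tab)$label  # cancer_dependent, perturbed_by_cancer
#' @export
classifyPpi <- function(tab, rThr = 0.5, nearZero = 0.2, pThr = 0.05,
                        directHintThr = 0.85) {
  stopifnot(all(c("rNormal", "pNormal", "rTumor", "pTumor") %in% names(tab)))
  cd <- tab$rTumor >= rThr & tab$pTumor < pThr & tab$rNormal < rThr
  pert <- tab$rNormal >= rThr & tab$pNormal < pThr & tab$rTumor <= nearZero
  conc <- tab$rNormal >= rThr & tab$pNormal < pThr &
          tab$rTumor >= rThr & tab$pTumor < pThr
  label <- rep("unclassified", nrow(tab))
  label[conc] <- "concordant"
  label[pert] <- "perturbed_by_cancer"
  label[cd] <- "cancer_dependent"
  tab$label <- label
  tab$directHint <- pmax(tab$rNormal, tab$rTumor) >= directHintThr
  tab
}

#' Label counts of a classified co-expression table
#'
#' @param tab output of [classifyPpi()].
#' @return named list of per-label counts plus the direct-hint count.
#' @export
coexprSummary <- function(tab) {
  lv <- c("cancer_dependent", "perturbed_by_cancer", "concordant",
          "unclassified")
  counts <- as.list(table(factor(tab$label, levels = lv)))
  counts$directHint <- sum(tab$directHint)
  counts$n <- nrow(tab)
  counts
}
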