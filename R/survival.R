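#' Per-patient signature score of a gene panel
#'
#' Aggregates a multi-gene expression panel into one score per patient:
#' \code{mean_z} averages per-gene z-scores (each gene centered/scaled
#' across patients), \code{mean_raw} averages raw expression.
#'
#' @param cohort a [SurvivalCohort-class].
#' @param genes panel gene symbols, all present in the cohort.
#' @param method \code{"mean_z"} (default) or \code{"mean_raw"}.
#' @return named numeric vector, one score per patient.
#' @export
signatureScore <- function(cohort, genes, method = c("mean_z", "mean_raw")) {
  method <- match.arg(method)
  genes <- normalizeSymbols(genes)
  expr <- exprValues(cohort)
  miss <- setdiff(genes, rownames(expr))
  if (length(miss))
    stop("gene(s) missing from cohort: ", paste(miss, collapse = ", "))
  m <- expr[genes, , drop = FALSE]
  if (method == "mean_z") {
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, stats::sd)
    if (any(sdv == 0))
      stop("constant expression for: ",
           paste(genes[sdv == 0], collapse = ", "))
    m <- (m - mu) / sdv
  }
  colMeans(m)
}

#' Split patients into low/high expression groups
#'
#' Median split: patients strictly above the median score are "high",
#' the rest (ties at the median included) are "low".
#'
#' @param score numeric vector (n >= 4, not constant).
#' @param rule currently only \code{"median"}.
#' @return factor with levels \code{low}, \code{high}.
#' @export
splitGroups <- function(score, rule = c("median")) {
  rule <- match.arg(rule)
  if (length(score) < 4) stop("need at least 4 patients to split")
  med <- stats::median(score)
  lab <- ifelse(score > med, "high", "low")
  if (length(unique(lab)) < 2)
    stop("cannot split: scores are constant (or all tie at the median)")
  factor(lab, levels = c("low", "high"))
}

#' Kaplan-Meier product-limit curve
#'
#' At each distinct event time t the survival estimate multiplies by
#' \code{1 - d/n}, with d the events at t and n the number still at risk
#' (subjects censored exactly at t count as at risk at t, the standard
#' convention).
#'
#' @param time follow-up times (months).
#' @param event 0/1 event indicators.
#' @return data.frame of class \code{KMCurve}: \code{time} (ascending
#'   distinct event times), \code{nRisk}, \code{nEvent},
#'   \code{survival}. All-censored input warns and yields a flat curve.
#' @examples
#' kmCurve(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
kmCurve <- function(time, event) {
  stopifnot(length(time) == length(event), all(time >= 0),
            all(event %in% c(0, 1)))
  evTimes <- sort(unique(time[event == 1]))
  if (!length(evTimes)) {
    warning("no events observed; survival curve is flat at 1")
    out <- data.frame(time = numeric(), nRisk = integer(),
                      nEvent = integer(), survival = numeric())
    class(out) <- c("KMCurve", class(out))
    return(out)
  }
  nRisk <- vapply(evTimes, function(t) sum(time >= t), 0L)
  nEvent <- vapply(evTimes, function(t) sum(time == t & event == 1), 0L)
  surv <- cumprod(1 - nEvent / nRisk)
  out <- data.frame(time = evTimes, nRisk = nRisk, nEvent = nEvent,
                    survival = surv)
  class(out) <- c("KMCurve", class(out))
  out
}

#' Survival-time quantile of a Kaplan-Meier curve
#'
#' The q-quantile survival time is the earliest event time at which the
#' curve has fallen to 1 - q or below (boundary inclusive): the median
#' is the first t with S(t) <= 0.5, the upper-quartile time the first t
#' with S(t) <= 0.75. \code{NA} when the curve never crosses.
#'
#' @param curve a [kmCurve()] result.
#' @param q quantile in (0, 1); 0.25 gives the upper-quartile time,
#'   0.5 the median.
#' @return time in months, or \code{NA}.
#' @export
quantileSurvival <- function(curve, q = 0.5) {
  stopifnot(q > 0, q < 1)
  hit <- which(curve$survival <= 1 - q + 1e-12)
  if (!length(hit)) NA_real_ else curve$time[hit[1L]]
}

#' Two-group log-rank test with the observed/expected ledger
#'
#' At each distinct event time the expected events in each group are
#' proportional to its share of the at-risk set; the variance is
#' hypergeometric. The statistic \code{(O - E)^2 / V} is referred to a
#' chi-square with one degree of freedom. The per-group observed and
#' expected totals are returned because they also feed the
#' observed/expected hazard-ratio estimate.
#'
#' @param time,event as in [kmCurve()].
#' @param group factor/vector with exactly two non-empty groups; the
#'   first level (or sorted-first value) is treated as "low".
#' @return list: \code{chi2}, \code{p}, \code{oLow}, \code{eLow},
#'   \code{oHigh}, \code{eHigh}, \code{varOE}.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("log-rank test needs exactly two non-empty groups")
  g1 <- levels(group)[1L]  # "low"
  evTimes <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in evTimes) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  O2 <- sum(event == 1) - O1
  E2 <- sum(event == 1) - E1
  chi2 <- if (V > 0) (O1 - E1)^2 / V else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, oLow = O1, eLow = E1, oHigh = O2, eHigh = E2,
       varOE = V)
}

#' Observed/expected hazard ratio with confidence interval
#'
#' Mantel-Haenszel-style estimate from the log-rank ledger:
#' \code{HR = (oHigh/eHigh) / (oLow/eLow)}, with the confidence interval
#' \code{exp(log HR +/- z * sqrt(1/eLow + 1/eHigh))}. This is the
#' KM-plot-style approximation, not a Cox fit.
#'
#' @param oLow,eLow,oHigh,eHigh observed/expected event counts per
#'   group; both expectations must be positive.
#' @param conf confidence level (default 0.95).
#' @return list \code{hr}, \code{ciLo}, \code{ciHi}.
#' @export
hazardRatio <- function(oLow, eLow, oHigh, eHigh, conf = 0.95) {
  if (eLow <= 0 || eHigh <= 0)
    stop("hazard ratio undefined: zero expected events in a group")
  hr <- (oHigh / eHigh) / (oLow / eLow)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / eLow + 1 / eHigh)
  list(hr = hr, ciLo = hr * exp(-z * se), ciHi = hr * exp(z * se))
}

#' Evaluate a multi-gene expression signature for survival prognosis
#'
#' Composes the whole panel evaluation: per-patient signature score,
#' median split into low/high expression groups, log-rank comparison,
#' observed/expected hazard ratio (high vs low) with its confidence
#' interval, and a survival-time quantile per group (default the
#' upper-quartile time, the first time S(t) <= 0.75).
#'
#' @inheritParams signatureScore
#' @param splitRule passed to [splitGroups()].
#' @param quantile survival quantile reported per group (default 0.25 =
#'   upper-quartile survival).
#' @return list of class \code{SignatureResult}: genes, splitRule, hr,
#'   hrCi, logrankChi2, p, quantileSurvivalLow/High, nLow, nHigh,
#'   and the per-group observed/expected ledger.
#' @export
evaluateSignature <- function(cohort, genes,
                              scoreMethod = c("mean_z", "mean_raw"),
                              splitRule = "median", quantile = 0.25) {
  scoreMethod <- match.arg(scoreMethod)
  score <- signatureScore(cohort, genes, scoreMethod)
  grp <- splitGroups(score, splitRule)
  tm <- survTime(cohort); ev <- survEvent(cohort)
  lr <- logrankTest(tm, ev, grp)
  hr <- hazardRatio(lr$oLow, lr$eLow, lr$oHigh, lr$eHigh)
  qLow <- quantileSurvival(
    suppressWarnings(kmCurve(tm[grp == "low"], ev[grp == "low"])), quantile)
  qHigh <- quantileSurvival(
    suppressWarnings(kmCurve(tm[grp == "high"], ev[grp == "high"])), quantile)
  structure(
    list(genes = normalizeSymbols(genes), scoreMethod = scoreMethod,
         splitRule = splitRule, hr = hr$hr, hrCi = c(hr$ciLo, hr$ciHi),
         logrankChi2 = lr$chi2, p = lr$p,
         quantileSurvivalLow = qLow, quantileSurvivalHigh = qHigh,
         quantile = quantile,
         nLow = sum(grp == "low"), nHigh = sum(grp == "high"),
         ledger = lr),
    class = "SignatureResult")
}

#' @export
print.SignatureResult <- function(x, ...) {
  cat(sprintf("Signature of %d gene(s): HR = %.2f (%.2f-%.2f), log-rank p = %.3g\n",
              length(x$genes), x$hr, x$hrCi[1], x$hrCi[2], x$p))
  cat(sprintf("  n(low) = %d, n(high) = %d; %.0f%%-survival: low %s, high %s months\n",
              x$nLow, x$nHigh, 100 * (1 - x$quantile),
              format(x$quantileSurvivalLow), format(x$quantileSurvivalHigh)))
  invisible(x)
}

#' Find a decisive subset of a prognostic signature
#'
#' Searches for a minimal gene subset D whose removal destroys the
#' panel's prognostic significance: the remaining signature's log-rank p
#' rises above \code{alpha}. \code{greedy} removes genes cumulatively in
#' decreasing order of their single-gene log-rank strength, re-testing
#' after each removal; \code{exhaustive_k} enumerates all subsets up to
#' size \code{maxK} (smallest first) and returns the first that works.
#' The full signature must be significant to begin with.
#'
#' @inheritParams signatureScore
#' @param strategy \code{"greedy"} or \code{"exhaustive_k"}.
#' @param alpha significance level (default 0.05).
#' @param maxK subset-size cap for the exhaustive search (default 7).
#' @return list: \code{decisive} (symbols; empty if none found within
#'   the strategy's budget), \code{found}, \code{pFull},
#'   \code{pRemaining} (p of the signature without the decisive subset).
#' @export
ablation <- function(cohort, genes, strategy = c("greedy", "exhaustive_k"),
                     alpha = 0.05, maxK = 7,
                     scoreMethod = c("mean_z", "mean_raw")) {
  strategy <- match.arg(strategy)
  scoreMethod <- match.arg(scoreMethod)
  genes <- normalizeSymbols(genes)
  full <- evaluateSignature(cohort, genes, scoreMethod)
  if (full$p >= alpha)
    stop("full signature is not significant (p = ", signif(full$p, 3),
         "); nothing to ablate")
  pWithout <- function(keep) {
    if (length(keep) < 1) return(1)
    evaluateSignature(cohort, keep, scoreMethod)$p
  }
  if (strategy == "greedy") {
    strength <- vapply(genes, function(g)
      evaluateSignature(cohort, g, scoreMethod)$logrankChi2, 0)
    ordered <- genes[order(-strength)]
    removed <- character()
    for (g in ordered) {
      removed <- c(removed, g)
      keep <- setdiff(genes, removed)
      if (!length(keep)) break
      p <- pWithout(keep)
      if (p > alpha)
        return(list(decisive = removed, found = TRUE, pFull = full$p,
                    pRemaining = p))
    }
    return(list(decisive = character(), found = FALSE, pFull = full$p,
                pRemaining = NA_real_))
  }
  # exhaustive over subset sizes 1..maxK, requiring a non-empty remainder
  for (k in seq_len(min(maxK, length(genes) - 1L))) {
    for (idx in utils::combn(length(genes), k, simplify = FALSE)) {
      keep <- genes[-idx]
      p <- pWithout(keep)
      if (p > alpha)
        return(list(decisive = genes[idx], found = TRUE, pFull = full$p,
                    pRemaining = p))
    }
  }
  list(decisive = character(), found = FALSE, pFull = full$p,
       pRemaining = NA_real_)
}
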