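---
title: "Methods: subinteractome scoring, co-expression shifts and signature survival analysis"
author: "orfsub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subinteractome scoring, co-expression shifts and signature survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfsub)
```

# The analysis in one page

`orfsub` prioritizes uncharacterized ORF proteins by the composition
and behavior of their physical-interaction neighborhoods. Four models
do the work:

1. **Subinteractome extraction.** Interaction records from any number
   of sources are merged into one undirected network; a protein's
   subinteractome is simply its neighbor set. The central assumption —
   inherited from how such partner lists are produced experimentally —
   is that every recorded partner is *a priori* equally likely to touch
   the target directly, so neighborhood composition, not edge
   confidence, carries the signal.
2. **Cancer-hallmark density.** The CH-score is
   $\mathrm{CH} = 10\,n_{CH}/n$, the number of hallmark-associated
   proteins per 10 partners in a subinteractome of $n$ partners. It is
   a density, so it is comparable across subinteractome sizes, and it
   is left unnormalized against a background rate: the prioritization
   threshold plays that role.
3. **Differential co-expression.** For an ORF–partner pair measured in
   a matched normal tissue and a tumor cohort, the Spearman
   correlations $(r_N, r_T)$ classify the interaction:
   tumor-only strong positive correlation (*cancer-dependent*),
   normal-only strong correlation collapsing in the tumor
   (*perturbed by cancer*), strong in both (*concordant*), else
   *unclassified*. The underlying assumption is the usual one for
   co-expression: proteins that function together are co-regulated, so
   a sign shift between conditions marks an interaction whose
   functional context changes with malignancy.
4. **Signature survival.** A gene panel is collapsed to one score per
   patient, patients are median-split, and the two groups are compared
   by the log-rank test; the hazard ratio is estimated from the
   log-rank observed/expected ledger. Proportionality of hazards is
   assumed throughout, as in any KM-plot-style analysis.

# Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| size window (`selectBySize`) | 7–100, both inclusive | partners | below 7 partners enrichment analysis is underpowered; above 100 the output terms grow redundant |
| CH threshold (`prioritize`) | 2 | hallmark proteins / 10 partners | two hallmark-associated partners per ten; sits near the 25th percentile of a score population with median ≈ 2.8 |
| `countSelf` (`chScore`) | `TRUE` | — | a hallmark-associated target protein contributes to its own numerator while the denominator stays the partner count; both settings give 1.0 for the one-in-ten worked example |
| `rThr` (`classifyPpi`) | 0.5 | Spearman r | the conventional "noticeable correlation" gate, applied with `p < 0.05` |
| `nearZero` (`classifyPpi`) | 0.2 | Spearman r | "collapsed in tumor" bound; the perturbed-pair examples this rule must capture have tumor r at or below ~0.06, so 0.2 is conservative; exposed as a parameter because it is a convention, not an estimate |
| `directHintThr` | 0.85 | Spearman r | co-expression this strong is treated as a hint of a direct physical interaction |
| DE gates (`deCall`) | \|log2FC\| ≥ 2, p < 0.05 | log2 fold change | the four-fold-change convention; the boundary value 2 itself counts as differentially expressed |
| `minCancers` (`panCancerGroup`) | 5 | cancers | membership gate of the pan-cancer group |
| majority rule (`panCancerGroup`) | > 2/3 | fraction of DE calls | "preferentially" up/down is not a standard quantity; the 2/3 supermajority is this package's definition and is stated in the output |
| ORA settings (`ora`) | min term 4, BH FDR < 0.1, coverage > 0.10, universe 19467 | — | genome protein-coding reference universe; a term must also cover more than 10% of the subinteractome to count as significant |
| split rule (`splitGroups`) | median, ties to low | — | auto-optimized cutoffs inflate type-I error and are deliberately not offered |
| `quantile` (`evaluateSignature`) | 0.25 | — | reports upper-quartile survival (first time S(t) ≤ 0.75), robust under heavy censoring where the median never crosses |

# Numerical choices

* **Spearman p-values** use the t approximation
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, adequate for
  the n ≥ 10 regime the pipeline targets; an exact permutation option
  exists for n ≤ 9. Ties get mid-ranks. $|r| = 1$ is reported with
  p = 0 rather than a denormal from the t formula.
* **Quantile convention** is type-7 linear interpolation for the
  CH-score percentile summary, and boundary-inclusive first crossing
  (smallest event time with $S(t) \le 1-q$) for survival quantiles.
* **Log-rank** uses the standard hypergeometric-variance ledger with
  subjects censored at an event time counted as at risk at that time.
  The hazard ratio $(O_h/E_h)/(O_l/E_l)$ is the Mantel–Haenszel-style
  estimate; it tracks Cox regression closely for moderate effects but
  is attenuated toward 1 for strong ones (at a true HR of 3 the
  recovered median is ≈ 2.65 at n = 500; the test suite documents this
  against a Cox cross-check). It was chosen over Cox to match
  KM-plot-style reporting and keep the module self-contained.
* **Ablation** offers a greedy strategy (drop genes in order of
  single-gene log-rank strength, re-testing after each removal) and an
  exhaustive one (all subsets up to size 7 by default). The greedy
  path can miss jointly-decisive sets no single member of which is
  prognostic; the exhaustive path is bounded to small panels by
  construction. Both are labelled in the result.
* **SVD imputation** initializes missing cells at row means and
  alternates rank-k reconstruction of the column-centered matrix with
  missing-cell refill until the largest refill change drops below
  `tol` (default 1e-6, `maxIter` 500). On exactly low-rank input this
  converges geometrically and recovers deleted cells to ~1e-9. On
  ternary call matrices, which are far from rank 2, the fixed point is
  approached very slowly; the result is then flagged
  `converged = FALSE` while the scores are already stable to well
  below any interpretable difference. The flag is honest, not alarming;
  raising `tol` to 1e-3 declares convergence on such data without
  changing the plotted configuration.
* **PCA encoding.** Clustering cancers by shared DE *patterns* calls
  for the signed ternary encoding (up = +1, down = −1, ns = 0,
  missing imputed), which is the default; continuous log2FC encoding
  is available when magnitudes matter. Columns (genes) are centered;
  rows are not scaled.
* **Gene identity** is case-insensitive symbol matching after
  uppercasing and whitespace stripping. No alias resolution is
  attempted beyond the MITAB "gene name" alias fields — the ten-source
  provenance gives no reconciliation rule, so none is guessed; a
  symbol conflict across sources simply yields two nodes.
* **Degenerate inputs** fail loudly where a statistic is undefined
  (empty subinteractome CH-score, constant vectors in correlation or
  splitting, zero expected events in a hazard ratio) and degrade
  gracefully where a valid empty result exists (empty networks, empty
  selections, all-censored KM curves with a warning).

# What the generators emulate — and what they do not

The synthetic-data module exists so that every stage of the pipeline
is testable against planted ground truth without cohort downloads.
Its defaults encode the study conditions of the motivating analysis:

* `genPpiNetwork`: a 219-member roster of which 177 are connected with
  the size distribution (63, 30, 40, 27, 6, 11) over the bins <7,
  7–15, 15–30, 30–70, 70–100, >100; 8 direct ORF–ORF edges; 517
  partners shared by exactly two ORFs; ≈768 interactions through
  partners shared by three or more (each such partner drawn with 3–5
  ORFs until the edge budget is spent). The realized histogram matches
  the configured one *exactly* by construction, which is what makes
  the census tests sharp.
* `genHallmarkAnnotation`: either exact per-ORF CH-score targets
  (flagging only single-ORF partners so scores never couple) or a
  prevalence default of 0.28 flagged partners, putting the expected
  CH-score at 2.8 per subinteractome.
* `genExpressionPair`: Gaussian copula with log-normal marginals; the
  latent correlation is solved from
  $\rho_S = (6/\pi)\arcsin(\rho/2)$, so Spearman targets are exact in
  expectation (recovered within ±0.05 at n = 2000).
* `genSurvivalCohort`: equal planted low/high groups, exponential
  event times with hazard `baselineHazard` (0.05/month) versus
  `baselineHazard × trueHr`, uniform administrative censoring on
  [0, T<sub>max</sub>] with T<sub>max</sub> solved numerically for the
  requested censored fraction (default 20%). Signature genes are
  shifted by 3 z-units in the high group so the median split recovers
  the planted labels essentially always.
* `genDeMatrix`: 219 genes × 19 cancers with a two-cancer co-regulated
  up-block (68 genes), a 100-gene down-block exclusive to one cancer
  plus a 10-gene spillover shared with a second, an up-only and a
  down-only cancer, a handful of pan-cancer genes, and 10% hidden
  cells (never emptying a row or column).

All generators draw from sub-streams derived from the master seed by
named keys, so adding a call never perturbs the draws of another, and
identical seeds give byte-identical outputs.

What passing tests on these inputs **does not** show: the generators
make no attempt at realistic RNA-seq count noise, batch effects, real
marginal expression distributions, non-proportional hazards, or the
correlated annotation structure of real hallmark gene sets. Recovery
of planted parameters demonstrates that the estimators and filters do
what they claim under their own assumptions — not that those
assumptions hold in TCGA-scale data. Real-cohort headline numbers
(externally reported hazard ratios, the 4317-PPI aggregate, cohort-specific DE
counts) depend on live databases and are out of scope; the reference
worked examples and in-text censuses are instead frozen as fixtures in
the test suite.

# Problem sizes used by the tests

The suite runs the full study-scale network (219 ORFs, ≈4600 edges)
for the census checks, 200 replicates for classification power, 60
cohorts of n = 500 for hazard-ratio recovery, 1000 null cohorts of
n = 60 for log-rank calibration, n = 2000 samples for copula recovery,
and exhaustive enumeration oracles at n ≤ 6 (permutations), N ≤ 25
(hypergeometric) and ≤ 12 nodes (shortest paths). These sizes were
chosen to make sampling error a small fraction of each tested
tolerance while keeping the whole suite around a minute.

# Known limitations

* The O/E hazard ratio is attenuated for strong effects; use it as a
  KM-plot-style summary, not a substitute for Cox regression.
* Pipelines with many ORF–partner pairs test many correlations;
  `classifyPpi` applies per-pair gates and leaves multiplicity control
  across pairs to the caller.
* The ORA module reports terms un-collapsed; redundancy reduction
  between overlapping terms (affinity-propagation style) is not
  implemented.
* Symbol-level gene identity cannot resolve aliases or retired
  symbols; upstream identifier hygiene is assumed.
* `quantileSurvival` reports `NA` when a curve never crosses the
  requested level — expected under light event rates, and propagated
  as-is into signature results.
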