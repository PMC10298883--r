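# orfsub

Subinteractome analysis of uncharacterized chromosome-specific
open-reading-frame (CxORFx) proteins in cancer.

About 10% of predicted human proteins are still functionally
uncharacterized; many of the CxORFx ("ORF") genes among them are
differentially expressed across cancers. Because an uncharacterized
protein's function can be read off the annotated proteins it physically
binds, a productive way to prioritize ORF proteins for cancer research
is to study each one's **subinteractome** — the set of all its known
physical protein partners — and ask how densely that neighborhood is
populated by proteins associated with the hallmarks of cancer, how its
co-expression with those partners shifts between normal and tumor
tissue, and whether expression signatures built from such genes carry
survival prognosis.

`orfsub` implements that analysis as a tested, reusable pipeline for
bioinformaticians and systems biologists:

* **Interactome aggregation** — parse PSI-MITAB 2.5/2.7 or plain edge-list
  TSVs from any number of interaction browsers, deduplicate unordered
  pairs across sources, drop self-loops, and census the result: direct
  ORF–ORF edges, partners shared by exactly two roster ORFs (potential
  heterotrimers) or by three and more (potential multimers), orphan
  roster members, subinteractome size histograms, and shortest
  ORF-to-ORF paths.
* **Cancer-hallmark scoring** — the CH-score of a subinteractome is the
  number of hallmark-associated proteins per 10 partners,
  `CH = 10 · n_CH / n_partners`, so a score of 1 means one
  hallmark-associated protein among 10 partners. Subinteractomes with
  7–100 partners are scored and prioritized at `CH ≥ 2`; hypergeometric
  over-representation analysis (Benjamini–Hochberg FDR < 0.1, minimum
  term size 4, term coverage > 10% of the subinteractome) annotates the
  hallmark "core".
* **Differential co-expression** — Spearman correlation of the ORF gene
  with each partner gene, separately in matched normal and tumor
  expression matrices; pairs are classified as *cancer-dependent*
  (strong positive correlation appears only in the tumor),
  *perturbed by cancer* (strong normal-tissue correlation collapses to
  near zero or negative in the tumor), *concordant*, or *unclassified*;
  `r ≥ 0.85` in either condition additionally hints at a direct
  physical interaction.
* **Survival signatures** — per-patient scores of multi-gene panels,
  median split into low/high groups, Kaplan–Meier curves, two-group
  log-rank test, observed/expected hazard ratio
  `HR = (O_high/E_high)/(O_low/E_low)` with
  `exp(log HR ± 1.96·√(1/E_low + 1/E_high))` confidence intervals,
  upper-quartile survival times, and a decisive-subset ablation that
  finds a minimal gene set whose removal destroys the panel's
  significance.
* **Expression patterns** — ternary DE calls (`|log2FC| ≥ 2`,
  `p < 0.05`), cancer-exclusive signatures, pan-cancer grouping
  (DE in ≥ 5 cancers; preferentially up/down by a 2/3 majority), and
  PCA of the gene × cancer call matrix by SVD with iterative
  imputation of missing cells (column-centered, no row scaling).
* **Synthetic data** — seeded generators for every input: a PPI network
  with an exact planted size distribution and partner-sharing
  structure, hallmark annotations hitting CH-score targets exactly,
  Gaussian-copula normal/tumor expression with exact expected Spearman
  targets, proportional-hazards cohorts with planted groups and tuned
  censoring, and clustered sparse DE matrices. Every generator returns
  a ground-truth ledger for parameter-recovery testing.

## Worked example

Generate a study-scale synthetic interactome (219-member roster, the
reference subinteractome-size distribution), score it, and evaluate a
survival signature:

```r
library(orfsub)

cfg <- simConfig(seed = 7)
ppi <- genPpiNetwork(cfg)
ppi$network
#> AggregatedNetwork: 4579 unique physical PPIs, 3657 proteins
#>   ORF roster: 219 targets ( 177 with >=1 partner )
#>   ORF-ORF edges: 8 | self-loops dropped: 0

subs <- allSubinteractomes(ppi$network, connectedOnly = TRUE)
sizeHistogram(subs)
#>       <7   [7,15)  [15,30)  [30,70) [70,100]     >100
#>       63       30       40       27        6       11

ann <- genHallmarkAnnotation(ppi$network, cfg = cfg)
pr <- prioritize(chScoreTable(selectBySize(subs), ann$annotation),
                 threshold = 2)
str(pr$summary)
#> List of 5
#>  $ median          : num 2.81
#>  $ p25             : num 2.22
#>  $ fractionSelected: num 0.816
#>  $ nSelected       : int 84
#>  $ n               : int 103

sv <- genSurvivalCohort(cfg)
evaluateSignature(sv$cohort, c("SIG1", "SIG2", "SIG3"))
#> Signature of 3 gene(s): HR = 2.01 (1.64-2.46), log-rank p = 2.77e-13
#>   n(low) = 250, n(high) = 250; 75%-survival: low 5.932683, high 2.703551 months
```

The histogram reproduces the configured size distribution exactly
(63 subinteractomes below 7 partners up to 11 above 100); 103 of the
177 connected ORFs fall in the 7–100 window; their median CH-score sits
near 2.8 with 84 prioritized at the ≥ 2 threshold. The survival panel,
planted with a two-fold hazard in the high-expression group, is
recovered with HR ≈ 2.0 and the high group's upper-quartile survival at
2.7 vs 5.9 months in the low group.

The same stages run end to end from files via `runPipeline()` (see
`?pipelineConfig` and `?readPipelineConfig` for the YAML layout), with
a report JSON recording the parameters, input hashes and in/out counts
of every filter.

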