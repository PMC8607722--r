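# scvarmap

Which brain cell populations are preferentially impacted by de novo
loss-of-function (LOF) variants in autism spectrum disorder? `scvarmap`
implements, as a tested R package, the integrative pipeline that answers
this question: it curates a compiled variant table, clusters single-cell
brain transcriptomes, calls per-cluster differentially expressed genes
under a four-test consensus, scores clusters for evolutionary constraint
(critical exons and pLI), maps LOF variant genes onto clusters with a
gene-set overlap engine, assigns cell identities from marker evidence,
and characterises the spatiotemporal (16 brain regions x 3 developmental
periods) and sorted-cell replication patterns of the implicated genes.

Because atlas-scale inputs (brain single-cell atlases, gnomAD,
developmental RNA-seq compendia) cannot be redistributed, the package
ships a first-class synthetic-data module that emulates every input with
planted ground truth — cell types and markers, constrained exons,
high-pLI genes, a variant-enriched cell-type program, prenatal
expression bias — so the recovery of each analysis stage is asserted by
the test suite rather than assumed.

## The statistics at the core

* **Consensus DE**: gene g is a DEG of cluster c iff the Wilcoxon
  rank-sum, Welch t, bimodal likelihood-ratio and two-part hurdle tests
  all give Bonferroni-adjusted p < 0.001 one-vs-rest. The bimodal test
  is an LRT under a zero-inflated normal (2Δℓ ~ χ², df = 2); the hurdle
  sums the logistic-detection and Gaussian-positive LRT parts.
* **Overlap enrichment**: for gene sets A, B in universe U, the one-sided
  hypergeometric upper-tail p with the sample odds ratio
  OR = (n11·n00)/(n10·n01) of the induced 2x2 table; Bonferroni across a
  cluster x gene-set batch, Benjamini–Hochberg for pathway collections
  (size bounds 50–1000, significant at p < 1e-3 and FDR < 0.01).
* **Critical exons**: an exon is critical at a developmental stage when
  its expression is at/above the 0.75 quantile while its non-synonymous
  burden (mutations per bp) is at/below the 0.25 quantile; cluster
  enrichment by a two-sample proportion test (z² ≡ Pearson χ²), pLI ≥ 0.9
  enrichment by the overlap engine.
* **Clustering**: log2(1 + CPM) → HVG selection by standardised variance
  → mitochondrial-fraction regression with clipping → PCA with an elbow
  rule → shared-nearest-neighbour graph (Jaccard weights, pruned < 1/15)
  → Leiden at a given resolution.

## Worked example

A synthetic study with a planted astrocyte LOF program (full code in the
package vignette):

```r
library(scvarmap)
cfg <- synthConfig(seed = 1,
                   variantCategoryCounts = c("de_novo:nonsense" = 200L,
                                             "de_novo:frameshift" = 150L,
                                             "de_novo:splicing" = 50L,
                                             "de_novo:missense" = 400L),
                   nLofGenes = NA)
syn  <- generateAll(cfg)
pipe <- runClusterPipeline(syn$sce, resolution = 0.8, nHvg = 1000, seed = 1)
cons <- consensusDE(runConsensusDE(pipe$sce, pipe$labeling))
lof  <- lofGeneSet(syn$variants)
batchEnrich(lapply(cons, function(d) d$gene[d$log2_fc > 0]),
            list(lof = geneIds(lof)), rownames(syn$sce))
```

The 500 cells split into 5 clusters (sizes 200/100/99/51/50, matching
the planted composition), and the LOF gene set lands on exactly one of
them:

```
  set_a a_size b_size overlap odds_ratio        p    p_adj
1     0     20    350       1      0.246 9.79e-01 1.00e+00
2     1     20    350       5      1.580 2.64e-01 1.00e+00
3     2     20    350      17     28.027 6.63e-11 3.32e-10
4     3     20    350       3      0.830 7.07e-01 1.00e+00
5     4     20    350       5      1.580 2.64e-01 1.00e+00
```

Cluster 2 — 17 of its 20 up-regulated consensus DEGs carry a de novo
LOF variant, odds ratio 28, Bonferroni p = 3.3e-10 — is annotated
`astrocyte` by the marker-evidence rule, exactly the planted enriched
program. The spatiotemporal association of the LOF genes peaks in the
prenatal period of the DFC and V1C region analogues (odds ratios 7.7
and 7.2, against ~1 elsewhere), recovering the planted prenatal bias.

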