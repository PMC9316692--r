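---
title: "Inferring relapse-associated regulatory networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring relapse-associated regulatory networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relapsegrn)
```

## The problem

When leukemia cells are exposed to a chemotherapeutic agent and the drug
pressure is then released, the transcriptome of the surviving population
reorganizes. The genes and miRNAs that are differentially expressed
between treated-and-released cells and controls — and, more specifically,
the ones that occupy central positions in the regulatory network wired
among them — are candidate drivers of tumour relapse. `relapsegrn`
implements that chain of inference as a reusable, testable pipeline:

1. **Differential expression** between two sample groups on raw RNA-seq
   counts (negative binomial model, median-of-ratios normalization).
2. **Functional exclusion** of genes annotated to configured ontology
   terms (e.g. generic stress-response and metabolism signatures that
   reflect the culture protocol rather than relapse biology).
3. **miRNA-target enrichment**: miRNAs whose known targets are
   over-represented in the DEG list (hypergeometric test, BH-adjusted at
   FDR 5%) are nominated as post-transcriptional regulators.
4. **Network construction**: a directed co-regulatory graph over the
   DEGs and enriched miRNAs, restricted to experimentally supported
   interactions and then contextualized to the disease by keeping only
   edges with at least one disease-associated endpoint.
5. **Hotspot detection**: the union, over degree, betweenness, closeness
   and eigenvector centrality, of the top 10% of nodes per measure.
6. **Functional-homogeneity validation**: pairwise GO semantic
   similarity among the network's genes compared against random gene
   sets with a one-sided two-sample Kolmogorov–Smirnov test, BH-adjusted
   across contrasts.

Every stage is driven by `pipeline_config()`, whose defaults are the
analysis constants of the study design this package supports: FDR
$\alpha = 0.05$, $|\log_2 \mathrm{FC}| \ge 1.5$, hotspot fraction 0.10,
100 random gene sets, evidence label `"experimental"`, disease context
`"leukemia"`.

## Statistical models and their assumptions

### Normalization and the NB Wald test

Counts $K_{gj}$ are assumed negative binomial with
$\mathrm{Var} = \mu + \alpha \mu^2$. Sample depth is removed by
median-of-ratios size factors: for sample $j$,
$s_j = \mathrm{median}_g \, K_{gj} / (\prod_{j'} K_{gj'})^{1/m}$ over
genes positive in all samples, computed on the log scale and normalized
to geometric mean 1 across samples (so equal columns give factors of 1).
This is the standard reference-based normalization for two-group RNA-seq
and is exact, not approximate, in this implementation; the test suite
cross-checks it against an independent reference implementation.

The per-gene test is a Wald statistic on
$\log_2 \widehat{\mathrm{FC}} = \log_2\frac{\bar{y}_B + c}{\bar{y}_A + c}$
(normalized group means, pseudocount $c = 0.5$), with standard error
from the NB variance function using a method-of-moments gene-wise
dispersion pooled across the two groups and floored at zero. p-values
are two-sided normal tails, BH-adjusted. Genes with all-zero counts in
both groups are reported with $\log_2\mathrm{FC} = 0$, $p = 1$ rather
than dropped.

This test is deliberately transparent: no dispersion shrinkage across
genes, no independent filtering, no outlier replacement. At $n = 5$ per
group it is mildly liberal (the suite asserts type-I error within 3x of
nominal under a null simulation), and with three replicates — a common
bench design — it has limited power at small effect sizes. For
production analyses of real data the `de_results.tsv` import path
(`read_de_results()`) lets any external DE engine's output drive the
downstream stages unchanged; the planted-truth recovery requirement for
this implementation is ranking quality (AUROC > 0.95 under the default
simulation conditions), not calibrated effect estimates.

DEG calling uses inclusive boundaries (`padj <= 0.05`,
`|log2FC| >= 1.5`): the thresholds are stated as "±1.5" style cutoffs
without strictness, and inclusivity is the reproducible, conservative
reading. The contrast definition (which group is "B") is the caller's
choice via the group factor levels; the pipeline does not fix a
particular time-point contrast.

### Over-representation

`hypergeom_upper(k, K, n, N)` is the exact upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, computed by direct
summation of $\binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$ in log space;
it equals the one-sided Fisher exact p-value of the corresponding 2x2
table. BH adjustment is the literal step-up rule. Decisions that shape
the results and are therefore fixed and documented:

* **Universe** = the genes tested for differential expression, not the
  genome. An enrichment universe wider than the measured genes biases
  p-values downward.
* Categories with zero query overlap (or outside the size bounds,
  default minimum 2) are skipped *before* adjustment, so $m$ is the
  number of actually tested categories; skipped categories are reported
  in the result's `"skipped"` attribute.
* Evidence filtering of miRNA→gene edges is **off** at the enrichment
  stage (the evidence requirement belongs to network construction);
  `filter_mirna_evidence = TRUE` switches it on for users who want the
  stricter reading.

### Network construction and hotspots

Candidates are DEGs plus enriched miRNAs. An interaction enters the
graph only if **both** endpoints are candidates (one-endpoint inclusion
would pull untested nodes into the centrality ranking) and its evidence
label matches the configuration. Disease contextualization keeps edges
with at least one disease-associated endpoint and is idempotent. The
same source→target pair typed both as tf→gene and mirna→gene is kept as
two typed edges, and degree counts each typed edge.

The four centralities are: total degree (in + out); betweenness on the
directed graph; harmonic closeness on the undirected skeleton (finite on
disconnected graphs, which evidence- and disease-filtered networks often
are); and eigenvector centrality of the undirected skeleton, computed by
shifted power iteration ($A + I$, uniform start, tolerance $10^{-10}$,
at most 10,000 steps). The shift leaves eigenvectors unchanged but
prevents the sign oscillation of bipartite graphs, and the deterministic
start keeps re-runs byte-identical. The hotspot rule per measure selects
rank $\le \lceil 0.10\,n \rceil$ with boundary ties *included* —
deterministic without arbitrary tie-breaking — and the hotspot set is
the union over measures. In sparse, star-like networks many nodes tie at
low centrality values, so the inclusive rule can select well beyond 10%
of nodes; the per-measure selections are returned so users can see why.
Whether the 10% applies jointly or separately per node kind
(gene/miRNA) is not dictated by the method; the default is joint, with
`hotspot_per_kind = TRUE` as the alternative.

### Semantic similarity and the homogeneity test

Term similarity is Wang's topology-only measure: each ancestor $t$ of a
term $A$ has semantic contribution $S_A(A) = 1$,
$S_A(t) = \max_{c \to t} w_{\mathrm{rel}} \cdot S_A(c)$ over DAG edges
inside $A$'s ancestor closure, with $w_{is\_a} = 0.8$,
$w_{part\_of} = 0.6$; then
$\mathrm{sim}(A,B) = \sum_{t \in \mathrm{anc}(A) \cap \mathrm{anc}(B)}
(S_A(t) + S_B(t)) / (SV(A) + SV(B))$. It was chosen over
information-content measures (Resnik, Lin) because it needs no
annotation corpus, is deterministic, and is the common default for
topology-only inputs. Gene-level similarity is the best-match average
of the term-similarity matrix. Cross-namespace pairs score 0 by
definition.

The homogeneity test compares all pairwise similarities among a
network's annotated genes against the pooled pairwise similarities of
100 same-size random sets drawn (without replacement) from the
annotated universe — random sets are matched on size only, the simplest
faithful construction when no covariate matching is specified. The
one-sided two-sample KS test asks whether the network's scores are
stochastically greater; the exact small-sample p-value is used when
both samples have at most 25 values, the asymptotic tail otherwise.

**Known limitation.** Pairwise scores within a gene set are not
independent — $\binom{s}{2}$ pairs share only $s$ genes — while the KS
reference distribution assumes they are. Under a null simulation the
test is well calibrated for small sets (the suite verifies a rejection
rate consistent with 0.05 at set size 4 over 200 replicates) but grows
anti-conservative as set size increases (empirically roughly 0.1–0.4 at
sizes 8–30 under the synthetic ontology). Homogeneity p-values for
large networks should therefore be read as enrichment-style scores, not
calibrated error rates; this caveat applies equally to any analysis
that feeds pooled pairwise similarities into a KS test.

## The synthetic-data generators

The generators stand in for unavailable bench data and external
database snapshots, and their defaults are the package's study
conditions, fixed once:

* `simulate_counts()`: NB counts, baseline means log-normal
  ($\log 100$, sd 1), common dispersion 0.1, 2000 genes, 5 samples per
  group, 10% DE genes at $|\log_2\mathrm{FC}| = 2$ with random sign.
  The log-normal/NB shape is standard for bulk RNA-seq; dispersion 0.1
  is a typical cell-line value.
* `simulate_regdb()`: 50 TFs (drawn from the gene universe, since a TF
  is itself a gene), 100 miRNAs, 50 targets per regulator, ~10% of
  targets being miRNAs so all four edge classes occur; planted miRNAs
  draw 80% of their targets from the planted DE pool versus a ~10%
  background rate; 70% of edges labelled experimental.
* `simulate_go()`: a complete tree of branching 3, depth 3 (40 terms)
  plus part_of shortcut edges from ~10% of leaves, background genes
  annotated to 1–2 random leaves; a planted module's genes are
  annotated only to leaves under one depth-1 branch, which guarantees
  high within-module Wang similarity.
* `simulate_disease()`: flags 30% of genes plus all planted miRNAs, so
  the planted structure survives contextualization while a substantial
  fraction of background edges is removed.

All generators are pure functions of their arguments including the
seed; `simulate_preset()` derives independent per-stage streams from
one master seed so individual stages can be regenerated alone.

What the generators do **not** emulate: library-size variation beyond
the NB noise (no planted size-factor differences), sample outliers and
batch effects, correlated co-expression among DE genes, hub-structured
(scale-free) background regulatory topology, multiple annotation
namespaces, annotation bias toward well-studied genes, and dependence
between the regulatory database and the ontology. Passing recovery
tests on this preset therefore demonstrates that the machinery is
correct and the planted signal is recoverable — not that the pipeline's
operating characteristics transfer to any particular real data set.

## Numerical and bookkeeping choices

* Pseudocount 0.5 on group means keeps fold changes finite for
  zero-mean groups; all-zero genes are defined to $p = 1$.
* Size factors require at least one gene positive in all samples;
  otherwise the run stops rather than silently switching reference.
* Functional-term exclusion propagates through both is_a and part_of
  descendants (ontology true-path convention) and is idempotent.
* BH is applied within each enrichment table, and across contrasts for
  the homogeneity p-values of one run.
* The run manifest contains the configuration snapshot, seed and MD5
  digests of every output — but no timestamps — so identical inputs
  reproduce identical trees.
* Test problem sizes (2000 genes, 5 + 5 samples, 100-miRNA database,
  40-term ontology, 200-replicate calibrations) are the package's
  chosen simulation scale: large enough for stable recovery statistics,
  small enough to iterate on quickly.

## Limitations

Beyond the KS calibration caveat above: the NB Wald test is a
simplified engine (use the import path for production DE calls); the
enrichment stage inherits whatever incompleteness the supplied
regulatory database has; hotspot membership is sensitive to the tie
structure of sparse networks; and identifiers are treated as opaque
strings — harmonizing miRNA naming conventions (e.g. precursor vs
mature arm names) is the caller's responsibility.
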