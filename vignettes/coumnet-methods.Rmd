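---
title: "Methods: attribute-enhanced clustering and multi-omics integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attribute-enhanced clustering and multi-omics integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coumnet)
```

`coumnet` analyses how a pCA-tolerant industrial yeast reorganizes its
transcriptome and physiology under p-coumaric acid stress. This vignette
documents the models behind each stage, the parameters that matter, the
synthetic data the pipeline is validated on, and the numerical and design
choices a maintainer should know about.

## Chemostat physiology

Steady-state chemostat mass balances give the specific conversion rate of
a compound as $q = 1000\,D\,(c_{feed}-c_{res})/(MW \cdot X)$ in
mmol g$^{-1}$ h$^{-1}$ (negative for consumption), with $D$ the dilution
rate (h$^{-1}$), $X$ the biomass (g DW L$^{-1}$) and $MW$ the molar mass
(built-in table: glucose 180.16, ethanol 46.07, glycerol 92.09, CO$_2$
44.01 g/mol; all overridable). Yields are concentration ratios over
consumed glucose. Percent changes between conditions are reported
relative to the control value and rounded to integers, matching how such
comparisons are conventionally printed; for signed rates the comparison
uses magnitudes so a faster consumption reads as an increase. Percent and
log2 changes obey $\log_2(1 + pct/100) = \log_2 FC$ for positive values —
a tested invariant. Carbon recovery is accepted as an input column and
never recomputed: that would need an elemental biomass composition the
data set does not carry. Note that log2 fold changes computed from
rounded condition averages need not match values computed upstream from
unrounded replicates; the functions compute from what they are given.

## The attribute-enhanced graph

Interactions below the STRING high-confidence cutoff (0.7 after
auto-rescaling 0–1000 integer scores) are discarded, as are edges
touching genes without a fold-change record — dropping, not imputing:
imputing log2FC = 0 would fabricate "unchanged" genes into a DEG-centric
network. The fold-change similarity $1 - |X_i - X_j|/d_{max}$ is
normalized by the largest fold-change gap $d_{max}$ **over retained
edges** by default; the score is only ever evaluated on edges, so
normalizing over all node pairs (available via `normalize = "pairs"`)
merely shrinks all scores by a constant factor. The edge weight is the
product of fold-change similarity and interaction confidence: the product
preserves [0, 1], is monotone in both arguments, and sends maximally
discordant pairs to zero; an arithmetic-mean combiner is available where
a softer penalty is wanted.

## Markov clustering and modularity

The MCL process is implemented directly on sparse matrices: self-loops
set to each node's maximum incident weight (stabilizes attractors),
column normalization, then alternating expansion (matrix square) and
inflation (entrywise power $r$, renormalize), pruning entries below
$10^{-5}$, until the iterate is idempotent to $10^{-8}$ (max entry
change) or 200 iterations, after which a warning flags the best-effort
partition. Columns are stochastic to $10^{-9}$ after every step.
Clusters are the attractor systems of the limit matrix; a node attracted
by two systems goes to the larger cluster, ties to the lexicographically
smallest member set, making the partition deterministic and invariant
under node relabeling. Cluster ids are renumbered by smallest member
name.

Weighted Newman modularity
$Q = \frac{1}{2m}\sum_{ij}(A_{ij} - k_i k_j/2m)\,\delta(c_i,c_j)$
(self-loops excluded) scores each partition; the inflation grid default
1.2–5.0 in steps of 0.2 spans coarse to fine granularity, and ties go to
the smaller inflation (coarser, more conservative clusters). Both the
partition and $Q$ are invariant under positive rescaling of the weights
— column normalization and modularity are scale-free — which is tested.
MCL runs on the enhanced-score weights by default; `weighted = FALSE`
gives plain topology for sensitivity checks.

Cluster selection keeps clusters with **more than 20 genes** whose
members inside the 1.5 × IQR whiskers all share one strict sign of
log2FC ("one quadrant"). Whisker outliers do not veto the direction
label and are not removed from the cluster: the filter describes the
fold-change distribution, not membership surgery.

## Hubs and enrichment

Centralities are computed per cluster on the **induced subgraph**,
unweighted by default: the weighted variants need a weight-to-distance
convention (we expose distance = 1/enhanced_score behind
`weighted = TRUE`), and unweighted topology is the conservative default
when the upstream analysis does not state one. Closeness is
$(n-1)/\sum d$ within a node's connected component; eigenvector scores
are scaled to a per-cluster maximum of 1 and rounded at the 10th decimal
so that exact symmetry (e.g. complete graphs) ranks as a tie rather than
as eigensolver noise. The hub rule — top 3 in at least 3 of 4 metrics,
capped at 3 per cluster by (rank sum, gene id) — is a declared heuristic
chosen to yield 2–4 hubs on clusters of 20–80 genes; `top_k` and
`min_metrics` are configurable because no canonical rule exists.

Term enrichment is the upper-tail hypergeometric test with BH correction
across terms **within each cluster** (the enrichment question is asked
per cluster), fold enrichment = observed/expected overlap, and the
cluster label is the lowest-FDR term at FDR ≤ 0.01 covering at least
half the cluster, ties broken by larger coverage then term id. The
p-values are validated against exhaustive enumeration of all draws on
small universes.

## Phenotype association

The upstream analysis tags genes as positively or negatively associated
with measured metabolites via Bayesian network inference over
Sturges-discretized data. `coumnet` keeps exactly that deliverable —
signed gene–phenotype links from discretized Bayesian scoring — with a
fully specified per-edge computation: both variables are cut into
$k = \lceil 1 + \log_2 n \rceil$ equal-width bins, and the score is the
Dirichlet–multinomial log evidence of the phenotype classes conditioned
on the gene classes (BDeu-style prior, equivalent sample size 1 split
across cells) minus the unconditional evidence. Conditioning multiplies
the parameter count by the number of gene classes, so the score has a
built-in complexity penalty: on independent Gaussian pairs at $n = 50$
it passes in well under 10% of seeds, and its null mean decreases with
$n$. The association sign comes from the Pearson correlation of the
**undiscretized** values — coarse bins make class-table signs ambiguous.
Full multi-parent structure search is deliberately out of scope; the
per-edge score is not claimed to reproduce any particular structure
learner's gene lists.

## Variants

Zygosity is unordered over the two alleles (phased and unphased
genotypes are identical); ploidy ≠ 2 is rejected because the three
classes — homozygous, heterozygous with reference, heterozygous without
reference — are diploid notions. Reference (`0/0`) and missing calls
carry no variant and are excluded. The consequence-to-tier table follows
the standard effect-predictor convention, including
`splice_region_variant` as LOW (only splice donor/acceptor sites are
HIGH); when one (variant, gene) pair carries several terms the most
severe tier wins. Summaries report distinct variants separately from
(variant, gene) rows, which exceed them whenever a variant annotates
multiple genes.

## Multi-omics integration

Edges point `variant → gene → pathway/phenotype` ("a variant may affect
the gene, leading to downstream alterations"). Gene-source edges carry
+1 when the gene's fold change and the target's alteration agree in
direction and −1 otherwise; variant edges are neutral (0) and only
MODERATE/HIGH-impact variants enter the network. Pathways contribute
edges only when their perturbation passes the FDR cutoff (0.01).
Phenotype change directions (ethanol rate up, biomass yield down) are
supplied explicitly from the physiology comparisons rather than inferred
from data — they are experimental facts of the condition contrast — and
gene→phenotype edges take the sign of the accepted association.
Fermentation/ethanol and ROS/redox memberships are node *attributes*,
keeping the graph layered; the final model is the sub-network whose
edges touch a hub or flagged gene, an idempotent extraction.

## The synthetic study

`synthetic_spec()` defaults define the validation conditions: 4 planted
clusters × 30 genes; intra-cluster edge probability 0.3 with confidences
in [0.75, 0.99]; inter-cluster probability 0.01 with confidences in
[0.40, 0.69], i.e. below the 0.7 filter, so the high-confidence subgraph
is cleanly modular and difficulty can be dialled via `p_in`/`p_out`;
cluster log2FC centers ±2 with per-gene noise SD 0.3 (clearly separated
up- and down-regulated clusters, as in the real contrast); 50 samples
split control/treated; one phenotype driven +1 by an up cluster
(`qEthanol`) and one −1 by a down cluster (`biomass_yield`) with noise
SD 0.1; 200 variants with uniform probabilities over the 12
zygosity × tier classes. Where the study conditions do not pin a value
(gene baselines at $\log_2$ 8 ± 1, significant synthetic FDRs, 5%
multi-gene variants) we chose once what is realistic for yeast RNA-seq
and kept it fixed. Expression is generated directly on log2 scale — no
count model — because differential-expression fitting is upstream of
this pipeline and downstream stages only consume log-scale values. One
seed drives all sub-generators.

What the generator does **not** emulate: real STRING topology
(hub-dominated degree distributions), count-level noise and
library-size effects, linkage between variants, or overlapping
functional terms. Passing tests therefore demonstrate correctness of the
computations and recoverability of planted structure under the stated
conditions — not performance on real yeast data, where cluster
boundaries are fuzzier and modularity lower.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on the
120-gene study (506 edges at seed 7), the MCL/modularity oracles on
graphs of up to 30 nodes (50 and 10 random draws), the association null
on 500 seeds at $n = 50$, and variant calibration at 1000 draws — sizes
at which every oracle (connected components, brute-force modularity
summation, exhaustive hypergeometric enumeration, truth-table zygosity)
is exact and the whole suite completes in well under a minute. All
randomness flows from explicit integer seeds; identical seeds give
byte-identical outputs.

## Known limitations

- MCL attractor interpretation assigns overlap deterministically but
  arbitrarily (larger cluster first); soft membership is not exposed.
- The association score assumes exchangeable samples; it ignores the
  control/treated block structure, which in the synthetic design is the
  main driver of both expression and phenotype — associations are
  correlational, never causal.
- Equal-width discretization is sensitive to single extreme outliers
  (they compress all other bins).
- The physiology comparison treats the two conditions as fixed averages;
  with duplicate chemostats there is no basis here for inferential
  error bars.
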