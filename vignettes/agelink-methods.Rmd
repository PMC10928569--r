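---
title: "Methods: linking age-dependent transcription to chromatin intermingling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking age-dependent transcription to chromatin intermingling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agelink)
```

## The problem

Human skin fibroblasts change their transcriptional program with age, and
those changes are accompanied by a reorganization of the three-dimensional
genome -- in particular of *interchromosomal intermingling*, the trans
contacts through which loci on different chromosomes co-localize. `agelink`
implements an integrative pipeline that (i) partitions a cross-sectional
RNA-seq cohort into data-driven age groups, (ii) selects robust
differentially expressed (DE) genes for each transition between consecutive
groups, (iii) identifies *bridge transcription factors* -- regulators that a
prize-collecting Steiner forest selects to connect the DE genes of one
transition to the DE genes of the next through a costed protein-interaction
network -- and (iv) decomposes balanced Hi-C contact maps into
large-average-submatrix (LAS) intermingling regions whose young/old
differences are then coupled back to the DE genes and bridge-TF targets.

Because the original cohort, interactome, regulon and Hi-C accessions are
external resources, the package ships a synthetic-data module that generates
all inputs with recorded planted structure. Every stage of the pipeline is
exercised, and judged, against that planted truth.

## Expression arm

**Normalization.** Within-sample comparisons use FPKM,
`count / (transcript_length/1e3) / (library_size/1e6)`. Between-sample
comparisons use median-of-ratios size factors (reference = per-gene
geometric mean over samples, genes containing a zero excluded from the
reference) and a variance-stabilizing transform. The VST here is the
shifted log `log2(count/size_factor + 1)`: the study tool's parametric VST
is deliberately not reproduced -- downstream stages only require a monotone,
variance-damped transform, and the package verifies by simulation that the
across-sample standard deviation after the transform varies far less with
the mean than the raw-count standard deviation does. A different transform
can be substituted wherever an `ExpressionMatrix`-like list with a `mat`
entry is accepted.

**Activity.** A gene is active in an age group when its mean FPKM over the
group's samples reaches 0.8, the end of the first mode of the bimodal
log-mean-FPKM histogram; genes with a mean strictly below the threshold are
inactive. Activity gates which proteins enter each transition network.

**Age-gene selection.** Age is regressed on standardized expression with an
L1 penalty (glmnet). The penalty grid `{0.25, 0.5, 1, 2, 4}` is relative:
grid values are mapped geometrically onto the data-driven path as
`lambda_max * (p / max(p))^3`, anchoring the largest grid value at the
smallest penalty that zeroes every coefficient. Any such grid therefore
spans "select almost everything" to "select nothing" regardless of the units
of age or expression; the support size is non-increasing in the penalty,
which is the property the grid encodes. The mid-grid penalty is the
pipeline default.

**Age groups.** Samples are clustered on the variance-stabilized profiles of
the selected genes with Euclidean distances and ward.D2 agglomeration
(squared-distance Ward update). The dendrogram is cut by cluster count
(default 6) rather than by phenetic height, because a height threshold does
not transfer across datasets; the height equivalent to the cut is recorded
in the returned object. Clusters whose age min-max ranges overlap are then
merged -- ties broken by merging the pair with the smallest combined range
first -- and groups are relabeled by ascending age midpoint. On the default
synthetic cohort this recovers the five planted groups exactly in most
seeds; in the remainder it merges one adjacent pair, which is why the
planted-truth evaluations of the downstream arms condition on the
generator's recorded group boundaries rather than on the estimated
clustering (the clustering operation has its own planted-recovery test with
well-separated clusters).

## Robust differential expression

The engine is a per-gene negative-binomial GLM with a log link, size-factor
offsets and a Wald test on the group coefficient. Dispersion is estimated by
the method of moments on normalized counts, pooled across the two groups by
degrees of freedom, floored at 1e-4 and capped at 50; coefficients come from
IRLS with closed-form 2x2 solves vectorized across all genes, which keeps
the 100-fold subsampling loop fast. The engine is intentionally simpler than
a full shrinkage estimator: what the pipeline contributes is the robustness
wrapper, and the engine only has to be calibrated, which the test suite
verifies (type-I error 0.05 +/- 0.02 under a matched NB null at n = 20 per
group).

Selection per transition applies three conjunctive filters:

1. a transition-specific p-value threshold, solved by quantile so that
   approximately `n_primary` genes with the smallest BH-adjusted p survive;
2. a robustness frequency: in each of `n_subsamples` (default 100) rounds,
   80% of the individuals per group are redrawn without replacement and the
   gene must reach adjusted p < 0.1 in at least `robustness_threshold`
   (default 0.7) of the rounds -- this damps the influence of outlier
   individuals;
3. an absolute log2-fold-change threshold, again solved by quantile toward
   `n_final` genes.

The default configuration carries the study-scale targets (~400 primary,
~170 final, appropriate for a 20,000-gene transcriptome). `sim_config()` is
the desk-scale companion for the synthetic cohort (2000 genes, 50 planted DE
genes per transition at |log2FC| >= 1): it sets `n_primary = 200` and
`n_final = 50` so that the fold-change filter is active at the planted
scale. The robustness threshold default of 0.7 is a configuration choice;
per-transition values can be supplied where a dataset's robustness profile
suggests them.

State signatures (one group versus all remaining samples, the `n_genes`
smallest adjusted p, split by direction) and the transcript-length imbalance
test (one-sided Welch t on log transcript length: down-regulated DE genes
shorter than non-DE, up-regulated longer; t = 0 and p = 0.5 returned for
degenerate equal constant inputs) complete this arm.

## Transition networks and the Steiner stage

PPI confidence scores x are reversed into costs
`1 - (x - min_score)/(max_score - min_score) + 0.01`; the pseudo-count
prevents zero-cost edges, so the best attainable PPI cost is exactly 0.01.
Regulatory TF-to-target edges are assigned that same minimum cost.

Network designs 1-5 are cumulative. Design 1 restricts the costed PPI to
genes active in either source-transition group, prizes source DE genes by
|log2FC|, adds separate target nodes for the next transition's DE genes
(prized likewise), and wires TFs in the PPI part to their targets among the
target nodes. Design 2 -- the pipeline default -- additionally injects the
bridge TFs of the next-older solved network as extra target nodes at the
minimum target prize, so regulators of the older program's drivers can be
discovered. Design 3 adds PPI edges among target nodes, design 4 adds the
remaining older-network nodes with their PPI edges to targets, and design 5
prizes those at the minimum target prize. For the oldest transition no older
network exists and the design falls back to the design-1 construction.

The prize-collecting Steiner forest minimizes
`sum(edge costs) + beta * sum(excluded prizes) + omega * (number of trees)`.
The per-tree penalty follows the dummy-root formulation (a virtual root
connected to every node at cost omega), so an isolated node may be bought as
a singleton tree when `beta * prize > omega`. `beta = 1` and `omega = 6` are
defaults recorded in all solver metadata; neither is dictated by the method
itself, and omega = 6 biases solutions toward a single forest at the desk
scale. Two solver modes are provided. Exact mode enumerates node subsets
(for a fixed subset, the optimal edge set is the minimum spanning forest
that admits only edges cheaper than omega) and is provably optimal up to 20
nodes. Heuristic mode grows a terminal-spanning tree from the metric closure
of the prized nodes, strong-prunes each component bottom-up
(`W(v) = beta*p(v) + sum over children of max(0, W(child) - edge cost)`),
drops components whose kept prize does not pay for their edges plus the tree
penalty, and hill-climbs over single-node inclusion flips on graphs up to
500 nodes. On random prized graphs of up to 12 nodes the heuristic matches
an independent brute-force enumeration of all subforests in at least 90% of
instances and is never better; exact mode matches always.

Roles in a solution are not exclusive: included prized nodes are
`source_de`/`target_de`, included unprized nodes are `steiner`, and a TF
incident to at least one *selected* regulatory edge into an included target
node is a `bridge_tf` -- selection of the edge, not mere incidence in the
input, is required.

## Hi-C arm

Maps are binned at 250 kb. Bins overlapping a blacklist interval or a
centromere extended by 2 Mb in both directions are masked (any-overlap
rule); masking is idempotent and applied to rows and columns. Balancing is
iterative proportional fitting to a doubly stochastic matrix: cis maps are
balanced per chromosome (symmetry restored exactly afterwards), trans maps
are balanced on the genome-wide matrix with all cis blocks removed, with
every unmasked row/column sum within relative 1e-6 of one; all-zero rows are
auto-masked with a warning and non-convergence is an error carrying the
residual. After `log(x+1)`, z-scores use moments pooled over all unmasked
cis entries for cis maps and separately over all trans entries for trans
maps. Distance-decay and insulation profiles (per-bin
`log2(window mean / chromosome mean)`) summarize the cis structure.

**LAS decomposition.** A contiguous submatrix with row/column interval
lengths k, l, unmasked-entry mean tau and effective entry count k_eff is
scored

`S = -log[(m-k+1)(n-l+1) * Phi(-tau * sqrt(k_eff))]`

with the Gaussian tail evaluated in log space. The multiplicity term counts
contiguous interval pairs, the correct null multiplicity for a search
restricted to contiguous submatrices; the original subset variant with
binomial coefficients is available as a configuration switch. The
decomposition repeatedly takes the best submatrix, accepts it when S reaches
the threshold, subtracts tau from its entries and continues; accepted scores
are non-increasing along the sequence. Matrices of at most 2048 cells are
searched exhaustively over all interval pairs via 2D prefix sums; larger
matrices use alternating row/column interval sweeps seeded from the
top-mean square windows at scales 4/8/16, the top cells and random cells.
An optional interval-length cap (`max_len`) bounds the search on large
chromosomes and excludes degenerate map-spanning intervals.

The study-scale default threshold is 0 (the score exceeds the
multiplicity-corrected Gaussian null at even odds). At the desk scale of the
toy genome, planted trans blocks score far above 100 while residual noise
and balancing structure stay below ~15, so `sim_config()` sets the threshold
to 20 with at most 20 submatrices per map and `max_len = 16`; this
calibration is part of the synthetic study conditions, analogous to choosing
the threshold by the resulting submatrix count at full scale.

**Replicates and difference maps.** Every submatrix detected in either
replicate is rescored in the other replicate's z-scored map and kept only
when it clears the threshold in both; this is what makes a pure-noise map
yield an empty condition-level result even though a single decomposition at
threshold 0 would almost always cross zero somewhere. The kept submatrices'
pixels form the condition's binarized intermingling map, along with the
Pearson correlation between paired scores. The young/old difference map
labels each pixel `young_only`, `old_only` or `shared`, and specificity is
the fraction of non-shared labels, reported separately for intra- and
interchromosomal pixels.

## Integration

Genes map to loci as `floor(start / resolution)`; a gene spanning several
bins takes the first in genomic order, and genes on masked bins are flagged
out. "Intermingling interactions" are counted at gene-pair granularity (a
pixel lookup per unordered gene pair) rather than pixel granularity, since
several genes can share a bin; pairs mapping to the same bin are excluded as
uninformative. Percentages are over labeled pairs; a gene with at least one
young- or old-specific pair is "specific". Empirical nulls redraw same-size
random gene sets (seeded); a zero exceedance count is printed as
`< 1/n_draws` while the stored value remains 0 -- the honest resolution of an
empirical null.

The direction analyzed per network follows the majority direction of that
network's target DE genes (configurable), generalizing the choice of
up-regulated targets for the youngest network and down-regulated for the
oldest. Per-TF intermingling change is the percentage of labeled pairs among
the TF's direction-matched DE targets that are condition-specific, NA when
no labeled pairs exist; TF feature tables are z-scored per feature over
non-missing TFs, clipped to [-2, 2] (a constant feature becomes 0 with a
warning), and exported with a complete-linkage hierarchical row order.

TF-level statistics use the hypergeometric upper tail throughout: target
enrichment per bridge TF (`Hypergeom(M, n, N)`, Bonferroni over the
network's bridge TFs, significant below 0.05) with M defaulting to the
tested expression universe rather than the full annotation; co-target edges
between TF pairs admitted when p is below 1e-15 and the shared-target
Jaccard proportion strictly exceeds 0.5; and a seeded permutation test for
regulatory-network density (edges/nodes, self-loops included). The
"confidence interval over N" of the enrichment is implemented as the p-range
over N' in [ceil(0.9N), floor(1.1N)] (2.5-97.5% span) -- the grid is a
documented convention, as the procedure is otherwise under-specified.

## The synthetic generator

`sim_spec()` defaults define the study conditions at desk scale: five age
groups of 20 individuals spanning 1-96 years (cut points 16/27/61/86); 2000
genes with NB counts (`mu = libsize * 2^(baseline + effects)`, constant
dispersion 0.05 -- the simplest model satisfying the Wald-test assumptions;
Poisson at dispersion 0); 50 linear-trend genes (0.01-0.03 log2/year) and 50
step DE genes per transition with |log2FC| in [1, 2]; planted age effects
positively coupled to log transcript length (coefficient 0.3); a scored
interactome (scores 150-1000) hosting 4 planted bridge TFs per
transition-pair network -- cohort genes with maximum-score edges to source DE
genes and regulons covering 60% of the matching target DE set -- plus 40
size-matched decoy TFs, with 20% of TFs self-targeting; and a toy genome of
four 14-16 Mb chromosomes at 250 kb (240 bins). The chromosomes are
near-equal deliberately: the doubly-stochastic trans normalization gives
each chromosome pair a mean level set by its partner-bin count, and strongly
unequal toy chromosomes would turn that desk-scale artifact into map-wide
z-score offsets that no real 22-chromosome genome exhibits.

Hi-C condition means are deterministic -- cis decay `(1+|i-j|)^-1` tiled with
shared TAD-like diagonal domains (8-12 bins), a constant trans background,
plus planted blocks -- and replicates add independent truncated Gaussian
noise (sd 1), so condition-specific structure can only come from the planted
blocks: young-specific blocks sit over the anchor regions where 60% of the
strongly down-with-age genes are placed, old-specific blocks over the
up-gene anchors, and shared trans blocks elsewhere. The shared cis domains
lock the intrachromosomal LAS coverage to the same signal in both
conditions, reproducing the finding that age-related reorganization is
almost entirely interchromosomal.

What the generator does **not** emulate: compartment/TAD hierarchies beyond
the flat diagonal domains, distance-dependent trans structure, per-gene
dispersion heterogeneity, sex structure, batch effects, or regulons inferred
from expression. Passing the planted-truth suite therefore demonstrates that
the machinery recovers the structures it models under realistic noise -- not
that it would be similarly sensitive on real data with these additional
complications.

## Problem sizes and numerical choices

The test and acceptance runs use the desk-scale conditions above: full-fate
runs of the pipeline (100 samples x 2000 genes, 100 DE subsamples per
transition, three Steiner networks of a few hundred nodes, forty 56-64-bin
contact maps) complete in about a minute. Ties in interval search resolve
to the first maximum; IRLS stops at coefficient changes below 1e-8 or 25
iterations with linear predictors clamped to [-30, 30]; balancing stops at
relative residual 1e-6 or errors at 5000 iterations; objective comparisons
in the Steiner solver use a 1e-12 strict-improvement margin; empirical
p-values are exceedance fractions with seeds threaded through every
stochastic call.

## Known limitations

The heuristic Steiner solver carries no optimality guarantee beyond the
small-instance equivalence checks; full-interactome provable optimality is
out of scope. The shifted-log VST under-stabilizes very low counts relative
to a parametric fit. The LAS residualization subtracts block means in place,
so strongly overlapping true blocks are recovered as merged shapes. Age
groups from ward.D2 can merge adjacent planted groups at desk-scale noise;
the grouping is a data-analytic definition, not an estimator with a
guarantee. Empirical p-values are bounded below by 1/n_perm.
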