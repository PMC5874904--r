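---
title: "Methods: gene co-occurrence networks and host-range inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene co-occurrence networks and host-range inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bacteriophage genomes are mosaics assembled by rampant horizontal gene
transfer; no gene is universal, so distant phages cannot be placed on a
single phylogeny. phagenet takes the gene, not the genome, as the unit of
analysis. A collection of phage proteomes is reduced to a binary membership
matrix $P$ (genomes $\times$ homologous gene clusters, $P_{ij} = 1$ iff
genome $i$ carries a member of cluster $j$), and $P$ is projected into two
simple undirected graphs:

* the **genome network** $A_\mathrm{genome} = \mathrm{sign}(P P^T)$ — genomes
  adjacent iff they share a cluster;
* the **gene network** $A_\mathrm{gene} = \mathrm{sign}(P^T P)$ — clusters
  adjacent iff some genome carries both.

Diagonals are discarded and all weights binarized. Everything downstream —
graph clustering, host-association statistics, the mutual-information search,
and host prediction — operates on these two graphs and on $P$.

## Gene clustering and filtering

The built-in clusterer is a deterministic greedy centroid scheme in the
UCLUST mold: sequences are visited in order of decreasing length (ties by
identifier) and join the first centroid whose global-alignment identity
reaches the threshold, else found a new cluster. Identity is computed from a
Needleman–Wunsch alignment with fixed scoring (match $+1$, mismatch $-1$, gap
open 5, gap extend 1) as matched columns over alignment columns, excluding
terminal-gap columns — the closest widely used analogue of the identity
USEARCH reports. The default threshold is 0.35: in phage protein data this
region balances the growth in total clusters against the growth in singleton
clusters, both of which increase monotonically with the threshold (the test
suite asserts this on generated families). The built-in clusterer is meant
for synthetic and desk-scale data; corpus-scale clusterings are supplied as
precomputed maps (TSV or USEARCH UC) and bypass it.

Clusters with fewer than 3 members are dropped before network construction:
singleton and doubleton clusters contribute no reliable co-occurrence signal.
Genomes losing every gene in this filter are reported and excluded.

## Markov clustering and inflation choice

`mcl_cluster()` is a from-scratch MCL: the adjacency matrix plus unit
self-loops is column-normalized into a random-walk matrix; expansion (matrix
squaring) and inflation (entrywise power, pruning below $10^{-8}$, column
renormalization) alternate until the largest entrywise change falls below
$10^{-6}$ (at most 200 iterations, with a warning on non-convergence).
Clusters are the connected components of the limit matrix's nonzero support.
Self-loops prevent period-two oscillation on bipartite-like structures; the
pruning and tolerance values are the customary desk-scale defaults of the
reference implementation of the algorithm. The readout by components makes
the rare overlapping-attractor case resolve deterministically (overlaps merge).

Inflation controls granularity. `sweep_inflation()` scores each partition
with the intracluster clustering coefficient (ICCC): for each cluster of
size $\ge 3$, the mean local clustering coefficient of its induced subgraph;
the ICCC is the size-weighted mean over such clusters (an unweighted mean is
available behind `weighted = FALSE`; the weighting is a documented choice,
since size weighting stops a swarm of tiny perfect clusters from dominating
the score). Ties in the argmax resolve to the smallest inflation.

Because no external `mcl` binary is assumed, correctness is pinned by a
committed fixture suite: twelve graphs of up to 30 nodes whose partitions at
inflations 1.5, 2 and 4 were produced by an independent implementation of
the same published algorithm and spot-checked against analytically known
partitions (disjoint cliques, barbells). Rotationally symmetric graphs such
as plain cycles are deliberately absent: their MCL split is degenerate and
decided by floating-point tie-breaking.

## Host profiles and MPD

Host metadata annotates each genome with a host genus (or unknown). Each
gene cluster receives a host-association vector counting the known-host
genomes that carry it, per genus; a genome's vector is the sum over its
clusters. Unknown-host genomes take part in network construction but
contribute to no profile and are excluded from mutual information and
prediction scoring.

The phylogenetic breadth of a profile is summarized by abundance-weighted
mean pairwise distance over the genus-level host tree:
$$\mathrm{MPD} = \frac{\sum_{i \ne j} d_{ij} f_i f_j}{\sum_{i \ne j} f_i f_j},$$
with $f_i$ the relative abundances and $d_{ij}$ cophenetic distances.
Conspecific pairs ($i = j$) are excluded from numerator and denominator, so a
single-genus profile has MPD exactly 0 and a two-genus profile has MPD equal
to the genera's distance regardless of weights. Note that
`picante::mpd(abundance.weighted = TRUE)` *includes* conspecific pairs in
the weighted mean and therefore returns smaller values on multi-genus
profiles; the excluded-diagonal form is used here because its invariants
(two-taxon case, tree-diameter bound) are the ones the analyses rely on. The
test suite checks the implementation against a brute-force double loop, not
against picante. An empty profile is `NA`, signaled distinctly from 0.

Strain-level trees are collapsed to genus level by placing each genus at the
most recent common ancestor of its strains; inter-genus distances are path
lengths between MRCAs, computed exactly from node depths. Non-monophyletic
genera are collapsed at the MRCA anyway, with a warning naming the intruding
taxa; a drop list removes misplaced leaves first. The returned tree keeps one
representative tip per genus with its terminal branch rescaled, which is
exact for monophyletic genera; the distance matrix, which downstream code
uses, is exact always.

## Topology versus host relatedness

For each unordered pair of known-host genomes, the mean over the rectangular
cluster-by-cluster submatrix of (a) BFS shortest-path lengths and (b) Jaccard
similarity of open neighborhoods is recorded together with the pair's host
phylogenetic distance. Pairs of clusters in different components are excluded
from the path mean (not treated as infinite) and counted; pairs with zero
similarity are dropped from the log-transformed regression and counted. Host
distance is then regressed by OLS on the log of each topology measure. On
host-structured data the path slope is positive and the similarity slope
negative: genes of phages with related hosts sit closer and share more
neighbors.

## Mutual information and the mimax search

The correspondence between graph structure and host labels is quantified by
the mutual information of the $\chi$ matrix (MCL clusters $\times$ host
genera, counts accumulated from the clusters' host vectors):
$$I(X, Y) = \sum_{x, y}\ p(x, y) \log \frac{p(x, y)}{p(x)\,p(y)},$$
in nats, with zero cells contributing 0. Natural logarithm keeps the values
comparable to $\ln(\text{number of genera})$, the attainable ceiling.

`mimax_search()` is the constrained greedy maximizer: repeatedly pick a
retained $\chi$ row uniformly at random; reject the deletion outright if any
genome would lose its last gene cluster; otherwise delete it iff the mutual
information strictly increases. It is implemented as exactly the single-chain
stochastic hill climber this description defines — no population or
crossover — with replicates supported through seeds. Termination, which the
procedure itself leaves open, is by a patience counter: stop after
`10 * nrow(chi)` consecutive non-accepted proposals (counting both infeasible
and non-improving ones; configurable) or $10^5$ proposals. Accepted steps
form a strictly increasing MI trajectory, and the coverage constraint is
replayed and asserted in the tests. Because single deletions cannot cross MI
valleys, the search is local; on small instances the tests compare 20 seeded
restarts against exhaustive subset enumeration.

mimax works best when MCL clusters are small and numerous, so
`granularity_boost()` first adds `edges_per_node = 5` random edges per node
(seeded, sampled without replacement among current non-neighbors, pairs
deduplicated; the realized count is logged) and reruns MCL at inflation 15.
The random edges break ties between near-identical neighborhoods and split
large clusters.

## Host prediction and enrichment

A phage's host is predicted as the argmax of its leave-one-out profile over
the mimax-retained clusters: the sum of its clusters' host vectors minus its
own contribution (one count of its own genus per cluster). Ties are flagged
and broken toward the genus with more genomes overall, then
lexicographically. Genomes whose clusters occur nowhere else get no
prediction and are excluded from accuracy denominators. The relationship
between correctness and profile MPD is fit by logistic regression with
McFadden's $R^2 = 1 - \ell_\mathrm{model}/\ell_\mathrm{null}$; under complete
separation a Firth bias-reduced fit is substituted and labeled. When every
profile is single-genus (MPD 0), predictions are correct by construction
whenever annotations are consistent — the test suite asserts exactly 100%
accuracy on that stratum.

External phages are mapped into the network by aligning their proteins to
cluster centroids (local alignment, BLOSUM62, gap 11/1) with a
Karlin–Altschul bit-score surrogate ($\lambda = 0.267$, $K = 0.041$);
hits need E $< 10^{-5}$ and bit score $> 50$. The surrogate is deterministic
and calibrated to protein-BLAST conventions but not bit-identical to BLAST.

Functional enrichment among retained genes is assessed by OLS of
post-reduction subsystem annotation counts on pre-reduction counts, flagging
subsystems outside the pointwise 99.9% confidence band for the *mean
response* ($t$, $n-2$ df). The mean-response band (rather than a prediction
band) is the default because the question is whether a subsystem departs
from the fitted retention trend; the prediction band is available via
`interval = "prediction"`. The fit is on counts; $R^2$ is invariant to
rescaling either column into frequencies (asserted in the tests), and both
the multiple and the adjusted $R^2$ are reported — with ~32 subsystem rows
they differ in the third decimal, and summary tables commonly print the
adjusted one. A bundled example table
(`inst/extdata/phage_subsystem_annotations.tsv`) carries subsystem counts
before and after a mimax reduction of a large RefSeq-era phage gene set; on
it the band flags baseplate, neck, replication and DNA-synthesis genes as
over-retained and packaging and regulatory genes as under-retained.

## The synthetic-data generator

`simulate_dataset()` emulates exactly the structure the analyses assume: a
genus-level host tree (balanced with unit branch lengths, or coalescent);
disjoint per-host pools of gene clusters; mosaic genomes drawing each gene
from their own host's pool with probability $1 - \mathrm{hgt\_rate}$ and
otherwise from a foreign pool chosen $\propto e^{-d/\mathrm{phylo\_decay}}$;
and genome-private singletons injected at `singleton_rate` to exercise the
small-cluster filter. Defaults — 8 hosts, 10 genomes per host, 30 genes per
genome from pools of 60, `hgt_rate = 0.1`, `phylo_decay = 2`,
`singleton_rate = 0.05` — describe a moderately sampled community in which
same-host genomes overlap strongly, cross-host sharing decays with
phylogenetic distance (nearest versus most distant genus weighted about
7:1), and rare genes exist. Optional sequences evolve each cluster from a
random ancestor with 10% per-site substitutions, so the built-in clusterer
recovers the ground truth at the 0.35 threshold (Rand index $\ge 0.95$,
asserted).

What the generator does **not** emulate: real phage genome architecture
(synteny, module order, lifestyle genes), unequal host sampling, sequence
convergence, or within-cluster point variation that affects host range.
Consequently, passing tests demonstrate that the algorithms recover planted
co-occurrence structure, not that real corpora will show comparable accuracy
— on real data, the mosaicism ceiling and uneven sampling reduce prediction
accuracy well below the synthetic 100%.

All randomness (tree shape, genome composition, edge augmentation, mimax
proposals) flows through R's Mersenne–Twister stream via per-stage seeds
derived from one global seed; a fixed configuration is bit-reproducible.

## Problem sizes and numerical notes

The test suite and the acceptance script run the full pipeline on the default
80-genome simulation (about 450 retained clusters, a ~19,000-edge gene
network), sweep MCL over a two-point grid there, and use 500–1000 random
instances for the MPD and mutual-information oracle checks — sizes chosen so
the whole suite completes in about two minutes on a laptop core while still
exercising every stage at meaningful scale. Degenerate inputs are handled
explicitly: empty profiles return `NA` (never 0), all-zero count matrices and
all-correct logistic inputs are errors, zero-length terminal branches are
allowed with a warning, and `sd = 0` predictors abort the regressions.

## Known limitations

* The greedy clusterer is quadratic and intended for thousands, not hundreds
  of thousands, of sequences.
* mimax is a local search; replicate seeds mitigate but do not remove the
  risk of inferior local optima on adversarial instances.
* Dense-matrix MCL is cubic per iteration; networks beyond a few thousand
  nodes call for the sparse external implementation, whose native output
  `read_mcl_clusters()` imports.
* Host prediction is single-label; polyvalent phages are outside scope.
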