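# phagenet

Gene co-occurrence networks for bacteriophage ecology and host-range
analysis.

## Why

Phage genomes are mosaics: genes move freely between viruses, no gene is
shared by all phages, and ordinary phylogenetics cannot relate distant
phages. `phagenet` works at the gene level instead. A set of phage proteomes
becomes a binary membership matrix **P** (genomes × homologous gene
clusters), which is projected into two simple graphs:

- **genome network** `sign(P Pᵀ)` — genomes adjacent iff they share a gene
  cluster;
- **gene network** `sign(Pᵀ P)` — clusters adjacent iff they co-occur in
  some genome.

On top of these the package provides, for microbial ecologists and phage
genomicists:

- a from-scratch **Markov Cluster (MCL)** implementation with an inflation
  sweep scored by the intracluster clustering coefficient (ICCC);
- **host-association profiles** and abundance-weighted **mean pairwise
  phylogenetic distance** (MPD) over a genus-level host tree,
  `MPD = Σ_{i≠j} d_ij f_i f_j / Σ_{i≠j} f_i f_j`;
- regressions of host phylogenetic distance on gene-network **shortest
  paths** and **neighborhood (Jaccard) similarity**;
- **mimax**: a constrained stochastic greedy search that deletes MCL
  clusters to maximize the mutual information
  `I(X,Y) = Σ p(x,y) log[p(x,y)/(p(x)p(y))]` (in nats) between graph
  clusters and host genera, never letting a genome lose its last gene;
- leave-one-out **majority-host prediction** with accuracy-versus-MPD
  logistic analysis and subsystem-annotation **enrichment** (99.9% CI
  outliers around the retention regression);
- a **synthetic-data generator** producing host-structured mosaic genomes so
  every stage is testable offline.

## Worked example

```r
library(phagenet)

# simulate a host-structured phage community and run the whole pipeline
sim <- simulate_dataset(simulation_config(seed = 1))
print(sim)
#> phage_sim: 80 genomes, 2528 genes, 608 gene clusters, 8 host genera (seed 1 )
res <- run_pipeline(sim, inflation_grid = c(2, 4), seed = 1)

# network topology tracks host relatedness: genomes whose genes share more
# edges infect closer hosts (negative slope, log-transformed predictor)
str(res$regression$similarity)
#> List of 6
#>  $ slope    : num -2.26
#>  $ intercept: num -1.15
#>  $ r_squared: num 0.862
#>  $ p_value  : num 0
#>  $ n_used   : int 3160
#>  $ n_dropped: int 0

# mimax deletes uninformative MCL clusters, raising the mutual information
print(res$mimax)
#> mimax_state: 162 rows retained; MI 1.74 -> 2.079 in 6238 proposals ( 284 accepted )

# leave-one-out majority-host prediction
acc <- res$accuracy
cat(sprintf("overall accuracy %.2f over %d genomes\n",
            attr(acc, "overall_accuracy"), attr(acc, "n_scored")))
#> overall accuracy 1.00 over 80 genomes
```

On this clean simulation the final MI (2.079 = ln 8) means retained clusters
identify the 8 host genera perfectly, and every leave-one-out profile is
single-host (MPD 0), where majority-host prediction cannot err. Real corpora
are far noisier; the slope signs and the MPD-0 guarantee, not the 100%, are
the transferable results.

Enrichment on the bundled subsystem annotation table (counts of RAST-style
functional annotations among a large phage gene set, before and after a
mimax reduction):

```r
tab <- read_annotation_table(system.file("extdata",
        "phage_subsystem_annotations.tsv", package = "phagenet"))
enr <- enrichment_outliers(tab, ci_level = 0.999)
cat(sprintf("R^2 = %.4f (adjusted %.4f); retained %.3f of annotations\n",
            enr$r_squared, enr$adj_r_squared, enr$proportion_retained))
#> R^2 = 0.9315 (adjusted 0.9292); retained 0.428 of annotations
enr$table[enr$table$direction != "none",
          c("subsystem", "pre", "post", "direction")]
#>                                 subsystem pre post direction
#> 6                Phage baseplate proteins  56   46      over
#> 7                       Phage replication 215  110      over
#> 8                         Phage packaging 144   37     under
#> 9                     Phage neck proteins  24   19      over
#> 13                    Phage DNA synthesis  46   33      over
#> 18 Phage nin genes-N-independent survival  17    0     under
#> 27          Regulation and cell signaling  22    1     under
```

Baseplate, neck, replication and DNA-synthesis genes are retained above the
global trend — functions known to mediate host recognition and within-host
reproduction — while packaging and regulatory genes fall below it.

A thin command-line front end is included at `inst/cli/phagenet.R`
(`simulate`, `run`, `enrich` subcommands).

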