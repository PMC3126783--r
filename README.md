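# seedcoex

Tools for analysing replicated transcriptome time courses of developing
seeds: who is expressed, which genes move together, what temporal shapes
dominate, and which promoter elements might explain the co-movement.

The package grew out of the analysis style used for the eight-stage
(globular embryo through mature embryo) Arabidopsis seed series measured
in triplicate on expression arrays, but every step is generic: any log2
expression matrix with a sample-to-stage design, any promoter FASTA and
any position-weight-matrix (PWM) collection can be fed through it.  A
synthetic-data generator with planted ground truth (cluster labels and
motif placements) makes the whole pipeline testable without any
downloads.

## What it computes

1. **Expressed-gene filter and stage medians.** A gene is "present" in a
   sample when its log2 intensity is at least 6.0; genes present in
   fewer than 3 samples are discarded.  Replicates are collapsed to
   per-stage medians.
2. **Sample QC.** PCA of samples in gene space (genes centered), and a
   permutation test of stage association whose statistic is the sum over
   genes of the between-stage sum of squares; p = (1 + #{permuted >=
   observed}) / (n_perm + 1).
3. **Coexpression network.** Pearson correlation r of stage-median
   profiles, an edge when r >= 0.90 (positive correlations only).  Edge
   significance via Fisher's Z: z = atanh(r), one-sided p from
   z·sqrt(n−3); with r = 0.90, n = 8 this gives p ≈ 0.0005.  Topology
   diagnostics: mean clustering coefficient over nodes with degree ≥ 2,
   degree histogram, and the scale-free fit — OLS of log10 p(k) on
   log10 k over ≤ 10 log-spaced degree bins, reporting γ = −slope and
   R², the scale-free topology criterion.  Subnetworks around seed genes
   by neighborhood expansion or connected components; SIF / TSV export.
4. **Fuzzy c-means clustering.** Profiles standardized to mean 0, sd 1,
   clustered with the Bezdek iteration (defaults c = 6, m = 1.75);
   cluster cores are genes with membership ≥ 0.90.
5. **Promoter motifs.** PWM scanning on both strands with a min-max
   normalized log-odds score ("relative score", cutoff 0.80); an
   independent caller that scores 10 length-matched 4th-order-Markov
   background sequences per promoter and keeps the largest hit set with
   estimated FDR ≤ 0.15; the consensus (sites found by both) is tested
   for overrepresentation: a PWM is flagged when its hit count exceeds
   the mean + SD of counts over all PWMs.  Also: AW-box
   ([CnTnG](n)7[CG]) scanning, promoter G+C content, per-position
   information content, and promoter extraction (1000 bp upstream +
   200 bp 5'UTR, truncated at upstream neighbors).

## Worked example

```r
library(seedcoex)

dir <- tempfile()
make_fixture(dir, seed = 1)           # synthetic 2000-gene, 300-promoter set

em  <- read_expression(file.path(dir, "expression.tsv"),
                       file.path(dir, "design.tsv"))
expressed <- filter_expressed(em, cutoff = 6.0, min_present = 3)
length(expressed)
#> [1] 1978

sm  <- stage_medians(expression_matrix(em$values[expressed, ], em$design))
net <- build_network(coexpression_edges(sm, threshold = 0.90), 0.90)
net
#> coexpression_network: 1978 nodes, 325141 edges (r >= 0.90)
topology_stats(net)
#> nodes 1978  edges 325141  mean k 328.8  median k 332  max k 333
#> clustering coefficient 1.000  scale-free R2 NA  gamma NA

fz <- fisher_z_pvalue(0.90, 8)
fz$p_value
#> [1] 0.0004974184

fcm <- fuzzy_cmeans(standardize_profiles(sm), centers = 6, m = 1.75, seed = 3)
lengths(cluster_cores(fcm, 0.90))
#> cluster1 cluster2 cluster3 cluster4 cluster5 cluster6
#>      323      321      333      334      334      333
```

The 1978 of 2000 genes passing the presence filter mirror how a 6.0
log2 cutoff trims the low end of a 6–12 baseline range; the six planted
temporal archetypes come back as six tight clusters (adjusted Rand
index 1.0 against the generator's truth), and almost all genes sit in
cores because the planted shapes are well separated.  The synthetic
network is far denser and more regular than a real transcriptome:
six archetypes make six near-cliques, so nearly every node has the
same degree, the clustering coefficient saturates at 1, and the
scale-free fit is undefined (fewer than five distinct degrees) — on
real data, with thousands of partially-correlated programs, the degree
distribution is broad and those diagnostics are informative.

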