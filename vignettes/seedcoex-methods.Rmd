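---
title: "Methods: coexpression, fuzzy clustering and promoter motifs for seed time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coexpression, fuzzy clustering and promoter motifs for seed time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcoex)
```

# Overview

`seedcoex` analyses replicated expression time courses of developing
seeds in five stages: presence filtering, stage-median summarisation and
sample QC; a Pearson-threshold coexpression network with topology
diagnostics; fuzzy c-means clustering of standardized temporal profiles;
and promoter motif detection with an overrepresentation test.  This
vignette explains each model, its assumptions, the tunable parameters,
and the design decisions taken where the method left genuine freedom.
It also describes exactly what the synthetic-data generator does and
does not emulate, so that the meaning of a passing test suite is clear.

# Expression QC

**Presence filter.** A gene is called present in a sample when its log2
intensity reaches `cutoff` (default 6.0, a "modest expression" level on
a log2 intensity scale); genes present in fewer than `min_present`
samples (default 3, i.e. one full stage of a triplicated design) are
treated as unexpressed.  Presence counts individual samples, not
stages, so a gene transiently expressed in a single stage survives.
The comparison is `>=`: a gene sitting exactly at the cutoff is
present.  The filter is monotone — raising either parameter can only
remove genes.

**Stage medians.** Replicates are collapsed by the per-stage median,
which is robust to a single aberrant replicate; an even number of
replicates yields the usual midpoint.  Stage order is taken from first
appearance in the design file rather than lexicographic order, so
series such as S9, S10 keep their temporal order.

**PCA.** Samples are projected in gene space after centering each gene
(no unit-variance scaling, since the data are already on a common log2
scale); variance fractions come from the singular values and sum to 1.
A matrix with zero total variance is an error, not a silent NaN.

**Stage association.** As a whole-set test of whether expression varies
across stages we use a permutation test: the statistic is the sum over
genes of the between-stage sum of squares of sample values, and stage
labels are permuted over samples.  The p-value is
(1 + #{permuted ≥ observed}) / (n_perm + 1), which can never reach 0
and attains 1/(n_perm + 1) at best.  The statistic is a natural
"pooled one-way ANOVA numerator"; its calibration is checked in the
test suite (empirical type-I error at nominal 0.05 over 200 null
simulations) rather than assumed.

# Coexpression network

Correlations are computed between per-gene **stage-median profiles**
(n = 8 points in the default design), not the 24 individual samples:
the temporal shape, not replicate scatter, should drive coexpression.
Genes with zero variance across stages are excluded because their
correlation is undefined.

An edge connects genes with Pearson r ≥ `threshold` (default 0.90),
**positive correlations only** — positive and negative coexpression
reflect different biology (synergy vs antagonism), and mixing them in
one graph obscures both.  The boundary is included (r = 0.90 is an
edge).  With only 8 observations per profile a stringent threshold is
essential; its significance is quantified by Fisher's Z transformation,
z = atanh(r), approximately normal with standard error 1/sqrt(n − 3),
giving a one-sided p ≈ 0.0005 for r = 0.90 at n = 8.  That number is a
property of the threshold and the design, independent of the data.

The all-pairs stage streams over gene blocks (`coexpression_edges`),
emitting only above-threshold pairs, so the dense gene × gene matrix is
never materialised and 12,000+ genes fit comfortably in memory.

**Topology diagnostics.** The local clustering coefficient
2·triangles(v) / (k_v(k_v − 1)) is averaged over nodes with degree ≥ 2;
nodes of degree < 2 have an undefined local coefficient and are
excluded from the mean (the alternative — counting them as 0 — would
conflate sparsity with low transitivity).  The degree histogram uses
fixed bins (1; 2–49; 50–99; … ; ≥300) so networks of different sizes
are comparable.  The scale-free fit bins empirical degree frequencies
p(k) into at most 10 logarithmically spaced degree bins (empty bins
dropped; when there are no more distinct degrees than bins, each
distinct degree is its own point), regresses log10 p(k) on log10 k by
ordinary least squares and reports γ = −slope and R² — the scale-free
topology criterion.  An upward slope is reported as R² = 0.  The test
suite verifies that degrees drawn from an exact k^−2 law give γ within
0.2 of 2 with R² ≥ 0.95.

**Subnetworks.** Around a set of seed genes, either the induced
subgraph on the seeds and their first neighbors ("neighborhood") or the
union of connected components containing a seed ("component").  Both
are provided because published subnetwork analyses do not always state
which expansion was used.

# Fuzzy c-means clustering

Profiles are standardized per gene to mean 0, sd 1 so that clustering
in Euclidean space groups temporal *shapes* irrespective of absolute
level.  Flat profiles have no shape and are dropped with a warning.

Clustering is the standard Bezdek alternating iteration: centers are
membership-weighted means with weights u^m, memberships follow
u_ij = 1 / Σ_k (d_ij/d_kj)^(2/(m−1)), and the objective
J = Σ u_ij^m d_ij² is non-increasing at every step (asserted in the
tests).  Defaults are c = 6 clusters — enough to separate the
recurring seed-maturation patterns (early-peak/decline, step-plateau,
late rise, and their mirror images) — and fuzzifier m = 1.75, a
moderate softness at which well-separated shapes still produce crisp
memberships.  Convergence stops when the largest membership change
falls below `tol` (default 1e−6, cap 1000 iterations); these two knobs
are not part of the model, only of its numerics.

Open choices resolved here: initialization is a symmetric Dirichlet
draw over memberships under the supplied seed (no k-means warm start,
keeping the routine self-contained and exactly reproducible); a profile
coinciding with a center receives membership 1 there; cluster labels
are canonicalized by the stage at which each center peaks, so cluster 1
is always the earliest-peaking shape and runs are comparable across
seeds.  Clustering operates on the 8 stage medians rather than the 24
samples, consistent with the network stage; a caller who prefers
sample-level clustering can pass that matrix instead.

**Cores.** The core of a cluster is the set of genes with membership ≥
0.90 — the high-confidence exemplars of the shape.  Above 0.5 a gene
can belong to at most one core.

# Promoter motif analysis

**PWMs.** Matrices are width × 4 base frequencies (A, C, G, T), rows
renormalized to 1 on load.  The text dialect is `>ID description`
followed by one row per position, blank lines between records.
Per-position information content is 2 − H bits (H the Shannon entropy,
0·log 0 ≡ 0).

**Relative-score scanning.** Each window on each strand is scored
S = Σ log(f′(base)/0.25) with f′ = (f + 0.01)/1.04 — a 0.01 pseudocount
against log(0) and a uniform background.  The relative score
(S − S_min)/(S_max − S_min) maps the worst attainable window to 0 and
the consensus to 1; a hit requires relative score ≥ 0.80.  This
min-max-normalized log-odds reconstructs the common "80% similarity"
semantics of PWM scanners; the pseudocount and background are declared
and configurable because different scanners differ in exactly these
internals.  Minus-strand windows are scored on the reverse complement
and reported in plus-strand coordinates (strand −1); windows containing
N are skipped rather than scored with a wildcard.

**Markov background and FDR calling.** A k-th order Markov model
(default k = 4) is trained on the input promoters with add-one
smoothing and lower-order fallbacks for sequence starts.  For each
promoter, 10 length-matched background sequences are sampled; candidate
raw-score thresholds are swept down the observed real-sequence window
scores, the FDR at threshold t is estimated as
(background hits at t / n_bg) / (real hits at t), and the largest hit
set with estimated FDR ≤ 0.15 is returned (empty when no threshold is
admissible).  This is a transparent threshold-sweep realisation of the
"matched Markov backgrounds + FDR bound" contract; it does not attempt
to reproduce any particular published caller's internal estimation
algorithm.

**Consensus and overrepresentation.** Only sites found by both the
relative-score scan and the FDR caller are retained; matching requires
identical (sequence, PWM, strand, start), which is well-defined because
both scanners use the same matrix width.  Per-PWM consensus counts over
a gene set are flagged as overrepresented when count > mean + SD of the
counts across *all* scanned PWMs, zero counts included (restricting to
PWMs with ≥ 1 hit would inflate both moments; a flag switches this).
The SD is the sample standard deviation (n − 1).

**AW-box.** The WRI1-binding pattern [CnTnG](n)7[CG] is matched
literally: a 13 bp window with C, T, G fixed at positions 1, 3, 5 and
C or G at position 13, on both strands.

**Promoter extraction.** 1000 bp upstream of the transcription start
plus the first 200 bp of transcribed leader; when the intergenic gap to
the upstream neighbor is shorter than 1000 bp, only the available
upstream sequence is used (available = tss − boundary − 1 on the plus
strand, mirrored on the minus strand), and sequences are clipped at
chromosome ends.  Minus-strand promoters are reverse-complemented so
every output reads 5′→3′.

# The synthetic-data generator

The generator exists so that every stage has a ground truth to recover.

**Expression.** Genes are assigned to archetypal stage profiles; the
value of gene i in stage s, replicate r is
baseline_i + template(s) + N(0, noise_sd).  The default archetypes are
the shapes that dominate maturing-seed transcriptomes: a
rise–peak–decline profile peaking at stage 5 of 8 (fatty-acid-synthesis
style), a ≥10 log2-unit step between stages 1 and 2 followed by a
plateau (oleosin/storage-protein style, a >1000-fold induction), a late
rise (LEA style), a flat profile, and mirror images of the first three.
Baselines are uniform on 6–12 log2 units so the presence filter at 6.0
actually removes something.  Noise is additive Gaussian on the log2
scale — the simplest model consistent with displayed log-scale
profiles; the default noise_sd = 0.25 is our choice (replicate-level
variance is rarely reported) and is exposed in the config.

The default fixture (2,000 genes, 8 stages × 3 replicates) uses the six
non-flat archetypes in equal proportions, matching the c = 6 default: a
flat profile has no shape after standardization, so it cannot be
recovered by shape clustering and is not planted (it remains available
in `default_archetypes()` for filter and degenerate-input tests).

**Promoters.** Backgrounds are sampled from the same Markov machinery
as the motif module, with all conditional distributions equal to the
target composition (default 33% G+C — plant promoters are A/T-rich,
below 35%).  Planted motifs are instances drawn from the PWM's
per-position distributions, inserted at uniform positions (overwriting
the background so coordinates stay simple, never overlapping each
other), reverse-complemented on the minus strand, and recorded in the
truth table.  The fixture plants the highest-information matrix of its
synthetic PWM collection in 60% of the 300 promoters — the recovery
benchmark is defined for sharp, information-rich motifs; a diffuse
matrix would measure the scanner's inherent ambiguity rather than the
pipeline's correctness.

**What the generator does not emulate.** Probe-level array artifacts
and normalization residue; correlated replicate noise (replicates are
i.i.d.); realistic promoter k-mer structure beyond the stationary
composition (no TATA elements, no CpG-like islands, no repeats); and
the long tail of partially-correlated expression programs that makes
real degree distributions broad.  Consequently, passing recovery tests
show that the algorithms are implemented correctly and are sensitive
under clean conditions — they do not show that the default thresholds
are optimal for any real dataset.

# Numerical choices and degenerate inputs

* Permutation p-values are never 0 by construction.
* Correlations of zero-variance profiles are undefined; such genes are
  excluded with a warning rather than propagating NaN.
* In FCM, a zero distance (or an overflowed membership row when m is
  very close to 1) yields a crisp assignment to the nearest center.
* The power-law fit refuses degree sequences with fewer than 5 distinct
  values; `topology_stats` then reports NA diagnostics with a warning
  instead of failing the whole run.
* A degenerate PWM whose min and max attainable scores coincide gives
  every window relative score 1 (vacuous but defined).
* All generators and stochastic routines take explicit seeds; the
  pipeline derives stage seeds from one master seed, and reruns are
  bit-identical (timings aside).

# Problem sizes

The bundled fixture and test suite are sized to exercise every code
path while staying quick: 2,000 genes × 24 samples for the recovery
runs, 300 promoters × 1,200 bp with a 20-matrix PWM collection for the
motif benchmark, 50,000 draws for the power-law recovery, 200 null
simulations × 99 permutations for test calibration, and ≤ 100-node
graphs / ≤ 10 kb sequences for the brute-force oracle comparisons.
These sizes are choices, not limits: the blockwise correlation stage
and the per-PWM scanners scale linearly in genes × genes and
sequence × matrix respectively, and have been exercised at
transcriptome scale.

# Known limitations

* The stage-association statistic is a pragmatic substitute for
  likelihood-based global tests; it shares their null (no stage
  effect) but not their power profile.
* The FDR caller estimates, not controls, the false discovery rate;
  the estimate is honest only insofar as the Markov background captures
  the null sequence composition.
* The enrichment rule (mean + SD) is a screening heuristic, not a
  calibrated test; it is kept because consensus filtering leaves too
  few hits for well-powered count models.
* Consensus matching requires exact coordinates; an `--overlap` style
  relaxation is not implemented because both in-package scanners share
  widths.  Hits from external scanners with different conventions need
  coordinate normalisation first.
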