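---
title: "Strain-level profiling with a hierarchical k-mer index: methods and design"
author: "strainsift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-level profiling with a hierarchical k-mer index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Different strains of one bacterial species can coexist in a microbiome
sample while differing by only a handful of variants, and those few
variants can matter: near-identical *E. coli* strains include both
pathogens and probiotics. Given a collection of reference genomes of one
species and a short-read sample, strainsift answers two questions: *which*
reference strains are present, and *at what relative abundance*. The
difficulty is the heterogeneous similarity structure of strain
collections — some pairs share almost all of their sequence, others less
than half — combined with the need to keep false positives out at low
sequencing depth, where random k-mer matches from sequencing errors look
like weak signal.

strainsift handles this with a two-level design. Strains are first grouped
into clusters of high mutual similarity, and a fast, conservative tree
search identifies which cluster(s) a sample supports. Only inside the
identified clusters is the expensive fine-grained question asked — which
individual strains explain the observed k-mer counts — where the search
space is small and *all* discriminative k-mers can be used, including ones
shared between clusters that the tree stage had to discard.

## Reference indexing

**K-mer representation.** Every genome is reduced to its set of canonical
k-mers (k = 31 by default; the canonical form is the lexicographically
smaller of a window and its reverse complement, so both strands map to one
key). Windows containing non-ACGT characters are skipped. Similarity
between genomes is the exact Jaccard index of their k-mer sets — no
sketching is used, which at the scale this package targets is both simpler
and exact; the Mash distance transform
$d = -\tfrac{1}{k}\ln\!\big(\tfrac{2j}{1+j}\big)$ is provided for
interpretation on a mutation-rate scale.

**Dereplication.** Reference collections often contain near-duplicate
accessions. Complete-linkage clustering at Jaccard similarity ≥ 0.99
groups them, and from each group the member with the highest average
similarity to the rest is kept (ties to the smallest id). This mirrors
standard practice for removing redundant references before strain
analysis.

**Clustering.** The representatives are clustered by single-linkage
agglomeration on distance 1 − Jaccard, and the dendrogram is cut at a
fixed similarity H = 0.95 (roughly 99.9% average nucleotide identity).
Single linkage makes the clusters exactly the connected components of the
"similarity ≥ H" graph, which is both easy to reason about and easy to
verify independently — the test suite checks the equivalence on random
matrices. Agglomeration ties are broken by the lexicographically smallest
member ids so that the dendrogram, and everything built from it, is
deterministic; under single linkage the tie-break cannot change cluster
membership at any cut.

**The cluster search tree (CST).** The dendrogram above the cut, with each
cluster contracted to a leaf, becomes a full binary tree. Each node *v*
must hold k-mers that are (i) shared by most strains below it and
(ii) found in no strain outside its subtree. Leaves start from their
cluster's k-mers filtered to those present in at least α% of the member
strains (α = 90; the boundary is inclusive, and single-strain clusters
keep everything). Shared k-mers of two siblings are then promoted
recursively to their parent, and any k-mer that still occurs in more than
one node afterwards is deleted everywhere. This promotion-and-deduplicate
procedure is equivalent to evaluating, per node, the intersection of the
leaf sets below it minus the union of all leaf sets outside its subtree;
the test suite verifies that equivalence against a direct set-formula
oracle on 100 random trees.

Two refinements follow. First, because the subtraction above only sees the
α-filtered leaf sets, a node could retain k-mers that exist in a
below-prevalence strain of a foreign cluster; a pruning pass removes every
node k-mer found in any strain outside the node's subtree, restoring
property (ii) at strain resolution. Second, nodes left with fewer than
1000 k-mers are *augmented*: they receive additional k-mers that occur in
at least one strain below them, in no strain outside, and in no other
node, preferring k-mers present in the largest fraction of the subtree's
strains. Sparse nodes are the dominant source of chance matches — a node
with a handful of k-mers is easily "hit" by sequencing errors — and the
1000 floor follows the observation that nodes below roughly that size in
comparable tree indexes cause false positives. Deeper nodes are augmented
first so a leaf can claim its own cluster's private k-mers before an
ancestor (for which they are also eligible) takes them. Nodes with no
eligible k-mers stay weak and are reported.

**Per-cluster strain matrices.** For every cluster, all k-mers of all
member strains are hashed to their presence pattern across the members,
and the rows with non-constant patterns form a binary matrix X (M k-mers ×
N strains). Rows are annotated as *strain-specific* (one strain),
*group-specific* (a proper subset, typically from shared structural
variants) or *joint* (a Hamming-distance-1 partner k-mer with the exactly
complementary pattern exists in the matrix — the signature of a SNV whose
two alleles split the cluster). The annotation is diagnostic; all rows are
used for identification. This hash-based construction computes the matrix
directly from k-mer sets, without a collinear-block decomposition of the
genomes: the presence pattern of a k-mer is the same quantity however it
is derived, and the set formulation keeps the build dependency-free and
exactly testable by window enumeration. Single-strain clusters get a
degenerate all-ones matrix over an evenly spaced sample of at most 5000 of
the strain's k-mers, used only for depth estimation.

## Searching a sample

All node k-mers and matrix k-mers are counted in the reads in one pass
(canonically, so read orientation is irrelevant), and each node receives
its count vector $C_v$. Two scores summarise a node: the matched fraction
$frac_v = |C^+_v| / |C_v|$ (share of node k-mers seen at all) and the mean
positive count $abund_v$, which is forced to 0 when $frac_v < 0.1$ — a
node of which less than a tenth is covered carries error matches, not
signal.

**Traversal.** The search is breadth-first from the root. For a node *v*
with parent *p*, both abundances are rounded half-up to integers and an
exact binomial test asks whether the drop from parent to child is
explainable by sequencing errors alone: with error rate e (1% by default),
the p-value is $P(X \le abund_p' - abund_v')$ for
$X \sim \mathrm{Bin}(abund_p',\, 1-e)$. A child whose abundance tracks its
parent's gives a difference near 0 and a tiny p-value — the null "this
match level is error" is rejected and the search continues below it; an
unsupported child gives a difference near $abund_p'$ and a p-value near 1,
and its subtree is never visited. The significance level is β = 0.05; a
negative difference always traverses. Both siblings may pass, which is how
multi-cluster samples are found. The root's children are always examined
when the root shows any signal; the same test applied at a leaf decides
whether the leaf becomes a candidate — applying it there too (the
description of the procedure leaves leaves implicit) prunes the false
sibling leaf early and lets the surviving candidate keep its full
root-to-leaf evidence path.

**Cluster acceptance.** For each candidate leaf the *evidence path* is the
path from the root of the maximal subtree containing that leaf and no
other candidate. Pooling the nodes on the path gives the weighted matched
fraction $F_v = \sum |C^+_i| / \sum |C_i|$ and the weighted mean count
$A_v = \sum |C^+_i| \cdot abund_i / \sum |C^+_i|$; a hit is reported when
$F_v > 0.4$. When several clusters are accepted, a path node's k-mers can
also occur in strains of another accepted cluster and its counts then
overstate the candidate's abundance; statistics are therefore computed in
two passes, the second subtracting the other accepted clusters'
first-pass $A$ estimates from the counts of shared k-mers (floored at 0;
an alternative mode excludes the shared k-mers instead). The two-pass
scheme makes the correction independent of processing order.

**Within-cluster resolution.** For each accepted cluster the observed
occurrence vector y over the matrix k-mers is assembled; entries for
k-mers that occur in any strain of another accepted cluster are zeroed,
and entries outside the 5th–95th percentile of the positive values are
zeroed once as outliers (repeat regions and contaminant matches sit in the
tails). Strains are then detected greedily: each strain is scored by
$f_j = X[,j] \cdot y$, the top strain is selected (ties to the smallest
id), and y is zeroed at all its k-mers, so already-explained evidence
cannot support a second strain. The first selection is attempted whenever
any strain scores positive; afterwards the loop continues only while at
least 1240 k-mers (31 × 40) retain nonzero counts, scaled down
proportionally to M/10 for matrices with fewer than 12400 rows so that
desk-scale matrices terminate sensibly.

**Depth estimation.** The selected strains' columns X′ and y enter a
non-negative elastic net: minimise
$\lVert y - X'\beta \rVert_2^2 + \lambda(\alpha_{en}\lVert\beta\rVert_1 +
\tfrac{1-\alpha_{en}}{2}\lVert\beta\rVert_2^2)$ subject to β ≥ 0. The
L2 component keeps groups of similar strains from collapsing onto one
representative (a pure lasso under-reports strains); the L1 component
still drives spurious selections to exactly zero, and strains with zero
estimated depth are dropped. Mixing and penalty are tuned by 5-fold
cross-validation over α_en ∈ {0.1, …, 1.0} and a 50-value log-spaced λ
path, with folds drawn deterministically from the run seed. No intercept
is fit and columns are not standardised — counts are proportional to depth
by construction and the binary columns share one scale. Rows whose y entry
was zeroed by masking or the outlier trim are excluded from the fit: those
zeros are artifacts of the correction, not observations, and would bias
the depths downward. With a single selected strain the problem is solved
by the closed-form one-variable coordinate update over the same CV grid
(the general solver requires at least two columns). β is in per-k-mer
coverage units; the factor $L/(L-k+1)$ for converting to nominal read
coverage is reported in the diagnostics.

**Relative abundance.** Within a cluster the depths are normalised to
within-cluster abundances $a$; across clusters each strain is weighted by
its cluster's tree abundance: $RA_i = a_i C_i / \sum_j a_j C_j$, with
$C_i$ the $A_v$ of strain i's cluster. The elastic net is fit per cluster,
matching the per-cluster matrices; a joint fit across clusters would mix
k-mer spaces of different sizes for no identifiability gain.

## Evaluation metrics

Predictions are scored by precision, recall and F1 at two levels: strain
level (the exact strain must match) and cluster level (a prediction in the
same cluster as a truth strain counts). Abundance profiles are compared by
the Jensen–Shannon divergence with base-2 logarithms, which bounds it in
[0, 1]; profiles of different composition are aligned by strain identity
(unmatched strains padded with zero mass), with positional zero-padding
available as an option. Metrics with zero denominators are defined as 0.

## The synthetic data generator

The package bundles a seeded generator so the whole pipeline is testable
without downloads. It emulates the structure the method targets: an
ancestral genome (50 kb by default) spawns one ancestor per cluster
(substitution rate 0.02, indel rate 10⁻³, Poisson(2) structural events of
0.5–2 kb), and each cluster ancestor spawns its strains (substitution rate
2.4 × 10⁻⁴, indel rate 2 × 10⁻⁵, one 80–150 bp deletion or tandem
duplication with probability 0.25). Those rates are chosen analytically so
that pairwise within-cluster Jaccard lands centrally inside the window the
pipeline's own thresholds define — at or above the clustering cutoff 0.95
but below the 0.99 dereplication threshold — while between-cluster
similarity stays far below the cutoff; the generator measures both after
generation and regenerates with a derived seed (bounded retries) if either
side is violated. The read simulator follows the common Illumina protocol
for paired 250 bp reads: normal fragment lengths 600 ± 150 truncated to
[read length, genome length], uniform strand, and uniform substitution
errors at 1% — a scalar error rate by design, since that is exactly the
quantity the binomial traversal test models. Mixtures concatenate and
shuffle per-strain read sets and record the depth- and length-weighted
truth profile.

What the generator does *not* emulate: real quality-score profiles and
position-dependent error rates, GC and coverage bias, repeat families and
horizontally transferred elements shared across distant strains, and
host/background reads. Passing tests on this generator therefore
demonstrate the correctness of the algorithms under their own model
assumptions — uniform coverage and a scalar error rate — not performance
on real metagenomes, where reference completeness and coverage bias
dominate.

## Problem sizes and numerical choices

The bundled test and verification runs use a 20-strain, 6-cluster species
of 50 kb genomes — a deliberate desk-scale stand-in for Mb-scale bacterial
genomes chosen so a full build-search-evaluate cycle completes in seconds;
every k-mer statistic in the pipeline (node sizes, matrix dimensions,
count distributions) scales linearly with genome length, and all
thresholds with a length dimension (the 1000 k-mer augmentation floor, the
1240 stop quantity) are either scale-free or scaled proportionally as
described above. Verification covers 60 single-strain samples at 10X
(cluster accuracy), 40 samples at 10X/5X/3X/1X (false-positive control),
and 30 within-cluster mixtures of 2/3/5 strains at the depth profiles
100/10, 100/50/10 and 100/70/50/20/10 (abundance accuracy by median JSD).

Remaining numerical conventions, chosen once and documented here:
abundance rounding in the binomial test is half-up (ties at .5 round away
from zero); percentile outliers are computed once per cluster over the
positive entries only, before iteration; selection and output ties break
by the smallest strain/cluster id; the Jaccard of two empty sets is an
error, not a value; the Mash transform caps at 1 for disjoint sets. Every
stage is deterministic given the run seed — the index serialises to
byte-identical files across rebuilds, and reruns of a search produce
identical profiles.

## Known limitations

The index is single-species by design; multi-species screening belongs to
an upstream profiler. Strains absent from the reference set can only be
reported as their nearest indexed relative — the method identifies *known*
strains. Depth below about 1X leaves too few covered k-mers for the
binomial test to separate signal from error, so recall decays there
(false positives stay controlled: the conservative direction of every
threshold is rejection). Quality scores are ignored; the error model is a
single scalar rate. Finally, the augmentation step can leave a node weak
when its subtree shares every k-mer with outside strains — typical for
extremely similar clusters — in which case the affected distinction is
deferred entirely to the within-cluster stage, which is exactly the
regime that stage is built for.
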