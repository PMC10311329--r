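---
title: "Self-supervised contrastive binning: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised contrastive binning: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Metagenomic assembly yields contigs from many organisms mixed together.
Binning groups contigs by genome of origin so that metagenome-assembled
genomes (MAGs) can be recovered without cultivation. `contrabin` does this
with a self-supervised contrastive embedding: no reference database, no
taxonomic annotation — the training signal comes entirely from the contigs
themselves.

## Features

Each contig is represented by:

* **Composition** — canonical tetranucleotide frequencies. All 256 DNA
  4-mers collapse under reverse complementation into 136 classes (16
  palindromes plus 120 complementary pairs); windows containing an N are
  skipped entirely rather than imputed. Pooling with the reverse complement
  makes the signature strand-agnostic, the standard convention for
  composition-based binning. Frequencies are normalized to sum to 1 per
  contig and are not further standardized before the network; the batch
  normalization in the first layer adapts to their scale.
* **Abundance** — the average mapped read depth per base in each sample,
  preprocessed by a piecewise transform that depends on the number of
  samples \(N\):
  \[
  f(a) = \begin{cases}
  \log a & N < 5 \text{ and long-read data} \\
  \frac{a}{100}\left\lceil \frac{a_\text{mean}}{100} \right\rceil & 5 \le N \le 20 \\
  a \big/ \sum_i a_i & N > 20
  \end{cases}
  \]
  Three reading notes on this rule as implemented here. First, a pseudocount
  of \(10^{-5}\) is added inside the log so that depth-0 contigs are
  representable; the base is natural (any fixed base only rescales one
  feature dimension). Second, \(a_\text{mean}\) and \(\sum_i a_i\) are
  computed *within the sample being transformed*, over the contigs of the
  task: the per-sample reading keeps samples commensurate, and the choice is
  isolated behind `transform_abundance()` so it can be revisited in one
  place. Third, the rule leaves the case \(N < 5\) with short-read data
  undefined; the package passes raw depths through unchanged there and says
  so in a message, as the least surprising completion.

Fragments produced by the must-link break-up (below) inherit their parent's
raw depth rather than being re-piled-up: depth is uniform in expectation
along a contig, and the approximation avoids a second pass over the BAM.

## Self-supervised constraints

Two kinds of pairwise constraints are generated from the assembly itself:

* **Must-links** simulate the break-up of long contigs: every contig of at
  least `break_min_length` (default 4 kb, at least twice the 1 kb input
  length filter) is split at its midpoint, and its two halves form one
  must-link pair. Two halves is the minimal scheme that yields exactly one
  unambiguous pair per contig.
* **Cannot-links** are uniformly random contig pairs. In a community of
  \(G\) comparably sized genomes a random pair is intra-genome with
  probability about \(1/G\), so the labels are noisy at a low, measurable
  rate; the test suite verifies the rate on a ground-truth community.
  Sibling fragments are excluded (they are known must-links), and the
  number of cannot-links is capped at \(\min(m, 4{\times}10^6)\), where
  \(m\) is the must-link count, to bound training time and fix the label
  ratio.

In multi-sample mode cannot-links are sampled within each sample's contig
set by default (contigs of different samples are never co-binned, so
cross-sample pairs carry no usable signal); a `cannot_link_scope = "global"`
switch restores pooled sampling.

## The embedding network

A siamese multilayer perceptron maps the 136 + \(N\) features to
\(\mathbb{R}^{100}\). Each of the two hidden blocks is affine → batch
normalization → leaky ReLU (slope 0.01) → dropout (rate 0.2); the output
head is affine. Both arms share all parameters, and pair batches are stacked
into a single forward pass so batch-normalization statistics are pooled
across arms (and across samples in multi-sample mode — one model per task).
The contrastive loss over must-links \(M\) and cannot-links \(C\) is

\[
L = \frac{1}{|M \cup C|} \sum_{(x_1,x_2)}
  y\, d\!\left(H(x_1), H(x_2)\right)^2 +
  (1-y)\, \max\{1 - d\!\left(H(x_1), H(x_2)\right), 0\}^2
\]

with \(d\) the Euclidean distance, \(y = 1\) for must-links, and margin 1
(configurable). There is no reconstruction term. The loss is minimized with
Adam; must- and cannot-link pairs are dealt into each mini-batch in their
global proportion so gradients stay balanced.

The forward and backward passes are implemented directly in matrix algebra
and verified against central finite differences in the test suite (loss
gradient to a relative error below \(10^{-4}\); the full backward pass
through batch normalization and the rectifier on a tiny network to
\(10^{-3}\)).

**Hyperparameters.** Hidden widths default to 512, epochs to 30, batch size
to 256 pairs, learning rate \(10^{-3}\). With a ~141-dimensional input and a
100-dimensional embedding, 512 units give ample capacity, and the batch
size / epoch pairing keeps the Adam step count meaningful on tasks whose
constraint sets number in the thousands of pairs, which is where
contig-level binning tasks of a few Mbp land. All four are exposed in
`training_config()` / `binning_config()`; wider nets and larger batches are
drop-in for larger communities.

Training, dropout and shuffling draw from an RNG seeded once per run, so a
`(config, seed)` pair reproduces the run bit-for-bit; the embedding of the
*original* (unbroken) contigs, computed in inference mode with running
normalization statistics, is what all clustering operates on.

## Short-read clustering

Short-read assemblies have many contigs per genome, so a graph/community
approach fits:

1. Euclidean distances on the concatenation [embedding, transformed
   abundance] (plain concatenation, no re-weighting).
2. Per node, keep the `max_edges` (default 200) nearest neighbours; the
   union of directed selections becomes an undirected graph with edge
   weight \(1 - d/d_\max\), where \(d_\max\) is the largest retained
   distance globally, clipped into \((0, 1]\). The normalization is isolated
   behind `build_graph()`.
3. Infomap community detection yields preliminary bins.
4. Any bin whose mean single-copy marker multiplicity \(G/N\) exceeds 1 is
   reclustered once (no nested re-splitting, for bounded behaviour) by
   weighted k-means on the embeddings: contig lengths are the observation
   weights, \(k\) is the highest multiplicity of any single marker in the
   bin, and the centers start at the contigs carrying that marker — the
   standard single-copy-gene-seeded scheme.

## Long-read clustering

Long-read assemblies have few, long contigs — sometimes one contig per
genome — which starves graph methods of edges. Instead, DBSCAN runs over a
fixed ladder of 12 neighbourhood radii
\(\varepsilon \in \{0.01, 0.05, 0.1, \ldots, 0.55\}\) on the L2-normalized
embeddings (the fixed ladder only makes sense on a bounded-scale space,
hence the normalization), with `min_samples = 5` — a small core size suited
to assemblies with few contigs. Every cluster of every run is a candidate
bin, and every noise point is a *singleton* candidate so that single-contig
genomes can compete.

Candidates are scored on a panel of 107 single-copy marker genes. With
\(G\) total marker hits and \(N\) distinct markers in a bin:

\[
\text{completeness} = \frac{N}{107},\qquad
\text{contamination} = \frac{G-N}{G},\qquad
F_1 = \frac{2\,\text{comp}\,(1-\text{cont})}{\text{comp} + (1-\text{cont})}
\]

A marker-free bin has contamination and \(F_1\) defined as 0 so it can
never win selection. Integration is greedy over a contamination ladder
\(\{0.1, 0.2, 0.3, 0.4, 0.5, 1\}\): at each level, repeatedly emit the
highest-\(F_1\) candidate whose contamination is below the level, remove its
contigs from every other candidate, and rescore the affected candidates
before the next query. Ties on \(F_1\) break to larger total length, then to
the lexicographically smallest contig id, making the procedure
deterministic. Note that because rescoring can *raise* a surviving
candidate's \(F_1\) (removing a contig can strip duplicated markers), the
emitted \(F_1\) sequence within one level is only guaranteed monotone when
candidates do not overlap. The whole procedure is checked against an
exhaustive step-by-step simulation on randomized instances.

Bins below `min_bin_size` (default 200 kb) are dropped from the final
output in both modes; `emit_leftover` optionally promotes unselected
contigs above that threshold to singleton bins.

## Marker annotation

The scoring layer treats marker ids as opaque strings read from a TSV
(`contig_id`, `marker_id`; duplicated rows are multiple hits), which keeps
the arithmetic decoupled from any profile database and the package testable
offline. The shipped default panel is a synthetic set of 107 symbolic ids
matching the community simulator. For real data, run a gene caller plus a
profile HMM search against a bacterial single-copy panel externally and
supply the resulting table; multiple hits of one marker on one contig are
counted as given.

## The community simulator

`simulate_community()` generates ground-truth fixtures that exercise every
stage:

* **Composition**: each genome draws a 3rd-order Markov transition matrix
  with Dirichlet(\(1/\text{divergence}\)) rows; divergence 0 reduces every
  genome to the uniform chain (compositionally indistinguishable — the test
  suite checks this degenerate case), and the default 0.1 yields
  between-genome tetramer distances comfortably above within-genome
  sampling noise, comparable to distinct bacterial species.
* **Contig lengths**: short-read-like assemblies use 60 contigs per genome
  with lognormal(8.5, 0.7) lengths in bp (median ≈ 5 kb, genome ≈ 370 kb);
  long-read-like assemblies split a 500 kb genome into 1–10 contigs, with
  the first genome always a single contig. These are deliberately
  desk-scale genomes: large enough to clear the 200 kb output filter and to
  carry stable tetramer statistics, small enough that a full pipeline run
  takes about a minute.
* **Abundance**: genome-by-sample mean depths are lognormal(3, 1); the
  depth of a contig in a sample is Poisson counting jitter around
  abundance × length, divided by length.
* **Markers**: one copy of each of the 107 panel ids per genome, placed on
  a uniformly chosen contig — symbolic planting (a TSV), not
  sequence-embedded genes, since scoring consumes annotations, not
  sequences.

What the simulator does **not** emulate: sequencing error and chimeric
contigs, strain-level mixtures, repeat-driven composition anomalies, GC
bias in coverage, or assembly fragmentation correlated with abundance.
Passing the suite therefore demonstrates the machinery is correct and the
method behaves as designed on communities with clean signals; it does not
by itself establish recovery rates on real assemblies.

Ground-truth evaluation is in base pairs: a bin's completeness is the
fraction of its majority genome's bp it captures, contamination the
fraction of the bin's bp from other genomes, and a genome counts as
recovered at the usual high-quality bar (completeness > 90 %,
contamination < 5 %).

## Numerical and degenerate-input choices

* Batch normalization uses population (biased) batch variance and momentum
  0.1 running updates; inference uses running statistics, so single-row and
  batched forward passes agree.
* The contrastive hinge is non-differentiable at \(d = 0\); the zero
  subgradient is used.
* Sequences shorter than 4 bp or all-N yield the all-zero tetramer profile.
* Empty clusters in weighted k-means are reseeded at the point farthest
  from its center; \(k\) is clamped to the bin size when a marker's
  multiplicity exceeds it.
* All stochastic entry points route through a save/restore RNG helper, so
  a single integer seed determines a run without clobbering the caller's
  RNG state.

## Problem sizes used in the checks

The packaged checks run the full pipeline on a 20-genome, 5-sample
short-read-like community (1200 contigs, ≈ 7 Mbp) and a 5-genome, 2-sample
long-read-like community (≈ 2.5 Mbp), with the ensemble-vs-single-ε
comparison repeated over 10 simulation seeds. These sizes were chosen as
the smallest communities that still exercise every branch of the method
(middle abundance branch at \(N = 5\), log branch at \(N = 2\) long-read,
marker-guided reclustering, noise-singleton rescue of a single-contig
genome).

## Known limitations

* The 107-id default panel is symbolic; real-data use requires an external
  annotation step.
* Infomap comes from igraph; its seeding is reproducible but its internals
  are outside this package's test surface (checked only via behavioural
  oracles on small graphs).
* DBSCAN is implemented with a dense distance matrix — appropriate for
  long-read assemblies (few contigs), quadratic in memory if misapplied to
  very large short-read tasks (where the graph path is the intended mode).
* The abundance-transform scope ambiguity (per-sample vs global
  \(a_\text{mean}\)) is resolved per-sample; both readings are defensible
  and the choice is confined to one function.
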