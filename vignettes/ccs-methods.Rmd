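---
title: "Condition-dependent correlation subgroups: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-dependent correlation subgroups: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccsbiclust)
```

## The model

A bicluster is a gene set $I$ and sample set $J$ such that every gene
pair in $I$ satisfies $|r(g_i, g_j)_J| > \theta$, where $r(\cdot,\cdot)_J$
is the Pearson correlation restricted to the samples in $J$: writing the
restriction as a bit mask $b$ over the $m$ samples, all means, variances
and cross-products are computed over the masked samples only. The masked
coefficient is implemented as the standard Pearson correlation
(covariance over the product of standard deviations) of the explicitly
subset vectors; `masked_pearson()` agrees with a textbook computation on
the subsets to $10^{-12}$ and with the unmasked correlation when the
mask is all ones.

Condition specificity is quantified by the BScore. For a candidate
$(I, J)$, let $N$ be the set of gene pairs from $I$ correlated (absolute
value above $\theta$) over $J$, and $M$ the set correlated over the
complement of $J$. Then

$$\mathrm{BScore}(I, J) = \frac{|N \cap M|}{|N \cup M|},$$

the Jaccard overlap of the within-condition and out-of-condition pair
sets. A bicluster is reported only if its BScore is below 0.01, i.e.
at most one percent of the observed pairwise structure survives outside
the bicluster's samples.

Assumptions worth making explicit: expression values are real and
complete (missing values are rejected at load time rather than imputed —
no imputation policy would be neutral for a correlation-based method);
linear correlation is the right notion of coherence (rank correlation is
out of scope); and a sample belongs to a candidate's condition exactly
when the defining sign pattern holds, as described next.

## Sample selection and the search

For a gene pair, each sample is assigned by the signs of the deviations
from the two genes' all-sample means: both positive (up-regulated
positive correlation, $J_1$), both negative (down-regulated positive,
$J_2$), product negative (negative correlation, $J_3$). All three
inequalities are strict, so a sample lying exactly on either gene's mean
joins no class; ties are measure-zero on continuous data, and the strict
reading matches the product-form of the negative rule. The classes are
pairwise disjoint by construction and their union misses only exact-mean
samples.

The per-base search scans partner genes in variability-sorted order; for
each pattern-class mask with at least `min_samples` samples whose seed
correlation passes $\theta$, the gene set grows greedily over **all**
genes in sorted order: a gene joins iff its masked correlation with every
current member exceeds $\theta$, with the mask frozen throughout growth.
Each grown candidate is scored; the base gene keeps the candidate with
the smallest BScore below 0.01, with ties broken toward the larger gene
set, and residual ties toward the first-encountered candidate in
(partner, class) order. Treating the incumbent's score as $+\infty$
before any candidate is seen makes the selection well defined from the
first candidate on; all three rules together make the search a pure
function of the matrix and parameters, so per-base searches can run in
any order (they are independent) and results are always reassembled in
sorted base order before merging.

Merging is a single pass of the doubly nested loop over the per-base
list: whenever two live biclusters share a gene and the union of their
gene and sample sets scores below 0.01, the union replaces the first and
kills the second, and the updated entry participates in the remaining
comparisons of the same pass. The pass is deliberately *not* iterated to
a fixed point, and the sample sets are unioned, not intersected — both
choices follow the published procedure literally rather than an
idealized transitive closure. Merged biclusters are not re-validated
against the all-pairs property (they generally violate it); only the
BScore bound is guaranteed for the final set, and each survivor's stored
score is recomputed on its final gene and sample sets.

## Parameters

* `theta` (default 0.8, dimensionless, in (0, 1]): minimum absolute
  pairwise correlation. The default reflects the observation that very
  high coexpression (around 0.84 and above) is strongly associated with
  co-regulation; at 0.8 a pair shares ~64% of variance over the selected
  samples.
* `theta_step` (0.05): if no bicluster is found, `theta` decreases by
  this step and the search reruns until a result appears or the
  threshold reaches 0 (`adaptive_theta = TRUE` by default). The set
  actually used is recorded as `theta_used`.
* `bscore_threshold` (0.01): maximum admissible BScore.
* `min_samples` (3): minimum samples for any correlation; a Pearson
  coefficient of fewer than three points is meaningless. Class masks
  below this are silently discarded during search (not errors). Note
  that three-point correlations are themselves extremely permissive — see
  Limitations.
* `base_number` ("auto"): all genes when the matrix has at most 2000
  rows, otherwise the 1000 most variable — the conventional cap used to
  restrict search time on genome-scale data, overridable.

Numerical conventions: standard deviations use the population formula
(divide by $n$) everywhere — variability sorting, variance filtering and
the generator — for consistency; the choice cannot affect any sort order
or the correlation values themselves. Variability sorting is stable
(original order breaks ties). Zero-variance genes over a mask yield
undefined correlations, which are treated as "not correlated" wherever a
pair set is assembled, and such genes can never be seeds or members.
When both $N$ and $M$ are empty the BScore is defined as 0; the search
itself can never produce that case (a seed pair guarantees one pair in
$N$), it only concerns direct API calls. When the complement of $J$ has
fewer than `min_samples` samples, $M$ is empty by the degenerate-pair
rule, which keeps the score well defined for biclusters spanning nearly
all samples — with the side effect discussed under Limitations.

One reading decision deserves note: the published per-base selection
step compares the candidate score written as a function of a sample set
that is never defined notationally; the only sample set in scope at that
point is the candidate's own class mask, and that is what this package
uses.

## The synthetic generator

The generator emulates the two planted-structure benchmark families used
to validate biclustering methods. *Constant* blocks hold a fixed signal
value plus Gaussian noise against a Gaussian background; *shift-scale*
blocks draw a base profile and fill each row with an affine image
(scale × base + shift) of it, so rows correlate at ±1 over the block's
columns in the noise-free limit. Five named presets reproduce the
standard benchmark dimensions (CNST.100.3 at 100 × 75 with 3 blocks, up
to SS.250.7 at 250 × 120 with 7). SS.200.5 is constant-type despite its
name; the preset follows the declared type of the benchmark table it
mirrors. Blocks are pairwise row- and column-disjoint by default, with
sizes jittered ±20% around `n_rows/(k+2)` × `n_cols/(k+1)`.

Unstated distributional details were fixed once: background sd 1,
constant signal value 5, noise sd 0.1, scales in [0.5, 2] with a 20%
sign flip (planting negative-correlation rows), shifts in [−2, 2]. The
intent of these values is a clearly super-threshold planted signal at
θ = 0.8 over a sub-threshold background. Generation is seed-deterministic
(same seed, bit-identical dataset), does not disturb the caller's RNG
stream, and the planted truth is returned as first-class bicluster
objects for scoring.

What the generator does **not** emulate: heavy-tailed and count-valued
expression, sample-level covariates and batch structure, overlapping
modules (overlap is intentionally off by default), and probe-level
artifacts. Passing the synthetic benchmarks therefore demonstrates
correctness of the search machinery under idealized Gaussian conditions,
not performance on real expression data.

## Evaluation

Recovery is the mean over planted biclusters of the best similarity to
any found bicluster; relevance swaps the roles. Similarity defaults to
the Jaccard index of the biclusters' *cell* sets (gene × sample pairs),
which credits agreement in both dimensions; a gene-set-only mode is
provided (`mode = "genes"`) because published match scores in this
literature are frequently computed on gene sets alone and the convention
behind any particular reported number is often unrecoverable. Both
scores are order-invariant; relevance, being a mean over found sets,
changes when exact duplicates are appended but not when they are merged.
An empty found set scores 0 by convention.

## Networks

A bicluster is equivalent to a condition-dependent module: over its own
samples, its genes form a complete correlation graph (guaranteed for
pre-merge biclusters by the all-pairs definition, and verified by
`module_report()` reporting density exactly 1), while over unrelated
samples the same genes are sparsely connected. `build_network()` uses a
*closed* threshold (|r| ≥ θ), the convention of coexpression-figure
edge definitions, whereas the search predicate is strict (> θ); the two
are configured independently and the boundary case is measure-zero.

## Known limitations

The following dynamics are intrinsic to the procedure as published and
are exercised (not hidden) by this package's tests and acceptance
script; they explain why cell-level recovery/relevance on the Gaussian
synthetic benchmarks is far below what one might expect from a method
that demonstrably finds the planted genes:

* **Sign-rule sample dilution.** $J_1$ contains *every* sample where
  both genes sit above their means — for Gaussian background roughly a
  quarter of the background columns — so sample sets of genuine
  biclusters carry substantial background admixture, and (for
  shift-scale blocks) exclude the block columns on the other side of the
  mean. Cell-level match scores are capped well below 1 by this alone.
* **Constant blocks are only detectable through impurity.** A constant
  block has no internal correlation (rows are i.i.d. noise around the
  constant), so a within-block seed passes θ only when the mask includes
  at least one column where both genes' background values exceed their
  means; the resulting two-level mixture then correlates everything in
  the block. The same mechanism occasionally admits a column of a
  *different* block, which pulls one foreign gene into the bicluster.
* **Merge chaining.** The union-based merge accepts any overlapping pair
  whose union still scores below 0.01. Unions grow sample sets, and once
  a union spans nearly all samples its complement drops below
  `min_samples`, making $M$ empty and the BScore identically 0 — so
  further merges are accepted unconditionally. One shared (e.g. foreign)
  gene is then enough to chain distinct planted blocks into a single
  broad bicluster.
* **Spurious negative-class pairs.** Conditioning on opposite-sign
  deviations manufactures correlation: two independent Gaussian genes
  restricted to their $J_3$ set have expected |r| around 0.6, and
  sampling noise pushes a non-negligible fraction of pairs past 0.8.
  Pure noise therefore yields spurious biclusters at the default
  threshold; they are genuinely condition-specific by the BScore
  criterion but biologically vacuous. Three-point masks are even more
  permissive (|r| of three random points exceeds 0.99 with probability
  about 9%), and merge chaining can union such chance findings into
  broad sets; raising `min_samples` suppresses them.

Users analysing real data can mitigate all four effects by inspecting
pre-merge per-base results (`find_bicluster_for_base()`), by raising
`min_samples`, and by filtering low-variability genes first
(`filter_low_variance()`, conventional cutoff 2.0 for microarray
intensities, with duplicate probes collapsed to their most variable row).

## Problem sizes in the test suite

The suite validates the search against literal brute-force replays of
the published loops on one hundred random 12 × 10 matrices (exact
agreement required), runs the full pipeline on the 100 × 75 and
150 × 100 benchmark presets across multiple seeds, and checks
determinism byte-for-byte. These sizes keep the whole suite comfortably
fast while covering every code path; the algorithm itself scales as
O(n³) in the gene count in the worst case, which is why `base_number`
caps the number of seeds on genome-scale inputs.
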