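---
title: "Trie-based motif discovery: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trie-based motif discovery: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motiftrie)
```

This vignette is the package's account of the science behind its two
phases — counting and optimization — and of the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model

A motif of width $k$ is a position weight matrix
$\alpha \in \mathbb{R}^{k \times 4}$, each row a distribution over
$\{A, C, G, T\}$ (the *positive model*). Everything that is not motif is
described by an order-$r$ Markov chain $\beta$ (the *negative model*).
A sequence of width $t$ holds $m = t - k + 1$ candidate offsets; the
occurrence model says how many offsets per sequence carry a motif
instance:

* **OOPS** — exactly one instance per sequence, uniform positional
  prior over valid offsets;
* **ZOOPS** — zero or one instance, with prior probability $\gamma$ of
  presence (the default, because a fraction of ChIP-seq peaks are
  artifactual or indirectly bound and carry no site);
* **ANR** — every window independently carries an instance with
  probability $\gamma$ (a per-window Bernoulli formulation; the model is
  named but not given equations in the motif-discovery literature's
  usual shorthand, and this is the conventional reading).

## Counting phase

### The sparse trie

All $k$-windows are inserted into a trie stored as a growable integer
table with six columns per node: child pointers for the four bases, the
terminal count, and a numeric code. Key properties, each enforced by a
test:

* the sum of terminal counts equals the number of inserted windows;
* re-inserting an existing k-mer increments its count and appends its
  address without creating nodes;
* decoding a terminal's 2-bit code reproduces the root-to-terminal
  spelling (the code is exact for $k \le 26$, where $2k$ bits fit a
  double's 53-bit mantissa; beyond that the column holds `NA` and all
  logic spells k-mers by traversal instead).

The table over-allocates geometrically, so node creation is amortized
constant-time. Child-cell occupancy — occupied child cells over
$4\nu$ — has an analytic average level of $\frac{2\nu}{4\nu} = 0.5$
under the balanced argument (between 0 and 4 children, 2 on average); in
practice trees over i.i.d. uniform DNA sit well below it because deep
nodes have close to one child (the acceptance script recomputes this
value, about 0.25 at $k = 12$ on 100 × 200 bp).

Addresses are stored as (sequence index, offset) pairs on the terminal
nodes. Offsets are 0-based and windows half-open; sequence indices are
1-based, the R convention. Counting is forward-strand only; reverse
complements are a scanning concern, not a counting one.

### Bounded-mismatch search

`kdive` walks the trie depth-first, accumulating mismatches against the
query and pruning a branch the moment the budget $d$ is exceeded;
reaching depth $k$ yields a match. Recursion depth is bounded by
$k \le 35$, so the call stack is safe. Its cost model: if each symbol
comparison mismatches independently with probability $p$, the number of
comparisons to the $d$-th mismatch is negative-binomial with mean $d/p$
— the package's `simulate_kdive_cost` verifies the closed form by
simulation. The premise $p = 3/4$ describes uniform random queries and
is an analysis device, not an algorithmic parameter.

### Enrichment and seeds

The expected count of k-mer $w$ is $m_{\text{total}} \cdot P(w \mid
\beta)$; significance is a one-sided binomial tail with
Benjamini–Hochberg correction across all stored k-mers. The literature
this design follows says only "hypothesis tests"; the binomial-vs-
background test is the minimal standard choice and is isolated behind
the operation boundary. Because motif instances are degenerate, counts
of near-neighbors are aggregated: the most significant k-mer absorbs
the counts of its Hamming-$d$ neighborhood (collected by `kdive`), the
neighborhood is removed, and the process repeats — a greedy rule chosen
here because no grouping procedure is standard; neighborhoods of
returned seeds are disjoint by construction.

## Background estimation and shuffling

When no control FASTA is supplied the control set is generated by
shuffling the peaks; a supplied control always takes precedence. Two
generators are exposed because the field uses both and neither is
canonical:

* **Markov shuffle** (default, order 2 — the common ChIP-seq
  convention): sample sequences of identical widths from the chain
  fitted to the peaks. The sampling fit is unsmoothed so only observed
  transitions are emitted; the downstream scoring fit is smoothed
  (pseudocount 0.01 per cell), so shuffled output always has finite
  likelihood.
* **Eulerian shuffle**: an exact $k$-let-count-preserving permutation
  (Altschul–Erickson: a random last-edge arborescence into the final
  $(k{-}1)$-mer, then a random Eulerian walk), preserving the terminal
  $(k{-}1)$-mers.

Transition tables are kept for every context length $0..r$ so the first
$r$ positions of a sequence are scored and sampled with the longest
context available, keeping whole-sequence scores well defined without
ad-hoc boundary conventions.

**N policy.** Ambiguous characters become `N` at normalization and any
k-window containing `N` is skipped in counting, scoring and EM;
low-complexity masking itself is upstream of this package. `N`
positions contribute zero to whole-sequence background totals, which is
consistent because every window that covers them is excluded from both
sides of the marginal decomposition.

## Optimization phase: fast EM

The E-step needs $P(s_i \mid p_u)$ at every offset. Computing each as a
fresh product costs $O(tm)$ per sequence; instead the whole-sequence
background log score is computed once and

$$\log P(s_i \mid p_u) = \text{total}_i - \text{winbg}_i[u] +
\sum_{j=1}^{k} \log \alpha_{j,\, s_{i,u+j-1}},$$

with the window background sums obtained by a sliding cumulative sum.
This is a pure refactoring of the likelihood — a property test asserts
equality with the naive three-product formula to $10^{-9}$ — and it is
what makes the E-step linear in sequence length. The window product
spans exactly $k$ symbols.

Everything runs in log space; sequences up to $10^4$ bases do not
underflow because only differences of log scores are exponentiated,
after a per-sequence max shift.

### Updates, convergence, numerical choices

* M-step: PWM rows are pseudocount-smoothed, posterior-weighted base
  frequencies over all windows; $\gamma$ becomes the mean per-sequence
  presence mass (ZOOPS) or mean window posterior (ANR). The PWM
  pseudocount (default 0.01 per cell) keeps every entry positive so log
  scores stay finite.
* The convergence "score" is the observed-data log-likelihood,
  evaluated before each update; iteration stops when its increment
  drops below `tol` (default 0.001) or after `max_iter` (default 1000)
  updates. With `tol = Inf` exactly one update is performed. The trace
  is nondecreasing for OOPS/ZOOPS (EM monotonicity; tested over random
  starts).
* Seed PWMs put weight 0.7 on the seed base and 0.1 elsewhere: the
  weight must exceed the background 0.25 while leaving mass for
  mutated instances; 0.7 is that compromise, fixed once.
* $\gamma$ is initialized at 0.5 and re-estimated each M-step (clamped
  to $[10^{-6}, 1-10^{-6}]$).
* Reverse-strand scanning is deliberately absent from the core EM: the
  counting phase is forward-strand, and symmetric treatment of both
  strands belongs to a scanning layer, not the occurrence model.

### Pipeline

`run_pipeline` chains: read and normalize → control (file or shuffle) →
background fit → trie → enrichment (falling back to the most frequent
k-mer, with a warning, if nothing passes `alpha`) → greedy seed grouping
→ EM per seed (10 seeds by default; enrichment ranking is reliable
enough that a short refined list suffices) → reports ranked by final
log-likelihood. For more than one motif, windows claimed by a reported
motif (posterior > 0.5) are masked to `N` before recounting — the
conventional extension, flagged experimental, since single-motif runs
are the primary design point. All stochastic steps draw from one
integer seed, so a fixed configuration is byte-reproducible.

## The synthetic generator: what it does and does not emulate

`generate_planted` builds peak-like datasets: background from a uniform
or fitted Markov model, one consensus of width $k$, instances implanted
at uniform non-overlapping offsets under OOPS/ZOOPS/ANR, each instance
mutated at exactly $j$ positions with $j \sim \text{Uniform}\{0..d\}$.
Exact-$j$ mutation (rather than a per-position error rate) makes the
Hamming bound a hard invariant, and gives closed-form true column
distributions: a column keeps its consensus base with probability
$1 - \bar{j}/k$, $\bar{j} = d/2$, and spreads the rest evenly. The
standard recovery setting used in the tests (500 sequences of width
100, $k = 10$, $d = 1$, $\gamma = 0.9$) is large enough for stable
column estimates while keeping the suite fast.

What it does not emulate: real peak-width and summit-offset
distributions, composite or co-occurring motifs, chromatin artifacts,
repeat content, GC heterogeneity between peaks. Passing recovery tests
therefore demonstrates correctness of the counting/EM machinery under
its own model assumptions, not field performance on real ChIP-seq
datasets.

## Comparison metrics

Six per-column quantities, averaged unweighted across aligned columns:
Euclidean and Manhattan distances, Hellinger distance
$\sqrt{1 - \text{bha}}$, Pearson correlation (defined as 1 for equal
constant columns and 0 for unequal constant ones — a zero-variance
convention), Bhattacharyya coefficient $\sum_i \sqrt{a_i b_i}$, and
Sandelin–Wasserman similarity $2 - \sum_i (a_i - b_i)^2$. Two
identities tie them together and are asserted on random columns:
$\text{hell}^2 + \text{bha} = 1$ and $\text{sw} = 2 - \text{euc}^2$.
Per-column averaging (rather than whole-matrix norms) is used because
it keeps every metric on a fixed scale regardless of motif width.
Motifs of unequal width are compared after `align_to_reference`, which
scans all offsets with at least 4 overlapping columns on both strands
and keeps the best mean Bhattacharyya — a documented choice, since no
alignment convention is canonical for this comparison.

## Known limitations

* Single-motif models only; no Dirichlet priors over columns, no joint
  multi-motif likelihood (masking is a pragmatic substitute).
* `k` must be given; the package does not estimate it.
* Counting is forward-strand; palindromic or strand-ambiguous motifs
  are discovered in whichever orientation dominates the counts.
* The binomial enrichment test treats window occurrences as
  independent, ignoring self-overlap of periodic k-mers; for strongly
  periodic seeds the expected-count model is slightly misspecified.
* Background orders above 8 are rejected (context tables grow as
  $4^r$).
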