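---
title: "Methods: cached-entropy G-tests and IPC-MB blanket discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cached-entropy G-tests and IPC-MB blanket discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmig)
```

## The problem and the model

A discrete Bayesian network is a DAG over categorical features together with
one conditional distribution per node given its parents. The Markov blanket
of a node — parents, children, and spouses (co-parents of its children) — is
the smallest conditioning set that shields the node from the rest of the
network. Discovering blankets from data is useful twice over: as local causal
structure learning and as principled feature selection.

`dcmig` implements IPC-MB, a constraint-based discovery algorithm that
interacts with the data exclusively through a black-box conditional
independence (CI) test answering "is X independent of Y given **Z**?" for
feature indices. The test is the G-test (log-likelihood-ratio test) on
multinomial counts; the package's core contribution is computing it from
cached joint-entropy terms so that the heavy per-test counting work is shared
across the thousands of tests a discovery run performs.

### Assumptions

The usual constraint-based assumptions apply, and a green oracle suite does
not remove them:

* **Faithfulness.** Every independence in the distribution reflects
  d-separation in the graph. Parameterizations that hide edges marginally
  (an XOR-like collider whose parents are marginally independent of the
  child) defeat any algorithm that prunes candidates with marginal tests
  first, IPC-MB included. The test fixtures use noisy-OR-style colliders for
  exactly this reason.
* **Sufficient data.** Verdicts are asymptotic chi-squared decisions; each
  conditioning stratum needs enough samples for the test to have power.
* **Causal sufficiency, discrete data, no missing values.**

## The G-test and its degrees of freedom

For the joint contingency table of `{X, Y} ∪ Z` with N samples, the
statistic is computed over non-zero cells as

\[
G = 2 \sum_{x,y,z} n_{xyz}\,
    \ln \frac{n_{xyz}\, n_{z}}{n_{xz}\, n_{yz}},
\]

the joint-count form of \(2N \sum P(x,y,z) \ln
\frac{P(x,y\mid z)}{P(x\mid z) P(y\mid z)}\). Natural logarithms are used
throughout, so every entropy in the package is in nats and no base conversion
ever occurs.

**Degrees of freedom.** The classical prescription eliminates unobserved
values before counting free parameters. The exact reference rule is not
printed in the sources this package follows, so the package adopts and
documents one reconstruction, used identically by all four backends: for
every observed conditioning configuration \(c\), count the x-values
\(r_x(c)\) and y-values \(r_y(c)\) with positive count in that stratum, and
sum \(\max(r_x(c)-1,0)\cdot\max(r_y(c)-1,0)\). With no conditioning set
there is a single global stratum. A total of zero (a constant feature, or
fully degenerate stratification) is treated as "no information": the test
returns independent with \(p = 1\) instead of consulting a
\(\chi^2(0)\).

**Verdicts.** Independence is accepted iff \(p \ge \alpha\) (ties keep the
null). An optional reliability rule — refuse tests whose potential table has
more than \(N/\text{factor}\) cells — ships disabled
(`min_samples_factor = 0`) so results are driven by the statistic alone.

## The decomposed form and its caches

The identity \(G = 2N\,I(X;Y\mid Z)\) and
\(I(X;Y\mid Z) = H(X,Z)+H(Y,Z)-H(X,Y,Z)-H(Z)\) let the statistic be
assembled from at most four joint-entropy terms. Joint entropy is symmetric
in its arguments, so terms are cached under order-free keys (sorted index
sets) in the Joint Entropy Table. \(H(\varnothing)=0\) by convention, so an
unconditional test is the same code path with three lookups.

On a cache miss the term's joint distribution is counted from the data,
which is also the only moment its zero cells are visible. Because the
degrees-of-freedom rule needs exactly those zeros, the miss path fills a
second cache with the DoF of **every** unordered pair of the set conditioned
on the remaining members. The reference description spells this out for
three-feature sets; the package generalizes it to all pairs-given-rest of
any set size, since the "only opportunity" argument is size-independent.
The result: after warm-up, most tests are four hash lookups and a handful of
additions, with no data access.

Two numerical choices matter here. Cancellation in the four-term sum can
produce tiny negative conditional mutual information; it is clamped to zero
before scaling by \(2N\) (the canonical path applies the same \(-10^{-9}\)
slack). And the cached-engine/canonical agreement contract is \(10^{-9}\)
relative on \(G\), exact on DoF and verdicts — the decomposition is an
identity, so only floating-point reordering separates the two routes.

Both caches serialize to flat JSON so runs on the same dataset can share
them across processes. No eviction is implemented; memory is reported as
entry counts (byte sizes are implementation details).

## AD-trees

The competing counting backend answers conjunctive sample-count queries from
a tree of AD-nodes (counts) and Vary-nodes (features) over a fixed feature
ordering, with two standard memory optimizations:

* **Zero suppression** — nodes for count 0 are never created; absent nodes
  answer 0.
* **MCV elision** — each Vary-node omits the subtree of its most common
  value; queries through it are reconstructed as parent count minus
  non-elided siblings. Ties break toward the smallest value index, a rule
  chosen (arbitrarily, but fixed) to make rebuilds deterministic.
* **Leaf-lists** — a node whose count is *strictly* below
  \(\lceil \text{llt}/100 \cdot N\rceil\) stores row indices instead of a
  subtree and is resolved by scanning them. Strict comparison makes
  `llt = 0` a true "off switch". The threshold is a percentage of N, given
  as 0/5/10 in the comparative experiment.

Static trees are fully expanded before the first query; dynamic trees start
as a bare root and expand exactly what queries touch. Determining a
Vary-node's MCV in dynamic mode requires counting all sibling values at
expansion time; that cost is accepted to keep counts exact. Contingency
tables are assembled by recursive descent with cellwise MCV reconstruction,
and are required (and tested) to be identical to direct counting at every
leaf-list setting.

## IPC-MB

Parent-child recognition conditions on subsets of strictly increasing size
(all size-0 tests, then size 1, 2, ...), removing a candidate the moment a
separating set is found and shrinking the pool immediately. Subsets are
enumerated lexicographically over sorted indices — the order is not inherent
to the algorithm, but a fixed total order is what makes test counts and
decision traces reproducible and backend-independent. Surviving candidates
are kept only if the reverse recognition run also keeps the target
(symmetry correction).

**Spouse conditioning.** For a spouse candidate Y reached through
\(X \in PC(T)\), the package tests \(T \not\perp Y \mid
\text{sepset}(T,Y) \cup \{X\}\): the separating set blocks every path that
made Y removable, and adding the shared child X re-opens precisely the
collider a spouse must form. The simpler alternative of conditioning on
\(PC(T)\) as a whole (`spouse_conditioning = "pc_only"`) is offered for
comparison but is not the default, because conditioning on a child collider
inside \(PC(T)\) can d-connect the target to nodes outside the blanket
(e.g. edges `Y→X→T, Y→W→C←T` leave \(T\) dependent on \(Y\) given
\(\{X, C\}\)), producing false spouses even with a perfect oracle. The
oracle validation suite runs under the default.

Recognition results are memoized within one `find_mb()` call (every
top-level recognition uses the pool "all features minus the target", so the
memo is exact). This is purely an implementation economy: it is
deterministic, identical across backends, and does not change any verdict.

## Synthetic data

`random_network()` draws a random topological order, up to `max_parents`
parents per node among its predecessors, node arities uniform on
`arity_range` (default 2–3, typical of discrete benchmark networks), and CPT
rows from a symmetric Dirichlet with concentration 0.5 — mildly sharp
conditionals, so edges are usually detectable without being deterministic.
`sample_network()` performs ancestral sampling in topological order,
deterministic given its integer seed; experiment harnesses derive per-cell
child seeds with a splitmix-style integer hash so any table cell can be
reproduced in isolation.

What the generator does *not* emulate: latent confounders, selection bias,
missing values, deterministic relationships, and unfaithful
parameterizations (it can produce weak edges, which is why finite-sample
tests use a fixed strong-CPT fixture rather than random draws). A green
test on this synthetic world therefore establishes correctness of the
machinery — exactness of the decomposition, count agreement, oracle
recovery — not robustness of blanket discovery on adversarial real data.

## Degenerate inputs and edge policies

* Empty conditioning sets, single-feature datasets and constant features are
  all legal; they flow through the DoF-zero rule above.
* Arities may exceed the largest observed value (a sidecar can declare
  values absent from a finite sample); inference from data is the default.
* The empty count query returns N; empty feature sets are rejected where a
  table is required.
* Caches are environments mutated in place; sharing them across runs is the
  intended use and is what the hit-rate metric measures.

## Known limitations

* No cache eviction: memory grows with the number of distinct term sets,
  which restricts very wide datasets (the comparative experiment's regime
  never needed eviction).
* The DoF rule is a documented reconstruction, not a verbatim reference
  formula; all backends share it, so cross-backend agreement is unaffected.
* Wall-clock and byte-level memory comparisons are out of scope; the
  harness asserts only on counts, rates and set equality.
* Continuous features, missing data, and assembling blankets into a global
  network are out of scope.
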