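---
title: "The GO-universal metric: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GO-universal metric: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GOuniversal)
```

## The model

The Gene Ontology is a rooted directed acyclic graph whose nodes are terms
and whose edges are `is_a` and `part_of` relations (the regulates family is
dropped at parse time; for this measure the two kept relations are treated
identically, since where a term occurs its parents occur regardless of the
relation type). The measure assigns each term a *topological position
characteristic*

$$\mu(\mathrm{root}) = 1, \qquad
  \mu(z) = \prod_{x \in \mathcal{P}_z} \frac{\mu(x)}{C(x)},$$

where $\mathcal{P}_z$ is the set of distinct parents of $z$ and $C(x)$ the
number of children of $x$. $\mu$ is a reachability measure: it shrinks when
a parent splits its specificity across many children, and when a term
accumulates constraints from several parents. The *topological information
content* is $IC(z) = -\ln \mu(z)$, in nats; roots carry $IC = 0$ and are
treated as biologically meaningless.

Two terms with exactly equal $\mu$ joined by a directed path are
*synonym* (topologically identical) terms — necessarily a chain of
single-child parents with single-parent children, the "growing deeper
without spreading sideways" pattern — and are assigned identical semantic
value. Because $\mu$ never increases along an edge, it is enough to detect
synonym *edges* and take transitive closures.

Similarity of $x$ and $y$ is the information of their most informative
common ancestor, normalised by the more informative of the pair:

$$S(x,y) = \frac{-\ln \mu_s(x,y)}{\max\{IC(x), IC(y)\}}, \qquad
  \mu_s(x,y) = \min\{\mu(t) : t \in \mathcal{A}(x,y)\},$$

with $\mathcal{A}(x,y)$ the intersection of the two *self-inclusive*
ancestor sets. The self-inclusive-intersection reading matters: a parent is
its own ancestor, so for a parent–child pair the parent itself is a
candidate, but the child is not — unconditionally adding both endpoints
would force $S = 1$ for every ancestor–descendant pair and contradicts the
published subgraph scores that `fixture_subgraph()` encodes. $d = 1 - S$ is a
metric (symmetry, identity exactly on synonym classes, triangle
inequality); the acceptance suite verifies these properties on sampled
triples over hundreds of random DAGs rather than taking them on faith.

Conventions at the boundaries: pairs involving a root (both ICs 0 would
divide by zero) score 0; cross-namespace pairs score 0 with a warning
rather than an error, because batch runs over mixed GAF files routinely
produce them.

## Underflow-safe arithmetic

On the full GO, $\mu$ reaches values around $10^{-117}$ and on deep dense
ontologies far below $10^{-308}$, the smallest normal double. Every partial
product is therefore renormalised immediately to a base-10
mantissa/exponent pair $(\alpha, \beta)$ with $0.1 \le \alpha < 1$ (exactly
1 only for $\mu = 1$) and integer $\beta \le 0$, and
$IC = -\ln\alpha - \beta\ln 10$ is computed without ever materialising
$\mu$ as a dense float. The test suite drives a 5,000-level chain whose
every node has ten children (about 50,000 terms, $\beta \approx -5000$) and
checks that IC stays finite and strictly increasing.

Published tables print $\mu$ in this same notation but with unnormalised
mantissas (e.g. `0.0456910e-27`); `parse_mu()` keeps mantissas exactly as
printed so the tables round-trip, and all comparisons order by
$\log_{10}\mu = \log_{10}\alpha + \beta$, which is immune to the
normalisation difference.

### The exact oracle

Since every recursion step multiplies unit fractions, $\mu$ is exactly
$1/D$ with $D$ the integer $\prod_x D(x)\,C(x)$. `oracle_mu_exact()`
recomputes $D$ with exact big-integer arithmetic (base-$10^4$ limbs,
implemented in plain R) and takes logs from the top limbs plus the limb
count, giving roughly $10^{-13}$ absolute log accuracy. The engine and the
oracle share no code path; on 200 seeded random DAGs of up to 40 terms the
maximum relative log-space discrepancy is below $10^{-12}$.

## Comparator measures

* **Wang**: each term's ancestors receive S-values by max-propagation with
  semantic factors 0.8 (`is_a`) and 0.6 (`part_of`); only the
  ancestor-induced sub-DAG of the query term is materialised. The relation
  label is retained on edges solely for this comparator.
* **Zhang**: leaf path-counts are summed bottom-up; the leaf baseline D is
  the reciprocal of the root's count, computed per namespace, and
  $IC_Z = -\ln D$. On multi-parent DAGs $D(\mathrm{root}) = 1$ always, but
  the sum of D over leaves is $n_{\mathrm{leaves}}/\mathrm{count(root)}$ —
  only trees give 1 — which the tests assert in this corrected form. The
  uniform variant divides by $\ln N$ with $N$ the namespace's term count.
* **Annotation frequency**: the simplest standard estimator — true-path
  propagated distinct-protein counts, $IC = -\ln(f(t)/f(\mathrm{root}))$ —
  since the family is referenced without a prescribed formula. Terms never
  used (directly or below) are absent from the table rather than given
  infinite IC.

## Protein-level similarity

Pairwise combinations (best-match average, average, maximum) operate on
**direct** annotation sets; the set-overlap family operates on
**ancestor-closed** sets. The closure is what makes set overlap meaningful
at all (direct sets of related proteins rarely intersect), but applying it
to Czekanowski-Dice forces the score to $2k/(2k+1)$ whenever one protein's
terms extend the other's along a path — independent of how informative the
extra term is. The tests demonstrate exactly that content-blindness, and
the IC-weighted variants that repair it: SimGIC/SimUIC (IC-weighted
Jaccard; SimUIC is the same functional form driven by topological rather
than annotation IC), SimDIC (Dice), SimUIX (universal index,
max-denominator), SimUI (unweighted). Since the union is at least the
larger set which is at least the mean, the variants order as
simgic ≤ simuix ≤ simdic on any input. Root terms stay in closures with
IC 0 — harmless to weighted sums, but they inflate SimUI's denominator and
numerator, which is documented here so SimUI is reproducible bit for bit.

Proteins with empty annotation sets (after evidence filtering) yield an
`NA` sentinel, not 0: the evaluation statistics exclude sentinels, matching
the practice of removing unannotated proteins before benchmarking. GAF
rows with a `NOT` qualifier are dropped, as are annotations to unknown or
obsolete terms (counted in a warning).

## Synthetic data

`generate_random_dag()` grows a single-root DAG node by node; the first
parent is drawn with weight $(1+\mathrm{level})^2$ so graphs develop depth
(a short root chain guarantees a level spread of at least 3), additional
parents (up to 3 by default, each with probability 0.3) are uniform, and
edges are `is_a` with probability 0.85, mirroring the relation mix of the
real ontology. `generate_annotations()` draws 1 + Poisson(2) direct terms
per protein with depth-biased probability (weight $1+\mathrm{level}$) and
evidence codes from {EXP, IDA, IEA, ISS} with weights .2/.3/.4/.1. These
defaults are fixed study conditions, not tuning knobs. What the generator
does *not* emulate: the real GO's scale (~47k terms), its namespace
structure, co-annotation correlations between related proteins, and
annotation shallowness biases — so green property tests certify the
algebraic guarantees of the measures, not their biological performance on
real corpora.

Problem sizes used by the test and acceptance runs — 200 random DAGs of
10–40 terms for oracle equivalence and monotonicity, 300 DAGs with 10,200
sampled triples for the metric property, $n = 10{,}000$ permuted labels for
the AUC null — were chosen to make Monte-Carlo error small relative to the
tolerances while completing in seconds to a few minutes.

## Evaluation statistics

ROC curves sweep descending distinct scores with ties grouped; AUC is
available both as the trapezoid integral and as the tie-corrected
Mann-Whitney rank statistic, which agree to machine precision and are
cross-checked against an independent implementation (pROC) in the tests.
Corpus-scale benchmark numbers (PPI networks, CESSM, orthologue sets)
require external databases and are deliberately out of scope; the
evaluation module ships the statistics, and the suite checks their internal
consistency (monotone-transform invariance, label-swap antisymmetry,
permuted-label AUC at 0.5 within Monte-Carlo error). The
precision/accuracy threshold defaults to the Youden-J optimum; that is a
generic operating point, explicitly not a published choice.

## Known limitations

* Levels and similarities on a truncated subgraph are only meaningful
  relative to that subgraph; `fixture_subgraph()` therefore injects published
  positions rather than recomputing them, and its printed levels (which
  refer to the full ontology) are carried as metadata, not recomputed.
* `wang_ic()` stores one S-value map per term, which is quadratic in the
  worst case; it is intended for subgraphs and moderate ontologies, not the
  full 47k-term GO in one call.
* The exact oracle's big-integer denominators grow roughly quadratically in
  digit count with DAG size; it is an oracle for hundreds of terms, not a
  production path.
* One printed walkthrough value (1.38639 for $-\ln(1/4) = 1.38629\ldots$)
  is a typographic slip in its source; tests compare against the closed
  form at $10^{-4}$ tolerance, which covers it.
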