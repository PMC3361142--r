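# GOuniversal

Topology-based semantic similarity for Gene Ontology terms and GO-annotated
proteins.

## The problem

Comparing gene products by function means comparing sets of GO terms, which
requires a similarity measure between terms. Annotation-frequency measures
(Resnik, Lin) make a term's information content depend on which corpus was
used to count annotations, so the "meaning" of a term changes between data
sources. Purely edge-based measures treat all edges at a level as equivalent.
This package implements a measure that uses only the intrinsic topology of
the GO directed acyclic graph.

## The measure

Each term `z` carries a topological position characteristic

```
mu(root) = 1,        mu(z) = prod over parents x of  mu(x) / C(x)
```

where `C(x)` is the number of children of `x`. Its topological information
content is `IC(z) = -ln mu(z)`. Because the product shrinks exponentially
with depth, `mu` is held as a normalised mantissa/exponent pair
`(alpha, beta)` with `mu = alpha * 10^beta`, `0.1 <= alpha < 1`, and
`IC = -ln(alpha) - beta * ln(10)` — the real GO reaches `beta ~ -116` and
beyond, far past double-precision underflow.

Similarity between terms `x` and `y` is the information of their most
informative common ancestor, normalised by the more informative of the two:

```
S(x, y) = -ln mu_s(x, y) / max(IC(x), IC(y)),
mu_s(x, y) = min{ mu(t) : t a common self-inclusive ancestor of x and y }
```

`d = 1 - S` is a genuine distance metric. Terms with equal `mu` joined by a
directed path ("synonym" terms: a single-child parent and its single-parent
child) get similarity exactly 1.

Also included, for comparison and for protein-level scoring: the Wang
S-value measure, the Zhang D-value measure under uniform-Resnik and Lin
scalings, annotation-frequency IC, protein functional similarity by
best-match average / average / maximum and by IC-weighted set overlap
(SimGIC, SimUIC, SimUI, SimDIC, SimUIX), Czekanowski-Dice, OBO 1.2 and
GAF 2.x parsers with evidence-code filtering, seeded random DAG/annotation
generators with an exact big-integer oracle for `mu`, and ROC / AUC /
precision / accuracy / Pearson evaluation statistics.

## Worked example

The twelve-node illustration DAG (root `0` with children `1`, `2`; `1 ->
{3, 4}`; `2 -> {4, 5, ...}`):

```r
library(GOuniversal)

fx <- fixture_walkthrough()
mu <- compute_mu(fx$dag)
mu_value(mu)[c("1", "3", "4", "5")]
#>          1          3          4          5
#> 0.50000000 0.25000000 0.04166667 0.16666667

ic <- ic_universal(mu)
round(ic$values[c("0", "1", "3", "4", "5")], 5)
#>       0       1       3       4       5
#> 0.00000 0.69315 1.38629 3.17805 1.79176
```

Node 4 has two parents — one with two children at `mu = 1/2`, one with three
children at `mu = 1/2` — so `mu(4) = 1/4 * 1/6 = 1/24` and
`IC(4) = -ln(1/24) = 3.17806` nats: the multi-parent term is far more
specific than its siblings at the same depth.

On the bundled GO biological-process subgraph (published per-term positions
injected, see `fixture_subgraph()`):

```r
f3 <- fixture_subgraph()
ic3 <- ic_universal(f3$injected_mu)
sim_universal(f3$dag, ic3, "GO:0042770", "GO:0042772")
#> [1] 0.9791979
sim_universal(f3$dag, ic3, "GO:0030330", "GO:0042771")
#> [1] 0.2475951
```

GO:0042771 is far more similar to its parent GO:0008630 (0.748) than to its
other parent GO:0030330 (0.248): the parent with lower reachability and
fewer children represents its child better.

## Command line

A thin CLI over the same functions lives at `inst/cli/gouniversal.R`
(installed to `cli/gouniversal.R`), with subcommands `ic`, `termsim`,
`funsim`, `simulate` and `evaluate`; outputs are TSV with the resolved
configuration embedded as a header comment.
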