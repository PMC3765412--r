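---
title: "Methods: ontology-driven gene relatedness ranking in gorank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-driven gene relatedness ranking in gorank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gorank)
```

## The problem

Given a handful of query genes, which *other* genes are functionally
related to them?  gorank answers this through the Gene Ontology: each
query gene is mapped to the terms it is directly annotated to (its
*keyword contexts*, KCs), the ontology is searched for terms that stand
in a strong structural relationship to all of those KCs at once, and the
genes annotated to the surviving terms are returned, ranked.

The structural relationship is grounded in *existence dependency*: a
part-of relation between two processes means the part cannot occur
without the whole, so terms connected to the KCs through part-of chains
are the ones whose presence genuinely implies (or is implied by) the
query's annotations.  Two candidate families are searched: lowest common
ancestors (LCAs) and top common descendants (TCDs) of the KCs in the
part-of structure.

## The part-of graph

GO states many part-of relations only implicitly.  `build_pog()` derives
the *part-of graph* (POG): the same term set, carrying an edge
`A part-of C` whenever the ontology states it or it follows from the two
mixed inference rules

* A is-a B and B part-of C  ⇒  A part-of C,
* A part-of B and B is-a C  ⇒  A part-of C,

iterated to a fixed point.  Because GO itself treats part-of as a
transitive relation, plain part-of∘part-of composition is included by
default; `partof_transitive = FALSE` restricts derivations to a single
part-of edge wrapped in is-a chains for users who want the strict
two-rule reading.  Internally the closure is computed as reachability on
a doubled graph (state = "have I used a part-of edge yet?"), which is
equivalent to the naive fixpoint — the test suite proves the equivalence
against a repeat-until-stable oracle on hundreds of random typed DAGs —
but runs in near-linear time per source node.  Every edge records
whether it was explicit or inferred, and nodes that end up without any
part-of relation are kept as isolated nodes, so annotation terms never
silently disappear.

## Term depth

Depth is measured along is-a edges only: part-of says nothing about how
*specific* a term is.  The depth of a term is the length of the longest
is-a-only path from its namespace root; under multiple inheritance the
longest distance governs, because a term inherits the characteristics of
*all* its supertypes and is therefore at least as specific as its
deepest one.  A breadth-first traversal would yield shortest distances
instead, so `assign_depths()` deliberately computes longest paths over a
topological order (linear time on a DAG) rather than BFS.  Terms whose
is-a chain never reaches a root — attached to the graph only via
part-of — receive depth 0 and an `unrooted` flag with a warning; real GO
namespaces do not exhibit such terms, but random and hand-built graphs
can.  Depths render as spreadsheet-style letters (0 → "A", 26 → "AA")
purely for display.

Equal depth does not mean equal *conceptual* depth across different
subtrees (kidney development sits at the same level as system
development); the method accepts this approximation.

## Meaningful candidates

A candidate LCA/TCD is *meaningful* for a KC set when

1. its depth differs from the depth of every KC, and
2. the POG path between the candidate and each KC contains no two terms
   of equal depth (endpoints included).

The rationale is again existence dependency: objects of the same type
(here: terms of the same depth) cannot depend on one another, so a chain
of dependencies must descend through strictly distinct levels.

Three points were genuinely open and are resolved as follows:

* **Quantification over paths.**  "The path" is ambiguous when the POG
  offers several routes.  gorank defaults to *universal* semantics — one
  route through an equal-depth pair condemns the candidate — because the
  worked examples declare candidates meaningless on the strength of a
  single bad path even when a clean direct route exists.  Note that the
  POG, being a closure, always contains the direct edge, which is a
  clean two-node path whenever condition 1 holds; existential semantics
  (`path_semantics = "exists"`) would therefore accept almost
  everything, and is offered only as an explicit opt-in.
* **Endpoints count.**  The KC and the candidate themselves are terms
  "in the path"; a KC of equal depth with another term on the route is a
  violation.
* **Self-candidates.**  A KC equal to the candidate is trivially
  satisfied, so a single-gene, single-annotation query returns the
  annotation term itself and thus its co-annotated genes.

Candidates are generated per combination of one KC per query gene,
deduplicated by (term, role), and kept meaningful if any combination
accepts them.  All iteration orders are lexicographic in the term
identifier, so verdicts, witnesses and rankings are bit-reproducible.
Path enumeration is exhaustive and therefore exponential in the worst
case; it is intended for ontology fragments and moderate neighbourhoods
(the candidate–KC interval is precomputed and the walk restricted to it,
which keeps practical cases small).

## Ranking

Scores flow from a microarray reference.  For a term annotating `b` of
the array's `a` genes, `k` of them among the `c` significant ones, the
term score is the cumulative hypergeometric mass

$$S = \sum_{i=0}^{k-1} \binom{b}{i}\binom{a-b}{c-i} \Big/ \binom{a}{c},$$

evaluated in log space (log-gamma binomial coefficients) so arrays with
tens of thousands of genes do not overflow; `k = 0` gives 0.  The sum
runs over the first `k` terms — the probability of seeing *fewer*
significant genes on the term than observed — i.e. the left cumulative
tail, which is the form the ranking uses throughout.  For the reference
configuration `a = 14500, b = 10153, c = 417, k = 300` exact
rational-arithmetic enumeration gives 0.7917656727520701, which the
implementation reproduces to 1e−10; that exact value is the frozen
regression baseline.  A term absent from
the array universe scores 0; `b` and `k` are always computed on the
intersection with the universe.

The rank of a KC combines its neighbourhood's scores PageRank-style:

$$R(KC) = (1 - p_1 - p_2)\,S(KC) + p_1 \sum_{v \in \mathrm{parents}} \frac{S(v)}{N_i(v)} + p_2 \sum_{v \in \mathrm{children}} \frac{S(v)}{N_i(v)}$$

The two sums are distinguished by the navigation story: `p1` is the
probability of stepping from the KC to a neighbour that describes the
target better (its POG parents), `p2` of stepping from a neighbour back
to the KC (its POG children) — mirroring the in/out-link asymmetry of
the web formulation it adapts.  `Ni(v)` is the number of part-of edges
entering `v`, floored at 1 for sources.  The neighbourhood is taken from
the POG (a containment structure) by default; `kcrank_graph = "go"`
reverts to the raw ontology graph.  With the default `p1 = 0.4`,
`p2 = 0.6` the self-score coefficient is exactly zero — a deliberate
property of the defaults, verified in the tests.

A candidate at `j` hierarchical levels from a KC inherits
`R(KC) · decay^{j-1}` with `decay = 0.7` by default; `j` is the absolute
is-a depth difference floored at 1, applied identically to LCAs and
TCDs.  Per gene, values over the gene's several KCs are aggregated with
`max` (default) or `sum`; per query, the per-gene values are summed and
multiplied by a proximity factor

$$\mathrm{prox} = \frac{1}{\text{height} \times \text{width}}$$

of the smallest window containing all the query's annotation terms.
Height spans hierarchical levels; width spans horizontal positions,
which require a canonical left-to-right order of each depth layer —
gorank uses lexicographic term order within layers, a deterministic and
documented stand-in for the drawing the notion presumes.  All terms
identical gives prox = 1.

Without a microarray, every term scores 1 and the ranking degrades
gracefully to decay and proximity structure.  Answers from LCAs and
TCDs are interleaved in a single ranking tagged by role; ties break
lexicographically.  Query genes are excluded from answers by default
(`exclude_query_genes = FALSE` to revert), matching how a search engine
should not return the query itself.

## The bundled example and the simulator

`nephrogenesis_example()` builds a 29-term kidney-development fragment
whose documented facts — one inferred part-of chain, four equal-depth
layers, the meaningful/meaningless verdicts of two worked queries and
their exact answer gene sets — are asserted by `check_example_facts()`
on every build.  The precise edge list beyond those facts is a minimal
curated completion; the fact suite, not the completion, is the contract.
Its microarray reference (50 genes, 10 significant, deterministic) is
synthetic and exists to exercise the scoring path.

`simulate_ontology()` generates layered random DAGs: each term gets one
is-a parent in the layer above — making its longest-path depth equal its
layer by construction — plus optional extra is-a parents and layer-respecting
part-of edges.  Annotations are drawn uniformly; significance flags are
Bernoulli.  This emulates the *shape* of ontology data (DAG structure,
mixed relation types, sparse annotation) but none of its semantics: no
correlation between annotation and topology, no evidence-code
structure, no realistic term-size distribution, and node counts far
below real GO.  Green property tests therefore certify algorithmic
correctness (closure, depths, verdicts agree with brute-force oracles),
not biological performance on full-scale GO.

Property suites run on hundreds of seeded random graphs of 4–15 nodes —
sizes chosen so the exhaustive oracles (fixpoint iteration, full path
enumeration) stay exact and the whole suite completes in well under a
minute, while still covering every branch of the algorithms.

## Numerical and degenerate-input choices

* Hypergeometric sums are clamped to `[0, 1]` against last-ulp drift and
  validated against R's `phyper` to 1e−10.
* Depth labels, witnesses, candidate sets, rankings: all tie-breaks are
  lexicographic in the term id; repeated runs are byte-identical.
* An unanswerable query (no annotated gene) is an error; a query whose
  meaningful terms carry no other genes returns an empty answer with a
  warning, not an error.
* Precision of an empty answer set is reported as `NA`, not 0, since
  its defining ratio is undefined there.
* Empty annotation input, non-binary significance flags, cycles and
  unknown edge endpoints are rejected with positional error messages.

## Limitations

Exhaustive path checking makes worst-case meaningfulness exponential in
the interval size between a candidate and a KC; dense transitive
neighbourhoods in a full ontology would need pruning strategies not
implemented here.  Depth equality is a proxy for type equality that is
known to misalign across distant subtrees.  The evaluation helpers
(recall/precision, the six-way configuration classifier) score answer
sets against externally supplied reference gene sets; the package ships
no benchmark data.
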