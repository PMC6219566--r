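---
title: "Aligning metabolic networks as hypergraphs: model, algorithm and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning metabolic networks as hypergraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypalign)
```

## The model

A metabolic network with $n$ metabolites and $m$ reactions is a hypergraph
$G(V, E)$: each reaction is the set of all metabolites it touches.  The
stoichiometric matrix maps onto this representation by binarization —
coefficient signs (and with them reaction direction and reversibility) are
deliberately discarded, and duplicate reaction columns are kept as
distinct hyperedges because curated maps routinely contain isozymic
duplicates.  The *order* $K$ of a hypergraph is its largest reaction size.

To align $G^a$ and $G^b$ we enumerate every candidate correspondence in
their *association hypergraph*: after appending a null vertex $N$ to each
network, its vertices are all pairs $(v_a, v_b)$ of padded vertices —
$(n_a+1)(n_b+1)$ of them — and its hyperedges are pairs of reactions.  A
pair of reactions of sizes $p$ and $q$ admits
$\max(p,q)!/(\max(p,q)-\min(p,q))!$ maximal injective matchings of their
metabolite sets; surplus metabolites of the larger reaction pair with the
other network's null vertex and leftover slots up to $K$ are filled with
$(N, N)$.  Only maximal matchings are enumerated: allowing a real
metabolite to pair with null while an unmatched real partner remains would
inflate a pair of two-metabolite reactions from its two natural hyperedges
to six.

Scores live in a sparse super-symmetric tensor $H$ of order
$K = \max(K_a, K_b)$ and dimension $(n_a+1)(n_b+1)$:

* diagonal entries $(i, \ldots, i)$ for a real pair $i = (v_a, v_b)$ hold
  $\lambda \, S_c(v_a, v_b)$, where $S_c$ is a compound structural
  similarity in $[0,1]$ supplied as a long-format table.  Missing pairs
  are imputed with the table mean; missing *self*-pairs default to 1,
  since a metabolite is maximally similar to itself;
* each enumerated hyperedge of a reaction pair holds
  $(1-\lambda)\, S_e(\mathrm{EC}_a, \mathrm{EC}_b)$, where $S_e$ is the
  inverse number of census enzymes under the lowest EC class the two
  enzyme numbers share (e.g. 1.1.1.1 vs 1.1.1.2 share 1.1.1.-).  Enzymes
  with different top-level classes score 0 — unrelated chemistry should
  not attract an alignment — and partial EC codes truncate the shared
  prefix at their first dash.

Zero-valued elements are never stored.  When two different reaction pairs
produce the same canonical hyperedge with different scores (common with
isozymes), the larger value is kept — an element records the best
supporting evidence — and one summary warning reports how often this
happened.  Null-involving diagonal entries take a configurable gap score,
0 by default.

## The optimisation

A binary assignment vector $x$ scores
$S(x) = H \otimes_1 x \otimes_2 x \cdots \otimes_K x$.  Relaxing the 0/1
constraints to $x^\top x = 1$ turns the maximisation into finding the
dominant Z-eigenpair $H \otimes x^{K-1} = \gamma x$, solved by the shifted
symmetric higher-order power method: from a non-negative start,

$$x' = H \otimes x^{K-1}, \qquad
  x \leftarrow \frac{\alpha x + (1-\alpha)\, x'/\lVert x'\rVert_2}
                    {\lVert \cdot \rVert_2}.$$

The explicit final renormalisation is required by the unit-sphere
constraint even though the damped update alone does not preserve it.
Because $H \ge 0$ and the start is non-negative, every iterate is
non-negative.

The tensor-vector product is computed *rotationally* from canonical
storage: one stored element with sorted subscripts contributes to one
output slot per **distinct** subscript value, weighted by the number of
distinct permutations of the remaining $K-1$ subscripts,
$(K-1)!/\prod_j m_j!$.  Using distinct values rather than literal
$K$-fold rotation matters when subscripts repeat — rotating $(1,1,2)$
literally would count the slot-1 contribution twice — and the
distinct-value rule is validated element-wise against a dense oracle that
materialises all subscript permutations.  The contribution table is built
once per tensor and sorted by (output slot, element) so floating-point
accumulation order, and hence every downstream number, is identical from
run to run.  Instrumentation counters confirm at most
$|\text{elements}| \times K$ contributions per product, versus the
$K!$-fold proliferation a dense symmetric expansion requires.

### Parameters

| parameter | default | meaning |
|---|---|---|
| $\lambda$ | 0.9 | weight of metabolite (vertex) similarity; reactions get $1-\lambda$.  Small $\lambda$ regimes are dominated by large blocks of equal-valued off-diagonal elements and converge to poor alignments, so metabolite-dominant weighting is the default. |
| $\alpha$ | 0.01 | damping/shift of the power update, in $[0,1)$.  Near 0: fast, accurate; near 1: barely moves and stalls at suboptima. |
| $\beta$ | 1 | uniform fraction of the start vector $x_0 = (1-\beta)x_r + \beta x_u$.  The uniform start reaches the best-scoring stationary points; random admixture degrades the discretized result. |
| `tol` | 1e-8 | convergence tolerance, applied to **both** the score change and the iterate change (below). |
| `max_iter` | 1000 | iteration cap; unconverged runs are flagged, not errors. |
| `gap_score` | 0 | diagonal score of null-involving pairs (alignment to a deletion/insertion). |
| census | union | enzyme census for $S_e$: by default the union of both networks' EC annotations; a global census can be supplied instead. |

### Convergence test

The score $\gamma_n = S(x_n)$ flattens quadratically in the iterate error,
so stopping on $|\Delta\gamma| < \text{tol}$ alone can halt with the
eigen-equation residual $\lVert H \otimes x^{K-1} - \gamma x\rVert_2$
still around $10^{-5}$.  The run therefore stops only when both
$|\Delta\gamma| < \text{tol}$ and $\lVert x_{n+1} - x_n \rVert_2 <
\text{tol}$; at $\alpha = 0.01$ the extra cost is a handful of
iterations, and converged runs then satisfy the residual diagnostic
comfortably.

## Discretization

The relaxation is loose for $K \ge 3$: with a metabolite-dominant tensor
the continuous optimum concentrates essentially all mass on the single
best-supported vertex pair ($\gamma \to \lambda \cdot \max S_c$), and the
remaining information survives only as residual mass spread over tens of
orders of magnitude.  Two consequences shape the implementation:

1. **Scale-peeled assignment.**  A single double-precision Kuhn-Munkres
   solve is numerically blind to weights below about $10^{-16}$ of the
   largest one — it would resolve the winner and scramble everything else.
   `discretize()` therefore solves the maximum-weight assignment scale by
   scale: each round rescales the remaining submatrix by its maximum,
   commits only assignments whose weight is within `rel_tol` ($10^{-6}$)
   of that maximum, removes the matched vertices, and repeats.  For
   weights of comparable magnitude this is exactly one maximum-weight
   assignment (the regime the exhaustive test oracle checks); across
   scales it implements the observation that no combination of
   lower-scale weights can outweigh a committed higher-scale one.  Null
   options enter with the iterate mass of the corresponding $(v, N)$ and
   $(N, v)$ coordinates.

2. **Greedy augmentation.**  Even with a zero gap score the null
   coordinates acquire iterate mass through edge coupling, so the
   mass-maximal assignment can leave a vertex unmatched although matching
   it strictly increases the discrete objective.  `refine_matching()`
   repairs this after the assignment: while some pair of unmatched
   vertices strictly raises the discrete score, the best such pair is
   added.  Pairs are never removed, so the result dominates the raw
   assignment under the tensor objective.

Ties inside a round are resolved by the deterministic assignment solver
and, for the forced-progress fallback, by first index; the whole pipeline
is a pure function of (inputs, parameters, seed).

## Synthetic benchmarks

`random_hypergraph()` draws reactions as uniform random subsets (sizes
uniform on $1..K_{\max}$), assigns each a synthetic four-level EC number,
and builds a compound similarity table with self-similarity 1 and
cross-similarities uniform on $[0, 0.3]$ — every metabolite is
structurally distinctive, which is the regime in which self-alignment
recovery is well-posed.  `knockout()` deletes reactions uniformly at
random and drops metabolites orphaned by the deletion (curated sub-maps
omit orphan compounds); metabolites that were already isolated in the
parent are kept, so a zero-reaction knockout reproduces the parent
exactly.  The ground truth is the identity on retained vertices.
`add_noise()` perturbs every stored tensor element with an additive
uniform draw on $(-\delta, +\delta)$, $\delta$ = fraction × mean stored
element value, clipped at zero; "mean intensity" is read as the mean over
stored elements, and the distribution choice (uniform) is a documented
convention, not a claim.

What the passing benchmarks do **not** show about real data: KEGG-scale
networks have hub ("currency") metabolites shared by hundreds of
reactions, correlated compound similarities (chemically related
metabolites cluster), partial and missing EC annotations, and orders far
above 4.  The generator emulates none of these, so perfect knockout
recovery here bounds the method's behaviour only in the
distinct-similarity regime; genome-scale accuracy is additionally
database-version dependent and is not asserted by the test suite.

Problem sizes used by the default suite: networks of 8–15 reactions
(orders up to 4), 20 replicate seeds per noise level, and tensors up to
dimension 8 per mode for the dense-oracle comparisons — sizes chosen so
the whole behavioural suite re-runs in well under a minute while still
exercising order-4 tensors and 300-element association hypergraphs.

## Degenerate inputs and edge cases

* Reaction columns of all zeros are rejected at binarization (a reaction
  with no metabolites is meaningless).
* Two edgeless hypergraphs have no alignable structure; the association
  order is undefined and an error.
* An empty similarity table has no mean to impute from and is rejected.
* A census inconsistent with a query (zero enzymes under a genuinely
  shared class) is an error rather than an infinite score.
* A start vector annihilated by the tensor ($H \otimes x^{K-1} = 0$)
  aborts with a diagnostic instead of dividing by zero.
* The null vertex id is chosen to avoid collision with a metabolite
  actually named "N".

## Known limitations

* The relaxation's global optimum is degenerate whenever several vertex
  pairs attain the maximal diagonal score; which one the iteration
  selects is decided by edge coupling.  The discretization recovers the
  full matching from residual ordering, but this is the fragile step —
  the same phenomenon that makes the continuous score a poor predictor of
  discretized quality.
* Maximal-matching enumeration grows factorially with reaction size;
  order-10+ reactions (large complexes, lumped biomass reactions) are
  impractical without further sparsification.
* Direction, reversibility and stoichiometric magnitudes are not modelled
  by design.
* Multi-start global-optimum certification is out of scope; the uniform
  start is a well-behaved default, not a guarantee.
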