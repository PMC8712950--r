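---
title: "Detecting protein complexes with a memetic search over weighted PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes with a memetic search over weighted PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

Protein complexes are groups of proteins that bind together and act as one
molecular machine. In a protein–protein interaction (PPI) network they
appear as clusters that are densely connected internally and sparsely
connected to the rest of the graph. This vignette explains the model behind
`imacomplex`, the parameters that matter, the synthetic benchmark the
package tests itself on, and the design decisions taken where the procedure
leaves genuine freedom.

## Edge weighting

Raw high-throughput interaction data is noisy, so every edge $(v, u)$ is
first scored with four independent evidence sources, each in $[0, 1]$:

* **Higher-order common neighbours.** With open neighbourhoods $N(\cdot)$
  (a protein is not its own neighbour),
  $$HCN(v,u) = \frac{|N(v) \cap N(u)|^2}{|N(v)|\,|N(u)|\,|N(v) \cup N(u)|}.$$
  Squaring the common-neighbour count rewards pairs whose neighbourhoods
  overlap strongly relative to the connectivity of both endpoints.
* **Co-expression.** The Pearson correlation $r$ of the two expression time
  courses, rescaled to $[0,1]$ as $(r + 1)/2$. All time points are used; no
  active-period filtering is applied.
* **Functional similarity.** The cosine of the binary GO-slim attribute
  vectors, $|T_v \cap T_u| / \sqrt{|T_v|\,|T_u|}$.
* **Co-localization.** $|SL(v) \cap SL(u)|^2 / (|SL(v)|\,|SL(u)|)$ over the
  subcellular compartment sets.

The edge weight is the plain arithmetic mean of the four components.
Missing evidence — an absent or zero-variance expression profile, an empty
term or compartment set — contributes 0 while the divisor stays 4, so a
fully supported edge always outranks a partially supported one. Edges whose
four components are all exactly zero carry no supporting evidence at all
and are removed as noise (an exact comparison, not a tolerance test);
isolated nodes are retained.

## Cluster fitness

A candidate cluster $C$ with internal weight sum $W_{in}$, border weight
sum $W_{out}$, $|E_C|$ internal and $|BE_C|$ border edges is scored with
five objectives:

$$\mathrm{cohesiveness} = \frac{W_{in}}{W_{in} + W_{out}}, \quad
\mathrm{density} = \frac{2 W_{in}}{|V_C|(|V_C|-1)}, \quad
\mathrm{AIEW} = \frac{W_{in}}{|E_C|},$$
$$\mathrm{ABEW} = \frac{W_{out}}{|BE_C|}, \quad
\mathrm{AWM} = \frac{\mathrm{AIEW}}{\mathrm{AIEW} + \mathrm{ABEW}},$$

combined as
$$FF(C) = \mathrm{cohesiveness} + \mathrm{density} + \mathrm{AIEW} -
\mathrm{ABEW} + \mathrm{AWM} \in [-1, 4].$$

Density and AIEW reward dense, reliable interiors; ABEW penalizes heavy
borders; cohesiveness and AWM reward separation from the rest of the
network. The fitness of an *individual* — one candidate clustering
$P = (P_1, \dots, P_k)$ — is $\sum_i FF(P_i)$.

Degenerate cases use zero-evidence conventions chosen so that clusters
without support cannot score: a singleton has density 0; no internal edges
gives AIEW 0; no border edges gives ABEW 0; $\mathrm{AIEW} +
\mathrm{ABEW} = 0$ gives AWM 0; $W_{in} + W_{out} = 0$ gives cohesiveness
0. On an unweighted network every edge counts with weight 1, which is the
"unweighted" variant of the method.

## The memetic search

`run_ima()` maximizes individual fitness with a genetic search hybridized
with per-cluster local optimization:

1. **Initialization.** Each supplied clustering (outputs of other
   detectors, or perturbed references) becomes one individual; clusters
   are filtered to network members and to the minimum size. The population
   is padded to `pop_size` by cycling individuals in decreasing fitness
   order.
2. **Selection.** Two parents by binary tournament (two uniform draws with
   replacement; the fitter wins, first-sampled on ties).
3. **Recombination.** The parents' clusters are pooled into a composite
   parent; exact-duplicate sets are collapsed to one copy. Each child's
   length is drawn uniformly from the interval spanned by the parents'
   lengths, and the child is filled by repeated binary tournaments over
   the composite clusters (ranked by $FF$), never re-selecting a cluster
   already in that child.
4. **Local optimization.** The fitter child, if its fitness exceeds
   `local_opt_gate` (default 0.8) times the current maximum population
   fitness, has each cluster refined by alternating greedy moves: remove
   the member whose removal most increases $FF$, then add the
   neighbourhood protein whose addition most increases $FF$; only strictly
   improving moves are taken, capped at 20 passes per cluster. If the
   optimized individual is not strictly fitter than the input, the
   optimization is discarded (identity-or-improve).
5. **Update.** The child joins the population pool and `pop_size`
   survivors are drawn by fitness-proportional roulette sampling without
   replacement. The best individual ever seen is recorded each generation,
   so the best-ever fitness trace is non-decreasing by construction.

After `max_iter` generations the recorded best is returned with clusters
below `min_cluster_size` dropped and exact duplicates removed.

### Design decisions in the search

Several points are genuinely open and were fixed as follows:

* **Duplicate complexes inside an individual.** Local optimization can
  converge two near-duplicate clusters of the same individual onto the
  same protein set. Because the fitness is a plain sum of $FF$ values, a
  duplicated strong complex would outscore retaining a distinct weak one,
  and the search then systematically trades real complexes for copies: on
  the planted benchmark below, the literal keep-duplicates variant loses
  two to three planted complexes in roughly half the runs (recovery
  F-measure $\ge 0.8$ in only ~55% of seeds, mean F 0.84 over 20 seeds).
  A complex found twice in one clustering is redundant — the same rule
  already applied to the composite parent — so `local_optimize()` keeps
  one copy of any duplicated cluster before its accept/revert test. With
  this rule the search recovers the planted complexes in 20/20 seeds
  (mean F 0.93) while every operator contract (strict improvement,
  identity-or-improve, move rules) is unchanged.
* **Removal candidates.** A member is removable if it is connected to at
  least one other protein in the network; only edge-less proteins are
  pinned. The stricter reading "has a neighbour outside the cluster" would
  make a cluster spanning a whole connected component unoptimizable — it
  could never shed a weakly attached member — which contradicts the
  intended behaviour on the pendant example in the test suite.
* **Population size.** The population size is exposed directly with
  default 24, matching the convention of building the initial population
  from three detectors at eight parameterizations each ($3 \times 8$).
  Smaller populations (e.g. 8) also work; the search is not very sensitive
  to this choice.
* **Stopping rule.** Exactly `max_iter` generations (default 60); there is
  no convergence-based early exit, which keeps runs deterministic in
  length and cost.
* **Determinism.** One RNG stream is seeded once per run from
  `rng_seed`; operators draw from it in a fixed order, and all
  score-tied choices break to lexicographic protein order. Identical
  seeds therefore give identical outputs.
* **Connectivity.** Clusters are not forced to stay connected; the
  $W_{in}$-based terms already penalize disconnection.
* **Non-positive fitness in the roulette.** Fitness can in principle be
  negative (a cluster that is all border); probabilities are then shifted
  so the minimum maps to $10^{-9}$.

## Evaluation metrics

`evaluate_complexes()` compares a detected set against a reference
catalogue with the field's standard suite. Two complexes match when their
overlap score $OS(A,B) = |A \cap B|^2 / (|A|\,|B|)$ reaches the threshold
$\lambda = 0.2$. The report contains precision/recall/F-measure, the
coverage rate $CR = \sum_s \max_t T_{st} / \sum_s N_s$, clustering-wise
$Sn$/$PPV$ and their geometric mean $ACC$, the maximum matching ratio
(exact maximum-weight one-to-one matching over all $OS > 0$ pairs, divided
by the reference count), the per-side best-Jaccard means combined
harmonically, and their sum, the total score in $[0, 5]$. As printed, the
coverage-rate and $Sn$ formulas coincide; both are implemented from their
own definitions and agree by construction — this is documented rather than
"fixed". Enrichment uses the upper-tail hypergeometric test against a
user-supplied annotation map, with the universe defaulting to the proteins
of the analyzed network; the co-localization score is the summed dominant
compartment count over summed complex sizes, with unlocalized members
counting toward the denominator only.

## The synthetic benchmark

`generate_benchmark()` plants non-overlapping complexes in a
planted-partition graph and emits attribute tables correlated with the
planted structure, emulating exactly the statistical assumptions the edge
weighting relies on: co-complex proteins co-express (shared latent time
course plus Gaussian noise), share a dominant GO term set, and share a
dominant compartment. The defaults define the package's reference study
conditions: 8 complexes of 5–8 proteins, within-complex edge probability
0.9, background edge probability 0.02, membership perturbation rate 0.3
for deriving noisy initial clusterings. Values with no external anchor
were fixed once at what co-expression/complex studies in yeast would call
realistic scale: 40 background proteins (comparable in number to the
planted proteins), 12 time points (a typical two-cycle expression course),
noise sd 0.25 (clear but imperfect co-expression), 3 GO terms per complex,
and a pool of 6 compartments.

What the benchmark does *not* emulate: scale-free degree structure,
overlapping complexes (supported in scoring but not planted by default),
correlated noise between evidence sources, and the sheer size of real
interactomes (thousands of nodes). Passing the recovery experiment
therefore shows that the optimizer and weighting behave as designed under
their own assumptions — not that the method attains any particular
accuracy on real data.

## Problem sizes and costs

The test suite and the acceptance script run at desk scale by design: the
recovery experiment uses ten ~90-protein benchmarks with 60 generations
and population 24 (about half a second per run); operator contracts are
exercised over 100 seeded short runs on a 4-complex benchmark; oracle
equivalences use random graphs of at most 15–20 nodes where brute-force
re-derivation is exact. The implementation itself is $O(\text{moves}
\times \text{cluster degree sum})$ per local optimization and handles
networks of a few thousand nodes in minutes.

## A worked run

```{r example, eval = FALSE}
library(imacomplex)

bench <- generate_benchmark(synthetic_spec(rng_seed = 1))
weighted <- build_weighted_network(bench$network, bench$attributes)
inits <- lapply(1:24, function(k) {
  perturb_gold(bench$gold, 0.3, bench$network, rng_seed = 1000 + k)
})
res <- run_ima(weighted, inits, ima_config(rng_seed = 1))
evaluate_complexes(res$complexes, bench$gold)
```

## Known limitations

* The composite fitness is an unweighted sum; there are no per-term
  coefficients to trade cohesion against separation.
* Initial clusterings must be supplied (or simulated); the package does
  not re-implement seed-expansion detectors to generate them.
* Exact-duplicate removal uses set equality only; highly overlapping but
  non-identical output complexes are not merged.
* The enrichment universe is the analyzed network, which is the common
  but not the only defensible choice.
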