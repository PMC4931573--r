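---
title: "Designing microbial consortia as Directed Steiner Hypertrees"
author: "multipus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing microbial consortia as Directed Steiner Hypertrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipus)
```

## The problem

Given a set of candidate *worker* organisms described by their metabolic
networks, a set of available *source* compounds and a set of *target*
compounds to produce, which consortium should be assembled, which reactions
(if any) must be inserted heterologously from *reference* organisms, and
which metabolites should be exchanged between the members? `multipus`
answers the purely topological version of this question: it finds all
minimum-cost reaction sets that produce every target from the sources,
where cost reflects that endogenous reactions are cheap, while inserting a
foreign gene or transporting a compound across organisms is expensive.

The model deliberately ignores stoichiometry, flux, thermodynamics and
growth: it is a first, combinatorial screen whose proposals should be
post-processed with quantitative methods (e.g. flux balance analysis).

## The hypergraph model

Compounds hosted by an organism are vertices — `(compound, organism)` pairs,
so pyruvate in two organisms is two vertices. Reactions are directed
hyperarcs from their substrate set to a product. A reaction needs *all* its
substrates; a hyperarc with more than one source is called *tentacular* and
its number of sources is its *spreadness*. Multi-product reactions are
split, losslessly, into sibling single-target arcs sharing one reaction
group id; reversible reactions are split into two directed reactions
(suffixes `__f`/`__r`), each carrying the full weight, because the model is
purely directional.

An instance is assembled in three steps (`mergeWorkerNetworks()`,
`addInsertionArcs()`, `addTransitionArcs()`, or `buildInstance()` in one
call):

* the disjoint union of the worker networks, every arc at weight
  `wWorker` (default 1);
* for every reference reaction a worker lacks (exact reaction-id match), an
  *insertion* copy in that worker at weight `wOther` (default 100),
  creating any missing compound vertices;
* for every compound present in two organisms, *transition* arcs in both
  directions at weight `wTransition` (default 100), optionally overridden
  per compound (e.g. acetate at 50 to model an organic-acid transporter
  known to exist).

The defaults 1/100/100 encode the prior that endogenous chemistry is
essentially free relative to genetic engineering and transport, while a
small positive `wWorker` makes optima also minimise the number of
endogenous steps. Cofactors must be removed beforehand
(`removeCofactors()`), otherwise ATP and water would connect everything to
everything.

A solution of the **Directed Steiner Hypertree (DSH)** problem is a
hyperarc set `A'` that is *rooted* at the sources S — its arcs can be
ordered so that each arc's substrates are supplied by S or by earlier
products (`isRooted()` decides this by a greedy schedule, which is complete
because firing an enabled arc never disables another) — and that produces
every target, at minimum total weight.

## The exact algorithm

On ordinary digraphs DSH is the classic directed Steiner tree problem; the
hardness concentrates in the tentacular arcs. The solver is
fixed-parameter tractable in the number of targets plus the total
spreadness:

1. **Ordered combinations.** Every solution uses some subset M of the
   tentacular arcs in a topological order; all ordered subsets are tried
   (`enumerateOrderedSubsets()`, at most 2^k·k! for k tentacular arcs).
   Combinations whose substrates lie outside the closure of S under all
   arcs can never fire and are skipped.
2. **Layers.** For a fixed M the sources of M become additional targets and
   the targets of M additional sources, stratified by layer
   (`computeLayers()`): a tentacular product may only feed targets consumed
   by strictly later tentacular arcs, giving the candidate-root sets S_Y
   (`candidateRoots()`).
3. **Forest DP.** The optimal way of linking everything with plain arcs is
   a minimum-weight forest covering the extended target set T', computed by
   a subset dynamic program: `SH(Y) = min(min_{s in S_Y} ST(s, Y),
   min_{Y' subset Y} SH(Y') + SH(Y\Y'))`, where `ST(s, Y)` is the directed
   Steiner arborescence on the tentacular-free graph, computed by the
   Dreyfus–Wagner subset DP (`steinerTree()`); shortest paths come from
   igraph. The optimum is the minimum of `weight(M) + SH(T')` over all
   combinations.
4. **Reconstruction.** Witness forests are interleaved with M by layer,
   pruned to inclusion-minimality (deterministic lexicographic scan to a
   fixpoint), and validated for rootedness and coverage.
   `enumerateOptimal()` backtracks over all co-optimal combinations, DP
   branches and Steiner witnesses — including parallel equal-weight arcs,
   which igraph's vertex-level path enumeration would collapse, so path
   backtracking is done at edge level — and deduplicates the minimalized
   arc sets.

### Design choices in the open corners

* **"X as set of leaves".** Minimal Steiner witnesses satisfy
  leaves ⊆ X (terminals may also be internal); requiring leaf-set equality
  would exclude valid optima, so containment-with-coverage is implemented.
* **Targets that are also sources.** By default a target must be the target
  of a used arc (strict reading of the coverage condition
  `T ⊆ tgt(A')`). A target that is also a source can then only be produced
  by an arc re-entering it — possibly via a cycle through the source
  itself, which a covering *forest* cannot represent. The solver therefore
  promotes one mandatory producing arc per such target into the ordered
  combination (the layer machinery is agnostic to the spreadness of
  must-use arcs) and removes plain promoted arcs from the Steiner graph so
  they are never paid twice. `allowSourceTargets = TRUE` instead treats
  such targets as satisfied for free.
* **Multi-product weight accounting.** Sibling arcs of one decomposed
  reaction each carry the full reaction weight, and the DP optimises over
  per-arc weights; `solutionWeight(..., perReaction = TRUE)` implements the
  alternative convention that counts a reaction once. The packaged
  fixtures and the generator use single-product reactions, where both
  conventions coincide.
* **Exact arithmetic.** Weights are small non-negative rationals; totals
  are compared exactly (integer-valued doubles sum exactly), and
  infeasibility is the distinguished value `Inf`, never a large number.
  All iteration orders are fixed by C-locale-sorted ids, so results are
  byte-reproducible across platforms and locales.
* **Guardrails.** By default the solver refuses more than 8 usable
  tentacular arcs or an extended target set beyond 12 vertices
  (`overrideGuardrails = TRUE` to proceed anyway); the brute-force oracle
  refuses more than 14 hyperarcs.

## Lossless compression

`compressInstance()` shrinks instances before solving by three reductions
that provably preserve the optimal weight: forward pruning (vertices
outside the closure of S, and arcs that can never fire), backward pruning
(vertices from which no chain of consumers reaches a target cannot occur in
an inclusion-minimal solution), and chain contraction (an unprotected
vertex with exactly one single-source in-arc and one single-source out-arc,
untouched by tentacular arcs, is contracted; any minimal solution uses the
two chain arcs together or not at all, so contraction is a bijection on
minimal solutions and preserves solution counts). `expandSolution()` maps
solutions back via the recorded expansion map at identical weight. The
pruning steps guarantee weight preservation, not count preservation: a
pruned vertex can by construction not occur in any minimal solution, but
the reductions are validated empirically against the brute-force oracle
rather than accompanied by a formal count-preservation proof.

## The brute-force oracle and the generator

`bruteForceDsh()` enumerates all 2^m arc subsets with a vectorised greedy
scheduler — an implementation deliberately independent of the DP code path
— and returns all inclusion-minimal optimal subsets. It is the ground
truth the solver is validated against.

`generateRandomInstance()` draws per-organism reaction sets over a shared
compound pool (shrinking the pool raises the compound overlap and hence the
number of transition arcs), runs the full construction pipeline and picks
terminals. With `feasible = TRUE` the sources are seeded with the
substrates of one random reaction and targets are sampled from the strictly
producible part of the closure of S, so solvability holds by construction.
The equivalence suites use two worker organisms with 3 compounds drawn from
a pool of 5 and 3 reactions each (2 when one reference reaction is added),
at most 2 tentacular reactions of spreadness ≤ 3, and 1–3 targets; these
sizes keep every generated instance within the oracle's subset-enumeration
reach (≤ 12 hyperarcs, ≤ 10 vertices per organism) while still exercising
insertions, transitions, tentacular combinations and infeasible cases. The
test suite sweeps 1000 such instances for solver/oracle agreement on both
the optimal weight and the complete set of minimalized optimal solutions,
500 random digraphs (≤ 8 vertices, ≤ 3 terminals) for the Steiner program
against exhaustive arborescence search, and 200 instances for compression
losslessness.

What the generator emulates — and what it does not: instances are small,
uniformly random and single-product, with none of the scale, hub structure
(currency metabolites), reaction reversibility patterns or compartmentation
of genome-scale models. Passing these suites shows the algorithms are
exact on the model's semantics; it does not show that desk-scale toys
capture the statistics of real GEMs, whose tentacular counts (hundreds,
with total spreadness in the hundreds) exceed this exact R implementation
and call for the guardrails above.

## The packaged case studies

Three fixtures (`consortiumFixture()`) reproduce the *composition* of the
two published consortium designs at desk scale — not the genome-scale KEGG
networks, which would require external data extraction:

* `antibiotics_toy`: a *S. cattleya*-like producer and a *M. barkeri*-like
  partner on cellulose; the penicillin/cephalosporin C branch (with the
  three-substrate ACV synthase as a tentacular insertion) plus the forced
  pyruvate/2-oxoadipate exchange yields the optimum
  528 = 28·1 + 3·100 + 2·100.
* `pdo_toy`: a *K. pneumoniae*-like PDO producer and a *M. mazei*-like
  methanogen on glycerol; optimum 110 = 10·1 + 1·100 (pyruvate exchanged).
* `pdo_acetate_toy`: the same topology plus a pyruvate→acetate step and
  acetate uptake; with the acetate transport discounted to 50 the optimum
  switches to the acetate exchange at 61 = 11·1 + 50. At uniform weights
  the same instance still optimises to the 110 pyruvate exchange, which is
  exactly why the discount is biologically interesting.

```{r fixtures}
out <- solveDsh(consortiumFixture("antibiotics_toy"))
out
breakdown(solutions(out)[[1]])
```

## Limitations

Beyond the deliberate exclusion of stoichiometry and flux: compound
matching across organisms is exact string identity of pre-normalised ids;
reaction identity for insertion is exact reaction-id equality; the
combination space grows as 2^k·k!, so genome-scale tentacular counts are
out of reach of this exact implementation; and completeness of co-optimal
enumeration through DP backtracking is validated empirically against the
oracle rather than proved.
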