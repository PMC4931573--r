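# multipus

Exact design of microbial consortia by Directed Steiner Hypertrees.

## The problem

Synthetic production of a compound often works better in a *consortium* of
microbes than in a single engineered organism: the work can be split, toxic
by-products can be consumed by a partner, and fewer genes need to be
inserted into any one member. But which organisms should be combined, which
reactions inserted, and which metabolites exchanged?

`multipus` answers the topological core of this question. The metabolic
networks of candidate **worker** organisms (and optional **reference**
organisms that naturally produce the targets) are assembled into a weighted
directed hypergraph:

* vertices are `(compound, organism)` pairs;
* a reaction is a hyperarc from its substrate set to a product — a reaction
  with several substrates is *tentacular*, and the sum of substrate counts
  over tentacular arcs is the *total spreadness*;
* endogenous worker reactions cost `w_worker` (default 1), heterologous
  **insertions** of reference reactions cost `w_other` (default 100), and
  cross-organism **transitions** (metabolite transport) cost
  `w_transition` (default 100, overridable per compound).

Given source compounds S and target compounds T, the **Directed Steiner
Hypertree (DSH)** problem asks for a minimum-weight hyperarc set A' that is
*rooted* at S (its arcs admit an ordering in which every substrate is
supplied by S or by an earlier product) with T ⊆ tgt(A'). The solver is
exact and fixed-parameter tractable in |T| plus the total spreadness: it
enumerates ordered combinations M of the tentacular arcs (≤ 2^k·k! of
them), derives layer structure, and runs a subset dynamic program

    SH_M(Y) = min( min_{s ∈ S_Y} ST(s, Y),
                   min_{∅ ⊂ Y' ⊂ Y} SH_M(Y') + SH_M(Y \ Y') )

whose base case ST(s, Y) is a Dreyfus–Wagner directed Steiner arborescence
on the tentacular-free graph; the optimum is min over M of
weight(M) + SH_M(T'). All co-optimal consortium designs can be enumerated.
A brute-force oracle, a seeded instance generator, a lossless pre-solve
compression and TSV/SBML/JSON/DOT input-output round the package out.

## A worked example

The packaged `pdo_acetate_toy` fixture is a two-organism consortium: a
*Klebsiella pneumoniae*-like 1,3-propanediol producer growing on glycerol
and a *Methanosarcina mazei*-like methanogen. The transport of acetate is
discounted to 50 (both species are known to handle organic acids), all
other transports cost 100:

```r
library(multipus)
inst <- consortiumFixture("pdo_acetate_toy")
inst
#> ConsortiumInstance over 2 worker organism(s): k_pneumoniae, m_mazei
#> Hypergraph with 14 vertices and 16 hyperarcs
#>   tentacular hyperarcs: 0 | total spreadness: 0
#>   categories: endogenous=12, transition=4
#>   sources: glycerol@k_pneumoniae
#>   targets: pdo@k_pneumoniae, methane@m_mazei
#>   weights: w_worker=1, w_other=100, w_transition=100 (+ 1 override(s))

out <- enumerateOptimal(inst)
out
#> DshOutcome: optimal weight 61 with 1 solution(s)
#>   first solution: endogenous=11, insertion=0, transition=1

arcOrdering(solutions(out)[[1]])
#>  [1] "r_glp1@k_pneumoniae" "r_glp2@k_pneumoniae" "r_glp3@k_pneumoniae"
#>  [4] "r_glp4@k_pneumoniae" "r_glp5@k_pneumoniae" "r_pdo1@k_pneumoniae"
#>  [7] "r_pdo2@k_pneumoniae" "r_poxB@k_pneumoniae"
#> [10] "tr:acetate:k_pneumoniae->m_mazei" "r_ack@m_mazei"
#> [13] "r_mtg2@m_mazei" "r_mtg3@m_mazei"
```

Reading: the optimum (weight 61 = 11 endogenous reactions at 1 plus one
acetate transport at 50) keeps the whole glycerol → PDO line in
*K. pneumoniae*, shunts pyruvate to acetate, exchanges **acetate** — the
growth-inhibiting by-product — and lets the methanogen turn it into
methane. The ordering printed is the rootedness witness: each reaction's
substrates are available before it fires. At uniform transport weight 100
the same instance instead exchanges pyruvate at total weight 110; the
discount is what makes the acetate-consuming consortium optimal.

The TSV dialect for your own networks has columns
`reaction_id  substrates  products  reversible` (semicolon-separated
compound ids, reversible ∈ {0,1}); SBML Level 2/3 core files are also read
(`readSBML()`, stoichiometry deliberately ignored). A thin command-line
front end ships at `inst/scripts/multipus.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","multipus.R",package="multipus"))')" \
  solve --network kp=kp.tsv --network mm=mm.tsv \
  --sources glycerol@kp --targets pdo@kp,methane@mm \
  --override transition:acetate=50 --enumerate-all --format json
```

Exit codes: 0 solved, 3 infeasible, 4 guardrail refusal, 1 usage/IO error.

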