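test_that("ordered-subset enumeration is complete, deterministic and guarded", {
  expect_identical(enumerateOrderedSubsets(character(0)), list(character(0)))
  two <- enumerateOrderedSubsets(c("b", "a"))
  expect_identical(two, list(character(0), "a", "b", c("a", "b"), c("b", "a")))
  expect_length(enumerateOrderedSubsets(c("a", "b", "c")), 16L)
  expect_length(enumerateOrderedSubsets(letters[1:3], maxK = 1L), 4L)
  expect_error(enumerateOrderedSubsets(letters[1:9]), "refusing")
  expect_length(enumerateOrderedSubsets(letters[1:9], maxK = 1L,
                                        overrideGuardrails = TRUE), 10L)
})

layerFixture <- function() {
  arcs <- rbind(
    arcRow("a1", "a1", c("p@o", "q@o"), "r@o", 5, "endogenous", "o"),
    arcRow("a2", "a2", c("r@o", "q@o"), "s@o", 5, "endogenous", "o"),
    arcRow("e1", "e1", "s@o", "p@o", 1, "endogenous", "o"),
    arcRow("e2", "e2", "s@o", "q@o", 1, "endogenous", "o"),
    arcRow("e3", "e3", "s@o", "t@o", 1, "endogenous", "o"))
  makeInstance(arcs, sources = "s@o", targets = "t@o")
}

test_that("layer maps follow the ordered combination", {
  inst <- layerFixture()
  # empty combination: T' = T at layer k+1 = 1, S' = S at layer 0
  c0 <- computeLayers(inst, character(0))
  expect_identical(c0@tPrime, "t@o")
  expect_equal(unname(c0@layerT["t@o"]), 1)
  expect_equal(unname(c0@layerS["s@o"]), 0)
  # M = (a1): sources of a1 join T' at layer 1, its target joins S' at 1
  c1 <- computeLayers(inst, "a1")
  expect_setequal(c1@tPrime, c("p@o", "q@o", "t@o"))
  expect_equal(unname(c1@layerT[c("p@o", "q@o")]), c(1, 1))
  expect_equal(unname(c1@layerT["t@o"]), 2)
  expect_equal(unname(c1@layerS["r@o"]), 1)
  # S takes precedence: s is also tgt(a2) but keeps layer 0
  c2 <- computeLayers(inst, c("a1", "a2"))
  expect_equal(unname(c2@layerS["s@o"]), 0)
  expect_error(computeLayers(inst, "e1"), "non-tentacular")
})

test_that("candidate roots implement S_Y", {
  inst <- layerFixture()
  c0 <- computeLayers(inst, character(0))
  expect_identical(candidateRoots(c0, "t@o"), "s@o")
  c2 <- computeLayers(inst, c("a1", "a2"))
  # Y containing a source of a_1 can only be served from S itself
  expect_identical(candidateRoots(c2, c("p@o", "t@o")), "s@o")
  # plain targets (layer k+1 = 3) can also be served by both tentacular
  # products (layers 1 and 2)
  expect_setequal(candidateRoots(c2, "t@o"), c("s@o", "r@o"))
  expect_error(candidateRoots(c2, character(0)), "non-empty")
  expect_error(candidateRoots(c2, "zz@o"), "subset")
})

test_that("SH covers isolated targets for free and sums disconnected components", {
  # t is a tentacular product: its singleton cover is the isolated node
  inst <- layerFixture()
  # two disconnected chains, two targets: SH is additive over the partition
  arcs <- rbind(
    arcRow("e1", "e1", "s1@o", "t1@o", 2, "endogenous", "o"),
    arcRow("e2", "e2", "s2@o", "t2@o", 3, "endogenous", "o"))
  disc <- makeInstance(arcs, sources = c("s1@o", "s2@o"),
                       targets = c("t1@o", "t2@o"))
  res <- solveSH(disc, character(0))
  expect_equal(res$weight, 5)
  expect_length(res$trees, 2L)
  expect_setequal(vapply(res$trees, function(tr) tr@weight, numeric(1)),
                  c(2, 3))
})

test_that("SH with no tentacular arcs equals the brute-force optimum", {
  checked <- 0L
  for (seed in 1:40) {
    inst <- randomOracleInstance(seed * 11L + 1L)
    if (totalSpreadness(inst) > 0L) next
    if (length(intersect(sources(inst), targets(inst)))) next
    bf <- bruteForceDsh(inst, limit = 14)
    sh <- solveSH(inst, character(0))
    if (solverStatus(bf) == "infeasible") expect_equal(sh$weight, Inf)
    else expect_equal(sh$weight, optimalWeight(bf))
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("the solver handles forced structures", {
  # single arc
  one <- makeInstance(arcRow("e1", "e1", "s@o", "t@o", 5, "endogenous", "o"),
                      sources = "s@o", targets = "t@o")
  out <- solveDsh(one)
  expect_equal(optimalWeight(out), 5)
  expect_length(solutions(out), 1L)
  # a target only producible through a tentacular arc pulls in both supply
  # chains and the combination M = (a)
  arcs <- rbind(
    arcRow("e1", "e1", "s@o", "u@o", 1, "endogenous", "o"),
    arcRow("e2", "e2", "s@o", "v@o", 1, "endogenous", "o"),
    arcRow("a", "a", c("u@o", "v@o"), "t@o", 2, "endogenous", "o"))
  inst <- makeInstance(arcs, sources = "s@o", targets = "t@o")
  out <- solveDsh(inst)
  expect_equal(optimalWeight(out), 4)
  expect_setequal(solutionArcs(solutions(out)[[1]]), c("e1", "e2", "a"))
  expect_identical(out@combinations[[1]], "a")
  # infeasibility is an outcome, not an error
  unreach <- makeInstance(arcRow("e1", "e1", "s@o", "u@o", 1, "endogenous", "o"),
                          sources = "s@o", targets = "t@o",
                          extraVertices = "t@o")
  expect_identical(solverStatus(solveDsh(unreach)), "infeasible")
})

test_that("strict and relaxed source-target semantics differ as specified", {
  # t is a source; producing it strictly needs the cycle through the arcs
  arcs <- rbind(
    arcRow("e1", "e1", "t@o", "a@o", 1, "endogenous", "o"),
    arcRow("e2", "e2", "a@o", "t@o", 1, "endogenous", "o"))
  inst <- makeInstance(arcs, sources = "t@o", targets = "t@o")
  strict <- solveDsh(inst)
  expect_equal(optimalWeight(strict), 2)
  expect_true(validateSolution(inst, solutions(strict)[[1]]))
  relaxed <- solveDsh(inst, allowSourceTargets = TRUE)
  expect_equal(optimalWeight(relaxed), 0)
  expect_length(solutionArcs(solutions(relaxed)[[1]]), 0L)
})

test_that("enumeration returns all co-optimal solutions and respects the cap", {
  # two parallel equal-weight arcs: exactly two optimal solutions
  arcs <- rbind(
    arcRow("e1", "e1", "s@o", "t@o", 3, "endogenous", "o"),
    arcRow("e2", "e2", "s@o", "t@o", 3, "endogenous", "o"))
  inst <- makeInstance(arcs, sources = "s@o", targets = "t@o")
  all2 <- enumerateOptimal(inst)
  expect_length(solutions(all2), 2L)
  expect_false(all2@truncated)
  capped <- enumerateOptimal(inst, cap = 1L)
  expect_length(solutions(capped), 1L)
  expect_true(capped@truncated)
  # unique-solution instance
  uniq <- enumerateOptimal(makeInstance(
    arcRow("e1", "e1", "s@o", "t@o", 1, "endogenous", "o"),
    sources = "s@o", targets = "t@o"))
  expect_length(solutions(uniq), 1L)
})

test_that("solver outputs satisfy the structural invariants", {
  for (seed in c(4, 14, 24, 34, 44)) {
    inst <- randomOracleInstance(seed)
    out <- enumerateOptimal(inst, cap = 200)
    if (solverStatus(out) == "infeasible") next
    for (sol in solutions(out)) {
      expect_true(validateSolution(inst, sol))
      expect_equal(totalWeight(sol), optimalWeight(out))
    }
  }
})

test_that("optimal weight is invariant under arc-table permutation and relabeling", {
  inst <- randomOracleInstance(7L)
  base <- optimalWeight(solveDsh(inst))
  # permute the arc table
  a <- hyperarcs(inst)
  set.seed(1); perm <- a[sample.int(nrow(a)), , drop = FALSE]
  H2 <- Hypergraph(vertices = vertices(inst), arcs = perm)
  inst2 <- methods::new("ConsortiumInstance", hypergraph = H2,
                        sources = sources(inst), targets = targets(inst),
                        weights = weightConfig(inst),
                        workerOrganisms = workerOrganisms(inst),
                        referenceReactions = character(0))
  expect_equal(optimalWeight(solveDsh(inst2)), base)
  # relabel vertices (prefix preserves the sort-stability of nothing: ids change)
  relab <- function(x) sub("^c", "zz", x)
  v <- vertices(inst); v$id <- relab(v$id); v$compound <- sub("^c", "zz", v$compound)
  a3 <- hyperarcs(inst)
  a3$sources <- lapply(a3$sources, relab); a3$target <- relab(a3$target)
  inst3 <- methods::new("ConsortiumInstance",
                        hypergraph = Hypergraph(vertices = v, arcs = a3),
                        sources = relab(sources(inst)),
                        targets = relab(targets(inst)),
                        weights = weightConfig(inst),
                        workerOrganisms = workerOrganisms(inst),
                        referenceReactions = character(0))
  expect_equal(optimalWeight(solveDsh(inst3)), base)
})

test_that("raising a weight or deleting arcs never decreases the optimum", {
  for (seed in c(12, 22)) {
    inst <- randomOracleInstance(seed)
    out <- solveDsh(inst)
    if (solverStatus(out) == "infeasible") next
    base <- optimalWeight(out)
    a <- hyperarcs(inst)
    used <- solutionArcs(solutions(out)[[1]])
    a$weight[a$id == used[1]] <- a$weight[a$id == used[1]] + 10
    up <- methods::new("ConsortiumInstance",
                       hypergraph = Hypergraph(vertices = vertices(inst),
                                               arcs = a),
                       sources = sources(inst), targets = targets(inst),
                       weights = weightConfig(inst),
                       workerOrganisms = workerOrganisms(inst),
                       referenceReactions = character(0))
    expect_gte(optimalWeight(solveDsh(up)), base)
    del <- hyperarcs(inst)
    del <- del[del$id != used[1], , drop = FALSE]
    dInst <- methods::new("ConsortiumInstance",
                          hypergraph = Hypergraph(vertices = vertices(inst),
                                                  arcs = del),
                          sources = sources(inst), targets = targets(inst),
                          weights = weightConfig(inst),
                          workerOrganisms = workerOrganisms(inst),
                          referenceReactions = character(0))
    d <- solveDsh(dInst)
    expect_true(solverStatus(d) == "infeasible" ||
                  optimalWeight(d) >= base)
  }
})

test_that("with uniform weights the optimum minimises the number of hyperarcs", {
  for (seed in c(5, 15, 25)) {
    inst <- generateRandomInstance(nOrganisms = 2L, nCompounds = 3L,
                                   compoundPool = 5L, nReactions = 3L,
                                   tentacularFraction = 0.3,
                                   maxTentacularArcs = 2L,
                                   weights = WeightConfig(1, 1, 1),
                                   seed = seed)
    if (nrow(hyperarcs(inst)) > 14L) next
    bf <- bruteForceDsh(inst, limit = 14)
    dp <- solveDsh(inst)
    expect_identical(solverStatus(bf), solverStatus(dp))
    if (solverStatus(bf) == "optimal") {
      minArcs <- min(lengths(lapply(solutions(bf), solutionArcs)))
      expect_equal(optimalWeight(dp), minArcs)
    }
  }
})

test_that("the tentacular guardrail refuses oversized instances unless overridden", {
  arcs <- do.call(rbind, lapply(1:9, function(i)
    arcRow(sprintf("a%d", i), sprintf("a%d", i),
           c("s1@o", "s2@o"), sprintf("t%d@o", i), 1, "endogenous", "o")))
  big <- makeInstance(arcs, sources = c("s1@o", "s2@o"), targets = "t1@o")
  expect_error(solveDsh(big), class = "multipus_guardrail")
  small <- makeInstance(arcs[1:3, ], sources = c("s1@o", "s2@o"),
                        targets = "t1@o")
  expect_error(solveDsh(small, maxTentacular = 2L),
               class = "multipus_guardrail")
  ok <- solveDsh(small, maxTentacular = 2L, overrideGuardrails = TRUE)
  expect_equal(optimalWeight(ok), 1)
})
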