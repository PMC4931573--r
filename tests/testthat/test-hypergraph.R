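test_that("spreadness counts sources and flags tentacular hyperarcs", {
  arcs <- rbind(
    arcRow("a1", "r1", "x@o", "y@o", 1, "endogenous", "o"),
    arcRow("a2", "r2", c("x@o", "y@o", "z@o"), "w@o", 1, "endogenous", "o"))
  H <- Hypergraph(arcs = arcs)
  s <- spreadness(H)
  expect_identical(unname(s[c("a1", "a2")]), c(1L, 3L))
  expect_identical(totalSpreadness(H), 3L)
  expect_error(spreadness(H, "nope"), "unknown hyperarc")
})

test_that("total spreadness equals the brute recount over tentacular arcs", {
  expect_identical(totalSpreadness(Hypergraph(arcs = rbind(
    arcRow("a1", "r1", "x@o", "y@o", 1, "endogenous", "o"),
    arcRow("a2", "r2", "y@o", "z@o", 1, "endogenous", "o")))), 0L)
  for (seed in 1:10) {
    inst <- randomOracleInstance(seed)
    sp <- lengths(hyperarcs(inst)$sources)
    expect_identical(totalSpreadness(inst), sum(sp[sp > 1L]))
    expect_identical(sum(spreadness(inst)[sp > 1L]), totalSpreadness(inst))
  }
})

test_that("multi-product reactions decompose into sibling single-target arcs", {
  rxn <- reactionSet("r1", list(c("a", "b")), list(c("c", "d")))
  H <- decomposeReactions(rxn, "o")
  a <- hyperarcs(H)
  expect_equal(nrow(a), 2L)
  expect_setequal(a$target, c("c@o", "d@o"))
  expect_true(all(vapply(a$sources, setequal, logical(1), c("a@o", "b@o"))))
  expect_identical(unique(a$reaction), "r1")

  single <- decomposeReactions(reactionSet("r2", list("a"), list("c")),
                               "o")
  expect_equal(nrow(hyperarcs(single)), 1L)
})

test_that("decomposition arc count equals total product count and reversible reactions split", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 10L
    prods <- lapply(seq_len(n), function(i)
      sprintf("p%d_%d", i, seq_len(sample.int(3L, 1L))))
    rxn <- reactionSet(sprintf("r%d", seq_len(n)),
                              as.list(sprintf("s%d", seq_len(n))), prods)
    H <- decomposeReactions(rxn, "o")
    expect_equal(nrow(hyperarcs(H)), sum(lengths(prods)))
  }
  rev <- reactionSet("r1", list("a"), list("b"), reversible = TRUE)
  Hr <- decomposeReactions(rev, "o")
  expect_setequal(hyperarcs(Hr)$reaction, c("r1__f", "r1__r"))
  bad <- reactionSet("rx", list(character(0)), list("b"))
  expect_error(decomposeReactions(bad, "o"), "rx")
})

test_that("closure is the least fixpoint of firing available arcs", {
  arcs <- rbind(
    arcRow("a1", "r1", "s@o", "t@o", 1, "endogenous", "o"),
    arcRow("a2", "r2", c("x@o", "y@o"), "z@o", 1, "endogenous", "o"))
  H <- Hypergraph(vertices = data.frame(
    id = c("s@o", "t@o", "x@o", "y@o", "z@o"),
    compound = c("s", "t", "x", "y", "z"), organism = "o"), arcs = arcs)
  expect_identical(closure(H, character(0), "s@o"), "s@o")
  expect_setequal(closure(H, "a1", "s@o"), c("s@o", "t@o"))
  # a reaction needs all its substrates: z is not produced from x alone
  expect_identical(closure(H, "a2", "x@o"), "x@o")
  expect_setequal(closure(H, "a2", c("x@o", "y@o")),
                  c("x@o", "y@o", "z@o"))
  expect_error(closure(H, "a9", "s@o"), "unknown")
})

test_that("closure is monotone and idempotent", {
  for (seed in 1:8) {
    inst <- randomOracleInstance(seed)
    H <- hypergraph(inst)
    ids <- hyperarcs(H)$id
    verts <- vertices(H)$id
    set.seed(seed)
    X <- sample(verts, 2L)
    X2 <- unique(c(X, sample(verts, 2L)))
    A <- sample(ids, min(6L, length(ids)))
    cX <- closure(H, A, X)
    expect_true(all(cX %in% closure(H, A, X2)))          # monotone
    expect_identical(closure(H, A, cX), cX)              # idempotent
    expect_true(all(X %in% cX))
  }
})

test_that("rootedness is decided by the greedy schedule with a witness", {
  arcs <- rbind(
    arcRow("a1", "r1", "s@o", "u@o", 1, "endogenous", "o"),
    arcRow("a2", "r2", c("u@o", "s@o"), "t@o", 1, "endogenous", "o"))
  H <- Hypergraph(arcs = arcs)
  expect_true(isRooted(H, character(0), "s@o")$rooted)
  r <- isRooted(H, c("a1", "a2"), "s@o")
  expect_true(r$rooted)
  expect_identical(r$ordering, c("a1", "a2"))
  expect_false(isRooted(H, "a2", "s@o")$rooted)
})

test_that("greedy rootedness agrees with exhaustive search over all orderings", {
  # a set is rooted iff some permutation of it is a valid firing schedule
  validOrdering <- function(H, ord, S) {
    a <- hyperarcs(H)
    avail <- S
    for (id in ord) {
      i <- match(id, a$id)
      if (!all(a$sources[[i]] %in% avail)) return(FALSE)
      avail <- c(avail, a$target[i])
    }
    TRUE
  }
  permutations <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (seed in 1:12) {
    inst <- randomOracleInstance(seed)
    H <- hypergraph(inst)
    ids <- hyperarcs(H)$id
    set.seed(seed)
    A <- sample(ids, min(5L, length(ids)))
    S <- sources(inst)
    res <- isRooted(H, A, S)
    exhaustive <- any(vapply(permutations(A), validOrdering, logical(1),
                             H = H, S = S))
    expect_identical(res$rooted, exhaustive)
    if (res$rooted) {
      expect_true(validOrdering(H, res$ordering, S))
      # rooted sets produce only vertices inside the closure of S
      tg <- hyperarcs(H)$target[match(A, ids)]
      expect_true(all(tg %in% closure(H, A, S)))
    }
  }
})

test_that("solution weight sums member arcs and reports the category breakdown", {
  arcs <- do.call(rbind, c(
    lapply(1:2, function(i) arcRow(sprintf("t%d", i), sprintf("t%d", i),
                                   sprintf("a%d@x", i), sprintf("a%d@y", i),
                                   100, "transition", "x->y")),
    lapply(1:3, function(i) arcRow(sprintf("i%d", i), sprintf("i%d", i),
                                   sprintf("b%d@x", i), sprintf("c%d@x", i),
                                   100, "insertion", "x")),
    lapply(1:28, function(i) arcRow(sprintf("e%02d", i), sprintf("e%02d", i),
                                    sprintf("d%d@x", i), sprintf("f%d@x", i),
                                    1, "endogenous", "x"))))
  H <- Hypergraph(arcs = arcs)
  sw <- solutionWeight(H, arcs$id)
  expect_equal(sw$weight, 528)
  expect_equal(sw$breakdown[["transition"]], 2L)
  expect_equal(sw$breakdown[["insertion"]], 3L)
  expect_equal(sw$breakdown[["endogenous"]], 28L)
  expect_equal(solutionWeight(H, character(0))$weight, 0)
  expect_error(solutionWeight(H, "zz"), "unknown")
})

test_that("per-reaction weighting counts sibling arcs once", {
  rxn <- reactionSet("r1", list("a"), list(c("b", "c")))
  H <- decomposeReactions(rxn, "o", weight = 7)
  ids <- hyperarcs(H)$id
  expect_equal(solutionWeight(H, ids)$weight, 14)               # per arc
  expect_equal(solutionWeight(H, ids, perReaction = TRUE)$weight, 7)
})
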