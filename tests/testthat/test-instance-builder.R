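twoOrgNetworks <- function() {
  list(
    orgA = reactionSet(c("ra1", "ra2", "ra3"),
                       list("a1", "a2", "a3"), list("a2", "a3", "a4")),
    orgB = reactionSet(c("rb1", "rb2", "rb3"),
                       list("b1", "b2", "b3"), list("b2", "b3", "b4")))
}

test_that("merging worker networks is a disjoint union at weight wWorker", {
  inst <- mergeWorkerNetworks(twoOrgNetworks(), WeightConfig(wWorker = 2))
  a <- hyperarcs(inst)
  expect_equal(nrow(a), 6L)
  expect_true(all(a$category == "endogenous"))
  expect_true(all(a$weight == 2))
  expect_setequal(workerOrganisms(inst), c("orgA", "orgB"))
  # single-organism merge reproduces the organism's own hypergraph
  one <- mergeWorkerNetworks(twoOrgNetworks()["orgA"])
  own <- decomposeReactions(twoOrgNetworks()$orgA, "orgA")
  expect_setequal(hyperarcs(one)$id, hyperarcs(own)$id)
})

test_that("organisms sharing compound ids get distinct vertices", {
  nets <- list(orgA = reactionSet("r1", list("glc"), list("pyr")),
               orgB = reactionSet("r2", list("glc"), list("pyr")))
  inst <- mergeWorkerNetworks(nets)
  expect_setequal(vertices(inst)$id,
                  c("glc@orgA", "pyr@orgA", "glc@orgB", "pyr@orgB"))
})

test_that("merge rejects duplicate organisms and empty networks", {
  nets <- twoOrgNetworks()
  expect_error(mergeWorkerNetworks(stats::setNames(nets, c("x", "x"))),
               "duplicate organism")
  nets$orgB <- nets$orgB[0, ]
  expect_error(mergeWorkerNetworks(nets), "empty network")
  expect_error(mergeWorkerNetworks(list()), "at least one")
})

test_that("insertion copies are created exactly where the reaction is absent", {
  ref <- reactionSet("ref1", list("x"), list("y"))
  # worker without the reaction: one insertion copy
  inst <- mergeWorkerNetworks(list(w1 = reactionSet("r1", list("a"), list("b"))))
  inst <- addInsertionArcs(inst, ref)
  a <- hyperarcs(inst)
  expect_equal(sum(a$category == "insertion"), 1L)
  expect_equal(a$weight[a$category == "insertion"], 100)
  expect_true(all(c("x@w1", "y@w1") %in% vertices(inst)$id))

  # reaction already present in the worker: no copy
  have <- mergeWorkerNetworks(list(w1 = reactionSet("ref1", list("x"), list("y"))))
  have <- addInsertionArcs(have, ref)
  expect_equal(sum(hyperarcs(have)$category == "insertion"), 0L)

  # 4 workers, present in exactly one: 3 copies
  nets <- c(list(w0 = reactionSet("ref1", list("x"), list("y"))),
            lapply(stats::setNames(1:3, paste0("w", 1:3)), function(i)
              reactionSet(paste0("r", i), list("a"), list("b"))))
  four <- addInsertionArcs(mergeWorkerNetworks(nets), ref)
  expect_equal(sum(hyperarcs(four)$category == "insertion"), 3L)
})

test_that("transition arcs join shared compounds in both directions", {
  nets <- list(orgA = reactionSet("r1", list("glc"), list("pyr")),
               orgB = reactionSet("r2", list("pyr"), list("ac")))
  inst <- addTransitionArcs(mergeWorkerNetworks(nets))
  a <- hyperarcs(inst)
  tr <- a[a$category == "transition", ]
  expect_setequal(tr$target, c("pyr@orgA", "pyr@orgB"))
  expect_setequal(unlist(tr$sources), c("pyr@orgA", "pyr@orgB"))
  expect_true(all(tr$weight == 100))
  # glc only lives in orgA: no transition for it
  expect_false(any(grepl("glc", tr$id)))
})

test_that("per-compound overrides apply to transitions only for that compound", {
  nets <- list(orgA = reactionSet("r1", list("glyc"), list("acetate")),
               orgB = reactionSet("r2", list("acetate"), list("ch4")))
  nets$orgB <- rbind(nets$orgB, reactionSet("r3", list("glyc"), list("x")))
  w <- WeightConfig(overrides = list(transition = c(acetate = 50)))
  inst <- addTransitionArcs(mergeWorkerNetworks(nets, w))
  tr <- hyperarcs(inst)
  tr <- tr[tr$category == "transition", ]
  ac <- grepl("^tr:acetate", tr$id)
  expect_true(all(tr$weight[ac] == 50))
  expect_true(all(tr$weight[!ac] == 100))
})

test_that("cofactor removal filters compounds and drops emptied reactions", {
  nw <- reactionSet(c("r1", "r2", "r3"),
                    list(c("atp", "glc"), "atp", c("a", "b")),
                    list(c("adp", "g6p"), "x", "adp"))
  res <- removeCofactors(nw, c("atp", "adp"))
  expect_equal(nrow(res$network), 1L)
  expect_identical(res$network$substrates[[1]], "glc")
  expect_identical(res$network$products[[1]], "g6p")
  expect_setequal(res$dropped$reaction_id, c("r2", "r3"))
  # empty cofactor list is the identity
  same <- removeCofactors(nw, character(0))
  expect_identical(same$network, nw)
  expect_equal(nrow(same$dropped), 0L)
})

test_that("disjoint-union arithmetic holds on generated instances", {
  for (seed in c(3, 6, 9)) {
    inst <- randomOracleInstance(seed)
    a <- hyperarcs(inst)
    v <- vertices(inst)
    endo <- a[a$category == "endogenous", ]
    # endogenous arc count is the sum over organisms
    perOrg <- table(endo$organism)
    expect_equal(sum(perOrg), nrow(endo))
    # transitions always join the same compound in two distinct organisms
    tr <- a[a$category == "transition", ]
    if (nrow(tr)) {
      src <- vapply(tr$sources, `[`, character(1), 1L)
      cs <- v$compound[match(src, v$id)]
      ct <- v$compound[match(tr$target, v$id)]
      expect_true(all(cs == ct))
      expect_true(all(v$organism[match(src, v$id)] !=
                        v$organism[match(tr$target, v$id)]))
      # both directions exist
      key <- paste(src, tr$target)
      rev <- paste(tr$target, src)
      expect_true(all(rev %in% key))
    }
  }
})

test_that("a single worker with no references has no transition or insertion arcs", {
  inst <- mergeWorkerNetworks(list(solo = reactionSet(
    c("r1", "r2"), list("a", "b"), list("b", "c"))))
  inst <- addTransitionArcs(inst)
  expect_true(all(hyperarcs(inst)$category == "endogenous"))
})
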