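#' Seeded random consortium instances
#'
#' Draws per-organism reaction sets over a shared compound pool (so that some
#' compounds occur in several organisms and transitions arise), runs the full
#' instance-construction pipeline (disjoint union, optional insertion copies
#' of reference reactions, transition arcs), and picks sources and targets.
#' With `feasible = TRUE` (the default), the sources are seeded with the
#' substrates of one randomly chosen reaction and the targets are sampled
#' from the strictly producible part of the closure of S, so the instance is
#' solvable by construction. Identical `seed` and parameters yield an
#' identical instance (byte-identical serialisation).
#'
#' @param nOrganisms number of worker organisms.
#' @param nCompounds compounds drawn per organism.
#' @param compoundPool size of the shared compound pool the organisms draw
#'   from; overlap between organisms (hence transition arcs) grows as the
#'   pool shrinks.
#' @param nReactions endogenous reactions per organism.
#' @param tentacularFraction probability that a reaction gets more than one
#'   substrate.
#' @param maxSpreadness maximum number of substrates of a tentacular
#'   reaction.
#' @param maxTentacularArcs cap on the total number of tentacular reactions
#'   across the instance (`Inf` for no cap).
#' @param nReferenceReactions single-substrate reference reactions inserted
#'   into every organism lacking them.
#' @param nSources,nTargets sizes of S and T.
#' @param feasible guarantee solvability by sampling targets from the
#'   producible closure of S.
#' @param weights a [WeightConfig-class].
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return A [ConsortiumInstance-class].
#' @export
generateRandomInstance <- function(nOrganisms = 2L, nCompounds = 3L,
                                   compoundPool = nCompounds + 2L,
                                   nReactions = 3L,
                                   tentacularFraction = 0.2,
                                   maxSpreadness = 2L,
                                   maxTentacularArcs = Inf,
                                   nReferenceReactions = 0L,
                                   nSources = 1L, nTargets = 2L,
                                   feasible = TRUE,
                                   weights = WeightConfig(),
                                   seed) {
  stopifnot(nOrganisms >= 1L, nCompounds >= 2L, compoundPool >= nCompounds,
            nReactions >= 1L, tentacularFraction >= 0, tentacularFraction <= 1,
            maxSpreadness >= 2L, nSources >= 1L, nTargets >= 1L)
  if (missing(seed)) stop("a seed is required for reproducible generation")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  pick <- function(x, size) x[sample.int(length(x), size)]
  pool <- sprintf("c%02d", seq_len(compoundPool))
  orgs <- sprintf("org%d", seq_len(nOrganisms))

  for (attempt in seq_len(50L)) {
    tentLeft <- maxTentacularArcs
    networks <- list()
    for (oi in seq_along(orgs)) {
      comps <- .csort(pick(pool, nCompounds))
      rid <- character(nReactions); subs <- vector("list", nReactions)
      prods <- vector("list", nReactions)
      for (r in seq_len(nReactions)) {
        spread <- 1L
        if (tentLeft > 0 && stats::runif(1) < tentacularFraction &&
            nCompounds > maxSpreadness) {
          spread <- pick(2:maxSpreadness, 1L)
          tentLeft <- tentLeft - 1L
        }
        s <- pick(comps, spread)
        p <- pick(setdiff(comps, s), 1L)
        rid[r] <- sprintf("r_%s_%d", orgs[oi], r)
        subs[[r]] <- .csort(s); prods[[r]] <- p
      }
      networks[[orgs[oi]]] <- .reactionSet(rid, subs, prods, FALSE)
    }
    refs <- NULL
    if (nReferenceReactions > 0L) {
      rid <- sprintf("ref_%d", seq_len(nReferenceReactions))
      subs <- vector("list", nReferenceReactions)
      prods <- vector("list", nReferenceReactions)
      for (r in seq_len(nReferenceReactions)) {
        s <- pick(pool, 1L)
        subs[[r]] <- s; prods[[r]] <- pick(setdiff(pool, s), 1L)
      }
      refs <- .reactionSet(rid, subs, prods, FALSE)
    }
    inst <- mergeWorkerNetworks(networks, weights)
    if (!is.null(refs)) inst <- addInsertionArcs(inst, refs)
    if (nOrganisms >= 2L) inst <- addTransitionArcs(inst)

    cc <- .compileHypergraph(inst@hypergraph)
    # seed S with the substrates of a random arc so that something can fire
    a0 <- sample.int(cc$m, 1L)
    sIdx <- cc$arc_src[[a0]]
    extra <- nSources - length(sIdx)
    if (extra > 0L) {
      others <- setdiff(seq_len(cc$n), sIdx)
      if (length(others)) sIdx <- c(sIdx, pick(others, min(extra, length(others))))
    }
    sIdx <- sort(unique(sIdx))
    avail <- .closureIdx(cc, seq_len(cc$m), sIdx)
    producible <- logical(cc$n)
    for (a in seq_len(cc$m))
      if (all(avail[cc$arc_src[[a]]])) producible[cc$arc_tgt[a]] <- TRUE
    candidates <- setdiff(which(producible), sIdx)
    if (feasible) {
      if (length(candidates) < nTargets) next
      tIdx <- sort(pick(candidates, nTargets))
    } else {
      others <- setdiff(seq_len(cc$n), sIdx)
      if (length(others) < nTargets) next
      tIdx <- sort(pick(others, nTargets))
    }
    return(setTerminals(inst, sources = cc$vid[sIdx], targets = cc$vid[tIdx]))
  }
  stop("could not generate a ", if (feasible) "feasible " else "",
       "instance with these parameters after 50 attempts")
}
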