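#' @describeIn Hypergraph vertex table accessor
#' @export
setMethod("vertices", "Hypergraph", function(x) x@vertices)

#' @describeIn Hypergraph hyperarc table accessor
#' @export
setMethod("hyperarcs", "Hypergraph", function(x) x@arcs)

#' @describeIn ConsortiumInstance vertex table of the underlying hypergraph
#' @export
setMethod("vertices", "ConsortiumInstance", function(x) x@hypergraph@vertices)

#' @describeIn ConsortiumInstance hyperarc table of the underlying hypergraph
#' @export
setMethod("hyperarcs", "ConsortiumInstance", function(x) x@hypergraph@arcs)

#' @rdname ConsortiumInstance-class
#' @param x a `ConsortiumInstance`.
#' @export
setMethod("sources", "ConsortiumInstance", function(x) x@sources)

#' @rdname ConsortiumInstance-class
#' @export
setMethod("targets", "ConsortiumInstance", function(x) x@targets)

#' @rdname ConsortiumInstance-class
#' @export
setMethod("workerOrganisms", "ConsortiumInstance", function(x) x@workerOrganisms)

#' @rdname ConsortiumInstance-class
#' @export
setMethod("weightConfig", "ConsortiumInstance", function(x) x@weights)

#' @rdname ConsortiumInstance-class
#' @export
hypergraph <- function(x) x@hypergraph

#' Spreadness of hyperarcs
#'
#' The spreadness of a hyperarc is its number of sources (substrates); a
#' hyperarc is *tentacular* when its spreadness exceeds one, i.e. the reaction
#' needs more than one substrate. The total spreadness of a hypergraph is the
#' sum of spreadness over its tentacular hyperarcs (single-source arcs
#' contribute nothing); together with the number of targets it is the
#' parameter in which the exact solver is fixed-parameter tractable.
#'
#' @param x a [Hypergraph-class] or [ConsortiumInstance-class].
#' @param arcIds character vector of hyperarc ids, or NULL for all arcs.
#' @return `spreadness()`: named integer vector; `totalSpreadness()`: a single
#'   integer.
#' @examples
#' arcs <- rbind(
#'   arcRow("a1", "r1", c("x@o", "y@o"), "z@o", 1, "endogenous", "o"),
#'   arcRow("a2", "r2", "z@o", "w@o", 1, "endogenous", "o"))
#' H <- Hypergraph(arcs = arcs)
#' spreadness(H)        # a1 = 2 (tentacular), a2 = 1
#' totalSpreadness(H)   # 2
#' @export
setMethod("spreadness", "Hypergraph", function(x, arcIds = NULL) {
  a <- x@arcs
  if (!is.null(arcIds)) {
    idx <- match(arcIds, a$id)
    if (anyNA(idx))
      stop("unknown hyperarc id(s): ",
           paste(arcIds[is.na(idx)], collapse = ", "), call. = FALSE)
    a <- a[idx, , drop = FALSE]
  }
  stats::setNames(lengths(a$sources), a$id)
})

#' @rdname spreadness
#' @export
setMethod("spreadness", "ConsortiumInstance",
          function(x, arcIds = NULL) spreadness(x@hypergraph, arcIds))

#' @rdname spreadness
#' @export
setMethod("totalSpreadness", "Hypergraph", function(x) {
  s <- lengths(x@arcs$sources)
  sum(s[s > 1L])
})

#' @rdname spreadness
#' @export
setMethod("totalSpreadness", "ConsortiumInstance",
          function(x) totalSpreadness(x@hypergraph))

#' One row of a hyperarc table
#'
#' Small helper to assemble hyperarc tables literally in examples, tests and
#' fixtures.
#'
#' @param id,reaction,sources,target,weight,category,organism hyperarc fields;
#'   `sources` is a character vector of vertex ids.
#' @return a one-row arc `data.frame` (rbind-able).
#' @export
arcRow <- function(id, reaction, sources, target, weight, category, organism) {
  df <- data.frame(id = id, reaction = reaction, target = target,
                   weight = weight, category = category, organism = organism,
                   stringsAsFactors = FALSE)
  df$sources <- list(as.character(sources))
  df[, c("id", "reaction", "sources", "target", "weight", "category",
         "organism")]
}

#' Decompose raw reactions into single-target hyperarcs
#'
#' A reaction with several products is split, without loss of information,
#' into sibling hyperarcs that share the full substrate set, the reaction
#' group id, the weight and the category, but keep one product each. A
#' reversible reaction is first split into two directed reactions whose ids
#' get the suffixes `__f` and `__r`, each carrying the full reaction weight
#' (the model is purely directional).
#'
#' @param reactions raw reaction set: `data.frame` with columns `reaction_id`,
#'   `substrates` (list column of compound ids), `products` (list column),
#'   `reversible` (logical). See [readNetworkTable()].
#' @param organism organism id hosting the reactions.
#' @param weight arc weight applied to every produced hyperarc.
#' @param category arc category, usually `"endogenous"` or `"insertion"`.
#' @return A [Hypergraph-class] whose arcs all have exactly one target.
#' @examples
#' rxn <- data.frame(reaction_id = "r1", reversible = FALSE)
#' rxn$substrates <- list(c("a", "b")); rxn$products <- list(c("c", "d"))
#' H <- decomposeReactions(rxn, organism = "org", weight = 1)
#' nrow(hyperarcs(H))  # 2 sibling arcs {a,b}->c and {a,b}->d
#' @export
decomposeReactions <- function(reactions, organism, weight = 1,
                               category = "endogenous") {
  bad <- lengths(reactions$substrates) == 0L | lengths(reactions$products) == 0L
  if (any(bad))
    stop("reaction(s) with empty substrate or product list: ",
         paste(reactions$reaction_id[bad], collapse = ", "), call. = FALSE)
  if (anyDuplicated(reactions$reaction_id))
    stop("duplicate reaction ids: ",
         paste(unique(reactions$reaction_id[duplicated(reactions$reaction_id)]),
               collapse = ", "), call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(reactions))) {
    rid <- reactions$reaction_id[i]
    subs <- reactions$substrates[[i]]
    prods <- reactions$products[[i]]
    dirs <- if (isTRUE(reactions$reversible[i])) {
      list(list(id = paste0(rid, "__f"), s = subs, p = prods),
           list(id = paste0(rid, "__r"), s = prods, p = subs))
    } else {
      list(list(id = rid, s = subs, p = prods))
    }
    for (d in dirs) {
      for (p in d$p) {
        aid <- if (length(d$p) > 1L) paste0(d$id, ":", p) else d$id
        rows[[length(rows) + 1L]] <-
          arcRow(id = paste0(aid, "@", organism), reaction = d$id,
                 sources = vertexId(d$s, organism),
                 target = vertexId(p, organism),
                 weight = weight, category = category, organism = organism)
      }
    }
  }
  arcs <- if (length(rows)) do.call(rbind, rows) else emptyArcs()
  Hypergraph(arcs = arcs)
}

#' Forward closure of a vertex set under selected hyperarcs
#'
#' The closure of X under a set of hyperarcs A' is the least fixpoint obtained
#' by starting from X and repeatedly firing any selected arc whose sources are
#' all already available, adding its target. It is the set of compounds the
#' reactions in A' can produce using only X as input; a tentacular arc fires
#' only once *all* its substrates are available. The result does not depend on
#' the iteration order; the closure operator is monotone and idempotent.
#'
#' @param x a [Hypergraph-class] or [ConsortiumInstance-class].
#' @param arcIds hyperarc ids to fire.
#' @param start character vector of starting vertex ids (X).
#' @return Sorted character vector of reachable vertex ids (a superset of
#'   `start`).
#' @export
setMethod("closure", "Hypergraph", function(x, arcIds, start) {
  cc <- .compileHypergraph(x)
  avail <- .closureIdx(cc, .arcIndex(cc, arcIds), .vertexIndex(cc, start))
  cc$vid[avail]
})

#' @rdname closure
#' @export
setMethod("closure", "ConsortiumInstance",
          function(x, arcIds, start) closure(x@hypergraph, arcIds, start))

#' Rootedness of a hyperarc set
#'
#' A hyperarc set A' is rooted at S when there exists an ordering
#' (a_1, ..., a_m) of its arcs such that the sources of each a_i are contained
#' in S together with the targets of the earlier arcs. Operationally the
#' ordering is found by a greedy schedule (fire any arc whose substrates are
#' available); greedy is complete because firing an enabled arc never disables
#' another.
#'
#' @param x a [Hypergraph-class] or [ConsortiumInstance-class].
#' @param arcIds hyperarc ids forming the candidate set A'.
#' @param sources character vector of root vertex ids S; defaults to
#'   `sources(x)` for instances.
#' @return A list with elements `rooted` (logical) and `ordering` (character
#'   witness ordering when rooted, otherwise NULL). The empty set is rooted
#'   with an empty ordering.
#' @export
setMethod("isRooted", "Hypergraph", function(x, arcIds, sources) {
  cc <- .compileHypergraph(x)
  ord <- .greedyOrderIdx(cc, .arcIndex(cc, arcIds), .vertexIndex(cc, sources))
  if (is.null(ord)) list(rooted = FALSE, ordering = NULL)
  else list(rooted = TRUE, ordering = cc$arc_id[ord])
})

#' @rdname isRooted
#' @export
setMethod("isRooted", "ConsortiumInstance", function(x, arcIds, sources) {
  if (missing(sources)) sources <- x@sources
  isRooted(x@hypergraph, arcIds, sources)
})

#' Total weight and category breakdown of an arc set
#'
#' Sums the weights of the given hyperarcs and counts them per category
#' (endogenous / insertion / transition). With `perReaction = TRUE`, sibling
#' arcs stemming from one decomposed multi-product reaction (same reaction
#' group id within one organism) are counted and weighted once per reaction
#' instead of once per arc; the two conventions coincide for single-product
#' reactions, and the per-arc convention (the default) is what the solver
#' optimises.
#'
#' @param x a [Hypergraph-class] or [ConsortiumInstance-class].
#' @param arcIds hyperarc ids.
#' @param perReaction count sibling arcs once per reaction group.
#' @return list with `weight` (number) and `breakdown` (named integer counts).
#' @export
setMethod("solutionWeight", "Hypergraph",
          function(x, arcIds, perReaction = FALSE) {
  cc <- .compileHypergraph(x)
  idx <- .arcIndex(cc, arcIds)
  if (perReaction) {
    keep <- !duplicated(paste(cc$arc_reaction[idx], cc$arc_org[idx]))
    w <- sum(cc$arc_w[idx[keep]])
  } else {
    w <- sum(cc$arc_w[idx])
  }
  list(weight = w, breakdown = .breakdownIdx(cc, idx, perReaction))
})

#' @rdname solutionWeight
#' @export
setMethod("solutionWeight", "ConsortiumInstance",
          function(x, arcIds, perReaction = FALSE)
            solutionWeight(x@hypergraph, arcIds, perReaction))

#' @rdname SolutionHypertree-class
#' @param x a `SolutionHypertree`.
#' @export
setMethod("solutionArcs", "SolutionHypertree", function(x) x@arcs)

#' @rdname SolutionHypertree-class
#' @export
setMethod("arcOrdering", "SolutionHypertree", function(x) x@ordering)

#' @rdname SolutionHypertree-class
#' @export
setMethod("totalWeight", "SolutionHypertree", function(x) x@totalWeight)

#' @rdname SolutionHypertree-class
#' @export
setMethod("breakdown", "SolutionHypertree", function(x) x@breakdown)

#' @rdname DshOutcome-class
#' @param x a `DshOutcome`.
#' @export
setMethod("solverStatus", "DshOutcome", function(x) x@status)

#' @rdname DshOutcome-class
#' @export
setMethod("optimalWeight", "DshOutcome", function(x) x@optimalWeight)

#' @rdname DshOutcome-class
#' @export
setMethod("solutions", "DshOutcome", function(x) x@solutions)

#' Validate a solution against an instance
#'
#' Checks the structural invariants every solver output must satisfy: the arc
#' set is rooted at the sources (the stored ordering is a valid witness), all
#' targets are covered (`T` is contained in the targets of the arc set, up to
#' `allowSourceTargets`), the weight and breakdown are consistent, the set is
#' inclusion-minimal, and its single-source part is a forest (every vertex has
#' at most one incoming plain arc) whose leaves lie in the extended target
#' set.
#'
#' @param instance a [ConsortiumInstance-class].
#' @param solution a [SolutionHypertree-class].
#' @param allowSourceTargets treat targets that are sources as satisfied.
#' @return TRUE invisibly; otherwise an error describing the violation.
#' @export
validateSolution <- function(instance, solution, allowSourceTargets = FALSE) {
  cc <- .compileHypergraph(instance@hypergraph)
  idx <- .arcIndex(cc, solution@arcs)
  sIdx <- .vertexIndex(cc, instance@sources)
  tIdx <- .vertexIndex(cc, instance@targets)

  # ordering witnesses rootedness
  ordIdx <- .arcIndex(cc, solution@ordering)
  if (!setequal(ordIdx, idx))
    stop("ordering is not a permutation of the solution arcs")
  avail <- logical(cc$n); avail[sIdx] <- TRUE
  for (a in ordIdx) {
    if (!all(avail[cc$arc_src[[a]]]))
      stop("ordering is not a valid rootedness witness at arc ",
           cc$arc_id[a])
    avail[cc$arc_tgt[a]] <- TRUE
  }
  if (!.coversIdx(cc, idx, tIdx, sIdx, allowSourceTargets))
    stop("solution does not cover all targets")
  if (!isTRUE(all.equal(sum(cc$arc_w[idx]), solution@totalWeight)))
    stop("stored totalWeight does not match the member arc weights")
  # inclusion-minimality
  for (a in idx) {
    if (.isFeasibleSetIdx(cc, setdiff(idx, a), sIdx, tIdx, allowSourceTargets))
      stop("solution is not inclusion-minimal: arc ", cc$arc_id[a],
           " is redundant")
  }
  # Single-source part is a forest with leaves in T' (T plus the tentacular
  # sources): every vertex has at most one incoming plain arc.
  plain <- idx[!cc$arc_tent[idx]]
  tent <- idx[cc$arc_tent[idx]]
  if (anyDuplicated(cc$arc_tgt[plain]))
    stop("single-source part is not a forest: a vertex has two incoming arcs")
  tPrime <- unique(c(tIdx, unlist(cc$arc_src[tent])))
  heads <- cc$arc_tgt[plain]
  tails <- vapply(cc$arc_src[plain], `[`, integer(1), 1L)
  leaves <- setdiff(heads, tails)
  if (!all(leaves %in% tPrime))
    stop("single-source part has a leaf outside the extended target set")
  invisible(TRUE)
}
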