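#' Lossless pre-solve compression of a DSH instance
#'
#' Shrinks an instance without changing the optimal DSH weight, by three
#' provably lossless reductions:
#' \enumerate{
#'   \item vertices outside the closure of S under all arcs can never be
#'     produced; they are removed together with every arc that needs them
#'     (arcs whose substrates cannot all be made can never fire);
#'   \item vertices that are not backward-useful -- not reachable from T in
#'     the reversed relation "v is a source of an arc whose target is
#'     useful" -- cannot contribute to any inclusion-minimal solution; they
#'     and the arcs producing them are removed;
#'   \item chains u -> v -> x are contracted into a single composite arc
#'     u -> x of summed weight when v is unprotected, has exactly one
#'     incoming and one outgoing arc, both single-source, is not a source or
#'     target of any tentacular arc, and u != x. Any minimal solution uses
#'     the two chain arcs together or not at all, so contraction is a
#'     bijection on minimal solutions.
#' }
#' Protected vertices (at least S and T) are never removed or contracted
#' away. Solutions of the compressed instance are restored to the original
#' one by [expandSolution()] via the returned [ExpansionMap-class].
#'
#' @param x a [ConsortiumInstance-class].
#' @param protect vertex ids that must survive; must contain the sources and
#'   targets (the default).
#' @param ... unused.
#' @return list with `instance` (the compressed [ConsortiumInstance-class])
#'   and `map` (an [ExpansionMap-class]).
#' @export
setMethod("compressInstance", "ConsortiumInstance",
          function(x, protect = c(x@sources, x@targets), ...) {
  if (!all(c(x@sources, x@targets) %in% protect))
    stop("protect must contain all sources and targets")
  cc <- .compileHypergraph(x@hypergraph)
  sIdx <- .vertexIndex(cc, x@sources)
  protIdx <- .vertexIndex(cc, unique(protect))

  # (i) forward pruning: arcs that can never fire, vertices never produced
  clo <- .closureIdx(cc, seq_len(cc$m), sIdx)
  tIdx <- .vertexIndex(cc, x@targets)
  if (!all(clo[tIdx]))
    stop("infeasible instance: target(s) ",
         paste(cc$vid[tIdx[!clo[tIdx]]], collapse = ", "),
         " cannot be produced from the sources", call. = FALSE)
  fireable <- vapply(seq_len(cc$m),
                     function(a) all(clo[cc$arc_src[[a]]]), logical(1))

  # (ii) backward usefulness from T over fireable arcs
  useful <- logical(cc$n)
  useful[tIdx] <- TRUE
  repeat {
    grew <- FALSE
    for (a in which(fireable)) {
      if (useful[cc$arc_tgt[a]] && !all(useful[cc$arc_src[[a]]])) {
        useful[cc$arc_src[[a]]] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  keepArc <- fireable & useful[cc$arc_tgt]
  keepV <- (clo & useful)
  keepV[protIdx] <- TRUE

  arcs <- x@hypergraph@arcs
  arcs <- arcs[arcs$id %in% cc$arc_id[keepArc], , drop = FALSE]
  verts <- x@hypergraph@vertices
  verts <- verts[verts$id %in% cc$vid[keepV], , drop = FALSE]

  # (iii) chain contraction
  expansion <- list()
  expandId <- function(id) {
    if (!is.null(expansion[[id]])) expansion[[id]] else id
  }
  repeat {
    srcs1 <- vapply(arcs$sources, function(s)
      if (length(s) == 1L) s else NA_character_, character(1))
    tentTouch <- unique(c(unlist(arcs$sources[is.na(srcs1)]),
                          arcs$target[is.na(srcs1)]))
    inCount <- table(arcs$target)
    outCount <- table(srcs1[!is.na(srcs1)])
    contracted <- FALSE
    for (v in .csort(setdiff(verts$id, unique(protect)))) {
      if (v %in% tentTouch) next
      if (is.na(inCount[v]) || inCount[v] != 1L) next
      if (is.na(outCount[v]) || outCount[v] != 1L) next
      ain <- which(arcs$target == v)
      aout <- which(!is.na(srcs1) & srcs1 == v)
      if (length(ain) != 1L || length(aout) != 1L) next
      if (is.na(srcs1[ain])) next  # incoming arc is tentacular
      u <- srcs1[ain]; xv <- arcs$target[aout]
      if (u == xv) next
      members <- c(expandId(arcs$id[ain]), expandId(arcs$id[aout]))
      nid <- paste0("cmp:", paste(members, collapse = "+"))
      newArc <- arcRow(id = nid, reaction = nid, sources = u, target = xv,
                       weight = arcs$weight[ain] + arcs$weight[aout],
                       category = "composite",
                       organism = arcs$organism[ain])
      expansion[[nid]] <- members
      expansion[[arcs$id[ain]]] <- NULL
      expansion[[arcs$id[aout]]] <- NULL
      arcs <- rbind(arcs[-c(ain, aout), , drop = FALSE], newArc)
      verts <- verts[verts$id != v, , drop = FALSE]
      contracted <- TRUE
      break
    }
    if (!contracted) break
  }
  rownames(arcs) <- NULL; rownames(verts) <- NULL
  inst <- new("ConsortiumInstance",
              hypergraph = Hypergraph(vertices = verts, arcs = arcs),
              sources = x@sources, targets = x@targets,
              weights = x@weights, workerOrganisms = x@workerOrganisms,
              referenceReactions = x@referenceReactions)
  list(instance = inst, map = new("ExpansionMap", map = expansion))
})

#' Expand a compressed-instance solution back to the original instance
#'
#' Replaces every composite arc by the ordered chain of original arcs it
#' stands for, recomputes a rootedness witness on the original instance and
#' verifies that the expanded solution covers the targets at unchanged total
#' weight.
#'
#' @param solution a [SolutionHypertree-class] solving the compressed
#'   instance.
#' @param map the [ExpansionMap-class] returned by [compressInstance()].
#' @param instance the *original* [ConsortiumInstance-class].
#' @param allowSourceTargets see [solveDsh()].
#' @return A [SolutionHypertree-class] on the original instance.
#' @export
expandSolution <- function(solution, map, instance,
                           allowSourceTargets = FALSE) {
  cc <- .compileHypergraph(instance@hypergraph)
  ids <- character(0)
  for (a in solution@arcs) {
    if (!is.null(map@map[[a]])) ids <- c(ids, map@map[[a]])
    else if (a %in% cc$arc_id) ids <- c(ids, a)
    else stop("arc '", a, "' is neither in the expansion map nor in the ",
              "original instance", call. = FALSE)
  }
  idx <- sort(unique(.arcIndex(cc, ids)))
  sIdx <- .vertexIndex(cc, instance@sources)
  tIdx <- .vertexIndex(cc, instance@targets)
  sol <- .solutionFromIdx(cc, idx, sIdx)
  if (!isTRUE(all.equal(sol@totalWeight, solution@totalWeight)))
    stop("expansion changed the total weight (", solution@totalWeight,
         " -> ", sol@totalWeight, ")", call. = FALSE)
  if (!.coversIdx(cc, idx, tIdx, sIdx, allowSourceTargets))
    stop("expanded solution does not cover the targets", call. = FALSE)
  sol
}
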