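#' Build a raw reaction set programmatically
#'
#' The raw reaction-set form carried through the pipeline: one row per
#' reaction with list columns of substrate and product compound ids and a
#' reversibility flag. [readNetworkTable()] and [readSBML()] produce the
#' same shape from files.
#'
#' @param reaction_id character vector of reaction ids.
#' @param substrates,products lists of character vectors (one per reaction).
#' @param reversible logical vector (recycled from length 1).
#' @return a raw reaction set `data.frame`.
#' @examples
#' reactionSet("r1", list(c("a", "b")), list("c"))
#' @export
reactionSet <- function(reaction_id, substrates, products,
                        reversible = FALSE) {
  .reactionSet(reaction_id, substrates, products, reversible)
}

#' Merge worker networks into a consortium instance
#'
#' Performs the disjoint union of the per-organism metabolic networks: each
#' organism keeps its own copy of every compound (vertex ids are
#' `"compound@organism"`), reversible reactions are split into two directed
#' reactions, multi-product reactions are decomposed into single-target
#' sibling arcs, and every endogenous arc gets weight `wWorker` (or a
#' per-reaction override). No cross-organism arcs exist yet; see
#' [addTransitionArcs()] and [addInsertionArcs()].
#'
#' @param networks named list, one raw reaction set per worker organism (names
#'   are the organism ids). A raw reaction set is a `data.frame` with columns
#'   `reaction_id`, `substrates` (list column), `products` (list column),
#'   `reversible` — as returned by [readNetworkTable()] or [readSBML()].
#' @param weights a [WeightConfig-class].
#' @param sources,targets optional character vectors of vertex ids to record
#'   as S and T. When `targets` is empty a placeholder-free instance cannot be
#'   validated, so targets may also be set later via [setTerminals()].
#' @return A [ConsortiumInstance-class].
#' @export
mergeWorkerNetworks <- function(networks, weights = WeightConfig(),
                                sources = character(0),
                                targets = character(0)) {
  if (length(networks) < 1L) stop("at least one worker network is required")
  orgs <- names(networks)
  if (is.null(orgs) || any(!nzchar(orgs)))
    stop("networks must be a named list (organism ids as names)")
  if (anyDuplicated(orgs))
    stop("duplicate organism id(s): ",
         paste(unique(orgs[duplicated(orgs)]), collapse = ", "))
  empty <- vapply(networks, function(nw) nrow(nw) == 0L, logical(1))
  if (any(empty))
    stop("empty network(s) for organism(s): ",
         paste(orgs[empty], collapse = ", "))
  parts <- lapply(orgs, function(o) {
    H <- decomposeReactions(networks[[o]], organism = o,
                            weight = weights@wWorker,
                            category = "endogenous")
    a <- H@arcs
    if (nrow(weights@overrides)) {
      for (i in seq_len(nrow(a))) {
        a$weight[i] <- .weightFor(weights, "endogenous", a$reaction[i])
      }
    }
    a
  })
  arcs <- do.call(rbind, parts)
  H <- Hypergraph(arcs = arcs)
  new("ConsortiumInstance", hypergraph = H,
      sources = sources, targets = targets,
      weights = weights, workerOrganisms = orgs,
      referenceReactions = character(0))
}

#' Set or replace the source and target vertex sets of an instance
#'
#' @param instance a [ConsortiumInstance-class].
#' @param sources,targets character vectors of vertex ids.
#' @return the updated instance (validated).
#' @export
setTerminals <- function(instance, sources = instance@sources,
                         targets = instance@targets) {
  instance@sources <- sources
  instance@targets <- targets
  validObject(instance)
  instance
}

#' Add insertion copies of reference reactions
#'
#' For every worker organism and every reference reaction the organism does
#' not already carry (matched by exact reaction id), a copy of the reaction is
#' inserted into that organism with weight `wOther` (or a per-reaction
#' override) and category `"insertion"`; compound vertices missing from the
#' organism are created. Insertion models heterologous expression of the
#' reference organism's enzyme in the worker.
#'
#' @param instance a [ConsortiumInstance-class] built by
#'   [mergeWorkerNetworks()].
#' @param referenceReactions raw reaction set of the reference organisms (the
#'   union A_o of their reactions).
#' @param weights a [WeightConfig-class]; defaults to the instance's.
#' @return the updated [ConsortiumInstance-class].
#' @export
addInsertionArcs <- function(instance, referenceReactions,
                             weights = instance@weights) {
  if (nrow(referenceReactions) == 0L) return(instance)
  arcs <- instance@hypergraph@arcs
  refIds <- character(0)
  newParts <- list()
  for (o in instance@workerOrganisms) {
    have <- unique(arcs$reaction[arcs$organism == o &
                                   arcs$category == "endogenous"])
    Href <- decomposeReactions(referenceReactions, organism = o,
                               weight = weights@wOther,
                               category = "insertion")
    aref <- Href@arcs
    keep <- !(aref$reaction %in% have)
    aref <- aref[keep, , drop = FALSE]
    if (nrow(aref)) {
      for (i in seq_len(nrow(aref)))
        aref$weight[i] <- .weightFor(weights, "insertion", aref$reaction[i])
      newParts[[o]] <- aref
    }
    refIds <- unique(c(refIds, Href@arcs$reaction))
  }
  allArcs <- do.call(rbind, c(list(arcs), unname(newParts)))
  instance@hypergraph <- Hypergraph(arcs = allArcs)
  instance@referenceReactions <- .csort(refIds)
  instance@weights <- weights
  if (length(instance@targets)) validObject(instance)
  instance
}

#' Add transition (transport) arcs between organisms
#'
#' For every compound hosted (after insertions) by two distinct worker
#' organisms, two directed single-source arcs are added, one per direction,
#' modelling the transport of that compound across the consortium. Each costs
#' `wTransition` unless a per-compound override applies (e.g. a cheaper
#' transport for acetate). No self-transitions are created.
#'
#' @param instance a [ConsortiumInstance-class].
#' @param weights a [WeightConfig-class]; defaults to the instance's.
#' @return the updated [ConsortiumInstance-class].
#' @export
addTransitionArcs <- function(instance, weights = instance@weights) {
  v <- instance@hypergraph@vertices
  rows <- list()
  cmp <- split(v, v$compound)
  for (compound in names(cmp)) {
    hosts <- .csort(unique(cmp[[compound]]$organism))
    if (length(hosts) < 2L) next
    for (i in seq_along(hosts)) for (j in seq_along(hosts)) {
      if (i == j) next
      from <- hosts[i]; to <- hosts[j]
      rid <- paste0("tr:", compound, ":", from, "->", to)
      rows[[length(rows) + 1L]] <-
        arcRow(id = rid, reaction = rid,
               sources = vertexId(compound, from),
               target = vertexId(compound, to),
               weight = .weightFor(weights, "transition", compound),
               category = "transition",
               organism = paste0(from, "->", to))
    }
  }
  if (length(rows)) {
    arcs <- do.call(rbind, c(list(instance@hypergraph@arcs), rows))
    instance@hypergraph <- Hypergraph(vertices = instance@hypergraph@vertices,
                                      arcs = arcs)
  }
  instance@weights <- weights
  if (length(instance@targets)) validObject(instance)
  instance
}

#' Remove cofactors from a raw reaction set
#'
#' Ubiquitous cofactors and co-enzymes (ATP, NADH, water, ...) would connect
#' essentially every reaction to every other and must be removed before the
#' topological analysis. Listed compounds are deleted from all substrate and
#' product lists; reactions left with an empty substrate or product list are
#' dropped and reported.
#'
#' @param network raw reaction set (`data.frame` with `reaction_id`,
#'   `substrates`, `products`, `reversible`).
#' @param cofactorIds character vector of compound ids to remove (see
#'   [readCofactorList()]).
#' @return list with `network` (the filtered reaction set) and `dropped`
#'   (`data.frame` of dropped reactions and the reason).
#' @export
removeCofactors <- function(network, cofactorIds) {
  if (length(cofactorIds) == 0L)
    return(list(network = network,
                dropped = data.frame(reaction_id = character(0),
                                     reason = character(0),
                                     stringsAsFactors = FALSE)))
  network$substrates <- lapply(network$substrates,
                               function(s) setdiff(s, cofactorIds))
  network$products <- lapply(network$products,
                             function(p) setdiff(p, cofactorIds))
  emptyS <- lengths(network$substrates) == 0L
  emptyP <- lengths(network$products) == 0L
  drop <- emptyS | emptyP
  dropped <- data.frame(
    reaction_id = network$reaction_id[drop],
    reason = ifelse(emptyS[drop], "no substrate left", "no product left"),
    stringsAsFactors = FALSE)
  list(network = network[!drop, , drop = FALSE], dropped = dropped)
}

#' Build a full consortium instance in one call
#'
#' Convenience pipeline: cofactor removal per network, [mergeWorkerNetworks()],
#' [addInsertionArcs()] (when reference reactions are given),
#' [addTransitionArcs()] (when there are at least two organisms), then
#' terminal assignment. Sources and targets are given as compound ids plus an
#' organism, or directly as vertex ids.
#'
#' @param networks named list of raw reaction sets (one per worker organism).
#' @param sources,targets character vectors of vertex ids
#'   (`"compound@organism"`).
#' @param referenceReactions optional raw reaction set of reference organisms.
#' @param weights a [WeightConfig-class].
#' @param cofactorIds compounds removed from every network before assembly.
#' @return A [ConsortiumInstance-class].
#' @export
buildInstance <- function(networks, sources, targets,
                          referenceReactions = NULL,
                          weights = WeightConfig(),
                          cofactorIds = character(0)) {
  networks <- lapply(networks,
                     function(nw) removeCofactors(nw, cofactorIds)$network)
  inst <- mergeWorkerNetworks(networks, weights)
  if (!is.null(referenceReactions) && nrow(referenceReactions) > 0L) {
    refs <- removeCofactors(referenceReactions, cofactorIds)$network
    inst <- addInsertionArcs(inst, refs)
  }
  if (length(inst@workerOrganisms) >= 2L)
    inst <- addTransitionArcs(inst)
  setTerminals(inst, sources = sources, targets = targets)
}
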