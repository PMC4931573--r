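#' Directed metabolic hypergraph
#'
#' A directed hypergraph H(V, A). Vertices are (compound, organism) pairs: the
#' same chemical species hosted by two organisms is two distinct vertices.
#' Hyperarcs are single-target after multi-product decomposition (see
#' [decomposeReactions()]): each has a non-empty set of source vertices (the
#' substrates), exactly one target vertex (one product), a non-negative weight
#' and a category. A hyperarc with more than one source is called
#' *tentacular*; its number of sources is its *spreadness*.
#'
#' @slot vertices `data.frame` with columns `id`, `compound`, `organism`.
#'   Vertex ids follow the `"compound@organism"` convention (see
#'   [vertexId()]) and are unique.
#' @slot arcs `data.frame` with columns `id`, `reaction` (group id shared by
#'   sibling arcs of one decomposed multi-product reaction), `sources` (list
#'   column of vertex ids), `target` (vertex id), `weight`, `category` (one of
#'   `"endogenous"`, `"insertion"`, `"transition"`, `"composite"`), `organism`
#'   (organism id; `"from->to"` for transitions; `"composite"` arcs produced by
#'   [compressInstance()] keep the organism of their first member).
#'
#' @seealso [ConsortiumInstance-class], [spreadness()], [closure()],
#'   [isRooted()]
#' @export
setClass("Hypergraph",
  representation(vertices = "data.frame", arcs = "data.frame"))

.arcCategories <- c("endogenous", "insertion", "transition", "composite")

setValidity("Hypergraph", function(object) {
  v <- object@vertices
  a <- object@arcs
  msg <- character(0)
  need_v <- c("id", "compound", "organism")
  need_a <- c("id", "reaction", "sources", "target", "weight", "category",
              "organism")
  if (!all(need_v %in% names(v)))
    return(paste("vertices must have columns:", paste(need_v, collapse = ", ")))
  if (!all(need_a %in% names(a)))
    return(paste("arcs must have columns:", paste(need_a, collapse = ", ")))
  if (anyDuplicated(v$id)) msg <- c(msg, "duplicated vertex ids")
  if (anyDuplicated(a$id)) msg <- c(msg, "duplicated hyperarc ids")
  if (nrow(a)) {
    ns <- lengths(a$sources)
    if (any(ns < 1L)) msg <- c(msg, "every hyperarc needs at least one source")
    if (any(is.na(a$weight)) || any(a$weight < 0))
      msg <- c(msg, "hyperarc weights must be non-negative")
    if (!all(a$category %in% .arcCategories))
      msg <- c(msg, paste("unknown hyperarc category; must be one of",
                          paste(.arcCategories, collapse = ", ")))
    refs <- unique(c(unlist(a$sources), a$target))
    if (!all(refs %in% v$id))
      msg <- c(msg, "hyperarc endpoints must be declared vertices")
    tr <- a$category == "transition"
    if (any(tr)) {
      if (any(ns[tr] != 1L))
        msg <- c(msg, "transition arcs must have exactly one source")
      src1 <- vapply(a$sources[tr], `[`, character(1), 1L)
      vs <- v[match(src1, v$id), ]
      vt <- v[match(a$target[tr], v$id), ]
      if (any(vs$compound != vt$compound, na.rm = TRUE))
        msg <- c(msg, "transition arcs must move a single compound")
      if (any(vs$organism == vt$organism, na.rm = TRUE))
        msg <- c(msg, "transition arcs must join two distinct organisms")
    }
    # sibling arcs (same reaction id within one organism) share source set,
    # weight, category and organism; the same reaction id may also appear as
    # an insertion copy in several organisms
    grp <- paste(a$reaction, a$organism)
    dup <- grp[duplicated(grp)]
    for (r in unique(dup)) {
      sib <- a[grp == r, ]
      key <- vapply(sib$sources,
                    function(s) paste(.csort(s), collapse = "|"), character(1))
      if (length(unique(key)) != 1L ||
          length(unique(sib$weight)) != 1L ||
          length(unique(sib$category)) != 1L ||
          length(unique(sib$organism)) != 1L) {
        msg <- c(msg, sprintf("sibling arcs of reaction '%s' disagree", r))
        break
      }
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Build a vertex id from compound and organism
#'
#' Vertex ids are the stable string `"compound@organism"`.
#'
#' @param compound character vector of compound identifiers.
#' @param organism character vector of organism identifiers.
#' @return character vector of vertex ids.
#' @export
vertexId <- function(compound, organism) paste0(compound, "@", organism)

#' Construct a Hypergraph
#'
#' @param vertices `data.frame` with columns `id`, `compound`, `organism`, or
#'   NULL to derive vertices from `"compound@organism"` arc endpoints.
#' @param arcs `data.frame` as described in [Hypergraph-class].
#' @return A validated [Hypergraph-class] object.
#' @export
Hypergraph <- function(vertices = NULL, arcs = emptyArcs()) {
  if (is.null(vertices)) {
    ids <- .csort(unique(c(unlist(arcs$sources), arcs$target)))
    parts <- strsplit(ids, "@", fixed = TRUE)
    vertices <- data.frame(
      id = ids,
      compound = vapply(parts, `[`, character(1), 1L),
      organism = vapply(parts, function(p) paste(p[-1], collapse = "@"),
                        character(1)),
      stringsAsFactors = FALSE)
  }
  rownames(vertices) <- NULL
  rownames(arcs) <- NULL
  new("Hypergraph", vertices = vertices, arcs = arcs)
}

#' @rdname Hypergraph
#' @export
emptyArcs <- function() {
  data.frame(id = character(0), reaction = character(0),
             sources = I(list()), target = character(0),
             weight = numeric(0), category = character(0),
             organism = character(0), stringsAsFactors = FALSE)
}

#' Weight configuration for consortium instances
#'
#' Holds the three category weights and optional per-compound or per-reaction
#' overrides. Endogenous reactions of worker organisms cost `wWorker`
#' (default 1), heterologous insertions of reference reactions cost `wOther`
#' (default 100), and cross-organism transports cost `wTransition`
#' (default 100). Keeping `wWorker` small but positive makes optima also
#' minimise the number of endogenous reactions used, while `wOther` and
#' `wTransition` dominate so insertions and transports are bought only when
#' necessary. Overrides refine single weights, e.g. a cheaper transport for
#' organic acids such as acetate.
#'
#' @slot wWorker non-negative number, weight of endogenous worker reactions.
#' @slot wOther non-negative number, weight of inserted reference reactions.
#' @slot wTransition non-negative number, weight of transport arcs.
#' @slot overrides `data.frame` with columns `category` (`"transition"` keys on
#'   the compound; `"endogenous"`/`"insertion"` key on the reaction id), `key`,
#'   `weight`.
#' @export
setClass("WeightConfig",
  representation(wWorker = "numeric", wOther = "numeric",
                 wTransition = "numeric", overrides = "data.frame"))

setValidity("WeightConfig", function(object) {
  w <- c(object@wWorker, object@wOther, object@wTransition)
  if (length(w) != 3L || any(is.na(w)) || any(w < 0))
    return("wWorker, wOther and wTransition must be single non-negative numbers")
  ov <- object@overrides
  if (!all(c("category", "key", "weight") %in% names(ov)))
    return("overrides must have columns category, key, weight")
  if (nrow(ov) && (any(ov$weight < 0) ||
                   !all(ov$category %in% c("endogenous", "insertion", "transition"))))
    return("override weights must be non-negative and categories valid")
  TRUE
})

#' @rdname WeightConfig-class
#' @param wWorker,wOther,wTransition category weights.
#' @param overrides `data.frame(category, key, weight)`; a convenience list of
#'   the form `list(transition = c(acetate = 50))` is also accepted.
#' @return A [WeightConfig-class].
#' @examples
#' WeightConfig()                                  # the default 1/100/100
#' WeightConfig(overrides = list(transition = c(acetate = 50)))
#' @export
WeightConfig <- function(wWorker = 1, wOther = 100, wTransition = 100,
                         overrides = NULL) {
  if (is.null(overrides)) {
    overrides <- data.frame(category = character(0), key = character(0),
                            weight = numeric(0), stringsAsFactors = FALSE)
  } else if (is.list(overrides) && !is.data.frame(overrides)) {
    overrides <- do.call(rbind, lapply(names(overrides), function(cat) {
      v <- overrides[[cat]]
      data.frame(category = cat, key = names(v), weight = as.numeric(v),
                 stringsAsFactors = FALSE)
    }))
  }
  rownames(overrides) <- NULL
  new("WeightConfig", wWorker = wWorker, wOther = wOther,
      wTransition = wTransition, overrides = overrides)
}

#' A Directed Steiner Hypertree instance
#'
#' The full input of the consortium-design problem: the merged hypergraph over
#' all worker organisms (endogenous reactions, insertion copies of reference
#' reactions, transition arcs), the source vertex set S, the target vertex set
#' T, the weight configuration and provenance of the reference reaction set.
#'
#' @slot hypergraph the [Hypergraph-class].
#' @slot sources character, vertex ids of available source compounds.
#' @slot targets character, vertex ids of the compounds to produce (non-empty).
#' @slot weights the [WeightConfig-class] used to weight the arcs.
#' @slot workerOrganisms character, the candidate consortium members.
#' @slot referenceReactions character, reaction ids of the reference set used
#'   for insertion copies (provenance record, possibly empty).
#' @export
setClass("ConsortiumInstance",
  representation(hypergraph = "Hypergraph", sources = "character",
                 targets = "character", weights = "WeightConfig",
                 workerOrganisms = "character",
                 referenceReactions = "character"))

setValidity("ConsortiumInstance", function(object) {
  v <- object@hypergraph@vertices$id
  if (!all(object@sources %in% v)) return("sources must be vertices")
  if (!all(object@targets %in% v)) return("targets must be vertices")
  if (anyDuplicated(object@workerOrganisms))
    return("worker organism ids must be distinct")
  TRUE
})
# A ready-to-solve instance needs a non-empty target set; emptiness is only
# allowed while an instance is being staged (merge, insertions, transitions),
# and the solvers refuse it.

#' A rooted hyperarc set solving (part of) a DSH instance
#'
#' An arc set A' together with a witness ordering proving rootedness at the
#' sources (every arc's substrates are supplied by S or by targets of earlier
#' arcs), its total weight and the per-category arc counts.
#'
#' @slot arcs character, hyperarc ids (A').
#' @slot ordering character, a permutation of `arcs` witnessing rootedness.
#' @slot totalWeight non-negative number, sum of member arc weights.
#' @slot breakdown named integer, arc counts per category.
#' @export
setClass("SolutionHypertree",
  representation(arcs = "character", ordering = "character",
                 totalWeight = "numeric", breakdown = "integer"))

setValidity("SolutionHypertree", function(object) {
  if (!setequal(object@ordering, object@arcs) ||
      length(object@ordering) != length(object@arcs))
    return("ordering must be a permutation of arcs")
  if (length(object@totalWeight) != 1L || object@totalWeight < 0)
    return("totalWeight must be a single non-negative number")
  TRUE
})

#' Result of the exact DSH solver or the brute-force oracle
#'
#' @slot status `"optimal"` or `"infeasible"`.
#' @slot optimalWeight the minimum total weight (`Inf` when infeasible).
#' @slot solutions list of [SolutionHypertree-class], deduplicated and
#'   inclusion-minimal; a single witness unless enumeration was requested.
#' @slot combinations list of character vectors: for each solution, the ordered
#'   tentacular-hyperarc combination it was reconstructed from (empty vector
#'   when the solution uses no tentacular arc; for the oracle, the tentacular
#'   members of the solution).
#' @slot truncated logical, `TRUE` when enumeration stopped at the cap.
#' @export
setClass("DshOutcome",
  representation(status = "character", optimalWeight = "numeric",
                 solutions = "list", combinations = "list",
                 truncated = "logical"))

setValidity("DshOutcome", function(object) {
  if (!object@status %in% c("optimal", "infeasible"))
    return("status must be 'optimal' or 'infeasible'")
  if (object@status == "infeasible" && length(object@solutions))
    return("infeasible outcomes carry no solutions")
  TRUE
})

#' Tentacular-free arc graph
#'
#' The ordinary weighted digraph obtained from a hypergraph by removing all
#' tentacular hyperarcs (those with more than one source). Parallel edges are
#' kept and retain their hyperarc ids.
#'
#' @slot vertices character, vertex ids.
#' @slot edges `data.frame` with columns `id`, `from`, `to`, `weight`.
#' @export
setClass("ArcGraph",
  representation(vertices = "character", edges = "data.frame"))

setValidity("ArcGraph", function(object) {
  e <- object@edges
  if (!all(c("id", "from", "to", "weight") %in% names(e)))
    return("edges must have columns id, from, to, weight")
  if (nrow(e) && !all(c(e$from, e$to) %in% object@vertices))
    return("edge endpoints must be vertices")
  if (nrow(e) && any(e$weight < 0)) return("edge weights must be non-negative")
  TRUE
})

#' Minimum-weight directed Steiner arborescence
#'
#' @slot root vertex id the tree is rooted at.
#' @slot terminals character, the terminal set X.
#' @slot weight total weight (`Inf` when some terminal is unreachable).
#' @slot arcs character, edge ids forming the witness arborescence.
#' @export
setClass("SteinerResult",
  representation(root = "character", terminals = "character",
                 weight = "numeric", arcs = "character"))

#' Ordered combination of tentacular hyperarcs with derived layers
#'
#' An ordered subset M = (a_1, ..., a_k) of tentacular hyperarcs, together with
#' the layer bookkeeping the solver derives from it: the extended target set
#' T' = T u src(M), the extended source set S' = S u tgt(M), and the layer maps
#' Layer_T (when a target must be available: the first layer whose tentacular
#' arc consumes it, k+1 for plain targets) and Layer_S (when a source becomes
#' available: 0 for members of S, else the layer producing it; S takes
#' precedence).
#'
#' @slot arcIds character, ordered tentacular hyperarc ids (possibly empty).
#' @slot tPrime character, extended targets T'.
#' @slot sPrime character, extended sources S'.
#' @slot layerT named numeric over `tPrime`.
#' @slot layerS named numeric over `sPrime`.
#' @export
setClass("OrderedCombination",
  representation(arcIds = "character", tPrime = "character",
                 sPrime = "character", layerT = "numeric", layerS = "numeric"))

#' Expansion map of a lossless compression
#'
#' Maps each composite arc id created by [compressInstance()] to the ordered
#' list of original arc ids it replaces. [expandSolution()] uses it to restore
#' solutions of the compressed instance to the original instance at identical
#' total weight.
#'
#' @slot map named list: composite arc id -> character vector of original ids.
#' @export
setClass("ExpansionMap", representation(map = "list"))
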