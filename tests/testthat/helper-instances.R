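# Shared helpers: tiny literal instances, canonical solution-set keys, and
# small independent brute-force oracles used to validate the graph
# algorithms.

# A single-organism instance from a literal arc table. Vertices are derived
# from the arc endpoints plus any extra ids (isolated sources etc.).
makeInstance <- function(arcs, sources, targets, extraVertices = character(0),
                         weights = WeightConfig()) {
  ids <- unique(c(unlist(arcs$sources), arcs$target, sources, targets,
                  extraVertices))
  parts <- strsplit(ids, "@", fixed = TRUE)
  v <- data.frame(id = ids,
                  compound = vapply(parts, `[`, character(1), 1L),
                  organism = vapply(parts, `[`, character(1), 2L),
                  stringsAsFactors = FALSE)
  H <- Hypergraph(vertices = v, arcs = arcs)
  methods::new("ConsortiumInstance", hypergraph = H,
               sources = sources, targets = targets, weights = weights,
               workerOrganisms = sort(unique(v$organism)),
               referenceReactions = character(0))
}

# canonical representation of a solution set: sorted keys of sorted arc ids
solutionKeys <- function(outcome) {
  sort(vapply(solutions(outcome),
              function(s) paste(sort(solutionArcs(s)), collapse = "|"),
              character(1)))
}

# the random-instance population used by the equivalence suites: two worker
# organisms drawing 3 compounds from a pool of 5 (or, with one reference
# reaction, 2 reactions each), at most 2 tentacular reactions, 1-3 targets;
# always within the brute-force oracle's reach (<= 12 hyperarcs)
randomOracleInstance <- function(seed) {
  withRef <- seed %% 3L == 0L
  generateRandomInstance(
    nOrganisms = 2L, nCompounds = 3L, compoundPool = 5L,
    nReactions = if (withRef) 2L else 3L,
    tentacularFraction = c(0, 0.3, 0.5)[1L + seed %% 3L],
    maxSpreadness = 2L + seed %% 2L,
    maxTentacularArcs = 2L,
    nReferenceReactions = as.integer(withRef),
    nSources = 1L + seed %% 2L,
    nTargets = 1L + seed %% 3L,
    feasible = seed %% 5L > 0L,
    seed = seed)
}

# Independent exhaustive oracle for directed Steiner arborescences: minimum
# weight over all edge subsets under which every terminal is reachable from
# the root (the minimal such subset is an arborescence). Deliberately shares
# no code with the package's dynamic program.
bruteSteinerWeight <- function(G, root, terminals) {
  e <- hyperarcs_of_graph(G)
  m <- nrow(e)
  stopifnot(m <= 14L)
  vids <- sort(unique(c(e$from, e$to, root, terminals)))
  fromI <- match(e$from, vids); toI <- match(e$to, vids)
  rootI <- match(root, vids); termI <- match(terminals, vids)
  best <- Inf
  for (msk in 0:(2^m - 1)) {
    sel <- which(bitwAnd(msk, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
    w <- sum(e$weight[sel])
    if (w >= best) next
    reach <- logical(length(vids)); reach[rootI] <- TRUE
    repeat {
      nxt <- sel[reach[fromI[sel]] & !reach[toI[sel]]]
      if (!length(nxt)) break
      reach[toI[nxt]] <- TRUE
    }
    if (all(reach[termI])) best <- w
  }
  best
}

hyperarcs_of_graph <- function(G) G@edges

# structural check of a Steiner witness: arcs form a tree oriented away from
# the root, every terminal is in the tree, every leaf is a terminal, weight
# matches
checkArborescence <- function(G, res) {
  e <- G@edges[match(res@arcs, G@edges$id), , drop = FALSE]
  if (res@weight == 0 && nrow(e) == 0L) return(TRUE)
  stopifnot(sum(e$weight) == res@weight)
  stopifnot(!anyDuplicated(e$to))          # in-degree <= 1
  reach <- res@root
  repeat {
    nxt <- e$to[e$from %in% reach & !(e$to %in% reach)]
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  stopifnot(all(e$to %in% reach), all(e$from %in% reach))  # connected
  stopifnot(all(res@terminals %in% c(reach, res@root)))
  leaves <- setdiff(e$to, e$from)
  stopifnot(all(leaves %in% res@terminals))
  TRUE
}

# random weighted multidigraph as an ArcGraph (for the Steiner suites)
randomArcGraph <- function(seed, nV = 6L, nE = 10L, maxW = 5L) {
  set.seed(seed)
  vid <- sprintf("v%d@o", seq_len(nV))
  from <- sample(vid, nE, replace = TRUE)
  to <- sample(vid, nE, replace = TRUE)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  if (!length(from)) return(randomArcGraph(seed + 1000L, nV, nE, maxW))
  edges <- data.frame(id = sprintf("e%d", seq_along(from)),
                      from = from, to = to,
                      weight = sample.int(maxW, length(from), replace = TRUE),
                      stringsAsFactors = FALSE)
  methods::new("ArcGraph", vertices = vid, edges = edges)
}
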