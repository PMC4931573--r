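#' Tentacular-free arc graph of a hypergraph
#'
#' Drops every tentacular hyperarc (spreadness > 1) and returns the remaining
#' single-source arcs as an ordinary weighted multidigraph. All Steiner-tree
#' computations of the solver run on this graph; the tentacular arcs are
#' handled separately by the ordered-combination layer.
#'
#' @param x a [Hypergraph-class] or [ConsortiumInstance-class].
#' @return An [ArcGraph-class]; edge ids are the hyperarc ids.
#' @export
setMethod("arcGraph", "Hypergraph", function(x) {
  a <- x@arcs
  keep <- lengths(a$sources) == 1L
  a <- a[keep, , drop = FALSE]
  edges <- data.frame(id = a$id,
                      from = vapply(a$sources, `[`, character(1), 1L),
                      to = a$target, weight = a$weight,
                      stringsAsFactors = FALSE)
  edges <- edges[.corder(edges$id), , drop = FALSE]
  rownames(edges) <- NULL
  new("ArcGraph", vertices = .csort(x@vertices$id), edges = edges)
})

#' @rdname arcGraph
#' @export
setMethod("arcGraph", "ConsortiumInstance", function(x) arcGraph(x@hypergraph))

# Internal graph context: integer-indexed edges over the sorted vertex ids,
# an all-pairs shortest-path matrix (igraph), and per-vertex incoming edge
# lists for path backtracking.
.graphContext <- function(vid, e_from, e_to, e_w, e_id) {
  n <- length(vid)
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (length(e_from))
    g <- igraph::add_edges(g, rbind(e_from, e_to))
  D <- igraph::distances(g, mode = "out",
                         weights = if (length(e_from)) e_w else NULL)
  inEdges <- vector("list", n)
  for (e in seq_along(e_from))
    inEdges[[e_to[e]]] <- c(inEdges[[e_to[e]]], e)
  list(vid = vid, n = n, e_from = e_from, e_to = e_to, e_w = e_w,
       e_id = e_id, D = unname(D), inEdges = inEdges)
}

.graphContextFromArcGraph <- function(G) {
  vid <- .csort(G@vertices)
  vindex <- stats::setNames(seq_along(vid), vid)
  e <- G@edges
  .graphContext(vid, unname(vindex[e$from]), unname(vindex[e$to]),
                e$weight, e$id)
}

# All shortest u -> v paths as lists of edge indices. `blocked` guards
# against zero-weight cycles; shortest simple paths are never lost by it.
.allShortestPaths <- function(gx, u, v, all = TRUE,
                              blocked = integer(0)) {
  if (u == v) return(list(integer(0)))
  if (!is.finite(gx$D[u, v])) return(list())
  out <- list()
  blocked <- c(blocked, v)
  for (e in gx$inEdges[[v]]) {
    x <- gx$e_from[e]
    if (x %in% blocked) next
    if (gx$D[u, x] + gx$e_w[e] == gx$D[u, v]) {
      for (p in .allShortestPaths(gx, u, x, all, blocked)) {
        out[[length(out) + 1L]] <- c(p, e)
        if (!all) return(out)
      }
    }
  }
  out
}

.popcount <- function(x) {
  cnt <- integer(length(x))
  while (any(x > 0)) {
    cnt <- cnt + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  cnt
}

.rowMinsList <- function(cols) {
  if (length(cols) == 0L) return(NULL)
  do.call(pmin, cols)
}

# Dreyfus-Wagner subset dynamic program. Returns the n x (2^t - 1) value
# matrix f: f[v, mask] is the minimum weight of an arborescence rooted at v
# containing all terminals of `mask` (leaves are terminals by minimality;
# terminals may be internal). Masks are bit-encoded over `termIdx` in
# sorted-vertex order.
.dwSteiner <- function(gx, termIdx) {
  t <- length(termIdx)
  full <- bitwShiftL(1L, t) - 1L
  f <- matrix(Inf, gx$n, full)
  for (j in seq_len(t))
    f[, bitwShiftL(1L, j - 1L)] <- gx$D[, termIdx[j]]
  if (t == 1L) return(f)
  pc <- .popcount(seq_len(full))
  masks <- seq_len(full)[order(pc, seq_len(full))]
  for (mask in masks) {
    if (pc[mask] < 2L) next
    g <- .dwMerge(f, mask)
    fin <- which(is.finite(g))
    if (!length(fin)) { f[, mask] <- Inf; next }
    cols <- lapply(fin, function(u) gx$D[, u] + g[u])
    f[, mask] <- .rowMinsList(cols)
  }
  f
}

# min over nonempty proper submask pairs of f[.,sub] + f[.,comp]
.dwMerge <- function(f, mask) {
  n <- nrow(f)
  g <- rep(Inf, n)
  sub <- bitwAnd(mask - 1L, mask)
  while (sub > 0L) {
    comp <- bitwXor(mask, sub)
    if (sub < comp) g <- pmin(g, f[, sub] + f[, comp])
    sub <- bitwAnd(sub - 1L, mask)
  }
  g
}

# Enumerate (all = TRUE) or pick one (all = FALSE) optimal Steiner
# arborescence(s) rooted at v covering `mask`, as sets of edge indices.
.dwTrees <- function(gx, termIdx, f, v, mask, all = TRUE) {
  bits <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(termIdx) - 1L)) > 0L)
  if (!is.finite(f[v, mask])) return(list())
  if (length(bits) == 1L)
    return(lapply(.allShortestPaths(gx, v, termIdx[bits], all), sort))
  out <- list()
  seen <- character(0)
  for (u in seq_len(gx$n)) {
    if (!is.finite(gx$D[v, u])) next
    gu <- .dwMergeAt(f, mask, u)
    if (gx$D[v, u] + gu != f[v, mask]) next
    sub <- bitwAnd(mask - 1L, mask)
    while (sub > 0L) {
      comp <- bitwXor(mask, sub)
      if (sub < comp && is.finite(f[u, sub]) && is.finite(f[u, comp]) &&
          f[u, sub] + f[u, comp] == gu) {
        lhs <- .dwTrees(gx, termIdx, f, u, sub, all)
        rhs <- .dwTrees(gx, termIdx, f, u, comp, all)
        paths <- .allShortestPaths(gx, v, u, all)
        for (p in paths) for (a in lhs) for (b in rhs) {
          tree <- sort(unique(c(p, a, b)))
          key <- paste(tree, collapse = ",")
          if (!key %in% seen) {
            seen <- c(seen, key)
            out[[length(out) + 1L]] <- tree
            if (!all) return(out)
          }
        }
      }
      sub <- bitwAnd(sub - 1L, mask)
    }
  }
  out
}

.dwMergeAt <- function(f, mask, u) {
  g <- Inf
  sub <- bitwAnd(mask - 1L, mask)
  while (sub > 0L) {
    comp <- bitwXor(mask, sub)
    if (sub < comp) g <- min(g, f[u, sub] + f[u, comp])
    sub <- bitwAnd(sub - 1L, mask)
  }
  g
}

#' Shortest path in the tentacular-free graph
#'
#' Minimum-weight directed path between two vertices; a subroutine of the
#' Steiner computation, exposed for inspection. Weight 0 with an empty edge
#' list when `from == to`; weight `Inf` when unreachable.
#'
#' @param G an [ArcGraph-class].
#' @param from,to vertex ids.
#' @return list with `weight` and `edges` (character vector of edge ids).
#' @export
shortestArcPath <- function(G, from, to) {
  gx <- .graphContextFromArcGraph(G)
  u <- match(from, gx$vid); v <- match(to, gx$vid)
  if (is.na(u) || is.na(v))
    stop("unknown vertex id(s): ",
         paste(c(from, to)[is.na(c(u, v))], collapse = ", "), call. = FALSE)
  if (!is.finite(gx$D[u, v]))
    return(list(weight = Inf, edges = character(0)))
  p <- .allShortestPaths(gx, u, v, all = FALSE)[[1]]
  list(weight = unname(gx$D[u, v]), edges = gx$e_id[p])
}

#' Minimum-weight directed Steiner arborescence
#'
#' Computes ST(x, X): the cheapest arborescence of the tentacular-free graph
#' rooted at `root` that contains every terminal in `terminals`, by the
#' Dreyfus-Wagner subset dynamic program (states are (vertex, terminal
#' subset); fixed-parameter tractable in the number of terminals). By
#' minimality every leaf of the witness is a terminal; terminals may also be
#' internal vertices of the tree.
#'
#' @param G an [ArcGraph-class].
#' @param root vertex id of the root x.
#' @param terminals non-empty character vector of terminal vertex ids X.
#' @return A [SteinerResult-class]; weight `Inf` with no arcs when some
#'   terminal is unreachable from the root.
#' @examples
#' edges <- rbind(
#'   arcRow("e1", "e1", "x@o", "a@o", 1, "endogenous", "o"),
#'   arcRow("e2", "e2", "a@o", "t1@o", 1, "endogenous", "o"),
#'   arcRow("e3", "e3", "a@o", "t2@o", 1, "endogenous", "o"))
#' G <- arcGraph(Hypergraph(arcs = edges))
#' steinerTree(G, "x@o", c("t1@o", "t2@o"))  # weight 3, shares edge e1
#' @export
steinerTree <- function(G, root, terminals) {
  if (length(terminals) < 1L) stop("at least one terminal is required")
  gx <- .graphContextFromArcGraph(G)
  r <- match(root, gx$vid)
  termIdx <- match(.csort(unique(terminals)), gx$vid)
  if (is.na(r) || anyNA(termIdx))
    stop("root and terminals must be vertices of the graph", call. = FALSE)
  f <- .dwSteiner(gx, termIdx)
  full <- bitwShiftL(1L, length(termIdx)) - 1L
  w <- f[r, full]
  arcs <- character(0)
  if (is.finite(w)) {
    tree <- .dwTrees(gx, termIdx, f, r, full, all = FALSE)[[1]]
    arcs <- gx$e_id[tree]
  }
  new("SteinerResult", root = root,
      terminals = .csort(unique(terminals)), weight = unname(w), arcs = arcs)
}
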