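#' Export solver outcomes as JSON or DOT
#'
#' JSON output is the full machine-readable outcome: status, optimal weight,
#' and per solution the sorted arc ids, the rootedness witness ordering, the
#' per-category breakdown and the tentacular combination used. DOT output
#' draws each solution as a diagram with one subgraph cluster per organism;
#' endogenous arcs are solid, insertions dashed, transitions bold (the visual
#' vocabulary of consortium pathway figures). Field order and arc order are
#' deterministic.
#'
#' @param outcome a [DshOutcome-class].
#' @param path output file; `NULL` returns the text instead.
#' @param format `"json"` or `"dot"`.
#' @param instance the [ConsortiumInstance-class] the outcome was computed
#'   on; required for DOT output (it supplies compounds and organisms).
#' @return the path (or the text when `path` is NULL), invisibly.
#' @export
writeSolutions <- function(outcome, path = NULL, format = c("json", "dot"),
                           instance = NULL) {
  format <- match.arg(format)
  txt <- if (format == "json") .solutionsJson(outcome)
         else .solutionsDot(outcome, instance)
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

.solutionsJson <- function(outcome) {
  if (outcome@status == "infeasible") {
    doc <- list(status = "infeasible")
  } else {
    doc <- list(
      status = "optimal",
      optimal_weight = outcome@optimalWeight,
      n_solutions = length(outcome@solutions),
      truncated = outcome@truncated,
      solutions = lapply(seq_along(outcome@solutions), function(i) {
        s <- outcome@solutions[[i]]
        list(arcs = as.list(s@arcs),
             ordering = as.list(s@ordering),
             total_weight = s@totalWeight,
             breakdown = as.list(s@breakdown),
             combination = as.list(outcome@combinations[[i]]))
      }))
  }
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE))
}

.solutionsDot <- function(outcome, instance) {
  if (is.null(instance))
    stop("DOT output needs the instance the outcome was computed on")
  if (outcome@status == "infeasible")
    return("digraph dsh { label=\"infeasible\"; }")
  v <- instance@hypergraph@vertices
  a <- instance@hypergraph@arcs
  esc <- function(x) gsub("\"", "\\\"", x, fixed = TRUE)
  nodeName <- function(id) paste0("\"", esc(id), "\"")
  out <- c("digraph dsh {", "  rankdir=LR;", "  node [shape=ellipse];")
  for (si in seq_along(outcome@solutions)) {
    sol <- outcome@solutions[[si]]
    arcs <- a[match(sol@arcs, a$id), , drop = FALSE]
    used <- .csort(unique(c(unlist(arcs$sources), arcs$target)))
    vv <- v[v$id %in% used, , drop = FALSE]
    out <- c(out, sprintf("  subgraph cluster_sol%d {", si),
             sprintf("    label=\"solution %d (weight %s)\";", si,
                     format(sol@totalWeight)))
    for (org in .csort(unique(vv$organism))) {
      out <- c(out, sprintf("    subgraph \"cluster_sol%d_%s\" {", si,
                            esc(org)),
               sprintf("      label=\"%s\";", esc(org)))
      ids <- .csort(vv$id[vv$organism == org])
      out <- c(out, sprintf("      %s [label=\"%s\"];",
                            vapply(paste0(ids, "#", si), nodeName,
                                   character(1)),
                            esc(vv$compound[match(ids, vv$id)])))
      out <- c(out, "    }")
    }
    style <- c(endogenous = "solid", insertion = "dashed",
               transition = "bold", composite = "dotted")
    for (i in seq_len(nrow(arcs))) {
      st <- style[[arcs$category[i]]]
      srcs <- arcs$sources[[i]]
      mid <- NULL
      if (length(srcs) > 1L) {
        # tentacular arc: draw through an explicit junction point
        mid <- sprintf("\"hyperarc_%s#%d\"", esc(arcs$id[i]), si)
        out <- c(out, sprintf("    %s [shape=point,label=\"\"];", mid))
        out <- c(out, sprintf("    %s -> %s [style=%s,arrowhead=none];",
                              vapply(paste0(.csort(srcs), "#", si), nodeName,
                                     character(1)), mid, st))
        out <- c(out, sprintf("    %s -> %s [style=%s,label=\"%s\"];",
                              mid, nodeName(paste0(arcs$target[i], "#", si)),
                              st, esc(arcs$reaction[i])))
      } else {
        out <- c(out, sprintf("    %s -> %s [style=%s,label=\"%s\"];",
                              nodeName(paste0(srcs, "#", si)),
                              nodeName(paste0(arcs$target[i], "#", si)),
                              st, esc(arcs$reaction[i])))
      }
    }
    out <- c(out, "  }")
  }
  c(out, "}")
}
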