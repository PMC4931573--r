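setMethod("show", "Hypergraph", function(object) {
  a <- object@arcs
  tent <- sum(lengths(a$sources) > 1L)
  cat("Hypergraph with", nrow(object@vertices), "vertices and", nrow(a),
      "hyperarcs\n")
  cat("  tentacular hyperarcs:", tent,
      "| total spreadness:", totalSpreadness(object), "\n")
  if (nrow(a)) {
    tb <- table(a$category)
    cat("  categories:",
        paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
        "\n")
  }
})

setMethod("show", "ConsortiumInstance", function(object) {
  cat("ConsortiumInstance over",
      length(object@workerOrganisms), "worker organism(s):",
      paste(object@workerOrganisms, collapse = ", "), "\n")
  show(object@hypergraph)
  cat("  sources:", paste(object@sources, collapse = ", "), "\n")
  cat("  targets:", paste(object@targets, collapse = ", "), "\n")
  w <- object@weights
  cat(sprintf("  weights: w_worker=%g, w_other=%g, w_transition=%g",
              w@wWorker, w@wOther, w@wTransition))
  if (nrow(w@overrides))
    cat(" (+", nrow(w@overrides), "override(s))")
  cat("\n")
})

setMethod("show", "WeightConfig", function(object) {
  cat(sprintf("WeightConfig: w_worker=%g, w_other=%g, w_transition=%g\n",
              object@wWorker, object@wOther, object@wTransition))
  if (nrow(object@overrides)) {
    cat("  overrides:\n")
    for (i in seq_len(nrow(object@overrides)))
      cat(sprintf("    %s:%s = %g\n", object@overrides$category[i],
                  object@overrides$key[i], object@overrides$weight[i]))
  }
})

setMethod("show", "SolutionHypertree", function(object) {
  cat("SolutionHypertree:", length(object@arcs), "hyperarcs, total weight",
      format(object@totalWeight), "\n")
  b <- object@breakdown
  cat("  breakdown:",
      paste(sprintf("%s=%d", names(b), b), collapse = ", "), "\n")
})

setMethod("show", "DshOutcome", function(object) {
  if (object@status == "infeasible") {
    cat("DshOutcome: infeasible (no rooted hyperarc set covers the targets)\n")
    return(invisible(NULL))
  }
  cat("DshOutcome: optimal weight", format(object@optimalWeight), "with",
      length(object@solutions), "solution(s)",
      if (object@truncated) "(truncated at cap)" else "", "\n")
  if (length(object@solutions)) {
    b <- object@solutions[[1]]@breakdown
    cat("  first solution:",
        paste(sprintf("%s=%d", names(b), b), collapse = ", "), "\n")
  }
})

setMethod("show", "SteinerResult", function(object) {
  cat("SteinerResult rooted at", object@root, "covering",
      length(object@terminals), "terminal(s): weight",
      format(object@weight), "with", length(object@arcs), "arc(s)\n")
})

setMethod("show", "OrderedCombination", function(object) {
  cat("OrderedCombination of", length(object@arcIds),
      "tentacular hyperarc(s)\n")
  if (length(object@arcIds))
    cat("  M =", paste(object@arcIds, collapse = " -> "), "\n")
  cat("  |T'| =", length(object@tPrime), "| |S'| =", length(object@sPrime),
      "\n")
})
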