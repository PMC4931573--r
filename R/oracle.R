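#' Brute-force reference solver for the DSH problem
#'
#' Enumerates all 2^m hyperarc subsets, keeps those that are rooted at the
#' sources (checked by a vectorised greedy scheduler, independent of the
#' dynamic-programming code path) and produce every target, and returns the
#' minimum weight together with *all* inclusion-minimal optimal subsets. This
#' is the oracle the exact solver is validated against; it is exponential in
#' the number of arcs and refuses instances above `limit`.
#'
#' @param x a [ConsortiumInstance-class].
#' @param limit refuse instances with more than this many hyperarcs
#'   (default 14).
#' @param allowSourceTargets see [solveDsh()].
#' @param ... unused.
#' @return A [DshOutcome-class]; its `combinations` slot records, per
#'   solution, the tentacular members in witness order.
#' @export
setMethod("bruteForceDsh", "ConsortiumInstance",
          function(x, limit = 14L, allowSourceTargets = FALSE, ...) {
  if (length(x@targets) == 0L)
    stop("instance has no targets; set them with setTerminals()")
  cc <- .compileHypergraph(x@hypergraph)
  m <- cc$m
  if (m > limit)
    stop(errorCondition(paste0(
      "instance has ", m, " hyperarcs; the brute-force oracle enumerates ",
      "2^m subsets and refuses m > ", limit,
      " (raise `limit` explicitly if you accept the cost)"),
      class = c("multipus_guardrail", "error", "condition")))
  sIdx <- sort(unique(.vertexIndex(cc, x@sources)))
  tIdx <- sort(unique(.vertexIndex(cc, x@targets)))

  nsub <- bitwShiftL(1L, m)
  subMask <- seq_len(nsub) - 1L
  member <- matrix(FALSE, nsub, max(m, 1L))
  for (j in seq_len(m))
    member[, j] <- bitwAnd(subMask, bitwShiftL(1L, j - 1L)) > 0L
  avail <- matrix(FALSE, nsub, cc$n)
  avail[, sIdx] <- TRUE
  fired <- matrix(FALSE, nsub, max(m, 1L))
  if (m > 0L) repeat {
    changed <- FALSE
    for (j in seq_len(m)) {
      ok <- member[, j] & !fired[, j]
      if (!any(ok)) next
      for (s in cc$arc_src[[j]]) ok <- ok & avail[, s]
      if (any(ok)) {
        fired[, j] <- fired[, j] | ok
        avail[, cc$arc_tgt[j]] <- avail[, cc$arc_tgt[j]] | ok
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rooted <- if (m > 0L) rowSums(member & !fired) == 0L else rep(TRUE, nsub)
  needT <- tIdx
  if (allowSourceTargets) needT <- setdiff(needT, sIdx)
  produced <- rep(TRUE, nsub)
  for (t in needT) {
    js <- which(cc$arc_tgt[seq_len(m)] == t)
    pt <- rep(FALSE, nsub)
    for (j in js) pt <- pt | fired[, j]
    produced <- produced & pt
  }
  weight <- if (m > 0L) as.numeric(member %*% cc$arc_w) else rep(0, nsub)
  feas <- rooted & produced
  if (!any(feas))
    return(new("DshOutcome", status = "infeasible", optimalWeight = Inf,
               solutions = list(), combinations = list(), truncated = FALSE))
  best <- min(weight[feas])
  cand <- which(feas & weight == best)
  cmask <- subMask[cand]
  minimal <- vapply(seq_along(cmask), function(i) {
    a <- cmask[i]
    !any(cmask != a & bitwAnd(a, cmask) == cmask)
  }, logical(1))
  cmask <- sort(cmask[minimal])
  sols <- list()
  combs <- list()
  for (msk in cmask) {
    arcIdx <- which(bitwAnd(msk, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)
    sol <- .solutionFromIdx(cc, arcIdx, sIdx)
    sols[[length(sols) + 1L]] <- sol
    ordIdx <- .arcIndex(cc, sol@ordering)
    combs[[length(combs) + 1L]] <- cc$arc_id[ordIdx[cc$arc_tent[ordIdx]]]
  }
  new("DshOutcome", status = "optimal", optimalWeight = best,
      solutions = sols, combinations = combs, truncated = FALSE)
})
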