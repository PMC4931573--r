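#' Enumerate ordered subsets of tentacular hyperarcs
#'
#' Every solution of the DSH problem uses some subset of the tentacular
#' hyperarcs in a topological order; the exact solver tries all ordered
#' subsets (there are at most 2^k * k! of them for k tentacular arcs).
#' Sequences are yielded by length, then lexicographically, each exactly
#' once.
#'
#' @param tentacularIds character vector of tentacular hyperarc ids.
#' @param maxK cap on the sequence length (defaults to all of them).
#' @param hardLimit refuse more than this many tentacular arcs (default 8)
#'   unless `overrideGuardrails` is set; the combination space grows as
#'   2^k * k!.
#' @param overrideGuardrails logical.
#' @return list of character vectors (the first is always the empty
#'   sequence).
#' @examples
#' length(enumerateOrderedSubsets(character(0)))    # 1
#' length(enumerateOrderedSubsets(c("a", "b")))     # 5
#' length(enumerateOrderedSubsets(c("a", "b", "c")))# 16
#' @export
enumerateOrderedSubsets <- function(tentacularIds, maxK = length(tentacularIds),
                                    hardLimit = 8L,
                                    overrideGuardrails = FALSE) {
  k <- length(tentacularIds)
  if (k > hardLimit && !overrideGuardrails)
    stop(errorCondition(paste0(
      "refusing to enumerate ordered subsets of ", k, " tentacular hyperarcs ",
      "(2^k k! combinations); raise hardLimit or set overrideGuardrails ",
      "= TRUE if you really want this"),
      class = c("multipus_guardrail", "error", "condition")))
  ids <- .csort(tentacularIds)
  out <- list(character(0))
  grow <- function(prefix, remaining, L) {
    if (length(prefix) == L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (r in remaining) grow(c(prefix, r), setdiff(remaining, r), L)
  }
  for (L in seq_len(min(k, maxK))) grow(character(0), ids, L)
  out
}

#' Layers induced by an ordered tentacular combination
#'
#' Given an ordered subset M of tentacular hyperarcs, the sources of M become
#' additional targets (they must be produced before their arc fires) and the
#' targets of M become additional sources (available to everything ordered
#' after). `Layer_T(t)` is the first layer whose tentacular arc consumes t
#' (k+1 for plain targets); `Layer_S(s)` is 0 for members of S (S takes
#' precedence) and otherwise the layer producing s.
#'
#' @param x a [ConsortiumInstance-class].
#' @param arcIds ordered character vector of tentacular hyperarc ids (M); may
#'   be empty.
#' @return An [OrderedCombination-class].
#' @export
computeLayers <- function(x, arcIds) {
  cc <- .compileHypergraph(x@hypergraph)
  M <- .arcIndex(cc, arcIds)
  if (any(!cc$arc_tent[M]))
    stop("non-tentacular hyperarc(s) in M: ",
         paste(arcIds[!cc$arc_tent[M]], collapse = ", "), call. = FALSE)
  k <- length(M)
  srcM <- lapply(M, function(a) cc$arc_src[[a]])
  tgtM <- cc$arc_tgt[M]
  sIdx <- .vertexIndex(cc, x@sources)
  tIdx <- .vertexIndex(cc, x@targets)
  termIdx <- sort(unique(c(tIdx, unlist(srcM))))
  layerT <- rep(k + 1, length(termIdx))
  for (i in rev(seq_len(k))) layerT[termIdx %in% srcM[[i]]] <- i
  spIdx <- sort(unique(c(sIdx, tgtM)))
  layerS <- rep(Inf, length(spIdx))
  for (i in rev(seq_len(k))) layerS[spIdx %in% tgtM[i]] <- i
  layerS[spIdx %in% sIdx] <- 0
  new("OrderedCombination",
      arcIds = cc$arc_id[M],
      tPrime = cc$vid[termIdx], sPrime = cc$vid[spIdx],
      layerT = stats::setNames(layerT, cc$vid[termIdx]),
      layerS = stats::setNames(layerS, cc$vid[spIdx]))
}

#' Candidate roots S_Y for a target subset
#'
#' The sources usable to cover a target subset Y are the extended sources
#' whose layer is strictly below the smallest layer of Y: a tentacular
#' product can only feed targets consumed by later tentacular arcs.
#'
#' @param combination an [OrderedCombination-class].
#' @param Y non-empty character vector of extended-target vertex ids.
#' @return character vector S_Y (sorted).
#' @export
candidateRoots <- function(combination, Y) {
  if (length(Y) == 0L) stop("Y must be non-empty")
  if (!all(Y %in% combination@tPrime))
    stop("Y must be a subset of the extended targets T'")
  cut <- min(combination@layerT[Y])
  .csort(names(combination@layerS)[combination@layerS < cut])
}

# ---------------------------------------------------------------------------
# internal solver engine

.solverContext <- function(instance, allowSourceTargets = FALSE) {
  if (length(instance@targets) == 0L)
    stop("instance has no targets; set them with setTerminals()")
  cc <- .compileHypergraph(instance@hypergraph)
  sIdx <- sort(unique(.vertexIndex(cc, instance@sources)))
  tIdx <- sort(unique(.vertexIndex(cc, instance@targets)))
  plain <- which(!cc$arc_tent)
  gx <- .graphContext(cc$vid,
                      vapply(cc$arc_src[plain], `[`, integer(1), 1L),
                      cc$arc_tgt[plain], cc$arc_w[plain], cc$arc_id[plain])
  gx$e_arcidx <- plain
  avail <- .closureIdx(cc, seq_len(cc$m), sIdx)
  producible <- logical(cc$n)
  for (a in seq_len(cc$m))
    if (all(avail[cc$arc_src[[a]]])) producible[cc$arc_tgt[a]] <- TRUE
  list(cc = cc, sIdx = sIdx, tIdx = tIdx, gx = gx,
       avail = avail, producible = producible,
       allow = allowSourceTargets, dwCache = new.env(parent = emptyenv()))
}

.ctxFeasible <- function(ctx) {
  ok <- ctx$producible[ctx$tIdx]
  if (ctx$allow) ok <- ok | ctx$tIdx %in% ctx$sIdx
  all(ok)
}

.dwCached <- function(ctx, termIdx, gx = ctx$gx, excl = integer(0)) {
  key <- paste(paste(termIdx, collapse = ","),
               paste(excl, collapse = ","), sep = "|")
  if (!is.null(ctx$dwCache[[key]])) return(ctx$dwCache[[key]])
  f <- .dwSteiner(gx, termIdx)
  ctx$dwCache[[key]] <- f
  f
}

# Base graph context minus the given plain arc indices (cached).
.gxExcluding <- function(ctx, plainM) {
  key <- paste("gx", paste(sort(plainM), collapse = ","))
  if (!is.null(ctx$dwCache[[key]])) return(ctx$dwCache[[key]])
  keep <- !(ctx$gx$e_arcidx %in% plainM)
  gx <- .graphContext(ctx$gx$vid, ctx$gx$e_from[keep], ctx$gx$e_to[keep],
                      ctx$gx$e_w[keep], ctx$gx$e_id[keep])
  gx$e_arcidx <- ctx$gx$e_arcidx[keep]
  ctx$dwCache[[key]] <- gx
  gx
}

# Evaluate one ordered combination M (arc indices): the SH_M subset DP.
# M normally holds tentacular arcs only; in strict mode it may also carry one
# mandatory plain producing arc per target that is also a source (such
# targets can only be produced by a cycle re-entering the source vertex,
# which a forest cannot represent, but a must-use arc whose source becomes an
# extra target can). Plain members are removed from the Steiner graph of this
# combination so they are never paid for twice.
.evalCombo <- function(ctx, M) {
  cc <- ctx$cc
  kM <- length(M)
  srcM <- lapply(M, function(a) cc$arc_src[[a]])
  tgtM <- cc$arc_tgt[M]
  termIdx <- sort(unique(c(ctx$tIdx, unlist(srcM))))
  t <- length(termIdx)
  plainM <- M[!cc$arc_tent[M]]
  gx <- if (length(plainM)) .gxExcluding(ctx, plainM) else ctx$gx
  layerT <- rep(kM + 1, t)
  for (i in rev(seq_len(kM))) layerT[termIdx %in% srcM[[i]]] <- i
  layerS <- rep(Inf, cc$n)
  for (i in rev(seq_len(kM))) layerS[tgtM[i]] <- i
  layerS[ctx$sIdx] <- 0
  needProd <- logical(cc$n)
  if (!ctx$allow) {
    needProd[ctx$tIdx] <- TRUE
    needProd[tgtM] <- FALSE
  }
  termBit <- integer(cc$n)
  termBit[termIdx] <- bitwShiftL(1L, seq_len(t) - 1L)
  f <- .dwCached(ctx, termIdx, gx, plainM)
  full <- bitwShiftL(1L, t) - 1L
  layerMin <- rep(Inf, full)
  for (mask in seq_len(full)) {
    low <- bitwAnd(mask, -mask)
    j <- which(bitwShiftL(1L, seq_len(t) - 1L) == low)
    rest <- bitwXor(mask, low)
    layerMin[mask] <- if (rest > 0L) min(layerT[j], layerMin[rest])
                      else layerT[j]
  }
  pc <- .popcount(seq_len(full))
  sh <- rep(Inf, full)
  rootsFor <- function(mask) {
    vs <- which(layerS < layerMin[mask])
    if (length(vs))
      vs <- vs[!(needProd[vs] & bitwAnd(termBit[vs], mask) > 0L)]
    vs
  }
  for (mask in seq_len(full)[order(pc, seq_len(full))]) {
    vs <- rootsFor(mask)
    best <- if (length(vs)) min(f[vs, mask]) else Inf
    sub <- bitwAnd(mask - 1L, mask)
    while (sub > 0L) {
      comp <- bitwXor(mask, sub)
      if (sub < comp) best <- min(best, sh[sub] + sh[comp])
      sub <- bitwAnd(sub - 1L, mask)
    }
    sh[mask] <- best
  }
  list(M = M, kM = kM, termIdx = termIdx, layerT = layerT, layerS = layerS,
       needProd = needProd, termBit = termBit, f = f, sh = sh, full = full,
       rootsFor = rootsFor, gx = gx, weightM = sum(cc$arc_w[M]),
       value = sum(cc$arc_w[M]) + sh[full])
}

# All (or one) optimal forests covering the full extended target set of an
# evaluated combination, as lists of arc-index sets.
.comboForests <- function(ctx, ev, all = TRUE) {
  gx <- ev$gx
  memo <- new.env(parent = emptyenv())
  enumF <- function(mask) {
    key <- as.character(mask)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- list()
    seen <- character(0)
    addSet <- function(s) {
      k <- paste(s, collapse = ",")
      if (!k %in% seen) {
        seen <<- c(seen, k)
        res[[length(res) + 1L]] <<- s
      }
    }
    done <- function() (!all) && length(res) > 0L
    for (v in ev$rootsFor(mask)) {
      if (done()) break
      if (is.finite(ev$f[v, mask]) && ev$f[v, mask] == ev$sh[mask]) {
        for (tree in .dwTrees(gx, ev$termIdx, ev$f, v, mask, all)) {
          addSet(sort(tree))
          if (done()) break
        }
      }
    }
    if (!done()) {
      sub <- bitwAnd(mask - 1L, mask)
      while (sub > 0L) {
        comp <- bitwXor(mask, sub)
        if (sub < comp && is.finite(ev$sh[sub]) && is.finite(ev$sh[comp]) &&
            ev$sh[sub] + ev$sh[comp] == ev$sh[mask]) {
          for (a in enumF(sub)) {
            for (b in enumF(comp)) {
              addSet(sort(unique(c(a, b))))
              if (done()) break
            }
            if (done()) break
          }
        }
        if (done()) break
        sub <- bitwAnd(sub - 1L, mask)
      }
    }
    memo[[key]] <- res
    res
  }
  forests <- enumF(ev$full)
  lapply(forests, function(edges) gx$e_arcidx[edges])
}

.solveDshCore <- function(instance, allowSourceTargets = FALSE,
                          maxTentacular = 8L, maxTprime = 12L,
                          overrideGuardrails = FALSE,
                          enumerate = FALSE, cap = Inf) {
  ctx <- .solverContext(instance, allowSourceTargets)
  cc <- ctx$cc
  infeasible <- new("DshOutcome", status = "infeasible", optimalWeight = Inf,
                    solutions = list(), combinations = list(),
                    truncated = FALSE)
  if (!.ctxFeasible(ctx)) return(infeasible)

  tentIdx <- which(cc$arc_tent)
  fireable <- function(a) all(ctx$avail[cc$arc_src[[a]]])
  usable <- tentIdx[vapply(tentIdx, fireable, logical(1))]
  k <- length(usable)
  if (k > maxTentacular && !overrideGuardrails)
    stop(errorCondition(paste0(
      "instance has ", k, " usable tentacular hyperarcs (guardrail ",
      maxTentacular, "); the combination space is 2^k k!. Set ",
      "overrideGuardrails = TRUE or raise maxTentacular to proceed"),
      class = c("multipus_guardrail", "error", "condition")))

  # Strict semantics: a target that is also a source can only be produced by
  # an arc re-entering it (possibly via a cycle through the source itself).
  # One mandatory producing arc per such target joins the ordered
  # combination; plain producers are taken out of the Steiner graph.
  overlap <- if (allowSourceTargets) integer(0)
             else intersect(ctx$tIdx, ctx$sIdx)
  producers <- integer(0)
  if (length(overlap)) {
    plainIdx <- which(!cc$arc_tent)
    producers <- plainIdx[cc$arc_tgt[plainIdx] %in% overlap &
                            vapply(plainIdx, fireable, logical(1))]
  }
  items <- sort(c(usable, producers))
  if (length(items) > max(maxTentacular, 10L) && !overrideGuardrails)
    stop(errorCondition(paste0(
      "combination item set has ", length(items), " hyperarcs (tentacular ",
      "plus mandatory producers of source-targets); refusing without ",
      "overrideGuardrails = TRUE"),
      class = c("multipus_guardrail", "error", "condition")))
  worstT <- length(unique(c(ctx$tIdx, unlist(cc$arc_src[items]))))
  if (worstT > maxTprime && !overrideGuardrails)
    stop(errorCondition(paste0(
      "extended target set would have ", worstT, " vertices (guardrail ",
      maxTprime, "); the subset DP is exponential in |T'|. Set ",
      "overrideGuardrails = TRUE or raise maxTprime to proceed"),
      class = c("multipus_guardrail", "error", "condition")))

  combos <- .orderedSubsetsIdx(items)
  if (length(overlap)) {
    okCombo <- vapply(combos, function(M) {
      tg <- cc$arc_tgt[M]
      all(vapply(overlap, function(t) sum(tg == t) == 1L, logical(1)))
    }, logical(1))
    combos <- combos[okCombo]
  }
  if (!length(combos)) return(infeasible)
  evals <- lapply(combos, function(M) .evalCombo(ctx, M))
  values <- vapply(evals, function(e) e$value, numeric(1))
  best <- min(values)
  if (!is.finite(best)) return(infeasible)

  sols <- list()
  combs <- list()
  keys <- character(0)
  truncated <- FALSE
  for (ev in evals[values == best]) {
    forests <- .comboForests(ctx, ev, all = enumerate)
    for (fo in forests) {
      arcIdx <- sort(unique(c(ev$M, fo)))
      arcIdx <- .minimalizeIdx(cc, arcIdx, ctx$sIdx, ctx$tIdx,
                               allowSourceTargets)
      w <- sum(cc$arc_w[arcIdx])
      if (w != best)
        stop("internal error: reconstructed solution weight ", w,
             " differs from the optimum ", best)
      key <- .setKey(arcIdx)
      if (key %in% keys) next
      if (length(sols) >= cap) { truncated <- TRUE; break }
      keys <- c(keys, key)
      sols[[length(sols) + 1L]] <- .solutionFromIdx(cc, arcIdx, ctx$sIdx)
      combs[[length(combs) + 1L]] <- cc$arc_id[ev$M]
    }
    if (truncated || (!enumerate && length(sols))) break
  }
  new("DshOutcome", status = "optimal", optimalWeight = best,
      solutions = sols, combinations = combs, truncated = truncated)
}

.orderedSubsetsIdx <- function(ids) {
  out <- list(integer(0))
  grow <- function(prefix, remaining, L) {
    if (length(prefix) == L) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (r in remaining) grow(c(prefix, r), setdiff(remaining, r), L)
  }
  for (L in seq_along(ids)) grow(integer(0), sort(ids), L)
  out
}

#' Exactly solve the Directed Steiner Hypertree problem
#'
#' Finds a minimum-weight hyperarc set A' rooted at the sources S such that
#' every target is produced (T is contained in tgt(A')). The algorithm
#' enumerates ordered combinations M of the tentacular hyperarcs, derives the
#' layer structure (see [computeLayers()]), and for each combination runs a
#' subset dynamic program SH_M over the extended target set whose base case
#' is the Dreyfus-Wagner directed Steiner tree on the tentacular-free graph:
#' `SH_M(Y) = min( min_{s in S_Y} ST(s, Y), min_{Y' subset Y} SH_M(Y') +
#' SH_M(Y \ Y') )`. The optimum is the minimum of `weight(M) + SH_M(T')` over
#' all combinations; it is fixed-parameter tractable in the number of targets
#' plus the total spreadness. The witness solution is assembled from M and
#' the covering forest, pruned to inclusion-minimality, and validated for
#' rootedness and coverage.
#'
#' Combinations whose tentacular sources lie outside the closure of S under
#' all arcs can never fire and are skipped.
#'
#' @param x a [ConsortiumInstance-class].
#' @param allowSourceTargets when TRUE, a target that is also a source counts
#'   as satisfied without being produced by an arc; the default is the strict
#'   reading (every target must be the target of a used arc).
#' @param maxTentacular,maxTprime guardrails on the number of usable
#'   tentacular hyperarcs and on |T'|; breaching either raises a refusal
#'   error unless `overrideGuardrails = TRUE`.
#' @param overrideGuardrails logical.
#' @param ... unused.
#' @return A [DshOutcome-class] with one witness solution (or an infeasible
#'   outcome; infeasibility is reported, not thrown).
#' @seealso [enumerateOptimal()] for all co-optimal solutions,
#'   [bruteForceDsh()] for the reference oracle.
#' @export
setMethod("solveDsh", "ConsortiumInstance",
          function(x, allowSourceTargets = FALSE, maxTentacular = 8L,
                   maxTprime = 12L, overrideGuardrails = FALSE, ...) {
  .solveDshCore(x, allowSourceTargets, maxTentacular, maxTprime,
                overrideGuardrails, enumerate = FALSE)
})

#' Enumerate all optimal DSH solutions
#'
#' Backtracks over all co-optimal ordered combinations, all co-optimal
#' branches of the SH_M dynamic program, and all co-optimal Steiner witnesses
#' (including parallel equal-weight arcs), minimalizes and deduplicates the
#' reconstructed arc sets, and returns up to `cap` distinct optimal
#' solutions.
#'
#' @param x a [ConsortiumInstance-class].
#' @param cap maximum number of solutions to return (>= 1); the outcome's
#'   `truncated` flag reports whether the cap was hit.
#' @inheritParams solveDsh
#' @return A [DshOutcome-class].
#' @export
setMethod("enumerateOptimal", "ConsortiumInstance",
          function(x, cap = 100L, allowSourceTargets = FALSE,
                   maxTentacular = 8L, maxTprime = 12L,
                   overrideGuardrails = FALSE, ...) {
  stopifnot(cap >= 1L)
  .solveDshCore(x, allowSourceTargets, maxTentacular, maxTprime,
                overrideGuardrails, enumerate = TRUE, cap = cap)
})

#' Minimum-weight forest cover for one ordered combination
#'
#' Runs the SH_M dynamic program for a fixed ordered combination of
#' tentacular hyperarcs and returns the optimal forest covering the extended
#' target set T', decomposed into its constituent Steiner trees.
#'
#' @param x a [ConsortiumInstance-class].
#' @param arcIds ordered character vector of tentacular hyperarc ids (M).
#' @param allowSourceTargets see [solveDsh()].
#' @return list with `weight` (SH_M(T'), `Inf` when no cover exists),
#'   `covered` (T'), and `trees` (list of [SteinerResult-class] for a witness
#'   forest; empty when `weight` is `Inf`).
#' @export
solveSH <- function(x, arcIds, allowSourceTargets = FALSE) {
  ctx <- .solverContext(x, allowSourceTargets)
  cc <- ctx$cc
  M <- .arcIndex(cc, arcIds)
  if (any(!cc$arc_tent[M]))
    stop("non-tentacular hyperarc(s) in M", call. = FALSE)
  ev <- .evalCombo(ctx, M)
  w <- ev$sh[ev$full]
  if (!is.finite(w))
    return(list(weight = Inf, covered = cc$vid[ev$termIdx], trees = list()))
  forest <- .comboForests(ctx, ev, all = FALSE)[[1]]
  trees <- .forestToTrees(ctx, ev, forest)
  list(weight = w, covered = cc$vid[ev$termIdx], trees = trees)
}

# Split a forest arc set into its trees (components followed from roots).
.forestToTrees <- function(ctx, ev, arcIdx) {
  cc <- ctx$cc
  if (!length(arcIdx)) return(list())
  heads <- cc$arc_tgt[arcIdx]
  tails <- vapply(cc$arc_src[arcIdx], `[`, integer(1), 1L)
  roots <- setdiff(tails, heads)
  trees <- list()
  assigned <- logical(length(arcIdx))
  for (r in sort(roots)) {
    member <- integer(0)
    frontier <- r
    repeat {
      nxt <- which(!assigned & tails %in% frontier)
      if (!length(nxt)) break
      assigned[nxt] <- TRUE
      member <- c(member, nxt)
      frontier <- heads[nxt]
    }
    if (length(member)) {
      arcs <- arcIdx[member]
      terms <- intersect(unique(cc$arc_tgt[arcs]), ev$termIdx)
      trees[[length(trees) + 1L]] <-
        new("SteinerResult", root = cc$vid[r],
            terminals = cc$vid[sort(terms)],
            weight = sum(cc$arc_w[arcs]),
            arcs = cc$arc_id[sort(arcs)])
    }
  }
  trees
}
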