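# Locale-independent (C collation) string ordering, so serialisations and
# solver tie-breaks are identical across platforms and locales.
.csort <- function(x) sort(x, method = "radix")
.corder <- function(...) order(..., method = "radix")

# Internal compiled form of a hypergraph: integer-indexed arcs sorted by id,
# so every solver iteration order is deterministic.

.compileHypergraph <- function(H) {
  v <- H@vertices
  a <- H@arcs
  vid <- .csort(v$id)
  vindex <- stats::setNames(seq_along(vid), vid)
  ord <- .corder(a$id)
  a <- a[ord, , drop = FALSE]
  list(
    vid = vid,
    vindex = vindex,
    n = length(vid),
    m = nrow(a),
    arc_id = a$id,
    arc_reaction = a$reaction,
    arc_src = lapply(a$sources, function(s) unname(vindex[s])),
    arc_tgt = unname(vindex[a$target]),
    arc_w = a$weight,
    arc_cat = a$category,
    arc_org = a$organism,
    arc_tent = lengths(a$sources) > 1L
  )
}

.arcIndex <- function(cc, arcIds) {
  idx <- match(arcIds, cc$arc_id)
  if (anyNA(idx))
    stop("unknown hyperarc id(s): ",
         paste(arcIds[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

.vertexIndex <- function(cc, vertexIds) {
  idx <- unname(cc$vindex[vertexIds])
  if (anyNA(idx))
    stop("unknown vertex id(s): ",
         paste(vertexIds[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

# Least fixpoint of firing the selected arcs from `startIdx`; returns a logical
# availability vector over vertices.
.closureIdx <- function(cc, arcIdx, startIdx) {
  avail <- logical(cc$n)
  avail[startIdx] <- TRUE
  fired <- logical(length(arcIdx))
  repeat {
    changed <- FALSE
    for (j in seq_along(arcIdx)) {
      if (fired[j]) next
      a <- arcIdx[j]
      if (all(avail[cc$arc_src[[a]]])) {
        fired[j] <- TRUE
        if (!avail[cc$arc_tgt[a]]) avail[cc$arc_tgt[a]] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  avail
}

# Greedy schedule: repeatedly fire any arc whose sources are available.
# Greedy is complete because firing an enabled arc never disables another, so
# the arc set is rooted iff the schedule exhausts it. Returns the witness
# ordering of arc indices, or NULL when not rooted.
.greedyOrderIdx <- function(cc, arcIdx, sourceIdx) {
  avail <- logical(cc$n)
  avail[sourceIdx] <- TRUE
  remaining <- arcIdx
  ordering <- integer(0)
  while (length(remaining)) {
    fired_any <- FALSE
    keep <- logical(length(remaining))
    for (j in seq_along(remaining)) {
      a <- remaining[j]
      if (all(avail[cc$arc_src[[a]]])) {
        ordering <- c(ordering, a)
        avail[cc$arc_tgt[a]] <- TRUE
        fired_any <- TRUE
      } else {
        keep[j] <- TRUE
      }
    }
    if (!fired_any) return(NULL)
    remaining <- remaining[keep]
  }
  ordering
}

# Strict coverage: every target is the target of some member arc (all member
# arcs fire when the set is rooted). With allowSourceTargets, targets that are
# sources are satisfied for free.
.coversIdx <- function(cc, arcIdx, targetIdx, sourceIdx,
                       allowSourceTargets = FALSE) {
  need <- targetIdx
  if (allowSourceTargets) need <- setdiff(need, sourceIdx)
  all(need %in% cc$arc_tgt[arcIdx])
}

.isFeasibleSetIdx <- function(cc, arcIdx, sourceIdx, targetIdx,
                              allowSourceTargets = FALSE) {
  !is.null(.greedyOrderIdx(cc, arcIdx, sourceIdx)) &&
    .coversIdx(cc, arcIdx, targetIdx, sourceIdx, allowSourceTargets)
}

# Remove arcs (deterministic lexicographic scan, iterated to a fixpoint) whose
# deletion preserves rootedness and coverage.
.minimalizeIdx <- function(cc, arcIdx, sourceIdx, targetIdx,
                           allowSourceTargets = FALSE) {
  current <- sort(arcIdx)
  repeat {
    dropped <- FALSE
    for (a in current) {
      trial <- setdiff(current, a)
      if (.isFeasibleSetIdx(cc, trial, sourceIdx, targetIdx,
                            allowSourceTargets)) {
        current <- trial
        dropped <- TRUE
      }
    }
    if (!dropped) break
  }
  current
}

.breakdownIdx <- function(cc, arcIdx, perReaction = FALSE) {
  cats <- .arcCategories
  if (perReaction) {
    keep <- !duplicated(paste(cc$arc_reaction[arcIdx], cc$arc_org[arcIdx]))
    arcIdx <- arcIdx[keep]
  }
  counts <- table(factor(cc$arc_cat[arcIdx], levels = cats))
  out <- stats::setNames(as.integer(counts), cats)
  out[out > 0 | names(out) %in% c("endogenous", "insertion", "transition")]
}

.solutionFromIdx <- function(cc, arcIdx, sourceIdx, perReaction = FALSE) {
  ordIdx <- .greedyOrderIdx(cc, sort(arcIdx), sourceIdx)
  if (is.null(ordIdx))
    stop("internal error: solution arc set is not rooted", call. = FALSE)
  w <- if (perReaction) {
    keep <- !duplicated(paste(cc$arc_reaction[arcIdx], cc$arc_org[arcIdx]))
    sum(cc$arc_w[arcIdx[keep]])
  } else sum(cc$arc_w[arcIdx])
  new("SolutionHypertree",
      arcs = cc$arc_id[sort(arcIdx)],
      ordering = cc$arc_id[ordIdx],
      totalWeight = w,
      breakdown = .breakdownIdx(cc, arcIdx, perReaction))
}

.setKey <- function(idx) paste(sort(idx), collapse = ",")

# Deterministic helper: raw reaction tables ------------------------------

.emptyReactionSet <- function() {
  data.frame(reaction_id = character(0), substrates = I(list()),
             products = I(list()), reversible = logical(0),
             stringsAsFactors = FALSE)
}

.reactionSet <- function(reaction_id, substrates, products,
                         reversible = FALSE) {
  stopifnot(length(substrates) == length(reaction_id),
            length(products) == length(reaction_id))
  if (length(reversible) == 1L)
    reversible <- rep(reversible, length(reaction_id))
  df <- data.frame(reaction_id = as.character(reaction_id),
                   reversible = as.logical(reversible),
                   stringsAsFactors = FALSE)
  df$substrates <- lapply(substrates, as.character)
  df$products <- lapply(products, as.character)
  df[, c("reaction_id", "substrates", "products", "reversible")]
}
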