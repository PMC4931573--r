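#' Read and write consortium instances as JSON documents
#'
#' The instance document is a JSON object with fields `schema_version`,
#' `worker_organisms`, `reference_reactions`, `vertices` (array of
#' `{id, compound, organism}`), `arcs` (array of `{id, reaction, sources,
#' target, weight, category, organism}`), `sources`, `targets` and `weights`
#' (`{w_worker, w_other, w_transition, overrides}`). The machine-readable
#' schema ships with the package (`system.file("schema",
#' "instance.schema.json", package = "multipus")`) and the reader enforces
#' the structural constraints it states; writing is deterministic (sorted
#' ids, fixed field order), so identical instances serialise byte-identically
#' and `readInstance(writeInstance(x))` is the identity on the in-memory
#' model.
#'
#' @param x a [ConsortiumInstance-class].
#' @param path file path; for `writeInstance()` use `NULL` to return the JSON
#'   string instead of writing.
#' @return `writeInstance()`: the path (or JSON string) invisibly;
#'   `readInstance()`: a [ConsortiumInstance-class].
#' @export
writeInstance <- function(x, path = NULL) {
  v <- x@hypergraph@vertices
  v <- v[.corder(v$id), , drop = FALSE]
  a <- x@hypergraph@arcs
  a <- a[.corder(a$id), , drop = FALSE]
  ov <- x@weights@overrides
  ov <- ov[.corder(ov$category, ov$key), , drop = FALSE]
  doc <- list(
    schema_version = "1.0",
    worker_organisms = as.list(.csort(x@workerOrganisms)),
    reference_reactions = as.list(.csort(x@referenceReactions)),
    vertices = lapply(seq_len(nrow(v)), function(i)
      list(id = v$id[i], compound = v$compound[i], organism = v$organism[i])),
    arcs = lapply(seq_len(nrow(a)), function(i)
      list(id = a$id[i], reaction = a$reaction[i],
           sources = as.list(.csort(a$sources[[i]])), target = a$target[i],
           weight = a$weight[i], category = a$category[i],
           organism = a$organism[i])),
    sources = as.list(.csort(x@sources)),
    targets = as.list(.csort(x@targets)),
    weights = list(w_worker = x@weights@wWorker,
                   w_other = x@weights@wOther,
                   w_transition = x@weights@wTransition,
                   overrides = lapply(seq_len(nrow(ov)), function(i)
                     list(category = ov$category[i], key = ov$key[i],
                          weight = ov$weight[i]))))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(as.character(json), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeInstance
#' @export
readInstance <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .validateInstanceDocument(doc, path)
  v <- do.call(rbind, lapply(doc$vertices, function(x)
    data.frame(id = x$id, compound = x$compound, organism = x$organism,
               stringsAsFactors = FALSE)))
  arcs <- do.call(rbind, lapply(doc$arcs, function(x)
    arcRow(id = x$id, reaction = x$reaction,
           sources = unlist(x$sources), target = x$target,
           weight = x$weight, category = x$category, organism = x$organism)))
  ovl <- doc$weights$overrides
  ov <- if (length(ovl))
    do.call(rbind, lapply(ovl, function(o)
      data.frame(category = o$category, key = o$key, weight = o$weight,
                 stringsAsFactors = FALSE)))
  else NULL
  w <- WeightConfig(wWorker = doc$weights$w_worker,
                    wOther = doc$weights$w_other,
                    wTransition = doc$weights$w_transition,
                    overrides = ov)
  new("ConsortiumInstance",
      hypergraph = Hypergraph(vertices = v, arcs = arcs),
      sources = as.character(unlist(doc$sources)),
      targets = as.character(unlist(doc$targets)),
      weights = w,
      workerOrganisms = as.character(unlist(doc$worker_organisms)),
      referenceReactions = as.character(unlist(doc$reference_reactions)))
}

# Structural checks mirroring inst/schema/instance.schema.json.
.validateInstanceDocument <- function(doc, path = "<document>") {
  fail <- function(...) stop(path, ": invalid instance document: ", ...,
                             call. = FALSE)
  need <- c("schema_version", "worker_organisms", "vertices", "arcs",
            "sources", "targets", "weights")
  miss <- setdiff(need, names(doc))
  if (length(miss)) fail("missing field(s): ", paste(miss, collapse = ", "))
  if (!identical(doc$schema_version, "1.0"))
    fail("unsupported schema_version '", doc$schema_version, "'")
  for (i in seq_along(doc$vertices)) {
    x <- doc$vertices[[i]]
    if (!all(c("id", "compound", "organism") %in% names(x)))
      fail("vertex #", i, " lacks id/compound/organism")
  }
  ids <- vapply(doc$vertices, `[[`, character(1), "id")
  if (anyDuplicated(ids)) fail("duplicated vertex ids")
  for (i in seq_along(doc$arcs)) {
    x <- doc$arcs[[i]]
    if (!all(c("id", "reaction", "sources", "target", "weight", "category",
               "organism") %in% names(x)))
      fail("arc #", i, " lacks a required field")
    if (length(x$sources) < 1L) fail("arc '", x$id, "' has no sources")
    if (!is.numeric(x$weight) || x$weight < 0)
      fail("arc '", x$id, "' has an invalid weight")
    if (!x$category %in% .arcCategories)
      fail("arc '", x$id, "' has unknown category '", x$category, "'")
    bad <- setdiff(c(unlist(x$sources), x$target), ids)
    if (length(bad))
      fail("arc '", x$id, "' references unknown vertex: ",
           paste(bad, collapse = ", "))
  }
  aids <- vapply(doc$arcs, `[[`, character(1), "id")
  if (anyDuplicated(aids)) fail("duplicated arc ids")
  if (!all(c("w_worker", "w_other", "w_transition") %in% names(doc$weights)))
    fail("weights must define w_worker, w_other, w_transition")
  bad <- setdiff(c(unlist(doc$sources), unlist(doc$targets)), ids)
  if (length(bad))
    fail("sources/targets reference unknown vertices: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
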