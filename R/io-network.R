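#' Read and write per-organism reaction tables
#'
#' The reaction-table dialect is a UTF-8 TSV with a header row and the
#' columns `reaction_id`, `substrates`, `products`, `reversible`:
#' substrates/products are semicolon-separated compound ids, `reversible` is
#' 0 or 1. Reversible rows are split into two directed reactions during
#' decomposition. Malformed rows are rejected with their line number;
#' duplicate reaction ids are rejected.
#'
#' @param path file path.
#' @param organism organism id the network belongs to (recorded by the
#'   caller; the raw reaction set itself is organism-agnostic).
#' @return `readNetworkTable()`: a raw reaction set (`data.frame` with
#'   columns `reaction_id`, `substrates`, `products`, `reversible`);
#'   `writeNetworkTable()`: the path, invisibly.
#' @export
readNetworkTable <- function(path, organism = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop(path, ": empty file", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("reaction_id", "substrates", "products", "reversible")
  if (!identical(header, need))
    stop(path, ":1: header must be exactly: ", paste(need, collapse = "\t"),
         call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  splitIds <- function(s) {
    out <- strsplit(s, ";", fixed = TRUE)[[1]]
    out[nzchar(out)]
  }
  rid <- character(length(rows))
  subs <- vector("list", length(rows))
  prods <- vector("list", length(rows))
  rev <- logical(length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    lineno <- i + 1L
    if (length(r) != 4L)
      stop(path, ":", lineno, ": expected 4 tab-separated fields, got ",
           length(r), call. = FALSE)
    if (!nzchar(r[1]))
      stop(path, ":", lineno, ": empty reaction_id", call. = FALSE)
    s <- splitIds(r[2]); p <- splitIds(r[3])
    if (length(s) == 0L || length(p) == 0L)
      stop(path, ":", lineno, ": reaction '", r[1],
           "' has an empty substrate or product list", call. = FALSE)
    if (!r[4] %in% c("0", "1"))
      stop(path, ":", lineno, ": reversible must be 0 or 1, got '", r[4],
           "'", call. = FALSE)
    rid[i] <- r[1]; subs[[i]] <- s; prods[[i]] <- p; rev[i] <- r[4] == "1"
  }
  if (anyDuplicated(rid))
    stop(path, ": duplicate reaction id(s): ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "), call. = FALSE)
  .reactionSet(rid, subs, prods, rev)
}

#' @rdname readNetworkTable
#' @param network a raw reaction set to serialise.
#' @export
writeNetworkTable <- function(network, path) {
  lines <- c(paste(c("reaction_id", "substrates", "products", "reversible"),
                   collapse = "\t"),
             vapply(seq_len(nrow(network)), function(i) {
               paste(network$reaction_id[i],
                     paste(network$substrates[[i]], collapse = ";"),
                     paste(network$products[[i]], collapse = ";"),
                     as.integer(network$reversible[i]), sep = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cofactor exclusion list
#'
#' One compound id per line; blank lines and lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @return character vector of compound ids.
#' @export
readCofactorList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
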