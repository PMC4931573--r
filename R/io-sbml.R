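#' Read a metabolic network from SBML
#'
#' Reads the species/reaction lists of an SBML Level 2 or Level 3 core
#' document into the raw reaction-set form: substrates and products are taken
#' from the reactant and product species references, the `reversible`
#' attribute is honoured, and stoichiometric values are deliberately ignored
#' (the consortium model is purely topological). Compartment suffixes are
#' stripped by a documented rule: when a species id ends in `_<compartment>`
#' for the compartment the species is declared in, that suffix is removed, so
#' the same chemical in different compartments maps to one compound id.
#' Reactions with no reactants or no products are skipped and reported via a
#' warning.
#'
#' @param path SBML file path.
#' @param organism organism id (unused in the raw set; kept for symmetry with
#'   [readNetworkTable()]).
#' @return A raw reaction set (`data.frame` with `reaction_id`, `substrates`,
#'   `products`, `reversible`).
#' @export
readSBML <- function(path, organism = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(path, ": cannot parse SBML: ",
                                           conditionMessage(e), call. = FALSE))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  species <- xml2::xml_find_all(doc, ".//sbml:listOfSpecies/sbml:species", ns)
  spId <- xml2::xml_attr(species, "id")
  spComp <- xml2::xml_attr(species, "compartment")
  compound <- spId
  suffix <- paste0("_", spComp)
  hasSuffix <- !is.na(spComp) & endsWith(spId, suffix)
  compound[hasSuffix] <- substr(spId[hasSuffix], 1L,
                                nchar(spId[hasSuffix]) -
                                  nchar(suffix[hasSuffix]))
  compoundOf <- stats::setNames(compound, spId)

  reactions <- xml2::xml_find_all(doc, ".//sbml:listOfReactions/sbml:reaction",
                                  ns)
  if (length(reactions) == 0L)
    stop(path, ": no reactions found", call. = FALSE)
  refIds <- function(rxn, listName) {
    refs <- xml2::xml_find_all(
      rxn, paste0("./sbml:", listName, "/sbml:speciesReference"), ns)
    sp <- xml2::xml_attr(refs, "species")
    unique(unname(compoundOf[sp[sp %in% names(compoundOf)]]))
  }
  rid <- character(0); subs <- list(); prods <- list(); rev <- logical(0)
  skipped <- character(0)
  for (rxn in reactions) {
    id <- xml2::xml_attr(rxn, "id")
    s <- refIds(rxn, "listOfReactants")
    p <- refIds(rxn, "listOfProducts")
    if (length(s) == 0L || length(p) == 0L) {
      skipped <- c(skipped, id)
      next
    }
    rAttr <- xml2::xml_attr(rxn, "reversible")
    rid <- c(rid, id)
    subs[[length(subs) + 1L]] <- s
    prods[[length(prods) + 1L]] <- p
    rev <- c(rev, is.na(rAttr) || identical(rAttr, "true"))
  }
  if (length(skipped))
    warning(path, ": skipped reaction(s) with no reactants or products: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(rid))
    stop(path, ": no usable reactions", call. = FALSE)
  .reactionSet(rid, subs, prods, rev)
}

#' Write a raw reaction set as a minimal SBML Level 3 document
#'
#' Serialises the species and reaction lists (no kinetics, no stoichiometry
#' beyond unit references, one default compartment). Mainly used to
#' round-trip networks between the table and SBML readers.
#'
#' @param network raw reaction set.
#' @param path output file path.
#' @param modelId model id attribute.
#' @return the path, invisibly.
#' @export
writeSBML <- function(network, path, modelId = "model") {
  compounds <- .csort(unique(c(unlist(network$substrates),
                             unlist(network$products))))
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    sprintf('  <model id="%s">', esc(modelId)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    sprintf('      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            esc(compounds)),
    '    </listOfSpecies>',
    '    <listOfReactions>')
  for (i in seq_len(nrow(network))) {
    lines <- c(lines,
      sprintf('      <reaction id="%s" reversible="%s">',
              esc(network$reaction_id[i]),
              tolower(as.character(network$reversible[i]))),
      '        <listOfReactants>',
      sprintf('          <speciesReference species="%s" constant="true"/>',
              esc(network$substrates[[i]])),
      '        </listOfReactants>',
      '        <listOfProducts>',
      sprintf('          <speciesReference species="%s" constant="true"/>',
              esc(network$products[[i]])),
      '        </listOfProducts>',
      '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
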