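#' Build the symbiosis class hierarchy
#'
#' Constructs the full class graph of symbiotic-interaction types: the root
#' class \code{symbiosis}, its two location-based children
#' \code{ectosymbiosis} and \code{endosymbiosis}, the outcome-based subtypes
#' under each (mutualism, commensalism, agonism and its intimate/transient
#' refinements, amensalism, antagonism, and the endosymbiotic
#' parasitism/parasitoidism/commensalism/mutualism quartet), and the
#' obligatory/facultative refinements of the eight refineable leaf families.
#' The symbiosis branch (root plus all descendants) contains exactly 34
#' classes. Two auxiliary outcome-process classes, \code{bodily harm} and
#' \code{bodily benefit}, are minted outside the branch, and three classes are
#' referenced as imports from the Gene Ontology: GO:0044419 (interspecies
#' interaction between organisms, the parent of symbiosis), GO:0051704
#' (multi-organism process) and GO:0051705 (multi-organism behavior, used in
#' the symbiosis equivalence axiom).
#'
#' Each minted class carries a verbatim textual definition and a
#' machine-readable differentia (pairwise outcome pattern, spatial mode,
#' contact mode, fatality, necessity) used by [classify_interaction()].
#'
#' @return An object of class \code{symbio_taxonomy}: a list with elements
#'   \code{classes} (data frame: \code{id}, \code{label}, \code{definition},
#'   \code{provenance}), \code{edges} (data frame of child/parent labels) and
#'   \code{differentia} (named list keyed by label).
#' @examples
#' tax <- build_taxonomy()
#' length(branch_labels(tax))  # 34
#' is_subclass(tax, "grazing", "transient agonism")
#' @export
build_taxonomy <- function() {
  rows <- taxonomy_table()
  classes <- data.frame(
    id = vapply(rows, `[[`, "", "id"),
    label = vapply(rows, `[[`, "", "label"),
    definition = vapply(rows, `[[`, "", "definition"),
    provenance = vapply(rows, `[[`, "", "provenance"),
    stringsAsFactors = FALSE
  )
  edges <- do.call(rbind, lapply(rows, function(r) {
    if (length(r$parents) == 0L) return(NULL)
    data.frame(child = r$label, parent = r$parents, stringsAsFactors = FALSE)
  }))
  differentia <- lapply(rows, `[[`, "differentia")
  names(differentia) <- classes$label
  tax <- structure(
    list(classes = classes, edges = edges, differentia = differentia),
    class = "symbio_taxonomy"
  )
  stopifnot(!is_cyclic_labels(edges))
  tax
}

# One row per class; minted SYMB ids follow the subtype table's row order.
taxonomy_table <- function() {
  n <- 0L
  symb_id <- function() {
    n <<- n + 1L
    sprintf("SYMB:%07d", n)
  }
  d <- function(pattern = NULL, spatial = NULL, contact = NULL,
                fatal = NULL, necessity = NULL) {
    list(pattern = pattern, spatial = spatial, contact = contact,
         fatal = fatal, necessity = necessity)
  }
  mk <- function(id, label, definition, parents, differentia = d(),
                 provenance = "minted") {
    list(id = id, label = label, definition = definition,
         parents = parents, differentia = differentia,
         provenance = provenance)
  }

  imported <- list(
    mk("GO:0051704", "multi-organism process", "",
       character(0), provenance = "imported"),
    mk("GO:0044419", "interspecies interaction between organisms", "",
       "multi-organism process", provenance = "imported"),
    mk("GO:0051705", "multi-organism behavior", "",
       character(0), provenance = "imported")
  )

  root <- mk(symb_id(), "symbiosis",
    "An interspecies interaction between two or more organisms in intimate association.",
    "interspecies interaction between organisms", d())

  ecto <- mk("APOLLO_SV:00000337", "ectosymbiosis",
    "A symbiosis where the organisms that are interacting remain physically external to one another.",
    "symbiosis", d(spatial = "ecto"))
  endo <- mk("APOLLO_SV:00000354", "endosymbiosis",
    "A symbiosis where one organism is physically contained within another extended organism.",
    "symbiosis", d(spatial = "endo"))

  pat <- list(
    pm = c("benefit", "harm"), pp = c("benefit", "benefit"),
    p0 = c("benefit", "neutral"), m0 = c("harm", "neutral"),
    mm = c("harm", "harm")
  )

  subtype <- list(
    mk(symb_id(), "agonism",
      "An ectosymbiosis that results in harm to one of the participating organisms and benefit to another participating organism",
      "ectosymbiosis", d(pat$pm, "ecto")),
    mk(symb_id(), "intimate agonism",
      "An agonism where the participating organisms, although physically external to one another, nevertheless have close and persistent physical contact for most or all of the interaction",
      "agonism", d(pat$pm, "ecto", "intimate_persistent")),
    mk(symb_id(), "ectosymbiotic parasitism",
      "An intimate agonism in which the harm is not fatal to the host",
      "intimate agonism", d(pat$pm, "ecto", "intimate_persistent", FALSE)),
    mk(symb_id(), "ectosymbiotic parasitoidism",
      "An intimate agonism in which the harm is fatal to the host",
      "intimate agonism", d(pat$pm, "ecto", "intimate_persistent", TRUE)),
    mk(symb_id(), "transient agonism",
      "An agonism where the participating organisms maintain significant physical separation from one another through most or all of the interaction",
      "agonism", d(pat$pm, "ecto", "transient")),
    mk(symb_id(), "grazing",
      "A transient agonism in which the harm is not fatal",
      "transient agonism", d(pat$pm, "ecto", "transient", FALSE)),
    mk(symb_id(), "predation",
      "A transient agonism in which the harm is fatal",
      "transient agonism", d(pat$pm, "ecto", "transient", TRUE)),
    mk(symb_id(), "amensalism",
      "An ectosymbiosis that results in harm to one of the participating organisms but neither harms nor benefits the other participating organisms",
      "ectosymbiosis", d(pat$m0, "ecto")),
    mk(symb_id(), "antagonism",
      "An ectosymbiosis that results in harm to all participating organisms",
      "ectosymbiosis", d(pat$mm, "ecto")),
    mk(symb_id(), "ectosymbiotic commensalism",
      "An ectosymbiosis that results in benefit to one participating organism and neither harm nor benefit to the other participating organisms",
      "ectosymbiosis", d(pat$p0, "ecto")),
    mk(symb_id(), "ectosymbiotic mutualism",
      "An ectosymbiosis that results in benefit to all participating organisms",
      "ectosymbiosis", d(pat$pp, "ecto")),
    mk(symb_id(), "endosymbiotic parasitism",
      "An endosymbiosis that results in benefit to the parasite and harm to the host",
      "endosymbiosis", d(pat$pm, "endo", fatal = FALSE)),
    mk(symb_id(), "endosymbiotic parasitoidism",
      "An endosymbiosis that results in benefit to the parasitoid and death to the host",
      "endosymbiosis", d(pat$pm, "endo", fatal = TRUE)),
    mk(symb_id(), "endosymbiotic commensalism",
      "An endosymbiosis that results in benefit to one organism and neither harm nor benefit to the other participating organisms",
      "endosymbiosis", d(pat$p0, "endo")),
    mk(symb_id(), "endosymbiotic mutualism",
      "An endosymbiosis that results in benefit to all participating organisms",
      "endosymbiosis", d(pat$pp, "endo"))
  )

  refineable <- c(
    "ectosymbiotic parasitism", "ectosymbiotic parasitoidism",
    "ectosymbiotic commensalism", "ectosymbiotic mutualism",
    "endosymbiotic parasitism", "endosymbiotic parasitoidism",
    "endosymbiotic commensalism", "endosymbiotic mutualism"
  )
  ob_defs <- c(
    "An ectosymbiotic parasitism that realizes a biological function that inheres in some proper part of the parasite",
    "An ectosymbiotic parasitoidism that realizes a biological function that inheres in some proper part of the parasitoid",
    "An ectosymbiotic commensalism that realizes a biological function that inheres in some proper part of the commensal organism that benefits",
    "An ectosymbiotic mutualism that realizes a biological function that inheres in some proper part of at least one of the organisms participating",
    "An endosymbiotic parasitism that realizes a biological function that inheres in some proper part of the parasite",
    "An endosymbiotic parasitoidism that realizes a biological function that inheres in some proper part of the parasitoid",
    "An endosymbiotic commensalism that realizes a biological function that inheres in some proper part of the commensal organism that benefits",
    "An endosymbiotic mutualism that realizes a biological function that inheres in some proper part of at least one of the organisms participating"
  )
  fac_defs <- c(
    "An ectosymbiotic parasitism that realizes some facultative parasite role inhering in an organism that is also realized by a bodily benefit to that organism",
    "An ectosymbiotic parasitoidism that realizes some facultative parasitoid role inhering in an organism that is also realized by a bodily benefit to that organism",
    "An ectosymbiotic commensalism that realizes some facultative commensal role inhering in an organism that is also realized by a bodily benefit to that organism",
    "An ectosymbiotic mutualism that realizes some facultative mutualist role inhering in an organism that is also realized by a bodily benefit to that organism",
    "An endosymbiotic parasitism that realizes some facultative parasite role inhering in an organism that is also realized by a bodily benefit to that organism",
    "An endosymbiotic parasitoidism that realizes some facultative parasitoid role inhering in an organism that is also realized by a bodily benefit to that organism",
    "An endosymbiotic commensalism that realizes some facultative commensal role inhering in an organism that is also realized by a bodily benefit to that organism",
    "An endosymbiotic mutualism that realizes some facultative mutualist role inhering in an organism that is also realized by a bodily benefit to that organism"
  )
  by_label <- function(lbl) subtype[[which(vapply(subtype, `[[`, "", "label") == lbl)]]
  refine <- function(prefix, necessity, defs) {
    lapply(seq_along(refineable), function(i) {
      base <- by_label(refineable[i])
      diff <- base$differentia
      diff$necessity <- necessity
      mk(symb_id(), paste(prefix, refineable[i]), defs[i], refineable[i], diff)
    })
  }
  obligatory <- refine("obligatory", "obligate", ob_defs)
  facultative <- refine("facultative", "facultative", fac_defs)

  outcome_classes <- list(
    mk("APOLLO_SV:00000371", "bodily harm",
      "A process consisting of a change in the structure integrity of some anatomical structure that weakens or strengthens some homeostasis disposition or function inhering in that anatomical structure, such that the strength of the disposition (function) deviates outside of the range that is necessary to maintain in homeostatic range those bodily qualities that its realization influences.",
      character(0)),
    mk("APOLLO_SV:00000372", "bodily benefit",
      "A process that facilitates the realization of one or more normal homeostasis dispositions borne by an organism and/or one or more causally relatively isolated parts of the organism.",
      character(0))
  )

  c(imported, list(root, ecto, endo), subtype, obligatory, facultative,
    outcome_classes)
}

#' @export
print.symbio_taxonomy <- function(x, ...) {
  minted <- sum(x$classes$provenance == "minted")
  imported <- sum(x$classes$provenance == "imported")
  cat("Symbiosis taxonomy:", nrow(x$classes), "classes (",
      minted, "minted,", imported, "imported )\n")
  cat("Symbiosis branch size:", length(branch_labels(x)), "\n")
  invisible(x)
}

# ---- graph helpers -------------------------------------------------------

is_cyclic_labels <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")])
  !igraph::is_dag(g)
}

tax_has_label <- function(tax, label) label %in% tax$classes$label

tax_stopifnot_label <- function(tax, label) {
  if (!tax_has_label(tax, label)) {
    stop_symbio("symbio_lookup_error",
                sprintf("unknown class label: '%s'", label))
  }
}

parents_of <- function(tax, label) {
  tax$edges$parent[tax$edges$child == label]
}

#' Ancestors of a class
#'
#' @param tax a [build_taxonomy()] graph
#' @param label class label (canonical or contracted synonym)
#' @param reflexive include the class itself?
#' @return character vector of ancestor labels, nearest first
#' @export
ancestors_of <- function(tax, label, reflexive = FALSE) {
  label <- canonical_label(label)
  tax_stopifnot_label(tax, label)
  out <- if (reflexive) label else character(0)
  frontier <- parents_of(tax, label)
  while (length(frontier) > 0L) {
    out <- c(out, frontier)
    frontier <- unique(unlist(lapply(frontier, parents_of, tax = tax)))
    frontier <- setdiff(frontier, out)
  }
  unique(out)
}

#' Descendants of a class
#' @inheritParams ancestors_of
#' @return character vector of descendant labels
#' @export
descendants_of <- function(tax, label, reflexive = FALSE) {
  label <- canonical_label(label)
  tax_stopifnot_label(tax, label)
  out <- if (reflexive) label else character(0)
  frontier <- tax$edges$child[tax$edges$parent == label]
  while (length(frontier) > 0L) {
    out <- c(out, frontier)
    frontier <- unique(unlist(lapply(
      frontier, function(l) tax$edges$child[tax$edges$parent == l])))
    frontier <- setdiff(frontier, out)
  }
  unique(out)
}

#' Labels of the symbiosis branch (root plus all descendants)
#' @param tax a [build_taxonomy()] graph
#' @return character vector of 34 labels
#' @export
branch_labels <- function(tax) {
  descendants_of(tax, "symbiosis", reflexive = TRUE)
}

#' Is one class a subclass of another?
#'
#' Reflexive, transitive subsumption over the is-a edges, computed
#' structurally (no DL reasoner involved).
#'
#' @inheritParams ancestors_of
#' @param child_label,ancestor_label class labels (synonyms accepted)
#' @return logical scalar
#' @examples
#' tax <- build_taxonomy()
#' is_subclass(tax, "grazing", "transient agonism")
#' @export
is_subclass <- function(tax, child_label, ancestor_label) {
  child_label <- canonical_label(child_label)
  ancestor_label <- canonical_label(ancestor_label)
  tax_stopifnot_label(tax, child_label)
  tax_stopifnot_label(tax, ancestor_label)
  ancestor_label %in% ancestors_of(tax, child_label, reflexive = TRUE)
}

#' Differentia of a minted class
#'
#' The partial interaction-profile constraints that characterise a class:
#' pairwise outcome pattern, spatial mode, contact mode, fatality and
#' necessity. Fields not constrained by the class are NULL.
#'
#' @inheritParams ancestors_of
#' @return named list with elements \code{pattern}, \code{spatial},
#'   \code{contact}, \code{fatal}, \code{necessity}
#' @export
differentia_of <- function(tax, label) {
  label <- canonical_label(label)
  tax_stopifnot_label(tax, label)
  if (tax$classes$provenance[tax$classes$label == label] != "minted") {
    stop_symbio("symbio_lookup_error",
                sprintf("'%s' is an imported class without differentia", label))
  }
  tax$differentia[[label]]
}

# ---- synonyms ------------------------------------------------------------

# Contracted spellings used by the scenario tables ("obligatory
# endoparasitism" etc.) mapped to the canonical subtype-table labels.
synonym_map <- local({
  families <- c("parasitism", "parasitoidism", "commensalism", "mutualism")
  prefixes <- c("", "obligatory ", "facultative ")
  short <- character(0)
  long <- character(0)
  for (p in prefixes) {
    for (loc in c("ecto", "endo")) {
      short <- c(short, paste0(p, loc, families))
      long <- c(long, paste0(p, loc, "symbiotic ", families))
    }
  }
  stats::setNames(long, short)
})

#' Canonical label for a (possibly contracted) class label
#'
#' Maps contracted spellings such as "obligatory endoparasitism" to their
#' canonical forms ("obligatory endosymbiotic parasitism"). Labels with no
#' known contraction are returned unchanged.
#'
#' @param label character vector of labels
#' @return character vector of canonical labels
#' @export
canonical_label <- function(label) {
  hit <- label %in% names(synonym_map)
  label[hit] <- unname(synonym_map[label[hit]])
  label
}

# cached default taxonomy for internal consumers (validator, injector, CLI)
.symbio_cache <- new.env(parent = emptyenv())

default_taxonomy <- function() {
  if (is.null(.symbio_cache$tax)) .symbio_cache$tax <- build_taxonomy()
  .symbio_cache$tax
}
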