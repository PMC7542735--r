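#' Create an empty referent-tracking store
#'
#' A referent-tracking store holds instance-level assertions about
#' particulars: a set of instance unique identifiers (IUIs of the form
#' \code{IUI-n}), a set of temporal regions (\code{t_n}, plus the
#' distinguished maximal region \code{t_max}, which denotes "at all times"),
#' instantiation tuples (particular instantiates type at region) and relation
#' tuples (particular relation particular, holding at a region). All
#' operations are functional: they return the updated store.
#'
#' @return an object of class \code{rt_store}
#' @examples
#' s <- rt_store()
#' s <- mint_iui(s)          # IUI-1
#' s <- declare_region(s, "t_1")
#' s <- assert_instantiation(s, "IUI-1", "human being", "t_1")
#' @export
rt_store <- function() {
  structure(
    list(
      iuis = character(0),
      regions = "t_max",
      instantiations = data.frame(particular = character(0),
                                  type = character(0),
                                  region = character(0),
                                  stringsAsFactors = FALSE),
      relations = data.frame(subject = character(0), relation = character(0),
                             object = character(0), holds_at = character(0),
                             note = character(0), stringsAsFactors = FALSE),
      taxa = data.frame(iui = character(0), taxid = character(0),
                        stringsAsFactors = FALSE),
      outcomes = data.frame(process = character(0), participant = character(0),
                            value = character(0), fatal = logical(0),
                            stringsAsFactors = FALSE)
    ),
    class = "rt_store"
  )
}

#' @export
print.rt_store <- function(x, ...) {
  cat("Referent-tracking store:",
      length(x$iuis), "IUIs,",
      length(x$regions), "temporal regions,",
      nrow(x$instantiations), "instantiation tuples,",
      nrow(x$relations), "relation tuples\n")
  invisible(x)
}

iui_index <- function(id) as.integer(sub("^IUI-", "", id))

#' Mint the next IUI
#'
#' Returns the store with a fresh IUI appended: \code{IUI-n} with
#' n = 1 + the largest existing index (or \code{start} for an empty store).
#'
#' @param store an [rt_store()]
#' @param start index for the first IUI of an empty store
#' @return the updated store; the minted id is \code{last_iui(store)}
#' @export
mint_iui <- function(store, start = 1L) {
  stopifnot(inherits(store, "rt_store"))
  n <- if (length(store$iuis) == 0L) start else max(iui_index(store$iuis)) + 1L
  store$iuis <- c(store$iuis, sprintf("IUI-%d", n))
  store
}

#' @rdname mint_iui
#' @export
last_iui <- function(store) {
  if (length(store$iuis) == 0L) return(NULL)
  store$iuis[[length(store$iuis)]]
}

#' Declare a temporal region
#'
#' @param store an [rt_store()]
#' @param id region id of the form \code{t_n} (\code{t_max} always exists)
#' @return the updated store (idempotent)
#' @export
declare_region <- function(store, id) {
  stopifnot(inherits(store, "rt_store"))
  if (!grepl("^t_([0-9]+|max)$", id)) {
    stop_symbio("symbio_param_error",
                sprintf("temporal region ids look like 't_n', got '%s'", id))
  }
  store$regions <- union(store$regions, id)
  store
}

is_declared <- function(store, id) {
  id %in% store$iuis || id %in% store$regions
}

check_declared <- function(store, ids) {
  missing <- ids[!vapply(ids, is_declared, NA, store = store)]
  if (length(missing) > 0L) {
    stop_symbio("symbio_integrity_error",
                sprintf("undeclared id(s): %s", paste(missing, collapse = ", ")))
  }
}

#' Assert an instantiation tuple
#'
#' Records that a particular instantiates a type during a temporal region.
#' The type may be a taxonomy class label (canonical or contracted), an NCBI
#' taxid, or free text. Set semantics: re-asserting an existing tuple leaves
#' the store unchanged.
#'
#' @param store an [rt_store()]
#' @param particular a declared IUI
#' @param type class label, taxid or free text
#' @param region a declared temporal region
#' @return the updated store
#' @export
assert_instantiation <- function(store, particular, type, region) {
  stopifnot(inherits(store, "rt_store"))
  if (!particular %in% store$iuis) {
    stop_symbio("symbio_integrity_error",
                sprintf("particular '%s' is not declared", particular))
  }
  if (!region %in% store$regions) {
    stop_symbio("symbio_integrity_error",
                sprintf("temporal region '%s' is not declared", region))
  }
  row <- data.frame(particular = particular, type = type, region = region,
                    stringsAsFactors = FALSE)
  dup <- store$instantiations$particular == particular &
    store$instantiations$type == type &
    store$instantiations$region == region
  if (!any(dup)) store$instantiations <- rbind(store$instantiations, row)
  store
}

# Closed relation vocabulary and the subject/object sorts each admits.
# "iui" = a particular, "region" = a temporal region.
relation_sorts <- list(
  "has-participant" = list(c("iui", "iui")),
  "occurs-in" = list(c("iui", "iui")),
  "part-of" = list(c("iui", "iui")),
  "precedes" = list(c("iui", "iui"), c("region", "region")),
  "occupies-temporal-region" = list(c("iui", "region")),
  "part-of-occurrent" = list(c("iui", "iui"), c("region", "region")),
  "proper-part-of-occurrent" = list(c("iui", "iui"), c("region", "region")),
  "has-output" = list(c("iui", "iui")),
  "has-input" = list(c("iui", "iui")),
  "located-in" = list(c("iui", "iui")),
  "spatially-disjoint-from" = list(c("iui", "iui"))
)

#' The closed relation vocabulary
#' @return character vector of admissible relation names
#' @export
relation_vocabulary <- function() names(relation_sorts)

id_sort <- function(store, id) {
  if (id %in% store$iuis) "iui" else if (id %in% store$regions) "region"
  else NA_character_
}

#' Assert a relation tuple
#'
#' Records that \code{subject relation object} holds during \code{holds_at}.
#' The relation must belong to the closed vocabulary
#' ([relation_vocabulary()]) and the subject/object sorts must fit it (e.g.
#' \code{occupies-temporal-region} relates a particular to a region;
#' \code{part-of-occurrent} relates two regions or two occurrent
#' particulars). Set semantics on repeats.
#'
#' @param store an [rt_store()]
#' @param subject,object declared IUIs or temporal regions
#' @param relation relation name
#' @param holds_at a declared temporal region (\code{t_max} = at all times)
#' @param note free-text annotation
#' @return the updated store
#' @export
assert_relation <- function(store, subject, relation, object,
                            holds_at = "t_max", note = "") {
  stopifnot(inherits(store, "rt_store"))
  if (!relation %in% names(relation_sorts)) {
    stop_symbio("symbio_vocabulary_error",
                sprintf("relation '%s' is not in the closed vocabulary", relation))
  }
  check_declared(store, c(subject, object))
  if (!holds_at %in% store$regions) {
    stop_symbio("symbio_integrity_error",
                sprintf("holds-at region '%s' is not declared", holds_at))
  }
  sorts <- c(id_sort(store, subject), id_sort(store, object))
  ok <- any(vapply(relation_sorts[[relation]],
                   function(s) identical(s, sorts), NA))
  if (!ok) {
    stop_symbio("symbio_sort_error", sprintf(
      "relation '%s' does not admit subject/object sorts %s/%s",
      relation, sorts[1L], sorts[2L]))
  }
  dup <- store$relations$subject == subject &
    store$relations$relation == relation &
    store$relations$object == object &
    store$relations$holds_at == holds_at
  if (!any(dup)) {
    store$relations <- rbind(store$relations, data.frame(
      subject = subject, relation = relation, object = object,
      holds_at = holds_at, note = note, stringsAsFactors = FALSE))
  }
  store
}

#' Attach a taxon identifier to a particular
#'
#' Taxon identifiers are opaque strings (NCBI taxids as printed); they drive
#' the interspecies validation rule.
#'
#' @param store an [rt_store()]
#' @param iui a declared IUI
#' @param taxid taxon identifier string
#' @return the updated store
#' @export
set_taxon <- function(store, iui, taxid) {
  stopifnot(inherits(store, "rt_store"))
  if (!iui %in% store$iuis) {
    stop_symbio("symbio_integrity_error",
                sprintf("particular '%s' is not declared", iui))
  }
  taxid <- as.character(taxid)
  hit <- store$taxa$iui == iui
  if (any(hit)) {
    store$taxa$taxid[hit] <- taxid
  } else {
    store$taxa <- rbind(store$taxa, data.frame(
      iui = iui, taxid = taxid, stringsAsFactors = FALSE))
  }
  store
}

#' Annotate the outcome of an interaction for one participant
#'
#' Optional metadata consumed by the neutralism validation rule.
#'
#' @param store an [rt_store()]
#' @param process the interaction's IUI
#' @param participant the participant's IUI
#' @param value "benefit", "harm" or "neutral"
#' @param fatal logical; meaningful only for "harm"
#' @return the updated store
#' @export
set_outcome <- function(store, process, participant, value, fatal = NA) {
  stopifnot(inherits(store, "rt_store"))
  check_declared(store, c(process, participant))
  if (!value %in% c("benefit", "harm", "neutral")) {
    stop_symbio("symbio_param_error",
                "outcome value must be 'benefit', 'harm' or 'neutral'")
  }
  hit <- store$outcomes$process == process &
    store$outcomes$participant == participant
  row <- data.frame(process = process, participant = participant,
                    value = value, fatal = as.logical(fatal),
                    stringsAsFactors = FALSE)
  if (any(hit)) store$outcomes[hit, ] <- row
  else store$outcomes <- rbind(store$outcomes, row)
  store
}

#' Participants of a process
#'
#' @param store an [rt_store()]
#' @param process a declared process IUI
#' @return character vector of participant IUIs (objects of the process's
#'   has-participant tuples), sorted by IUI index
#' @export
participants_of <- function(store, process) {
  stopifnot(inherits(store, "rt_store"))
  if (!process %in% store$iuis) {
    stop_symbio("symbio_integrity_error",
                sprintf("process '%s' is not declared", process))
  }
  hit <- store$relations$relation == "has-participant" &
    store$relations$subject == process
  p <- unique(store$relations$object[hit])
  p[order(iui_index(p))]
}

#' Check the temporal ordering assertions of a store
#'
#' Verifies that \code{precedes} is a strict partial order (irreflexive and
#' acyclic after transitive closure) and that the occurrent-parthood
#' relations are acyclic. Violations are reported, not raised.
#'
#' @param store an [rt_store()]
#' @return a list with \code{consistent} (logical), \code{order} (topological
#'   order of the process IUIs appearing in precedes tuples, NULL if
#'   inconsistent) and \code{violations} (character vector of descriptions)
#' @export
temporal_check <- function(store) {
  stopifnot(inherits(store, "rt_store"))
  violations <- character(0)

  prec <- store$relations[store$relations$relation == "precedes", , drop = FALSE]
  refl <- prec$subject == prec$object
  if (any(refl)) {
    violations <- c(violations, sprintf(
      "precedes is not irreflexive: %s precedes itself",
      paste(unique(prec$subject[refl]), collapse = ", ")))
  }
  order <- NULL
  if (nrow(prec) > 0L) {
    g <- igraph::graph_from_data_frame(prec[, c("subject", "object")])
    if (!igraph::is_dag(g)) {
      violations <- c(violations, "precedes contains a cycle")
    } else {
      ord <- names(igraph::topo_sort(g, mode = "out"))
      order <- ord[ord %in% store$iuis]
    }
  } else {
    order <- character(0)
  }

  part <- store$relations[store$relations$relation %in%
    c("part-of-occurrent", "proper-part-of-occurrent"), , drop = FALSE]
  proper <- part[part$relation == "proper-part-of-occurrent", , drop = FALSE]
  if (any(proper$subject == proper$object)) {
    violations <- c(violations,
                    "proper-part-of-occurrent is not irreflexive")
  }
  # part-of-occurrent tolerates reflexivity; cycles over the non-reflexive
  # edges (proper parthood implies parthood) are genuine violations
  strict <- part[part$subject != part$object, , drop = FALSE]
  if (nrow(strict) > 0L) {
    g <- igraph::graph_from_data_frame(strict[, c("subject", "object")])
    if (!igraph::is_dag(g)) {
      violations <- c(violations, "occurrent parthood contains a cycle")
    }
  }

  list(consistent = length(violations) == 0L, order = order,
       violations = violations)
}

# ---- canonical form & equality ------------------------------------------

region_index <- function(id) {
  ifelse(id == "t_max", Inf, suppressWarnings(as.numeric(sub("^t_", "", id))))
}

canonical_store <- function(store) {
  o <- order(iui_index(store$iuis))
  store$iuis <- store$iuis[o]
  store$regions <- store$regions[order(region_index(store$regions),
                                       store$regions)]
  inst <- store$instantiations
  inst <- inst[order(inst$particular, inst$type, inst$region), , drop = FALSE]
  rownames(inst) <- NULL
  store$instantiations <- inst
  rel <- store$relations
  rel <- rel[order(rel$subject, rel$relation, rel$object, rel$holds_at), ,
             drop = FALSE]
  rownames(rel) <- NULL
  store$relations <- rel
  tx <- store$taxa[order(store$taxa$iui), , drop = FALSE]
  rownames(tx) <- NULL
  store$taxa <- tx
  oc <- store$outcomes
  oc <- oc[order(oc$process, oc$participant), , drop = FALSE]
  rownames(oc) <- NULL
  store$outcomes <- oc
  store
}

#' Are two stores equal?
#'
#' Compares the canonical (sorted) form of each component; tuple order and
#' note formatting do not affect equality of tuple sets.
#'
#' @param a,b [rt_store()] objects
#' @param ignore_notes drop the free-text note column before comparing
#' @return logical scalar
#' @export
rt_equal <- function(a, b, ignore_notes = FALSE) {
  a <- canonical_store(a)
  b <- canonical_store(b)
  if (ignore_notes) {
    a$relations$note <- NULL
    b$relations$note <- NULL
  }
  isTRUE(all.equal(unclass(a), unclass(b), check.attributes = FALSE))
}
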