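#' The validation rule catalogue
#'
#' The rules enforce the axioms of the representation at the instance level:
#'
#' * R1 MIN_PARTICIPANTS — a symbiosis-branch instance must have at least 2
#'   has-participant tuples. One asserted participant positively violates the
#'   minimum-cardinality-2 axiom (error); zero asserted participants is
#'   treated as incomplete assertion (warning).
#' * R2 INTERSPECIES — the participants with known taxa must span at least
#'   two taxa (error); participants without taxa are skipped with an info
#'   finding.
#' * R3 ENDO_LOCATION — an endosymbiosis-branch instance should have a
#'   located-in tuple among its participants (warning if absent); a
#'   spatially-disjoint-from tuple among them contradicts the endo axiom
#'   (error).
#' * R4 ECTO_LOCATION — dual of R3 for the ecto branch: located-in among the
#'   participants contradicts it (error); absence of spatially-disjoint-from
#'   evidence is a warning.
#' * R5 TEMPORAL_PARTHOOD — the region occupied by an interaction must be an
#'   occurrent part of each participant's existence region (warning if
#'   unasserted).
#' * R6 PRECEDES_ORDER — precedes must be a strict partial order, and
#'   occurrent parthood acyclic (error).
#' * R7 NEUTRALISM — a symbiosis instance must not carry all-neutral outcome
#'   annotations (error): an interaction affecting none of its participants
#'   is a contradiction.
#' * R8 INTIMACY_EVIDENCE — advisory: an ecto instance with neither contact
#'   nor multi-organism-behaviour evidence (no occurs-in assertion) yields an
#'   info finding.
#'
#' @return data frame with columns \code{rule_id}, \code{name},
#'   \code{severity} (the severity of a positive violation) and
#'   \code{threshold} (R1's participant minimum; NA elsewhere)
#' @export
list_rules <- function() {
  data.frame(
    rule_id = paste0("R", 1:8),
    name = c("MIN_PARTICIPANTS", "INTERSPECIES", "ENDO_LOCATION",
             "ECTO_LOCATION", "TEMPORAL_PARTHOOD", "PRECEDES_ORDER",
             "NEUTRALISM", "INTIMACY_EVIDENCE"),
    severity = c("error", "error", "error", "error", "warning", "error",
                 "error", "info"),
    threshold = c(2L, rep(NA_integer_, 7L)),
    stringsAsFactors = FALSE
  )
}

#' Validate a referent-tracking store against the taxonomy axioms
#'
#' Runs the full rule catalogue ([list_rules()]) over the store. Instances of
#' symbiosis-branch classes are recognised through their instantiation types
#' (canonical labels and contracted synonyms alike). The result is a pure,
#' deterministic function of the store and taxonomy: findings are sorted by
#' (rule id, subject).
#'
#' @param store an [rt_store()]
#' @param tax a [build_taxonomy()] graph
#' @return a data frame of class \code{symbio_validation} with columns
#'   \code{rule_id}, \code{severity}, \code{subject}, \code{message}
#' @examples
#' report <- validate_store(build_scenario(1))
#' sum(report$severity == "error")  # 0
#' @export
validate_store <- function(store, tax = default_taxonomy()) {
  stopifnot(inherits(store, "rt_store"))
  check_declared(store, unique(c(store$instantiations$particular,
                                 store$relations$subject,
                                 store$relations$object)))
  findings <- list()
  emit <- function(rule_id, severity, subject, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      rule_id = rule_id, severity = severity, subject = subject,
      message = message, stringsAsFactors = FALSE)
  }

  branch <- branch_labels(tax)
  inst <- store$instantiations
  inst$canonical <- canonical_label(inst$type)
  sym <- inst[inst$canonical %in% branch, , drop = FALSE]
  endo_desc <- descendants_of(tax, "endosymbiosis", reflexive = TRUE)
  ecto_desc <- descendants_of(tax, "ectosymbiosis", reflexive = TRUE)

  rel <- store$relations
  pair_rel <- function(relname, ids) {
    # any tuple of `relname` with both ends among `ids`
    hit <- rel$relation == relname & rel$subject %in% ids & rel$object %in% ids
    any(hit)
  }

  # region reachability over occurrent-parthood edges (reflexive)
  part_edges <- rel[rel$relation %in%
    c("part-of-occurrent", "proper-part-of-occurrent"), c("subject", "object")]
  region_reaches <- function(from, to) {
    if (from == to) return(TRUE)
    if (nrow(part_edges) == 0L) return(FALSE)
    seen <- from
    frontier <- from
    while (length(frontier) > 0L) {
      nxt <- unique(part_edges$object[part_edges$subject %in% frontier])
      if (to %in% nxt) return(TRUE)
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    FALSE
  }

  for (k in seq_len(nrow(sym))) {
    p <- sym$particular[k]
    cls <- sym$canonical[k]
    parts <- participants_of(store, p)

    # R1 MIN_PARTICIPANTS
    if (length(parts) == 1L) {
      emit("R1", "error", p, sprintf(
        "%s instantiates '%s' but has 1 asserted participant; the symbiosis axiom requires has-participant min 2",
        p, cls))
    } else if (length(parts) == 0L) {
      emit("R1", "warning", p, sprintf(
        "%s instantiates '%s' but no has-participant tuples are asserted (axiom requires min 2)",
        p, cls))
    }

    # R2 INTERSPECIES
    if (length(parts) >= 2L) {
      taxids <- store$taxa$taxid[match(parts, store$taxa$iui)]
      unknown <- parts[is.na(taxids)]
      if (length(unknown) > 0L) {
        emit("R2", "info", p, sprintf(
          "participants without taxon identifiers skipped: %s",
          paste(unknown, collapse = ", ")))
      }
      known <- taxids[!is.na(taxids)]
      if (length(known) >= 2L && length(unique(known)) < 2L) {
        emit("R2", "error", p, sprintf(
          "all participants of %s share taxon %s; an interspecies interaction requires organisms of different species",
          p, known[1L]))
      }
    }

    # R3 / R4 spatial coherence
    if (cls %in% endo_desc) {
      if (length(parts) >= 2L && pair_rel("spatially-disjoint-from", parts)) {
        emit("R3", "error", p, sprintf(
          "%s is an endosymbiosis but its participants are asserted spatially-disjoint-from one another",
          p))
      } else if (!pair_rel("located-in", parts)) {
        emit("R3", "warning", p, sprintf(
          "%s is an endosymbiosis but no located-in tuple is asserted among its participants",
          p))
      }
    }
    if (cls %in% ecto_desc) {
      if (length(parts) >= 2L && pair_rel("located-in", parts)) {
        emit("R4", "error", p, sprintf(
          "%s is an ectosymbiosis but one participant is asserted located-in another",
          p))
      } else if (!pair_rel("spatially-disjoint-from", parts)) {
        emit("R4", "warning", p, sprintf(
          "%s is an ectosymbiosis but no spatially-disjoint-from tuple is asserted among its participants",
          p))
      }
    }

    # R5 TEMPORAL_PARTHOOD
    occupied <- unique(c(
      sym$region[k],
      rel$object[rel$relation == "occupies-temporal-region" & rel$subject == p]))
    for (q in parts) {
      exist <- unique(inst$region[inst$particular == q])
      ok <- any(vapply(occupied, function(ti) {
        any(vapply(exist, function(tq) region_reaches(ti, tq), NA))
      }, NA))
      if (!ok) {
        emit("R5", "warning", p, sprintf(
          "the region occupied by %s is not asserted to be an occurrent part of the existence region of participant %s",
          p, q))
      }
    }

    # R7 NEUTRALISM
    oc <- store$outcomes[store$outcomes$process == p, , drop = FALSE]
    if (nrow(oc) > 0L && all(oc$value == "neutral")) {
      emit("R7", "error", p, sprintf(
        "%s carries all-neutral outcome annotations; a symbiosis affecting none of its participants is a contradiction",
        p))
    }

    # R8 INTIMACY_EVIDENCE (advisory, ecto branch)
    if (cls %in% ecto_desc) {
      has_evidence <- any(rel$relation == "occurs-in" & rel$subject == p)
      if (!has_evidence) {
        emit("R8", "info", p, sprintf(
          "%s is an ectosymbiosis with neither contact nor multi-organism-behaviour evidence asserted",
          p))
      }
    }
  }

  # R6 PRECEDES_ORDER (store-wide)
  tc <- temporal_check(store)
  for (v in tc$violations) emit("R6", "error", "<store>", v)

  out <- if (length(findings) == 0L) {
    data.frame(rule_id = character(0), severity = character(0),
               subject = character(0), message = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
  out <- out[order(out$rule_id, out$subject, out$message), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("symbio_validation", "data.frame")
  out
}

#' Error-severity findings of a validation report
#' @param report a [validate_store()] report
#' @return the subset of findings with severity "error"
#' @export
validation_errors <- function(report) {
  out <- report[report$severity == "error", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.symbio_validation <- function(x, ...) {
  n <- table(factor(x$severity, levels = c("error", "warning", "info")))
  cat(sprintf("Validation report: %d error(s), %d warning(s), %d info\n",
              n[["error"]], n[["warning"]], n[["info"]]))
  if (nrow(x) > 0L) print.data.frame(x)
  invisible(x)
}
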