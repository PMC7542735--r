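# Seeded synthetic scenario generation and fault injection for negative
# testing of the validator.

# taxon pools: hosts and symbionts drawn from the taxa appearing in the
# worked scenarios (taxids are opaque strings; the pools are disjoint so a
# generated interaction always spans two species)
host_taxa <- c("9606", "7165", "7029", "6945")
symbiont_taxa <- c("5855", "5551", "9", "1280", "5763")

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic host/symbiont interaction chain
#'
#' Emulates the shape of the vector-borne transmission scenario: one
#' symbiont aggregate engaging in a chain of successive interactions with a
#' series of hosts. Each interaction carries two has-participant tuples, an
#' occupies-temporal-region tuple, a temporal-parthood tuple into the host's
#' existence region, a located-in tuple for endo types, outcome annotations
#' consistent with its type, and a precedes edge to the next interaction in
#' the chain (\code{chain_length} interactions give
#' \code{chain_length - 1} precedes tuples forming a path). Generation is
#' deterministic given the seed, and the result validates with zero
#' error-severity findings.
#'
#' @param chain_length number of interactions in the chain (>= 1)
#' @param types class labels to sample interaction types from (canonical or
#'   contracted labels of symbiosis-branch classes)
#' @param seed integer seed
#' @param tax taxonomy used to resolve labels
#' @return an [rt_store()]
#' @examples
#' s <- generate_synthetic(chain_length = 3, seed = 1)
#' sum(validate_store(s)$severity == "error")  # 0
#' @export
generate_synthetic <- function(chain_length = 3L,
                               types = c("obligatory endoparasitism",
                                         "obligatory endocommensalism"),
                               seed = 1L,
                               tax = default_taxonomy()) {
  chain_length <- as.integer(chain_length)
  if (is.na(chain_length) || chain_length < 1L) {
    stop_symbio("symbio_param_error", "chain_length must be a positive integer")
  }
  canon <- canonical_label(types)
  unknown <- canon[!canon %in% branch_labels(tax)]
  if (length(unknown) > 0L) {
    stop_symbio("symbio_lookup_error", sprintf(
      "not symbiosis-branch classes: %s", paste(unknown, collapse = ", ")))
  }
  endo_desc <- descendants_of(tax, "endosymbiosis", reflexive = TRUE)

  with_seed(seed, {
    k <- chain_length
    sym_taxon <- sample(symbiont_taxa, 1L)
    hosts_taxon <- sample(host_taxa, k, replace = TRUE)
    type_of <- types[sample(length(types), k, replace = TRUE)]

    s <- rt_store()
    # IUI-1 = the symbiont aggregate; IUI-2..IUI-(k+1) = hosts;
    # IUI-(k+2).. = the interactions; regions parallel the IUIs
    for (i in seq_len(2L * k + 1L)) s <- mint_iui(s)
    for (i in seq_len(2L * k + 1L)) s <- declare_region(s, sprintf("t_%d", i))
    s <- assert_instantiation(s, "IUI-1", "object aggregate", "t_1")
    s <- set_taxon(s, "IUI-1", sym_taxon)
    for (i in seq_len(k)) {
      host <- sprintf("IUI-%d", i + 1L)
      s <- assert_instantiation(s, host, "organism", sprintf("t_%d", i + 1L))
      s <- set_taxon(s, host, hosts_taxon[i])
    }
    for (i in seq_len(k)) {
      proc <- sprintf("IUI-%d", k + 1L + i)
      host <- sprintf("IUI-%d", i + 1L)
      t_proc <- sprintf("t_%d", k + 1L + i)
      t_host <- sprintf("t_%d", i + 1L)
      lbl <- type_of[i]
      s <- assert_instantiation(s, proc, lbl, t_proc)
      s <- assert_relation(s, proc, "has-participant", "IUI-1", t_proc)
      s <- assert_relation(s, proc, "has-participant", host, t_proc)
      s <- assert_relation(s, proc, "occupies-temporal-region", t_proc)
      s <- assert_relation(s, t_proc, "part-of-occurrent", t_host)
      s <- assert_relation(s, t_proc, "part-of-occurrent", "t_1")
      canon_lbl <- canonical_label(lbl)
      if (canon_lbl %in% endo_desc) {
        s <- assert_relation(s, "IUI-1", "located-in", host, t_proc)
      } else {
        s <- assert_relation(s, "IUI-1", "spatially-disjoint-from", host, t_proc)
      }
      # outcome annotations implied by the interaction type's differentia
      diff <- differentia_of(tax, canon_lbl)
      pattern <- diff$pattern
      if (is.null(pattern)) pattern <- c("benefit", "neutral")
      s <- set_outcome(s, proc, "IUI-1", pattern[1L],
                       fatal = if (pattern[1L] == "harm") isTRUE(diff$fatal) else NA)
      s <- set_outcome(s, proc, host, pattern[2L],
                       fatal = if (pattern[2L] == "harm") isTRUE(diff$fatal) else NA)
      if (i > 1L) {
        prev <- sprintf("IUI-%d", k + i)
        s <- assert_relation(s, prev, "precedes", proc,
                             sprintf("t_%d", k + i))
      }
    }
    s
  })
}

#' Inject a validation fault into a store
#'
#' Returns a mutated copy of the store guaranteed to trigger the validation
#' rule matching the fault kind:
#' \describe{
#'   \item{drop_participant}{removes has-participant tuples from one
#'     interaction until exactly one remains (rule R1)}
#'   \item{same_species}{sets all participants of one interaction to the
#'     same taxon (rule R2)}
#'   \item{precedes_cycle}{reverses an existing precedes tuple to close a
#'     cycle (rule R6)}
#'   \item{all_neutral}{annotates one interaction's participants with
#'     all-neutral outcomes (rule R7)}
#'   \item{endo_spatial_contradiction}{asserts spatially-disjoint-from
#'     between the participants of an endosymbiosis instance (rule R3)}
#' }
#' Target selection is seeded and deterministic.
#'
#' @param store a valid [rt_store()]
#' @param fault fault kind (see above)
#' @param seed integer seed for target selection
#' @param tax taxonomy used to recognise interaction instances
#' @return the mutated store
#' @examples
#' bad <- inject_fault(build_scenario(1), "drop_participant")
#' any(validate_store(bad)$rule_id == "R1")
#' @export
inject_fault <- function(store,
                         fault = c("drop_participant", "same_species",
                                   "precedes_cycle", "all_neutral",
                                   "endo_spatial_contradiction"),
                         seed = 1L, tax = default_taxonomy()) {
  stopifnot(inherits(store, "rt_store"))
  fault <- match.arg(fault)
  branch <- branch_labels(tax)
  inst <- store$instantiations
  inst$canonical <- canonical_label(inst$type)
  sym <- inst[inst$canonical %in% branch, , drop = FALSE]
  pick <- function(xs) if (length(xs) == 1L) xs else sample(xs, 1L)
  not_applicable <- function(why) {
    stop_symbio("symbio_param_error",
                sprintf("fault '%s' is not applicable: %s", fault, why))
  }

  with_seed(seed, switch(fault,
    drop_participant = {
      cand <- sym$particular[vapply(sym$particular, function(p) {
        length(participants_of(store, p)) >= 2L
      }, NA)]
      if (length(cand) == 0L) {
        not_applicable("no interaction with >= 2 participants")
      }
      p <- pick(cand)
      keep <- participants_of(store, p)[1L]
      drop <- store$relations$relation == "has-participant" &
        store$relations$subject == p & store$relations$object != keep
      store$relations <- store$relations[!drop, , drop = FALSE]
      store
    },
    same_species = {
      cand <- sym$particular[vapply(sym$particular, function(p) {
        parts <- participants_of(store, p)
        length(parts) >= 2L && all(parts %in% store$taxa$iui)
      }, NA)]
      if (length(cand) == 0L) {
        not_applicable("no interaction whose participants all carry taxa")
      }
      p <- pick(cand)
      parts <- participants_of(store, p)
      taxid <- store$taxa$taxid[store$taxa$iui == parts[1L]]
      for (q in parts) store <- set_taxon(store, q, taxid)
      store
    },
    precedes_cycle = {
      prec <- store$relations[store$relations$relation == "precedes", ,
                              drop = FALSE]
      if (nrow(prec) == 0L) not_applicable("no precedes tuples to invert")
      i <- pick(seq_len(nrow(prec)))
      assert_relation(store, prec$object[i], "precedes", prec$subject[i],
                      prec$holds_at[i],
                      note = "injected: closes a precedes cycle")
    },
    all_neutral = {
      cand <- sym$particular[vapply(sym$particular, function(p) {
        length(participants_of(store, p)) >= 1L
      }, NA)]
      if (length(cand) == 0L) {
        not_applicable("no interaction with asserted participants")
      }
      p <- pick(cand)
      store$outcomes <- store$outcomes[store$outcomes$process != p, ,
                                       drop = FALSE]
      for (q in participants_of(store, p)) {
        store <- set_outcome(store, p, q, "neutral")
      }
      store
    },
    endo_spatial_contradiction = {
      endo_desc <- descendants_of(tax, "endosymbiosis", reflexive = TRUE)
      cand <- sym$particular[sym$canonical %in% endo_desc]
      cand <- cand[vapply(cand, function(p) {
        length(participants_of(store, p)) >= 2L
      }, NA)]
      if (length(cand) == 0L) {
        not_applicable("no endosymbiosis instance with >= 2 participants")
      }
      p <- pick(cand)
      parts <- participants_of(store, p)
      region <- store$instantiations$region[
        store$instantiations$particular == p][1L]
      # drop any located-in between the participants so the contradiction
      # stands alone
      drop <- store$relations$relation == "located-in" &
        store$relations$subject %in% parts &
        store$relations$object %in% parts
      store$relations <- store$relations[!drop, , drop = FALSE]
      assert_relation(store, parts[1L], "spatially-disjoint-from", parts[2L],
                      region,
                      note = "injected: contradicts the endosymbiosis location axiom")
    }
  ))
}
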