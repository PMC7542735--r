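#' Build one of the three worked scenario stores
#'
#' Reconstructs, tuple for tuple, the referent-tracking analyses of three
#' host-symbiont scenarios:
#'
#' * Scenario 1 — ectoparasitism: a Trichophyton rubrum colony (taxid 5551)
#'   causing ringworm on the skin of a human host's right elbow
#'   (4 instantiation tuples, 5 relation tuples).
#' * Scenario 2 — obligatory endoparasitism and obligatory endocommensalism:
#'   Plasmodium vivax (taxid 5855) transmitted between two human hosts
#'   (taxid 9606) by an Anopheles gambiae mosquito vector (taxid 7165)
#'   (9 particulars, 19 relation tuples, with a four-step precedes chain).
#' * Scenario 3 — obligatory endomutualism: a Buchnera aphidicola bacterium
#'   (taxid 9) synthesising tryptophan for its pea aphid host (taxid 7029)
#'   (6 particulars, 11 relation tuples).
#'
#' The printed source tables omit has-participant tuples linking the
#' Scenario 3 endomutualism (IUI-18) to the aphid and the bacterium; the
#' verbatim fixture omits them too (which the validator reports as a
#' warning-level incompleteness). \code{augmented = TRUE} adds the two
#' missing tuples.
#'
#' @param id scenario number, 1, 2 or 3
#' @param augmented Scenario 3 only: add the omitted has-participant tuples
#' @return an [rt_store()]
#' @examples
#' s1 <- build_scenario(1)
#' participants_of(s1, "IUI-4")
#' @export
build_scenario <- function(id, augmented = FALSE) {
  if (!id %in% 1:3) {
    stop_symbio("symbio_lookup_error", sprintf("unknown scenario id: %s", id))
  }
  switch(id, scenario_1(), scenario_2(), scenario_3(augmented))
}

# bulk builders keep the fixtures close to the shape of the printed tables
fixture_store <- function(first_iui, n_iuis, regions, inst, rel, taxa) {
  s <- rt_store()
  for (i in seq_len(n_iuis)) s <- mint_iui(s, start = first_iui)
  for (r in regions) s <- declare_region(s, r)
  for (row in inst) s <- assert_instantiation(s, row[[1]], row[[2]], row[[3]])
  for (row in rel) {
    s <- assert_relation(s, row[[1]], row[[2]], row[[3]], row[[4]],
                         note = row[[5]])
  }
  for (tx in taxa) s <- set_taxon(s, tx[[1]], tx[[2]])
  s
}

scenario_1 <- function() {
  fixture_store(
    first_iui = 1L, n_iuis = 4L,
    regions = c("t_1", "t_2", "t_3"),
    inst = list(
      list("IUI-1", "human being", "t_1"),
      list("IUI-2", "object aggregate", "t_2"),
      list("IUI-3", "skin of posterior part of right elbow", "t_1"),
      list("IUI-4", "ectoparasitism", "t_3")
    ),
    rel = list(
      list("IUI-4", "has-participant", "IUI-1", "t_3",
           "Ectoparasitism has participant Mr. Jones"),
      list("IUI-4", "has-participant", "IUI-2", "t_3",
           "Ectoparasitism has participant the colony of T. rubrum"),
      list("IUI-4", "occurs-in", "IUI-3", "t_3",
           "The ectoparasitism occurs in the skin of the posterior part of Mr. Jones' right elbow"),
      list("IUI-3", "part-of", "IUI-1", "t_1",
           "The skin of the posterior part of Mr. Jones' right elbow is part of Mr. Jones"),
      list("t_3", "part-of-occurrent", "t_1", "t_max",
           "The temporal interval occupied by the ectoparasitism is part of the temporal interval occupied by Mr. Jones existence")
    ),
    taxa = list(list("IUI-1", "9606"), list("IUI-2", "5551"))
  )
}

scenario_2 <- function() {
  fixture_store(
    first_iui = 4L, n_iuis = 9L,
    regions = paste0("t_", 4:12),
    inst = list(
      list("IUI-4", "human being", "t_4"),
      list("IUI-5", "Anopheles gambiae", "t_5"),
      list("IUI-6", "object aggregate", "t_6"),
      list("IUI-7", "human being", "t_7"),
      list("IUI-8", "object aggregate", "t_8"),
      list("IUI-9", "obligatory endoparasitism", "t_9"),
      list("IUI-10", "obligatory endocommensalism", "t_10"),
      list("IUI-11", "obligatory endoparasitism", "t_11"),
      list("IUI-12", "obligatory endocommensalism", "t_12")
    ),
    rel = list(
      list("IUI-9", "has-participant", "IUI-4", "t_9",
           "The obligatory endoparasitism denoted by IUI-9 has participant Mr. Joaquin"),
      list("IUI-9", "has-participant", "IUI-6", "t_9",
           "The obligatory endoparasitism denoted by IUI-9 has participant the aggregate of P. vivax parasites denoted by IUI-6"),
      list("IUI-10", "has-participant", "IUI-5", "t_10",
           "The obligatory endocommensalism denoted by IUI-10 has participant the A. gambiae mosquito denoted by IUI-5"),
      list("IUI-10", "has-participant", "IUI-6", "t_10",
           "The obligatory endocommensalism denoted by IUI-10 has participant the aggregate of P. vivax parasites denoted by IUI-6"),
      list("IUI-11", "has-participant", "IUI-7", "t_11",
           "The obligatory endoparasitism denoted by IUI-11 has participant Mrs. Chang"),
      list("IUI-11", "has-participant", "IUI-8", "t_11",
           "The obligatory endoparasitism denoted by IUI-11 has participant the aggregate of P. vivax sporozoites denoted by IUI-8"),
      list("IUI-12", "has-participant", "IUI-5", "t_12",
           "The obligatory endocommensalism denoted by IUI-12 has participant the A. gambiae mosquito denoted by IUI-5"),
      list("IUI-12", "has-participant", "IUI-8", "t_12",
           "The obligatory endocommensalism denoted by IUI-12 has participant the aggregate of P. vivax sporozoites denoted by IUI-8"),
      list("IUI-9", "precedes", "IUI-10", "t_9",
           "The obligatory endoparasitism denoted by IUI-9 precedes the obligatory endocommensalism denoted by IUI-10"),
      list("IUI-10", "precedes", "IUI-11", "t_10",
           "The obligatory endocommensalism denoted by IUI-10 precedes the obligatory endoparasitism denoted by IUI-11"),
      list("IUI-11", "precedes", "IUI-12", "t_11",
           "The obligatory endoparasitism denoted by IUI-11 precedes the obligatory endocommensalism denoted by IUI-12"),
      list("IUI-9", "occupies-temporal-region", "t_9", "t_max",
           "The obligatory endoparasitism denoted by IUI-9 occupies the temporal interval t_9"),
      list("IUI-10", "occupies-temporal-region", "t_10", "t_max",
           "The obligatory endocommensalism denoted by IUI-10 occupies the temporal interval t_10"),
      list("IUI-11", "occupies-temporal-region", "t_11", "t_max",
           "The obligatory endoparasitism denoted by IUI-11 occupies the temporal interval t_11"),
      list("IUI-12", "occupies-temporal-region", "t_12", "t_max",
           "The obligatory endocommensalism denoted by IUI-12 occupies the temporal interval t_12"),
      list("t_9", "part-of-occurrent", "t_4", "t_max",
           "The temporal interval occupied by the first obligatory endoparasitism is part of the temporal interval in which Mr. Joaquin has lived"),
      list("t_10", "part-of-occurrent", "t_5", "t_max",
           "The temporal interval occupied by the first obligatory endocommensalism is part of the temporal interval in which the mosquito has lived"),
      list("t_11", "part-of-occurrent", "t_7", "t_max",
           "The temporal interval occupied by the second obligatory endoparasitism is part of the temporal interval in which Mrs. Chang has lived"),
      list("t_12", "part-of-occurrent", "t_5", "t_max",
           "The temporal interval occupied by the second obligatory endocommensalism is part of the temporal interval in which the mosquito has lived")
    ),
    taxa = list(
      list("IUI-4", "9606"), list("IUI-5", "7165"), list("IUI-6", "5855"),
      list("IUI-7", "9606"), list("IUI-8", "5855")
    )
  )
}

scenario_3 <- function(augmented = FALSE) {
  s <- fixture_store(
    first_iui = 13L, n_iuis = 6L,
    regions = paste0("t_", 13:18),
    inst = list(
      list("IUI-13", "Acyrthosiphon pisum", "t_13"),
      list("IUI-14", "Buchnera aphidicola (Acyrthosiphon pisum)", "t_14"),
      list("IUI-15", "tryptophan biosynthetic process", "t_15"),
      list("IUI-16", "translation", "t_16"),
      list("IUI-17", "tryptophan", "t_17"),
      list("IUI-18", "obligatory endomutualism", "t_18")
    ),
    rel = list(
      list("IUI-15", "has-participant", "IUI-14", "t_15",
           "The tryptophan biosynthetic process has participant the B. aphidicola bacterium"),
      list("IUI-15", "has-output", "IUI-17", "t_15",
           "The tryptophan biosynthetic process has the tryptophan molecule"),
      list("IUI-16", "has-participant", "IUI-13", "t_16",
           "The translation process has participant the A. pisum aphid"),
      list("IUI-16", "has-input", "IUI-17", "t_16",
           "The translation process has input the tryptophan molecule"),
      list("IUI-15", "precedes", "IUI-16", "t_15",
           "The tryptophan biosynthetic process precedes the translation process in the host"),
      list("IUI-15", "proper-part-of-occurrent", "IUI-18", "t_15",
           "The tryptophan biosynthetic process is a proper occurrent part of the obligatory endomutualism"),
      list("IUI-18", "occupies-temporal-region", "t_18", "t_max",
           "The obligatory endomutualism occupies the temporal interval t_18"),
      list("t_15", "proper-part-of-occurrent", "t_14", "t_max",
           "The temporal interval occupied by the tryptophan biosynthetic process is a proper occurrent part of the temporal interval in which the B. aphidicola bacterium has lived"),
      list("t_16", "proper-part-of-occurrent", "t_13", "t_max",
           "The temporal interval occupied by the translation process is a proper occurrent part of the temporal interval in which the aphid has lived"),
      list("t_16", "proper-part-of-occurrent", "t_18", "t_max",
           "The temporal interval occupied by the translation process is a proper occurrent part of the temporal interval occupied by the obligatory endomutualism"),
      list("t_15", "proper-part-of-occurrent", "t_18", "t_max",
           "The temporal interval occupied by the tryptophan biosynthetic process is a proper occurrent part of the temporal interval occupied by the obligatory endomutualism")
    ),
    taxa = list(list("IUI-13", "7029"), list("IUI-14", "9"))
  )
  if (augmented) {
    s <- assert_relation(s, "IUI-18", "has-participant", "IUI-13", "t_18",
                         note = "augmented: endomutualism has participant the aphid")
    s <- assert_relation(s, "IUI-18", "has-participant", "IUI-14", "t_18",
                         note = "augmented: endomutualism has participant the bacterium")
  }
  s
}
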