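# Frozen expected tuple tables for the three scenario fixtures, written out
# independently of the fixture builders (notes excluded: they are annotation,
# not part of the tuple identity).

inst_df <- function(...) {
  m <- matrix(c(...), ncol = 3L, byrow = TRUE)
  data.frame(particular = m[, 1], type = m[, 2], region = m[, 3],
             stringsAsFactors = FALSE)
}

rel_df <- function(...) {
  m <- matrix(c(...), ncol = 4L, byrow = TRUE)
  data.frame(subject = m[, 1], relation = m[, 2], object = m[, 3],
             holds_at = m[, 4], stringsAsFactors = FALSE)
}

expected_instantiations <- list(
  inst_df(
    "IUI-1", "human being", "t_1",
    "IUI-2", "object aggregate", "t_2",
    "IUI-3", "skin of posterior part of right elbow", "t_1",
    "IUI-4", "ectoparasitism", "t_3"
  ),
  inst_df(
    "IUI-4", "human being", "t_4",
    "IUI-5", "Anopheles gambiae", "t_5",
    "IUI-6", "object aggregate", "t_6",
    "IUI-7", "human being", "t_7",
    "IUI-8", "object aggregate", "t_8",
    "IUI-9", "obligatory endoparasitism", "t_9",
    "IUI-10", "obligatory endocommensalism", "t_10",
    "IUI-11", "obligatory endoparasitism", "t_11",
    "IUI-12", "obligatory endocommensalism", "t_12"
  ),
  inst_df(
    "IUI-13", "Acyrthosiphon pisum", "t_13",
    "IUI-14", "Buchnera aphidicola (Acyrthosiphon pisum)", "t_14",
    "IUI-15", "tryptophan biosynthetic process", "t_15",
    "IUI-16", "translation", "t_16",
    "IUI-17", "tryptophan", "t_17",
    "IUI-18", "obligatory endomutualism", "t_18"
  )
)

expected_relations <- list(
  rel_df(
    "IUI-4", "has-participant", "IUI-1", "t_3",
    "IUI-4", "has-participant", "IUI-2", "t_3",
    "IUI-4", "occurs-in", "IUI-3", "t_3",
    "IUI-3", "part-of", "IUI-1", "t_1",
    "t_3", "part-of-occurrent", "t_1", "t_max"
  ),
  rel_df(
    "IUI-9", "has-participant", "IUI-4", "t_9",
    "IUI-9", "has-participant", "IUI-6", "t_9",
    "IUI-10", "has-participant", "IUI-5", "t_10",
    "IUI-10", "has-participant", "IUI-6", "t_10",
    "IUI-11", "has-participant", "IUI-7", "t_11",
    "IUI-11", "has-participant", "IUI-8", "t_11",
    "IUI-12", "has-participant", "IUI-5", "t_12",
    "IUI-12", "has-participant", "IUI-8", "t_12",
    "IUI-9", "precedes", "IUI-10", "t_9",
    "IUI-10", "precedes", "IUI-11", "t_10",
    "IUI-11", "precedes", "IUI-12", "t_11",
    "IUI-9", "occupies-temporal-region", "t_9", "t_max",
    "IUI-10", "occupies-temporal-region", "t_10", "t_max",
    "IUI-11", "occupies-temporal-region", "t_11", "t_max",
    "IUI-12", "occupies-temporal-region", "t_12", "t_max",
    "t_9", "part-of-occurrent", "t_4", "t_max",
    "t_10", "part-of-occurrent", "t_5", "t_max",
    "t_11", "part-of-occurrent", "t_7", "t_max",
    "t_12", "part-of-occurrent", "t_5", "t_max"
  ),
  rel_df(
    "IUI-15", "has-participant", "IUI-14", "t_15",
    "IUI-15", "has-output", "IUI-17", "t_15",
    "IUI-16", "has-participant", "IUI-13", "t_16",
    "IUI-16", "has-input", "IUI-17", "t_16",
    "IUI-15", "precedes", "IUI-16", "t_15",
    "IUI-15", "proper-part-of-occurrent", "IUI-18", "t_15",
    "IUI-18", "occupies-temporal-region", "t_18", "t_max",
    "t_15", "proper-part-of-occurrent", "t_14", "t_max",
    "t_16", "proper-part-of-occurrent", "t_13", "t_max",
    "t_16", "proper-part-of-occurrent", "t_18", "t_max",
    "t_15", "proper-part-of-occurrent", "t_18", "t_max"
  )
)

sort_tuples <- function(df) {
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}
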