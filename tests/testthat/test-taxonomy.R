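tax <- build_taxonomy()

test_that("the symbiosis branch has the expected shape and size", {
  branch <- branch_labels(tax)
  expect_length(branch, 34L)
  expect_setequal(
    intersect(branch, c("ectosymbiosis", "endosymbiosis")),
    c("ectosymbiosis", "endosymbiosis"))
  # only ecto/endo partition the branch directly under the root
  expect_setequal(tax$edges$child[tax$edges$parent == "symbiosis"],
                  c("ectosymbiosis", "endosymbiosis"))
  # no class sits under both location branches
  ecto <- descendants_of(tax, "ectosymbiosis")
  endo <- descendants_of(tax, "endosymbiosis")
  expect_length(intersect(ecto, endo), 0L)
  # exactly 8 obligatory and 8 facultative refinements
  expect_length(grep("^obligatory ", branch), 8L)
  expect_length(grep("^facultative ", branch), 8L)
  # acyclic with every minted branch class reachable from the root
  expect_true(all(vapply(branch, function(l) {
    is_subclass(tax, l, "symbiosis")
  }, NA)))
})

test_that("imported classes and minted identifiers are as published", {
  imported <- tax$classes[tax$classes$provenance == "imported", ]
  expect_setequal(imported$id, c("GO:0044419", "GO:0051704", "GO:0051705"))
  expect_equal(ancestors_of(tax, "symbiosis"),
               c("interspecies interaction between organisms",
                 "multi-organism process"))
  id_of <- function(l) tax$classes$id[tax$classes$label == l]
  expect_equal(id_of("ectosymbiosis"), "APOLLO_SV:00000337")
  expect_equal(id_of("endosymbiosis"), "APOLLO_SV:00000354")
  expect_equal(id_of("bodily harm"), "APOLLO_SV:00000371")
  expect_equal(id_of("bodily benefit"), "APOLLO_SV:00000372")
  # the two auxiliary outcome classes are minted outside the branch
  expect_false(any(c("bodily harm", "bodily benefit") %in% branch_labels(tax)))
  # every minted class carries a textual definition
  minted <- tax$classes[tax$classes$provenance == "minted", ]
  expect_true(all(nzchar(minted$definition)))
  # local identifiers are deterministic across rebuilds
  expect_identical(tax$classes$id, build_taxonomy()$classes$id)
})

test_that("subsumption follows the chained definitions", {
  expect_true(is_subclass(tax, "grazing", "transient agonism"))
  expect_true(is_subclass(tax, "grazing", "agonism"))
  expect_false(is_subclass(tax, "endosymbiotic mutualism", "ectosymbiosis"))
  expect_true(is_subclass(tax, "obligatory endosymbiotic mutualism", "symbiosis"))
  expect_true(is_subclass(tax, "symbiosis", "symbiosis"))  # reflexive
  expect_error(is_subclass(tax, "no such class", "symbiosis"),
               class = "symbio_lookup_error")
})

test_that("contracted labels resolve to their canonical forms", {
  expect_equal(canonical_label("obligatory endoparasitism"),
               "obligatory endosymbiotic parasitism")
  expect_equal(canonical_label("ectoparasitism"), "ectosymbiotic parasitism")
  expect_equal(canonical_label(c("endomutualism", "grazing")),
               c("endosymbiotic mutualism", "grazing"))
  expect_true(is_subclass(tax, "obligatory endomutualism", "endosymbiosis"))
})

test_that("differentia expose the discriminating characteristics", {
  d <- differentia_of(tax, "antagonism")
  expect_identical(sort(d$pattern), c("harm", "harm"))
  expect_identical(d$spatial, "ecto")
  expect_null(d$contact)
  # the root constrains nothing beyond being a symbiosis
  expect_true(all(vapply(differentia_of(tax, "symbiosis"), is.null, NA)))
  expect_identical(differentia_of(tax, "predation")$fatal, TRUE)
  expect_identical(differentia_of(tax, "obligatory endosymbiotic commensalism")$necessity,
                   "obligate")
  expect_error(differentia_of(tax, "multi-organism process"),
               class = "symbio_lookup_error")
  expect_error(differentia_of(tax, "nonexistent"),
               class = "symbio_lookup_error")
})
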