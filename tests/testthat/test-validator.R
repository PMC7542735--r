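tax <- build_taxonomy()

test_that("the rule catalogue publishes R1..R8 with the axiom's cardinality", {
  rules <- list_rules()
  expect_equal(rules$rule_id, paste0("R", 1:8))
  expect_equal(rules$threshold[rules$name == "MIN_PARTICIPANTS"], 2L)
  expect_equal(rules$severity[rules$name == "NEUTRALISM"], "error")
  expect_equal(rules$severity[rules$name == "INTIMACY_EVIDENCE"], "info")
})

# a minimal well-formed endosymbiosis instance to mutate in the rule tests
make_endo_store <- function() {
  s <- rt_store()
  for (i in 1:3) s <- mint_iui(s)
  for (r in c("t_1", "t_2", "t_3")) s <- declare_region(s, r)
  s <- assert_instantiation(s, "IUI-1", "human being", "t_1")
  s <- assert_instantiation(s, "IUI-2", "object aggregate", "t_2")
  s <- assert_instantiation(s, "IUI-3", "endosymbiotic parasitism", "t_3")
  s <- assert_relation(s, "IUI-3", "has-participant", "IUI-1", "t_3")
  s <- assert_relation(s, "IUI-3", "has-participant", "IUI-2", "t_3")
  s <- assert_relation(s, "IUI-2", "located-in", "IUI-1", "t_3")
  s <- assert_relation(s, "t_3", "part-of-occurrent", "t_1")
  s <- assert_relation(s, "t_3", "part-of-occurrent", "t_2")
  s <- set_taxon(s, "IUI-1", "9606")
  s <- set_taxon(s, "IUI-2", "1280")
  s
}

test_that("a well-formed instance validates without findings of any severity", {
  report <- validate_store(make_endo_store(), tax)
  expect_equal(nrow(report), 0L)
})

test_that("one asserted participant violates the min-2 axiom; none is incomplete", {
  s <- make_endo_store()
  s$relations <- s$relations[!(s$relations$relation == "has-participant" &
                                 s$relations$object == "IUI-2"), ]
  report <- validate_store(s, tax)
  expect_true(any(report$rule_id == "R1" & report$severity == "error"))
  expect_match(report$message[report$rule_id == "R1"], "min 2")

  s0 <- make_endo_store()
  s0$relations <- s0$relations[s0$relations$relation != "has-participant", ]
  report0 <- validate_store(s0, tax)
  expect_true(any(report0$rule_id == "R1" & report0$severity == "warning"))
  expect_false(any(report0$rule_id == "R1" & report0$severity == "error"))
})

test_that("conspecific participants violate the interspecies requirement", {
  s <- set_taxon(make_endo_store(), "IUI-2", "9606")
  report <- validate_store(s, tax)
  expect_true(any(report$rule_id == "R2" & report$severity == "error"))
  # participants without taxa are skipped with an info finding, not an error
  s2 <- make_endo_store()
  s2$taxa <- s2$taxa[s2$taxa$iui != "IUI-2", ]
  report2 <- validate_store(s2, tax)
  expect_true(any(report2$rule_id == "R2" & report2$severity == "info"))
  expect_false(any(report2$severity == "error"))
})

test_that("spatial assertions must cohere with the location branch", {
  # endo instance with spatially-disjoint participants: contradiction
  s <- assert_relation(make_endo_store(), "IUI-2", "spatially-disjoint-from",
                       "IUI-1", "t_3")
  report <- validate_store(s, tax)
  expect_true(any(report$rule_id == "R3" & report$severity == "error"))
  # endo instance without located-in: warning only
  s2 <- make_endo_store()
  s2$relations <- s2$relations[s2$relations$relation != "located-in", ]
  report2 <- validate_store(s2, tax)
  expect_true(any(report2$rule_id == "R3" & report2$severity == "warning"))
  expect_false(any(report2$severity == "error"))
  # ecto instance with located-in participants: contradiction
  s3 <- make_endo_store()
  s3$instantiations$type[s3$instantiations$particular == "IUI-3"] <-
    "ectosymbiotic mutualism"
  report3 <- validate_store(s3, tax)
  expect_true(any(report3$rule_id == "R4" & report3$severity == "error"))
})

test_that("missing temporal parthood is reported as incompleteness", {
  s <- make_endo_store()
  s$relations <- s$relations[s$relations$relation != "part-of-occurrent", ]
  report <- validate_store(s, tax)
  expect_equal(sum(report$rule_id == "R5"), 2L)
  expect_true(all(report$severity[report$rule_id == "R5"] == "warning"))
})

test_that("a precedes cycle is an error", {
  s <- build_scenario(2)
  s <- assert_relation(s, "IUI-12", "precedes", "IUI-9", "t_12")
  report <- validate_store(s, tax)
  expect_true(any(report$rule_id == "R6" & report$severity == "error"))
})

test_that("all-neutral outcome annotations contradict the definition of symbiosis", {
  s <- make_endo_store()
  s <- set_outcome(s, "IUI-3", "IUI-1", "neutral")
  s <- set_outcome(s, "IUI-3", "IUI-2", "neutral")
  report <- validate_store(s, tax)
  expect_true(any(report$rule_id == "R7" & report$severity == "error"))
  # consistent annotations do not fire R7
  s2 <- set_outcome(make_endo_store(), "IUI-3", "IUI-2", "benefit")
  s2 <- set_outcome(s2, "IUI-3", "IUI-1", "harm", fatal = FALSE)
  expect_false(any(validate_store(s2, tax)$rule_id == "R7"))
})

test_that("ecto instances without intimacy evidence get an advisory finding", {
  s1 <- build_scenario(1)  # has an occurs-in assertion: no advisory
  expect_false(any(validate_store(s1, tax)$rule_id == "R8"))
  s <- s1
  s$relations <- s$relations[s$relations$relation != "occurs-in", ]
  report <- validate_store(s, tax)
  expect_true(any(report$rule_id == "R8" & report$severity == "info"))
})

test_that("validation is deterministic", {
  s <- inject_fault(build_scenario(2), "precedes_cycle", seed = 5)
  expect_identical(validate_store(s, tax), validate_store(s, tax))
})
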