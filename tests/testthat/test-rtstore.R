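test_that("IUI minting is sequential and unique", {
  s <- rt_store()
  s <- mint_iui(s)
  expect_equal(last_iui(s), "IUI-1")
  s <- mint_iui(mint_iui(s))
  s <- mint_iui(s)
  expect_equal(last_iui(s), "IUI-4")
  expect_false(any(duplicated(s$iuis)))
  # configured starting index
  s2 <- mint_iui(rt_store(), start = 13L)
  expect_equal(last_iui(s2), "IUI-13")
  expect_equal(last_iui(mint_iui(s2)), "IUI-14")
})

test_that("assertions enforce referential integrity and set semantics", {
  s <- declare_region(mint_iui(rt_store()), "t_1")
  s <- assert_instantiation(s, "IUI-1", "human being", "t_1")
  n <- nrow(s$instantiations)
  s <- assert_instantiation(s, "IUI-1", "human being", "t_1")
  expect_equal(nrow(s$instantiations), n)  # idempotent
  expect_error(assert_instantiation(s, "IUI-99", "organism", "t_1"),
               class = "symbio_integrity_error")
  expect_error(assert_instantiation(s, "IUI-1", "organism", "t_99"),
               class = "symbio_integrity_error")
  expect_error(declare_region(s, "yesterday"), class = "symbio_param_error")
})

test_that("relation tuples respect the closed vocabulary and sorts", {
  s <- mint_iui(mint_iui(rt_store()))
  s <- declare_region(s, "t_1")
  s <- assert_relation(s, "IUI-2", "has-participant", "IUI-1", "t_1")
  expect_equal(nrow(s$relations), 1L)
  s <- assert_relation(s, "IUI-2", "has-participant", "IUI-1", "t_1")
  expect_equal(nrow(s$relations), 1L)  # idempotent
  expect_error(assert_relation(s, "IUI-2", "eats", "IUI-1", "t_1"),
               class = "symbio_vocabulary_error")
  # occupies-temporal-region relates a particular to a region, not two IUIs
  expect_error(assert_relation(s, "IUI-2", "occupies-temporal-region", "IUI-1"),
               class = "symbio_sort_error")
  # has-participant cannot take a region object
  expect_error(assert_relation(s, "IUI-2", "has-participant", "t_1"),
               class = "symbio_sort_error")
  # region-region and iui-iui occurrent parthood are both admissible
  s <- declare_region(s, "t_2")
  expect_silent(s <- assert_relation(s, "t_1", "part-of-occurrent", "t_2"))
  expect_silent(s <- assert_relation(s, "IUI-1", "proper-part-of-occurrent", "IUI-2"))
  expect_true("precedes" %in% relation_vocabulary())
  expect_length(relation_vocabulary(), 11L)
})

test_that("participants_of returns the asserted participant set", {
  s2 <- build_scenario(2)
  expect_equal(participants_of(s2, "IUI-10"), c("IUI-5", "IUI-6"))
  s3 <- build_scenario(3)
  expect_equal(participants_of(s3, "IUI-15"), "IUI-14")
  expect_equal(participants_of(s3, "IUI-17"), character(0))
  expect_error(participants_of(s3, "IUI-99"),
               class = "symbio_integrity_error")
})

test_that("temporal_check orders the scenario 2 chain and reports cycles", {
  tc <- temporal_check(build_scenario(2))
  expect_true(tc$consistent)
  expect_equal(tc$order, c("IUI-9", "IUI-10", "IUI-11", "IUI-12"))

  expect_true(temporal_check(rt_store())$consistent)

  s <- mint_iui(mint_iui(rt_store()))
  s <- declare_region(s, "t_1")
  s <- assert_relation(s, "IUI-1", "precedes", "IUI-2", "t_1")
  s <- assert_relation(s, "IUI-2", "precedes", "IUI-1", "t_1")
  tc <- temporal_check(s)
  expect_false(tc$consistent)
  expect_match(paste(tc$violations, collapse = " "), "cycle")
})

test_that("re-asserting a whole fixture leaves the store unchanged", {
  s <- build_scenario(1)
  again <- s
  for (i in seq_len(nrow(s$instantiations))) {
    again <- assert_instantiation(again, s$instantiations$particular[i],
                                  s$instantiations$type[i],
                                  s$instantiations$region[i])
  }
  for (i in seq_len(nrow(s$relations))) {
    again <- assert_relation(again, s$relations$subject[i],
                             s$relations$relation[i], s$relations$object[i],
                             s$relations$holds_at[i], s$relations$note[i])
  }
  expect_true(rt_equal(s, again))
})
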