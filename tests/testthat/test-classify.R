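tax <- build_taxonomy()

test_that("worked pairwise profiles classify to their published subtypes", {
  expect_equal(
    classify_interaction(tax, interaction_profile(
      c("benefit", "harm"), fatal = FALSE, spatial = "endo",
      necessity = "obligate")),
    "obligatory endosymbiotic parasitism")
  expect_equal(
    classify_interaction(tax, interaction_profile(
      c("benefit", "harm"), fatal = TRUE, spatial = "ecto",
      contact = "transient")),
    "predation")
  expect_equal(
    classify_interaction(tax, interaction_profile(
      c("benefit", "benefit"), spatial = "endo", necessity = "obligate")),
    "obligatory endosymbiotic mutualism")
  expect_equal(
    classify_interaction(tax, interaction_profile(
      c("benefit", "harm"), fatal = FALSE, spatial = "ecto",
      contact = "intimate_persistent")),
    "ectosymbiotic parasitism")
  expect_equal(
    classify_interaction(tax, interaction_profile(
      c("harm", "neutral"), spatial = "ecto")),
    "amensalism")
})

test_that("a three-party host/beneficiary/bystander profile is both a parasitism and a commensalism", {
  labels <- classify_interaction(tax, interaction_profile(
    c("benefit", "harm", "neutral"), fatal = FALSE, spatial = "endo"))
  expect_setequal(labels,
                  c("endosymbiotic parasitism", "endosymbiotic commensalism"))
})

test_that("undefined outcome combinations raise the defined errors", {
  expect_error(
    classify_interaction(tax, interaction_profile(c("neutral", "neutral"))),
    class = "symbio_neutralism_error")
  expect_error(
    classify_interaction(tax, interaction_profile(
      c("harm", "neutral"), spatial = "endo")),
    class = "symbio_unsupported_error")
  expect_error(
    classify_interaction(tax, interaction_profile(
      c("harm", "harm"), spatial = "endo")),
    class = "symbio_unsupported_error")
  expect_error(
    classify_interaction(tax, interaction_profile(
      c("benefit", "harm"), fatal = FALSE, spatial = "ecto")),
    class = "symbio_ambiguity_error")
  expect_error(
    classify_interaction(tax, interaction_profile(c("benefit", "harm"))),
    class = "symbio_ambiguity_error")
})

test_that("harm without fatality information defaults to non-fatal with a warning", {
  expect_warning(
    labels <- classify_interaction(tax, interaction_profile(
      c("benefit", "harm"), spatial = "endo")),
    "fatality")
  expect_equal(labels, "endosymbiotic parasitism")
})

test_that("profile construction enforces its invariants", {
  expect_error(interaction_profile("benefit"), class = "symbio_param_error")
  expect_error(interaction_profile(c("good", "bad")),
               class = "symbio_param_error")
  expect_error(interaction_profile(c("benefit", "harm"),
                                   fatal = c(TRUE, FALSE)),
               class = "symbio_param_error")
  p <- interaction_profile(c("+", "-", "0"), fatal = TRUE)
  expect_equal(p$outcomes, c("benefit", "harm", "neutral"))
  expect_equal(p$fatal, c(NA, TRUE, NA))
})

test_that("classification is exhaustive over the discrete profile space", {
  for (case in enumerate_cases()) {
    res <- classify_outcome(tax, case)
    if (is.null(res$error)) {
      expect_gt(length(res$labels), 0L)
    } else {
      expect_true(res$error %in% defined_errors)
    }
  }
})

test_that("every returned label satisfies the differentia of all its ancestors", {
  minted_branch <- branch_labels(tax)
  for (case in enumerate_cases()) {
    res <- classify_outcome(tax, case)
    if (is.null(res$error)) {
      for (lbl in res$labels) {
        for (anc in ancestors_of(tax, lbl, reflexive = TRUE)) {
          if (!anc %in% minted_branch) next
          expect_true(
            oracle_satisfies(case, differentia_of(tax, anc)),
            label = sprintf("case -> %s violates ancestor %s", lbl, anc))
        }
      }
    }
  }
})

test_that("no profile classifies into both location branches at once", {
  ecto <- descendants_of(tax, "ectosymbiosis", reflexive = TRUE)
  endo <- descendants_of(tax, "endosymbiosis", reflexive = TRUE)
  for (case in enumerate_cases()) {
    res <- classify_outcome(tax, case)
    if (is.null(res$error)) {
      expect_false(any(res$labels %in% ecto) && any(res$labels %in% endo))
    }
  }
})

test_that("profiles satisfying a class differentia classify to it or a descendant", {
  for (lbl in branch_labels(tax)) {
    diff <- differentia_of(tax, lbl)
    family <- descendants_of(tax, lbl, reflexive = TRUE)
    for (case in enumerate_cases()) {
      if (!oracle_satisfies(case, diff)) next
      res <- classify_outcome(tax, case)
      if (is.null(res$error)) {
        expect_true(any(res$labels %in% family),
                    label = sprintf("satisfier of '%s' classified as [%s]",
                                    lbl, paste(res$labels, collapse = ", ")))
      } else {
        expect_true(res$error %in% defined_errors)
      }
    }
  }
})
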