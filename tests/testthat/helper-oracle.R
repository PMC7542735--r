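# Independent brute-force oracle for the classifier tests.
#
# The oracle re-derives differentia satisfaction directly from the
# characteristics of a pairwise case (outcome pattern, spatial mode, contact
# mode, fatality, necessity), without going through the classifier or the
# taxonomy traversal code it is checking.

# all discrete pairwise cases: 5 patterns x 2 spatial x 3 contact x
# 3 necessity x 3 fatality states (TRUE / FALSE / unstated)
enumerate_cases <- function() {
  patterns <- list(
    c("benefit", "benefit"), c("benefit", "neutral"), c("benefit", "harm"),
    c("harm", "neutral"), c("harm", "harm")
  )
  cases <- list()
  for (pat in patterns) {
    for (spatial in c("ecto", "endo")) {
      for (contact in c("intimate_persistent", "transient", "unspecified")) {
        for (necessity in c("obligate", "facultative", "none")) {
          for (fatal in list(TRUE, FALSE, NA)) {
            cases[[length(cases) + 1L]] <- list(
              pattern = pat, spatial = spatial, contact = contact,
              necessity = necessity, fatal = fatal)
          }
        }
      }
    }
  }
  cases
}

case_profile <- function(case) {
  interaction_profile(case$pattern, fatal = case$fatal,
                      spatial = case$spatial, contact = case$contact,
                      necessity = case$necessity)
}

# does the case satisfy a differentia constraint set? (independent re-check)
oracle_satisfies <- function(case, diff) {
  if (!is.null(diff$pattern) &&
      !identical(sort(diff$pattern), sort(case$pattern))) {
    return(FALSE)
  }
  if (!is.null(diff$spatial) && diff$spatial != case$spatial) return(FALSE)
  if (!is.null(diff$contact) && diff$contact != case$contact) return(FALSE)
  if (!is.null(diff$fatal)) {
    effective <- isTRUE(case$fatal)  # unstated fatality defaults to non-fatal
    if (diff$fatal != effective) return(FALSE)
  }
  if (!is.null(diff$necessity)) {
    if (!"benefit" %in% case$pattern) return(FALSE)
    if (diff$necessity != case$necessity) return(FALSE)
  }
  TRUE
}

classify_quietly <- function(tax, profile) {
  suppressWarnings(classify_interaction(tax, profile))
}

defined_errors <- c("symbio_neutralism_error", "symbio_unsupported_error",
                    "symbio_ambiguity_error")

# classify and fold the outcome into a tagged list
classify_outcome <- function(tax, case) {
  tryCatch(
    list(labels = classify_quietly(tax, case_profile(case)), error = NULL),
    symbio_error = function(e) list(labels = NULL, error = class(e)[1L])
  )
}
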