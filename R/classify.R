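#' Construct an interaction profile
#'
#' An interaction profile is the classifier's input: the per-participant
#' outcome of the interaction (benefit, harm or neutral, with fatality for
#' harmed participants), the spatial mode (participants external to one
#' another vs. one located within another extended organism), the contact
#' mode for external interactions (close persistent contact vs. significant
#' physical separation), and the necessity of the interaction for each
#' benefiting participant (obligate: realizes a biological function;
#' facultative: realizes a role, merely advantageous).
#'
#' @param outcomes character vector (length >= 2), one of "benefit", "harm",
#'   "neutral" per participant; the shorthand "+", "-", "0" is accepted.
#' @param fatal logical vector parallel to \code{outcomes} (or a scalar,
#'   recycled); meaningful only where the outcome is "harm". NA means
#'   "not stated".
#' @param spatial "ecto", "endo" or "unspecified".
#' @param contact "intimate_persistent", "transient" or "unspecified";
#'   consulted only for ecto benefit/harm pairs.
#' @param necessity "obligate", "facultative" or "none"; a scalar applying to
#'   all benefiting participants, or a per-participant vector.
#' @param taxa optional character vector of taxon identifiers per participant.
#' @return an object of class \code{symbio_profile}
#' @examples
#' interaction_profile(c("benefit", "harm"), spatial = "endo",
#'                     necessity = "obligate")
#' @export
interaction_profile <- function(outcomes, fatal = NA,
                                spatial = c("unspecified", "ecto", "endo"),
                                contact = c("unspecified",
                                            "intimate_persistent", "transient"),
                                necessity = "none",
                                taxa = NULL) {
  shorthand <- c("+" = "benefit", "-" = "harm", "0" = "neutral")
  outcomes <- as.character(outcomes)
  hit <- outcomes %in% names(shorthand)
  outcomes[hit] <- shorthand[outcomes[hit]]
  if (length(outcomes) < 2L) {
    stop_symbio("symbio_param_error", "a profile needs >= 2 participants")
  }
  if (!all(outcomes %in% c("benefit", "harm", "neutral"))) {
    stop_symbio("symbio_param_error",
                "outcomes must be 'benefit', 'harm' or 'neutral'")
  }
  scalar_fatal <- length(fatal) == 1L
  fatal <- rep_len(as.logical(fatal), length(outcomes))
  # a scalar fatal describes the harmed participant(s); a full vector must
  # respect the invariant that only harm can be fatal
  if (!scalar_fatal && any(fatal & outcomes != "harm", na.rm = TRUE)) {
    stop_symbio("symbio_param_error", "fatal = TRUE requires outcome 'harm'")
  }
  fatal[outcomes != "harm"] <- NA
  spatial <- match.arg(spatial)
  contact <- match.arg(contact)
  necessity <- rep_len(as.character(necessity), length(outcomes))
  if (!all(necessity %in% c("obligate", "facultative", "none"))) {
    stop_symbio("symbio_param_error",
                "necessity must be 'obligate', 'facultative' or 'none'")
  }
  if (!is.null(taxa) && length(taxa) != length(outcomes)) {
    stop_symbio("symbio_param_error", "one taxon per participant")
  }
  structure(
    list(outcomes = outcomes, fatal = fatal, spatial = spatial,
         contact = contact, necessity = necessity, taxa = taxa),
    class = "symbio_profile"
  )
}

#' @export
print.symbio_profile <- function(x, ...) {
  mark <- c(benefit = "+", harm = "-", neutral = "0")[x$outcomes]
  mark[which(x$fatal)] <- "-(fatal)"
  cat("Interaction profile:", paste(mark, collapse = "/"),
      "| spatial:", x$spatial, "| contact:", x$contact,
      "| necessity:", paste(unique(x$necessity), collapse = ","), "\n")
  invisible(x)
}

#' Classify an interaction profile into the most specific subtype(s)
#'
#' Each unordered pair of participants is reduced to a pairwise outcome
#' pattern and mapped through the taxonomy differentia: benefit/benefit to
#' the mutualism family, benefit/neutral to commensalism, benefit/harm to the
#' agonism family (ecto, split on contact mode and fatality) or to
#' endosymbiotic parasitism/parasitoidism (endo, split on fatality),
#' harm/neutral to amensalism and harm/harm to antagonism (both ecto-only).
#' Obligate or facultative necessity refines the eight refineable classes to
#' their "obligatory ..."/"facultative ..." child. For more than two
#' participants the union of the pairwise classifications is returned (pairs
#' whose pattern is undefined under the given spatial mode contribute
#' nothing, provided some pair classifies).
#'
#' Errors (classed conditions): an all-neutral profile raises
#' \code{symbio_neutralism_error} (a symbiosis in which no organism is
#' affected is a contradiction, so no such class exists); a harm/neutral or
#' harm/harm pattern under the endo mode raises
#' \code{symbio_unsupported_error} (endosymbiosis is defined only for
#' mutualism, commensalism, parasitism and parasitoidism); an ecto
#' benefit/harm pair without a stated contact mode, or an unspecified
#' spatial mode, raises \code{symbio_ambiguity_error}.
#'
#' @param tax a [build_taxonomy()] graph
#' @param profile an [interaction_profile()]
#' @return character vector of most specific class labels (deduplicated)
#' @examples
#' tax <- build_taxonomy()
#' classify_interaction(tax, interaction_profile(
#'   c("benefit", "harm"), fatal = FALSE, spatial = "endo",
#'   necessity = "obligate"))
#' @export
classify_interaction <- function(tax, profile) {
  stopifnot(inherits(profile, "symbio_profile"))
  if (all(profile$outcomes == "neutral")) {
    stop_symbio("symbio_neutralism_error", paste(
      "all-neutral outcomes denote 'neutralism', a contradiction:",
      "a process in which an organism affects another, in which no",
      "organism is affected"))
  }
  idx <- seq_along(profile$outcomes)
  pairs <- utils::combn(idx, 2L, simplify = FALSE)
  multi <- length(idx) > 2L
  labels <- character(0)
  classified_any <- FALSE
  for (pr in pairs) {
    res <- tryCatch(
      classify_pair(tax, profile, pr[1L], pr[2L]),
      symbio_unsupported_error = function(e) if (multi) e else stop(e),
      symbio_neutralism_error = function(e) if (multi) e else stop(e)
    )
    if (inherits(res, "condition")) next
    classified_any <- TRUE
    labels <- c(labels, res)
  }
  if (!classified_any) {
    stop_symbio("symbio_unsupported_error",
                "no participant pair has a pattern defined under this spatial mode")
  }
  unique(labels)
}

# Classify one unordered participant pair (i, j).
classify_pair <- function(tax, profile, i, j) {
  oi <- profile$outcomes[i]
  oj <- profile$outcomes[j]
  pattern <- sort(c(oi, oj))
  if (identical(pattern, c("neutral", "neutral"))) {
    stop_symbio("symbio_neutralism_error",
                "neutral/neutral pair denotes 'neutralism'")
  }
  spatial <- profile$spatial
  if (spatial == "unspecified") {
    stop_symbio("symbio_ambiguity_error",
                "spatial mode (ecto/endo) must be specified to classify")
  }

  beneficiaries <- c(i, j)[c(oi, oj) == "benefit"]
  refine <- function(base) {
    nec <- setdiff(unique(profile$necessity[beneficiaries]), "none")
    if (length(nec) == 0L) return(base)
    vapply(nec, function(n) {
      paste(if (n == "obligate") "obligatory" else "facultative", base)
    }, "")
  }
  harmed_fatal <- function() {
    harmed <- c(i, j)[c(oi, oj) == "harm"][1L]
    f <- profile$fatal[harmed]
    if (is.na(f)) {
      warning("harm asserted without fatality information; assuming non-fatal",
              call. = FALSE)
      f <- FALSE
    }
    f
  }

  if (identical(pattern, c("benefit", "benefit"))) {
    return(refine(if (spatial == "ecto") "ectosymbiotic mutualism"
                  else "endosymbiotic mutualism"))
  }
  if (identical(pattern, c("benefit", "neutral"))) {
    return(refine(if (spatial == "ecto") "ectosymbiotic commensalism"
                  else "endosymbiotic commensalism"))
  }
  if (identical(pattern, c("benefit", "harm"))) {
    if (spatial == "endo") {
      base <- if (harmed_fatal()) "endosymbiotic parasitoidism"
              else "endosymbiotic parasitism"
      return(refine(base))
    }
    # ecto: split on contact mode first
    if (profile$contact == "unspecified") {
      stop_symbio("symbio_ambiguity_error", paste(
        "an ecto benefit/harm pair needs a contact mode to separate",
        "intimate agonism from transient agonism"))
    }
    if (profile$contact == "intimate_persistent") {
      base <- if (harmed_fatal()) "ectosymbiotic parasitoidism"
              else "ectosymbiotic parasitism"
      return(refine(base))
    }
    # transient agonism is not refineable by necessity
    return(if (harmed_fatal()) "predation" else "grazing")
  }
  if (identical(pattern, c("harm", "neutral"))) {
    if (spatial == "endo") {
      stop_symbio("symbio_unsupported_error",
                  "harm/neutral (amensalism) is defined only for ectosymbiosis")
    }
    return("amensalism")
  }
  # harm/harm
  if (spatial == "endo") {
    stop_symbio("symbio_unsupported_error",
                "harm/harm (antagonism) is defined only for ectosymbiosis")
  }
  "antagonism"
}
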