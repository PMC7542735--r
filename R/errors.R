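# Classed conditions so callers can catch specific failure modes.

stop_symbio <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "symbio_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

# error classes used throughout:
#   symbio_neutralism_error      - all-neutral outcome pattern (neutralism)
#   symbio_unsupported_error     - pattern undefined for the spatial mode
#   symbio_ambiguity_error       - required discriminating field unspecified
#   symbio_lookup_error          - unknown label / id
#   symbio_vocabulary_error      - relation outside the closed vocabulary
#   symbio_sort_error            - subject/object sorts do not fit the relation
#   symbio_integrity_error       - dangling reference in a store
#   symbio_parse_error           - malformed export document
#   symbio_format_error          - unsupported export format
#   symbio_param_error           - invalid generator/fault parameters
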