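# Deterministic serialization of taxonomies and referent-tracking stores.
#
# Three formats are supported for both object kinds:
#   "json" - a plain JSON dump with stable key order;
#   "ttl"  - Turtle: classes as owl:Class with rdfs:label, an IAO:0000115
#            definition annotation and rdfs:subClassOf axioms; relation
#            tuples as standard RDF reification (rdf:Statement) annotated
#            with their holds-at region; the three printed equivalence
#            axioms (symbiosis, ectosymbiosis, endosymbiosis) as OWL class
#            expressions;
#   "ofn"  - an OWL functional-syntax style text (Declaration /
#            AnnotationAssertion / SubClassOf / EquivalentClasses for the
#            taxonomy; a functional-style tuple dialect for stores).
#
# Emission is canonical (sorted statements, fixed prefix table), so
# identical inputs yield byte-identical documents, and import(export(x))
# reconstructs x exactly.

symbio_formats <- c("json", "ttl", "ofn")

PREFIXES <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#",
  xsd = "http://www.w3.org/2001/XMLSchema#",
  obo = "http://purl.obolibrary.org/obo/",
  symb = "http://example.org/symbiotax/"
)

ttl_prefix_header <- function() {
  sprintf("@prefix %s: <%s> .", names(PREFIXES), unname(PREFIXES))
}

ofn_prefix_header <- function() {
  sprintf("Prefix(%s:=<%s>)", names(PREFIXES), unname(PREFIXES))
}

curie_to_qname <- function(id) {
  ifelse(startsWith(id, "SYMB:"),
         paste0("symb:", sub(":", "_", id)),
         paste0("obo:", sub(":", "_", id)))
}

qname_to_curie <- function(q) {
  local <- sub("^[a-z]+:", "", q)
  sub("_(?=[0-9]+$)", ":", local, perl = TRUE)
}

esc_lit <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  gsub("\"", "\\\"", s, fixed = TRUE)
}

unesc_lit <- function(s) {
  s <- gsub("\\\"", "\"", s, fixed = TRUE)
  gsub("\\\\", "\\", s, fixed = TRUE)
}

# split "a ; b ; c ." segments, respecting quoted literals
split_segments <- function(line) {
  line <- sub("\\s*\\.\\s*$", "", line)
  chars <- strsplit(line, "")[[1]]
  out <- character(0)
  buf <- character(0)
  in_quote <- FALSE
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\"" && (i == 1L || chars[i - 1L] != "\\")) in_quote <- !in_quote
    if (!in_quote && ch == ";" && i > 1L && chars[i - 1L] == " ") {
      out <- c(out, trimws(paste(buf, collapse = "")))
      buf <- character(0)
    } else {
      buf <- c(buf, ch)
    }
    i <- i + 1L
  }
  c(out, trimws(paste(buf, collapse = "")))
}

first_literal <- function(s) {
  m <- regmatches(s, regexpr('"(?:[^"\\\\]|\\\\.)*"', s, perl = TRUE))
  if (length(m) == 0L) return(NA_character_)
  unesc_lit(substr(m, 2L, nchar(m) - 1L))
}

new_document <- function(kind, format, content) {
  structure(list(kind = kind, format = format, content = content),
            class = "symbio_document")
}

#' @export
print.symbio_document <- function(x, ...) {
  cat(sprintf("<symbio_document: %s, format %s, %d lines>\n",
              x$kind, x$format, length(strsplit(x$content, "\n")[[1]])))
  invisible(x)
}

#' Write an export document to a file
#' @param doc a [export_taxonomy()] / [export_store()] document
#' @param path output file path
#' @return the path, invisibly
#' @export
write_document <- function(doc, path) {
  stopifnot(inherits(doc, "symbio_document"))
  writeLines(doc$content, path, useBytes = TRUE)
  invisible(path)
}

# ---- differentia codec ---------------------------------------------------

diff_to_string <- function(d) {
  parts <- character(0)
  if (!is.null(d$pattern)) {
    parts <- c(parts, paste0("pattern=", paste(d$pattern, collapse = "|")))
  }
  for (f in c("spatial", "contact", "necessity")) {
    if (!is.null(d[[f]])) parts <- c(parts, paste0(f, "=", d[[f]]))
  }
  if (!is.null(d$fatal)) {
    parts <- c(parts, paste0("fatal=", tolower(as.character(d$fatal))))
  }
  paste(parts, collapse = "; ")
}

string_to_diff <- function(s) {
  d <- list(pattern = NULL, spatial = NULL, contact = NULL, fatal = NULL,
            necessity = NULL)
  if (is.na(s) || !nzchar(s)) return(d)
  for (part in strsplit(s, "; ", fixed = TRUE)[[1]]) {
    kv <- strsplit(part, "=", fixed = TRUE)[[1]]
    key <- kv[1L]
    val <- kv[2L]
    d[[key]] <- switch(key,
      pattern = strsplit(val, "|", fixed = TRUE)[[1]],
      fatal = as.logical(toupper(val)),
      val)
  }
  d
}

# ---- taxonomy export -----------------------------------------------------

#' Export the taxonomy to a standard document format
#'
#' Serializes every class with its label, textual definition annotation
#' (IAO:0000115), machine-readable differentia and is-a axioms. Imported
#' classes are emitted as references (identifier, label, parent) only. In
#' the "ttl" and "ofn" formats the three printed equivalence axioms are
#' additionally emitted as OWL class expressions: symbiosis as an
#' interspecies interaction with a minimum-cardinality-2 participant
#' restriction (or an occurrent multi-organism-behavior part), and
#' ecto-/endosymbiosis via spatially-disjoint-from / located-in existential
#' restrictions. Output is deterministic: exporting the same graph twice
#' yields identical bytes.
#'
#' @param tax a [build_taxonomy()] graph
#' @param format "json", "ttl" (Turtle) or "ofn" (functional-syntax style)
#' @return a \code{symbio_document}
#' @examples
#' doc <- export_taxonomy(build_taxonomy(), "ttl")
#' tax2 <- import_document(doc)
#' @export
export_taxonomy <- function(tax, format = c("json", "ttl", "ofn")) {
  stopifnot(inherits(tax, "symbio_taxonomy"))
  format <- check_format(format)
  cls <- tax$classes
  parents <- lapply(cls$label, function(l) parents_of(tax, l))
  content <- switch(format,
    json = taxonomy_json(tax, parents),
    ttl = taxonomy_ttl(tax, parents),
    ofn = taxonomy_ofn(tax, parents))
  new_document("taxonomy", format, content)
}

check_format <- function(format) {
  if (length(format) == 1L && !format %in% symbio_formats) {
    stop_symbio("symbio_format_error",
                sprintf("unsupported format '%s'", format))
  }
  match.arg(format, symbio_formats)
}

taxonomy_json <- function(tax, parents) {
  cls <- tax$classes
  records <- lapply(seq_len(nrow(cls)), function(i) {
    list(id = cls$id[i], label = cls$label[i], definition = cls$definition[i],
         parents = I(parents[[i]]),
         differentia = diff_to_string(tax$differentia[[cls$label[i]]]),
         provenance = cls$provenance[i])
  })
  jsonlite::toJSON(list(kind = "taxonomy", classes = records),
                   auto_unbox = TRUE, pretty = TRUE)
}

taxonomy_ttl <- function(tax, parents) {
  cls <- tax$classes
  id_of <- stats::setNames(cls$id, cls$label)
  lines <- c(ttl_prefix_header(), "")
  for (i in seq_len(nrow(cls))) {
    segs <- c(
      sprintf("%s a owl:Class", curie_to_qname(cls$id[i])),
      sprintf("rdfs:label \"%s\"", esc_lit(cls$label[i]))
    )
    if (nzchar(cls$definition[i])) {
      segs <- c(segs, sprintf("obo:IAO_0000115 \"%s\"",
                              esc_lit(cls$definition[i])))
    }
    ds <- diff_to_string(tax$differentia[[cls$label[i]]])
    if (cls$provenance[i] == "minted") {
      segs <- c(segs, sprintf("symb:differentia \"%s\"", esc_lit(ds)))
    }
    segs <- c(segs, sprintf("symb:provenance \"%s\"", cls$provenance[i]))
    for (p in parents[[i]]) {
      segs <- c(segs, sprintf("rdfs:subClassOf %s",
                              curie_to_qname(id_of[[p]])))
    }
    lines <- c(lines, paste0(paste(segs, collapse = " ; "), " ."))
  }
  c(lines, "", "# equivalence axioms", equivalence_axioms_ttl(id_of))
}

# the three printed equivalence axioms, as single-line Turtle
equivalence_axioms_ttl <- function(id_of) {
  q <- function(l) curie_to_qname(id_of[[l]])
  min2 <- function(filler) paste0(
    "[ a owl:Restriction ; owl:onProperty symb:has-participant ; ",
    "owl:minQualifiedCardinality \"2\"^^xsd:nonNegativeInteger ; ",
    "owl:onClass ", filler, " ]")
  some <- function(prop, filler) paste0(
    "[ a owl:Restriction ; owl:onProperty symb:", prop,
    " ; owl:someValuesFrom ", filler, " ]")
  inter <- function(...) paste0(
    "[ a owl:Class ; owl:intersectionOf ( ", paste(..., sep = " "), " ) ]")
  union <- function(...) paste0(
    "[ a owl:Class ; owl:unionOf ( ", paste(..., sep = " "), " ) ]")

  symbiosis <- paste0(
    q("symbiosis"), " owl:equivalentClass ",
    inter(q("interspecies interaction between organisms"),
          union(min2(inter("symb:organism",
                           some("is-bearer-of", "symb:contact"))),
                inter(some("has-occurrent-part",
                           q("multi-organism behavior")),
                      min2("symb:organism")))), " .")
  ecto <- paste0(
    q("ectosymbiosis"), " owl:equivalentClass ",
    inter(q("symbiosis"),
          some("has-participant",
               inter("symb:organism",
                     some("spatially-disjoint-from", "symb:organism")))), " .")
  endo <- paste0(
    q("endosymbiosis"), " owl:equivalentClass ",
    inter(q("symbiosis"),
          some("has-participant",
               inter("symb:organism",
                     some("located-in", "symb:organism")))), " .")
  c(symbiosis, ecto, endo)
}

taxonomy_ofn <- function(tax, parents) {
  cls <- tax$classes
  id_of <- stats::setNames(cls$id, cls$label)
  lines <- c(ofn_prefix_header(),
             "Ontology(<http://example.org/symbiotax/taxonomy>")
  for (i in seq_len(nrow(cls))) {
    qn <- curie_to_qname(cls$id[i])
    lines <- c(lines, sprintf("Declaration(Class(%s))", qn),
               sprintf("AnnotationAssertion(rdfs:label %s \"%s\")",
                       qn, esc_lit(cls$label[i])))
    if (nzchar(cls$definition[i])) {
      lines <- c(lines, sprintf("AnnotationAssertion(obo:IAO_0000115 %s \"%s\")",
                                qn, esc_lit(cls$definition[i])))
    }
    if (cls$provenance[i] == "minted") {
      lines <- c(lines, sprintf("AnnotationAssertion(symb:differentia %s \"%s\")",
                                qn,
                                esc_lit(diff_to_string(tax$differentia[[cls$label[i]]]))))
    }
    lines <- c(lines, sprintf("AnnotationAssertion(symb:provenance %s \"%s\")",
                              qn, cls$provenance[i]))
    for (p in parents[[i]]) {
      lines <- c(lines, sprintf("SubClassOf(%s %s)", qn,
                                curie_to_qname(id_of[[p]])))
    }
  }
  lines <- c(lines, equivalence_axioms_ofn(id_of), ")")
  lines
}

equivalence_axioms_ofn <- function(id_of) {
  q <- function(l) curie_to_qname(id_of[[l]])
  min2 <- function(filler) sprintf(
    "ObjectMinCardinality(2 symb:has-participant %s)", filler)
  some <- function(prop, filler) sprintf(
    "ObjectSomeValuesFrom(symb:%s %s)", prop, filler)
  inter <- function(...) sprintf("ObjectIntersectionOf(%s)",
                                 paste(..., sep = " "))
  union <- function(...) sprintf("ObjectUnionOf(%s)", paste(..., sep = " "))
  c(
    sprintf("EquivalentClasses(%s %s)", q("symbiosis"),
            inter(q("interspecies interaction between organisms"),
                  union(min2(inter("symb:organism",
                                   some("is-bearer-of", "symb:contact"))),
                        inter(some("has-occurrent-part",
                                   q("multi-organism behavior")),
                              min2("symb:organism"))))),
    sprintf("EquivalentClasses(%s %s)", q("ectosymbiosis"),
            inter(q("symbiosis"),
                  some("has-participant",
                       inter("symb:organism",
                             some("spatially-disjoint-from", "symb:organism"))))),
    sprintf("EquivalentClasses(%s %s)", q("endosymbiosis"),
            inter(q("symbiosis"),
                  some("has-participant",
                       inter("symb:organism",
                             some("located-in", "symb:organism")))))
  )
}

# ---- store export --------------------------------------------------------

#' Export a referent-tracking store
#'
#' Serializes every IUI, temporal region, instantiation tuple and relation
#' tuple, plus taxon and outcome metadata, losslessly. In Turtle, relation
#' tuples are emitted as standard RDF reification (one \code{rdf:Statement}
#' per tuple) carrying the holds-at region and the free-text note, so the
#' temporal qualification survives round trips through plain triple stores.
#'
#' @param store an [rt_store()]
#' @param format "json", "ttl" or "ofn"
#' @return a \code{symbio_document}
#' @examples
#' doc <- export_store(build_scenario(1), "json")
#' s2 <- import_document(doc)
#' rt_equal(build_scenario(1), s2)
#' @export
export_store <- function(store, format = c("json", "ttl", "ofn")) {
  stopifnot(inherits(store, "rt_store"))
  format <- check_format(format)
  store <- canonical_store(store)
  content <- switch(format,
    json = store_json(store),
    ttl = store_ttl(store),
    ofn = store_ofn(store))
  new_document("rt_store", format, content)
}

store_json <- function(store) {
  df_records <- function(df) {
    if (nrow(df) == 0L) return(list())
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  jsonlite::toJSON(list(
    kind = "rt_store",
    iuis = store$iuis,
    regions = store$regions,
    instantiations = df_records(store$instantiations),
    relations = df_records(store$relations),
    taxa = df_records(store$taxa),
    outcomes = df_records(store$outcomes)
  ), auto_unbox = TRUE, pretty = TRUE, na = "null")
}

store_ttl <- function(store) {
  lines <- c(ttl_prefix_header(), "")
  for (iui in store$iuis) {
    lines <- c(lines, sprintf("symb:%s a symb:Particular .", iui))
  }
  for (tx_i in seq_len(nrow(store$taxa))) {
    lines <- c(lines, sprintf("symb:%s symb:taxon \"%s\" .",
                              store$taxa$iui[tx_i], store$taxa$taxid[tx_i]))
  }
  for (r in store$regions) {
    lines <- c(lines, sprintf("symb:%s a symb:TemporalRegion .", r))
  }
  inst <- store$instantiations
  for (i in seq_len(nrow(inst))) {
    lines <- c(lines, sprintf(
      "symb:inst-%d a symb:InstantiationTuple ; symb:particular symb:%s ; symb:instantiatedType \"%s\" ; symb:atRegion symb:%s .",
      i, inst$particular[i], esc_lit(inst$type[i]), inst$region[i]))
  }
  rel <- store$relations
  for (i in seq_len(nrow(rel))) {
    note <- if (nzchar(rel$note[i])) {
      sprintf(" ; symb:note \"%s\"", esc_lit(rel$note[i]))
    } else ""
    lines <- c(lines, sprintf(
      "symb:rel-%d a rdf:Statement ; rdf:subject symb:%s ; rdf:predicate symb:%s ; rdf:object symb:%s ; symb:holdsAt symb:%s%s .",
      i, rel$subject[i], rel$relation[i], rel$object[i], rel$holds_at[i], note))
  }
  oc <- store$outcomes
  for (i in seq_len(nrow(oc))) {
    fatal <- if (is.na(oc$fatal[i])) "" else {
      sprintf(" ; symb:fatal \"%s\"^^xsd:boolean", tolower(oc$fatal[i]))
    }
    lines <- c(lines, sprintf(
      "symb:out-%d a symb:OutcomeAnnotation ; symb:process symb:%s ; symb:participant symb:%s ; symb:value \"%s\"%s .",
      i, oc$process[i], oc$participant[i], oc$value[i], fatal))
  }
  lines
}

store_ofn <- function(store) {
  lines <- c(ofn_prefix_header(), "Store(<http://example.org/symbiotax/store>")
  lines <- c(lines, sprintf("Particular(symb:%s)", store$iuis))
  if (nrow(store$taxa) > 0L) {
    lines <- c(lines, sprintf("Taxon(symb:%s \"%s\")",
                              store$taxa$iui, store$taxa$taxid))
  }
  lines <- c(lines, sprintf("TemporalRegion(symb:%s)", store$regions))
  inst <- store$instantiations
  if (nrow(inst) > 0L) {
    lines <- c(lines, sprintf("Instantiation(symb:%s \"%s\" symb:%s)",
                              inst$particular, esc_lit(inst$type), inst$region))
  }
  rel <- store$relations
  if (nrow(rel) > 0L) {
    lines <- c(lines, sprintf("Relation(symb:%s symb:%s symb:%s symb:%s \"%s\")",
                              rel$subject, rel$relation, rel$object,
                              rel$holds_at, esc_lit(rel$note)))
  }
  oc <- store$outcomes
  if (nrow(oc) > 0L) {
    lines <- c(lines, sprintf("Outcome(symb:%s symb:%s \"%s\" \"%s\")",
                              oc$process, oc$participant, oc$value,
                              tolower(as.character(oc$fatal))))
  }
  c(lines, ")")
}

# ---- import --------------------------------------------------------------

#' Import an export document
#'
#' Reconstructs a taxonomy graph or a referent-tracking store from a
#' document produced by [export_taxonomy()] / [export_store()] (or any text
#' conforming to the documented dialect). The object kind and format are
#' detected from the content; \code{import(export(x))} reproduces \code{x}.
#'
#' @param doc a \code{symbio_document}, a file path, or the document text
#'   (single string or character vector of lines)
#' @return a \code{symbio_taxonomy} or an \code{rt_store}
#' @export
import_document <- function(doc) {
  if (inherits(doc, "symbio_document")) {
    lines <- doc$content
  } else if (is.character(doc) && length(doc) == 1L && !grepl("\n", doc) &&
             file.exists(doc)) {
    lines <- readLines(doc, warn = FALSE)
  } else if (is.character(doc)) {
    lines <- unlist(strsplit(doc, "\n", fixed = TRUE))
  } else {
    stop_symbio("symbio_parse_error", "cannot interpret document input")
  }
  lines <- paste(lines, collapse = "\n")
  lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  stripped <- trimws(lines)
  stripped <- stripped[nzchar(stripped)]
  if (length(stripped) == 0L) {
    stop_symbio("symbio_parse_error", "empty document")
  }
  if (startsWith(stripped[1L], "{")) return(import_json(lines))
  if (startsWith(stripped[1L], "@prefix")) return(import_ttl(stripped))
  if (startsWith(stripped[1L], "Prefix(")) return(import_ofn(stripped))
  stop_symbio("symbio_parse_error",
              "unrecognised document format (expected JSON, Turtle or functional syntax)")
}

import_json <- function(lines) {
  x <- tryCatch(
    jsonlite::fromJSON(paste(lines, collapse = "\n"), simplifyVector = FALSE),
    error = function(e) {
      stop_symbio("symbio_parse_error", paste("JSON parse error:", conditionMessage(e)))
    })
  if (identical(x$kind, "taxonomy")) return(taxonomy_from_records(x$classes))
  if (identical(x$kind, "rt_store")) return(store_from_records(x))
  stop_symbio("symbio_parse_error", "JSON document has no recognised 'kind'")
}

taxonomy_from_records <- function(records) {
  classes <- data.frame(
    id = vapply(records, function(r) r$id, ""),
    label = vapply(records, function(r) r$label, ""),
    definition = vapply(records, function(r) r$definition, ""),
    provenance = vapply(records, function(r) r$provenance, ""),
    stringsAsFactors = FALSE
  )
  edges <- do.call(rbind, lapply(records, function(r) {
    ps <- unlist(r$parents)
    if (length(ps) == 0L) return(NULL)
    data.frame(child = r$label, parent = ps, stringsAsFactors = FALSE)
  }))
  differentia <- lapply(records, function(r) {
    if (identical(r$provenance, "minted")) string_to_diff(r$differentia)
    else string_to_diff("")
  })
  names(differentia) <- classes$label
  structure(list(classes = classes, edges = edges, differentia = differentia),
            class = "symbio_taxonomy")
}

store_from_records <- function(x) {
  s <- rt_store()
  s$iuis <- as.character(unlist(x$iuis))
  s$regions <- union("t_max", as.character(unlist(x$regions)))
  bind <- function(records, cols, coerce = as.character) {
    if (length(records) == 0L) return(NULL)
    do.call(rbind, lapply(records, function(r) {
      vals <- lapply(cols, function(cn) {
        v <- r[[cn]]
        if (is.null(v)) NA else v
      })
      names(vals) <- cols
      as.data.frame(vals, stringsAsFactors = FALSE)
    }))
  }
  inst <- bind(x$instantiations, c("particular", "type", "region"))
  if (!is.null(inst)) s$instantiations <- inst
  rel <- bind(x$relations, c("subject", "relation", "object", "holds_at", "note"))
  if (!is.null(rel)) {
    rel$note[is.na(rel$note)] <- ""
    s$relations <- rel
  }
  taxa <- bind(x$taxa, c("iui", "taxid"))
  if (!is.null(taxa)) {
    taxa$taxid <- as.character(taxa$taxid)
    s$taxa <- taxa
  }
  oc <- bind(x$outcomes, c("process", "participant", "value", "fatal"))
  if (!is.null(oc)) {
    oc$fatal <- as.logical(oc$fatal)
    s$outcomes <- oc
  }
  canonical_store(s)
}

strip_symb <- function(x) sub("^symb:", "", x)

import_ttl <- function(lines) {
  lines <- lines[!startsWith(lines, "@prefix")]
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (any(grepl("owl:Class", lines, fixed = TRUE))) {
    return(ttl_taxonomy(lines))
  }
  ttl_store(lines)
}

ttl_taxonomy <- function(lines) {
  lines <- lines[!grepl("owl:equivalentClass", lines, fixed = TRUE)]
  records <- list()
  labels_by_qname <- character(0)
  parsed <- list()
  for (ln in lines) {
    segs <- split_segments(ln)
    head <- strsplit(segs[1L], " ", fixed = TRUE)[[1]]
    if (length(head) != 3L || head[2L] != "a" || head[3L] != "owl:Class") {
      stop_symbio("symbio_parse_error",
                  sprintf("cannot parse Turtle class statement: %s", ln))
    }
    qn <- head[1L]
    rec <- list(id = qname_to_curie(qn), label = NA, definition = "",
                differentia = "", provenance = NA, parent_qnames = character(0))
    for (seg in segs[-1L]) {
      pred <- strsplit(seg, " ", fixed = TRUE)[[1]][1L]
      if (pred == "rdfs:label") rec$label <- first_literal(seg)
      else if (pred == "obo:IAO_0000115") rec$definition <- first_literal(seg)
      else if (pred == "symb:differentia") rec$differentia <- first_literal(seg)
      else if (pred == "symb:provenance") rec$provenance <- first_literal(seg)
      else if (pred == "rdfs:subClassOf") {
        rec$parent_qnames <- c(rec$parent_qnames,
                               strsplit(seg, " ", fixed = TRUE)[[1]][2L])
      }
    }
    labels_by_qname[qn] <- rec$label
    parsed[[length(parsed) + 1L]] <- rec
  }
  records <- lapply(parsed, function(rec) {
    list(id = rec$id, label = rec$label, definition = rec$definition,
         parents = unname(labels_by_qname[rec$parent_qnames]),
         differentia = rec$differentia, provenance = rec$provenance)
  })
  taxonomy_from_records(records)
}

ttl_store <- function(lines) {
  s <- rt_store()
  inst <- list(); rel <- list(); taxa <- list(); oc <- list()
  for (ln in lines) {
    segs <- split_segments(ln)
    head <- strsplit(segs[1L], " ", fixed = TRUE)[[1]]
    subj <- strip_symb(head[1L])
    get <- function(pred) {
      hit <- segs[startsWith(segs, paste0(pred, " "))]
      if (length(hit) == 0L) return(NA_character_)
      hit[1L]
    }
    obj_of <- function(pred) {
      seg <- get(pred)
      if (is.na(seg)) return(NA_character_)
      strip_symb(strsplit(seg, " ", fixed = TRUE)[[1]][2L])
    }
    lit_of <- function(pred) {
      seg <- get(pred)
      if (is.na(seg)) return(NA_character_)
      first_literal(seg)
    }
    if (length(head) >= 3L && head[2L] == "a") {
      kind <- head[3L]
      if (kind == "symb:Particular") {
        s$iuis <- c(s$iuis, subj)
      } else if (kind == "symb:TemporalRegion") {
        s$regions <- union(s$regions, subj)
      } else if (kind == "symb:InstantiationTuple") {
        inst[[length(inst) + 1L]] <- data.frame(
          particular = obj_of("symb:particular"),
          type = lit_of("symb:instantiatedType"),
          region = obj_of("symb:atRegion"), stringsAsFactors = FALSE)
      } else if (kind == "rdf:Statement") {
        note <- lit_of("symb:note")
        rel[[length(rel) + 1L]] <- data.frame(
          subject = obj_of("rdf:subject"),
          relation = obj_of("rdf:predicate"),
          object = obj_of("rdf:object"),
          holds_at = obj_of("symb:holdsAt"),
          note = if (is.na(note)) "" else note, stringsAsFactors = FALSE)
      } else if (kind == "symb:OutcomeAnnotation") {
        fl <- get("symb:fatal")
        oc[[length(oc) + 1L]] <- data.frame(
          process = obj_of("symb:process"),
          participant = obj_of("symb:participant"),
          value = lit_of("symb:value"),
          fatal = if (is.na(fl)) NA else as.logical(toupper(first_literal(fl))),
          stringsAsFactors = FALSE)
      } else {
        stop_symbio("symbio_parse_error",
                    sprintf("unknown statement kind: %s", ln))
      }
    } else if (length(head) >= 2L && head[2L] == "symb:taxon") {
      taxa[[length(taxa) + 1L]] <- data.frame(
        iui = subj, taxid = first_literal(segs[1L]), stringsAsFactors = FALSE)
    } else {
      stop_symbio("symbio_parse_error",
                  sprintf("cannot parse Turtle statement: %s", ln))
    }
  }
  if (length(inst) > 0L) s$instantiations <- do.call(rbind, inst)
  if (length(rel) > 0L) s$relations <- do.call(rbind, rel)
  if (length(taxa) > 0L) s$taxa <- do.call(rbind, taxa)
  if (length(oc) > 0L) s$outcomes <- do.call(rbind, oc)
  canonical_store(s)
}

import_ofn <- function(lines) {
  lines <- lines[!startsWith(lines, "Prefix(")]
  if (length(lines) < 2L || !identical(lines[length(lines)], ")")) {
    stop_symbio("symbio_parse_error",
                "truncated functional-syntax document (missing closing ')')")
  }
  if (startsWith(lines[1L], "Ontology(")) {
    return(ofn_taxonomy(lines[-c(1L, length(lines))]))
  }
  if (startsWith(lines[1L], "Store(")) {
    return(ofn_store(lines[-c(1L, length(lines))]))
  }
  stop_symbio("symbio_parse_error",
              "functional-syntax document is neither Ontology(...) nor Store(...)")
}

ofn_taxonomy <- function(lines) {
  decl <- list()  # qname -> record
  order <- character(0)
  for (ln in lines) {
    if (grepl("^Declaration\\(Class\\((.+)\\)\\)$", ln)) {
      qn <- sub("^Declaration\\(Class\\((.+)\\)\\)$", "\\1", ln)
      decl[[qn]] <- list(id = qname_to_curie(qn), label = NA, definition = "",
                         differentia = "", provenance = NA,
                         parent_qnames = character(0))
      order <- c(order, qn)
    } else if (startsWith(ln, "AnnotationAssertion(")) {
      m <- regmatches(ln, regexec(
        "^AnnotationAssertion\\((\\S+) (\\S+) \"((?:[^\"\\\\]|\\\\.)*)\"\\)$",
        ln, perl = TRUE))[[1]]
      if (length(m) != 4L) {
        stop_symbio("symbio_parse_error",
                    sprintf("cannot parse annotation: %s", ln))
      }
      prop <- m[2L]; qn <- m[3L]; val <- unesc_lit(m[4L])
      if (prop == "rdfs:label") decl[[qn]]$label <- val
      else if (prop == "obo:IAO_0000115") decl[[qn]]$definition <- val
      else if (prop == "symb:differentia") decl[[qn]]$differentia <- val
      else if (prop == "symb:provenance") decl[[qn]]$provenance <- val
    } else if (startsWith(ln, "SubClassOf(")) {
      m <- regmatches(ln, regexec("^SubClassOf\\((\\S+) (\\S+)\\)$", ln))[[1]]
      if (length(m) != 3L) {
        stop_symbio("symbio_parse_error", sprintf("cannot parse axiom: %s", ln))
      }
      decl[[m[2L]]]$parent_qnames <- c(decl[[m[2L]]]$parent_qnames, m[3L])
    } else if (startsWith(ln, "EquivalentClasses(")) {
      next
    } else {
      stop_symbio("symbio_parse_error", sprintf("cannot parse line: %s", ln))
    }
  }
  labels_by_qname <- vapply(decl, function(r) r$label, "")
  records <- lapply(order, function(qn) {
    rec <- decl[[qn]]
    list(id = rec$id, label = rec$label, definition = rec$definition,
         parents = unname(labels_by_qname[rec$parent_qnames]),
         differentia = rec$differentia, provenance = rec$provenance)
  })
  taxonomy_from_records(records)
}

ofn_store <- function(lines) {
  s <- rt_store()
  inst <- list(); rel <- list(); taxa <- list(); oc <- list()
  lit <- '"((?:[^"\\\\]|\\\\.)*)"'
  for (ln in lines) {
    if (grepl("^Particular\\(symb:(\\S+)\\)$", ln)) {
      s$iuis <- c(s$iuis, sub("^Particular\\(symb:(\\S+)\\)$", "\\1", ln))
    } else if (grepl("^TemporalRegion\\(symb:(\\S+)\\)$", ln)) {
      s$regions <- union(s$regions,
                         sub("^TemporalRegion\\(symb:(\\S+)\\)$", "\\1", ln))
    } else if (startsWith(ln, "Taxon(")) {
      m <- regmatches(ln, regexec(paste0("^Taxon\\(symb:(\\S+) ", lit, "\\)$"),
                                  ln, perl = TRUE))[[1]]
      taxa[[length(taxa) + 1L]] <- data.frame(
        iui = m[2L], taxid = unesc_lit(m[3L]), stringsAsFactors = FALSE)
    } else if (startsWith(ln, "Instantiation(")) {
      m <- regmatches(ln, regexec(
        paste0("^Instantiation\\(symb:(\\S+) ", lit, " symb:(\\S+)\\)$"),
        ln, perl = TRUE))[[1]]
      if (length(m) != 4L) {
        stop_symbio("symbio_parse_error", sprintf("cannot parse: %s", ln))
      }
      inst[[length(inst) + 1L]] <- data.frame(
        particular = m[2L], type = unesc_lit(m[3L]), region = m[4L],
        stringsAsFactors = FALSE)
    } else if (startsWith(ln, "Relation(")) {
      m <- regmatches(ln, regexec(
        paste0("^Relation\\(symb:(\\S+) symb:(\\S+) symb:(\\S+) symb:(\\S+) ",
               lit, "\\)$"), ln, perl = TRUE))[[1]]
      if (length(m) != 6L) {
        stop_symbio("symbio_parse_error", sprintf("cannot parse: %s", ln))
      }
      rel[[length(rel) + 1L]] <- data.frame(
        subject = m[2L], relation = m[3L], object = m[4L], holds_at = m[5L],
        note = unesc_lit(m[6L]), stringsAsFactors = FALSE)
    } else if (startsWith(ln, "Outcome(")) {
      m <- regmatches(ln, regexec(
        paste0("^Outcome\\(symb:(\\S+) symb:(\\S+) ", lit, " ", lit, "\\)$"),
        ln, perl = TRUE))[[1]]
      if (length(m) != 5L) {
        stop_symbio("symbio_parse_error", sprintf("cannot parse: %s", ln))
      }
      oc[[length(oc) + 1L]] <- data.frame(
        process = m[2L], participant = m[3L], value = m[4L],
        fatal = as.logical(toupper(m[5L])), stringsAsFactors = FALSE)
    } else {
      stop_symbio("symbio_parse_error", sprintf("cannot parse line: %s", ln))
    }
  }
  if (length(inst) > 0L) s$instantiations <- do.call(rbind, inst)
  if (length(rel) > 0L) s$relations <- do.call(rbind, rel)
  if (length(taxa) > 0L) s$taxa <- do.call(rbind, taxa)
  if (length(oc) > 0L) s$outcomes <- do.call(rbind, oc)
  canonical_store(s)
}

#' Are two taxonomy graphs equal?
#'
#' Compares classes, is-a edges and differentia up to ordering.
#' @param a,b \code{symbio_taxonomy} objects
#' @return logical scalar
#' @export
taxonomy_equal <- function(a, b) {
  canon <- function(t) {
    cls <- t$classes[order(t$classes$id), , drop = FALSE]
    rownames(cls) <- NULL
    e <- t$edges[order(t$edges$child, t$edges$parent), , drop = FALSE]
    rownames(e) <- NULL
    diffs <- t$differentia[order(names(t$differentia))]
    list(classes = cls, edges = e, differentia = diffs)
  }
  isTRUE(all.equal(canon(a), canon(b), check.attributes = FALSE))
}
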