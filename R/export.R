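# Deterministic serialization of annotation sets to JSON, CSV and BioC-XML.
# Ordering is always by identity key, key order in JSON objects is fixed, and
# two exports of the same state are byte-identical.

EXPORT_SCHEMA_VERSION <- "1.0"

# BioC passage offsets are absolute over the concatenation of sections in
# canonical order separated by single newlines.
section_offsets <- function(doc) {
  lens <- nchar(doc$sections)
  offs <- cumsum(c(0L, utils::head(lens + 1L, -1L)))  # +1 for the newline
  stats::setNames(as.integer(offs), names(doc$sections))
}

export_records <- function(coll, round, annotator, document_ids, types) {
  recs <- list(mentions = list(), relationships = list(), assertions = list(),
               labels = list())
  for (doc in sort(document_ids)) {
    set <- get_set(coll, round, annotator, doc)
    r <- set_as_records(set, doc)
    if ("mention" %in% types) recs$mentions <- c(recs$mentions, r$mentions)
    if ("relationship" %in% types)
      recs$relationships <- c(recs$relationships, r$relationships)
    if ("assertion" %in% types) recs$assertions <- c(recs$assertions, r$assertions)
    if ("label" %in% types) recs$labels <- c(recs$labels, r$labels)
  }
  recs
}

resolve_export_annotator <- function(coll, round, annotator, document_ids) {
  if (identical(annotator, "consensus")) {
    for (doc in document_ids)
      materialize_consensus(coll, doc, round)
    return(CONSENSUS_ANNOTATOR)
  }
  annotator
}

#' Export annotations
#'
#' Serializes one annotator's annotations (or the machine annotator's, or the
#' majority-voting consensus via `annotator = "consensus"`) for a document or
#' the whole collection, in one of three formats. Serialization is
#' deterministic: annotations are ordered by identity key and two exports of
#' the same state are byte-identical. An empty scope exports an
#' empty-but-valid file.
#'
#' @param coll A collection.
#' @param format `"json"`, `"csv"` or `"bioc"`.
#' @param annotator Annotator id, `"AutoTron"`, or `"consensus"`.
#' @param types Annotation types to include; default all. (`"mention"`
#'   implies the concept links, which live on the mentions.)
#' @param document_id Restrict to one document; default whole collection.
#' @param round Round index.
#' @param path Optional output path; for CSV with several types, a directory
#'   receiving one `<type>.csv` per type.
#' @return The serialized content: a string for JSON/BioC, a named list of
#'   CSV strings (one per type) for CSV. Written to `path` when given.
#' @export
export_annotations <- function(coll, format = c("json", "csv", "bioc"),
                               annotator, types = ANNOTATION_TYPES,
                               document_id = NULL, round = current_round(coll),
                               path = NULL) {
  format <- match.arg(format)
  types <- match.arg(types, ANNOTATION_TYPES, several.ok = TRUE)
  # BioC relation nodes reference mention annotations, so relationships are
  # only representable alongside their mentions
  if (format == "bioc" && "relationship" %in% types)
    types <- union(types, "mention")
  round <- check_round(coll, round)
  document_ids <- if (is.null(document_id)) names(coll$documents) else document_id
  for (doc in document_ids) get_document(coll, doc)
  annotator <- resolve_export_annotator(coll, round, annotator, document_ids)
  known <- c(names(coll$ann[[round]]), coll$members, MACHINE_ANNOTATOR,
             CONSENSUS_ANNOTATOR)
  if (!annotator %in% known) abort_domain("unknown annotator '%s'", annotator)
  recs <- export_records(coll, round, annotator, document_ids, types)
  out <- switch(format,
    json = export_json(coll, round, annotator, recs),
    csv  = export_csv(recs, types),
    bioc = export_bioc(coll, round, annotator, document_ids, types))
  if (!is.null(path)) {
    if (format == "csv" && length(out) > 1L) {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      for (type in names(out))
        writeLines(out[[type]], file.path(path, paste0(type, ".csv")), sep = "")
    } else {
      content <- if (is.list(out)) out[[1]] else out
      writeLines(content, path, sep = "")
    }
  }
  invisible(out)
}

export_json <- function(coll, round, annotator, recs) {
  payload <- list(schema_version = EXPORT_SCHEMA_VERSION,
                  format = "annostore-json",
                  collection = coll$collection_id,
                  round = round,
                  annotator = annotator,
                  annotations = recs)
  paste0(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                       null = "null", digits = NA,
                                       pretty = TRUE)), "\n")
}

csv_line <- function(fields) {
  quoted <- vapply(fields, function(f) {
    f <- as.character(f)
    if (grepl('[",\n]', f)) paste0('"', gsub('"', '""', f), '"') else f
  }, character(1))
  paste0(paste(quoted, collapse = ","), "\n")
}

REL_CSV_COLS <- as.vector(t(outer(c("subject", "predicate", "object"),
                                  c("_kind", "_section", "_start", "_end",
                                    "_surface", "_value"), paste0)))

export_csv <- function(recs, types) {
  out <- list()
  header <- function(cols) csv_line(c(cols, "schema_version"))
  with_version <- function(fields, ...) c(fields, EXPORT_SCHEMA_VERSION)
  if ("mention" %in% types) {
    rows <- vapply(seq_along(recs$mentions), function(i) {
      m <- recs$mentions[[i]]
      csv_line(with_version(c(m$document, m$section, m$start, m$end, m$surface,
                              paste(unlist(m$concepts), collapse = ";"),
                              m$created), i == 1L))
    }, character(1))
    out$mention <- paste0(header(c("document", "section", "start", "end",
                                   "surface", "concepts", "created")),
                          paste(rows, collapse = ""))
  }
  if ("relationship" %in% types) {
    comp_fields <- function(comp) {
      if (comp$kind == "mention")
        c("mention", comp$section, comp$start, comp$end, comp$surface, "")
      else if (comp$kind == "concept")
        c("concept", "", "", "", "", comp$concept)
      else c("text", "", "", "", "", comp$text)
    }
    rows <- vapply(seq_along(recs$relationships), function(i) {
      r <- recs$relationships[[i]]
      csv_line(with_version(c(r$document, comp_fields(r$subject),
                              comp_fields(r$predicate), comp_fields(r$object),
                              r$created), i == 1L))
    }, character(1))
    out$relationship <- paste0(header(c("document", REL_CSV_COLS, "created")),
                               paste(rows, collapse = ""))
  }
  if ("assertion" %in% types) {
    rows <- vapply(seq_along(recs$assertions), function(i) {
      a <- recs$assertions[[i]]
      csv_line(with_version(c(a$document, a$subject, a$predicate, a$object,
                              a$created), i == 1L))
    }, character(1))
    out$assertion <- paste0(header(c("document", "subject", "predicate",
                                     "object", "created")),
                            paste(rows, collapse = ""))
  }
  if ("label" %in% types) {
    rows <- vapply(seq_along(recs$labels), function(i) {
      l <- recs$labels[[i]]
      csv_line(with_version(c(l$document, l$label, l$created), i == 1L))
    }, character(1))
    out$label <- paste0(header(c("document", "label", "created")),
                        paste(rows, collapse = ""))
  }
  out
}

bioc_infon <- function(parent, key, value) {
  node <- xml2::xml_add_child(parent, "infon", `key` = key)
  xml2::xml_text(node) <- as.character(value)
  node
}

bioc_child <- function(parent, name, text = NULL, ...) {
  node <- xml2::xml_add_child(parent, name, ...)
  if (!is.null(text)) xml2::xml_text(node) <- as.character(text)
  node
}

export_bioc <- function(coll, round, annotator, document_ids, types) {
  docxml <- xml2::xml_new_root("collection")
  bioc_child(docxml, "source", "annostore")
  xml2::xml_add_child(docxml, "date")
  bioc_child(docxml, "key", "annostore.key")
  bioc_infon(docxml, "collection", coll$collection_id)
  bioc_infon(docxml, "round", round)
  bioc_infon(docxml, "annotator", annotator)
  bioc_infon(docxml, "schema_version", EXPORT_SCHEMA_VERSION)
  for (doc_id in sort(document_ids)) {
    doc <- get_document(coll, doc_id)
    set <- get_set(coll, round, annotator, doc_id)
    recs <- set_as_records(set, doc_id)
    offs <- section_offsets(doc)
    dnode <- xml2::xml_add_child(docxml, "document")
    bioc_child(dnode, "id", doc_id)
    if ("label" %in% types && length(recs$labels) > 0L)
      bioc_infon(dnode, "labels",
                 as.character(jsonlite::toJSON(lapply(recs$labels, function(l)
                   list(label = l$label, created = l$created)),
                   auto_unbox = TRUE)))
    # annotation ids must be stable across exports: derive them from the
    # identity-key sort order, not from store-internal ids
    mention_xml_id <- function(m)
      sprintf("M%d", match(mention_key(doc_id, m$section, m$start, m$end),
                           vapply(recs$mentions, function(x)
                             mention_key(doc_id, x$section, x$start, x$end),
                             character(1))))
    for (section in names(doc$sections)) {
      pnode <- xml2::xml_add_child(dnode, "passage")
      bioc_infon(pnode, "section", section)
      bioc_child(pnode, "offset", offs[[section]])
      bioc_child(pnode, "text", unname(doc$sections[[section]]))
      if ("mention" %in% types) {
        for (m in recs$mentions) {
          if (m$section != section) next
          anode <- xml2::xml_add_child(pnode, "annotation",
                                       id = mention_xml_id(m))
          bioc_infon(anode, "annotator", annotator)
          if (length(m$concepts) > 0L) {
            ids <- unlist(m$concepts)
            bioc_infon(anode, "concept_ids", paste(ids, collapse = ";"))
            first <- get_concept(coll, ids[[1]])
            if (!is.null(first)) bioc_infon(anode, "type", first$type)
          }
          bioc_infon(anode, "created", m$created)
          xml2::xml_add_child(anode, "location",
                              offset = as.character(offs[[section]] + m$start),
                              length = as.character(m$end - m$start))
          bioc_child(anode, "text", m$surface)
        }
      }
    }
    if ("relationship" %in% types) {
      for (i in seq_along(recs$relationships)) {
        r <- recs$relationships[[i]]
        rnode <- xml2::xml_add_child(dnode, "relation", id = sprintf("R%d", i))
        bioc_infon(rnode, "kind", "relationship")
        for (role in c("subject", "predicate", "object")) {
          comp <- r[[role]]
          bioc_infon(rnode, paste0(role, "_kind"), comp$kind)
          if (comp$kind == "concept")
            bioc_infon(rnode, paste0(role, "_value"), comp$concept)
          if (comp$kind == "text")
            bioc_infon(rnode, paste0(role, "_value"), comp$text)
        }
        bioc_infon(rnode, "created", r$created)
        for (role in c("subject", "predicate", "object")) {
          comp <- r[[role]]
          if (comp$kind == "mention")
            xml2::xml_add_child(rnode, "node",
                                refid = mention_xml_id(comp), role = role)
        }
      }
    }
    if ("assertion" %in% types) {
      # assertions are concept-only: BioC relations with zero nodes, the
      # three components carried as infons (documented dialect choice)
      for (i in seq_along(recs$assertions)) {
        a <- recs$assertions[[i]]
        rnode <- xml2::xml_add_child(dnode, "relation", id = sprintf("A%d", i))
        bioc_infon(rnode, "kind", "assertion")
        bioc_infon(rnode, "subject", a$subject)
        bioc_infon(rnode, "predicate", a$predicate)
        bioc_infon(rnode, "object", a$object)
        bioc_infon(rnode, "created", a$created)
      }
    }
  }
  paste0(as.character(docxml), "\n")
}
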