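# Transactional import: the whole file is validated against the data-model
# invariants on a working copy of the store and committed only if every
# record passes (all-or-nothing per file).

clone_collection <- function(coll) {
  new <- new.env(parent = emptyenv())
  for (field in ls(coll, all.names = TRUE)) assign(field, get(field, coll), new)
  class(new) <- "annostore_collection"
  new
}

commit_clone <- function(coll, clone) {
  for (field in ls(clone, all.names = TRUE)) assign(field, get(field, clone), coll)
  invisible(coll)
}

# A clone of the collection with all annotations removed (same documents,
# registry, labels, members, round structure) — the target of round trips.
skeleton_clone <- function(coll) {
  new <- clone_collection(coll)
  new$ann <- rep(list(list()), length(coll$rounds))
  new$counter <- 0L
  new
}

import_mention_record <- function(coll, annotator, round, rec, where) {
  doc <- rec$document
  text <- tryCatch(section_text(coll, doc, rec$section), annostore_error = function(e)
    abort_domain("%s: %s", where, conditionMessage(e)))
  start <- as.integer(rec$start); end <- as.integer(rec$end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end || end > nchar(text))
    abort_domain("%s: invalid span [%s,%s)", where, rec$start, rec$end)
  if (!identical(slice_text(text, start, end), rec$surface))
    abort_domain("%s: surface '%s' does not match text slice '%s'",
                 where, rec$surface, slice_text(text, start, end))
  set <- get_set(coll, round, annotator, doc)
  key <- mention_key(doc, rec$section, start, end)
  concepts <- sort(as.character(unlist(rec$concepts)))
  for (cid in concepts)
    if (is.null(get_concept(coll, cid)))
      abort_domain("%s: unknown concept '%s'", where, cid)
  for (m in set$mentions) {
    if (identical(mention_key_of(m), key)) {
      merged <- sort(unique(c(m$concepts, concepts)))
      if (!identical(sort(m$concepts), merged)) {
        m$concepts <- merged
        set$mentions[[m$id]] <- m
        put_set(coll, round, annotator, doc, set)
        return("updated")
      }
      return("skipped")
    }
  }
  m <- create_mention(coll, annotator, doc, rec$section, start, end,
                      concepts = concepts, round = round)
  if (!is.null(rec$created)) {
    set <- get_set(coll, round, annotator, doc)
    set$mentions[[m$id]]$created <- rec$created
    put_set(coll, round, annotator, doc, set)
  }
  "added"
}

# find or create the annotator's mention at the component's span
component_from_record <- function(coll, annotator, round, doc, comp, where) {
  kind <- comp$kind
  if (identical(kind, "concept")) return(comp_concept(comp$concept))
  if (identical(kind, "text")) return(comp_text(comp$text))
  if (!identical(kind, "mention"))
    abort_domain("%s: unknown component kind '%s'", where, kind)
  rec <- list(document = doc, section = comp$section, start = comp$start,
              end = comp$end, surface = comp$surface, concepts = list())
  import_mention_record(coll, annotator, round, rec, where)
  set <- get_set(coll, round, annotator, doc)
  key <- mention_key(doc, comp$section, as.integer(comp$start),
                     as.integer(comp$end))
  for (m in set$mentions)
    if (identical(mention_key_of(m), key)) return(comp_mention(m$id))
  abort_domain("%s: failed to resolve mention component", where)
}

import_relationship_record <- function(coll, annotator, round, rec, where) {
  doc <- rec$document
  get_document(coll, doc)
  comps <- lapply(c("subject", "predicate", "object"), function(role)
    component_from_record(coll, annotator, round, doc, rec[[role]],
                          paste0(where, " ", role)))
  set <- get_set(coll, round, annotator, doc)
  key <- rel_key_of(list(subject = comps[[1]], predicate = comps[[2]],
                         object = comps[[3]]), set)
  for (r in set$relationships)
    if (identical(rel_key_of(r, set), key)) return("skipped")
  r <- suppressWarnings(create_relationship(
    coll, annotator, doc, comps[[1]], comps[[2]], comps[[3]], round = round))
  if (!is.null(rec$created)) {
    set <- get_set(coll, round, annotator, doc)
    set$relationships[[r$id]]$created <- rec$created
    put_set(coll, round, annotator, doc, set)
  }
  "added"
}

import_assertion_record <- function(coll, annotator, round, rec, where) {
  set <- get_set(coll, round, annotator, rec$document)
  key <- paste(rec$subject, rec$predicate, rec$object, sep = .SEP)
  dup <- any(vapply(set$assertions, function(a)
    identical(assertion_key_of(a), key), logical(1)))
  if (dup) return("skipped")
  a <- create_assertion(coll, annotator, rec$document, rec$subject,
                        rec$predicate, rec$object, round = round)
  if (!is.null(rec$created)) {
    set <- get_set(coll, round, annotator, rec$document)
    set$assertions[[a$id]]$created <- rec$created
    put_set(coll, round, annotator, rec$document, set)
  }
  "added"
}

import_label_record <- function(coll, annotator, round, rec, where) {
  get_document(coll, rec$document)
  if (!rec$label %in% coll$labels)
    abort_domain("%s: label '%s' not in the collection's label set", where,
                 rec$label)
  set <- get_set(coll, round, annotator, rec$document, create = TRUE)
  if (any(vapply(set$labels, function(l) identical(l$label, rec$label),
                 logical(1))))
    return("skipped")
  l <- list(id = next_id(coll, "l"), document_id = rec$document,
            label = rec$label, created = rec$created %||% now_utc(coll))
  set$labels[[l$id]] <- l
  put_set(coll, round, annotator, rec$document, set)
  "added"
}

#' Import annotations
#'
#' Reads a file produced by [export_annotations()] (JSON, CSV or BioC-XML)
#' and adds its annotations to the collection. Every record is validated
#' against the data-model invariants — spans in bounds, surface equal to the
#' text slice, known documents, registered concepts, labels in the label set
#' — before anything is committed; one bad record rejects the whole file,
#' with the record named in the error. Records identical (by identity key) to
#' annotations the annotator already holds are skipped.
#'
#' @param coll A collection (documents and concepts referenced by the file
#'   must already exist).
#' @param input File path or the serialized content itself. For CSV, a named
#'   list/vector of per-type contents or a directory path.
#' @param format `"json"`, `"csv"` or `"bioc"`.
#' @param annotator Override the annotator recorded in the file.
#' @param round Round index.
#' @return Import report: counts of added / skipped records per type.
#' @export
import_annotations <- function(coll, input, format = c("json", "csv", "bioc"),
                               annotator = NULL, round = current_round(coll)) {
  format <- match.arg(format)
  round <- check_round(coll, round)
  clone <- clone_collection(coll)
  report <- switch(format,
    json = import_json(clone, input, annotator, round),
    csv  = import_csv(clone, input, annotator, round),
    bioc = import_bioc(clone, input, annotator, round))
  commit_clone(coll, clone)
  report
}

as_content <- function(input) {
  if (is_string(input) && !grepl("\n", input) && file.exists(input))
    read_utf8(input) else input
}

tally <- function(outcomes) {
  list(added = sum(outcomes == "added") + sum(outcomes == "updated"),
       skipped = sum(outcomes == "skipped"))
}

import_json <- function(coll, input, annotator, round) {
  x <- jsonlite::fromJSON(as_content(input), simplifyVector = FALSE)
  if (!identical(x$format, "annostore-json"))
    abort_domain("not an annostore JSON export")
  annotator <- annotator %||% x$annotator
  assert_string(annotator, "annotator")
  a <- x$annotations
  res <- list()
  res$mention <- vapply(seq_along(a$mentions), function(i)
    import_mention_record(coll, annotator, round, a$mentions[[i]],
                          sprintf("mention %d", i)), character(1))
  res$relationship <- vapply(seq_along(a$relationships), function(i)
    import_relationship_record(coll, annotator, round, a$relationships[[i]],
                               sprintf("relationship %d", i)), character(1))
  res$assertion <- vapply(seq_along(a$assertions), function(i)
    import_assertion_record(coll, annotator, round, a$assertions[[i]],
                            sprintf("assertion %d", i)), character(1))
  res$label <- vapply(seq_along(a$labels), function(i)
    import_label_record(coll, annotator, round, a$labels[[i]],
                        sprintf("label %d", i)), character(1))
  lapply(res, tally)
}

parse_csv_text <- function(txt) {
  utils::read.csv(text = txt, colClasses = "character", check.names = FALSE)
}

import_csv <- function(coll, input, annotator, round) {
  assert_string(annotator %||% "", "annotator (required for CSV import)")
  contents <- if (is.list(input) || (is.character(input) && !is.null(names(input)))) {
    lapply(input, identity)
  } else if (is_string(input) && dir.exists(input)) {
    files <- list.files(input, pattern = "\\.csv$", full.names = TRUE)
    stats::setNames(lapply(files, read_utf8),
                    tools::file_path_sans_ext(basename(files)))
  } else {
    # single CSV: sniff the type from the header
    txt <- as_content(input)
    head1 <- strsplit(txt, "\n", fixed = TRUE)[[1]][[1]]
    type <- if (grepl("surface", head1) && !grepl("subject", head1)) "mention"
            else if (grepl("subject_kind", head1)) "relationship"
            else if (grepl("subject", head1)) "assertion"
            else "label"
    stats::setNames(list(txt), type)
  }
  res <- list()
  for (type in intersect(c("mention", "relationship", "assertion", "label"),
                         names(contents))) {
    df <- parse_csv_text(contents[[type]])
    outcomes <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
      where <- sprintf("%s row %d", type, i)
      row <- df[i, ]
      outcomes[[i]] <- switch(type,
        mention = import_mention_record(coll, annotator, round, list(
          document = row$document, section = row$section,
          start = row$start, end = row$end, surface = row$surface,
          concepts = if (nzchar(row$concepts))
            strsplit(row$concepts, ";", fixed = TRUE)[[1]] else list(),
          created = row$created), where),
        relationship = {
          comp <- function(role) {
            kind <- row[[paste0(role, "_kind")]]
            if (kind == "mention")
              list(kind = "mention", section = row[[paste0(role, "_section")]],
                   start = row[[paste0(role, "_start")]],
                   end = row[[paste0(role, "_end")]],
                   surface = row[[paste0(role, "_surface")]])
            else if (kind == "concept")
              list(kind = "concept", concept = row[[paste0(role, "_value")]])
            else list(kind = "text", text = row[[paste0(role, "_value")]])
          }
          import_relationship_record(coll, annotator, round, list(
            document = row$document, subject = comp("subject"),
            predicate = comp("predicate"), object = comp("object"),
            created = row$created), where)
        },
        assertion = import_assertion_record(coll, annotator, round, list(
          document = row$document, subject = row$subject,
          predicate = row$predicate, object = row$object,
          created = row$created), where),
        label = import_label_record(coll, annotator, round, list(
          document = row$document, label = row$label, created = row$created),
          where))
    }
    res[[type]] <- outcomes
  }
  lapply(res, tally)
}

import_bioc <- function(coll, input, annotator, round) {
  xml <- xml2::read_xml(as_content(input))
  infon <- function(node, key) {
    hit <- xml2::xml_find_first(node, sprintf("./infon[@key='%s']", key))
    if (inherits(hit, "xml_missing")) NULL else xml2::xml_text(hit)
  }
  annotator <- annotator %||% infon(xml, "annotator")
  assert_string(annotator, "annotator")
  res <- list(mention = character(0), relationship = character(0),
              assertion = character(0), label = character(0))
  for (dnode in xml2::xml_find_all(xml, "./document")) {
    doc_id <- xml2::xml_text(xml2::xml_find_first(dnode, "./id"))
    get_document(coll, doc_id)
    mention_by_xmlid <- list()
    for (pnode in xml2::xml_find_all(dnode, "./passage")) {
      section <- infon(pnode, "section")
      poff <- as.integer(xml2::xml_text(xml2::xml_find_first(pnode, "./offset")))
      for (anode in xml2::xml_find_all(pnode, "./annotation")) {
        loc <- xml2::xml_find_first(anode, "./location")
        aoff <- as.integer(xml2::xml_attr(loc, "offset"))
        alen <- as.integer(xml2::xml_attr(loc, "length"))
        start <- aoff - poff
        surface <- xml2::xml_text(xml2::xml_find_first(anode, "./text"))
        cids <- infon(anode, "concept_ids")
        rec <- list(document = doc_id, section = section, start = start,
                    end = start + alen, surface = surface,
                    concepts = if (is.null(cids)) list()
                               else strsplit(cids, ";", fixed = TRUE)[[1]],
                    created = infon(anode, "created"))
        where <- sprintf("annotation %s", xml2::xml_attr(anode, "id"))
        res$mention <- c(res$mention,
                         import_mention_record(coll, annotator, round, rec, where))
        mention_by_xmlid[[xml2::xml_attr(anode, "id")]] <-
          list(kind = "mention", section = section, start = start,
               end = start + alen, surface = surface)
      }
    }
    for (rnode in xml2::xml_find_all(dnode, "./relation")) {
      kind <- infon(rnode, "kind")
      where <- sprintf("relation %s", xml2::xml_attr(rnode, "id"))
      if (identical(kind, "assertion")) {
        rec <- list(document = doc_id, subject = infon(rnode, "subject"),
                    predicate = infon(rnode, "predicate"),
                    object = infon(rnode, "object"),
                    created = infon(rnode, "created"))
        res$assertion <- c(res$assertion,
                           import_assertion_record(coll, annotator, round, rec,
                                                   where))
      } else {
        nodes <- xml2::xml_find_all(rnode, "./node")
        by_role <- stats::setNames(xml2::xml_attr(nodes, "refid"),
                                   xml2::xml_attr(nodes, "role"))
        comp <- function(role) {
          ckind <- infon(rnode, paste0(role, "_kind"))
          if (identical(ckind, "mention")) {
            m <- mention_by_xmlid[[by_role[[role]]]]
            if (is.null(m)) abort_domain("%s: node refid not found", where)
            m
          } else if (identical(ckind, "concept")) {
            list(kind = "concept", concept = infon(rnode, paste0(role, "_value")))
          } else {
            list(kind = "text", text = infon(rnode, paste0(role, "_value")))
          }
        }
        rec <- list(document = doc_id, subject = comp("subject"),
                    predicate = comp("predicate"), object = comp("object"),
                    created = infon(rnode, "created"))
        res$relationship <- c(res$relationship,
                              import_relationship_record(coll, annotator, round,
                                                         rec, where))
      }
    }
    labs <- infon(dnode, "labels")
    if (!is.null(labs) && nzchar(labs)) {
      for (rec in jsonlite::fromJSON(labs, simplifyVector = FALSE)) {
        res$label <- c(res$label,
                       import_label_record(coll, annotator, round,
                                           list(document = doc_id,
                                                label = rec$label,
                                                created = rec$created),
                                           sprintf("label '%s'", rec$label)))
      }
    }
  }
  lapply(res, tally)
}

#' Verify a format round trip
#'
#' Exports every annotator's annotations of a round, imports them into a
#' fresh skeleton of the collection (same documents, registry and labels, no
#' annotations), and compares the canonical serializations of the original
#' and re-imported state.
#'
#' @param coll A collection.
#' @param format `"json"`, `"csv"` or `"bioc"`.
#' @param round Round index.
#' @return List with `identical` (logical) and, on failure, `diff` (the two
#'   canonical serializations).
#' @export
roundtrip_check <- function(coll, format = c("json", "csv", "bioc"),
                            round = current_round(coll)) {
  format <- match.arg(format)
  round <- check_round(coll, round)
  fresh <- skeleton_clone(coll)
  for (annotator in sort(names(coll$ann[[round]]))) {
    out <- export_annotations(coll, format, annotator = annotator, round = round)
    import_annotations(fresh, out, format, annotator = annotator, round = round)
  }
  a <- canonical_state(coll, round)
  b <- canonical_state(fresh, round)
  if (identical(a, b)) list(identical = TRUE)
  else list(identical = FALSE, diff = list(original = a, reimported = b))
}
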