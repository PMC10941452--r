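#' Create an annotation collection
#'
#' A collection groups documents, a concept registry, a label set, a team of
#' annotators and an ordered list of annotation rounds. The returned object is
#' an environment: operations such as [create_mention()] mutate it in place.
#'
#' @param name,description Collection name and description (both mandatory).
#' @param creator Creator user id. Only the creator may edit members, labels,
#'   and start new rounds.
#' @param collection_id Identifier; defaults to a slug of `name`.
#' @param members Optional initial annotator ids (may be empty and edited later).
#' @param labels Optional initial document-label vocabulary.
#' @return An object of class `annostore_collection`.
#' @export
create_collection <- function(name, description, creator,
                              collection_id = gsub("[^A-Za-z0-9_-]+", "_", name),
                              members = character(), labels = character()) {
  assert_string(name, "name"); assert_string(description, "description")
  assert_string(creator, "creator")
  coll <- new.env(parent = emptyenv())
  coll$collection_id <- collection_id
  coll$name <- name
  coll$description <- description
  coll$creator <- creator
  coll$members <- unique(c(creator, members))
  coll$labels <- unique(as.character(labels))
  coll$registry <- data.frame(identifier = character(), name = character(),
                              type = character(), description = character(),
                              stringsAsFactors = FALSE)
  coll$documents <- list()
  coll$rounds <- list(list(round_index = 1L, members = coll$members,
                           source_round = NULL))
  coll$ann <- list(list())        # ann[[round]][[annotator]][[document]] = set
  coll$counter <- 0L
  coll$fixed_time <- NULL
  class(coll) <- "annostore_collection"
  coll
}

#' @export
print.annostore_collection <- function(x, ...) {
  cat(sprintf("<annostore collection '%s'>\n", x$collection_id))
  cat(sprintf("  %d document(s), %d concept(s), %d member(s), %d round(s)\n",
              length(x$documents), nrow(x$registry), length(x$members),
              length(x$rounds)))
  invisible(x)
}

check_creator <- function(coll, by) {
  if (!identical(by, coll$creator))
    abort_domain("only the collection creator ('%s') may do this", coll$creator)
}

#' Add an annotator to a collection
#' @param coll A collection.
#' @param member Annotator id to add.
#' @param by Calling user; must be the creator.
#' @export
add_member <- function(coll, member, by = coll$creator) {
  check_creator(coll, by); assert_string(member, "member")
  coll$members <- unique(c(coll$members, member))
  invisible(coll)
}

#' Add labels to a collection's label vocabulary
#' @inheritParams add_member
#' @param labels Character vector of labels to add.
#' @export
add_label <- function(coll, labels, by = coll$creator) {
  check_creator(coll, by)
  coll$labels <- unique(c(coll$labels, as.character(labels)))
  invisible(coll)
}

# ---- concept registry -------------------------------------------------------

#' Register concepts in a collection's registry
#'
#' Concepts are ontology-agnostic: an identifier (URI or ID), a display name,
#' a type (e.g. "Gene", "Disease") and an optional description. Identifier,
#' name and type are mandatory. Re-registering an identical record is a no-op;
#' re-registering a conflicting record is an error.
#'
#' @param coll A collection.
#' @param concepts Data frame with columns `identifier`, `name`, `type` and
#'   optionally `description`.
#' @return The collection, invisibly.
#' @export
register_concepts <- function(coll, concepts) {
  stopifnot(is.data.frame(concepts))
  need <- c("identifier", "name", "type")
  if (!all(need %in% names(concepts)))
    abort_domain("concepts need columns identifier, name, type")
  if (!"description" %in% names(concepts)) concepts$description <- ""
  concepts <- concepts[, c(need, "description")]
  concepts[] <- lapply(concepts, as.character)
  concepts$description[is.na(concepts$description)] <- ""
  for (i in seq_len(nrow(concepts))) {
    row <- concepts[i, ]
    if (!nzchar(row$identifier) || !nzchar(row$name) || !nzchar(row$type) ||
        anyNA(row[, need]))
      abort_domain("row %d: identifier, name and type are mandatory", i)
    j <- match(row$identifier, coll$registry$identifier)
    if (is.na(j)) {
      coll$registry <- rbind(coll$registry, row)
    } else if (!identical(unname(unlist(coll$registry[j, ])), unname(unlist(row)))) {
      abort_domain("concept '%s' already registered with conflicting fields",
                   row$identifier)
    }
  }
  rownames(coll$registry) <- NULL
  invisible(coll)
}

get_concept <- function(coll, identifier) {
  j <- match(identifier, coll$registry$identifier)
  if (is.na(j)) return(NULL)
  as.list(coll$registry[j, ])
}

# ---- documents --------------------------------------------------------------

#' Construct a document
#'
#' @param document_id Document id, unique within a collection.
#' @param sections Named character vector of section texts; order is the
#'   canonical section order (used e.g. for BioC passage offsets).
#' @param metadata Optional list (title, abstract, authors, venue,
#'   publication_date, external_id).
#' @export
new_document <- function(document_id, sections, metadata = NULL) {
  assert_string(document_id, "document_id")
  if (length(sections) == 0L || is.null(names(sections)) ||
      any(!nzchar(names(sections))))
    abort_domain("document '%s' needs at least one named section", document_id)
  if (anyDuplicated(names(sections)))
    abort_domain("document '%s' has duplicate section names", document_id)
  structure(list(document_id = document_id,
                 sections = vapply(sections, as.character, character(1)),
                 metadata = metadata),
            class = "annostore_document")
}

#' Add a document to a collection
#' @param coll A collection.
#' @param document A document built with [new_document()] (or by an ingest
#'   reader).
#' @export
add_document <- function(coll, document) {
  stopifnot(inherits(document, "annostore_document"))
  if (document$document_id %in% names(coll$documents))
    abort_domain("document id '%s' already in collection", document$document_id)
  coll$documents[[document$document_id]] <- document
  invisible(coll)
}

get_document <- function(coll, document_id) {
  d <- coll$documents[[document_id]]
  if (is.null(d)) abort_domain("unknown document '%s'", document_id)
  d
}

section_text <- function(coll, document_id, section) {
  d <- get_document(coll, document_id)
  if (!section %in% names(d$sections))
    abort_domain("unknown section '%s' in document '%s'", section, document_id)
  unname(d$sections[[section]])
}

# ---- rounds -----------------------------------------------------------------

#' Number of the latest round
#' @param coll A collection.
#' @export
current_round <- function(coll) length(coll$rounds)

check_round <- function(coll, round) {
  round <- as.integer(round)
  if (round < 1L || round > length(coll$rounds))
    abort_domain("round %d does not exist", round)
  round
}

#' Start a new annotation round
#'
#' The new round starts as a deep copy of the previous round's annotations for
#' every member carried over; members new to the round start empty. Rounds are
#' isolated after creation: edits in one never affect another.
#'
#' @param coll A collection.
#' @param members Annotator ids participating in the new round (non-empty).
#' @param by Calling user; must be the collection creator.
#' @return The new round's index.
#' @export
new_round <- function(coll, members, by = coll$creator) {
  check_creator(coll, by)
  members <- unique(as.character(members))
  if (length(members) == 0L) abort_domain("a round needs at least one member")
  unknown <- setdiff(members, c(coll$members, MACHINE_ANNOTATOR))
  if (length(unknown) > 0L)
    abort_domain("not collection members: %s", paste(unknown, collapse = ", "))
  prev <- current_round(coll)
  r <- prev + 1L
  coll$rounds[[r]] <- list(round_index = r, members = members, source_round = prev)
  carried <- coll$ann[[prev]][intersect(names(coll$ann[[prev]]), members)]
  # R list semantics give a genuine deep copy here
  coll$ann[[r]] <- carried
  r
}

round_annotators <- function(coll, round, document_id = NULL) {
  sets <- coll$ann[[round]]
  if (is.null(sets)) return(character(0))
  if (is.null(document_id)) return(names(sets))
  has <- vapply(sets, function(bydoc) {
    s <- bydoc[[document_id]]
    !is.null(s) && (length(s$mentions) + length(s$relationships) +
                    length(s$assertions) + length(s$labels)) > 0L
  }, logical(1))
  names(sets)[has]
}

get_set <- function(coll, round, annotator, document_id, create = FALSE) {
  s <- coll$ann[[round]][[annotator]][[document_id]]
  if (is.null(s)) {
    if (!create) return(empty_set())
    s <- empty_set()
    coll$ann[[round]][[annotator]][[document_id]] <- s
  }
  s
}

put_set <- function(coll, round, annotator, document_id, set) {
  coll$ann[[round]][[annotator]][[document_id]] <- set
  invisible(coll)
}

# ---- canonical serialization ------------------------------------------------

set_as_records <- function(set, document_id) {
  comp_rec <- function(comp) {
    if (comp$kind == "concept") list(kind = "concept", concept = comp$ref)
    else list(kind = "text", text = comp$ref)
  }
  mention_rec <- function(m) list(
    document = document_id, section = m$section, start = m$start, end = m$end,
    surface = m$surface, concepts = as.list(sort(m$concepts)), created = m$created)
  rel_rec <- function(r) {
    resolve <- function(comp) {
      if (comp$kind == "mention") {
        m <- set$mentions[[comp$ref]]
        list(kind = "mention", section = m$section, start = m$start, end = m$end,
             surface = m$surface)
      } else comp_rec(comp)
    }
    list(document = document_id, subject = resolve(r$subject),
         predicate = resolve(r$predicate), object = resolve(r$object),
         created = r$created)
  }
  ass_rec <- function(a) list(document = document_id, subject = a$subject,
                              predicate = a$predicate, object = a$object,
                              created = a$created)
  lab_rec <- function(l) list(document = document_id, label = l$label,
                              created = l$created)
  keyed_sorted <- function(lst, keyf, recf) {
    if (length(lst) == 0L) return(list())
    keys <- vapply(lst, keyf, character(1))
    unname(lapply(lst[order(keys)], recf))
  }
  list(
    mentions = keyed_sorted(set$mentions, mention_key_of, mention_rec),
    relationships = keyed_sorted(set$relationships,
                                 function(r) rel_key_of(r, set), rel_rec),
    assertions = keyed_sorted(set$assertions, assertion_key_of, ass_rec),
    labels = keyed_sorted(set$labels, label_key_of, lab_rec)
  )
}

#' Canonical serialization of one round's annotation state
#'
#' Deterministic JSON (sorted annotators, documents and identity keys) used
#' for round-isolation checks and format round-trip verification.
#'
#' @param coll A collection.
#' @param round Round index.
#' @return A JSON string.
#' @export
canonical_state <- function(coll, round = current_round(coll)) {
  round <- check_round(coll, round)
  sets <- coll$ann[[round]]
  out <- list()
  for (annotator in sort(names(sets))) {
    bydoc <- sets[[annotator]]
    recs <- list()
    for (doc in sort(names(bydoc))) {
      s <- bydoc[[doc]]
      # an empty set carries no annotations: indistinguishable from absence
      if (length(s$mentions) + length(s$relationships) +
          length(s$assertions) + length(s$labels) == 0L) next
      recs[[doc]] <- set_as_records(s, doc)
    }
    if (length(recs) > 0L) out[[annotator]] <- recs
  }
  canonical_json(out)
}
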