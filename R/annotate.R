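# Reserved annotator id under which automatic annotations are stored.
MACHINE_ANNOTATOR <- "AutoTron"

check_annotator <- function(coll, annotator, round) {
  assert_string(annotator, "annotator")
  if (identical(annotator, MACHINE_ANNOTATOR)) return(invisible(annotator))
  # the round records the members it started with; members added to the
  # collection afterwards may annotate the current round too
  allowed <- coll$rounds[[round]]$members
  if (round == current_round(coll)) allowed <- union(allowed, coll$members)
  if (!annotator %in% allowed)
    abort_domain("'%s' is not a member of round %d", annotator, round)
  invisible(annotator)
}

#' Annotate a mention
#'
#' A mention is a contiguous character span in one section of a document,
#' addressed by 0-based half-open offsets over the section text exactly as
#' ingested. Overlapping an existing mention (own or another annotator's) is
#' permitted. The surface string is recomputed from the section text, never
#' trusted from the caller.
#'
#' @param coll A collection.
#' @param annotator Annotator id (a member of the round).
#' @param document_id Document id.
#' @param section Section name.
#' @param start,end 0-based half-open character offsets, `0 <= start < end <=
#'   nchar(section text)`.
#' @param concepts Concept identifiers to link immediately (must be
#'   registered).
#' @param round Round index; defaults to the latest round.
#' @return The stored mention (a list with `id`, `section`, `start`, `end`,
#'   `surface`, `concepts`), invisibly.
#' @export
create_mention <- function(coll, annotator, document_id, section, start, end,
                           concepts = character(), round = current_round(coll)) {
  round <- check_round(coll, round)
  check_annotator(coll, annotator, round)
  text <- section_text(coll, document_id, section)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end || end > nchar(text))
    abort_domain("invalid span [%s,%s) for section '%s' (length %d)",
                 start, end, section, nchar(text))
  concepts <- unique(as.character(concepts))
  for (cid in concepts)
    if (is.null(get_concept(coll, cid)))
      abort_domain("concept '%s' is not registered", cid)
  m <- list(id = next_id(coll, "m"), document_id = document_id,
            section = section, start = start, end = end,
            surface = slice_text(text, start, end),
            concepts = concepts, created = now_utc(coll))
  set <- get_set(coll, round, annotator, document_id, create = TRUE)
  set$mentions[[m$id]] <- m
  put_set(coll, round, annotator, document_id, set)
  invisible(m)
}

#' Snap a span to token boundaries
#'
#' Convenience helper mirroring whole-token selection: a token is a maximal
#' run of non-space characters (a sequence of characters between two spaces).
#' The span is widened to the boundaries of the tokens it touches. Never
#' enforced by [create_mention()], which accepts arbitrary valid offsets.
#'
#' @param text Section text.
#' @param start,end 0-based half-open offsets.
#' @return Integer vector `c(start, end)` on token boundaries.
#' @export
token_align <- function(text, start, end) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_space <- grepl("^\\s$", chars)
  s <- start
  while (s > 0L && !is_space[s]) s <- s - 1L
  e <- end
  while (e < length(chars) && !is_space[e + 1L]) e <- e + 1L
  c(s, e)
}

#' Annotate all occurrences of a surface string
#'
#' Finds every occurrence of `surface` in every section of the document
#' (case-sensitive exact substring match by default; left-to-right scan,
#' non-overlapping: the scan resumes at the end of each match) and creates one
#' mention per occurrence, each linked to `concepts`. Occurrences this
#' annotator already annotated with an identical (span, concept set) are not
#' duplicated. An absent surface yields an empty list, not an error.
#'
#' @inheritParams create_mention
#' @param surface Non-empty string to search for.
#' @param ignore_case Match case-insensitively.
#' @return List of the mentions created (possibly empty), invisibly.
#' @export
annotate_all <- function(coll, annotator, document_id, surface,
                         concepts = character(), ignore_case = FALSE,
                         round = current_round(coll)) {
  assert_string(surface, "surface")
  round <- check_round(coll, round)
  check_annotator(coll, annotator, round)
  doc <- get_document(coll, document_id)
  concepts <- unique(as.character(concepts))
  existing <- get_set(coll, round, annotator, document_id)$mentions
  existing_keys <- vapply(existing, function(m)
    paste(mention_key_of(m), paste(sort(m$concepts), collapse = ","), sep = .SEP),
    character(1))
  made <- list()
  for (section in names(doc$sections)) {
    text <- unname(doc$sections[[section]])
    if (!nzchar(text)) next
    hits <- if (ignore_case) {
      gregexpr(escape_regex(surface), text, ignore.case = TRUE, perl = TRUE)[[1]]
    } else {
      gregexpr(surface, text, fixed = TRUE)[[1]]
    }
    if (hits[1] == -1L) next
    for (pos in as.integer(hits)) {
      start <- pos - 1L
      end <- start + nchar(surface)
      key <- paste(mention_key(document_id, section, start, end),
                   paste(sort(concepts), collapse = ","), sep = .SEP)
      if (key %in% existing_keys) next
      m <- create_mention(coll, annotator, document_id, section, start, end,
                          concepts = concepts, round = round)
      existing_keys <- c(existing_keys, key)
      made[[length(made) + 1L]] <- m
    }
  }
  invisible(made)
}

#' Link a concept to a mention
#'
#' Adds a registered concept to the mention's linked set; a mention can have
#' more than one linked concept. If the concept is unknown, a full concept
#' record may be supplied via `register_if_new` and is then registered
#' collection-wide (on-the-fly concept creation). Re-linking an already linked
#' concept is an idempotent no-op.
#'
#' @inheritParams create_mention
#' @param mention_id Id of a mention owned by `annotator`.
#' @param concept_id Concept identifier.
#' @param register_if_new Optional one-row data frame (identifier, name, type,
#'   description) registered when `concept_id` is not yet in the registry.
#' @return The updated mention, invisibly.
#' @export
link_concept <- function(coll, annotator, document_id, mention_id, concept_id,
                         register_if_new = NULL, round = current_round(coll)) {
  round <- check_round(coll, round)
  set <- get_set(coll, round, annotator, document_id)
  m <- set$mentions[[mention_id]]
  if (is.null(m)) abort_domain("unknown mention '%s' for annotator '%s'",
                               mention_id, annotator)
  if (is.null(get_concept(coll, concept_id))) {
    if (is.null(register_if_new))
      abort_domain("concept '%s' is not registered", concept_id)
    if (!identical(register_if_new$identifier[[1]], concept_id))
      abort_domain("register_if_new identifier does not match '%s'", concept_id)
    register_concepts(coll, register_if_new)
  }
  if (!concept_id %in% m$concepts) {
    m$concepts <- c(m$concepts, concept_id)
    set$mentions[[mention_id]] <- m
    put_set(coll, round, annotator, document_id, set)
  }
  invisible(m)
}

# ---- relationship components ------------------------------------------------

#' Relationship component constructors
#'
#' A relationship mixes mention and concept components; a free-text payload is
#' allowed on the predicate role only.
#'
#' @param mention_id,concept_id,text Component payload.
#' @return A component list (`kind`, `ref`).
#' @export
comp_mention <- function(mention_id) list(kind = "mention", ref = mention_id)

#' @rdname comp_mention
#' @export
comp_concept <- function(concept_id) list(kind = "concept", ref = concept_id)

#' @rdname comp_mention
#' @export
comp_text <- function(text) list(kind = "text", ref = text)

check_component <- function(coll, set, comp, role) {
  if (!is.list(comp) || is.null(comp$kind))
    abort_domain("%s must be built with comp_mention/comp_concept/comp_text", role)
  switch(comp$kind,
    mention = {
      if (is.null(set$mentions[[comp$ref]]))
        abort_domain("%s references mention '%s' not owned by this annotator on this document",
                     role, comp$ref)
    },
    concept = {
      if (is.null(get_concept(coll, comp$ref)))
        abort_domain("%s references unregistered concept '%s'", role, comp$ref)
    },
    text = {
      if (role != "predicate")
        abort_domain("free-text payload is allowed on the predicate role only")
      assert_string(comp$ref, "free-text predicate")
    },
    abort_domain("unknown component kind '%s'", comp$kind)
  )
  invisible(comp)
}

#' Annotate a relationship
#'
#' A relationship has exactly three components — subject, predicate, object —
#' directed subject to object. Each component is a mention or a registered
#' concept; the predicate may alternatively be free text. At least one
#' component must be a mention; mention components may span different
#' sentences. The two mention components may be the same mention
#' (self-relation), which is permitted with a warning.
#'
#' @inheritParams create_mention
#' @param subject,predicate,object Components built with [comp_mention()],
#'   [comp_concept()] or [comp_text()] (predicate only).
#' @return The stored relationship, invisibly.
#' @export
create_relationship <- function(coll, annotator, document_id, subject, predicate,
                                object, round = current_round(coll)) {
  round <- check_round(coll, round)
  check_annotator(coll, annotator, round)
  get_document(coll, document_id)
  # force component arguments before snapshotting the set: building a
  # component may itself create the mention it references
  force(subject); force(predicate); force(object)
  set <- get_set(coll, round, annotator, document_id)
  check_component(coll, set, subject, "subject")
  check_component(coll, set, predicate, "predicate")
  check_component(coll, set, object, "object")
  kinds <- c(subject$kind, predicate$kind, object$kind)
  if (!any(kinds == "mention"))
    abort_domain("at least one of the three components must be a mention")
  if (subject$kind == "mention" && object$kind == "mention" &&
      identical(subject$ref, object$ref))
    warning("subject and object are the identical mention (self-relation)")
  r <- list(id = next_id(coll, "r"), subject = subject, predicate = predicate,
            object = object, created = now_utc(coll))
  set$relationships[[r$id]] <- r
  put_set(coll, round, annotator, document_id, set)
  invisible(r)
}

#' Change the role of a relationship component
#'
#' Swaps or reassigns roles within a stored relationship (e.g. a mention that
#' was the subject becomes the object). The result must still satisfy the
#' relationship validity rules.
#'
#' @inheritParams create_mention
#' @param relationship_id Id of a relationship owned by `annotator`.
#' @param role_from,role_to Two distinct roles among subject/predicate/object;
#'   their payloads are exchanged.
#' @export
change_role <- function(coll, annotator, document_id, relationship_id,
                        role_from, role_to, round = current_round(coll)) {
  round <- check_round(coll, round)
  set <- get_set(coll, round, annotator, document_id)
  r <- set$relationships[[relationship_id]]
  if (is.null(r)) abort_domain("unknown relationship '%s'", relationship_id)
  roles <- c("subject", "predicate", "object")
  if (!role_from %in% roles || !role_to %in% roles || role_from == role_to)
    abort_domain("roles must be two distinct of subject/predicate/object")
  tmp <- r[[role_from]]; r[[role_from]] <- r[[role_to]]; r[[role_to]] <- tmp
  for (role in roles)
    if (r[[role]]$kind == "text" && role != "predicate")
      abort_domain("free-text payload is allowed on the predicate role only")
  set$relationships[[relationship_id]] <- r
  put_set(coll, round, annotator, document_id, set)
  invisible(r)
}

#' Annotate an assertion
#'
#' An assertion is a document-level subject-predicate-object triple whose
#' components are all registered concepts, unbound to any mention. A duplicate
#' identical (subject, predicate, object) assertion by the same annotator is
#' an idempotent no-op.
#'
#' @inheritParams create_mention
#' @param subject,predicate,object Registered concept identifiers.
#' @return The stored (or pre-existing identical) assertion, invisibly.
#' @export
create_assertion <- function(coll, annotator, document_id, subject, predicate,
                             object, round = current_round(coll)) {
  round <- check_round(coll, round)
  check_annotator(coll, annotator, round)
  get_document(coll, document_id)
  for (cid in c(subject, predicate, object)) {
    assert_string(cid, "assertion component")
    if (is.null(get_concept(coll, cid)))
      abort_domain("concept '%s' is not registered", cid)
  }
  set <- get_set(coll, round, annotator, document_id)
  key <- paste(subject, predicate, object, sep = .SEP)
  for (a in set$assertions)
    if (identical(assertion_key_of(a), key)) return(invisible(a))
  a <- list(id = next_id(coll, "a"), subject = subject, predicate = predicate,
            object = object, created = now_utc(coll))
  set$assertions[[a$id]] <- a
  put_set(coll, round, annotator, document_id, set)
  invisible(a)
}

#' Set an annotator's labels on a document
#'
#' Replaces the annotator's label set for the document (select/deselect
#' semantics): labels present in `labels` are selected, all others
#' deselected. Every label must belong to the collection's label vocabulary.
#'
#' @inheritParams create_mention
#' @param labels Character vector (possibly empty) of labels to select.
#' @return The stored label annotations, invisibly.
#' @export
set_labels <- function(coll, annotator, document_id, labels,
                       round = current_round(coll)) {
  round <- check_round(coll, round)
  check_annotator(coll, annotator, round)
  get_document(coll, document_id)
  labels <- unique(as.character(labels))
  bad <- setdiff(labels, coll$labels)
  if (length(bad) > 0L)
    abort_domain("label(s) not in the collection's label set: %s",
                 paste(bad, collapse = ", "))
  set <- get_set(coll, round, annotator, document_id, create = TRUE)
  keep <- Filter(function(l) l$label %in% labels, set$labels)
  have <- vapply(keep, function(l) l$label, character(1))
  for (lab in setdiff(labels, have)) {
    l <- list(id = next_id(coll, "l"), document_id = document_id, label = lab,
              created = now_utc(coll))
    keep[[l$id]] <- l
  }
  set$labels <- keep
  put_set(coll, round, annotator, document_id, set)
  invisible(set$labels)
}

#' Delete an annotation
#'
#' Deletes one annotation owned by the calling annotator. Deleting a mention
#' cascades: its concept links go with it and every relationship referencing
#' it is deleted too (a relationship with a dangling component would violate
#' its own validity rule). Cascaded deletions are reported, never silent.
#'
#' @inheritParams create_mention
#' @param annotation_id Id of a mention, relationship, assertion or label
#'   annotation owned by `annotator`.
#' @return A report list: `deleted` (the id), `type`, and `cascaded`
#'   (character vector of relationship ids removed by cascade).
#' @export
delete_annotation <- function(coll, annotator, document_id, annotation_id,
                              round = current_round(coll)) {
  round <- check_round(coll, round)
  set <- get_set(coll, round, annotator, document_id)
  cascaded <- character(0)
  type <- NULL
  if (!is.null(set$mentions[[annotation_id]])) {
    type <- "mention"
    refs <- vapply(set$relationships, function(r)
      any(vapply(list(r$subject, r$predicate, r$object), function(comp)
        comp$kind == "mention" && identical(comp$ref, annotation_id), logical(1))),
      logical(1))
    cascaded <- names(set$relationships)[refs]
    set$relationships[cascaded] <- NULL
    set$mentions[[annotation_id]] <- NULL
  } else if (!is.null(set$relationships[[annotation_id]])) {
    type <- "relationship"
    set$relationships[[annotation_id]] <- NULL
  } else if (!is.null(set$assertions[[annotation_id]])) {
    type <- "assertion"
    set$assertions[[annotation_id]] <- NULL
  } else if (!is.null(set$labels[[annotation_id]])) {
    type <- "label"
    set$labels[[annotation_id]] <- NULL
  } else {
    abort_domain("unknown annotation '%s' for annotator '%s'", annotation_id,
                 annotator)
  }
  put_set(coll, round, annotator, document_id, set)
  list(deleted = annotation_id, type = type, cascaded = cascaded)
}

#' Copy annotations from a teammate
#'
#' Deep-copies a teammate's annotations on a document into the calling
#' annotator's set, so both end up with the same (or partial) set. Copying a
#' relationship copies its component mentions too (dependency closure).
#' Annotations the target already holds (identical identity key) are skipped;
#' the return value counts annotations actually added. Applied twice, the
#' operation is idempotent.
#'
#' @param coll A collection.
#' @param document_id Document id.
#' @param from,to Source and target annotator ids.
#' @param ids Optional annotation ids restricting the selection; default
#'   copies everything `from` holds on the document.
#' @param round Round index.
#' @return Number of annotations added.
#' @export
copy_annotations <- function(coll, document_id, from, to, ids = NULL,
                             round = current_round(coll)) {
  round <- check_round(coll, round)
  check_annotator(coll, to, round)
  src <- get_set(coll, round, from, document_id)
  dst <- get_set(coll, round, to, document_id, create = TRUE)
  all_ids <- c(names(src$mentions), names(src$relationships),
               names(src$assertions), names(src$labels))
  if (is.null(ids)) ids <- all_ids
  bad <- setdiff(ids, all_ids)
  if (length(bad) > 0L)
    abort_domain("annotation(s) not in '%s' set on '%s': %s", from, document_id,
                 paste(bad, collapse = ", "))
  added <- 0L

  dst_mention_keys <- function()
    vapply(dst$mentions, mention_key_of, character(1))
  # returns the id of the target's mention with this key, copying if needed
  ensure_mention <- function(src_mention) {
    keys <- dst_mention_keys()
    hit <- names(dst$mentions)[keys == mention_key_of(src_mention)]
    if (length(hit) > 0L) return(hit[[1]])
    m <- src_mention
    m$id <- next_id(coll, "m")
    m$created <- now_utc(coll)
    dst$mentions[[m$id]] <<- m
    added <<- added + 1L
    m$id
  }

  for (id in intersect(ids, names(src$mentions))) ensure_mention(src$mentions[[id]])

  dst_rel_keys <- function()
    vapply(dst$relationships, function(r) rel_key_of(r, dst), character(1))
  for (id in intersect(ids, names(src$relationships))) {
    r <- src$relationships[[id]]
    key <- rel_key_of(r, src)
    if (key %in% dst_rel_keys()) next
    r2 <- r
    for (role in c("subject", "predicate", "object")) {
      if (r2[[role]]$kind == "mention")
        r2[[role]]$ref <- ensure_mention(src$mentions[[r2[[role]]$ref]])
    }
    r2$id <- next_id(coll, "r")
    r2$created <- now_utc(coll)
    dst$relationships[[r2$id]] <- r2
    added <- added + 1L
  }

  dst_ass_keys <- vapply(dst$assertions, assertion_key_of, character(1))
  for (id in intersect(ids, names(src$assertions))) {
    a <- src$assertions[[id]]
    if (assertion_key_of(a) %in% dst_ass_keys) next
    a$id <- next_id(coll, "a")
    a$created <- now_utc(coll)
    dst$assertions[[a$id]] <- a
    dst_ass_keys <- c(dst_ass_keys, assertion_key_of(a))
    added <- added + 1L
  }

  dst_labels <- vapply(dst$labels, function(l) l$label, character(1))
  for (id in intersect(ids, names(src$labels))) {
    l <- src$labels[[id]]
    if (l$label %in% dst_labels) next
    l$id <- next_id(coll, "l")
    l$created <- now_utc(coll)
    dst$labels[[l$id]] <- l
    dst_labels <- c(dst_labels, l$label)
    added <- added + 1L
  }

  put_set(coll, round, to, document_id, dst)
  added
}

#' Concept suggestions for a mention
#'
#' Lists the concepts that other annotators linked to mentions with the
#' identical span, with the number of annotators per concept, sorted by that
#' count (descending, ties by identifier). The calling annotator's own links
#' are excluded. An empty data frame means no teammate annotated the span.
#'
#' @inheritParams create_mention
#' @param mention_id Id of a mention owned by `annotator`.
#' @return Data frame with columns `identifier`, `name`, `type`,
#'   `n_annotators`.
#' @export
suggest_concepts <- function(coll, annotator, document_id, mention_id,
                             round = current_round(coll)) {
  round <- check_round(coll, round)
  set <- get_set(coll, round, annotator, document_id)
  m <- set$mentions[[mention_id]]
  if (is.null(m)) abort_domain("unknown mention '%s'", mention_id)
  key <- mention_key_of(m)
  counts <- list()
  for (other in setdiff(names(coll$ann[[round]]), annotator)) {
    oset <- get_set(coll, round, other, document_id)
    linked <- character(0)
    for (om in oset$mentions)
      if (identical(mention_key_of(om), key)) linked <- c(linked, om$concepts)
    for (cid in unique(linked))
      counts[[cid]] <- (counts[[cid]] %||% 0L) + 1L
  }
  if (length(counts) == 0L)
    return(data.frame(identifier = character(), name = character(),
                      type = character(), n_annotators = integer(),
                      stringsAsFactors = FALSE))
  ids <- names(counts)
  n <- vapply(counts, identity, integer(1))
  ord <- order(-n, ids)
  info <- lapply(ids[ord], function(cid) get_concept(coll, cid) %||%
                   list(identifier = cid, name = cid, type = ""))
  data.frame(identifier = ids[ord],
             name = vapply(info, function(x) x$name, character(1)),
             type = vapply(info, function(x) x$type, character(1)),
             n_annotators = unname(n[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}
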