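# Statistics panels and baseline-diff provenance. All statistics are pure
# functions of the store: recomputation after a serialization round trip
# yields identical reports.

count_set <- function(set) {
  c(mentions = length(set$mentions),
    concept_links = sum(vapply(set$mentions, function(m) length(m$concepts),
                               integer(1)), 0L),
    relationships = length(set$relationships),
    assertions = length(set$assertions),
    labels = length(set$labels))
}

#' Annotation count summary
#'
#' Personal (one annotator) or global (all annotators) counts per annotation
#' type, number of annotated documents and of annotators, and — in global
#' mode — the collection-scope Fleiss' kappa per annotation type.
#'
#' @param coll A collection.
#' @param mode `"global"` or `"personal"`.
#' @param annotator Required in personal mode.
#' @param document_id Restrict to one document.
#' @param round Round index.
#' @param with_kappa Include per-type Fleiss' kappa (global mode only).
#' @return A list of class `stats_report`.
#' @export
summarize_annotations <- function(coll, mode = c("global", "personal"),
                                  annotator = NULL, document_id = NULL,
                                  round = current_round(coll),
                                  with_kappa = mode == "global") {
  mode <- match.arg(mode)
  round <- check_round(coll, round)
  if (mode == "personal") assert_string(annotator, "annotator")
  annotators <- if (mode == "personal") annotator
                else scope_annotators(coll, round, document_id,
                                      include_machine = TRUE)
  docs <- if (is.null(document_id)) names(coll$documents) else document_id
  totals <- c(mentions = 0L, concept_links = 0L, relationships = 0L,
              assertions = 0L, labels = 0L)
  annotated_docs <- character(0)
  for (a in annotators) {
    for (doc in docs) {
      set <- get_set(coll, round, a, doc)
      n <- count_set(set)
      totals <- totals + n
      if (sum(n) > 0L) annotated_docs <- union(annotated_docs, doc)
    }
  }
  kappa <- NULL
  if (isTRUE(with_kappa) && mode == "global") {
    kappa <- vapply(ANNOTATION_TYPES, function(type)
      fleiss_agreement(coll, type, round, document_id)$kappa, numeric(1))
  }
  structure(list(mode = mode, annotator = annotator, scope = document_id %||%
                   "collection", round_index = round, counts = totals,
                 n_annotated_documents = length(annotated_docs),
                 n_annotators = length(annotators), fleiss = kappa),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("Annotation statistics [%s, %s, round %d]\n",
              if (x$mode == "personal") paste0("personal: ", x$annotator)
              else "global", x$scope, x$round_index))
  cat(sprintf("  documents annotated: %d   annotators: %d\n",
              x$n_annotated_documents, x$n_annotators))
  for (k in names(x$counts)) cat(sprintf("  %-14s %d\n", k, x$counts[[k]]))
  if (!is.null(x$fleiss)) {
    cat("  Fleiss' kappa by type:\n")
    for (t in names(x$fleiss))
      cat(sprintf("    %-13s %s\n", t,
                  if (is.na(x$fleiss[[t]])) "UNDEFINED"
                  else sprintf("%.4f", x$fleiss[[t]])))
  }
  invisible(x)
}

#' Concept-type distributions
#'
#' Frequency tables of the concept types used in concept linking and of the
#' concepts filling the subject / predicate / object roles of relationships
#' and assertions. Free-text predicates have no concept type; they are
#' excluded from the role distributions and counted separately.
#'
#' @inheritParams summarize_annotations
#' @return A list of class `distribution_report`: `global_type_counts`,
#'   `linked_concept_counts`, `role_type_counts` (per role), and
#'   `n_freetext_predicates`.
#' @export
concept_distributions <- function(coll, round = current_round(coll),
                                  document_id = NULL, annotators = NULL) {
  round <- check_round(coll, round)
  annotators <- annotators %||% scope_annotators(coll, round, document_id,
                                                 include_machine = TRUE)
  docs <- if (is.null(document_id)) names(coll$documents) else document_id
  type_of <- function(cid) (get_concept(coll, cid) %||% list(type = "?"))$type
  linked <- list(); roles <- list(subject = list(), predicate = list(),
                                  object = list())
  freetext <- 0L
  bump <- function(tab, key) { tab[[key]] <- (tab[[key]] %||% 0L) + 1L; tab }
  for (a in annotators) for (doc in docs) {
    set <- get_set(coll, round, a, doc)
    for (m in set$mentions) for (cid in m$concepts) linked <- bump(linked, cid)
    for (r in set$relationships) for (role in names(roles)) {
      comp <- r[[role]]
      if (comp$kind == "concept") {
        roles[[role]] <- bump(roles[[role]], comp$ref)
      } else if (comp$kind == "text") {
        freetext <- freetext + 1L
      } else {
        m <- set$mentions[[comp$ref]]
        for (cid in m$concepts) roles[[role]] <- bump(roles[[role]], cid)
      }
    }
    for (s in set$assertions) for (role in names(roles))
      roles[[role]] <- bump(roles[[role]], s[[role]])
  }
  by_type <- function(tab) {
    if (length(tab) == 0L) return(stats::setNames(integer(0), character(0)))
    counts <- vapply(tab, identity, integer(1))
    types <- vapply(names(tab), type_of, character(1))
    out <- tapply(counts, types, sum)
    stats::setNames(as.integer(out), names(out))
  }
  all_tab <- linked
  for (role in names(roles)) for (k in names(roles[[role]]))
    all_tab[[k]] <- (all_tab[[k]] %||% 0L) + roles[[role]][[k]]
  structure(list(
    global_type_counts = by_type(all_tab),
    linked_concept_counts = if (length(linked) == 0L) integer(0)
                            else sort(vapply(linked, identity, integer(1)),
                                      decreasing = TRUE),
    linked_type_counts = by_type(linked),
    role_type_counts = lapply(roles, by_type),
    role_concept_counts = lapply(roles, function(tab)
      if (length(tab) == 0L) integer(0)
      else sort(vapply(tab, identity, integer(1)), decreasing = TRUE)),
    n_freetext_predicates = freetext),
    class = "distribution_report")
}

#' Per-document annotation counts
#'
#' One row per document with annotation counts by type, plus the percentage
#' of documents with at least one annotation (the collection progress
#' indicator; presentation thresholds green > 80 percent / red < 20 percent
#' are carried as metadata).
#'
#' @inheritParams summarize_annotations
#' @return Data frame, one row per document; attribute `progress_percent`.
#' @export
per_document_counts <- function(coll, round = current_round(coll)) {
  round <- check_round(coll, round)
  annotators <- scope_annotators(coll, round, include_machine = TRUE)
  rows <- lapply(names(coll$documents), function(doc) {
    totals <- c(mentions = 0L, concept_links = 0L, relationships = 0L,
                assertions = 0L, labels = 0L)
    for (a in annotators)
      totals <- totals + count_set(get_set(coll, round, a, doc))
    cbind(data.frame(document = doc, stringsAsFactors = FALSE),
          as.data.frame(as.list(totals)))
  })
  df <- do.call(rbind, rows) %||%
    data.frame(document = character(), mentions = integer(),
               concept_links = integer(), relationships = integer(),
               assertions = integer(), labels = integer())
  annotated <- sum(rowSums(df[, -1, drop = FALSE]) > 0)
  progress <- if (nrow(df) == 0L) 0 else 100 * annotated / nrow(df)
  structure(df, progress_percent = progress,
            progress_thresholds = c(green_above = 80, red_below = 20))
}

#' Annotator counts per document
#'
#' @inheritParams summarize_annotations
#' @return Data frame with columns `document`, `n_annotators`.
#' @export
annotators_per_document <- function(coll, round = current_round(coll)) {
  round <- check_round(coll, round)
  data.frame(document = names(coll$documents),
             n_annotators = vapply(names(coll$documents), function(doc)
               length(setdiff(round_annotators(coll, round, doc),
                              CONSENSUS_ANNOTATOR)), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# ---- baseline diff ----------------------------------------------------------

# pair-key matching: relationships and assertions are matched between
# baseline and final by their (subject, object) endpoints; a predicate
# change on a matched pair is an update, an endpoint change is
# added + deleted. Concept links are matched by span; a changed concept set
# is an update. Mentions are present/absent by span.
diff_items <- function(coll, round, annotator_set, docs, type) {
  out <- list()
  merge_in <- function(items) {
    for (k in names(items)) {
      if (is.null(out[[k]])) out[[k]] <- items[[k]]
      else out[[k]] <- sort(unique(c(out[[k]], items[[k]])))
    }
    out
  }
  for (annotator in annotator_set) for (doc in docs) {
    set <- get_set(coll, round, annotator, doc)
    items <- list()
    if (type == "relationship") {
      for (r in set$relationships) {
        k <- paste(doc, rel_pair_key_of(r, set), sep = .SEP)
        items[[k]] <- sort(unique(c(items[[k]], comp_key(r$predicate, set))))
      }
    } else if (type == "assertion") {
      for (a in set$assertions) {
        k <- paste(doc, assertion_pair_key_of(a), sep = .SEP)
        items[[k]] <- sort(unique(c(items[[k]], a$predicate)))
      }
    } else if (type == "concept") {
      for (m in set$mentions) {
        if (length(m$concepts) == 0L) next
        k <- mention_key_of(m)
        items[[k]] <- sort(unique(c(items[[k]], m$concepts)))
      }
    } else if (type == "mention") {
      for (m in set$mentions) items[[mention_key_of(m)]] <- "PRESENT"
    } else if (type == "label") {
      for (l in set$labels) items[[label_key_of(l)]] <- "PRESENT"
    }
    out <- merge_in(items)
  }
  out
}

#' Provenance diff against a baseline annotator
#'
#' Classifies a final annotation set against a baseline (typically the
#' automatic annotations): relationships and assertions are matched by their
#' (subject, object) pair — same predicate is `confirmed`, a different
#' predicate is `updated`; concept links are matched by mention span — the
#' same concept set is `confirmed`, a changed set `updated`; items only in
#' the final set are `added`, only in the baseline `deleted`. The four
#' classes partition the union of baseline and final keys.
#'
#' @param coll A collection.
#' @param baseline Baseline annotator id (e.g. `"AutoTron"`).
#' @param final Final annotator id, or several (their distinct annotations
#'   are pooled).
#' @param type `"mention"`, `"concept"`, `"relationship"`, `"assertion"` or
#'   `"label"`.
#' @param document_id Restrict to one document.
#' @param round_baseline,round_final Rounds the two sets are read from
#'   (defaults: baseline round 1, final the latest round).
#' @return A list of class `diff_report` with counts and itemized key lists
#'   per class.
#' @export
diff_against_baseline <- function(coll, baseline, final, type,
                                  document_id = NULL,
                                  round_baseline = 1L,
                                  round_final = current_round(coll)) {
  type <- match.arg(type, ANNOTATION_TYPES)
  docs <- if (is.null(document_id)) names(coll$documents) else document_id
  base <- diff_items(coll, check_round(coll, round_baseline), baseline, docs, type)
  fin <- diff_items(coll, check_round(coll, round_final), final, docs, type)
  keys <- union(names(base), names(fin))
  classes <- vapply(keys, function(k) {
    in_b <- !is.null(base[[k]]); in_f <- !is.null(fin[[k]])
    if (in_b && in_f) {
      if (identical(base[[k]], fin[[k]])) "confirmed" else "updated"
    } else if (in_f) "added" else "deleted"
  }, character(1))
  split_keys <- function(cls) sort(keys[classes == cls])
  structure(list(annotation_type = type,
                 baseline = paste(baseline, collapse = "+"),
                 final = paste(final, collapse = "+"),
                 counts = c(added = sum(classes == "added"),
                            updated = sum(classes == "updated"),
                            deleted = sum(classes == "deleted"),
                            confirmed = sum(classes == "confirmed")),
                 added = split_keys("added"), updated = split_keys("updated"),
                 deleted = split_keys("deleted"),
                 confirmed = split_keys("confirmed"),
                 n_universe = length(keys)),
            class = "diff_report")
}

#' @export
print.diff_report <- function(x, ...) {
  cat(sprintf("Diff [%s] %s -> %s: added %d, updated %d, deleted %d, confirmed %d\n",
              x$annotation_type, x$baseline, x$final,
              x$counts[["added"]], x$counts[["updated"]],
              x$counts[["deleted"]], x$counts[["confirmed"]]))
  invisible(x)
}
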