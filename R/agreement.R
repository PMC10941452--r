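ANNOTATION_TYPES <- c("mention", "concept", "relationship", "assertion", "label")

# Category assigned to items an annotator did not annotate.
ABSENT <- "ABSENT"

# Annotator id of the consensus "virtual annotator".
CONSENSUS_ANNOTATOR <- "IAA"

#' One annotator's unitized items for one annotation type
#'
#' Returns a named character vector: names are document-qualified item keys,
#' values are categories. Items/categories per type: mentions — span key,
#' PRESENT; concept links — (span key, concept id), PRESENT; relationships —
#' (subject key, object key), category = predicate identity; assertions —
#' (subject id, object id), category = predicate id; labels — (document,
#' label), PRESENT. When an annotator holds several relationships on the same
#' (subject, object) pair, the lexicographically smallest predicate key is
#' the category (deterministic).
#' @noRd
annotator_items <- function(coll, round, annotator, document_ids, type) {
  out <- character(0)
  for (doc in document_ids) {
    set <- get_set(coll, round, annotator, doc)
    if (type == "mention") {
      for (m in set$mentions) out[mention_key_of(m)] <- "PRESENT"
    } else if (type == "concept") {
      for (m in set$mentions)
        for (k in link_keys_of(m)) out[k] <- "PRESENT"
    } else if (type == "relationship") {
      for (r in set$relationships) {
        item <- paste(doc, rel_pair_key_of(r, set), sep = .SEP)
        cat <- comp_key(r$predicate, set)
        if (is.na(out[item]) || cat < out[item]) out[item] <- cat
      }
    } else if (type == "assertion") {
      for (a in set$assertions) {
        item <- paste(doc, assertion_pair_key_of(a), sep = .SEP)
        cat <- a$predicate
        if (is.na(out[item]) || cat < out[item]) out[item] <- cat
      }
    } else if (type == "label") {
      for (l in set$labels) out[paste(doc, l$label, sep = .SEP)] <- "PRESENT"
    }
  }
  out
}

scope_annotators <- function(coll, round, document_id = NULL,
                             include_machine = FALSE) {
  sets <- coll$ann[[round]]
  anns <- names(sets) %||% character(0)
  has <- vapply(anns, function(a) {
    bydoc <- sets[[a]]
    docs <- names(bydoc)
    if (!is.null(document_id)) docs <- intersect(docs, document_id)
    any(vapply(docs, function(d) {
      s <- bydoc[[d]]
      (length(s$mentions) + length(s$relationships) + length(s$assertions) +
         length(s$labels)) > 0L
    }, logical(1)))
  }, logical(1))
  ann <- anns[has]
  if (!include_machine) ann <- setdiff(ann, MACHINE_ANNOTATOR)
  sort(setdiff(ann, CONSENSUS_ANNOTATOR))
}

#' Unitize annotation sets into a rating table
#'
#' Maps the free-form annotations of all in-scope annotators to a fixed
#' items-by-categories table of rater counts, the form required by kappa
#' statistics: items are the union of identity keys observed across
#' annotators, each annotator contributes exactly one category per item
#' (`ABSENT` when they did not annotate it), so the rater count is constant
#' across items.
#'
#' @param coll A collection.
#' @param type One of `"mention"`, `"concept"`, `"relationship"`,
#'   `"assertion"`, `"label"`.
#' @param round Round index.
#' @param document_id Restrict to one document; default pools items across
#'   the whole collection (document id is part of every item key).
#' @param annotators Rater ids; default every annotator with at least one
#'   annotation in scope, excluding the machine annotator.
#' @param items Optional item-key filter (e.g. consensus-covered items).
#' @return An object of class `rating_table`: list with `items`,
#'   `categories`, integer matrix `counts` (items x categories) and
#'   `n_raters`.
#' @export
unitize <- function(coll, type, round = current_round(coll), document_id = NULL,
                    annotators = NULL, items = NULL) {
  type <- match.arg(type, ANNOTATION_TYPES)
  round <- check_round(coll, round)
  if (is.null(annotators))
    annotators <- scope_annotators(coll, round, document_id)
  if (length(annotators) < 2L)
    abort_domain("unitization needs at least 2 annotators in scope (got %d)",
                 length(annotators))
  docs <- if (is.null(document_id)) names(coll$documents) else document_id
  per <- lapply(annotators, function(a) annotator_items(coll, round, a, docs, type))
  names(per) <- annotators
  universe <- sort(unique(unlist(lapply(per, names), use.names = FALSE)))
  if (!is.null(items)) universe <- intersect(universe, items)
  cats <- sort(unique(c(unlist(per, use.names = FALSE), ABSENT)))
  counts <- matrix(0L, nrow = length(universe), ncol = length(cats),
                   dimnames = list(universe, cats))
  for (a in annotators) {
    v <- per[[a]]
    assigned <- ifelse(universe %in% names(v), v[universe], ABSENT)
    for (i in seq_along(universe))
      counts[i, assigned[[i]]] <- counts[i, assigned[[i]]] + 1L
  }
  structure(list(items = universe, categories = cats, counts = counts,
                 n_raters = length(annotators), annotators = annotators,
                 annotation_type = type),
            class = "rating_table")
}

#' @export
print.rating_table <- function(x, ...) {
  cat(sprintf("<rating table: %d item(s) x %d categories, %d raters (%s)>\n",
              length(x$items), length(x$categories), x$n_raters,
              x$annotation_type %||% "?"))
  invisible(x)
}

#' Fleiss' kappa
#'
#' Chance-corrected agreement among two or more raters over a fixed item set
#' (Fleiss 1971). With `n` raters, `N` items and counts `n_ij`:
#' `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`, `Pbar = mean_i P_i`,
#' `p_j = sum_i n_ij / (N n)`, `Pe = sum_j p_j^2`,
#' `kappa = (Pbar - Pe) / (1 - Pe)`.
#' When every rater assigns every item identically, `Pbar = 1` and kappa is 1
#' by definition even when `Pe = 1` (agreement is literally perfect, despite
#' the 0/0 form). An empty table yields `NA` (undefined).
#'
#' @param table A `rating_table` or an items-by-categories integer matrix
#'   with a constant row sum (the rater count).
#' @return Kappa in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
fleiss_kappa <- function(table) {
  m <- if (inherits(table, "rating_table")) table$counts else as.matrix(table)
  if (length(m) == 0L || nrow(m) == 0L) return(NA_real_)
  n <- unique(rowSums(m))
  if (length(n) != 1L)
    abort_domain("rating table rows must sum to a constant rater count")
  if (n < 2L) abort_domain("Fleiss' kappa needs at least 2 raters")
  N <- nrow(m)
  P_i <- (rowSums(m^2) - n) / (n * (n - 1))
  Pbar <- mean(P_i)
  p_j <- colSums(m) / (N * n)
  Pe <- sum(p_j^2)
  if (Pbar == 1) return(1)
  if (Pe == 1) return(NA_real_)
  (Pbar - Pe) / (1 - Pe)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two raters rating the same items;
#' ranges between -1 and 1. `p_o` is the fraction of items rated identically;
#' `p_e = sum_j P_a(j) P_b(j)` the chance agreement from the raters' marginal
#' category distributions; `kappa = (p_o - p_e) / (1 - p_e)`, defined as 1
#' when `p_o = 1`.
#'
#' @param a,b Equal-length category vectors over the same item list.
#' @return Kappa in `[-1, 1]`, or `NA_real_` for empty input.
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) abort_domain("category sequences differ in length")
  if (length(a) == 0L) return(NA_real_)
  a <- as.character(a); b <- as.character(b)
  p_o <- mean(a == b)
  if (p_o == 1) return(1)
  cats <- union(a, b)
  p_a <- vapply(cats, function(k) mean(a == k), numeric(1))
  p_b <- vapply(cats, function(k) mean(b == k), numeric(1))
  p_e <- sum(p_a * p_b)
  if (p_e == 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

new_agreement_report <- function(measure, type, scope, round, kappa, n_items,
                                 n_raters, annotators = NULL) {
  structure(list(measure = measure, annotation_type = type, scope = scope,
                 round_index = round, kappa = kappa, n_items = n_items,
                 n_raters = n_raters, annotators = annotators),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  kap <- if (is.na(x$kappa)) "UNDEFINED" else sprintf("%.4f", x$kappa)
  cat(sprintf("%s kappa [%s, %s, round %d]: %s  (%d items, %d raters)\n",
              tools::toTitleCase(x$measure), x$annotation_type, x$scope,
              x$round_index, kap, x$n_items, x$n_raters))
  invisible(x)
}

#' Fleiss' kappa agreement report
#'
#' Computes Fleiss' kappa for one annotation type at collection scope
#' (pooling items across documents) or for a single document. Scopes with
#' fewer than two annotators yield an `NA` (undefined) kappa rather than an
#' error.
#'
#' @inheritParams unitize
#' @return An `agreement_report`.
#' @export
fleiss_agreement <- function(coll, type, round = current_round(coll),
                             document_id = NULL, annotators = NULL,
                             items = NULL) {
  scope <- if (is.null(document_id)) "collection" else document_id
  tab <- tryCatch(unitize(coll, type, round, document_id, annotators, items),
                  annostore_error = function(e) NULL)
  if (is.null(tab))
    return(new_agreement_report("fleiss", type, scope, round, NA_real_, 0L,
                                length(annotators %||%
                                  scope_annotators(coll, round, document_id))))
  new_agreement_report("fleiss", type, scope, round, fleiss_kappa(tab),
                       length(tab$items), tab$n_raters, tab$annotators)
}

#' Pairwise Cohen's kappa
#'
#' Unitizes the scope restricted to the selected pair of annotators and
#' applies Cohen's kappa; computed on a single document or on the entire
#' collection.
#'
#' @inheritParams unitize
#' @param annotator_a,annotator_b The two distinct raters.
#' @return An `agreement_report`.
#' @export
pairwise_cohen <- function(coll, annotator_a, annotator_b, type,
                           round = current_round(coll), document_id = NULL) {
  if (identical(annotator_a, annotator_b))
    abort_domain("Cohen's kappa needs two distinct annotators")
  in_scope <- scope_annotators(coll, round, document_id, include_machine = TRUE)
  for (a in c(annotator_a, annotator_b))
    if (!a %in% in_scope)
      abort_domain("annotator '%s' has no annotations in scope", a)
  tab <- unitize(coll, type, round, document_id,
                 annotators = c(annotator_a, annotator_b))
  per <- lapply(c(annotator_a, annotator_b), function(a)
    annotator_items(coll, round, a,
                    if (is.null(document_id)) names(coll$documents) else document_id,
                    type))
  cat_of <- function(v) ifelse(tab$items %in% names(v), v[tab$items], ABSENT)
  scope <- if (is.null(document_id)) "collection" else document_id
  new_agreement_report("cohen", type, scope, round,
                       cohen_kappa(cat_of(per[[1]]), cat_of(per[[2]])),
                       length(tab$items), 2L, c(annotator_a, annotator_b))
}

#' Per-round Fleiss' kappa
#'
#' One collection-scope Fleiss report per round for an annotation type.
#' Rounds with fewer than two annotators are reported with an `NA` kappa, not
#' dropped.
#'
#' @inheritParams unitize
#' @return Data frame with columns `round`, `kappa`, `n_items`, `n_raters`.
#' @export
agreement_by_round <- function(coll, type, document_id = NULL) {
  rows <- lapply(seq_along(coll$rounds), function(r) {
    rep <- fleiss_agreement(coll, type, round = r, document_id = document_id)
    data.frame(round = r, kappa = rep$kappa, n_items = rep$n_items,
               n_raters = rep$n_raters)
  })
  do.call(rbind, rows)
}

# keyed payloads of one annotator's set, for consensus materialization
keyed_payloads <- function(set, document_id, type) {
  out <- list()
  if (type == "mention") {
    for (m in set$mentions) out[[mention_key_of(m)]] <- m
  } else if (type == "concept") {
    for (m in set$mentions)
      for (cid in m$concepts)
        out[[paste(mention_key_of(m), cid, sep = .SEP)]] <-
          list(mention = m, concept = cid)
  } else if (type == "relationship") {
    for (r in set$relationships) {
      resolved <- r
      for (role in c("subject", "predicate", "object"))
        if (r[[role]]$kind == "mention")
          resolved[[role]]$mention <- set$mentions[[r[[role]]$ref]]
      out[[rel_key_of(r, set)]] <- resolved
    }
  } else if (type == "assertion") {
    for (a in set$assertions) out[[assertion_key_of(a)]] <- a
  } else if (type == "label") {
    for (l in set$labels) out[[label_key_of(l)]] <- l
  }
  out
}

#' Strict-majority consensus on a document
#'
#' Selects every annotation (by identity key) held by more than half of the
#' document's annotators, where the annotator count `n` is the number of
#' annotators with at least one annotation of any type on the document in the
#' round. The machine annotator is excluded from the rater pool by default.
#'
#' @inheritParams unitize
#' @param document_id The document.
#' @param include_machine Count the reserved machine annotator as a rater.
#' @return An object of class `consensus_set`: data frame with columns `key`,
#'   `support`, `n_annotators`, plus the payloads needed to materialize the
#'   entries (attribute `payloads`).
#' @export
majority_vote <- function(coll, document_id, type, round = current_round(coll),
                          include_machine = FALSE) {
  type <- match.arg(type, ANNOTATION_TYPES)
  round <- check_round(coll, round)
  get_document(coll, document_id)
  raters <- round_annotators(coll, round, document_id)
  if (!include_machine) raters <- setdiff(raters, MACHINE_ANNOTATOR)
  raters <- setdiff(raters, CONSENSUS_ANNOTATOR)
  n <- length(raters)
  support <- list(); payloads <- list()
  for (a in raters) {
    kp <- keyed_payloads(get_set(coll, round, a, document_id), document_id, type)
    for (k in names(kp)) {
      support[[k]] <- (support[[k]] %||% 0L) + 1L
      if (is.null(payloads[[k]])) payloads[[k]] <- kp[[k]]
    }
  }
  keys <- names(support)
  sup <- vapply(support, identity, integer(1))
  keep <- sup > n / 2
  keys <- sort(keys[keep])
  df <- data.frame(key = keys,
                   support = unname(sup[keys]),
                   n_annotators = rep(n, length(keys)),
                   stringsAsFactors = FALSE)
  structure(df, payloads = payloads[keys], annotation_type = type,
            document_id = document_id, round_index = round,
            class = c("consensus_set", "data.frame"))
}

#' Materialize the consensus as a virtual annotator
#'
#' Stores the strict-majority consensus of every annotation type for a
#' document under the reserved annotator id `"IAA"` (Inter Annotator
#' Agreement), so it can be loaded, copied and exported like a teammate's
#' annotation set.
#'
#' @inheritParams majority_vote
#' @return Number of annotations stored.
#' @export
materialize_consensus <- function(coll, document_id,
                                  round = current_round(coll),
                                  include_machine = FALSE) {
  round <- check_round(coll, round)
  set <- empty_set()
  stored <- 0L
  mention_ids <- list()   # span key -> id in the consensus set
  ensure_cons_mention <- function(m) {
    key <- mention_key_of(m)
    if (!is.null(mention_ids[[key]])) return(mention_ids[[key]])
    m2 <- m; m2$id <- next_id(coll, "m"); m2$concepts <- character(0)
    m2$created <- now_utc(coll)
    set$mentions[[m2$id]] <<- m2
    mention_ids[[key]] <<- m2$id
    m2$id
  }
  cons <- function(type) majority_vote(coll, document_id, type, round,
                                       include_machine)
  for (m in attr(cons("mention"), "payloads")) {
    ensure_cons_mention(m); stored <- stored + 1L
  }
  for (p in attr(cons("concept"), "payloads")) {
    id <- ensure_cons_mention(p$mention)
    mm <- set$mentions[[id]]
    mm$concepts <- unique(c(mm$concepts, p$concept))
    set$mentions[[id]] <- mm
    stored <- stored + 1L
  }
  for (r in attr(cons("relationship"), "payloads")) {
    r2 <- r
    for (role in c("subject", "predicate", "object")) {
      if (r2[[role]]$kind == "mention") {
        r2[[role]]$ref <- ensure_cons_mention(r2[[role]]$mention)
        r2[[role]]$mention <- NULL
      }
    }
    r2$id <- next_id(coll, "r"); r2$created <- now_utc(coll)
    set$relationships[[r2$id]] <- r2
    stored <- stored + 1L
  }
  for (a in attr(cons("assertion"), "payloads")) {
    a$id <- next_id(coll, "a"); a$created <- now_utc(coll)
    set$assertions[[a$id]] <- a
    stored <- stored + 1L
  }
  for (l in attr(cons("label"), "payloads")) {
    l$id <- next_id(coll, "l"); l$created <- now_utc(coll)
    set$labels[[l$id]] <- l
    stored <- stored + 1L
  }
  put_set(coll, round, CONSENSUS_ANNOTATOR, document_id, set)
  stored
}
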