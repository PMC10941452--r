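# Seeded generators for corpora, lexicons, planted associations and
# multi-annotator annotation sets with controllable agreement. Documents are
# assembled from sentence templates so every gold offset is exact by
# construction; a gold ledger records every planted key so expected test
# statistics are recomputable without re-parsing text.

SYNTH_GENES <- data.frame(
  surface = c("TP53", "BRCA1", "EGFR", "KRAS", "MYC", "PTEN", "RB1", "BRAF",
              "ALK", "ERBB2"),
  id = paste0("GENE:", c(7157, 672, 1956, 3845, 4609, 5728, 5925, 673, 238,
                         2064)),
  type = "Gene", stringsAsFactors = FALSE)
SYNTH_GENES$name <- SYNTH_GENES$surface

SYNTH_DISEASES <- data.frame(
  surface = c("lung cancer", "breast cancer", "colorectal cancer", "melanoma",
              "glioblastoma", "prostate cancer", "ovarian cancer",
              "gastric cancer"),
  id = paste0("MESH:", c("D008175", "D001943", "D015179", "D008545", "D005909",
                         "D011471", "D010051", "D013274")),
  name = c("Lung Neoplasms", "Breast Neoplasms", "Colorectal Neoplasms",
           "Melanoma", "Glioblastoma", "Prostatic Neoplasms",
           "Ovarian Neoplasms", "Stomach Neoplasms"),
  type = "Disease", stringsAsFactors = FALSE)

# association sentence templates: pre <gene> mid <disease> post.
# Each template's trigger words drive the default aspect/keyword scorers to
# exactly the recorded predicate, so automatic annotation recovers every
# planted association.
GCA_TEMPLATES <- list(
  list(pre = "", mid = " is overexpressed and promotes ", post = ".",
       predicate = "oncogene"),
  list(pre = "", mid = " is downregulated and promotes ", post = ".",
       predicate = "tumor suppressor"),
  list(pre = "", mid = " is overexpressed and inhibits ", post = ".",
       predicate = "tumor suppressor"),
  list(pre = "", mid = " is associated with ", post = ".",
       predicate = "biomarker"))

GDA_TEMPLATES <- list(
  list(pre = "", mid = " mutations are frequent in ", post = ".",
       predicate = "Genomic Alterations"),
  list(pre = "", mid = " is a biomarker of ", post = ".",
       predicate = "Biomarker"),
  list(pre = "", mid = " therapy ameliorates ", post = ".",
       predicate = "Therapeutic"))

SYNTH_FILLERS <- c("Patients were enrolled in a multicenter study.",
                   "Samples were profiled by whole exome sequencing.",
                   "Survival outcomes were recorded over five years.",
                   "The cohort comprised adult patients.",
                   "Clinical variables were collected at baseline.")

predicate_concept_id <- function(task, predicate)
  paste0(task, ":", gsub(" ", "_", predicate))

#' Synthetic-study configuration
#'
#' Defaults mirror the shape of a two-round expert annotation study: ten
#' abstracts per task annotated by three annotators, with moderate
#' disagreement injected by the keep/swap probabilities.
#'
#' @param seed Mandatory integer seed; generation is a pure function of the
#'   configuration.
#' @param task `"GCA"` (sentence-level relationships) or `"GDA"`
#'   (document-level assertions).
#' @param n_documents Number of documents.
#' @param sentence_range Range (min, max) of sentences per document.
#' @param density Probability that a sentence carries a planted association.
#' @param n_annotators Number of annotators.
#' @param p_keep Probability an annotator retains a gold annotation.
#' @param q_swap Probability a kept relationship/assertion predicate is
#'   swapped to a random alternative.
#' @param adoption Probability an annotator adopts a consensus entry in
#'   round 2 of [gen_round_study()].
#' @return A config list.
#' @export
synth_config <- function(seed, task = c("GCA", "GDA"), n_documents = 10,
                         sentence_range = c(6, 10), density = 0.5,
                         n_annotators = 3, p_keep = 0.85, q_swap = 0.25,
                         adoption = 0.5) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  task <- match.arg(task)
  stopifnot(density >= 0, density <= 1, p_keep >= 0, p_keep <= 1,
            q_swap >= 0, q_swap <= 1, adoption >= 0, adoption <= 1,
            n_annotators >= 1, n_documents >= 1)
  list(seed = as.integer(seed), task = task, n_documents = n_documents,
       sentence_range = sentence_range, density = density,
       n_annotators = n_annotators, p_keep = p_keep, q_swap = q_swap,
       adoption = adoption)
}

# stage-scoped substreams: each generator stage reseeds from the base seed
# plus a fixed offset, so adding a stage never reshuffles earlier output
stage_seed <- function(config, offset) {
  set.seed((config$seed %% 1000000L) * 1000L + offset)
}

synth_vocab <- function(task) {
  if (task == "GCA") GCA_VOCAB else setdiff(GDA_VOCAB, "NA")
}

#' Generate a synthetic corpus with planted associations
#'
#' Builds a collection of template-assembled abstracts in which every planted
#' gene-disease association is expressed with in-lexicon surfaces and an
#' in-rule-table trigger inside a single sentence, plus the gene/disease
#' lexicons and a gold ledger of every planted mention, concept link,
#' association and document label. Each (gene, disease) pair is used at most
#' once per document.
#'
#' @param config From [synth_config()].
#' @return List with `collection`, `lexicons`, `ledger`, `config`. The
#'   collection has annotator members `ann1..annK` but no annotations yet.
#' @export
gen_corpus <- function(config) {
  stage_seed(config, 1L)
  task <- config$task
  templates <- if (task == "GCA") GCA_TEMPLATES else GDA_TEMPLATES
  annotators <- paste0("ann", seq_len(config$n_annotators))
  coll <- create_collection(paste0("synthetic-", tolower(task)),
                            "synthetic template corpus with planted associations",
                            creator = "creator", members = annotators,
                            labels = c("relevant", "not-relevant"))
  coll$fixed_time <- "2024-01-01T00:00:00Z"
  coll$rounds[[1]]$members <- coll$members
  register_concepts(coll, data.frame(identifier = SYNTH_GENES$id,
                                     name = SYNTH_GENES$name,
                                     type = SYNTH_GENES$type))
  register_concepts(coll, data.frame(identifier = SYNTH_DISEASES$id,
                                     name = SYNTH_DISEASES$name,
                                     type = SYNTH_DISEASES$type))
  register_concepts(coll, data.frame(
    identifier = predicate_concept_id(task, synth_vocab(task)),
    name = synth_vocab(task), type = "Predicate"))

  gold_mentions <- list(); gold_assoc <- list(); gold_labels <- list()
  n_pairs <- nrow(SYNTH_GENES) * nrow(SYNTH_DISEASES)
  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("doc-%03d", d)
    n_sent <- sample(config$sentence_range[1]:config$sentence_range[2], 1)
    is_assoc <- stats::runif(n_sent) < config$density
    pair_idx <- sample(n_pairs, sum(is_assoc))  # unique pairs per document
    sentences <- character(n_sent)
    offset <- 0L; k <- 0L
    for (s in seq_len(n_sent)) {
      if (is_assoc[[s]]) {
        k <- k + 1L
        gi <- ((pair_idx[[k]] - 1L) %% nrow(SYNTH_GENES)) + 1L
        di <- ((pair_idx[[k]] - 1L) %/% nrow(SYNTH_GENES)) + 1L
        tmpl <- templates[[sample(length(templates), 1)]]
        g <- SYNTH_GENES[gi, ]; dz <- SYNTH_DISEASES[di, ]
        sent <- paste0(tmpl$pre, g$surface, tmpl$mid, dz$surface, tmpl$post)
        g_start <- offset + nchar(tmpl$pre)
        dz_start <- g_start + nchar(g$surface) + nchar(tmpl$mid)
        gold_mentions[[length(gold_mentions) + 1L]] <- data.frame(
          document = doc_id, section = "abstract", start = g_start,
          end = g_start + nchar(g$surface), surface = g$surface,
          concept = g$id, stringsAsFactors = FALSE)
        gold_mentions[[length(gold_mentions) + 1L]] <- data.frame(
          document = doc_id, section = "abstract", start = dz_start,
          end = dz_start + nchar(dz$surface), surface = dz$surface,
          concept = dz$id, stringsAsFactors = FALSE)
        gold_assoc[[length(gold_assoc) + 1L]] <- data.frame(
          document = doc_id, subject = g$id, object = dz$id,
          predicate = predicate_concept_id(task, tmpl$predicate),
          sentence = s, g_start = g_start, g_end = g_start + nchar(g$surface),
          d_start = dz_start, d_end = dz_start + nchar(dz$surface),
          stringsAsFactors = FALSE)
      } else {
        sent <- SYNTH_FILLERS[[sample(length(SYNTH_FILLERS), 1)]]
      }
      sentences[[s]] <- sent
      offset <- offset + nchar(sent) + 1L   # single joining space
    }
    text <- paste(sentences, collapse = " ")
    add_document(coll, new_document(doc_id, c(abstract = text)))
    gold_labels[[length(gold_labels) + 1L]] <- data.frame(
      document = doc_id,
      label = if (any(is_assoc)) "relevant" else "not-relevant",
      stringsAsFactors = FALSE)
  }
  bind <- function(lst, proto) if (length(lst) == 0L) proto else do.call(rbind, lst)
  ledger <- list(
    mentions = bind(gold_mentions, data.frame(
      document = character(), section = character(), start = integer(),
      end = integer(), surface = character(), concept = character())),
    associations = bind(gold_assoc, data.frame(
      document = character(), subject = character(), object = character(),
      predicate = character(), sentence = integer(), g_start = integer(),
      g_end = integer(), d_start = integer(), d_end = integer())),
    labels = do.call(rbind, gold_labels),
    edits = list())
  lexicons <- list(gene = SYNTH_GENES[, c("surface", "id", "name", "type")],
                   disease = SYNTH_DISEASES[, c("surface", "id", "name", "type")])
  list(collection = coll, lexicons = lexicons, ledger = ledger, config = config)
}

annotator_mention <- function(coll, annotator, doc, section, start, end,
                              concept = NULL, round) {
  set <- get_set(coll, round, annotator, doc)
  key <- mention_key(doc, section, start, end)
  for (m in set$mentions)
    if (identical(mention_key_of(m), key)) {
      if (!is.null(concept) && !concept %in% m$concepts)
        link_concept(coll, annotator, doc, m$id, concept, round = round)
      return(m$id)
    }
  m <- create_mention(coll, annotator, doc, section, start, end,
                      concepts = concept %||% character(0), round = round)
  m$id
}

#' Generate per-annotator annotation sets from the gold ledger
#'
#' Each annotator keeps each gold annotation with probability `p_keep` and,
#' for kept associations, swaps the predicate to a random alternative with
#' probability `q_swap`. Applied edits (drops and swaps) are appended to the
#' ledger so every expected agreement statistic is recomputable.
#'
#' @param corpus From [gen_corpus()].
#' @param round Round to populate.
#' @return The corpus, with `ledger$edits` filled in (one entry per
#'   annotator: data frames `kept_mentions`, `kept_assoc` with `swapped_to`).
#' @export
gen_annotator_sets <- function(corpus, round = 1L) {
  config <- corpus$config
  coll <- corpus$collection
  led <- corpus$ledger
  task <- config$task
  vocab_ids <- predicate_concept_id(task, synth_vocab(task))
  for (j in seq_len(config$n_annotators)) {
    stage_seed(config, 100L + j)
    annotator <- paste0("ann", j)
    gm <- led$mentions
    keep_m <- stats::runif(nrow(gm)) < config$p_keep
    for (i in which(keep_m))
      annotator_mention(coll, annotator, gm$document[[i]], gm$section[[i]],
                        gm$start[[i]], gm$end[[i]], gm$concept[[i]], round)
    ga <- led$associations
    keep_a <- stats::runif(nrow(ga)) < config$p_keep
    swap_a <- stats::runif(nrow(ga)) < config$q_swap
    swapped_to <- rep(NA_character_, nrow(ga))
    for (i in which(keep_a)) {
      pred <- ga$predicate[[i]]
      if (swap_a[[i]]) {
        alternatives <- setdiff(vocab_ids, pred)
        pred <- alternatives[[sample(length(alternatives), 1)]]
        swapped_to[[i]] <- pred
      }
      if (task == "GCA") {
        sid <- annotator_mention(coll, annotator, ga$document[[i]], "abstract",
                                 ga$g_start[[i]], ga$g_end[[i]],
                                 ga$subject[[i]], round)
        oid <- annotator_mention(coll, annotator, ga$document[[i]], "abstract",
                                 ga$d_start[[i]], ga$d_end[[i]],
                                 ga$object[[i]], round)
        create_relationship(coll, annotator, ga$document[[i]],
                            comp_mention(sid), comp_concept(pred),
                            comp_mention(oid), round = round)
      } else {
        create_assertion(coll, annotator, ga$document[[i]], ga$subject[[i]],
                         pred, ga$object[[i]], round = round)
      }
    }
    gl <- led$labels
    keep_l <- stats::runif(nrow(gl)) < config$p_keep
    for (i in which(keep_l))
      set_labels(coll, annotator, gl$document[[i]], gl$label[[i]], round = round)
    led$edits[[annotator]] <- list(
      kept_mentions = gm[keep_m, , drop = FALSE],
      kept_assoc = cbind(ga[, , drop = FALSE],
                         kept = keep_a, swapped_to = swapped_to),
      kept_labels = gl[keep_l, , drop = FALSE])
  }
  corpus$ledger <- led
  corpus
}

consensus_unitize_items <- function(coll, document_id, type, round) {
  cons <- majority_vote(coll, document_id, type, round)
  payloads <- attr(cons, "payloads")
  vapply(seq_along(payloads), function(i) {
    p <- payloads[[i]]
    if (type == "mention") mention_key_of(p)
    else if (type == "concept") paste(mention_key_of(p$mention), p$concept,
                                      sep = .SEP)
    else if (type == "relationship") {
      ck <- function(comp) {
        if (comp$kind == "mention") paste0("m", .SEP, mention_key_of(comp$mention))
        else if (comp$kind == "concept") paste0("c", .SEP, comp$ref)
        else paste0("t", .SEP, tolower(trimws(comp$ref)))
      }
      paste(document_id, paste(ck(p$subject), ck(p$object), sep = .SEP),
            sep = .SEP)
    }
    else if (type == "assertion") paste(document_id, p$subject, p$object,
                                        sep = .SEP)
    else paste(document_id, p$label, sep = .SEP)
  }, character(1))
}

adopt_entry <- function(coll, annotator, document_id, type, payload, round) {
  set <- get_set(coll, round, annotator, document_id)
  if (type == "mention") {
    annotator_mention(coll, annotator, document_id, payload$section,
                      payload$start, payload$end, round = round)
  } else if (type == "concept") {
    annotator_mention(coll, annotator, document_id, payload$mention$section,
                      payload$mention$start, payload$mention$end,
                      payload$concept, round)
  } else if (type == "relationship") {
    pair_of <- function(r, s) rel_pair_key_of(r, s)
    # pair key of the consensus payload, built from its resolved components
    ck <- function(comp) {
      if (comp$kind == "mention") paste0("m", .SEP, mention_key_of(comp$mention))
      else if (comp$kind == "concept") paste0("c", .SEP, comp$ref)
      else paste0("t", .SEP, tolower(trimws(comp$ref)))
    }
    target_pair <- paste(ck(payload$subject), ck(payload$object), sep = .SEP)
    for (rid in names(set$relationships)) {
      r <- set$relationships[[rid]]
      if (identical(pair_of(r, set), target_pair)) {
        if (identical(comp_key(r$predicate, set), ck(payload$predicate)))
          return(invisible(NULL))
        delete_annotation(coll, annotator, document_id, rid, round)
        set <- get_set(coll, round, annotator, document_id)
      }
    }
    mention_ref <- function(comp) {
      if (comp$kind != "mention") return(comp_concept(comp$ref))
      m <- comp$mention
      comp_mention(annotator_mention(coll, annotator, document_id, m$section,
                                     m$start, m$end, round = round))
    }
    pred <- if (payload$predicate$kind == "concept")
      comp_concept(payload$predicate$ref)
    else if (payload$predicate$kind == "text") comp_text(payload$predicate$ref)
    else mention_ref(payload$predicate)
    suppressWarnings(create_relationship(coll, annotator, document_id,
                                         mention_ref(payload$subject), pred,
                                         mention_ref(payload$object),
                                         round = round))
  } else if (type == "assertion") {
    for (aid in names(set$assertions)) {
      a <- set$assertions[[aid]]
      if (identical(a$subject, payload$subject) &&
          identical(a$object, payload$object)) {
        if (identical(a$predicate, payload$predicate)) return(invisible(NULL))
        delete_annotation(coll, annotator, document_id, aid, round)
      }
    }
    create_assertion(coll, annotator, document_id, payload$subject,
                     payload$predicate, payload$object, round = round)
  } else if (type == "label") {
    set <- get_set(coll, round, annotator, document_id)
    have <- vapply(set$labels, function(l) l$label, character(1))
    if (!payload$label %in% have)
      set_labels(coll, annotator, document_id, c(have, payload$label),
                 round = round)
  }
  invisible(NULL)
}

#' Generate a two-round synthetic annotation study
#'
#' Reproduces the workflow shape of a collaborative annotation study: round 1
#' is the automatic baseline (the machine annotator run on every document)
#' plus per-annotator edits (keep/swap, as in [gen_annotator_sets()]); round
#' 2 duplicates round 1, after which each annotator adopts each
#' strict-majority consensus entry with probability `adoption` (missing
#' entries are added; a conflicting predicate on the same pair is replaced).
#'
#' @param config From [synth_config()].
#' @return List with `collection`, `lexicons`, `ledger`, `config`, and
#'   `consensus_items`: the unitization item keys covered by the round-1
#'   consensus, per annotation type (for agreement evaluation restricted to
#'   consensus-covered items).
#' @export
gen_round_study <- function(config) {
  corpus <- gen_corpus(config)
  coll <- corpus$collection
  for (doc in names(coll$documents))
    run_autotron(coll, doc, task = config$task, lexicons = corpus$lexicons,
                 round = 1L)
  corpus <- gen_annotator_sets(corpus, round = 1L)
  annotators <- paste0("ann", seq_len(config$n_annotators))
  cons <- list(); items <- list()
  for (type in ANNOTATION_TYPES) {
    cons[[type]] <- list()
    keys <- character(0)
    for (doc in names(coll$documents)) {
      cv <- majority_vote(coll, doc, type, round = 1L)
      cons[[type]][[doc]] <- cv
      keys <- c(keys, consensus_unitize_items(coll, doc, type, round = 1L))
    }
    items[[type]] <- keys
  }
  new_round(coll, annotators)
  stage_seed(config, 900L)
  for (j in seq_along(annotators)) {
    for (type in ANNOTATION_TYPES) {
      for (doc in names(coll$documents)) {
        payloads <- attr(cons[[type]][[doc]], "payloads")
        for (p in payloads) {
          if (stats::runif(1) < config$adoption)
            adopt_entry(coll, annotators[[j]], doc, type, p, round = 2L)
        }
      }
    }
  }
  corpus$consensus_items <- items
  corpus
}
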