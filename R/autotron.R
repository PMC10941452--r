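# Pluggable automatic-annotation pipeline: lexicon entity linking, rule-based
# sentence splitting, multi-instance bag construction, and pluggable
# predicate scorers with deterministic keyword-rule defaults for the two
# bundled tasks:
#   GDA (gene-disease association)            -> document-level assertions,
#       predicate vocabulary {Therapeutic, Biomarker, Genomic Alterations, NA}
#   GCA (gene expression-cancer association)  -> sentence-level relationships,
#       predicate vocabulary {biomarker, tumor suppressor, oncogene}

GDA_VOCAB <- c("Therapeutic", "Biomarker", "Genomic Alterations", "NA")
GCA_VOCAB <- c("biomarker", "tumor suppressor", "oncogene")

#' Read an entity lexicon
#'
#' A lexicon maps surface strings to concepts of a single type (one lexicon
#' per type; ambiguity across types is handled by separate lexicons). CSV
#' columns: `surface`, `id`, `name`, `type`.
#'
#' @param path CSV file path.
#' @return Lexicon data frame.
#' @export
read_lexicon <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  as_lexicon(df)
}

as_lexicon <- function(df) {
  need <- c("surface", "id", "name", "type")
  if (!all(need %in% names(df))) abort_domain("lexicon needs columns %s",
                                              paste(need, collapse = ", "))
  if (any(!nzchar(df$surface))) abort_domain("lexicon surfaces must be non-empty")
  if (anyDuplicated(df$surface)) abort_domain("one concept per surface per lexicon")
  df[, need]
}

#' Dictionary entity linking
#'
#' Deterministic left-to-right longest-match scan of each lexicon over each
#' text field: at every position the longest lexicon surface anchored there
#' wins; matches within one lexicon never overlap (the scan resumes at match
#' end); matches from different lexicons may overlap.
#'
#' @param sections Named character vector of text fields.
#' @param lexicons A lexicon data frame or list of them (see [read_lexicon()]).
#' @param ignore_case Case-fold before matching.
#' @return Data frame with columns `section`, `start`, `end` (0-based
#'   half-open), `surface`, `id`, `name`, `type`.
#' @export
link_entities <- function(sections, lexicons, ignore_case = FALSE) {
  if (is.data.frame(lexicons)) lexicons <- list(lexicons)
  if (length(lexicons) == 0L) abort_domain("at least one lexicon required")
  out <- list()
  for (lex in lexicons) {
    lex <- as_lexicon(lex)
    surfaces <- lex$surface[order(-nchar(lex$surface), lex$surface)]
    pattern <- paste(escape_regex(surfaces), collapse = "|")
    for (section in names(sections)) {
      text <- unname(sections[[section]])
      if (!nzchar(text)) next
      hits <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)[[1]]
      if (hits[1] == -1L) next
      lens <- attr(hits, "match.length")
      for (i in seq_along(hits)) {
        start <- as.integer(hits[[i]]) - 1L
        end <- start + lens[[i]]
        surf <- slice_text(text, start, end)
        j <- if (ignore_case) match(tolower(surf), tolower(lex$surface))
             else match(surf, lex$surface)
        out[[length(out) + 1L]] <- data.frame(
          section = section, start = start, end = end, surface = surf,
          id = lex$id[[j]], name = lex$name[[j]], type = lex$type[[j]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(section = character(), start = integer(), end = integer(),
                      surface = character(), id = character(), name = character(),
                      type = character(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$section, df$start, df$end, df$id), , drop = FALSE]
}

DEFAULT_ABBREVIATIONS <- c("e.g.", "i.e.", "al.", "Fig.", "cf.", "vs.", "Dr.",
                           "No.", "approx.")

#' Rule-based sentence splitting
#'
#' Splits on sentence-final punctuation (`.?!`) followed by whitespace and an
#' uppercase letter or digit; a configurable abbreviation list suppresses
#' splits after tokens such as `e.g.`. Spans are 0-based half-open and tile
#' the text: concatenating the spans and the inter-span whitespace gaps
#' reproduces the input.
#'
#' @param text A string.
#' @param abbreviations Tokens (ending in a period) after which no split
#'   occurs.
#' @return Data frame with columns `start`, `end`, `text`.
#' @export
split_sentences <- function(text, abbreviations = DEFAULT_ABBREVIATIONS) {
  empty <- data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (!is_string(text) || !nzchar(text)) return(empty)
  n <- nchar(text)
  m <- gregexpr("[.?!][[:space:]]+(?=[A-Z0-9])", text, perl = TRUE)[[1]]
  breaks <- integer(0)   # 0-based starts of follow-on sentences
  ends <- integer(0)     # 0-based exclusive ends of the sentences they close
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      p <- as.integer(m[[i]])          # 1-based position of the punctuation
      before <- substr(text, 1, p)
      token <- sub("^.*[[:space:]]", "", before)
      if (token %in% abbreviations) next
      ends <- c(ends, p)
      breaks <- c(breaks, p - 1L + lens[[i]])
    }
  }
  first_non_space <- regexpr("[^[:space:]]", text)
  start0 <- if (first_non_space == -1L) 0L else as.integer(first_non_space) - 1L
  starts <- c(start0, breaks)
  ends <- c(ends, n)
  data.frame(start = starts, end = ends,
             text = vapply(seq_along(starts),
                           function(i) slice_text(text, starts[[i]], ends[[i]]),
                           character(1)),
             stringsAsFactors = FALSE)
}

#' Multi-instance bags from entity links
#'
#' Under multi-instance learning, sentences are divided into bags based on
#' pairs of concepts: for every pair (concept of `type_a`, concept of
#' `type_b`), the bag collects every sentence containing at least one mention
#' of each; pairs with no co-occurring sentence produce no bag.
#'
#' @param links Entity-link data frame (one section) from [link_entities()].
#' @param sentences Sentence spans from [split_sentences()] over the same
#'   section text.
#' @param type_a,type_b Concept types of the pair members (e.g. "Gene",
#'   "Disease").
#' @return List of bags; each bag is a list with `pair` (ids), `a`, `b`
#'   (concept records) and `sentences` (data frame of sentence index and the
#'   two mention spans).
#' @export
build_bags <- function(links, sentences, type_a, type_b) {
  if (nrow(links) == 0L || nrow(sentences) == 0L) return(list())
  in_sentence <- function(row, s)
    row$start >= sentences$start[[s]] && row$end <= sentences$end[[s]]
  links_a <- links[links$type == type_a, , drop = FALSE]
  links_b <- links[links$type == type_b, , drop = FALSE]
  bags <- list()
  for (ida in sort(unique(links_a$id))) {
    for (idb in sort(unique(links_b$id))) {
      rows <- list()
      for (s in seq_len(nrow(sentences))) {
        ai <- which(vapply(seq_len(nrow(links_a)), function(i)
          links_a$id[[i]] == ida && in_sentence(links_a[i, ], s), logical(1)))
        bi <- which(vapply(seq_len(nrow(links_b)), function(i)
          links_b$id[[i]] == idb && in_sentence(links_b[i, ], s), logical(1)))
        if (length(ai) > 0L && length(bi) > 0L) {
          rows[[length(rows) + 1L]] <- data.frame(
            sentence = s,
            a_start = links_a$start[[ai[[1]]]], a_end = links_a$end[[ai[[1]]]],
            b_start = links_b$start[[bi[[1]]]], b_end = links_b$end[[bi[[1]]]])
        }
      }
      if (length(rows) > 0L) {
        a_row <- links_a[match(ida, links_a$id), ]
        b_row <- links_b[match(idb, links_b$id), ]
        bags[[length(bags) + 1L]] <- list(
          pair = c(ida, idb),
          a = list(id = ida, name = a_row$name, type = a_row$type),
          b = list(id = idb, name = b_row$name, type = b_row$type),
          sentences = do.call(rbind, rows))
      }
    }
  }
  bags
}

# ---- scorers ----------------------------------------------------------------

#' Default keyword scorer for GDA predicates
#'
#' Deterministic stand-in for a trained bag-level relation extractor: scores
#' each sentence 1 for a predicate whose trigger keyword occurs, and scores
#' `NA` 1 when no trigger fires (`NA` means "no association" and suppresses
#' output downstream).
#'
#' @param triggers Named list mapping each non-NA GDA predicate to a character
#'   vector of lower-case trigger substrings.
#' @return A scorer: `function(sentence_text) -> named numeric` over the GDA
#'   vocabulary, values in `[0, 1]`.
#' @export
gda_keyword_scorer <- function(triggers = list(
    "Therapeutic" = c("therapy", "therapeutic", "treats", "ameliorates"),
    "Biomarker" = c("biomarker", "marker of"),
    "Genomic Alterations" = c("mutation", "mutations", "amplification",
                              "deletion", "translocation"))) {
  force(triggers)
  function(sentence_text) {
    low <- tolower(sentence_text)
    scores <- stats::setNames(numeric(length(GDA_VOCAB)), GDA_VOCAB)
    for (pred in names(triggers))
      if (any(vapply(triggers[[pred]], function(t) grepl(t, low, fixed = TRUE),
                     logical(1))))
        scores[[pred]] <- 1
    if (sum(scores) == 0) scores[["NA"]] <- 1
    scores
  }
}

#' Default keyword scorers for the three GCA aspects
#'
#' The gene-cancer association is inferred from three per-sentence aspects:
#' CGE (change of gene expression: increased / decreased / unchanged), CCS
#' (change of cancer status: progression / regression / unchanged) and GCI
#' (gene-cancer interaction: observed / none). Each default scorer fires on
#' lower-cased trigger substrings.
#'
#' @return Named list of three scorer functions, each
#'   `function(sentence_text) -> named numeric` over the aspect's values.
#' @export
gca_aspect_scorers <- function() {
  keyword_aspect <- function(value_triggers, fallback) {
    force(value_triggers); force(fallback)
    function(sentence_text) {
      low <- tolower(sentence_text)
      vals <- c(names(value_triggers), fallback)
      scores <- stats::setNames(numeric(length(vals)), vals)
      for (v in names(value_triggers))
        if (any(vapply(value_triggers[[v]], function(t) grepl(t, low, fixed = TRUE),
                       logical(1))))
          scores[[v]] <- 1
      if (sum(scores) == 0) scores[[fallback]] <- 1
      scores
    }
  }
  list(
    cge = keyword_aspect(list(
      increased = c("overexpressed", "upregulated", "up-regulated", "elevated"),
      decreased = c("downregulated", "down-regulated", "silenced", "reduced")),
      fallback = "unchanged"),
    ccs = keyword_aspect(list(
      progression = c("promotes", "accelerates", "drives"),
      regression = c("inhibits", "suppresses", "impairs")),
      fallback = "unchanged"),
    gci = keyword_aspect(list(
      observed = c("promotes", "accelerates", "drives", "inhibits",
                   "suppresses", "impairs", "associated with",
                   "correlates with")),
      fallback = "none")
  )
}

#' Default GCA inference rule table
#'
#' Maps (CGE, CCS, GCI) aspect-value triples to a GCA predicate. Minimal
#' default mapping: with an observed interaction, concordant expression
#' change and disease progression imply oncogene (decreased expression with
#' progression, or increased with regression, implies tumor suppressor); an
#' association without an expression change is a biomarker. Triples with
#' `gci = none` map to no predicate (the sentence is skipped).
#'
#' @return Data frame with columns `cge`, `ccs`, `gci`, `predicate`.
#' @export
gca_default_rules <- function() {
  rules <- rbind(
    c("increased", "progression", "observed", "oncogene"),
    c("decreased", "regression",  "observed", "oncogene"),
    c("decreased", "progression", "observed", "tumor suppressor"),
    c("increased", "regression",  "observed", "tumor suppressor"),
    c("unchanged", "progression", "observed", "biomarker"),
    c("unchanged", "regression",  "observed", "biomarker"),
    c("unchanged", "unchanged",   "observed", "biomarker"),
    c("increased", "unchanged",   "observed", "biomarker"),
    c("decreased", "unchanged",   "observed", "biomarker"))
  stats::setNames(as.data.frame(rules, stringsAsFactors = FALSE),
                  c("cge", "ccs", "gci", "predicate"))
}

#' Read a GCA rule table from CSV
#' @param path CSV with columns `cge`, `ccs`, `gci`, `predicate`.
#' @export
read_gca_rules <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  need <- c("cge", "ccs", "gci", "predicate")
  if (!all(need %in% names(df))) abort_domain("rule table needs columns %s",
                                              paste(need, collapse = ", "))
  df[, need]
}

auto_component <- function(id, name, type, positions = NULL) {
  list(id = id, name = name, type = type, positions = positions)
}

validate_auto_annotation <- function(ann) {
  for (role in c("subject", "predicate", "object")) {
    comp <- ann[[role]]
    ok <- is.list(comp) &&
      all(vapply(c("id", "name", "type"),
                 function(f) is_string(comp[[f]]) && nzchar(comp[[f]]),
                 logical(1)))
    if (!ok)
      abort_domain("automatic annotation contract violation: %s lacks concept id/name/type",
                   role)
  }
  if (!ann$kind %in% c("relationship", "assertion"))
    abort_domain("automatic annotation kind must be relationship or assertion")
  invisible(ann)
}

#' Predict gene-disease associations at bag level
#'
#' For each bag, the per-sentence predicate scores are averaged (the
#' score-level analogue of averaging sentence representations) and the
#' arg-max predicate is emitted as a document-level assertion. Ties break
#' deterministically by the fixed vocabulary order (and are reported in the
#' `ties` attribute). The `NA` predicate denotes "no association" and
#' suppresses the bag's output. Assertions carry no mention positions unless
#' `ground = TRUE`.
#'
#' @param bags Bags from [build_bags()] (gene as pair member a, disease as b).
#' @param sentences Sentence spans (with `text`) the bags index into.
#' @param scorer A GDA scorer, e.g. [gda_keyword_scorer()].
#' @param ground Attach the first mention positions to subject/object.
#' @return List of automatic annotations (kind `"assertion"`).
#' @export
predict_gda <- function(bags, sentences, scorer = gda_keyword_scorer(),
                        ground = FALSE) {
  out <- list(); ties <- 0L
  for (bag in bags) {
    score_mat <- vapply(bag$sentences$sentence, function(s)
      score_vector(scorer(sentences$text[[s]]), GDA_VOCAB), numeric(length(GDA_VOCAB)))
    avg <- rowMeans(matrix(score_mat, nrow = length(GDA_VOCAB),
                           dimnames = list(GDA_VOCAB, NULL)))
    best <- GDA_VOCAB[avg == max(avg)]
    if (length(best) > 1L) ties <- ties + 1L
    pred <- best[[1]]            # fixed vocabulary order breaks ties
    if (pred == "NA") next
    positions <- function(prefix) {
      if (!ground) return(NULL)
      row <- bag$sentences[1, ]
      list(list(section = attr(sentences, "section") %||% "text",
                start = row[[paste0(prefix, "_start")]],
                end = row[[paste0(prefix, "_end")]]))
    }
    ann <- list(kind = "assertion",
                subject = auto_component(bag$a$id, bag$a$name, bag$a$type,
                                         positions("a")),
                predicate = auto_component(paste0("GDA:", gsub(" ", "_", pred)),
                                           pred, "Predicate"),
                object = auto_component(bag$b$id, bag$b$name, bag$b$type,
                                        positions("b")),
                score = max(avg))
    out[[length(out) + 1L]] <- validate_auto_annotation(ann)
  }
  attr(out, "ties") <- ties
  out
}

score_vector <- function(scores, vocab) {
  v <- stats::setNames(numeric(length(vocab)), vocab)
  common <- intersect(names(scores), vocab)
  v[common] <- scores[common]
  if (any(v < 0 | v > 1)) abort_domain("scorer values must lie in [0, 1]")
  v
}

#' Predict gene expression-cancer associations at sentence level
#'
#' For every sentence containing at least one gene and one cancer mention,
#' each aspect scorer's arg-max value is computed and the (CGE, CCS, GCI)
#' triple is looked up in the rule table; a hit emits one relationship per
#' (gene mention, cancer mention) pair with the predicate concept and both
#' mention positions; a miss skips the sentence (counted in the `skipped`
#' attribute).
#'
#' @param links Entity links for the section (gene and cancer lexicons).
#' @param sentences Sentence spans with `text`.
#' @param section Section name the offsets refer to.
#' @param aspect_scorers Named list (cge, ccs, gci) of scorers, see
#'   [gca_aspect_scorers()].
#' @param rules Rule table, see [gca_default_rules()].
#' @param gene_type,cancer_type Concept types of subject and object mentions.
#' @return List of automatic annotations (kind `"relationship"`).
#' @export
predict_gca <- function(links, sentences, section = "text",
                        aspect_scorers = gca_aspect_scorers(),
                        rules = gca_default_rules(),
                        gene_type = "Gene", cancer_type = "Disease") {
  out <- list(); skipped <- 0L
  argmax <- function(scores) names(scores)[which.max(scores)]
  for (s in seq_len(nrow(sentences))) {
    inside <- links$start >= sentences$start[[s]] & links$end <= sentences$end[[s]]
    genes <- links[inside & links$type == gene_type, , drop = FALSE]
    cancers <- links[inside & links$type == cancer_type, , drop = FALSE]
    if (nrow(genes) == 0L || nrow(cancers) == 0L) next
    stext <- sentences$text[[s]]
    triple <- vapply(c("cge", "ccs", "gci"), function(a)
      argmax(aspect_scorers[[a]](stext)), character(1))
    hit <- which(rules$cge == triple[["cge"]] & rules$ccs == triple[["ccs"]] &
                   rules$gci == triple[["gci"]])
    if (length(hit) == 0L) { skipped <- skipped + 1L; next }
    pred <- rules$predicate[[hit[[1]]]]
    for (gi in seq_len(nrow(genes))) {
      for (ci in seq_len(nrow(cancers))) {
        g <- genes[gi, ]; d <- cancers[ci, ]
        ann <- list(kind = "relationship",
          subject = auto_component(g$id, g$name, g$type,
            list(list(section = section, start = g$start, end = g$end))),
          predicate = auto_component(paste0("GCA:", gsub(" ", "_", pred)),
                                     pred, "Predicate"),
          object = auto_component(d$id, d$name, d$type,
            list(list(section = section, start = d$start, end = d$end))),
          score = 1)
        out[[length(out) + 1L]] <- validate_auto_annotation(ann)
      }
    }
  }
  attr(out, "skipped") <- skipped
  out
}

#' Run automatic annotation on a document
#'
#' Executes the selected task's pipeline (entity linking over the supplied
#' lexicons, sentence splitting, bag construction for GDA, rule lookup for
#' GCA, or any user-supplied plugins honouring the same scorer contract) and
#' stores the outputs in the collection under the reserved machine annotator
#' id `"AutoTron"`, replacing any previous automatic set for the document
#' (idempotent refresh). The stored set is the baseline for provenance diffs
#' and the starting point users edit.
#'
#' @param coll A collection.
#' @param document_id Document to annotate.
#' @param task `"GDA"` or `"GCA"`.
#' @param lexicons List of lexicons (gene, disease/cancer).
#' @param plugins Optional overrides: `gda_scorer`, `aspect_scorers`, `rules`,
#'   `abbreviations`.
#' @param round Round index.
#' @return Number of annotations stored.
#' @export
run_autotron <- function(coll, document_id, task = c("GDA", "GCA"), lexicons,
                         plugins = list(), round = current_round(coll)) {
  task <- match.arg(task)
  round <- check_round(coll, round)
  doc <- get_document(coll, document_id)
  if (all(!nzchar(doc$sections)))
    abort_domain("document '%s' has no non-empty text field", document_id)
  put_set(coll, round, MACHINE_ANNOTATOR, document_id, empty_set())
  anns <- list()
  per_section <- list()
  for (section in names(doc$sections)) {
    text <- unname(doc$sections[[section]])
    if (!nzchar(text)) next
    links <- link_entities(stats::setNames(c(text), section), lexicons)
    sentences <- split_sentences(text, plugins$abbreviations %||%
                                   DEFAULT_ABBREVIATIONS)
    if (task == "GDA") {
      bags <- build_bags(links, sentences, "Gene", "Disease")
      got <- predict_gda(bags, sentences,
                         scorer = plugins$gda_scorer %||% gda_keyword_scorer())
    } else {
      got <- predict_gca(links, sentences, section = section,
                         aspect_scorers = plugins$aspect_scorers %||%
                           gca_aspect_scorers(),
                         rules = plugins$rules %||% gca_default_rules())
    }
    anns <- c(anns, got)
  }
  stored <- 0L
  for (ann in anns) {
    validate_auto_annotation(ann)
    for (role in c("subject", "predicate", "object")) {
      comp <- ann[[role]]
      register_concepts(coll, data.frame(identifier = comp$id, name = comp$name,
                                         type = comp$type, description = "",
                                         stringsAsFactors = FALSE))
    }
    if (ann$kind == "assertion") {
      create_assertion(coll, MACHINE_ANNOTATOR, document_id, ann$subject$id,
                       ann$predicate$id, ann$object$id, round = round)
    } else {
      mention_of <- function(comp) {
        pos <- comp$positions[[1]]
        set <- get_set(coll, round, MACHINE_ANNOTATOR, document_id)
        key <- mention_key(document_id, pos$section, pos$start, pos$end)
        for (m in set$mentions)
          if (identical(mention_key_of(m), key)) {
            link_concept(coll, MACHINE_ANNOTATOR, document_id, m$id, comp$id,
                         round = round)
            return(m$id)
          }
        m <- create_mention(coll, MACHINE_ANNOTATOR, document_id, pos$section,
                            pos$start, pos$end, concepts = comp$id, round = round)
        m$id
      }
      sid <- mention_of(ann$subject)
      oid <- mention_of(ann$object)
      create_relationship(coll, MACHINE_ANNOTATOR, document_id,
                          subject = comp_mention(sid),
                          predicate = comp_concept(ann$predicate$id),
                          object = comp_mention(oid),
                          round = round)
    }
    stored <- stored + 1L
  }
  stored
}
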