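gene_lex <- data.frame(surface = "TP53", id = "GENE:7157", name = "TP53",
                       type = "Gene", stringsAsFactors = FALSE)
disease_lex <- data.frame(surface = c("lung cancer", "cancer"),
                          id = c("MESH:D008175", "MESH:D009369"),
                          name = c("Lung Neoplasms", "Neoplasms"),
                          type = "Disease", stringsAsFactors = FALSE)

test_that("entity linking finds exact non-overlapping longest matches", {
  links <- link_entities(c(text = "TP53 suppresses lung cancer."),
                         list(gene_lex, disease_lex))
  expect_equal(nrow(links), 2)
  expect_equal(links$start, c(0L, 16L))
  expect_equal(links$end, c(4L, 27L))
  expect_equal(links$id, c("GENE:7157", "MESH:D008175"))
  # longest match wins within a lexicon
  links2 <- link_entities(c(text = "breast cancer"),
                          data.frame(surface = c("breast cancer", "cancer"),
                                     id = c("D1", "D2"), name = c("a", "b"),
                                     type = "Disease"))
  expect_equal(links2$surface, "breast cancer")
  expect_equal(nrow(link_entities(c(text = ""), list(gene_lex))), 0)
  # case folding is opt-in
  expect_equal(nrow(link_entities(c(text = "tp53"), list(gene_lex))), 0)
  expect_equal(nrow(link_entities(c(text = "tp53"), list(gene_lex),
                                  ignore_case = TRUE)), 1)
})

test_that("entity links match a brute-force substring scan", {
  set.seed(31)
  for (i in 1:20) {
    words <- sample(c("TP53", "foo", "bar", "lung", "cancer", "lung cancer"),
                    30, replace = TRUE)
    text <- paste(words, collapse = " ")
    links <- link_entities(c(text = text), list(gene_lex))
    expect_equal(nrow(links), count_occurrences(text, "TP53"))
    for (j in seq_len(nrow(links)))
      expect_equal(substr(text, links$start[[j]] + 1, links$end[[j]]), "TP53")
  }
})

test_that("sentence splitting respects abbreviations and tiles the text", {
  expect_equal(nrow(split_sentences("A. B.")), 2)
  expect_equal(nrow(split_sentences("")), 0)
  s <- split_sentences("We use e.g. TP53 here. Next sentence.")
  expect_equal(nrow(s), 2)  # no split inside the configured "e.g."
  expect_equal(s$text[[2]], "Next sentence.")
  # spans reproduce the original text slices
  text <- "First result. Second result! Third?  Fourth one."
  s <- split_sentences(text)
  for (i in seq_len(nrow(s)))
    expect_equal(substr(text, s$start[[i]] + 1, s$end[[i]]), s$text[[i]])
  # no split when the next character is lower case
  expect_equal(nrow(split_sentences("approx. half of cases")), 1)
})

test_that("bag construction groups co-occurring pairs by sentence", {
  text <- "TP53 alters lung cancer. TP53 modulates lung cancer."
  links <- link_entities(c(text = text), list(gene_lex, disease_lex))
  sents <- split_sentences(text)
  bags <- build_bags(links, sents, "Gene", "Disease")
  expect_length(bags, 1)
  expect_equal(nrow(bags[[1]]$sentences), 2)
  # entities in different sentences produce no bag
  text2 <- "TP53 was assayed. Then lung cancer developed."
  bags2 <- build_bags(link_entities(c(text = text2), list(gene_lex, disease_lex)),
                      split_sentences(text2), "Gene", "Disease")
  expect_length(bags2, 0)
})

test_that("bag construction equals brute-force pair-by-sentence enumeration", {
  set.seed(55)
  genes <- data.frame(surface = paste0("GN", 1:5),
                      id = paste0("G:", 1:5), name = paste0("GN", 1:5),
                      type = "Gene")
  diseases <- data.frame(surface = paste0("DX", 1:5),
                         id = paste0("D:", 1:5), name = paste0("DX", 1:5),
                         type = "Disease")
  for (trial in 1:10) {
    sents <- vapply(1:20, function(i) {
      toks <- sample(c(genes$surface, diseases$surface, "filler"), 4,
                     replace = TRUE)
      paste0(paste(toks, collapse = " "), ".")
    }, character(1))
    text <- paste(sents, collapse = " ")
    links <- link_entities(c(text = text), list(genes, diseases))
    spans <- split_sentences(text)
    bags <- build_bags(links, spans, "Gene", "Disease")
    # brute force over all (pair, sentence) containment checks
    expected <- list()
    for (g in genes$id) for (d in diseases$id) {
      hits <- vapply(seq_len(nrow(spans)), function(s) {
        inside <- links$start >= spans$start[[s]] & links$end <= spans$end[[s]]
        any(links$id[inside] == g) && any(links$id[inside] == d)
      }, logical(1))
      if (any(hits)) expected[[paste(g, d)]] <- which(hits)
    }
    got <- lapply(bags, function(b) b$sentences$sentence)
    names(got) <- vapply(bags, function(b) paste(b$pair[1], b$pair[2]),
                         character(1))
    expect_equal(got[order(names(got))], expected[order(names(expected))])
  }
})

test_that("bag-level GDA prediction averages scores and suppresses NA", {
  sents <- data.frame(start = c(0, 10), end = c(9, 19),
                      text = c("s1", "s2"), stringsAsFactors = FALSE)
  bag <- list(pair = c("G:1", "D:1"),
              a = list(id = "G:1", name = "g", type = "Gene"),
              b = list(id = "D:1", name = "d", type = "Disease"),
              sentences = data.frame(sentence = c(1, 2), a_start = 0, a_end = 1,
                                     b_start = 2, b_end = 3))
  scorer <- function(text) c("Biomarker" = if (text == "s1") 0.8 else 0.6)
  out <- predict_gda(list(bag), sents, scorer)
  expect_length(out, 1)
  expect_equal(out[[1]]$predicate$name, "Biomarker")
  expect_equal(out[[1]]$score, 0.7)
  expect_null(out[[1]]$subject$positions)   # assertions are ungrounded
  # an all-NA bag emits nothing
  out2 <- predict_gda(list(bag), sents, function(text) c("NA" = 1))
  expect_length(out2, 0)
  # ties break by the fixed vocabulary order and are counted
  out3 <- predict_gda(list(bag), sents,
                      function(text) c(Therapeutic = 0.5, Biomarker = 0.5))
  expect_equal(out3[[1]]$predicate$name, "Therapeutic")
  expect_equal(attr(out3, "ties"), 1L)
  expect_length(predict_gda(list(), sents, scorer), 0)
})

test_that("sentence-level GCA prediction applies the rule table with grounding", {
  text <- "TP53 is overexpressed and inhibits lung cancer."
  links <- link_entities(c(abstract = text), list(gene_lex, disease_lex))
  sents <- split_sentences(text)
  out <- predict_gca(links, sents, section = "abstract")
  expect_length(out, 1)
  expect_equal(out[[1]]$predicate$name, "tumor suppressor")
  pos <- out[[1]]$subject$positions[[1]]
  expect_equal(c(pos$start, pos$end), c(0L, 4L))
  expect_equal(out[[1]]$object$positions[[1]]$start, 35L)
  # a sentence with a gene but no disease yields nothing
  out2 <- predict_gca(link_entities(c(abstract = "TP53 is overexpressed."),
                                    list(gene_lex, disease_lex)),
                      split_sentences("TP53 is overexpressed."))
  expect_length(out2, 0)
  # an aspect triple missing from the rule table skips the sentence
  empty_rules <- gca_default_rules()[0, ]
  out3 <- predict_gca(links, sents, aspect_scorers = gca_aspect_scorers(),
                      rules = empty_rules)
  expect_length(out3, 0)
  expect_equal(attr(out3, "skipped"), 1L)
})

test_that("run_autotron stores under the machine annotator and refreshes idempotently", {
  corpus <- gen_corpus(small_synth_config(3))
  coll <- corpus$collection
  doc <- names(coll$documents)[[1]]
  n1 <- run_autotron(coll, doc, "GCA", corpus$lexicons)
  state1 <- canonical_state(coll, 1)
  n2 <- run_autotron(coll, doc, "GCA", corpus$lexicons)
  expect_equal(n1, n2)
  # re-running replaces the previous machine set instead of duplicating it
  expect_identical(canonical_state(coll, 1), state1)
  expect_error(run_autotron(coll, doc, "XYZ", corpus$lexicons))
})

test_that("scorer contract violations are rejected before anything is stored", {
  bad <- list(kind = "relationship",
              subject = list(id = "G:1", name = "g", type = ""),
              predicate = list(id = "P:1", name = "p", type = "Predicate"),
              object = list(id = "D:1", name = "d", type = "Disease"))
  expect_error(annostore:::validate_auto_annotation(bad), "contract")
  expect_error(annostore:::score_vector(c(Biomarker = 1.7), GDA_VOCAB), "0, 1")
})
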