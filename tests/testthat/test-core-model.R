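test_that("mention creation recomputes the surface and permits overlap", {
  coll <- make_demo_collection()
  m <- create_mention(coll, "a1", "d1", "text", 0, 5)
  expect_equal(m$surface, "BRCA1")
  m2 <- create_mention(coll, "a1", "d1", "text", 24, 37)
  expect_equal(m2$surface, "breast cancer")
  # overlapping span by the same annotator is permitted
  m3 <- create_mention(coll, "a1", "d1", "text", 24, 30)
  expect_equal(m3$surface, "breast")
  expect_length(coll$ann[[1]][["a1"]][["d1"]]$mentions, 3)
})

test_that("invalid spans, sections and annotators are rejected", {
  coll <- make_demo_collection()
  expect_error(create_mention(coll, "a1", "d1", "text", 5, 5), "invalid span")
  expect_error(create_mention(coll, "a1", "d1", "text", -1, 3), "invalid span")
  expect_error(create_mention(coll, "a1", "d1", "text", 0, 999), "invalid span")
  expect_error(create_mention(coll, "a1", "d1", "body", 0, 3), "unknown section")
  expect_error(create_mention(coll, "eve", "d1", "text", 0, 3), "not a member")
})

test_that("annotate_all creates one linked mention per occurrence", {
  coll <- make_demo_collection()
  made <- annotate_all(coll, "a1", "d2", "TP53", concepts = "GENE:7157")
  expect_length(made, 3)  # one in the title, two in the abstract
  expect_true(all(vapply(made, function(m) identical(m$concepts, "GENE:7157"),
                         logical(1))))
  # identical (span, concept set) occurrences are not duplicated on re-run
  expect_length(annotate_all(coll, "a1", "d2", "TP53", concepts = "GENE:7157"), 0)
  expect_length(annotate_all(coll, "a1", "d2", "ABSENT-SURFACE"), 0)
})

test_that("annotate_all count equals the naive substring-scan oracle", {
  set.seed(404)
  coll <- create_collection("r", "random docs", "boss", members = "a1")
  for (i in 1:10) {
    words <- sample(c("alpha", "beta", "gamma", "delta", "beta-like"), 60,
                    replace = TRUE)
    add_document(coll, new_document(paste0("doc", i),
                                    c(text = paste(words, collapse = " "))))
    text <- paste(words, collapse = " ")
    for (surface in c("beta", "gamma delta", "zeta")) {
      made <- annotate_all(coll, "a1", paste0("doc", i), surface)
      expect_length(made, count_occurrences(text, surface))
      for (m in made) expect_equal(m$surface, surface)
    }
  }
})

test_that("concept linking registers new concepts and is idempotent", {
  coll <- make_demo_collection()
  m <- create_mention(coll, "a1", "d1", "text", 24, 37)
  link_concept(coll, "a1", "d1", m$id, "MESH:D001943")
  m <- link_concept(coll, "a1", "d1", m$id, "MESH:D001943")
  expect_length(m$concepts, 1)
  # a mention can have more than one linked concept
  m <- link_concept(coll, "a1", "d1", m$id, "NEW:1",
                    register_if_new = data.frame(identifier = "NEW:1",
                                                 name = "Novel", type = "Gene"))
  expect_length(m$concepts, 2)
  expect_equal(get_concept(coll, "NEW:1")$name, "Novel")
  expect_error(link_concept(coll, "a1", "d1", m$id, "UNKNOWN:9"),
               "not registered")
})

test_that("concept registry enforces uniqueness and idempotent re-registration", {
  coll <- make_demo_collection()
  n <- nrow(coll$registry)
  register_concepts(coll, data.frame(identifier = "GENE:672", name = "BRCA1",
                                     type = "Gene"))
  expect_equal(nrow(coll$registry), n)
  expect_error(register_concepts(coll, data.frame(identifier = "GENE:672",
                                                  name = "Other", type = "Gene")),
               "conflicting")
  expect_error(register_concepts(coll, data.frame(identifier = "X", name = "",
                                                  type = "T")), "mandatory")
})

test_that("relationships require three distinct roles and at least one mention", {
  coll <- make_demo_collection()
  m1 <- create_mention(coll, "a1", "d1", "text", 0, 5)
  m2 <- create_mention(coll, "a1", "d1", "text", 24, 37)
  r <- create_relationship(coll, "a1", "d1", comp_mention(m1$id),
                           comp_concept("MESH:D009369"), comp_mention(m2$id))
  expect_equal(r$subject$kind, "mention")
  # concept-only triple violates the at-least-one-mention rule
  expect_error(create_relationship(coll, "a1", "d1", comp_concept("GENE:672"),
                                   comp_concept("MESH:D009369"),
                                   comp_concept("MESH:D001943")),
               "at least one")
  # exactly one mention suffices; free-text predicate allowed
  r2 <- create_relationship(coll, "a1", "d1", comp_concept("GENE:672"),
                            comp_text("inhibits"), comp_mention(m2$id))
  expect_equal(r2$predicate$ref, "inhibits")
  # free text is predicate-only
  expect_error(create_relationship(coll, "a1", "d1", comp_text("x"),
                                   comp_concept("MESH:D009369"),
                                   comp_mention(m2$id)),
               "predicate role only")
  # self-relation permitted with a warning
  expect_warning(create_relationship(coll, "a1", "d1", comp_mention(m1$id),
                                     comp_concept("MESH:D009369"),
                                     comp_mention(m1$id)),
                 "self-relation")
})

test_that("a mention component's role can be swapped later", {
  coll <- make_demo_collection()
  m1 <- create_mention(coll, "a1", "d1", "text", 0, 5)
  m2 <- create_mention(coll, "a1", "d1", "text", 24, 37)
  r <- create_relationship(coll, "a1", "d1", comp_mention(m1$id),
                           comp_concept("MESH:D009369"), comp_mention(m2$id))
  r <- change_role(coll, "a1", "d1", r$id, "subject", "object")
  expect_equal(r$subject$ref, m2$id)
  expect_equal(r$object$ref, m1$id)
})

test_that("assertions are concept-only and duplicate-idempotent", {
  coll <- make_demo_collection()
  a1 <- create_assertion(coll, "a1", "d1", "GENE:672", "MESH:D009369",
                         "MESH:D001943")
  a2 <- create_assertion(coll, "a1", "d1", "GENE:672", "MESH:D009369",
                         "MESH:D001943")
  expect_equal(a1$id, a2$id)
  expect_length(coll$ann[[1]][["a1"]][["d1"]]$assertions, 1)
  expect_error(create_assertion(coll, "a1", "d1", "GENE:672", "NOPE",
                                "MESH:D001943"), "not registered")
})

test_that("labels follow select/deselect semantics within the collection set", {
  coll <- make_demo_collection()
  set_labels(coll, "a1", "d1", c("relevant", "not-relevant"))
  expect_length(coll$ann[[1]][["a1"]][["d1"]]$labels, 2)
  set_labels(coll, "a1", "d1", "relevant")
  expect_length(coll$ann[[1]][["a1"]][["d1"]]$labels, 1)
  set_labels(coll, "a1", "d1", character(0))
  expect_length(coll$ann[[1]][["a1"]][["d1"]]$labels, 0)
  expect_error(set_labels(coll, "a1", "d1", "unknown-label"), "label")
})

test_that("deleting a mention cascades to referencing relationships", {
  coll <- make_demo_collection()
  m1 <- create_mention(coll, "a1", "d1", "text", 0, 5)
  m2 <- create_mention(coll, "a1", "d1", "text", 24, 37)
  r <- create_relationship(coll, "a1", "d1", comp_mention(m1$id),
                           comp_concept("MESH:D009369"), comp_mention(m2$id))
  rep <- delete_annotation(coll, "a1", "d1", m1$id)
  expect_equal(rep$type, "mention")
  expect_equal(rep$cascaded, r$id)
  expect_length(coll$ann[[1]][["a1"]][["d1"]]$relationships, 0)
  # double delete errors
  expect_error(delete_annotation(coll, "a1", "d1", m1$id), "unknown annotation")
  # deleting a label removes only that label
  set_labels(coll, "a1", "d1", "relevant")
  lid <- names(coll$ann[[1]][["a1"]][["d1"]]$labels)[[1]]
  rep <- delete_annotation(coll, "a1", "d1", lid)
  expect_equal(rep$type, "label")
  expect_length(rep$cascaded, 0)
})

test_that("copying pulls the dependency closure and skips duplicates", {
  coll <- make_demo_collection()
  m1 <- create_mention(coll, "a1", "d1", "text", 0, 5, concepts = "GENE:672")
  m2 <- create_mention(coll, "a1", "d1", "text", 24, 37)
  r <- create_relationship(coll, "a1", "d1", comp_mention(m1$id),
                           comp_concept("MESH:D009369"), comp_mention(m2$id))
  # copying only the relationship copies its component mentions too
  n <- copy_annotations(coll, "d1", "a1", "a2", ids = r$id)
  expect_equal(n, 3)
  expect_length(coll$ann[[1]][["a2"]][["d1"]]$mentions, 2)
  # idempotence: a second copy adds nothing and leaves the state unchanged
  before <- canonical_state(coll, 1)
  expect_equal(copy_annotations(coll, "d1", "a1", "a2"), 0)
  expect_identical(canonical_state(coll, 1), before)
  expect_error(copy_annotations(coll, "d1", "a1", "a2", ids = "m-999999"),
               "not in")
})

test_that("concept suggestions count teammates per concept, excluding the caller", {
  coll <- make_demo_collection()
  for (a in c("a1", "a2"))
    create_mention(coll, a, "d1", "text", 24, 37, concepts = "MESH:D001943")
  create_mention(coll, "a3", "d1", "text", 24, 37, concepts = "MESH:D009369")
  mine <- create_mention(coll, "boss", "d1", "text", 24, 37,
                         concepts = "GENE:672")
  sugg <- suggest_concepts(coll, "boss", "d1", mine$id)
  expect_equal(sugg$identifier, c("MESH:D001943", "MESH:D009369"))
  expect_equal(sugg$n_annotators, c(2L, 1L))
  expect_false("GENE:672" %in% sugg$identifier)  # caller's own link excluded
  lone <- create_mention(coll, "boss", "d1", "text", 0, 2)
  expect_equal(nrow(suggest_concepts(coll, "boss", "d1", lone$id)), 0)
})

test_that("a new round duplicates the last round and stays isolated", {
  coll <- make_demo_collection()
  populate_identical_sets(coll, c("a1", "a2"))
  n1 <- length(coll$ann[[1]][["a1"]][["d1"]]$mentions)
  r <- new_round(coll, c("a1", "a3"))
  expect_equal(r, 2L)
  # carried member keeps a deep copy; new member starts empty
  expect_length(coll$ann[[2]][["a1"]][["d1"]]$mentions, n1)
  expect_null(coll$ann[[2]][["a3"]])
  expect_null(coll$ann[[2]][["a2"]])
  before <- canonical_state(coll, 1)
  mid <- names(coll$ann[[2]][["a1"]][["d1"]]$mentions)[[1]]
  delete_annotation(coll, "a1", "d1", mid, round = 2)
  expect_identical(canonical_state(coll, 1), before)
  expect_error(new_round(coll, "a1", by = "a2"), "creator")
  expect_error(new_round(coll, character(0)), "at least one member")
})

test_that("token alignment widens a span to whole space-delimited tokens", {
  text <- "BRCA1 is an oncogene"
  expect_equal(token_align(text, 7, 8), c(6, 8))    # inside "is"
  expect_equal(token_align(text, 0, 3), c(0, 5))    # part of "BRCA1"
  expect_equal(token_align(text, 6, 11), c(6, 11))  # already aligned
})

test_that("a collection survives a save/load cycle byte-identically", {
  coll <- make_demo_collection()
  populate_identical_sets(coll, c("a1", "a2"))
  new_round(coll, "a1")
  dir <- tempfile("store")
  save_collection(coll, dir)
  back <- load_collection(dir)
  expect_identical(canonical_state(coll, 1), canonical_state(back, 1))
  expect_identical(canonical_state(coll, 2), canonical_state(back, 2))
  expect_identical(coll$registry, back$registry)
})
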