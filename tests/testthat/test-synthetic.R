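test_that("generation is a pure function of the configuration", {
  a <- gen_annotator_sets(gen_corpus(small_synth_config(7)))
  b <- gen_annotator_sets(gen_corpus(small_synth_config(7)))
  expect_identical(canonical_state(a$collection, 1),
                   canonical_state(b$collection, 1))
  expect_identical(a$ledger$associations, b$ledger$associations)
  c3 <- gen_corpus(small_synth_config(8))
  expect_false(identical(a$ledger$associations, c3$ledger$associations))
})

test_that("the gold ledger is consistent with the generated text", {
  corpus <- gen_corpus(synth_config(21, n_documents = 5))
  coll <- corpus$collection
  gm <- corpus$ledger$mentions
  for (i in seq_len(nrow(gm))) {
    text <- section_text(coll, gm$document[[i]], gm$section[[i]])
    expect_identical(substr(text, gm$start[[i]] + 1, gm$end[[i]]),
                     gm$surface[[i]])
  }
  # exactly two planted mentions per planted association
  expect_equal(nrow(gm), 2L * nrow(corpus$ledger$associations))
  # planted pairs are unique per document
  ga <- corpus$ledger$associations
  expect_false(any(duplicated(ga[, c("document", "subject", "object")])))
})

test_that("zero density yields no associations and no automatic relationships", {
  corpus <- gen_corpus(synth_config(5, n_documents = 3, density = 0))
  expect_equal(nrow(corpus$ledger$associations), 0)
  coll <- corpus$collection
  n <- sum(vapply(names(coll$documents), function(d)
    run_autotron(coll, d, "GCA", corpus$lexicons), numeric(1)))
  expect_equal(n, 0)
})

test_that("the empirical keep fraction matches its binomial expectation", {
  # aim for ~1000 gold mentions: 3-sigma binomial bound at p = 0.7
  cfg <- synth_config(17, n_documents = 60, sentence_range = c(8, 10),
                      density = 0.7, n_annotators = 1, p_keep = 0.7, q_swap = 0)
  corpus <- gen_annotator_sets(gen_corpus(cfg))
  n_gold <- nrow(corpus$ledger$mentions)
  expect_gt(n_gold, 500)
  kept <- nrow(corpus$ledger$edits$ann1$kept_mentions)
  p_hat <- kept / n_gold
  sigma <- sqrt(0.7 * 0.3 / n_gold)
  expect_lt(abs(p_hat - 0.7), 3 * sigma)
})

test_that("predicate swapping yields the expected pairwise agreement", {
  # p = 1, q = 1 with 2 alternative predicates: two annotators pick the same
  # replacement with probability 1/2
  cfg <- synth_config(19, n_documents = 60, sentence_range = c(8, 10),
                      density = 0.7, n_annotators = 2, p_keep = 1, q_swap = 1)
  corpus <- gen_annotator_sets(gen_corpus(cfg))
  e1 <- corpus$ledger$edits$ann1$kept_assoc
  e2 <- corpus$ledger$edits$ann2$kept_assoc
  n <- nrow(e1)
  expect_gt(n, 200)
  agree <- mean(e1$swapped_to == e2$swapped_to)
  sigma <- sqrt(0.25 / n)
  expect_lt(abs(agree - 0.5), 3 * sigma)
  # with p = 1, q = 0 all annotators are identical: Fleiss' kappa is 1
  cfg2 <- small_synth_config(23, p_keep = 1, q_swap = 0)
  corpus2 <- gen_annotator_sets(gen_corpus(cfg2))
  for (type in c("mention", "concept", "relationship", "label"))
    expect_identical(fleiss_agreement(corpus2$collection, type)$kappa, 1,
                     info = type)
})

test_that("generated collections pass the data-model invariants on reload", {
  corpus <- gen_annotator_sets(gen_corpus(small_synth_config(29)))
  dir <- tempfile("synth")
  save_collection(corpus$collection, dir)
  # load_collection re-validates every span/surface pair
  back <- load_collection(dir)
  expect_identical(canonical_state(corpus$collection, 1),
                   canonical_state(back, 1))
})
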