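test_that("summaries report exact counts and personal mode filters globally", {
  coll <- make_demo_collection()
  populate_identical_sets(coll, c("a1", "a2"))
  g <- summarize_annotations(coll, "global", with_kappa = FALSE)
  expect_equal(unname(g$counts["mentions"]), 6L)       # 3 per annotator
  expect_equal(unname(g$counts["relationships"]), 2L)
  expect_equal(unname(g$counts["assertions"]), 2L)
  expect_equal(unname(g$counts["labels"]), 4L)
  expect_equal(g$n_annotated_documents, 2L)
  expect_equal(g$n_annotators, 2L)
  p1 <- summarize_annotations(coll, "personal", annotator = "a1")
  p2 <- summarize_annotations(coll, "personal", annotator = "a2")
  expect_equal(p1$counts + p2$counts, g$counts)
  # empty collection: all zeros, kappa undefined
  e <- summarize_annotations(make_demo_collection(), "global")
  expect_true(all(e$counts == 0))
  expect_true(all(is.na(e$fleiss)))
})

test_that("concept distributions exclude untyped free-text predicates", {
  coll <- make_demo_collection()
  m1 <- create_mention(coll, "a1", "d1", "text", 0, 5, concepts = "GENE:672")
  m2 <- create_mention(coll, "a1", "d1", "text", 24, 37,
                       concepts = "MESH:D001943")
  create_relationship(coll, "a1", "d1", comp_mention(m1$id),
                      comp_text("inhibits"), comp_mention(m2$id))
  d <- concept_distributions(coll)
  expect_equal(unname(d$linked_type_counts[["Gene"]]), 1L)
  expect_equal(unname(d$linked_type_counts[["Disease"]]), 1L)
  expect_equal(d$n_freetext_predicates, 1L)
  expect_false("?" %in% names(d$role_type_counts$predicate))
  # role totals equal a brute-force recount of concept-bearing components
  total_roles <- sum(unlist(d$role_type_counts))
  expect_equal(total_roles, 2L)  # subject mention concept + object mention concept
})

test_that("per-document tables match global totals and the progress ratio", {
  coll <- make_demo_collection()
  for (i in 3:15) add_document(coll, new_document(sprintf("x%02d", i),
                                                  c(text = "filler text")))
  populate_identical_sets(coll, "a1")   # annotations on d1 and d2 only
  create_mention(coll, "a2", "d1", "text", 0, 5)
  tab <- per_document_counts(coll)
  expect_equal(nrow(tab), 15)
  # 2 annotated documents of 15
  expect_equal(attr(tab, "progress_percent"), 100 * 2 / 15)
  g <- summarize_annotations(coll, "global", with_kappa = FALSE)
  expect_equal(sum(tab$mentions), unname(g$counts["mentions"]))
  apd <- annotators_per_document(coll)
  expect_equal(apd$n_annotators[apd$document == "d1"], 2L)
  expect_equal(apd$n_annotators[apd$document == "d2"], 1L)
})

test_that("the baseline diff classifies predicate changes as updates", {
  coll <- make_demo_collection()
  # baseline: AutoTron holds (G1, Biomarker, D1); final annotator swaps predicate
  register_concepts(coll, data.frame(
    identifier = c("P:bio", "P:ther"), name = c("Biomarker", "Therapeutic"),
    type = "Predicate"))
  create_assertion(coll, "AutoTron", "d1", "GENE:672", "P:bio", "MESH:D001943")
  create_assertion(coll, "a1", "d1", "GENE:672", "P:ther", "MESH:D001943")
  rep <- diff_against_baseline(coll, "AutoTron", "a1", "assertion",
                               round_final = 1L)
  expect_equal(rep$counts[["added"]], 0L)
  expect_equal(rep$counts[["deleted"]], 0L)
  expect_equal(rep$counts[["updated"]], 1L)
  expect_equal(rep$counts[["confirmed"]], 0L)
  # identical sets are all confirmed
  create_assertion(coll, "a2", "d1", "GENE:672", "P:bio", "MESH:D001943")
  rep2 <- diff_against_baseline(coll, "AutoTron", "a2", "assertion",
                                round_final = 1L)
  expect_equal(rep2$counts[["confirmed"]], 1L)
  expect_equal(sum(rep2$counts), rep2$n_universe)
})

test_that("statistics are identical after a serialization round trip", {
  corpus <- gen_annotator_sets(gen_corpus(small_synth_config(13)))
  coll <- corpus$collection
  dir <- tempfile("store")
  save_collection(coll, dir)
  back <- load_collection(dir)
  a <- summarize_annotations(coll, "global", with_kappa = FALSE)
  b <- summarize_annotations(back, "global", with_kappa = FALSE)
  expect_identical(a$counts, b$counts)
  expect_identical(concept_distributions(coll)$global_type_counts,
                   concept_distributions(back)$global_type_counts)
})
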