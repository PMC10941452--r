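test_that("unitization gives one category per annotator per item", {
  coll <- make_demo_collection()
  # a1 and a2 link (span, C1); a3 annotates nothing at that span
  for (a in c("a1", "a2"))
    create_mention(coll, a, "d1", "text", 24, 37, concepts = "MESH:D001943")
  create_mention(coll, "a3", "d1", "text", 0, 5)
  tab <- unitize(coll, "concept", annotators = c("a1", "a2", "a3"))
  expect_equal(length(tab$items), 1)
  expect_equal(tab$n_raters, 3)
  expect_equal(sort(unname(tab$counts[1, ])), c(1, 2))
  expect_equal(unname(tab$counts[1, "ABSENT"]), 1)
  # every row sums to the rater count
  expect_true(all(rowSums(tab$counts) == tab$n_raters))
})

test_that("relationship unitization measures predicate choice per pair", {
  coll <- make_demo_collection()
  preds <- c("MESH:D009369", "MESH:D009369", "MESH:D008175")
  for (i in 1:3) {
    a <- paste0("a", i)
    m1 <- create_mention(coll, a, "d1", "text", 0, 5)
    m2 <- create_mention(coll, a, "d1", "text", 24, 37)
    create_relationship(coll, a, "d1", comp_mention(m1$id),
                        comp_concept(preds[[i]]), comp_mention(m2$id))
  }
  tab <- unitize(coll, "relationship")
  expect_equal(length(tab$items), 1)
  counts <- tab$counts[1, setdiff(colnames(tab$counts), "ABSENT")]
  expect_equal(sort(unname(counts)), c(1, 2))
  expect_error(unitize(coll, "relationship", annotators = "a1"),
               "at least 2 annotators")
})

test_that("Fleiss' kappa reproduces the hand-derived and frozen oracle values", {
  tab <- matrix(c(3, 0, 0, 3, 2, 1, 1, 2), ncol = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(tab), 1 / 3, tolerance = 1e-14)
  # frozen values from an independent library implementation
  # (statsmodels.stats.inter_rater.fleiss_kappa) on fixed random tables
  set.seed(42)
  expected <- c(-0.19999999999999996, -0.011904761904762, 0.027027027027026987)
  for (k in 1:3) {
    n_items <- sample(5:12, 1); n_cat <- sample(2:4, 1); n_rater <- sample(2:5, 1)
    m <- t(sapply(seq_len(n_items), function(i)
      as.vector(rmultinom(1, n_rater, rep(1, n_cat)))))
    expect_equal(fleiss_kappa(m), expected[[k]], tolerance = 1e-12)
  }
  # degenerate cases
  expect_true(is.na(fleiss_kappa(matrix(numeric(0), nrow = 0, ncol = 2))))
  # all raters identical on every item across >=2 categories
  expect_identical(fleiss_kappa(matrix(c(3, 0, 0, 3), 2, byrow = TRUE)), 1)
  # single category for all raters: perfect agreement, kappa 1 by definition
  expect_identical(fleiss_kappa(matrix(c(3, 3), ncol = 1)), 1)
})

test_that("Cohen's kappa reproduces hand-derived and frozen oracle values", {
  expect_equal(cohen_kappa(c("x", "x", "y", "y"), c("x", "y", "y", "y")), 0.5)
  expect_equal(cohen_kappa(c("x", "y"), c("y", "x")), -1)  # floor of the range
  expect_identical(cohen_kappa(letters[1:4], letters[1:4]), 1)
  expect_true(is.na(cohen_kappa(character(0), character(0))))
  expect_error(cohen_kappa(c("x"), c("x", "y")), "length")
  # frozen value from scikit-learn cohen_kappa_score on fixed sequences
  set.seed(99)
  a <- sample(letters[1:3], 20, replace = TRUE)
  b <- sample(letters[1:3], 20, replace = TRUE)
  expect_equal(cohen_kappa(a, b), -0.11553784860557759, tolerance = 1e-12)
})

test_that("kappa is invariant under item and category permutations", {
  set.seed(7)
  for (i in 1:25) {
    m <- random_rating_table()
    k <- fleiss_kappa(m)
    expect_equal(fleiss_kappa(m[sample(nrow(m)), , drop = FALSE]), k,
                 tolerance = 1e-12)
    expect_equal(fleiss_kappa(m[, sample(ncol(m)), drop = FALSE]), k,
                 tolerance = 1e-12)
    a <- sample(letters[1:3], 30, replace = TRUE)
    b <- sample(letters[1:3], 30, replace = TRUE)
    perm <- sample(30)
    expect_equal(cohen_kappa(a[perm], b[perm]), cohen_kappa(a, b),
                 tolerance = 1e-12)
  }
})

test_that("majority voting applies the strict more-than-half rule", {
  coll <- make_demo_collection()
  add_member(coll, "a4")
  # support 2 of 3 annotators: included (2 > 1.5)
  for (a in c("a1", "a2")) create_mention(coll, a, "d1", "text", 0, 5)
  create_mention(coll, "a3", "d1", "text", 6, 8)
  cons <- majority_vote(coll, "d1", "mention")
  expect_equal(nrow(cons), 1)
  expect_equal(cons$support, 2L)
  expect_equal(cons$n_annotators, 3L)
  # support exactly 2 of 4: excluded (2 is not > 2)
  create_mention(coll, "a4", "d1", "text", 9, 11)
  cons <- majority_vote(coll, "d1", "mention")
  expect_equal(nrow(cons), 0)
  # a single annotator's annotations are all consensus (1 > 0.5)
  create_mention(coll, "a1", "d2", "title", 0, 4)
  cons <- majority_vote(coll, "d2", "mention")
  expect_equal(cons$support, 1L)
  expect_equal(cons$n_annotators, 1L)
})

test_that("consensus can be materialized and copied like a teammate's set", {
  coll <- make_demo_collection()
  populate_identical_sets(coll, c("a1", "a2", "a3"))
  n <- materialize_consensus(coll, "d1")
  expect_gt(n, 0)
  iaa <- coll$ann[[1]][["IAA"]][["d1"]]
  expect_length(iaa$relationships, 1)
  expect_length(iaa$assertions, 1)
  # copyable into a member's set
  got <- copy_annotations(coll, "d1", "IAA", "boss")
  expect_gt(got, 0)
})

test_that("pairwise Cohen agreement works at document and collection scope", {
  coll <- make_demo_collection()
  populate_identical_sets(coll, c("a1", "a2"))
  rep <- pairwise_cohen(coll, "a1", "a2", "mention")
  expect_identical(rep$kappa, 1)
  expect_error(pairwise_cohen(coll, "a1", "a1", "mention"), "distinct")
  expect_error(pairwise_cohen(coll, "a1", "a3", "mention"), "no annotations")
  # disjoint annotation sets: each item ABSENT for the other rater
  coll2 <- make_demo_collection()
  create_mention(coll2, "a1", "d1", "text", 0, 5)
  create_mention(coll2, "a2", "d1", "text", 6, 8)
  rep2 <- pairwise_cohen(coll2, "a1", "a2", "mention")
  expect_lte(rep2$kappa, 0)
})

test_that("per-round agreement reports undefined rounds instead of dropping them", {
  coll <- make_demo_collection()
  create_mention(coll, "a1", "d1", "text", 0, 5)   # single annotator
  byr <- agreement_by_round(coll, "mention")
  expect_equal(nrow(byr), 1)
  expect_true(is.na(byr$kappa[[1]]))
  # a second round where all annotators agree perfectly
  new_round(coll, c("a1", "a2"))
  for (a in c("a1", "a2")) create_mention(coll, a, "d1", "text", 0, 5, round = 2)
  byr <- agreement_by_round(coll, "mention")
  expect_identical(byr$kappa[[2]], 1)
})
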