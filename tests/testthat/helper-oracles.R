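# Independent oracles and fixture builders. The kappa oracles are naive
# loop-level evaluations of the textbook formulas, deliberately coded
# differently from the package implementation.

fleiss_oracle <- function(m) {
  m <- as.matrix(m)
  N <- nrow(m)
  if (N == 0L) return(NA_real_)
  n <- sum(m[1, ])
  P <- numeric(N)
  for (i in seq_len(N)) {
    acc <- 0
    for (j in seq_len(ncol(m))) acc <- acc + m[i, j] * (m[i, j] - 1)
    P[i] <- acc / (n * (n - 1))
  }
  Pbar <- sum(P) / N
  pe <- 0
  for (j in seq_len(ncol(m))) pe <- pe + (sum(m[, j]) / (N * n))^2
  if (Pbar == 1) return(1)
  (Pbar - pe) / (1 - pe)
}

cohen_oracle <- function(a, b) {
  if (length(a) == 0L) return(NA_real_)
  tab <- table(factor(a, levels = union(a, b)), factor(b, levels = union(a, b)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (po == 1) return(1)
  (po - pe) / (1 - pe)
}

random_rating_table <- function() {
  n_items <- sample(2:15, 1)
  n_cat <- sample(2:5, 1)
  n_rater <- sample(2:6, 1)
  t(vapply(seq_len(n_items), function(i)
    as.vector(stats::rmultinom(1, n_rater, stats::runif(n_cat))),
    numeric(n_cat)))
}

# a tiny collection with planted multi-annotator annotations of all types
make_demo_collection <- function(annotators = c("a1", "a2", "a3"),
                                 labels = c("relevant", "not-relevant")) {
  coll <- create_collection("demo", "demo collection", "boss",
                            members = annotators, labels = labels)
  register_concepts(coll, data.frame(
    identifier = c("GENE:672", "MESH:D001943", "MESH:D009369", "GENE:7157",
                   "MESH:D008175"),
    name = c("BRCA1", "Breast Neoplasms", "Oncogenes", "TP53",
             "Lung Neoplasms"),
    type = c("Gene", "Disease", "Predicate", "Gene", "Disease")))
  add_document(coll, new_document(
    "d1", c(text = "BRCA1 is an oncogene in breast cancer")))
  add_document(coll, new_document(
    "d2", c(title = "TP53 in lung cancer",
            abstract = "TP53 suppresses lung cancer. TP53 is mutated.")))
  coll
}

# identical full-type annotation sets for every annotator (perfect agreement)
populate_identical_sets <- function(coll, annotators, round = 1L) {
  for (a in annotators) {
    m1 <- create_mention(coll, a, "d1", "text", 0, 5, concepts = "GENE:672",
                         round = round)
    m2 <- create_mention(coll, a, "d1", "text", 24, 37,
                         concepts = "MESH:D001943", round = round)
    create_relationship(coll, a, "d1", comp_mention(m1$id),
                        comp_concept("MESH:D009369"), comp_mention(m2$id),
                        round = round)
    create_assertion(coll, a, "d1", "GENE:672", "MESH:D009369",
                     "MESH:D001943", round = round)
    set_labels(coll, a, "d1", "relevant", round = round)
    m3 <- create_mention(coll, a, "d2", "abstract", 0, 4,
                         concepts = "GENE:7157", round = round)
    set_labels(coll, a, "d2", "not-relevant", round = round)
  }
  invisible(coll)
}

# brute-force strict-majority consensus over label keys
brute_majority_keys <- function(key_sets) {
  n <- length(key_sets)
  all_keys <- unique(unlist(key_sets))
  support <- vapply(all_keys, function(k)
    sum(vapply(key_sets, function(s) k %in% s, logical(1))), integer(1))
  sort(all_keys[support > n / 2])
}

# naive left-to-right non-overlapping substring occurrence counter
count_occurrences <- function(text, surface) {
  n <- 0L; from <- 1L
  repeat {
    hit <- regexpr(surface, substring(text, from), fixed = TRUE)
    if (hit == -1L) break
    n <- n + 1L
    from <- from + as.integer(hit) - 1L + nchar(surface)
  }
  n
}

small_synth_config <- function(seed, ...) {
  synth_config(seed, n_documents = 2, sentence_range = c(3, 5), ...)
}
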