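test_that("kmerize folds case, splits on non-alphanumerics, keeps short tokens", {
  b <- kmerize("heart", k = 4)
  expect_identical(b$counts, c(eart = 1, hear = 1)[names(b$counts)])
  expect_setequal(names(b$counts), c("hear", "eart"))
  expect_identical(kmerize("Heart", 4)$counts, kmerize("heart", 4)$counts)
  expect_identical(names(kmerize("at", 4)$counts), "at")
  expect_error(kmerize("x", k = 1), "at least 2")
  # punctuation acts as a separator, counts accumulate
  b2 <- kmerize("ab-ab", 2)
  expect_identical(unname(b2$counts["ab"]), 2)
})

test_that("weights are smoothed inverse document frequencies", {
  w <- build_weights(c("abcd x", "abcd y", "abcd z"), k = 4)
  expect_equal(unname(w$weights["abcd"]), 1)  # present in every doc
  w4 <- build_weights(c("abcd", "efgh", "ijkl", "mnop"), k = 4)
  expect_equal(unname(w4$weights["abcd"]), 1 + log(5 / 2))
  expect_equal(w4$unseen, 1 + log(5))
  expect_true(all(w4$weights > 0))
  expect_error(build_weights(character(0)), "non-empty")
})

test_that("similarity is a bounded symmetric weighted cosine", {
  w <- build_weights(c("ab cd"), k = 2)  # both k-mers get weight 1
  a <- kmerize("ab", 2)
  both <- kmerize("ab cd", 2)
  other <- kmerize("xy", 2)
  expect_equal(kmer_similarity(a, a, w), 1)
  expect_equal(kmer_similarity(a, other, w), 0)
  expect_equal(kmer_similarity(a, both, w), 1 / sqrt(2))
  expect_equal(kmer_similarity(both, a, w), kmer_similarity(a, both, w))
})

test_that("profile text uses direct names (concise) or closure names (complete)", {
  ont <- chain_ontology()
  w <- build_weights(vapply(ont$ids, term_text, "", ontology = ont), k = 4)
  empty <- encode_profile_text(phenotype_profile("e"), ont, "concise", 4)
  expect_length(empty$counts, 0)

  concise <- encode_profile_text(phenotype_profile("c", terms = "MP:C"),
                                 ont, "concise", 4)
  expect_identical(concise$counts, kmerize("increased heart weight", 4)$counts)

  complete <- encode_profile_text(phenotype_profile("c", terms = "MP:C"),
                                  ont, "complete", 4)
  expect_identical(complete$counts, kmerize(
    c("cardiovascular system phenotype", "abnormal heart weight",
      "increased heart weight"), 4)$counts)

  redundant <- encode_profile_text(
    phenotype_profile("bc", terms = c("MP:B", "MP:C")), ont, "complete", 4)
  expect_identical(redundant$counts, complete$counts)
})

test_that("term mapping retrieves exact names and breaks ties by id", {
  ont <- chain_ontology()
  w <- build_weights(vapply(ont$ids, term_text, "", ontology = ont), k = 4)
  bags <- ontology_term_bags(ont, 4)
  expect_identical(map_term("increased heart weight", ont, w, bags), "MP:C")
  # a term's own text maps to itself for every term
  for (t in ont$ids) {
    expect_identical(map_term(term_text(ont, t), ont, w, bags), t)
  }
  # equal similarity -> lexicographically smallest id
  tie <- parse_obo(paste("[Term]", "id: Z:1", "name: alpha beta", "",
                         "[Term]", "id: Z:2", "name: beta alpha",
                         sep = "\n"))
  wt <- build_weights(c("alpha beta"), k = 4)
  expect_identical(map_term("alpha beta", tie, wt), "Z:1")
  expect_warning(out <- map_term("qqqq", tie, wt), "no target")
  expect_identical(out, NA_character_)
})

test_that("planted cross-ontology matches map to the intended term", {
  target <- parse_obo(paste(
    "[Term]", "id: MP:1", "name: abnormal kidney morphology", "",
    "[Term]", "id: MP:2", "name: increased heart weight", "",
    "[Term]", "id: MP:3", "name: absent startle reflex", sep = "\n"))
  w <- build_weights(vapply(target$ids, term_text, "", ontology = target),
                     k = 4)
  # HP-like phrasing sharing most tokens with exactly one target
  expect_identical(map_term("enlarged heart weight", target, w), "MP:2")
  expect_identical(map_term("abnormal kidney shape", target, w), "MP:1")
})

test_that("text search equals an exhaustive cosine oracle", {
  set.seed(42)
  vocab <- c("heart", "kidney", "weight", "reflex", "tail", "bone",
             "increased", "absent", "small", "fused")
  docs <- vapply(1:200, function(i) {
    paste(sample(vocab, sample(2:5, 1), replace = TRUE), collapse = " ")
  }, "")
  names(docs) <- sprintf("d%03d", 1:200)
  w <- build_weights(docs, k = 4)
  bags <- lapply(docs, kmerize, k = 4)
  q <- kmerize("increased heart weight", 4)
  sims <- vapply(bags, oracle_cosine, numeric(1), b = q, w = w)
  for (k in c(1, 5, 15)) {
    hits <- text_knn(q, bags, w, k)
    oracle <- names(sims)[order(-sims, names(sims))][1:k]
    expect_identical(hits$id, oracle)
    expect_equal(hits$similarity, unname(sims[oracle]), tolerance = 1e-12)
  }
  # identical document ranks first with similarity 1
  self <- text_knn(bags[["d001"]], bags, w, 1)
  expect_identical(self$id, "d001")
  expect_equal(self$similarity, 1)
  expect_warning(none <- text_knn(kmerize("", 4), bags, w, 3), "empty")
  expect_identical(nrow(none), 0L)
})
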