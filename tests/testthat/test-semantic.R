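test_that("corpora become trajectories with document-bounded windows", {
  b <- corpus_bundle(c(1L, 2L, 1L), c("a", "b"))
  tr <- corpus_to_trajectory(b)
  expect_equal(tr$states, c(1L, 2L, 1L))
  expect_equal(tr$n_states, 2)

  expect_error(corpus_bundle(c(1L, 3L), c("a", "b")), "vocabulary")

  # SR contributions never cross a document break: in [a b | b a], a is
  # followed by b only in document 1
  b2 <- corpus_bundle(c(1L, 2L, 2L, 1L), c("a", "b"), doc_breaks = c(1L, 3L))
  sr <- sr_empirical(corpus_to_trajectory(b2), gamma = 0.5)
  # first visit of a: 1 + no future b contribution from doc 2
  # visits of a: positions 1 (doc1) and 4 (doc2, terminal)
  expect_equal(sr[1, 2], 0.5 / 2)  # only the doc-1 continuation counts
  sr_nobreak <- sr_empirical(corpus_to_trajectory(
    corpus_bundle(c(1L, 2L, 2L, 1L), c("a", "b"))), gamma = 0.5)
  expect_gt(sr_nobreak[2, 1], sr[2, 1])
})

test_that("top words rank by activation with stable ties", {
  X <- rbind(a = c(0.1, 5), b = c(3, 5), c = c(2, 5), d = c(9, 0))
  emb <- as_dsi_embedding(X, X, labels = rownames(X))
  expect_equal(top_words(emb, 1, k = 3), c("d", "b", "c"))
  expect_equal(top_words(emb, 1, k = 1), "d")
  # ties broken by vocabulary order
  expect_equal(top_words(emb, 2, k = 3), c("a", "b", "c"))
  # rescaling leaves the list unchanged
  emb2 <- as_dsi_embedding(X * 100, X, labels = rownames(X))
  expect_equal(top_words(emb2, 1, k = 3), top_words(emb, 1, k = 3))
  expect_warning(tw <- top_words(emb, 1, k = 10), "truncat")
  expect_length(tw, 4)
})

test_that("conceptual specificity matches the category-oracle arithmetic", {
  # 10 categories x 10 words; a unit whose TOP-10 is one whole category
  cats <- rep(sprintf("c%02d", 1:10), each = 10)
  vocab <- sprintf("%s_w%02d", cats, rep(1:10, 10))
  names(cats) <- vocab
  oracle <- category_similarity_oracle(cats)

  X <- matrix(0, 100, 3)
  X[1:10, 1] <- 10:1                   # unit 1: all of category 1
  X[seq(1, 100, by = 10), 2] <- 10:1   # unit 2: one word of each category
  X[1, 3] <- 1                         # unit 3: a single active word
  emb <- as_dsi_embedding(X, X, labels = vocab)
  rep1 <- conceptual_specificity(emb, oracle, n_null = 1000, seed = 5)

  expect_equal(rep1$s_unit[1], 1)          # all 45 pairs same category
  expect_equal(rep1$s_unit[2], 0)          # no two words share a category
  s_null <- attr(rep1, "s_null")
  expect_lt(abs(s_null - 0.1), 0.05)       # collision probability ~ 1/10
  expect_equal(rep1$specificity[1], 1 / s_null - 1, tolerance = 1e-9)
  expect_equal(rep1$specificity[2], -1)
  # a unit whose TOP-10 ties into zero activation has no tuning profile
  expect_true(is.na(rep1$s_unit[3]))
  expect_false(rep1$significant[3])

  # reproducible under a fixed seed
  rep2 <- conceptual_specificity(emb, oracle, n_null = 1000, seed = 5)
  expect_identical(rep1$s_unit, rep2$s_unit)
  expect_identical(attr(rep1, "threshold"), attr(rep2, "threshold"))
})

test_that("significance calls concept units against a graded null", {
  # 25 categories of 8 words under 5 supercategories: the null's 95th
  # percentile sits at the sibling-category level (0.25), between diffuse
  # and concept-specific TOP-10 lists
  cats <- rep(sprintf("c%02d", 1:25), each = 8)
  vocab <- sprintf("%s_w%d", cats, rep(1:8, 25))
  names(cats) <- vocab
  supers <- setNames(rep(sprintf("s%d", 1:5), each = 5),
                     sprintf("c%02d", 1:25))
  oracle <- category_similarity_oracle(cats, supercategories = supers)

  X <- matrix(0, 200, 2)
  X[1:8, 1] <- 8:1          # concept unit: one whole category in its TOP-10
  X[9:10, 1] <- 0.5         # plus two sibling-category words
  X[seq(1, 200, by = 8), 2] <- 25:1   # diffuse unit
  emb <- as_dsi_embedding(X, X, labels = vocab)
  rep <- conceptual_specificity(emb, oracle, n_null = 1000, seed = 7)
  expect_equal(attr(rep, "threshold"), 0.25)
  expect_true(rep$significant[1])
  expect_false(rep$significant[2])
  expect_gt(rep$specificity[1], rep$specificity[2])
})

test_that("population similarity computes cosine and dissimilarity", {
  X <- rbind(a = c(1, 0, 1), b = c(1, 0, 1), c = c(0, 1, 0), d = c(2, 0, 2))
  emb <- as_dsi_embedding(X, X, labels = rownames(X))
  wp <- tibble::tibble(word1 = c("a", "a", "a"), word2 = c("b", "c", "d"))
  ps <- population_similarity(emb, wp)
  expect_equal(ps$similarity, c(1, 0, 1), tolerance = 1e-12)

  pd <- population_similarity(emb, wp, metric = "pearson_dissimilarity")
  expect_equal(pd$similarity[1], 0, tolerance = 1e-12)

  # zero vectors are flagged NA
  X0 <- rbind(a = c(1, 1), z = c(0, 0))
  emb0 <- as_dsi_embedding(X0, X0, labels = rownames(X0))
  expect_warning(
    p0 <- population_similarity(emb0,
                                tibble::tibble(word1 = "a", word2 = "z")),
    "degenerate")
  expect_true(is.na(p0$similarity))

  # reference scores give a Spearman rank correlation
  wp2 <- tibble::tibble(word1 = c("a", "a"), word2 = c("b", "c"),
                        score = c(0.9, 0.1))
  expect_equal(attr(population_similarity(emb, wp2), "spearman"), 1)
})

test_that("largest-element shares distinguish one-hot from distributed codes", {
  onehot <- as_dsi_embedding(diag(4), diag(4))
  expect_true(all(largest_element_share(onehot)$share == 1))
  emb <- toy_word_embedding()
  expect_true(all(largest_element_share(emb)$share == 0.5))
  zero <- as_dsi_embedding(matrix(0, 3, 2), matrix(0, 3, 2))
  expect_true(all(is.na(largest_element_share(zero)$share)))
})

test_that("analogies recombine factor units on the hand-built embedding", {
  emb <- toy_word_embedding()
  # Germany : Berlin :: France : Paris, i.e. x(France) + x(Berlin) - x(Germany)
  res <- analogy(emb, "Germany", "Berlin", "France")
  expect_equal(res$word[1], "Paris")
  # the partial variant with 2 dimensions flips capital on, country off
  res2 <- analogy(emb, "Germany", "Berlin", "France", k_dims = 2)
  expect_equal(res2$word[1], "Paris")
  # k_dims = D reproduces the full-vector result
  res_full <- analogy(emb, "Germany", "Berlin", "France", k_dims = 4)
  expect_equal(res_full$similarity, res$similarity)
  expect_error(analogy(emb, "Germany", "Berlin", "France", k_dims = 9),
               "k_dims")

  # b = a: the query reduces to x(c); top-1 is c's nearest other word
  res3 <- analogy(emb, "Germany", "Germany", "France")
  sims <- sapply(setdiff(rownames(emb$X), c("Germany", "France")), function(w) {
    sum(emb$X["France", ] * emb$X[w, ]) /
      sqrt(sum(emb$X["France", ]^2) * sum(emb$X[w, ]^2))
  })
  expect_equal(res3$word[1], names(which.max(sims)))
})

test_that("analogy accuracy is exact on consistent quadruples and chance on shuffled", {
  emb <- toy_word_embedding()
  quads <- tibble::tibble(
    a = c("Germany", "Berlin", "France", "Paris"),
    b = c("Berlin", "Germany", "Paris", "France"),
    c = c("France", "Paris", "Germany", "Berlin"),
    d = c("Paris", "France", "Berlin", "Germany"))
  expect_equal(analogy_accuracy(emb, quads), 1)
  expect_equal(analogy_accuracy(emb, quads, k_dims = 2), 1)

  # corrupting answers destroys accuracy
  bad <- quads
  bad$d <- bad$a
  expect_equal(analogy_accuracy(emb, bad), 0)
})
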