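test_that("embed_sentence looks up dictionary vectors with OOV fallback", {
  dict <- word_vector_dictionary(c("blood", "glucose"), d = 3, seed = 2)
  m <- embed_sentence(c("blood", "glucose", "unknown", "tokens", "here"), dict)
  expect_equal(dim(m), c(5, 3))
  expect_equal(m[1, ], unname(dict$vectors["blood", ]))
  expect_equal(m[3, ], dict$fallback)
  all_oov <- embed_sentence(c("aa", "bb"), dict)
  expect_true(all(all_oov == 0))
  expect_error(embed_sentence(character(0), dict), "non-empty")
})

test_that("segmentation fusion follows the weight/sum/normalize/argmax procedure", {
  # single classifier with weight 1 is the identity ensemble
  h1 <- matrix(c(0.7, 0.1, 0.1, 0.1), ncol = 1)
  h2 <- matrix(c(0.1, 0.1, 0.1, 0.7), ncol = 1)
  res <- fuse_segmentation(list(h1, h2), WS = 1)
  expect_equal(res$labels, c("B", "S"))
  # zero-weight classifier is ignored
  hA <- cbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1))
  res2 <- fuse_segmentation(list(hA), WS = c(1, 0))
  expect_equal(res2$labels, "B")
  # hand-computed fusion with a B-vs-M tie resolved to B
  hp <- cbind(c(0.6, 0.2, 0.1, 0.1), c(0.2, 0.6, 0.1, 0.1))
  res3 <- fuse_segmentation(list(hp), WS = c(0.5, 0.5))
  expect_equal(as.vector(res3$fused), c(0.4, 0.4, 0.1, 0.1))
  expect_equal(res3$labels, "B")
  expect_error(fuse_segmentation(list(hp), WS = c(0, 0)), "zero")
  # invariance to scaling all weights by a positive constant
  res4 <- fuse_segmentation(list(hp, hA), WS = c(0.3, 0.6))
  res5 <- fuse_segmentation(list(hp, hA), WS = c(0.1, 0.2))
  expect_equal(res4$fused, res5$fused)
  expect_equal(res4$labels, res5$labels)
})

test_that("entity fusion works over 7 categories with CL-order tie-break", {
  e_conf <- matrix(c(0.04, 0.04, 0.76, 0.04, 0.04, 0.04, 0.04), ncol = 1)
  res <- fuse_entity_tags(list(e_conf), WT = 1)
  expect_equal(res$labels, "CL3")
  expect_length(ENTITY_CATEGORIES, 7)
  # confident tagger 1 dominates at WT = (0.9, 0.1)
  e2 <- cbind(c(0.04, 0.04, 0.76, 0.04, 0.04, 0.04, 0.04),
              c(0.76, 0.04, 0.04, 0.04, 0.04, 0.04, 0.04))
  res2 <- fuse_entity_tags(list(e2), WT = c(0.9, 0.1))
  expect_equal(res2$labels, "CL3")
  scaled <- fuse_entity_tags(list(e2), WT = c(0.45, 0.05))
  expect_equal(res2$fused, scaled$fused)
})

test_that("decode_words reconstructs text exactly, repairing malformed runs", {
  expect_equal(decode_words(c("S", "S", "S"), c("a", "b", "c"))$words,
               c("a", "b", "c"))
  expect_equal(decode_words(c("B", "E", "S"), c("a", "b", "c"))$words,
               c("ab", "c"))
  expect_equal(decode_words(c("M", "E"), c("a", "b"))$words, "ab")
  expect_error(decode_words(c("B", "E"), c("a")), "same length")
  # concatenation invariant over random label sequences, incl. malformed
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    labs <- sample(BMES_LABELS, n, replace = TRUE)
    txt <- sample(letters, n, replace = TRUE)
    dec <- decode_words(labs, txt)
    expect_equal(paste(dec$words, collapse = ""), paste(txt, collapse = ""))
  }
})

test_that("word feature vectors are normalized row-sums of character vectors", {
  fused <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0.25, 0.25, 0.25, 0.25))
  wq <- word_feature_vectors(fused, word_index = c(1, 1, 2))
  expect_equal(wq[, 1], c(0.5, 0.5, 0, 0))
  expect_equal(wq[, 2], c(0.25, 0.25, 0.25, 0.25))
  expect_equal(colSums(wq), c(1, 1))
  # single-character word is the identity
  wq1 <- word_feature_vectors(fused[, 1, drop = FALSE], 1)
  expect_equal(wq1[, 1], fused[, 1])
  expect_error(word_feature_vectors(fused[, 0, drop = FALSE], integer(0)),
               "empty word")
})

test_that("losses match closed forms and are bounded", {
  perfect <- matrix(rep(c(1, 0, 0, 0), 3), nrow = 4)
  expect_equal(segmentation_loss(perfect, c("B", "B", "B")), 0)
  uni <- matrix(0.25, nrow = 4, ncol = 5)
  expect_equal(segmentation_loss(uni, sample(BMES_LABELS, 5, replace = TRUE)), 0.75)
  two <- cbind(c(0.8, 0.1, 0.05, 0.05), c(0.2, 0.6, 0.1, 0.1))
  expect_equal(segmentation_loss(two, c("B", "M")), 0.3)
  uni7 <- matrix(1 / 7, nrow = 7, ncol = 4)
  expect_equal(entity_loss(uni7, rep("CL2", 4)), 6 / 7)
  expect_equal(total_loss(0.3, 0.5), 0.8)
  expect_error(segmentation_loss(uni, c("B", "B")), "length")
  # bounds on random fused matrices
  set.seed(9)
  for (rep in 1:10) {
    p <- matrix(stats::runif(4 * 6), nrow = 4)
    p <- sweep(p, 2, colSums(p), "/")
    l <- segmentation_loss(p, sample(BMES_LABELS, 6, replace = TRUE))
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("fit_ensemble_weights prefers a gold-faithful classifier and never worsens loss", {
  corpus <- tiny_corpus(q = c(0.98, 0.3, 0.3), n_docs = 6, seed = 4)
  fw <- fit_ensemble_weights(corpus)
  expect_true(fw$WS[1] > fw$WS[2] && fw$WS[1] > fw$WS[3])
  expect_true(all(fw$WS >= 0 & fw$WS <= 1))
  expect_true(all(diff(fw$trace) <= 1e-12))
  expect_lte(fw$trace[length(fw$trace)], fw$trace[1])
  # single classifier: loss is invariant to the weight scale
  co1 <- gen_emr_corpus(corpus_gen_spec(n_docs = 2, classifier_fidelity = 0.8,
                                        M = 1, N = 1, seed = 2))
  l_a <- cbrmatch:::corpus_loss(co1, 0.3, 0.3)
  l_b <- cbrmatch:::corpus_loss(co1, 0.9, 0.9)
  expect_equal(l_a, l_b)
  expect_error(fit_ensemble_weights(list()), "non-empty")
})

test_that("extract_key_data returns ordered numeric matches", {
  pats <- default_key_patterns()
  res <- extract_key_data("fasting blood glucose 7.2 mmol/L", pats)
  expect_equal(res$index, "fasting blood glucose")
  expect_equal(res$value, 7.2)
  expect_equal(nrow(extract_key_data("no labs mentioned", pats)), 0)
  two <- extract_key_data(
    "fasting blood glucose 7.2 then postprandial blood glucose 11.5", pats)
  expect_equal(two$index, c("fasting blood glucose", "postprandial blood glucose"))
  expect_equal(two$value, c(7.2, 11.5))
  expect_error(extract_key_data("x", c(bad = "glucose [0-9]+")), "capture group")
})

test_that("assemble_key_features merges by patient with last-wins duplicates", {
  kd <- data.frame(index = c("fasting blood glucose", "hba1c"),
                   value = c(7.2, 6.1))
  kt <- data.frame(span = c("diabetes", "thirst", "metformin"),
                   category = c("CL3", "CL4", "CL6"))
  rec <- assemble_key_features(kd, kt, "P1")
  expect_length(rec$key_data, 2)
  expect_equal(nrow(rec$key_text), 3)
  rec2 <- assemble_key_features(kd, NULL, "P1")
  expect_equal(nrow(rec2$key_text), 0)
  dup <- data.frame(index = rep("fasting blood glucose", 2), value = c(7.2, 7.4))
  expect_warning(rec3 <- assemble_key_features(dup, kt, "P1"), "duplicate")
  expect_equal(unname(rec3$key_data["fasting blood glucose"]), 7.4)
  expect_error(assemble_key_features(kd, kt, "P1", data_patient_id = "P2"),
               "mismatch")
})
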