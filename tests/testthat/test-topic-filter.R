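test_that("single-topic model degenerates to the smoothed unigram distribution", {
  docs <- list(c("a", "b", "b"), c("c", "a"), c("b"))
  m <- fit_lda(docs, lda_config(n_topics = 1, alpha = 1, beta = 0.01,
                                n_iter = 20, burn_in = 10))
  expect_true(all(m$doc_topic == 1))
  counts <- c(a = 2, b = 3, c = 1)
  expected <- (counts + 0.01) / (6 + 3 * 0.01)
  expect_equal(m$topic_word[1, names(counts)], expected, tolerance = 1e-12)
  # weight ranking equals corpus frequency ranking in the degenerate model
  tt <- top_terms(m, 1, n = 10)
  expect_identical(tt$term, c("b", "a", "c"))
  expect_identical(tt$count, c(3L, 2L, 1L))
})

test_that("gibbs sampling is deterministic and rows normalize", {
  tp <- two_topic_docs(50, seed = 2)
  cfg <- lda_config(n_topics = 3, alpha = 0.5, beta = 0.01,
                    n_iter = 60, burn_in = 20, seed = 9)
  m1 <- fit_lda(tp$docs, cfg)
  m2 <- fit_lda(tp$docs, cfg)
  expect_identical(m1$topic_word, m2$topic_word)
  expect_identical(m1$doc_topic, m2$doc_topic)
  expect_true(all(abs(rowSums(m1$doc_topic) - 1) < 1e-8))
  expect_true(all(abs(rowSums(m1$topic_word) - 1) < 1e-8))
  expect_true(all(m1$doc_topic >= 0) && all(m1$topic_word >= 0))
  expect_error(fit_lda(list(character(), character()), cfg),
               class = "eventpulse_validation_error")
})

test_that("a planted two-topic partition is recovered", {
  tp <- two_topic_docs(200, seed = 7)
  m <- fit_lda(tp$docs, lda_config(n_topics = 2, alpha = 0.1, beta = 0.01,
                                   n_iter = 200, burn_in = 100, seed = 3))
  planted1 <- setNames(rep(0, 40), c(tp$vocab1, tp$vocab2))
  planted1[tp$vocab1] <- 1 / 20
  planted2 <- setNames(rep(0, 40), c(tp$vocab1, tp$vocab2))
  planted2[tp$vocab2] <- 1 / 20
  tw <- m$topic_word[, names(planted1)]
  perm_id <- (cosine(tw[1, ], planted1) + cosine(tw[2, ], planted2)) / 2
  perm_sw <- (cosine(tw[1, ], planted2) + cosine(tw[2, ], planted1)) / 2
  expect_gte(max(perm_id, perm_sw), 0.95)
  # the top term of each matched topic belongs to its planted vocabulary
  match1 <- if (perm_id >= perm_sw) tp$vocab1 else tp$vocab2
  match2 <- if (perm_id >= perm_sw) tp$vocab2 else tp$vocab1
  expect_true(top_terms(m, 1, 1)$term %in% match1)
  expect_true(top_terms(m, 2, 1)$term %in% match2)

  # held-out fold-in: a doc of topic-exclusive words scores > 0.95 there
  ho <- list(sample(tp$vocab1, 20, TRUE))
  sc <- score_documents(m, ho, seed = 5)
  k1 <- if (perm_id >= perm_sw) 1L else 2L
  expect_gt(sc[1, k1], 0.95)
  expect_true(all(abs(rowSums(sc) - 1) < 1e-8))
})

test_that("empty held-out documents score uniformly and are flagged", {
  tp <- two_topic_docs(30, seed = 4)
  m <- fit_lda(tp$docs, lda_config(n_topics = 2, alpha = 0.1, beta = 0.01,
                                   n_iter = 50, burn_in = 20, seed = 1))
  expect_message(sc <- score_documents(m, list(character(), c("zzz"))),
                 "no in-vocabulary tokens")
  expect_equal(sc[1, ], c(topic_1 = 0.5, topic_2 = 0.5))
  expect_identical(attr(sc, "oov_docs"), c(1L, 2L))
})

test_that("topic filtering applies a sharp, monotone membership threshold", {
  records <- tibble::tibble(id = as.character(1:4))
  scores <- rbind(c(0.95, 0.05), c(0.949, 0.051), c(0.5, 0.5), c(0.2, 0.8))
  kept <- filter_by_topics(records, scores, topics = 1, threshold = 0.95)
  expect_identical(kept$id, "1")
  # membership sums over all selected topics
  kept2 <- filter_by_topics(records, scores, topics = c(1, 2), threshold = 0.95)
  expect_identical(kept2$id, as.character(1:4))
  # lowering the threshold can only grow the survivor set
  for (thr in c(0.9, 0.5, 0.2)) {
    expect_true(all(kept$id %in% filter_by_topics(records, scores, 1, thr)$id))
  }
  expect_error(filter_by_topics(records, scores, integer()),
               class = "eventpulse_validation_error")
})

test_that("a two-topic model beats a one-topic model on held-out perplexity", {
  tp <- two_topic_docs(150, seed = 11)
  cfg2 <- lda_config(n_topics = 2, alpha = 0.1, beta = 0.01,
                     n_iter = 150, burn_in = 50, seed = 2)
  cfg1 <- lda_config(n_topics = 1, alpha = 0.1, beta = 0.01,
                     n_iter = 150, burn_in = 50, seed = 2)
  m2 <- fit_lda(tp$docs, cfg2)
  m1 <- fit_lda(tp$docs, cfg1)
  ho <- withr::with_seed(12, {
    c(lapply(1:20, function(i) sample(tp$vocab1, 15, TRUE)),
      lapply(1:20, function(i) sample(tp$vocab2, 15, TRUE)))
  })
  expect_lt(lda_perplexity(m2, ho), lda_perplexity(m1, ho))
})

test_that("top_terms caps at vocabulary size and validates the topic index", {
  docs <- list(c("a", "b"), c("c"))
  m <- fit_lda(docs, lda_config(n_topics = 1, alpha = 1, beta = 0.01,
                                n_iter = 10, burn_in = 5))
  expect_identical(nrow(top_terms(m, 1, n = 99)), 3L)
  expect_error(top_terms(m, 2), class = "eventpulse_validation_error")
})

test_that("model serialization writes the documented directory layout", {
  tp <- two_topic_docs(20, seed = 5)
  m <- fit_lda(tp$docs, lda_config(n_topics = 2, alpha = 0.5, beta = 0.01,
                                   n_iter = 20, burn_in = 10))
  d <- withr::local_tempdir()
  write_lda_model(m, d)
  expect_true(all(file.exists(file.path(
    d, c("vocabulary.tsv", "topic_word.csv", "doc_topic.csv", "config.json")))))
  vv <- read.delim(file.path(d, "vocabulary.tsv"))
  expect_identical(vv$term, m$vocabulary)
})
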