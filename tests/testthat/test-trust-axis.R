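test_that("axis construction reproduces the analytic toy cases", {
  anchors1 <- tibble::tibble(positive = "good", negative = "bad")
  m1 <- toy_embedding(rbind(good = c(1, 0), bad = c(-1, 0)))
  expect_equal(build_trust_axis(m1, anchors1), c(1, 0))

  anchors2 <- tibble::tibble(positive = c("good", "fine"),
                             negative = c("bad", "awful"))
  m2 <- toy_embedding(rbind(good = c(1, 0), bad = c(-1, 0),
                            fine = c(3, 1), awful = c(3, -1)))
  expect_equal(build_trust_axis(m2, anchors2), c(1 / sqrt(2), 1 / sqrt(2)))

  # swapping the lists negates the axis exactly
  swapped <- tibble::tibble(positive = anchors2$negative,
                            negative = anchors2$positive)
  expect_equal(build_trust_axis(m2, swapped), -build_trust_axis(m2, anchors2))

  # pair order never matters
  expect_equal(build_trust_axis(m2, anchors2[2:1, ]),
               build_trust_axis(m2, anchors2))

  # OOV pairs are skipped with a message; all-OOV errors
  anchors3 <- tibble::tibble(positive = c("good", "missing"),
                             negative = c("bad", "gone"))
  expect_message(ax <- build_trust_axis(m2, anchors3), "skipped 1")
  expect_equal(ax, c(1, 0))
  expect_error(
    build_trust_axis(m2, tibble::tibble(positive = "x", negative = "y")),
    class = "eventpulse_validation_error"
  )
})

test_that("projection returns exact cosines, NA for OOV, and is rotation invariant", {
  m <- toy_embedding(rbind(good = c(1, 0), bad = c(-1, 0),
                           probe = c(0, 2), along = c(3, 0)))
  axis <- build_trust_axis(m, tibble::tibble(positive = "good", negative = "bad"))
  expect_equal(project_term(m, axis, "along"), 1)
  expect_equal(project_term(m, axis, "probe"), 0)
  expect_true(is.na(project_term(m, axis, "absent")))
  tab <- project_terms(m, axis, c("along", "absent"))
  expect_identical(tab$oov, c(FALSE, TRUE))

  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  mr <- toy_embedding(m$vectors %*% R)
  axr <- build_trust_axis(mr, tibble::tibble(positive = "good", negative = "bad"))
  expect_equal(project_term(mr, axr, "probe"), 0, tolerance = 1e-12)
  expect_equal(project_term(mr, axr, "along"), 1, tolerance = 1e-12)
})

test_that("embedding training is deterministic and separates co-occurrence clusters", {
  v1 <- paste0("red", 1:8); v2 <- paste0("blu", 1:8)
  docs <- withr::with_seed(3, {
    c(lapply(1:150, function(i) sample(v1, 10, TRUE)),
      lapply(1:150, function(i) sample(v2, 10, TRUE)))
  })
  cfg <- sgns_config(dim = 20, window = 4, negative = 5, epochs = 4,
                     min_count = 2, subsample = 0, seed = 9)
  m1 <- train_sgns(docs, cfg)
  m2 <- train_sgns(docs, cfg)
  expect_identical(m1$vectors, m2$vectors)

  V <- m1$vectors / sqrt(rowSums(m1$vectors^2))
  S <- V %*% t(V)
  in1 <- rownames(V) %in% v1
  within <- mean(S[in1, in1][upper.tri(S[in1, in1])])
  across <- mean(S[in1, !in1])
  expect_gt(within, across)

  # optimization makes progress over the early epochs
  expect_lt(m1$epoch_loss[4], m1$epoch_loss[1])
  expect_lt(m1$epoch_loss[2], m1$epoch_loss[1])

  # vocabulary respects the min-count filter
  docs2 <- c(docs, list(c("rareword", "red1")))
  m3 <- train_sgns(docs2, cfg)
  expect_false("rareword" %in% rownames(m3$vectors))
  expect_error(train_sgns(list(), cfg), class = "eventpulse_validation_error")
  expect_error(train_sgns(list(c("a", "b")), cfg),
               class = "eventpulse_validation_error")
})

test_that("period comparison handles identical corpora and one-sided vocabulary", {
  v <- c(trust_anchors()$positive[1:3], trust_anchors()$negative[1:3],
         "doctor", "filler1", "filler2")
  docs <- withr::with_seed(5, lapply(1:120, function(i) sample(v, 12, TRUE)))
  cfg <- sgns_config(dim = 16, window = 3, negative = 3, epochs = 2,
                     min_count = 2, subsample = 0, seed = 4)
  mA <- train_sgns(docs, cfg)
  mB <- train_sgns(docs, cfg)
  terms <- tibble::tibble(term = c("doctor", "pcp"), group = "clinician")
  suppressMessages(rep0 <- compare_periods(mA, mB, terms = terms))
  expect_identical(rep0$delta[1], 0)
  # a term absent pre but present post: no delta, post score reported
  expect_true(rep0$oov_pre[2] && rep0$oov_post[2])
  docs_post <- c(docs, withr::with_seed(6, lapply(1:20, function(i) {
    c("pcp", sample(v, 8, TRUE))
  })))
  mC <- train_sgns(docs_post, cfg)
  suppressMessages(rep1 <- compare_periods(mA, mC, terms = terms))
  expect_true(rep1$oov_pre[2])
  expect_false(rep1$oov_post[2])
  expect_true(is.na(rep1$delta[2]))
  expect_false(is.na(rep1$score_post[2]))
  td <- tidy(rep1)
  expect_identical(nrow(td), 4L)
})

test_that("planted anchor co-occurrence flips the projected trust score", {
  spec <- corpus_spec(
    seed = 77,
    pre_start = "2022-01-01", pre_end = "2022-02-28",
    post_start = "2022-03-01", post_end = "2022-04-30",
    base_daily_users = 10, engagement_multiplier = 1,
    trust_plants = dplyr::bind_rows(
      tibble::tibble(term = "doctor", period = "pre", polarity = "positive"),
      tibble::tibble(term = "doctor", period = "post", polarity = "negative")
    ),
    trust_excess = 0.8, duplicate_rate = 0
  )
  co <- generate_corpus(spec)
  tk <- tokenize_tweets(label_period(co$tweets, period_config(
    "2022-01-01", "2022-02-28", "2022-04-30")))
  cfg <- sgns_config(dim = 50, window = 5, negative = 5, epochs = 5,
                     min_count = 5, subsample = 0, seed = 1)
  mp <- train_sgns(tk[tk$period == "pre", ], cfg)
  mq <- train_sgns(tk[tk$period == "post", ], cfg)
  rp <- compare_periods(mp, mq)
  doctor <- rp[rp$term == "doctor", ]
  expect_gt(doctor$score_pre, 0)
  expect_lt(doctor$score_post, 0)
  expect_lt(doctor$delta, 0)
})

test_that("embeddings round-trip through the word2vec text format", {
  m <- toy_embedding(rbind(aa = c(0.25, -1.5, 3), bb = c(1e-3, 2, -0.125)))
  f <- withr::local_tempfile(fileext = ".txt")
  write_embeddings(m, f)
  back <- read_embeddings(f)
  expect_identical(rownames(back), c("aa", "bb"))
  expect_equal(unname(back), unname(m$vectors), tolerance = 1e-6)
})
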