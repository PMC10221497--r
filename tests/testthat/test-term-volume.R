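test_that("tfidf weights match hand computation and the ubiquity rule", {
  docs <- list(c("a", "b"), c("a"), c("c"))
  tf <- compute_tfidf(docs)
  expect_equal(as.numeric(tf$weights[1, "b"]), 1 * log(3))
  # a term in every document carries zero weight everywhere
  expect_equal(unname(tf$idf["a"]), log(3 / 2))
  docs2 <- list(c("x", "y"), c("x"), c("x", "z"))
  tf2 <- compute_tfidf(docs2)
  expect_true(all(tf2$weights[, "x"] == 0))
  # an empty document is an all-zero row
  tf3 <- compute_tfidf(list(c("a"), character()))
  expect_true(all(tf3$weights[2, ] == 0))
  expect_error(compute_tfidf(list()), class = "eventpulse_validation_error")
  td <- tidy(tf)
  expect_identical(td$term[td$document == 1], c("a", "b"))
})

test_that("tfidf equals the brute-force double loop on random small corpora", {
  for (seed in c(2, 3)) {
    docs <- withr::with_seed(seed, {
      lapply(1:50, function(i) sample(letters[1:10], sample(0:12, 1), TRUE))
    })
    tf <- compute_tfidf(docs)
    brute <- brute_force_tfidf(docs)
    expect_identical(colnames(tf$weights), colnames(brute))
    expect_equal(max(abs(as.matrix(tf$weights) - brute)), 0)
  }
})

test_that("polarity split partitions non-neutral records", {
  df <- tibble::tibble(
    id = as.character(1:3),
    sentiment = factor(c("negative", "neutral", "positive"),
                       c("negative", "neutral", "positive"))
  )
  sp <- split_by_polarity(df)
  expect_identical(sp$negative$id, "1")
  expect_identical(sp$positive$id, "3")
  expect_identical(nrow(sp$negative) + nrow(sp$positive), 2L)
  all_neutral <- df[2, ]
  sp2 <- split_by_polarity(all_neutral)
  expect_identical(nrow(sp2$negative), 0L)
  expect_identical(nrow(sp2$positive), 0L)
})

make_volume_corpus <- function() {
  tibble::tibble(
    id = as.character(1:8),
    tokens = list(
      c("doctor", "visit"), c("doctor", "hipaa"), c("hipaa", "law"),
      c("doctor", "law"), c("doctor", "hipaa"), c("hipaa", "x"),
      c("doctor", "y"), c("law", "z")
    ),
    sentiment = factor(
      c("negative", "positive", "negative", "positive",
        "negative", "positive", "negative", "neutral"),
      c("negative", "neutral", "positive")),
    period = factor(c("pre", "pre", "pre", "pre", "post", "post", "post", "post"),
                    c("pre", "post"))
  )
}

test_that("volume counts match a manual tally and standardize per polarity panel", {
  terms <- tibble::tibble(term = c("doctor", "hipaa"), group = "probe")
  vt <- volume_table(make_volume_corpus(), terms)
  expect_identical(nrow(vt), 8L)
  get <- function(tm, per, pol) {
    vt$count[vt$term == tm & vt$period == per & vt$polarity == pol]
  }
  expect_identical(get("doctor", "pre", "negative"), 1L)
  expect_identical(get("doctor", "pre", "positive"), 2L)
  expect_identical(get("doctor", "post", "negative"), 2L)
  expect_identical(get("hipaa", "post", "positive"), 1L)
  for (pol in c("negative", "positive")) {
    z <- vt$zscore[vt$polarity == pol]
    expect_lt(abs(mean(z)), 1e-12)
    expect_equal(sd(z), 1)
  }
  # invariant to record order
  vt2 <- volume_table(make_volume_corpus()[sample(8), ], terms)
  expect_identical(as.data.frame(vt), as.data.frame(vt2))
  # unseen terms appear with zero counts
  terms3 <- tibble::tibble(term = c("doctor", "ghost"), group = "probe")
  vt3 <- volume_table(make_volume_corpus(), terms3)
  expect_true(all(vt3$count[vt3$term == "ghost"] == 0L))
})

test_that("constant panels map to all-zero scores and inflating post counts raises post z", {
  df <- make_volume_corpus()
  terms <- tibble::tibble(term = "doctor", group = "probe")
  one_each <- tibble::tibble(
    id = as.character(1:4),
    tokens = list("doctor", "doctor", "doctor", "doctor"),
    sentiment = factor(c("negative", "negative", "positive", "positive"),
                       c("negative", "neutral", "positive")),
    period = factor(c("pre", "post", "pre", "post"), c("pre", "post"))
  )
  vt0 <- volume_table(one_each, terms)
  expect_true(all(vt0$zscore == 0))

  terms2 <- tibble::tibble(term = c("doctor", "hipaa"), group = "probe")
  base <- volume_table(df, terms2)
  boosted <- dplyr::bind_rows(df, df[df$period == "post", ], df[df$period == "post", ])
  vt_b <- volume_table(boosted, terms2)
  gap <- function(v) {
    mean(v$zscore[v$period == "post"]) - mean(v$zscore[v$period == "pre"])
  }
  expect_gt(gap(vt_b), gap(base))
})

test_that("exemplar selection ranks by weight, keeps ties, drops URLs, shrinks with quantile", {
  tweets <- tibble::tibble(
    id = c(sprintf("t%02d", 1:20), "t21"),
    text = c(paste("doctor filler", sprintf("w%02d", 1:19)),
             "doctor spam http://link.example",
             "nothing relevant here")
  )
  tweets$text[1:19] <- paste(tweets$text[1:19],
                             sapply(1:19, function(i) {
                               paste(rep("doctor", i - 1), collapse = " ")
                             }))
  tok <- tokenize_tweets(tweets)
  tf <- compute_tfidf(tok)
  # 19 distinct weights after URL exclusion: the 0.95 quantile keeps the top one
  ex <- select_exemplars(tf, tok, "doctor", quantile = 0.95)
  expect_identical(ex$id, "t19")
  # monotone: lower quantiles keep supersets
  ex50 <- select_exemplars(tf, tok, "doctor", quantile = 0.50)
  expect_true(all(ex$id %in% ex50$id))
  expect_gte(nrow(ex50), nrow(ex))
  # URL post excluded regardless of weight
  expect_false("t20" %in% ex50$id)
  # equal weights: everyone survives at any quantile (ties kept at the cut)
  eq <- tibble::tibble(id = as.character(1:5),
                       text = rep("doctor alone here", 5))
  eqt <- tokenize_tweets(eq)
  tfe <- compute_tfidf(eqt)
  expect_identical(nrow(select_exemplars(tfe, eqt, "doctor", 0.99)), 5L)
  # OOV term: empty result with a warning
  expect_warning(none <- select_exemplars(tfe, eqt, "ghost"), "not in vocabulary")
  expect_identical(nrow(none), 0L)
})
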