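test_that("identical spec and seed reproduce the corpus byte for byte", {
  c1 <- generate_corpus(small_spec(seed = 42))
  c2 <- generate_corpus(small_spec(seed = 42))
  expect_identical(c1, c2)
  c3 <- generate_corpus(small_spec(seed = 43))
  expect_false(identical(c1$tweets$text, c3$tweets$text))
})

test_that("record bookkeeping: conservation, unique ids, shared duplicate labels", {
  co <- generate_corpus(small_spec(seed = 3, duplicate_rate = 0.2))
  labels <- co$truth$labels
  expect_identical(nrow(co$tweets), nrow(labels))
  expect_false(any(duplicated(labels$id)))
  n_dup <- sum(!is.na(labels$duplicate_of))
  expect_identical(nrow(co$tweets), (nrow(co$tweets) - n_dup) + n_dup)
  # each duplicate carries the originating record's planted labels and text
  dups <- labels[!is.na(labels$duplicate_of), ]
  src <- labels[match(dups$duplicate_of, labels$id), ]
  expect_identical(dups$topic, src$topic)
  expect_identical(dups$sentiment, src$sentiment)
  texts <- setNames(co$tweets$text, co$tweets$id)
  expect_identical(unname(texts[dups$id]), unname(texts[dups$duplicate_of]))
})

test_that("with duplicate_rate zero deduplication leaves the corpus unchanged", {
  co <- generate_corpus(small_spec(seed = 5, duplicate_rate = 0))
  expect_true(all(is.na(co$truth$labels$duplicate_of)))
  expect_identical(nrow(deduplicate_tweets(co$tweets)), nrow(co$tweets))
})

test_that("daily unique users follow the stepped Poisson intensity", {
  # 40 pre days at 50/day and a x6 step, checked against the Poisson SE;
  # the empirical post/pre mean ratio must sit within 3 SE of 6
  spec <- corpus_spec(
    seed = 11,
    pre_start = "2020-01-01", pre_end = "2020-04-09",
    post_start = "2020-04-10", post_end = "2020-07-18",
    base_daily_users = 50, engagement_multiplier = 6
  )
  co <- generate_corpus(spec)
  du <- co$truth$daily_users
  expect_identical(nrow(du), 200L)
  pre <- du$users[du$period == "pre"]
  post <- du$users[du$period == "post"]
  # mean within 4 SE of the configured intensity in each period
  expect_lt(abs(mean(pre) - 50), 4 * sqrt(50 / 100))
  expect_lt(abs(mean(post) - 300), 4 * sqrt(300 / 100))
  ratio <- mean(post) / mean(pre)
  se_ratio <- ratio * sqrt(1 / sum(post) + 1 / sum(pre))
  expect_lt(abs(ratio - 6), 3 * se_ratio)
  # generated daily user counts match distinct generated users per day
  users_per_day <- tapply(co$truth$labels$user_id, co$truth$labels$date,
                          function(u) length(unique(u)))
  expect_identical(as.integer(users_per_day[as.character(du$date)]),
                   as.integer(du$users))
})

test_that("trust planting inserts anchor co-occurrence at the excess rate", {
  tokens <- c("the", "doctor", "said", "so", "doctor", "here")
  expect_identical(
    plant_trust_cooccurrence(tokens, "doctor", "positive", rate = 0),
    tokens
  )
  expect_identical(
    plant_trust_cooccurrence(character(), "doctor", "positive"),
    character()
  )
  expect_error(
    plant_trust_cooccurrence(tokens, "doctor", "sideways"),
    class = "eventpulse_validation_error"
  )
  anchors <- trust_anchors()
  count_cooc <- function(toks, window = 3L) {
    hits <- which(toks == "doctor")
    sum(vapply(hits, function(h) {
      lo <- max(1L, h - window); hi <- min(length(toks), h + window)
      sum(toks[lo:hi] %in% anchors$positive)
    }, numeric(1)))
  }
  withr::with_seed(99, {
    planted <- replicate(50, count_cooc(
      plant_trust_cooccurrence(tokens, "doctor", "positive", rate = 1)))
  })
  expect_gt(sum(planted), count_cooc(tokens) * 50)
  # positive planting never inserts negative anchors
  withr::with_seed(1, {
    out <- plant_trust_cooccurrence(tokens, "doctor", "positive", rate = 1)
  })
  expect_false(any(out %in% anchors$negative))
  expect_true(any(out %in% anchors$positive))
})

test_that("invalid specs fail naming the offending field", {
  expect_error(small_spec(base_daily_users = 0), "base_daily_users",
               class = "eventpulse_validation_error")
  expect_error(small_spec(duplicate_rate = 1.5), "duplicate_rate",
               class = "eventpulse_validation_error")
  expect_error(
    small_spec(sentiment_probs = list(pre = c(0.5, 0.4, 0.2),
                                      post = c(0.45, 0.40, 0.15))),
    "sentiment_probs", class = "eventpulse_validation_error"
  )
  expect_error(
    corpus_spec(pre_start = "2022-05-01", pre_end = "2022-04-01"),
    "pre_end", class = "eventpulse_validation_error"
  )
  expect_error(
    small_spec(trust_plants = tibble::tibble(
      term = "notavocabword", period = "pre", polarity = "positive")),
    "trust_plants", class = "eventpulse_validation_error"
  )
})

test_that("corpus JSONL and ground-truth sidecar round-trip", {
  co <- generate_corpus(small_spec(seed = 8))
  f <- withr::local_tempfile(fileext = ".jsonl")
  g <- withr::local_tempfile(fileext = ".json")
  write_corpus_jsonl(co$tweets, f)
  write_ground_truth(co, g)
  back <- read_corpus_jsonl(f)
  expect_identical(back$id, co$tweets$id)
  expect_identical(back$text, co$tweets$text)
  truth <- jsonlite::read_json(g)
  expect_length(truth$labels, nrow(co$tweets))
})
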