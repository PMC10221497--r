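#' Anchor word pairs spanning the trust dimension
#'
#' Seven antonym pairs; pair `i` of the positive list is matched with pair
#' `i` of the negative list. These are the default anchors both for the
#' semantic-axis construction and for the synthetic generator's planted
#' co-occurrence.
#'
#' @return A tibble with columns `positive` and `negative`.
#' @export
trust_anchors <- function() {
  tibble(
    positive = c("trust", "trustworthy", "faith", "reliable",
                 "confidence", "certainty", "conviction"),
    negative = c("mistrust", "untrustworthy", "distrust", "unreliable",
                 "skepticism", "uncertainty", "doubt")
  )
}

#' Target terms projected onto the trust dimension
#'
#' Clinician-related and health-information-related unigrams; `"healthcare"`
#' is carried in the clinician group as a system-level trust probe.
#'
#' @return A tibble with columns `term` and `group`.
#' @export
trust_terms <- function() {
  tibble(
    term = c("doctor", "provider", "physician", "nurse", "ob", "gyn",
             "obgyn", "pcp", "healthcare",
             "app", "information", "periodtracking", "tracking",
             "phi", "hipaa", "data"),
    group = rep(c("clinician", "health_information"), c(9L, 7L))
  )
}

#' Sentiment marker lexicon used by the synthetic generator
#'
#' Three disjoint marker sets. The generator stamps exactly one marker of
#' the planted label's set into each synthetic post, which makes the default
#' lexicon classifier exact on synthetic corpora.
#'
#' @return A named list of character vectors (`negative`, `neutral`,
#'   `positive`).
#' @export
sentiment_markers <- function() {
  list(
    negative = c("angry", "afraid", "outraged", "betrayed", "horrified"),
    neutral  = c("update", "report", "note", "statement", "thread"),
    positive = c("hopeful", "grateful", "relieved", "reassured", "encouraged")
  )
}

#' Default planted topic vocabularies
#'
#' Five topics: a policy/legality topic and a health-privacy topic (the two
#' an operator would select downstream), one confounder topic, and two
#' trust-talk topics carrying the positive and negative anchor words so both
#' poles of the trust axis are attested in every period.
#'
#' @return A named list of character vectors.
#' @export
default_topic_vocab <- function() {
  anchors <- trust_anchors()
  list(
    policy_legality = c("roe", "wade", "dobbs", "court", "state", "law",
                        "constitution", "ruling", "legal", "ban", "rights",
                        "supreme", "opinion", "draft", "decision", "abortion",
                        "overturn", "precedent", "justice", "vote"),
    health_privacy = c("privacy", "hipaa", "phi", "data", "app", "tracking",
                       "doctor", "nurse", "provider", "physician", "ob",
                       "gyn", "obgyn", "pcp", "healthcare", "information",
                       "periodtracking", "health", "record", "share",
                       "period", "private"),
    confounder_music = c("michael", "jackson", "music", "song", "album",
                         "concert", "dance", "pop", "thriller", "tour",
                         "stage", "guitar", "lyrics", "band", "fans"),
    trust_positive_talk = c(anchors$positive, "always", "respect", "good",
                            "safe", "honest"),
    trust_negative_talk = c(anchors$negative, "never", "worry", "bad",
                            "unsafe", "dishonest")
  )
}

#' Default planted trust directives
#'
#' Emulates the qualitative pre/post pattern reported for the study system:
#' clinician terms that start with a positive trust connotation flip to
#' negative after the boundary; terms already negative stay negative.
#'
#' @return A tibble with columns `term`, `period`, `polarity`.
#' @export
default_trust_plants <- function() {
  pos_pre <- c("doctor", "physician", "ob", "app", "information", "data")
  neg_pre <- c("nurse", "provider", "healthcare", "hipaa", "tracking", "phi")
  dplyr::bind_rows(
    tibble(term = pos_pre, period = "pre", polarity = "positive"),
    tibble(term = neg_pre, period = "pre", polarity = "negative"),
    tibble(term = c(pos_pre, neg_pre), period = "post", polarity = "negative")
  )
}

#' Specification of a synthetic tweet corpus
#'
#' Defines the study window (a pre period and a post period separated by a
#' known boundary), a Poisson daily unique-user intensity with an optional
#' multiplicative step at the boundary, a per-period topic mixture, planted
#' per-post sentiment labels with an optional post-period shift, planted
#' trust co-occurrence directives, and a verbatim-duplicate rate.
#'
#' Default engagement and sentiment settings emulate the study conditions at
#' desk scale: a x6.77 step in daily users at the boundary, and per-period
#' sentiment probabilities whose expected encoded scores are 0.44 (pre) and
#' 0.35 (post).
#'
#' @param seed Integer RNG seed; a single stream drives all sampling.
#' @param pre_start,pre_end,post_start,post_end Period dates,
#'   `pre_start <= pre_end < post_start <= post_end`.
#' @param base_daily_users Mean unique users per pre-period day (Poisson).
#' @param engagement_multiplier Multiplicative step applied to the daily
#'   intensity in the post period.
#' @param tweets_per_user Mean posts per active user per day; each active
#'   user posts `1 + Poisson(tweets_per_user - 1)` times, so must be >= 1.
#' @param topic_vocab Named list of word vectors, one per planted topic.
#' @param topic_mix Named list with `pre` and `post` probability vectors
#'   over the topics (each sums to 1).
#' @param sentiment_probs Named list with `pre` and `post` probability
#'   vectors over (negative, neutral, positive).
#' @param trust_plants Tibble of directives (`term`, `period`,
#'   `polarity` in `"positive"`/`"negative"`); see
#'   [plant_trust_cooccurrence()].
#' @param duplicate_rate Probability a post is emitted twice verbatim.
#' @param trust_excess Probability a directive fires on a post containing
#'   its target term.
#' @param trust_window Maximum token offset at which planted anchor words
#'   are inserted after the target term.
#' @param anchors Anchor pairs used by the trust plants.
#' @param mean_tokens Mean number of topic tokens per post.
#' @return A validated list of class `corpus_spec`.
#' @export
corpus_spec <- function(seed = 1L,
                        pre_start = "2020-01-01", pre_end = "2022-05-01",
                        post_start = "2022-05-02", post_end = "2022-10-17",
                        base_daily_users = 30,
                        engagement_multiplier = 6.77,
                        tweets_per_user = 1.3,
                        topic_vocab = default_topic_vocab(),
                        topic_mix = list(
                          pre  = c(policy_legality = 0.35, health_privacy = 0.25,
                                   confounder_music = 0.10, trust_positive_talk = 0.15,
                                   trust_negative_talk = 0.15),
                          post = c(policy_legality = 0.33, health_privacy = 0.27,
                                   confounder_music = 0.05, trust_positive_talk = 0.12,
                                   trust_negative_talk = 0.23)
                        ),
                        sentiment_probs = list(
                          pre  = c(negative = 0.32, neutral = 0.48, positive = 0.20),
                          post = c(negative = 0.45, neutral = 0.40, positive = 0.15)
                        ),
                        trust_plants = default_trust_plants(),
                        duplicate_rate = 0.05,
                        trust_excess = 0.8,
                        trust_window = 2L,
                        anchors = trust_anchors(),
                        mean_tokens = 10) {
  spec <- list(
    seed = as.integer(seed),
    pre_start = as.Date(pre_start), pre_end = as.Date(pre_end),
    post_start = as.Date(post_start), post_end = as.Date(post_end),
    base_daily_users = base_daily_users,
    engagement_multiplier = engagement_multiplier,
    tweets_per_user = tweets_per_user,
    topic_vocab = topic_vocab,
    topic_mix = lapply(topic_mix, function(p) p / 1),
    sentiment_probs = sentiment_probs,
    trust_plants = as_tibble(trust_plants),
    duplicate_rate = duplicate_rate,
    trust_excess = trust_excess,
    trust_window = as.integer(trust_window),
    anchors = anchors,
    mean_tokens = mean_tokens
  )
  validate_corpus_spec(spec)
  structure(spec, class = "corpus_spec")
}

validate_corpus_spec <- function(spec) {
  validate_that(spec$pre_start <= spec$pre_end, "pre_end", "must be >= pre_start")
  validate_that(spec$pre_end < spec$post_start, "post_start", "must be after pre_end")
  validate_that(spec$post_start <= spec$post_end, "post_end", "must be >= post_start")
  validate_that(spec$base_daily_users > 0, "base_daily_users", "must be positive")
  validate_that(spec$engagement_multiplier > 0, "engagement_multiplier", "must be positive")
  validate_that(spec$tweets_per_user >= 1, "tweets_per_user", "must be >= 1")
  validate_that(spec$duplicate_rate >= 0 && spec$duplicate_rate <= 1,
                "duplicate_rate", "must be in [0, 1]")
  validate_that(spec$trust_excess >= 0 && spec$trust_excess <= 1,
                "trust_excess", "must be in [0, 1]")
  validate_that(spec$trust_window >= 1, "trust_window", "must be >= 1")
  validate_that(length(spec$topic_vocab) >= 1 && all(lengths(spec$topic_vocab) > 0),
                "topic_vocab", "must contain at least one nonempty topic")
  for (per in c("pre", "post")) {
    mix <- spec$topic_mix[[per]]
    validate_that(!is.null(mix) && length(mix) == length(spec$topic_vocab),
                  "topic_mix", sprintf("%s mixture must have one entry per topic", per))
    validate_that(abs(sum(mix) - 1) < 1e-9 && all(mix >= 0),
                  "topic_mix", sprintf("%s mixture must be a probability vector", per))
    sp <- spec$sentiment_probs[[per]]
    validate_that(!is.null(sp) && length(sp) == 3L,
                  "sentiment_probs", sprintf("%s must have 3 entries", per))
    validate_that(abs(sum(sp) - 1) < 1e-9 && all(sp >= 0),
                  "sentiment_probs", sprintf("%s must be a probability vector", per))
  }
  if (nrow(spec$trust_plants) > 0) {
    validate_that(all(spec$trust_plants$polarity %in% c("positive", "negative")),
                  "trust_plants", "polarity must be 'positive' or 'negative'")
    validate_that(all(spec$trust_plants$period %in% c("pre", "post")),
                  "trust_plants", "period must be 'pre' or 'post'")
    vocab_words <- unique(unlist(spec$topic_vocab))
    validate_that(all(spec$trust_plants$term %in% vocab_words),
                  "trust_plants", "every target term must occur in the topic vocabulary")
  }
  invisible(TRUE)
}

#' Insert anchor-word co-occurrence around a target term
#'
#' For every occurrence of `term` in `tokens`, with probability `rate`,
#' inserts `n_insert` words drawn from the directed anchor list (positive
#' anchors for `polarity = "positive"`, negative anchors otherwise) at a
#' random offset of at most `window` tokens after the occurrence.
#'
#' @param tokens Character vector of tokens.
#' @param term Target term.
#' @param polarity `"positive"` or `"negative"`.
#' @param anchors Anchor-pair tibble as from [trust_anchors()].
#' @param rate Excess co-occurrence rate in `[0, 1]`; `rate = 0` returns the
#'   input unchanged.
#' @param window Maximum insertion offset (tokens).
#' @param n_insert Anchor words inserted per firing occurrence.
#' @return The token vector with any planted anchor words inserted.
#' @export
plant_trust_cooccurrence <- function(tokens, term, polarity,
                                     anchors = trust_anchors(),
                                     rate = 1, window = 2L, n_insert = 2L) {
  validate_that(polarity %in% c("positive", "negative"), "polarity",
                "must be 'positive' or 'negative'")
  if (length(tokens) == 0L || rate <= 0) return(tokens)
  pool <- anchors[[polarity]]
  hits <- which(tokens == term)
  if (length(hits) == 0L) return(tokens)
  out <- tokens
  # process occurrences right-to-left so earlier indices stay valid
  for (pos in rev(hits)) {
    if (runif(1) >= rate) next
    ins <- sample(pool, n_insert, replace = TRUE)
    at <- min(pos + sample.int(window, 1L) - 1L, length(out))
    out <- append(out, ins, after = at)
  }
  out
}

#' Generate a synthetic tweet corpus with planted ground truth
#'
#' Draws, for every calendar day in the configured windows, a Poisson number
#' of unique users (intensity stepped by `engagement_multiplier` after the
#' boundary); each user posts one or more tweets whose text is sampled from
#' a planted topic vocabulary, stamped with one sentiment marker token, and
#' optionally enriched with anchor-word co-occurrence per the trust
#' directives. A configurable fraction of posts is re-emitted verbatim under
#' a fresh id to exercise deduplication. A single seeded RNG stream drives
#' all sampling, so output is deterministic given the spec.
#'
#' @param spec A [corpus_spec()].
#' @return A list of class `synthetic_corpus` with elements
#'   \describe{
#'     \item{tweets}{tibble `id`, `timestamp` (POSIXct UTC), `user_id`, `text`.}
#'     \item{truth}{list with `daily_users` (tibble `date`, `period`, `users`),
#'       `labels` (tibble `id`, `user_id`, `date`, `period`, `topic`,
#'       `sentiment`, `duplicate_of`), and `trust_plants` (the directives).}
#'   }
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  validate_corpus_spec(spec)
  markers <- sentiment_markers()
  topics <- names(spec$topic_vocab)
  sent_levels <- c("negative", "neutral", "positive")

  with_seed(spec$seed, {
    days <- c(seq(spec$pre_start, spec$pre_end, by = "day"),
              seq(spec$post_start, spec$post_end, by = "day"))
    periods <- ifelse(days <= spec$pre_end, "pre", "post")
    lambda <- ifelse(periods == "pre", spec$base_daily_users,
                     spec$base_daily_users * spec$engagement_multiplier)
    n_users_day <- rpois(length(days), lambda)

    daily_users <- tibble(date = days, period = factor(periods, c("pre", "post")),
                          users = n_users_day)

    rows <- vector("list", sum(n_users_day) * 2L)
    k <- 0L
    tid <- 0L
    for (d in seq_along(days)) {
      per <- periods[d]
      nu <- n_users_day[d]
      if (nu == 0L) next
      mix <- spec$topic_mix[[per]]
      sp <- spec$sentiment_probs[[per]]
      plants <- spec$trust_plants[spec$trust_plants$period == per, , drop = FALSE]
      day0 <- as.POSIXct(paste(days[d], "00:00:00"), tz = "UTC")
      for (u in seq_len(nu)) {
        uid <- sprintf("u%s-%04d", format(days[d], "%Y%m%d"), u)
        n_tw <- 1L + rpois(1L, spec$tweets_per_user - 1)
        for (tw in seq_len(n_tw)) {
          tid <- tid + 1L
          topic <- sample(topics, 1L, prob = mix)
          sent <- sample(sent_levels, 1L, prob = sp)
          n_tok <- max(4L, rpois(1L, spec$mean_tokens))
          toks <- sample(spec$topic_vocab[[topic]], n_tok, replace = TRUE)
          toks <- append(toks, sample(markers[[sent]], 1L),
                         after = sample.int(length(toks) + 1L, 1L) - 1L)
          if (nrow(plants) > 0) {
            for (j in seq_len(nrow(plants))) {
              toks <- plant_trust_cooccurrence(
                toks, plants$term[j], plants$polarity[j],
                anchors = spec$anchors, rate = spec$trust_excess,
                window = spec$trust_window
              )
            }
          }
          k <- k + 1L
          rows[[k]] <- list(
            id = sprintf("t%08d", tid),
            timestamp = day0 + floor(runif(1L, 0, 86400)),
            user_id = uid, text = paste(toks, collapse = " "),
            date = days[d], period = per, topic = topic, sentiment = sent,
            duplicate_of = NA_character_
          )
          if (spec$duplicate_rate > 0 && runif(1L) < spec$duplicate_rate) {
            tid <- tid + 1L
            k <- k + 1L
            dup <- rows[[k - 1L]]
            dup$duplicate_of <- dup$id
            dup$id <- sprintf("t%08d", tid)
            dup$timestamp <- dup$timestamp + 1
            rows[[k]] <- dup
          }
        }
      }
    }
    rows <- rows[seq_len(k)]

    labels <- tibble(
      id = vapply(rows, `[[`, character(1), "id"),
      user_id = vapply(rows, `[[`, character(1), "user_id"),
      date = as.Date(vapply(rows, function(r) as.character(r$date), character(1))),
      period = factor(vapply(rows, `[[`, character(1), "period"), c("pre", "post")),
      topic = vapply(rows, `[[`, character(1), "topic"),
      sentiment = vapply(rows, `[[`, character(1), "sentiment"),
      duplicate_of = vapply(rows, `[[`, character(1), "duplicate_of")
    )
    tweets <- tibble(
      id = labels$id,
      timestamp = as.POSIXct(vapply(rows, function(r) as.numeric(r$timestamp), numeric(1)),
                             origin = "1970-01-01", tz = "UTC"),
      user_id = labels$user_id,
      text = vapply(rows, `[[`, character(1), "text")
    )

    structure(
      list(tweets = tweets,
           truth = list(daily_users = daily_users, labels = labels,
                        trust_plants = spec$trust_plants)),
      class = "synthetic_corpus"
    )
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  n_dup <- sum(!is.na(x$truth$labels$duplicate_of))
  cat(sprintf("<synthetic_corpus> %d posts (%d verbatim duplicates), %d days\n",
              nrow(x$tweets), n_dup, nrow(x$truth$daily_users)))
  invisible(x)
}

#' Write the ground-truth sidecar of a synthetic corpus
#'
#' @param corpus A `synthetic_corpus`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(corpus, path) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  truth <- corpus$truth
  out <- list(
    daily_users = lapply(seq_len(nrow(truth$daily_users)), function(i) {
      list(date = as.character(truth$daily_users$date[i]),
           period = as.character(truth$daily_users$period[i]),
           users = truth$daily_users$users[i])
    }),
    labels = lapply(seq_len(nrow(truth$labels)), function(i) {
      r <- truth$labels[i, ]
      list(id = r$id, date = as.character(r$date), period = as.character(r$period),
           topic = r$topic, sentiment = r$sentiment,
           duplicate_of = if (is.na(r$duplicate_of)) NULL else r$duplicate_of)
    }),
    trust_plants = truth$trust_plants
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
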