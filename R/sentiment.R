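#' Marker-lexicon sentiment classifier
#'
#' The shipping default of the pluggable classifier contract: a function that
#' maps a character vector of texts to an `n x 3` probability matrix over
#' (negative, neutral, positive). Probabilities are marker-token counts with
#' a small symmetric smoothing, so a text with no markers is exactly uniform
#' (and classifies as neutral under the tie rule). On synthetic corpora,
#' where each post carries exactly one marker of its planted label's set,
#' the classifier is exact.
#'
#' Any function with the same signature and a row-stochastic output can be
#' plugged into [classify_sentiment()] in its place (e.g. a wrapper around a
#' transformer sentiment model).
#'
#' @param markers Named list of `negative`, `neutral`, `positive` marker
#'   token sets (default [sentiment_markers()]).
#' @param smoothing Symmetric pseudo-count added to each label.
#' @return A function `texts -> n x 3 matrix` of class
#'   `c("lexicon_classifier", "sentiment_classifier", "function")`.
#' @export
lexicon_classifier <- function(markers = sentiment_markers(), smoothing = 0.01) {
  force(markers); force(smoothing)
  f <- function(texts) {
    toks <- tokenize_text(texts)
    counts <- vapply(toks, function(tk) {
      c(sum(tk %in% markers$negative),
        sum(tk %in% markers$neutral),
        sum(tk %in% markers$positive))
    }, numeric(3))
    counts <- t(counts) + smoothing
    probs <- counts / rowSums(counts)
    colnames(probs) <- c("negative", "neutral", "positive")
    probs
  }
  class(f) <- c("lexicon_classifier", "sentiment_classifier", "function")
  f
}

# argmax with ties broken toward neutral, then negative
sentiment_label <- function(probs) {
  labs <- c("negative", "neutral", "positive")
  pref <- c("neutral", "negative", "positive")
  apply(probs, 1L, function(p) {
    cand <- labs[p >= max(p) - 1e-12]
    pref[pref %in% cand][1L]
  })
}

#' Classify per-post sentiment and encode it ordinally
#'
#' Applies a pluggable classifier (text -> probability 3-vector), takes the
#' argmax label with ties broken toward neutral then negative, and encodes
#' labels as negative = 0, neutral = 0.5, positive = 1.0.
#'
#' @param tweets A data frame with a `text` column.
#' @param classifier A classifier as from [lexicon_classifier()] (any
#'   function mapping a character vector to a row-stochastic `n x 3`
#'   matrix).
#' @return The input as a tibble with columns `p_negative`, `p_neutral`,
#'   `p_positive`, `sentiment` (factor), and `encoded` appended.
#' @export
classify_sentiment <- function(tweets, classifier = lexicon_classifier()) {
  out <- as_tibble(tweets)
  probs <- classifier(out$text)
  if (!is.matrix(probs) || ncol(probs) != 3L || nrow(probs) != nrow(out) ||
      any(!is.finite(probs)) || any(probs < -1e-12) ||
      any(abs(rowSums(probs) - 1) > 1e-8)) {
    abort("classifier contract violation: output must be an n x 3 row-stochastic matrix",
          class = "eventpulse_contract_error")
  }
  lab <- sentiment_label(probs)
  out$p_negative <- probs[, 1L]
  out$p_neutral <- probs[, 2L]
  out$p_positive <- probs[, 3L]
  out$sentiment <- factor(lab, levels = c("negative", "neutral", "positive"))
  out$encoded <- unname(c(negative = 0, neutral = 0.5, positive = 1)[lab])
  out
}

#' Construct a daily series
#'
#' Validates the regular-grid contract used by the counterfactual model:
#' strictly increasing gap-free daily dates and a single pre/post boundary.
#'
#' @param df A data frame with `date`, `value`, `period` columns.
#' @param kind `"sentiment"` or `"engagement"` (metadata only).
#' @return A tibble of class `daily_series` with attribute `kind`.
#' @export
as_daily_series <- function(df, kind = c("sentiment", "engagement")) {
  kind <- match.arg(kind)
  out <- as_tibble(df)[, c("date", "value", "period")]
  stopifnot(inherits(out$date, "Date"))
  validate_that(!is.unsorted(out$date, strictly = TRUE) &&
                  all(diff(as.integer(out$date)) == 1L),
                "date", "must be a gap-free daily grid")
  validate_that(all(out$period %in% c("pre", "post")), "period", "must be pre/post")
  per <- as.character(out$period)
  validate_that(!is.unsorted(match(per, c("pre", "post"))),
                "period", "pre must precede post")
  if (kind == "sentiment") {
    validate_that(all(out$value >= 0 & out$value <= 1), "value", "sentiment must lie in [0, 1]")
  } else {
    validate_that(all(out$value >= 0), "value", "engagement must be nonnegative")
  }
  out$period <- factor(per, levels = c("pre", "post"))
  structure(out, class = c("daily_series", class(out)), kind = kind)
}

# full daily grid + period factor from labeled records
daily_grid <- function(dates, periods) {
  boundary <- max(dates[periods == "pre"])
  grid <- seq(min(dates), max(dates), by = "day")
  tibble(date = grid,
         period = factor(ifelse(grid <= boundary, "pre", "post"), c("pre", "post")))
}

#' Daily mean encoded sentiment
#'
#' Averages encoded sentiment scores per UTC day. Days with no posts are
#' filled by linear interpolation between neighboring observed days (the
#' counterfactual model requires a regular grid); leading/trailing gaps take
#' the nearest observed value.
#'
#' @param tweets Classified, period-labeled records (columns `encoded`,
#'   `date`, `period`).
#' @return A `daily_series` tibble (`date`, `value`, `period`).
#' @export
daily_sentiment <- function(tweets) {
  if (nrow(tweets) == 0L) abort("no records to aggregate")
  stopifnot(all(c("encoded", "date", "period") %in% names(tweets)))
  obs <- as_tibble(tweets) %>%
    dplyr::group_by(.data$date) %>%
    dplyr::summarise(value = mean(.data$encoded), .groups = "drop")
  grid <- daily_grid(tweets$date, tweets$period)
  merged <- dplyr::left_join(grid, obs, by = "date")
  if (anyNA(merged$value)) {
    merged$value <- approx(x = as.integer(obs$date), y = obs$value,
                           xout = as.integer(merged$date), rule = 2)$y
  }
  as_daily_series(merged, "sentiment")
}

#' Daily unique-user engagement
#'
#' Counts distinct `user_id` values per UTC day among the supplied records
#' (intended to be the post-deduplication, post-topic-filter set). Days with
#' no posts count 0.
#'
#' @param tweets Period-labeled records (columns `user_id`, `date`,
#'   `period`).
#' @return A `daily_series` tibble (`date`, `value`, `period`).
#' @export
daily_engagement <- function(tweets) {
  if (nrow(tweets) == 0L) abort("no records to aggregate")
  stopifnot(all(c("user_id", "date", "period") %in% names(tweets)))
  obs <- as_tibble(tweets) %>%
    dplyr::group_by(.data$date) %>%
    dplyr::summarise(value = dplyr::n_distinct(.data$user_id), .groups = "drop")
  grid <- daily_grid(tweets$date, tweets$period)
  merged <- dplyr::left_join(grid, obs, by = "date")
  merged$value[is.na(merged$value)] <- 0
  as_daily_series(merged, "engagement")
}

#' Write a daily series as CSV
#'
#' @param series A `daily_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
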