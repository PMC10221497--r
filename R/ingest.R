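#' Read a JSONL tweet corpus
#'
#' Reads one JSON object per line with keys `id`, `timestamp` (ISO-8601),
#' `user_id`, and `text`. Malformed lines (unparseable JSON or missing keys)
#' are skipped with a message; if more than `max_malformed_frac` of nonempty
#' lines are malformed the read fails, on the grounds that the file is
#' probably not the expected dialect.
#'
#' @param path Path to a JSONL file as written by [write_corpus_jsonl()].
#' @param max_malformed_frac Hard-error threshold on the fraction of
#'   malformed lines (default 0.1).
#' @return A tibble with columns `id`, `timestamp` (POSIXct, UTC),
#'   `user_id`, `text`, in file order. The number of skipped lines is
#'   attached as attribute `n_skipped`.
#' @export
read_corpus_jsonl <- function(path, max_malformed_frac = 0.1) {
  if (!file.exists(path)) {
    abort(sprintf("corpus file not found: %s", path), class = "eventpulse_io_error")
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- tibble(
      id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      user_id = character(), text = character()
    )
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  parsed <- lapply(lines, function(ln) {
    rec <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    if (is.null(rec) || !is.list(rec)) return(NULL)
    if (!all(c("id", "timestamp", "user_id", "text") %in% names(rec))) return(NULL)
    ts <- suppressWarnings(as.POSIXct(rec$timestamp, tz = "UTC",
                                      tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")))
    if (is.na(ts)) return(NULL)
    list(id = as.character(rec$id), timestamp = ts,
         user_id = as.character(rec$user_id), text = as.character(rec$text))
  })
  ok <- !vapply(parsed, is.null, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped / length(lines) > max_malformed_frac) {
    abort(sprintf("%d of %d lines malformed (> %.0f%% threshold)",
                  n_skipped, length(lines), 100 * max_malformed_frac),
          class = "eventpulse_io_error")
  }
  if (n_skipped > 0L) {
    inform(sprintf("read_corpus_jsonl: skipped %d malformed line(s)", n_skipped))
  }
  kept <- parsed[ok]
  out <- tibble(
    id = vapply(kept, `[[`, character(1), "id"),
    timestamp = as.POSIXct(vapply(kept, function(r) as.numeric(r$timestamp), numeric(1)),
                           origin = "1970-01-01", tz = "UTC"),
    user_id = vapply(kept, `[[`, character(1), "user_id"),
    text = vapply(kept, `[[`, character(1), "text")
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a tweet corpus as JSONL
#'
#' @param tweets A data frame with columns `id`, `timestamp`, `user_id`, `text`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(tweets, path) {
  stopifnot(all(c("id", "timestamp", "user_id", "text") %in% names(tweets)))
  lines <- vapply(seq_len(nrow(tweets)), function(i) {
    jsonlite::toJSON(list(
      id = tweets$id[i],
      timestamp = format(tweets$timestamp[i], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      user_id = tweets$user_id[i],
      text = tweets$text[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# normalized text used as the deduplication key: lowercase, whitespace collapsed
normalize_text <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

#' Tokenize raw post text
#'
#' Applies, in order: lowercasing; URL removal; replacement of user mentions
#' (`@handle`) by the placeholder token `"mentionuser"`; stripping of the
#' hashtag sign while keeping the tag word; splitting on non-alphanumeric
#' characters; dropping tokens shorter than `min_length` unless whitelisted;
#' optional stop-word removal (intended for topic modeling and TF-IDF, not
#' for embedding context windows).
#'
#' @param text Character vector of raw texts.
#' @param stopwords Optional character vector of tokens to drop.
#' @param min_length Minimum token length kept (default 2).
#' @param keep_short Short tokens kept regardless of length; defaults to the
#'   domain terms `"ob"` and `"phi"`.
#' @return A list of character vectors, one per input text.
#' @export
tokenize_text <- function(text, stopwords = NULL, min_length = 2L,
                          keep_short = c("ob", "phi")) {
  x <- stringr::str_to_lower(text)
  x <- stringr::str_replace_all(x, "(https?://|www\\.)\\S+", " ")
  x <- stringr::str_replace_all(x, "@\\w+", " mentionuser ")
  x <- stringr::str_replace_all(x, "#", " ")
  toks <- stringr::str_split(x, "[^a-z0-9]+")
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    tk <- tk[nchar(tk) >= min_length | tk %in% keep_short]
    if (!is.null(stopwords)) tk <- tk[!tk %in% stopwords]
    tk
  })
}

#' Tokenize the texts of a tweet table
#'
#' Adds a list-column `tokens` with the output of [tokenize_text()].
#'
#' @param tweets A data frame with a `text` column.
#' @inheritParams tokenize_text
#' @return The input as a tibble with a `tokens` list-column appended.
#' @export
tokenize_tweets <- function(tweets, stopwords = NULL, min_length = 2L,
                            keep_short = c("ob", "phi")) {
  out <- as_tibble(tweets)
  out$tokens <- tokenize_text(out$text, stopwords = stopwords,
                              min_length = min_length, keep_short = keep_short)
  out
}

#' Remove duplicate posts by normalized text
#'
#' Keeps the first occurrence (in input order) of each whitespace-collapsed,
#' lowercased text; record ids play no role in the key.
#'
#' @param tweets A data frame with a `text` column.
#' @return The surviving rows, input order preserved, as a tibble. The number
#'   of removed rows is attached as attribute `n_removed`.
#' @export
deduplicate_tweets <- function(tweets) {
  out <- as_tibble(tweets)
  key <- normalize_text(out$text)
  keep <- !duplicated(key)
  res <- out[keep, , drop = FALSE]
  attr(res, "n_removed") <- sum(!keep)
  res
}

#' Period configuration
#'
#' Defines the analysis window and its boundary. Posts dated on or before
#' `boundary` (UTC calendar date) are labeled `"pre"`; later posts up to
#' `end` are `"post"`.
#'
#' @param pre_start,boundary,end Dates (or strings coercible to dates) with
#'   `pre_start < boundary < end`.
#' @return A list of class `period_config`.
#' @export
period_config <- function(pre_start = "2020-01-01",
                          boundary = "2022-05-01",
                          end = "2022-10-17") {
  cfg <- list(
    pre_start = as.Date(pre_start),
    boundary = as.Date(boundary),
    end = as.Date(end)
  )
  validate_that(!any(vapply(cfg, is.na, logical(1))), "period_config", "dates must be parseable")
  validate_that(cfg$pre_start < cfg$boundary, "boundary", "must be after pre_start")
  validate_that(cfg$boundary < cfg$end, "end", "must be after boundary")
  structure(cfg, class = "period_config")
}

#' Label each post with its analysis period
#'
#' Day binning is by UTC calendar date of the timestamp. Posts outside
#' `[pre_start, end]` are excluded with a message.
#'
#' @param tweets A data frame with a `timestamp` column.
#' @param cfg A [period_config()].
#' @return A tibble with `date` (Date) and `period` (factor `pre`/`post`)
#'   columns appended; excluded-row count attached as attribute `n_excluded`.
#' @export
label_period <- function(tweets, cfg = period_config()) {
  stopifnot(inherits(cfg, "period_config"))
  out <- as_tibble(tweets)
  out$date <- as.Date(out$timestamp, tz = "UTC")
  in_range <- out$date >= cfg$pre_start & out$date <= cfg$end
  n_excluded <- sum(!in_range)
  if (n_excluded > 0L) {
    inform(sprintf("label_period: excluded %d record(s) outside [%s, %s]",
                   n_excluded, cfg$pre_start, cfg$end))
  }
  out <- out[in_range, , drop = FALSE]
  out$period <- factor(ifelse(out$date <= cfg$boundary, "pre", "post"),
                       levels = c("pre", "post"))
  attr(out, "n_excluded") <- n_excluded
  out
}
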