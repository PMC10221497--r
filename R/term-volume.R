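#' Compute a TF-IDF matrix
#'
#' The variant is fixed so downstream thresholds are exact: `tf` is the raw
#' count of a term in a document, `idf(t) = ln(N / df_t)` with `df_t` the
#' number of documents containing `t` (unsmoothed), and the weight is
#' `tf * idf`. A term present in every document has weight 0 everywhere.
#'
#' @param docs A data frame with a `tokens` list-column or a list of token
#'   vectors.
#' @return An object of class `tfidf_matrix`: sparse `weights` and `tf`
#'   (documents x terms, Matrix `dgCMatrix`), `idf` (named vector), and
#'   `vocabulary`.
#' @export
compute_tfidf <- function(docs) {
  tokens <- as_token_list(docs)
  if (length(tokens) == 0L) abort("no documents", class = "eventpulse_validation_error")
  vocab <- sort(unique(unlist(tokens)))
  if (length(vocab) == 0L) {
    abort("empty vocabulary", class = "eventpulse_validation_error")
  }
  n <- length(tokens)
  triplets <- purrr::imap(tokens, function(tk, d) {
    if (length(tk) == 0L) return(NULL)
    tab <- table(tk)
    list(i = rep.int(as.integer(d), length(tab)),
         j = match(names(tab), vocab),
         x = as.numeric(tab))
  })
  triplets <- purrr::compact(triplets)
  tf <- Matrix::sparseMatrix(
    i = unlist(lapply(triplets, `[[`, "i")),
    j = unlist(lapply(triplets, `[[`, "j")),
    x = unlist(lapply(triplets, `[[`, "x")),
    dims = c(n, length(vocab)), dimnames = list(NULL, vocab)
  )
  df <- Matrix::colSums(tf > 0)
  idf <- log(n / df)
  weights <- tf %*% Matrix::Diagonal(x = idf)
  colnames(weights) <- vocab
  structure(list(weights = weights, tf = tf, idf = setNames(idf, vocab),
                 vocabulary = vocab),
            class = "tfidf_matrix")
}

#' @export
print.tfidf_matrix <- function(x, ...) {
  cat(sprintf("<tfidf_matrix> %d documents x %d terms (idf = ln(N/df), weight = tf * idf)\n",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' @describeIn compute_tfidf Long-format nonzero weights (`document`,
#'   `term`, `tf`, `idf`, `weight`).
#' @method tidy tfidf_matrix
#' @param x A `tfidf_matrix`.
#' @param ... Unused.
#' @export
tidy.tfidf_matrix <- function(x, ...) {
  m <- methods::as(x$tf, "TsparseMatrix")
  tibble(
    document = m@i + 1L,
    term = x$vocabulary[m@j + 1L],
    tf = m@x,
    idf = unname(x$idf[m@j + 1L]),
    weight = m@x * unname(x$idf[m@j + 1L])
  ) %>%
    dplyr::arrange(.data$document, .data$term)
}

#' Split classified records by sentiment polarity
#'
#' @param tweets Classified records (column `sentiment`).
#' @return A named list with the `negative`-labeled and `positive`-labeled
#'   rows; neutral records belong to neither.
#' @export
split_by_polarity <- function(tweets) {
  stopifnot("sentiment" %in% names(tweets))
  out <- as_tibble(tweets)
  list(negative = out[out$sentiment == "negative", , drop = FALSE],
       positive = out[out$sentiment == "positive", , drop = FALSE])
}

#' Standardized pre/post term volumes by sentiment polarity
#'
#' Counts, per (term, period, polarity), the posts whose token set contains
#' the term, then standardizes counts to z-scores within each polarity
#' panel (across all term x period cells of that panel). A zero-variance
#' panel maps to all-zero scores. Terms never occurring are included with
#' zero counts.
#'
#' @param tweets Classified, period-labeled, tokenized records (columns
#'   `sentiment`, `period`, `tokens`).
#' @param terms Target terms tibble (`term`, `group`), default
#'   [trust_terms()].
#' @return A tibble of class `volume_table`: `term`, `group`, `period`,
#'   `polarity`, `count`, `zscore`.
#' @export
volume_table <- function(tweets, terms = trust_terms()) {
  stopifnot(all(c("sentiment", "period", "tokens") %in% names(tweets)))
  split <- split_by_polarity(tweets)
  cells <- tidyr::expand_grid(
    terms,
    period = factor(c("pre", "post"), c("pre", "post")),
    polarity = c("negative", "positive")
  )
  cells$count <- purrr::pmap_int(
    list(cells$term, as.character(cells$period), cells$polarity),
    function(tm, per, pol) {
      set <- split[[pol]]
      set <- set[set$period == per, , drop = FALSE]
      sum(vapply(set$tokens, function(tk) tm %in% tk, logical(1)))
    }
  )
  out <- cells %>%
    dplyr::group_by(.data$polarity) %>%
    dplyr::mutate(zscore = if (sd(.data$count) > 0) {
      (.data$count - mean(.data$count)) / sd(.data$count)
    } else {
      0
    }) %>%
    dplyr::ungroup()
  structure(out, class = c("volume_table", class(out)))
}

#' Select exemplar posts for a term by TF-IDF weight
#'
#' Ranks the posts containing `term` by the term's TF-IDF weight in the
#' post and keeps those at or above the per-term weight quantile (ties at
#' the cut are kept). Posts whose raw text contains a URL are excluded
#' regardless of weight, as a proxy for dropping headline/link posts.
#'
#' @param tfidf A [compute_tfidf()] result whose rows align with `tweets`.
#' @param tweets The records the matrix was computed from (columns `id`,
#'   `text`).
#' @param term Target term.
#' @param quantile Weight quantile in `(0, 1)` (default 0.95).
#' @return A tibble (`id`, `weight`, `text`) sorted by weight descending.
#' @export
select_exemplars <- function(tfidf, tweets, term, quantile = 0.95) {
  stopifnot(inherits(tfidf, "tfidf_matrix"), nrow(tweets) == nrow(tfidf$weights))
  validate_that(quantile > 0 && quantile < 1, "quantile", "must be in (0, 1)")
  if (!term %in% tfidf$vocabulary) {
    warn(sprintf("select_exemplars: term '%s' not in vocabulary", term))
    return(tibble(id = character(), weight = numeric(), text = character()))
  }
  w <- as.numeric(tfidf$weights[, term])
  containing <- as.numeric(tfidf$tf[, term]) > 0
  has_url <- stringr::str_detect(tweets$text, "(https?://|www\\.)\\S+")
  keep <- containing & !has_url
  if (!any(keep)) {
    return(tibble(id = character(), weight = numeric(), text = character()))
  }
  cut <- quantile(w[keep], probs = quantile, type = 7)
  sel <- which(keep & w >= cut)
  sel <- sel[order(-w[sel])]
  tibble(id = tweets$id[sel], weight = w[sel], text = tweets$text[sel])
}

#' Write exemplar posts as JSONL
#'
#' @param exemplars Tibble from [select_exemplars()], plus a `term` column
#'   or the `term` argument.
#' @param path Output path.
#' @param term Term name recorded on each line (if not already a column).
#' @return `path`, invisibly.
#' @export
write_exemplars_jsonl <- function(exemplars, path, term = NULL) {
  lines <- vapply(seq_len(nrow(exemplars)), function(i) {
    jsonlite::toJSON(list(
      term = exemplars$term[i] %||% term,
      id = exemplars$id[i],
      weight = exemplars$weight[i],
      text = exemplars$text[i]
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
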