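# coerce a tokens input (data frame with `tokens` list-column, or a bare
# list of character vectors) to a list of token vectors
as_token_list <- function(docs) {
  if (is.data.frame(docs)) {
    if (!"tokens" %in% names(docs)) {
      abort("`docs` data frame must carry a `tokens` list-column (see tokenize_tweets())")
    }
    return(docs$tokens)
  }
  stopifnot(is.list(docs))
  docs
}

#' Configuration for the collapsed-Gibbs LDA sampler
#'
#' Defaults follow common collapsed-Gibbs practice: symmetric priors
#' `alpha = 50 / n_topics` and `beta = 0.01`, 1,000 sweeps with 200 burn-in,
#' and post-burn-in count averaging. The short documents typical of
#' social-media corpora often warrant a much smaller `alpha` (the
#' document-topic prior acts as `alpha` pseudo-tokens per topic, which caps
#' the attainable membership probability of a short document).
#'
#' @param n_topics Number of topics (>= 1).
#' @param alpha Symmetric document-topic Dirichlet prior (> 0).
#' @param beta Symmetric topic-word Dirichlet prior (> 0).
#' @param n_iter Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before count averaging
#'   (`n_iter > burn_in >= 0`).
#' @param seed Integer RNG seed.
#' @return A list of class `lda_config`.
#' @export
lda_config <- function(n_topics = 20L, alpha = 50 / n_topics, beta = 0.01,
                       n_iter = 1000L, burn_in = 200L, seed = 1L) {
  cfg <- list(n_topics = as.integer(n_topics), alpha = alpha, beta = beta,
              n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              seed = as.integer(seed))
  validate_that(cfg$n_topics >= 1L, "n_topics", "must be >= 1")
  validate_that(cfg$alpha > 0 && cfg$beta > 0, "alpha/beta", "priors must be > 0")
  validate_that(cfg$n_iter > cfg$burn_in && cfg$burn_in >= 0L,
                "n_iter", "must satisfy n_iter > burn_in >= 0")
  structure(cfg, class = "lda_config")
}

#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Topic-word and document-topic distributions are estimated from
#' post-burn-in averaged assignment counts with Dirichlet smoothing.
#' Sampling sweeps documents and tokens in fixed order from a single seeded
#' RNG stream, so the fit is deterministic given `(docs, config)`.
#'
#' @param docs A data frame with a `tokens` list-column (see
#'   [tokenize_tweets()]) or a list of character token vectors.
#' @param config An [lda_config()].
#' @return An object of class `lda_model` with elements `topic_word`
#'   (K x V rows summing to 1), `doc_topic` (N x K rows summing to 1),
#'   `vocabulary` (terms in column order), `term_counts`, `assignments`,
#'   and `config`.
#' @export
fit_lda <- function(docs, config = lda_config()) {
  stopifnot(inherits(config, "lda_config"))
  tokens <- as_token_list(docs)
  if (length(tokens) == 0L || all(lengths(tokens) == 0L)) {
    abort("cannot fit LDA on an empty corpus", class = "eventpulse_validation_error")
  }
  vocab <- sort(unique(unlist(tokens)))
  V <- length(vocab)
  idx <- lapply(tokens, function(tk) match(tk, vocab) - 1L)
  term_counts <- table(factor(unlist(tokens), levels = vocab))

  res <- with_seed(config$seed, {
    lda_gibbs_cpp(idx, V, config$n_topics, config$alpha, config$beta,
                  config$n_iter, config$burn_in)
  })
  K <- config$n_topics
  tw <- res$topic_word_counts + config$beta
  topic_word <- tw / rowSums(tw)
  dt <- res$doc_topic_counts + config$alpha
  doc_topic <- dt / rowSums(dt)
  colnames(topic_word) <- vocab
  rownames(topic_word) <- paste0("topic_", seq_len(K))
  colnames(doc_topic) <- rownames(topic_word)

  structure(
    list(topic_word = topic_word, doc_topic = doc_topic, vocabulary = vocab,
         term_counts = as.integer(term_counts), assignments = res$assignments,
         config = config, n_docs = length(tokens)),
    class = "lda_model"
  )
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d topics, %d documents, %d terms\n",
              x$config$n_topics, x$n_docs, length(x$vocabulary)))
  invisible(x)
}

#' Per-document topic probabilities
#'
#' With `docs` omitted, returns the stored training-set document-topic
#' matrix. For held-out documents the model folds them in by Gibbs-sampling
#' their token assignments with the topic-word distribution held fixed.
#' Documents with zero in-vocabulary tokens get a uniform row and are
#' flagged in the `"oov_docs"` attribute.
#'
#' @param model A fitted [fit_lda()] model.
#' @param docs Optional held-out documents (data frame with `tokens` or a
#'   token list).
#' @param n_iter,burn_in Fold-in Gibbs sweeps.
#' @param seed RNG seed for the fold-in sampler.
#' @return An N x K matrix of probabilities, rows summing to 1.
#' @export
score_documents <- function(model, docs = NULL, n_iter = 100L, burn_in = 50L,
                            seed = model$config$seed + 1L) {
  stopifnot(inherits(model, "lda_model"))
  if (is.null(docs)) return(model$doc_topic)
  tokens <- as_token_list(docs)
  idx <- lapply(tokens, function(tk) {
    m <- match(tk, model$vocabulary)
    m[!is.na(m)] - 1L
  })
  oov <- which(lengths(idx) == 0L)
  out <- with_seed(seed, {
    lda_fold_in_cpp(idx, model$topic_word, model$config$alpha,
                    as.integer(n_iter), as.integer(burn_in))
  })
  colnames(out) <- rownames(model$topic_word)
  if (length(oov) > 0L) {
    inform(sprintf("score_documents: %d document(s) with no in-vocabulary tokens (uniform rows)",
                   length(oov)))
  }
  attr(out, "oov_docs") <- oov
  out
}

#' Retain records by posterior topic membership
#'
#' A record survives iff the sum of its topic probabilities over the
#' selected topics is at least `threshold`. Topic selection is an explicit
#' operator input; see [select_topics_by_terms()] for a reproducible helper.
#'
#' @param records Data frame of records, rows aligned with `scores`.
#' @param scores N x K probability matrix from [score_documents()].
#' @param topics Integer indices (or `topic_*` names) of the selected topics.
#' @param threshold Membership threshold in `(0, 1]` (default 0.95).
#' @return The surviving rows of `records` as a tibble, with the summed
#'   selected-topic probability in column `topic_prob`.
#' @export
filter_by_topics <- function(records, scores, topics, threshold = 0.95) {
  validate_that(length(topics) >= 1L, "topics", "at least one topic must be selected")
  validate_that(threshold > 0 && threshold <= 1, "threshold", "must be in (0, 1]")
  stopifnot(nrow(records) == nrow(scores))
  if (is.character(topics)) topics <- match(topics, colnames(scores))
  validate_that(!anyNA(topics) && all(topics >= 1L & topics <= ncol(scores)),
                "topics", "topic indices out of range")
  prob <- rowSums(scores[, topics, drop = FALSE])
  out <- as_tibble(records)[prob >= threshold, , drop = FALSE]
  out$topic_prob <- prob[prob >= threshold]
  out
}

#' Top-weighted terms of a topic
#'
#' @param model A fitted `lda_model`.
#' @param topic Topic index in `1..K`.
#' @param n Number of terms (capped at the vocabulary size).
#' @return A tibble (`term`, `weight`, `count`) sorted by weight descending,
#'   ties broken lexicographically.
#' @export
top_terms <- function(model, topic, n = 10L) {
  stopifnot(inherits(model, "lda_model"))
  validate_that(topic >= 1L && topic <= model$config$n_topics, "topic", "out of range")
  w <- model$topic_word[topic, ]
  ord <- order(-w, names(w))
  keep <- head(ord, n)
  tibble(term = names(w)[keep], weight = unname(w[keep]),
         count = model$term_counts[keep])
}

#' Select topics whose top terms contain given salient terms
#'
#' A reproducible stand-in for the manual inspect-and-pick step: returns the
#' indices of every topic whose `n_top` highest-weighted terms intersect
#' `salient_terms`.
#'
#' @param model A fitted `lda_model`.
#' @param salient_terms Character vector of terms of interest.
#' @param n_top Number of top terms examined per topic.
#' @return Integer vector of topic indices (possibly empty).
#' @export
select_topics_by_terms <- function(model, salient_terms, n_top = 10L) {
  hits <- vapply(seq_len(model$config$n_topics), function(k) {
    any(top_terms(model, k, n_top)$term %in% salient_terms)
  }, logical(1))
  which(hits)
}

#' Held-out perplexity of an LDA model
#'
#' Computes `exp(-mean log p(w | d))` over all in-vocabulary tokens, with
#' document mixtures obtained by fold-in.
#'
#' @inheritParams score_documents
#' @return A single number (lower is better).
#' @export
lda_perplexity <- function(model, docs, n_iter = 100L, burn_in = 50L,
                           seed = model$config$seed + 2L) {
  tokens <- as_token_list(docs)
  theta <- score_documents(model, tokens, n_iter = n_iter, burn_in = burn_in,
                           seed = seed)
  ll <- 0
  n_tok <- 0
  for (d in seq_along(tokens)) {
    m <- match(tokens[[d]], model$vocabulary)
    m <- m[!is.na(m)]
    if (length(m) == 0L) next
    pw <- as.numeric(theta[d, ] %*% model$topic_word[, m, drop = FALSE])
    ll <- ll + sum(log(pw))
    n_tok <- n_tok + length(m)
  }
  if (n_tok == 0L) abort("no in-vocabulary tokens in `docs`")
  exp(-ll / n_tok)
}

#' @describeIn fit_lda Tidy a fitted model: `matrix = "beta"` returns
#'   per-topic term probabilities (`topic`, `term`, `beta`);
#'   `matrix = "gamma"` returns per-document topic probabilities
#'   (`document`, `topic`, `gamma`).
#' @method tidy lda_model
#' @param x A fitted `lda_model`.
#' @param matrix Which probability matrix to tidy.
#' @param ... Unused.
#' @export
tidy.lda_model <- function(x, matrix = c("beta", "gamma"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "beta") {
    as_tibble(x$topic_word, rownames = "topic") %>%
      tidyr::pivot_longer(-"topic", names_to = "term", values_to = "beta") %>%
      dplyr::mutate(topic = match(.data$topic, rownames(x$topic_word)))
  } else {
    as_tibble(x$doc_topic) %>%
      dplyr::mutate(document = dplyr::row_number()) %>%
      tidyr::pivot_longer(-"document", names_to = "topic", values_to = "gamma") %>%
      dplyr::mutate(topic = match(.data$topic, colnames(x$doc_topic)))
  }
}

#' @describeIn fit_lda One-row model summary.
#' @method glance lda_model
#' @export
glance.lda_model <- function(x, ...) {
  tibble(n_topics = x$config$n_topics, n_docs = x$n_docs,
         n_terms = length(x$vocabulary), n_iter = x$config$n_iter,
         burn_in = x$config$burn_in, alpha = x$config$alpha,
         beta = x$config$beta)
}

#' Serialize a fitted LDA model to a directory
#'
#' Writes `vocabulary.tsv` (term, corpus count), `topic_word.csv`,
#' `doc_topic.csv`, and `config.json`.
#'
#' @param model A fitted `lda_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lda_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(term = model$vocabulary, count = model$term_counts),
    file.path(dir, "vocabulary.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  utils::write.csv(model$topic_word, file.path(dir, "topic_word.csv"), row.names = TRUE)
  utils::write.csv(model$doc_topic, file.path(dir, "doc_topic.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(model$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
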