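#' Configuration for skip-gram negative-sampling training
#'
#' Defaults are the usual word2vec settings, sized so that the synthetic
#' corpora used here converge quickly: 100 dimensions, symmetric window 5,
#' 5 negatives from the unigram^0.75 distribution, 5 epochs of
#' single-threaded SGD with a linearly decaying learning rate, minimum
#' count 5, and frequency subsampling at 1e-3.
#'
#' @param dim Embedding dimension.
#' @param window Maximum symmetric context window (the effective window is
#'   resampled uniformly in `1..window` per center word, as in word2vec).
#' @param negative Negative samples per (center, context) pair.
#' @param epochs Training epochs.
#' @param min_count Minimum corpus frequency for a word to enter the
#'   vocabulary.
#' @param subsample Frequency-subsampling threshold (0 disables).
#' @param learning_rate Initial SGD learning rate.
#' @param seed Integer RNG seed.
#' @return A list of class `sgns_config`.
#' @export
sgns_config <- function(dim = 100L, window = 5L, negative = 5L, epochs = 5L,
                        min_count = 5L, subsample = 1e-3,
                        learning_rate = 0.025, seed = 1L) {
  cfg <- list(dim = as.integer(dim), window = as.integer(window),
              negative = as.integer(negative), epochs = as.integer(epochs),
              min_count = as.integer(min_count), subsample = subsample,
              learning_rate = learning_rate, seed = as.integer(seed))
  validate_that(cfg$dim >= 2L, "dim", "must be >= 2")
  validate_that(cfg$window >= 1L, "window", "must be >= 1")
  validate_that(cfg$negative >= 1L, "negative", "must be >= 1")
  validate_that(cfg$epochs >= 1L, "epochs", "must be >= 1")
  validate_that(cfg$min_count >= 1L, "min_count", "must be >= 1")
  validate_that(cfg$learning_rate > 0, "learning_rate", "must be > 0")
  structure(cfg, class = "sgns_config")
}

#' Train skip-gram negative-sampling embeddings
#'
#' For each (center, context) pair within the dynamic window, maximizes
#' `log sigma(u_c . v_w) + sum_k log sigma(-u_nk . v_w)` with negatives from
#' the unigram^0.75 distribution; SGD with a linearly decaying learning
#' rate. Training is single-threaded and draws from a single seeded RNG
#' stream, so it is deterministic given `(docs, config)`. Words below
#' `min_count` are dropped from the vocabulary (and from the token
#' sequence, so windows span the gaps).
#'
#' @param docs A data frame with a `tokens` list-column or a list of token
#'   vectors. Context windows are intended to run over unfiltered token
#'   sequences (no stop-word removal).
#' @param config An [sgns_config()].
#' @return An object of class `sgns_model`: `vectors` (V x dim input/center
#'   vectors, rownames are words), `context_vectors`, `counts`,
#'   `epoch_loss` (mean pair loss per epoch), and `config`.
#' @export
train_sgns <- function(docs, config = sgns_config()) {
  stopifnot(inherits(config, "sgns_config"))
  tokens <- as_token_list(docs)
  counts <- table(unlist(tokens))
  if (length(counts) == 0L) {
    abort("cannot train embeddings on an empty corpus",
          class = "eventpulse_validation_error")
  }
  counts <- counts[counts >= config$min_count]
  if (length(counts) == 0L) {
    abort("no word reaches min_count; lower `min_count` or enlarge the corpus",
          class = "eventpulse_validation_error")
  }
  vocab <- sort(names(counts))
  counts <- as.numeric(counts[vocab])
  idx <- lapply(tokens, function(tk) {
    m <- match(tk, vocab)
    m[!is.na(m)] - 1L
  })
  idx <- idx[lengths(idx) > 0L]

  res <- with_seed(config$seed, {
    sgns_train_cpp(idx, counts, config$dim, config$window, config$negative,
                   config$epochs, config$learning_rate, config$subsample)
  })
  vectors <- res$vectors
  rownames(vectors) <- vocab
  context_vectors <- res$context_vectors
  rownames(context_vectors) <- vocab
  structure(
    list(vectors = vectors, context_vectors = context_vectors,
         counts = setNames(counts, vocab), epoch_loss = res$epoch_loss,
         config = config),
    class = "sgns_model"
  )
}

#' @export
print.sgns_model <- function(x, ...) {
  cat(sprintf("<sgns_model> %d words x %d dims, %d epochs (final mean pair loss %.4f)\n",
              nrow(x$vectors), x$config$dim, x$config$epochs,
              tail(x$epoch_loss, 1)))
  invisible(x)
}

unit_vec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(NULL)
  v / nv
}

#' Build the trust axis from anchor antonym pairs
#'
#' For each anchor pair with both words in the model vocabulary, the
#' difference vector (positive minus negative) is unit-normalized; the axis
#' is the unit-normalized mean of these pair vectors, so no single pair
#' dominates. Pairs with an out-of-vocabulary member are skipped and listed
#' in the `"skipped_pairs"` attribute.
#'
#' @param model An [train_sgns()] model.
#' @param anchors Anchor pairs as from [trust_anchors()].
#' @return A unit-norm numeric axis vector.
#' @export
build_trust_axis <- function(model, anchors = trust_anchors()) {
  stopifnot(inherits(model, "sgns_model"))
  vocab <- rownames(model$vectors)
  in_vocab <- anchors$positive %in% vocab & anchors$negative %in% vocab
  if (!any(in_vocab)) {
    abort("no anchor pair has both members in the vocabulary",
          class = "eventpulse_validation_error")
  }
  skipped <- anchors[!in_vocab, , drop = FALSE]
  if (nrow(skipped) > 0L) {
    inform(sprintf("build_trust_axis: skipped %d pair(s) with OOV members: %s",
                   nrow(skipped),
                   paste(skipped$positive, skipped$negative, sep = "/", collapse = ", ")))
  }
  pairs <- anchors[in_vocab, , drop = FALSE]
  diffs <- lapply(seq_len(nrow(pairs)), function(i) {
    unit_vec(model$vectors[pairs$positive[i], ] - model$vectors[pairs$negative[i], ])
  })
  diffs <- diffs[!vapply(diffs, is.null, logical(1))]
  if (length(diffs) == 0L) abort("all pair difference vectors have zero norm")
  axis <- unit_vec(Reduce(`+`, diffs) / length(diffs))
  if (is.null(axis)) abort("axis has zero norm")
  axis
}

#' Project a term onto a semantic axis
#'
#' Cosine similarity between the term's center-word vector and the
#' (unit-norm) axis. Out-of-vocabulary terms get `NA`, never a default
#' score.
#'
#' @param model An `sgns_model`.
#' @param axis A unit-norm axis vector, as from [build_trust_axis()].
#' @param term A single word.
#' @return A score in `[-1, 1]`, or `NA` if the term is out of vocabulary.
#' @export
project_term <- function(model, axis, term) {
  stopifnot(inherits(model, "sgns_model"), length(term) == 1L)
  if (!term %in% rownames(model$vectors)) return(NA_real_)
  v <- model$vectors[term, ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) abort(sprintf("term '%s' has a zero-norm vector", term))
  sum(v * axis) / (nv * sqrt(sum(axis^2)))
}

#' Project a set of terms onto a semantic axis
#'
#' @inheritParams project_term
#' @param terms Character vector of words.
#' @return A tibble (`term`, `score`, `oov`).
#' @export
project_terms <- function(model, axis, terms) {
  tibble(
    term = terms,
    score = unname(vapply(terms, function(tm) project_term(model, axis, tm),
                          numeric(1))),
    oov = !(terms %in% rownames(model$vectors))
  )
}

#' Compare trust-dimension scores between periods
#'
#' Builds the trust axis independently inside each period's embedding model
#' (avoiding any cross-model vector alignment) and projects the target
#' terms; the delta is post minus pre where both scores exist. Terms out of
#' vocabulary in both periods are reported but carry no scores.
#'
#' @param model_pre,model_post `sgns_model`s trained with the same
#'   configuration on the two period corpora.
#' @param anchors Anchor pairs (default [trust_anchors()]).
#' @param terms Target terms with groups (default [trust_terms()]).
#' @return A tibble of class `trust_axis_report`: `term`, `group`,
#'   `score_pre`, `score_post`, `delta`, `oov_pre`, `oov_post`.
#' @export
compare_periods <- function(model_pre, model_post, anchors = trust_anchors(),
                            terms = trust_terms()) {
  axis_pre <- build_trust_axis(model_pre, anchors)
  axis_post <- build_trust_axis(model_post, anchors)
  pre <- project_terms(model_pre, axis_pre, terms$term)
  post <- project_terms(model_post, axis_post, terms$term)
  out <- tibble(
    term = terms$term, group = terms$group,
    score_pre = pre$score, score_post = post$score,
    delta = post$score - pre$score,
    oov_pre = pre$oov, oov_post = post$oov
  )
  structure(out, class = c("trust_axis_report", class(out)))
}

#' @describeIn compare_periods Long-format scores (`term`, `group`,
#'   `period`, `score`, `oov`).
#' @method tidy trust_axis_report
#' @param x A `trust_axis_report`.
#' @param ... Unused.
#' @export
tidy.trust_axis_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = x$term, group = x$group, period = "pre",
           score = x$score_pre, oov = x$oov_pre),
    tibble(term = x$term, group = x$group, period = "post",
           score = x$score_post, oov = x$oov_post)
  ) %>%
    dplyr::mutate(period = factor(.data$period, c("pre", "post"))) %>%
    dplyr::arrange(.data$group, .data$term, .data$period)
}

#' Write embeddings in word2vec text format
#'
#' First line `V dim`, then one word and its vector per line.
#'
#' @param model An `sgns_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(model$vectors), ncol(model$vectors)), con)
  apply_fmt <- apply(model$vectors, 1L, function(v) {
    paste(sprintf("%.8g", v), collapse = " ")
  })
  writeLines(paste(rownames(model$vectors), apply_fmt), con)
  invisible(path)
}

#' Read embeddings in word2vec text format
#'
#' @param path Input path.
#' @return A matrix with words as rownames.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  words <- vapply(parts, `[[`, character(1), 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(mat) <- words
  mat
}
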