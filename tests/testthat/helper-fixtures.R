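# compact corpus specifications used across tests

small_spec <- function(seed = 1L, base_daily_users = 6,
                       engagement_multiplier = 2, ...) {
  corpus_spec(
    seed = seed,
    pre_start = "2022-03-01", pre_end = "2022-04-09",
    post_start = "2022-04-10", post_end = "2022-04-19",
    base_daily_users = base_daily_users,
    engagement_multiplier = engagement_multiplier,
    ...
  )
}

small_period_cfg <- function() {
  period_config("2022-03-01", "2022-04-09", "2022-04-19")
}

# planted two-topic corpus with disjoint 20-word vocabularies
two_topic_docs <- function(n_per_topic = 200L, len = 15L, seed = 7L) {
  v1 <- paste0("alpha", 1:20)
  v2 <- paste0("beta", 1:20)
  withr::with_seed(seed, {
    docs <- c(lapply(seq_len(n_per_topic), function(i) sample(v1, len, TRUE)),
              lapply(seq_len(n_per_topic), function(i) sample(v2, len, TRUE)))
  })
  list(docs = docs, vocab1 = v1, vocab2 = v2,
       truth = rep(1:2, each = n_per_topic))
}

# cosine between two numeric vectors
cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# hand-rolled sgns_model carrying fixed vectors, for analytic axis tests
toy_embedding <- function(vectors) {
  structure(
    list(vectors = vectors, context_vectors = vectors,
         counts = setNames(rep(10, nrow(vectors)), rownames(vectors)),
         epoch_loss = NA_real_,
         config = sgns_config(dim = ncol(vectors), min_count = 1)),
    class = "sgns_model"
  )
}

# brute-force joint-Gaussian evaluation of the local-level model:
# mu_1 ~ N(m0, P0), mu_t = mu_1 + sum of t-1 innovations, y_t = mu_t + eps_t
brute_force_local_level <- function(y, s2o, s2l, m0, P0) {
  n <- length(y)
  Sig <- outer(seq_len(n), seq_len(n),
               function(i, j) P0 + s2l * (pmin(i, j) - 1)) + diag(s2o, n)
  L <- chol(Sig)
  z <- backsolve(L, y - m0, transpose = TRUE)
  loglik <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
  filtered_mean <- vapply(seq_len(n), function(t) {
    cov_mu_y <- P0 + s2l * (pmin(t, seq_len(t)) - 1)
    m0 + as.numeric(cov_mu_y %*% solve(Sig[seq_len(t), seq_len(t), drop = FALSE],
                                       y[seq_len(t)] - m0))
  }, numeric(1))
  list(loglik = loglik, filtered_mean = filtered_mean)
}

# brute-force TF-IDF double loop
brute_force_tfidf <- function(docs) {
  vocab <- sort(unique(unlist(docs)))
  n <- length(docs)
  out <- matrix(0, n, length(vocab), dimnames = list(NULL, vocab))
  for (d in seq_len(n)) {
    for (v in vocab) {
      tf <- sum(docs[[d]] == v)
      df <- sum(vapply(docs, function(x) v %in% x, logical(1)))
      out[d, v] <- tf * log(n / df)
    }
  }
  out
}
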