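#' Fit an LDA model by collapsed Gibbs sampling
#'
#' Latent Dirichlet allocation: every document is a Dirichlet-distributed
#' mixture theta over `k` topics, every topic a distribution phi over the
#' vocabulary. Inference integrates theta and phi out and samples only the
#' token-level topic assignments `z` (collapsed Gibbs). After the final
#' sweep, point estimates are read off the count matrices with smoothing:
#' `phi[t, w] = (n_tw + eta) / (n_t + V * eta)` and
#' `theta[d, t] = (n_dt + alpha) / (N_d + k * alpha)`.
#'
#' Identical inputs and seed give a bit-identical model. No burn-in is
#' discarded: estimates come from the final state, which for the corpus
#' sizes targeted here is indistinguishable from averaging late sweeps.
#'
#' @param bows list of bag-of-words matrices from [to_bag_of_words()], one
#'   per document, all non-empty.
#' @param vocab the `nt_vocab` the bags were built against.
#' @param k number of topics (>= 1).
#' @param alpha symmetric per-document Dirichlet concentration
#'   (default `1/k`).
#' @param eta topic-word smoothing (default 0.01).
#' @param n_iterations Gibbs sweeps (default 1000).
#' @param seed RNG seed.
#' @param record keep the `z` state after every sweep (only sensible for
#'   tiny corpora; used by exact-posterior cross-checks).
#' @return An `nt_lda` model: `k`, `alpha`, `eta`, `phi` (k x V, rows sum
#'   to 1), `theta` (D x k, rows sum to 1), `z` (list per document of
#'   1-based topic assignments), `seed`, `n_iterations`, `terms`, and
#'   optionally `z_trace`.
#' @export
fit_lda <- function(bows, vocab, k, alpha = 1 / k, eta = 0.01,
                    n_iterations = 1000L, seed = 1L, record = FALSE) {
  stopifnot(inherits(vocab, "nt_vocab"), k >= 1L, n_iterations >= 1L,
            alpha > 0, eta > 0)
  V <- length(vocab$terms)
  lens <- vapply(bows, function(b) sum(b[, "count"]), numeric(1))
  if (any(lens == 0)) {
    bad <- names(bows)[lens == 0]
    if (is.null(bad)) bad <- which(lens == 0)
    stop("document(s) with no in-vocabulary tokens: ",
         paste(bad, collapse = ", "))
  }
  if (k > sum(lens)) {
    warning("k exceeds the total token count; most topics will stay empty")
  }
  flat <- flatten_bows(bows, V)
  set.seed(seed)
  fit <- .lda_gibbs_cpp(flat$doc, flat$word, length(bows), V, as.integer(k),
                        alpha, eta, as.integer(n_iterations), record)
  phi <- (fit$n_tw + eta) / (fit$n_t + V * eta)
  theta <- (fit$n_dt + alpha) / (lens + k * alpha)
  colnames(phi) <- vocab$terms
  z_flat <- fit$z + 1L
  model <- list(k = as.integer(k), alpha = alpha, eta = eta,
                phi = phi, theta = theta,
                z = split(z_flat, flat$doc + 1L),
                seed = as.integer(seed), n_iterations = as.integer(n_iterations),
                terms = vocab$terms, doc_lengths = lens)
  if (record) model$z_trace <- fit$z_trace + 1L
  class(model) <- "nt_lda"
  model
}

# Expand (index, count) bags into one row per token, 0-based for C++.
# Token order is deterministic: by document, then by increasing word index.
flatten_bows <- function(bows, V) {
  doc <- integer(0)
  word <- integer(0)
  for (d in seq_along(bows)) {
    b <- bows[[d]]
    if (nrow(b) == 0L) next
    if (any(b[, "index"] < 1L | b[, "index"] > V)) {
      stop("bag-of-words index outside vocabulary in document ", d)
    }
    w <- rep(b[, "index"], b[, "count"])
    doc <- c(doc, rep(d, length(w)))
    word <- c(word, w)
  }
  list(doc = doc - 1L, word = word - 1L)
}

#' @export
print.nt_lda <- function(x, ...) {
  cat(sprintf("<nt_lda> k=%d, %d documents, V=%d, %d Gibbs sweeps (seed %d)\n",
              x$k, nrow(x$theta), ncol(x$phi), x$n_iterations, x$seed))
  invisible(x)
}

#' Dominant topic of a document
#'
#' The topic with the highest mixture probability; ties go to the lowest
#' topic index.
#'
#' @param theta_d either a single k-vector of topic probabilities or a
#'   D x k matrix (one row per document).
#' @return Integer topic index/indices (1-based).
#' @export
dominant_topic <- function(theta_d) {
  if (is.matrix(theta_d)) return(apply(theta_d, 1L, which.max))
  which.max(theta_d)
}

#' Per-word log2 likelihood of a corpus under a fitted model
#'
#' The (negated-perplexity) score used for model selection:
#' `(1 / total tokens) * sum_d sum_w count * log2(sum_t theta[d,t] * phi[t,w])`.
#' More negative means a worse fit; a model with uniform `phi` over V terms
#' scores exactly `-log2(V)`.
#'
#' @param model an `nt_lda` model.
#' @param bows the bag-of-words corpus to score, aligned with the model's
#'   `theta` rows (held-in scoring: the training corpus).
#' @return A single number (log base 2, per word).
#' @export
log_perplexity <- function(model, bows) {
  stopifnot(inherits(model, "nt_lda"), length(bows) == nrow(model$theta))
  V <- ncol(model$phi)
  total <- 0
  n_tokens <- 0
  for (d in seq_along(bows)) {
    b <- bows[[d]]
    if (nrow(b) == 0L) next
    if (any(b[, "index"] > V)) stop("word index outside vocabulary in doc ", d)
    pw <- as.vector(model$theta[d, , drop = FALSE] %*%
                      model$phi[, b[, "index"], drop = FALSE])
    total <- total + sum(b[, "count"] * log2(pw))
    n_tokens <- n_tokens + sum(b[, "count"])
  }
  total / n_tokens
}

#' UMass intrinsic topic coherence
#'
#' For each topic, take the `top_n` highest-probability words and score all
#' ordered pairs (higher-ranked word conditions): with `D(w)` the number of
#' corpus documents containing `w` and `D(wi, wj)` the number containing
#' both, the topic score is
#' `2 / (n (n - 1)) * sum_{i<j} log((D(wi, wj) + 1) / D(wi))`
#' and the model score is the mean over topics. Co-occurrence counts come
#' from the same bag-of-words corpus the model was trained on (intrinsic
#' coherence, no external reference corpus).
#'
#' @param model an `nt_lda` model.
#' @param bows bag-of-words corpus supplying document co-occurrence counts.
#' @param top_n number of top words per topic (>= 2, default 10).
#' @return Mean coherence across topics; attribute `per_topic` has the
#'   per-topic scores.
#' @export
umass_coherence <- function(model, bows, top_n = 10L) {
  stopifnot(inherits(model, "nt_lda"), top_n >= 2L)
  V <- ncol(model$phi)
  # presence matrix: docs x V, logical
  present <- matrix(FALSE, nrow = length(bows), ncol = V)
  for (d in seq_along(bows)) {
    b <- bows[[d]]
    if (nrow(b) > 0L) present[d, b[, "index"]] <- TRUE
  }
  doc_freq <- colSums(present)
  per_topic <- vapply(seq_len(model$k), function(t) {
    top <- top_words_idx(model$phi[t, ], model$terms, top_n)
    n <- length(top)
    if (n < 2L) return(NA_real_)
    s <- 0
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        co <- sum(present[, top[i]] & present[, top[j]])
        s <- s + log((co + 1) / doc_freq[top[i]])
      }
    }
    2 * s / (n * (n - 1))
  }, numeric(1))
  out <- mean(per_topic)
  attr(out, "per_topic") <- per_topic
  out
}

# Indices of the top_n entries of a phi row, descending weight, ties
# broken lexicographically by term.
top_words_idx <- function(phi_row, terms, top_n) {
  ord <- order(-phi_row, terms)
  ord[seq_len(min(top_n, length(ord)))]
}

#' Topic keyword tables
#'
#' The `top_n` highest-probability terms per topic with their phi weights
#' (non-increasing; ties broken lexicographically) — the data behind
#' per-topic keyword bar plots.
#'
#' @param model an `nt_lda` model.
#' @param top_n keywords per topic (default 10; capped at V).
#' @return Named list (one entry per topic) of `data.frame(term, weight)`.
#' @export
topic_keywords <- function(model, top_n = 10L) {
  stopifnot(inherits(model, "nt_lda"))
  out <- lapply(seq_len(model$k), function(t) {
    idx <- top_words_idx(model$phi[t, ], model$terms, top_n)
    data.frame(term = model$terms[idx], weight = unname(model$phi[t, idx]),
               stringsAsFactors = FALSE)
  })
  names(out) <- paste0("topic_", seq_len(model$k))
  out
}

#' Sweep the number of topics and select the best model
#'
#' Fits one model per `k` in `k_grid`, recording UMass coherence and
#' per-word log2 likelihood. Selection codifies the coherence/perplexity
#' trade-off: maximize coherence, and when several k's coherences fall
#' within `tie_window` of the best, prefer among them the log-perplexity
#' closest to zero (then the smaller k).
#'
#' @param bows,vocab corpus as for [fit_lda()].
#' @param k_grid integer vector of candidate topic counts
#'   (default `c(3, 5, 7, 10)`).
#' @param alpha `NULL` for the per-k default `1/k`, or a fixed value.
#' @param eta,n_iterations,seed passed to [fit_lda()] (same seed per k).
#' @param top_n top words per topic for coherence.
#' @param tie_window coherence width regarded as a near-tie (default 0.01).
#' @return List with `records` (`data.frame(k, coherence, log_perplexity)`),
#'   `k` (chosen), and `models` (named list of fitted models).
#' @export
select_k <- function(bows, vocab, k_grid = c(3L, 5L, 7L, 10L), alpha = NULL,
                     eta = 0.01, n_iterations = 1000L, seed = 1L,
                     top_n = 10L, tie_window = 0.01) {
  stopifnot(length(k_grid) >= 1L)
  models <- list()
  records <- data.frame(k = integer(0), coherence = numeric(0),
                        log_perplexity = numeric(0))
  for (k in k_grid) {
    a <- if (is.null(alpha)) 1 / k else alpha
    m <- fit_lda(bows, vocab, k = k, alpha = a, eta = eta,
                 n_iterations = n_iterations, seed = seed)
    records <- rbind(records, data.frame(
      k = k,
      coherence = as.numeric(umass_coherence(m, bows, top_n = top_n)),
      log_perplexity = log_perplexity(m, bows)))
    models[[as.character(k)]] <- m
  }
  chosen <- choose_k(records, tie_window)
  list(records = records, k = chosen, models = models)
}

#' @rdname select_k
#' @param records a `data.frame(k, coherence, log_perplexity)`, e.g. a
#'   published sweep table, to which only the selection rule is applied.
#' @export
choose_k <- function(records, tie_window = 0.01) {
  best <- max(records$coherence)
  cand <- records[records$coherence >= best - tie_window, , drop = FALSE]
  cand <- cand[order(-cand$log_perplexity, cand$k), , drop = FALSE]
  cand$k[1L]
}
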