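make_bows <- function(streams) {
  vocab <- build_vocabulary(streams)
  list(vocab = vocab, bows = lapply(streams, to_bag_of_words, vocab = vocab))
}

test_that("k = 1 collapses to the smoothed empirical word distribution", {
  d <- make_bows(list(c("a", "a", "b"), c("b", "c")))
  m <- fit_lda(d$bows, d$vocab, k = 1, n_iterations = 5, seed = 1)
  expect_equal(unname(m$theta[, 1]), c(1, 1))
  counts <- c(a = 2, b = 2, c = 1)
  expect_equal(unname(m$phi[1, ]), unname((counts + m$eta) / (5 + 3 * m$eta)))
  expect_equal(rowSums(m$phi), 1, ignore_attr = TRUE)
  expect_equal(rowSums(m$theta), c(1, 1), ignore_attr = TRUE)
})

test_that("two disjoint-vocabulary document blocks get distinct dominant topics", {
  set.seed(42)
  streams <- c(
    lapply(1:10, function(i) sample(letters[1:5], 30, replace = TRUE)),
    lapply(1:10, function(i) sample(letters[6:10], 30, replace = TRUE)))
  d <- make_bows(streams)
  m <- fit_lda(d$bows, d$vocab, k = 2, alpha = 0.1, n_iterations = 500,
               seed = 9)
  dom <- dominant_topic(m$theta)
  expect_equal(length(unique(dom[1:10])), 1L)
  expect_equal(length(unique(dom[11:20])), 1L)
  expect_true(dom[1] != dom[11])
})

test_that("identical seed and inputs give a bit-identical model", {
  gen <- generate_corpus(small_synth_config(seed = 6))
  d <- make_bows(preprocess_corpus(gen$corpus))
  m1 <- fit_lda(d$bows, d$vocab, k = 3, n_iterations = 50, seed = 123)
  m2 <- fit_lda(d$bows, d$vocab, k = 3, n_iterations = 50, seed = 123)
  expect_identical(m1$z, m2$z)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$theta, m2$theta)
  m3 <- fit_lda(d$bows, d$vocab, k = 3, n_iterations = 50, seed = 124)
  expect_false(identical(m1$z, m3$z))
})

test_that("count conservation holds in the final Gibbs state", {
  gen <- generate_corpus(small_synth_config(seed = 8))
  d <- make_bows(preprocess_corpus(gen$corpus))
  m <- fit_lda(d$bows, d$vocab, k = 3, n_iterations = 20, seed = 5)
  n_d <- vapply(d$bows, function(b) sum(b[, "count"]), numeric(1))
  expect_equal(lengths(m$z), as.integer(n_d), ignore_attr = TRUE)
  z_all <- unlist(m$z)
  expect_equal(length(z_all), sum(n_d))
  expect_true(all(z_all >= 1L & z_all <= 3L))
})

test_that("empty documents are rejected by name", {
  v <- build_vocabulary(list(c("a", "b")))
  bows <- list(doc_a = to_bag_of_words(c("a", "b"), v),
               doc_b = to_bag_of_words("z", v))
  expect_error(fit_lda(bows, v, k = 2), "doc_b")
})

test_that("dominant_topic takes the argmax with lowest-index ties", {
  expect_equal(dominant_topic(c(0.2, 0.7, 0.1)), 2L)
  expect_equal(dominant_topic(c(0.5, 0.5)), 1L)
  expect_equal(dominant_topic(1), 1L)
  expect_equal(dominant_topic(rbind(c(0.2, 0.8), c(0.9, 0.1))), c(2L, 1L))
})

test_that("log_perplexity matches closed forms and hand arithmetic", {
  uniform <- structure(list(k = 2L, alpha = 0.5, eta = 0.1,
                            phi = matrix(1 / 10, 2, 10),
                            theta = matrix(c(0.3, 0.7), 1),
                            terms = letters[1:10]),
                       class = "nt_lda")
  bows <- list(cbind(index = c(1L, 4L), count = c(2L, 1L)))
  expect_equal(log_perplexity(uniform, bows), -log2(10))

  certain <- structure(list(k = 2L, phi = matrix(c(1, 1, 0, 0), 2, 2),
                            theta = matrix(c(0.4, 0.6), 1),
                            terms = c("a", "b")),
                       class = "nt_lda")
  expect_equal(log_perplexity(certain, list(cbind(index = 1L, count = 1L))), 0)

  # 3-token document, k=2, V=4, known theta/phi: brute-force mixture
  phi <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.4, 0.4))
  theta <- matrix(c(0.25, 0.75), 1)
  m <- structure(list(k = 2L, phi = phi, theta = theta, terms = letters[1:4]),
                 class = "nt_lda")
  b <- list(cbind(index = c(1L, 3L), count = c(2L, 1L)))
  pw <- as.numeric(theta %*% phi)
  expect_equal(log_perplexity(m, b), (2 * log2(pw[1]) + log2(pw[3])) / 3)

  expect_error(log_perplexity(m, list(cbind(index = 9L, count = 1L))),
               "vocabulary")
})

test_that("UMass coherence reproduces hand counts and its symmetries", {
  # docs {a,b}, {a}, {b}: D(a)=2, D(a,b)=1 -> log((1+1)/2) = 0
  d <- make_bows(list(c("a", "b"), "a", "b"))
  m <- structure(list(k = 1L, phi = matrix(c(0.6, 0.4), 1),
                      terms = c("a", "b")), class = "nt_lda")
  expect_equal(as.numeric(umass_coherence(m, d$bows, top_n = 2)), 0)

  # perfectly co-occurring top words give positive pair terms
  d2 <- make_bows(list(c("a", "b"), c("a", "b"), c("c")))
  m2 <- structure(list(k = 1L, phi = matrix(c(0.5, 0.4, 0.1), 1),
                       terms = c("a", "b", "c")), class = "nt_lda")
  expect_gt(as.numeric(umass_coherence(m2, d2$bows, top_n = 2)), 0)

  # two topics with identical top-word lists score identically
  m3 <- structure(list(k = 2L, phi = rbind(c(0.6, 0.3, 0.1),
                                           c(0.55, 0.35, 0.1)),
                       terms = c("a", "b", "c")), class = "nt_lda")
  sc <- attr(umass_coherence(m3, d2$bows, top_n = 2), "per_topic")
  expect_equal(sc[1], sc[2])
})

test_that("topic keywords are ranked by weight with sane degenerate cases", {
  streams <- list(rep("febbre", 5), c("febbre", "tosse"), c("medico"))
  d <- make_bows(streams)
  m <- fit_lda(d$bows, d$vocab, k = 1, n_iterations = 5, seed = 1)
  kw <- topic_keywords(m)
  expect_equal(kw$topic_1$term[1], "febbre")
  expect_equal(nrow(topic_keywords(m, top_n = 50)$topic_1), 3L)
  expect_true(all(diff(kw$topic_1$weight) <= 0))
})

test_that("the k-selection rule maximizes coherence with perplexity tie-breaks", {
  # singleton grid
  gen <- generate_corpus(small_synth_config(seed = 10))
  d <- make_bows(preprocess_corpus(gen$corpus))
  sel <- select_k(d$bows, d$vocab, k_grid = 3L, n_iterations = 30, seed = 2)
  expect_equal(sel$k, 3L)
  expect_equal(nrow(sel$records), 1L)

  # published sweep: coherence clearly separates -> k = 3
  published <- data.frame(k = c(3L, 5L, 7L, 10L),
                          coherence = c(0.407, 0.332, 0.299, 0.346),
                          log_perplexity = c(-7.248, -7.337, -7.398, -7.5239))
  expect_equal(choose_k(published), 3L)

  # near-tie in coherence resolved by perplexity closer to zero
  tied <- data.frame(k = c(3L, 5L), coherence = c(0.400, 0.405),
                     log_perplexity = c(-7.0, -7.5))
  expect_equal(choose_k(tied), 3L)
})
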