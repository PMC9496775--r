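test_that("default TF-IDF embedder is deterministic, unit-norm, orthogonal on disjoint vocabularies", {
  streams <- list(d1 = c("febbre", "tosse"), d2 = c("febbre", "tosse"),
                  d3 = c("medico", "reparto"))
  emb <- embed_documents(streams)
  expect_equal(emb[1, ], emb[2, ])
  expect_equal(sqrt(rowSums(emb^2)), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(sum(emb[1, ] * emb[3, ]), 0)
  expect_error(embed_documents(streams, embedder = "bert"), "unknown")
})

test_that("external embedder adapter validates its output", {
  streams <- list(a = "x", b = "y")
  emb <- embed_documents(streams, embedder = function(s) {
    matrix(seq_len(2 * length(s)), nrow = length(s))
  })
  expect_equal(dim(emb), c(2L, 2L))
  expect_equal(attr(emb, "embedder"), "external")
  expect_error(embed_documents(streams, embedder = function(s) {
    matrix(NaN, length(s), 2)
  }), "finite")
})

test_that("dimensionality reduction: identity, exact subspaces, sign convention", {
  set.seed(1)
  x <- matrix(rnorm(40), 8, 5)
  emb <- embed_documents(list(a = "x"), embedder = function(s) x[1, , drop = FALSE])
  expect_equal(unclass(reduce_dimensions(emb, method = "none")), unclass(emb))

  # rank-1 data: 1 component preserves geometry exactly
  v <- c(1, 2, 3, 4)
  rank1 <- outer(c(0.5, 1, 2, 3.5), v)
  red <- reduce_dimensions(structure(rank1, class = c("nt_embedding", "matrix", "array")),
                           n_components = 1)
  expect_equal(as.matrix(dist(red)), as.matrix(dist(rank1)))

  # 3 collinear points in 10-d: second component carries no variance
  base <- rnorm(10)
  coll <- rbind(0 * base, 1 * base, 2 * base)
  red2 <- reduce_dimensions(structure(coll, class = c("nt_embedding", "matrix", "array")),
                            n_components = 2)
  expect_lt(stats::var(red2[, 2]), 1e-20)

  expect_error(reduce_dimensions(structure(coll, class = c("nt_embedding", "matrix", "array")),
                                 n_components = 20), "exceeds")

  # deterministic sign: repeated runs identical
  y <- matrix(rnorm(60), 12, 5)
  e <- structure(y, class = c("nt_embedding", "matrix", "array"))
  expect_identical(reduce_dimensions(e, 3), reduce_dimensions(e, 3))
})

test_that("mutual reachability dominates raw distances and core distances", {
  set.seed(2)
  x <- matrix(rnorm(30), 15, 2)
  mr <- mutual_reachability(x, min_samples = 4)
  off <- upper.tri(mr$mreach)
  expect_true(all(mr$mreach[off] >= mr$dist[off] - 1e-12))
  core_mat <- outer(mr$core, mr$core, pmax)
  expect_true(all(mr$mreach[off] >= core_mat[off] - 1e-12))
})

test_that("Prim MST weight equals brute force over all spanning trees (n <= 7)", {
  for (n in c(4L, 5L, 6L, 7L)) {
    set.seed(n)
    x <- matrix(runif(2 * n), n, 2)
    w <- as.matrix(dist(x))
    edges <- narratopics:::prim_mst(w)
    expect_equal(sum(edges[, "weight"]), brute_force_mst_weight(w),
                 tolerance = 1e-12)
  }
})

test_that("too few points for a cluster yields all-noise with a warning", {
  x <- matrix(rnorm(10), 5, 2)
  expect_warning(cl <- hdbscan_cluster(x, min_cluster_size = 10), "noise")
  expect_equal(cl$labels, rep(-1L, 5))
  expect_equal(cl$strengths, rep(0, 5))
})

test_that("two far blobs plus one outlier give 2 clusters and 1 noise point", {
  set.seed(33)
  x <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 10, 0.1), 20, 2),
             c(50, 50))
  cl <- hdbscan_cluster(x, min_cluster_size = 5)
  expect_equal(length(cl$sizes), 2L)
  expect_equal(cl$n_noise, 1L)
  expect_equal(cl$labels[41], -1L)
  expect_equal(length(unique(cl$labels[1:20])), 1L)
  expect_equal(length(unique(cl$labels[21:40])), 1L)
  # cluster 1 is the largest, strengths of noise are 0, others in (0, 1]
  expect_equal(unname(cl$sizes[1]), max(cl$sizes))
  expect_equal(cl$strengths[41], 0)
  expect_true(all(cl$strengths[1:40] > 0 & cl$strengths[1:40] <= 1))
})

test_that("labels match the frozen reference-implementation fixture (ARI = 1)", {
  fix <- read.csv(test_path("fixtures", "hdbscan_oracle.csv"))
  for (s in unique(fix$set)) {
    g <- fix[fix$set == s, ]
    cl <- hdbscan_cluster(as.matrix(g[, c("x", "y")]),
                          min_cluster_size = 5, min_samples = 5)
    expect_equal(ari(cl$labels, g$oracle_label), 1.0,
                 info = paste("point set", s))
    expect_equal(sum(cl$labels == -1), sum(g$oracle_label == -1),
                 info = paste("noise count, point set", s))
  }
})

test_that("clusters are renumbered by decreasing size", {
  set.seed(4)
  x <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
             matrix(rnorm(20, 8, 0.1), 10, 2))
  cl <- hdbscan_cluster(x, min_cluster_size = 5)
  expect_equal(names(cl$sizes)[1], "1")
  expect_true(all(diff(unname(cl$sizes)) <= 0))
  expect_equal(assign_topics(cl), cl$labels)
})

test_that("class-based TF-IDF reproduces hand arithmetic", {
  tabs <- class_tfidf_keywords(list("1" = c("febbre", "febbre", "tosse"),
                                    "2" = c("paziente", "paziente", "tosse")))
  A <- attr(tabs, "A")
  expect_equal(A, 3)
  t1 <- tabs[["1"]]
  expect_equal(t1$term[1], "febbre")
  expect_equal(t1$weight[t1$term == "febbre"], 2 * log(1 + 3 / 2))
  expect_equal(t1$weight[t1$term == "tosse"], 1 * log(1 + 3 / 2))
  expect_false("paziente" %in% t1$term)
})

test_that("c-TF-IDF scaling invariance and degenerate single cluster", {
  base <- list("1" = c(rep("a", 2), "b"), "2" = c(rep("c", 3), "b"))
  scaled <- lapply(base, function(x) rep(x, 3))
  w1 <- class_tfidf_keywords(base)
  w2 <- class_tfidf_keywords(scaled)
  expect_equal(w1[["1"]]$term, w2[["1"]]$term)
  expect_equal(w1[["2"]]$term, w2[["2"]]$term)

  single <- class_tfidf_keywords(list("1" = c("a", "a", "b")))
  expect_equal(single[["1"]]$term[1], "a")
  expect_equal(single[["1"]]$weight,
               c(2 * log(1 + 3 / 2), 1 * log(1 + 3 / 1)))

  expect_error(class_tfidf_keywords(list("-1" = c("x"))), "no non-noise")
  expect_error(class_tfidf_keywords(list("1" = character(0))), "empty")
})

test_that("noise cluster is excluded from keyword extraction but kept in grouping", {
  streams <- list(a = c("x", "y"), b = c("x", "z"), c = c("w"))
  groups <- group_streams_by_cluster(streams, c(1L, 1L, -1L))
  expect_equal(names(groups), c("-1", "1"))
  kw <- class_tfidf_keywords(groups)
  expect_equal(names(kw), "1")
})
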