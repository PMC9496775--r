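#' Embed documents into a vector space
#'
#' The default embedder is a deterministic, download-free stand-in for a
#' pre-trained multilingual sentence encoder: L2-normalized TF-IDF vectors
#' over the corpus vocabulary (smoothed idf `log((1 + D) / (1 + df)) + 1`).
#' Two documents with disjoint vocabularies are exactly orthogonal under
#' it. Pass a function for an external encoder (e.g. a sentence-transformer
#' adapter): it receives the stream list and must return a D x d numeric
#' matrix with finite entries, one row per document in corpus order.
#'
#' @param streams named list of token character vectors (one per document).
#' @param embedder `"tfidf"` or a function `streams -> matrix`.
#' @param seed RNG seed forwarded to stochastic external embedders (the
#'   default embedder is deterministic and ignores it).
#' @return An `nt_embedding`: numeric matrix D x d with attributes
#'   `embedder` and `terms` (for the default embedder).
#' @export
embed_documents <- function(streams, embedder = "tfidf", seed = 1L) {
  stopifnot(length(streams) > 0L)
  if (is.function(embedder)) {
    emb <- embedder(streams)
    id <- "external"
  } else if (identical(embedder, "tfidf")) {
    vocab <- build_vocabulary(streams)
    D <- length(streams)
    idf <- log((1 + D) / (1 + vocab$df)) + 1
    emb <- matrix(0, nrow = D, ncol = length(vocab$terms))
    for (d in seq_len(D)) {
      b <- to_bag_of_words(streams[[d]], vocab)
      if (nrow(b) > 0L) emb[d, b[, "index"]] <- b[, "count"] * idf[b[, "index"]]
    }
    norms <- sqrt(rowSums(emb^2))
    emb[norms > 0, ] <- emb[norms > 0, , drop = FALSE] / norms[norms > 0]
    attr(emb, "terms") <- vocab$terms
    id <- "tfidf"
  } else {
    stop("unknown embedder: ", embedder)
  }
  if (!is.matrix(emb) || nrow(emb) != length(streams) || any(!is.finite(emb))) {
    stop("embedder must return a finite matrix with one row per document")
  }
  rownames(emb) <- names(streams)
  attr(emb, "embedder") <- id
  class(emb) <- c("nt_embedding", class(emb))
  emb
}

#' Reduce embedding dimensionality
#'
#' Default `method = "pca"` projects onto the top principal directions
#' (centered, unscaled), with a deterministic sign convention: within each
#' component the largest-magnitude loading is positive. `"none"` returns
#' the input unchanged. A function performs external reduction (e.g. a UMAP
#' adapter) and must return a D x n_components matrix.
#'
#' @param emb an `nt_embedding` (D x d).
#' @param n_components target dimension (<= d; default 5, the customary
#'   output dimension of UMAP in embedding-clustering topic pipelines).
#' @param method `"pca"`, `"none"`, or a function `(emb, n_components) -> matrix`.
#' @param seed forwarded to stochastic external reducers; the defaults are
#'   deterministic.
#' @return An `nt_embedding` of width `n_components` (or `d` for "none").
#' @export
reduce_dimensions <- function(emb, n_components = 5L, method = "pca", seed = 1L) {
  if (identical(method, "none")) return(emb)
  if (n_components > ncol(emb)) {
    stop("n_components (", n_components, ") exceeds embedding dimension (",
         ncol(emb), ")")
  }
  if (is.function(method)) {
    red <- method(emb, n_components)
    if (!is.matrix(red) || nrow(red) != nrow(emb)) {
      stop("external reducer must return one row per document")
    }
  } else if (identical(method, "pca")) {
    x <- unclass(emb)
    attributes(x) <- attributes(x)["dim"]
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
    rot <- pc$rotation
    flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
    flip[flip == 0] <- 1
    red <- pc$x %*% diag(flip, ncol(pc$x))
  } else {
    stop("unknown reduction method: ", method)
  }
  rownames(red) <- rownames(emb)
  colnames(red) <- NULL
  attr(red, "embedder") <- attr(emb, "embedder")
  class(red) <- c("nt_embedding", class(red))
  red
}
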