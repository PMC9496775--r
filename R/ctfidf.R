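#' Class-based TF-IDF cluster keywords
#'
#' The keyword-extraction step of the embedding/clustering track: all
#' documents of a cluster are concatenated into one pseudo-document and
#' each term is weighted by
#' `W(t, c) = tf(t, c) * log(1 + A / tf(t))`,
#' where `tf(t, c)` is the count of `t` in cluster `c`'s concatenation,
#' `tf(t)` the count of `t` across all clusters, and `A` the average token
#' count per cluster. The noise cluster `-1` is excluded both from the
#' tables and from the computation of `A` and `tf(t)`.
#'
#' @param streams_by_cluster named list: cluster id (as character) mapped to
#'   the concatenated token vector of its documents. Use
#'   [group_streams_by_cluster()] to build it from per-document streams.
#' @param top_n keywords per cluster (default 10).
#' @return An `nt_ctfidf`: named list (per non-noise cluster) of
#'   `data.frame(term, weight)` with non-increasing weights, ties broken
#'   lexicographically; attribute `A` carries the normalizer.
#' @examples
#' tabs <- class_tfidf_keywords(list(
#'   "1" = c("febbre", "febbre", "tosse"),
#'   "2" = c("paziente", "paziente", "tosse")))
#' tabs[["1"]]
#' @export
class_tfidf_keywords <- function(streams_by_cluster, top_n = 10L) {
  streams_by_cluster <-
    streams_by_cluster[names(streams_by_cluster) != "-1"]
  if (length(streams_by_cluster) == 0L) {
    stop("no non-noise cluster to extract keywords from")
  }
  sizes <- lengths(streams_by_cluster)
  if (any(sizes == 0L)) {
    stop("empty concatenation for cluster(s) ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  }
  A <- mean(sizes)
  tf_all <- table(unlist(streams_by_cluster, use.names = FALSE))
  out <- lapply(streams_by_cluster, function(toks) {
    tf_c <- table(toks)
    terms <- names(tf_c)
    w <- as.numeric(tf_c) * log(1 + A / as.numeric(tf_all[terms]))
    df <- data.frame(term = terms, weight = w, stringsAsFactors = FALSE)
    df <- df[df$weight > 0, , drop = FALSE]
    df <- df[order(-df$weight, df$term), , drop = FALSE]
    rownames(df) <- NULL
    head(df, top_n)
  })
  attr(out, "A") <- A
  class(out) <- "nt_ctfidf"
  out
}

#' @export
print.nt_ctfidf <- function(x, ...) {
  cat(sprintf("<nt_ctfidf> keywords for %d clusters (A = %.2f)\n",
              length(x), attr(x, "A")))
  invisible(x)
}

#' Concatenate per-document token streams by cluster label
#'
#' @param streams named list of per-document token vectors (corpus order).
#' @param labels integer vector of cluster/topic labels aligned with
#'   `streams` (`-1` allowed).
#' @return Named list mapping each label (as character, ascending, `-1`
#'   first) to the concatenated tokens of its documents.
#' @export
group_streams_by_cluster <- function(streams, labels) {
  stopifnot(length(streams) == length(labels))
  ids <- sort(unique(labels))
  out <- lapply(ids, function(l) {
    unlist(streams[labels == l], use.names = FALSE)
  })
  names(out) <- as.character(ids)
  out
}
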