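#' Topic-by-class contingency table
#'
#' Counts documents by (assigned topic, class label), the structure behind
#' the semi-supervised evaluation of both topic-modeling tracks. Topics are
#' sorted ascending so the noise topic `-1`, when present, comes first.
#'
#' @param topic_assignments integer vector of per-document topic ids
#'   (`-1` allowed for unassigned documents).
#' @param labels character vector of class labels (`PASC` / `NON_PASC`,
#'   any spelling accepted by [normalize_labels()]), aligned by document.
#' @return An `nt_contingency`: `data.frame(topic, n_pasc, n_non_pasc)`
#'   with attribute `N` (total documents).
#' @examples
#' contingency_table(c(1, 1, 2), c("non-PASC", "non-PASC", "PASC"))
#' @export
contingency_table <- function(topic_assignments, labels) {
  if (length(topic_assignments) == 0L) stop("empty topic assignments")
  if (length(topic_assignments) != length(labels)) {
    stop("topic assignments (", length(topic_assignments),
         ") and labels (", length(labels), ") differ in length")
  }
  labels <- normalize_labels(labels)
  if (any(labels == "UNLABELED")) {
    stop("all documents must be labeled PASC or non-PASC for evaluation")
  }
  topics <- sort(unique(topic_assignments))
  out <- data.frame(
    topic = topics,
    n_pasc = vapply(topics, function(t) {
      sum(topic_assignments == t & labels == "PASC")
    }, integer(1)),
    n_non_pasc = vapply(topics, function(t) {
      sum(topic_assignments == t & labels == "NON_PASC")
    }, integer(1)))
  attr(out, "N") <- length(labels)
  class(out) <- c("nt_contingency", "data.frame")
  out
}

#' Construct a contingency table from printed counts
#'
#' Convenience constructor for published topic-distribution tables.
#'
#' @param topic integer vector of topic ids.
#' @param n_pasc,n_non_pasc integer count vectors aligned with `topic`.
#' @return An `nt_contingency`.
#' @export
as_contingency <- function(topic, n_pasc, n_non_pasc) {
  stopifnot(length(topic) == length(n_pasc),
            length(topic) == length(n_non_pasc),
            all(n_pasc >= 0), all(n_non_pasc >= 0))
  ord <- order(topic)
  out <- data.frame(topic = as.integer(topic[ord]),
                    n_pasc = as.integer(n_pasc[ord]),
                    n_non_pasc = as.integer(n_non_pasc[ord]))
  attr(out, "N") <- sum(out$n_pasc) + sum(out$n_non_pasc)
  class(out) <- c("nt_contingency", "data.frame")
  out
}

#' Map unsupervised topics onto the two classes by majority counts
#'
#' The predicted Positive class is the non-noise topic holding the most
#' PASC documents; the predicted Negative class is the non-noise topic
#' holding the most non-PASC documents. Ties go to the lower topic id. If
#' both rules pick the same topic, the Positive class keeps it and the
#' Negative class takes the best remaining topic. The noise topic `-1` is
#' never eligible.
#'
#' @param table an `nt_contingency`.
#' @return List with `positive` and `negative` topic ids.
#' @export
map_topics_to_classes <- function(table) {
  stopifnot(inherits(table, "nt_contingency"))
  t2 <- table[table$topic != -1L, , drop = FALSE]
  if (nrow(t2) < 2L) {
    stop("degenerate mapping: need at least 2 non-noise topics, have ",
         nrow(t2))
  }
  by_pasc <- t2$topic[order(-t2$n_pasc, t2$topic)]
  by_non <- t2$topic[order(-t2$n_non_pasc, t2$topic)]
  positive <- by_pasc[1L]
  negative <- by_non[1L]
  if (negative == positive) negative <- by_non[2L]
  list(positive = positive, negative = negative)
}

#' Semi-supervised accuracy of a topic model
#'
#' With topics mapped to classes, true positives are the PASC documents in
#' the positive topic and true negatives the non-PASC documents in the
#' negative topic; accuracy is `(TP + TN) / N` with `N` counting *all*
#' documents, including those in other topics and in the noise topic (which
#' are credited to neither class). Percentages are reported to 2 decimals,
#' rounding half up.
#'
#' @param table an `nt_contingency`.
#' @param mapping a list with `positive`/`negative` topic ids; computed via
#'   [map_topics_to_classes()] when omitted.
#' @return An `nt_evaluation`: list with `positive_topic`, `negative_topic`,
#'   `tp`, `tn`, `n`, `accuracy`, `accuracy_pct`, `grouped_fraction` (named
#'   per class, with `_pct` twins) and `n_unassigned` per class.
#' @export
semi_supervised_accuracy <- function(table, mapping = NULL) {
  stopifnot(inherits(table, "nt_contingency"))
  if (is.null(mapping)) mapping <- map_topics_to_classes(table)
  if (!all(c(mapping$positive, mapping$negative) %in% table$topic) ||
      mapping$positive == -1L || mapping$negative == -1L ||
      mapping$positive == mapping$negative) {
    stop("invalid topic-to-class mapping for this table")
  }
  N <- attr(table, "N")
  tp <- table$n_pasc[table$topic == mapping$positive]
  tn <- table$n_non_pasc[table$topic == mapping$negative]
  noise <- table[table$topic == -1L, , drop = FALSE]
  out <- list(
    positive_topic = mapping$positive,
    negative_topic = mapping$negative,
    tp = tp, tn = tn, n = N,
    accuracy = (tp + tn) / N,
    accuracy_pct = round_half_up(100 * (tp + tn) / N, 2L),
    grouped_fraction = c(
      PASC = grouped_fraction(table, "PASC"),
      NON_PASC = grouped_fraction(table, "NON_PASC")),
    n_unassigned = c(
      PASC = if (nrow(noise)) noise$n_pasc else 0L,
      NON_PASC = if (nrow(noise)) noise$n_non_pasc else 0L))
  out$grouped_fraction_pct <- round_half_up(100 * out$grouped_fraction, 2L)
  class(out) <- "nt_evaluation"
  out
}

#' @export
print.nt_evaluation <- function(x, ...) {
  cat(sprintf(paste0(
    "<nt_evaluation> positive topic %d, negative topic %d\n",
    "  TP = %d, TN = %d, N = %d -> accuracy %.2f%%\n",
    "  grouped fraction: PASC %.2f%%, non-PASC %.2f%%; unassigned: %d PASC, %d non-PASC\n"),
    x$positive_topic, x$negative_topic, x$tp, x$tn, x$n, x$accuracy_pct,
    x$grouped_fraction_pct["PASC"], x$grouped_fraction_pct["NON_PASC"],
    x$n_unassigned["PASC"], x$n_unassigned["NON_PASC"]))
  invisible(x)
}

#' Grouped fraction of a class
#'
#' The share of a class's documents that land in that class's single best
#' (non-noise) topic: `max_t count(class, t) / total(class)`.
#'
#' @param table an `nt_contingency`.
#' @param class `"PASC"` or `"NON_PASC"` (any accepted spelling).
#' @return A fraction in `[0, 1]`.
#' @export
grouped_fraction <- function(table, class) {
  stopifnot(inherits(table, "nt_contingency"))
  class <- normalize_labels(class)
  col <- if (class == "PASC") "n_pasc" else "n_non_pasc"
  total <- sum(table[[col]])
  if (total == 0L) stop("no documents of class ", class, " in the table")
  t2 <- table[table$topic != -1L, , drop = FALSE]
  max(t2[[col]]) / total
}

#' Machine-readable topic-distribution report
#'
#' Long-format (topic, class, count) rows plus the per-topic keyword lists
#' — the data behind per-class topic-distribution bar charts and keyword
#' bar plots.
#'
#' @param table an `nt_contingency`.
#' @param keywords optional keyword tables: output of [topic_keywords()] or
#'   [class_tfidf_keywords()]. Entries are matched to topics by name
#'   (`topic_<id>` or `<id>`); topics without keywords (e.g. `-1`) get `NULL`.
#' @return List with `distribution` (`data.frame(topic, class, count)`),
#'   `keywords`, and `N`.
#' @export
distribution_report <- function(table, keywords = NULL) {
  stopifnot(inherits(table, "nt_contingency"))
  dist <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    data.frame(topic = rep(table$topic[i], 2L),
               class = c("PASC", "NON_PASC"),
               count = c(table$n_pasc[i], table$n_non_pasc[i]))
  }))
  kw <- NULL
  if (!is.null(keywords)) {
    kw <- lapply(table$topic, function(t) {
      hit <- match(TRUE, names(keywords) %in% c(as.character(t),
                                                paste0("topic_", t)))
      if (is.na(hit)) NULL else head(keywords[[hit]], 10L)
    })
    names(kw) <- as.character(table$topic)
  }
  list(distribution = dist, keywords = kw, N = attr(table, "N"))
}

# round half up at `digits` decimals (82.105 -> 82.11), unlike base R's
# round-half-even
round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}
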