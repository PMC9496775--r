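#' Labeled narrative corpora
#'
#' An `nt_corpus` is a data frame with columns `doc_id`, `text`, `label` and
#' `source`, one row per document, in a stable order. Labels take values in
#' `"PASC"`, `"NON_PASC"` and `"UNLABELED"`; the positive class (`PASC`,
#' post-acute sequelae of COVID-19) is the one the semi-supervised
#' evaluation tries to recover.
#'
#' @param texts character vector of raw document texts (non-empty after
#'   whitespace stripping).
#' @param labels character vector of class labels, recycled if length 1.
#'   See [normalize_labels()] for accepted spellings.
#' @param doc_ids optional character vector of unique document identifiers;
#'   generated as `doc_001`, ... when absent.
#' @param sources optional character vector of provenance strings.
#' @return An object of class `nt_corpus` (a `data.frame`).
#' @examples
#' corp <- corpus(c("ho avuto febbre e stanchezza", "i miei colleghi in corsia"),
#'                c("PASC", "non-PASC"))
#' n_docs(corp)
#' @export
corpus <- function(texts, labels = "UNLABELED", doc_ids = NULL, sources = NULL) {
  texts <- as.character(texts)
  if (length(texts) == 0L) stop("a corpus must contain at least one document")
  if (any(!nzchar(trimws(texts)))) {
    stop("documents ", paste(which(!nzchar(trimws(texts))), collapse = ", "),
         " are empty after whitespace stripping")
  }
  labels <- normalize_labels(rep_len(as.character(labels), length(texts)))
  if (is.null(doc_ids)) {
    doc_ids <- sprintf("doc_%03d", seq_along(texts))
  }
  doc_ids <- as.character(doc_ids)
  if (anyDuplicated(doc_ids)) stop("doc_id values must be unique within a corpus")
  if (is.null(sources)) sources <- rep("", length(texts))
  out <- data.frame(doc_id = doc_ids, text = texts, label = labels,
                    source = rep_len(as.character(sources), length(texts)),
                    stringsAsFactors = FALSE)
  class(out) <- c("nt_corpus", "data.frame")
  out
}

#' @export
print.nt_corpus <- function(x, ...) {
  cnt <- label_counts(x)
  cat(sprintf("<nt_corpus> %d documents (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", ")))
  invisible(x)
}

#' Number of documents in a corpus
#' @param corpus an `nt_corpus`.
#' @return Integer document count.
#' @export
n_docs <- function(corpus) nrow(corpus)

#' Per-class document counts
#' @param corpus an `nt_corpus`.
#' @return Named integer vector over the label levels present.
#' @export
label_counts <- function(corpus) {
  tab <- table(corpus$label)
  setNames(as.integer(tab), names(tab))
}

#' Map free-form class tags onto the label enum
#'
#' Accepts case-insensitive variants of the two class names ("PASC",
#' "non-PASC", "non_pasc", "nonPASC", ...) plus "UNLABELED"/""/NA for
#' unlabeled documents. Any other value is rejected rather than coerced.
#'
#' @param x character vector of raw labels.
#' @return Character vector with values in `PASC`, `NON_PASC`, `UNLABELED`.
#' @export
normalize_labels <- function(x) {
  key <- gsub("[-_ ]", "", tolower(as.character(x)))
  key[is.na(key) | key == ""] <- "unlabeled"
  map <- c(pasc = "PASC", nonpasc = "NON_PASC", unlabeled = "UNLABELED")
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop("unmappable label value(s) ", paste(unique(x[bad]), collapse = ", "),
         " in row(s) ", paste(bad, collapse = ", "))
  }
  out
}

#' Read a labeled corpus from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row. The text and
#' label columns are required; `doc_id` and `source` columns are used when
#' present and generated/defaulted otherwise. Rows whose text is empty after
#' whitespace stripping are dropped and counted in the load report (attached
#' as attribute `load_report` and emitted via `message()`).
#'
#' @param path path to an existing CSV file.
#' @param text_column,label_column names of the text and label columns.
#' @param quiet suppress the load-report message.
#' @return An [corpus()] object; `attr(, "load_report")` holds rows read,
#'   rows dropped and class counts.
#' @export
read_corpus_csv <- function(path, text_column = "text", label_column = "label",
                            quiet = FALSE) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  fileEncoding = "UTF-8")
  for (col in c(text_column, label_column)) {
    if (!col %in% names(raw)) {
      stop("required column '", col, "' not present in ", path)
    }
  }
  keep <- nzchar(trimws(raw[[text_column]])) & !is.na(raw[[text_column]])
  dropped <- which(!keep)
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no non-empty documents in ", path)
  corp <- corpus(
    texts = raw[[text_column]],
    labels = raw[[label_column]],
    doc_ids = if ("doc_id" %in% names(raw)) raw$doc_id else NULL,
    sources = if ("source" %in% names(raw)) raw$source else basename(path)
  )
  report <- list(rows_read = length(keep), rows_dropped = length(dropped),
                 dropped_rows = dropped, class_counts = label_counts(corp))
  attr(corp, "load_report") <- report
  if (!quiet) {
    message(sprintf("read %d rows from %s: kept %d, dropped %d empty (%s)",
                    report$rows_read, path, nrow(corp), report$rows_dropped,
                    paste(sprintf("%s=%d", names(report$class_counts),
                                  report$class_counts), collapse = ", ")))
  }
  corp
}

#' Write a corpus to CSV
#'
#' Standard CSV quoting, UTF-8, header `doc_id,text,label,source`. The
#' written file round-trips through [read_corpus_csv()]: texts, labels and
#' document order are preserved exactly.
#'
#' @param corpus a non-empty `nt_corpus`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus_csv <- function(corpus, path) {
  stopifnot(inherits(corpus, "nt_corpus"))
  if (nrow(corpus) == 0L) stop("refusing to write an empty corpus")
  df <- as.data.frame(corpus)[, c("doc_id", "text", "label", "source")]
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Descriptive word-count statistics of a corpus
#'
#' Summarizes per-document token counts overall and per class: minimum,
#' maximum, mean, median and interquartile range (words/document). By
#' default tokens are whitespace-delimited runs of the raw text, i.e. the
#' counts describe the corpus *before* cleaning; pass a different
#' `tokenizer` (e.g. one applying [clean_text()]) for post-cleaning counts.
#'
#' @param corpus a non-empty `nt_corpus`.
#' @param tokenizer function mapping one raw text to a token count rule;
#'   must return an integer count. Default counts whitespace tokens.
#' @return A `data.frame` with one row per class plus `"ALL"`, columns
#'   `class`, `n_docs`, `min`, `max`, `mean`, `median`, `iqr`.
#' @export
corpus_summary <- function(corpus, tokenizer = count_whitespace_tokens) {
  stopifnot(inherits(corpus, "nt_corpus"), nrow(corpus) > 0L)
  counts <- vapply(corpus$text, tokenizer, numeric(1), USE.NAMES = FALSE)
  one <- function(cls, x) {
    data.frame(class = cls, n_docs = length(x), min = min(x), max = max(x),
               mean = mean(x), median = stats::median(x),
               iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(sort(unique(corpus$label)), function(cls) {
    one(cls, counts[corpus$label == cls])
  })
  out <- do.call(rbind, c(rows, list(one("ALL", counts))))
  rownames(out) <- NULL
  class(out) <- c("nt_corpus_summary", "data.frame")
  out
}

#' @rdname corpus_summary
#' @param text a single character string.
#' @export
count_whitespace_tokens <- function(text) {
  length(strsplit(trimws(text), "\\s+")[[1]])
}
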