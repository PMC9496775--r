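#' Clean raw narrative text
#'
#' Applies the cleaning steps in a fixed order: lowercasing, URL removal,
#' replacement of punctuation/special characters with spaces, optional
#' removal of digits-only tokens, and collapse of redundant separators.
#' Letters (including accented Italian letters) and underscores always
#' survive; hyphens survive only with `keep_hyphens = TRUE`. The operation
#' is idempotent: cleaning already-clean text is a no-op.
#'
#' @param raw a character vector of raw texts.
#' @param keep_hyphens keep intra-word hyphens (default `FALSE`, so
#'   `"covid-19"` becomes `"covid 19"` and then, under `remove_digits`,
#'   `"covid"`).
#' @param remove_digits drop tokens consisting only of digits (default `TRUE`).
#' @param url_removal strip `http(s)://...` and `www....` runs (default `TRUE`).
#' @return Cleaned character vector (possibly empty strings).
#' @examples
#' clean_text("La FEBBRE, e' tornata! https://x.it")
#' @export
clean_text <- function(raw, keep_hyphens = FALSE, remove_digits = TRUE,
                       url_removal = TRUE) {
  x <- tolower(as.character(raw))
  if (url_removal) {
    x <- gsub("(https?://|www\\.)[^[:space:]]+", " ", x, perl = TRUE)
  }
  allowed <- if (keep_hyphens) "[^\\p{L}\\p{N}_-]+" else "[^\\p{L}\\p{N}_]+"
  x <- gsub(allowed, " ", x, perl = TRUE)
  if (keep_hyphens) {
    # strip hyphens not embedded in a token ("- word -", "--")
    x <- gsub("(^|\\s)-+|-+(\\s|$)", " ", x, perl = TRUE)
  }
  if (remove_digits) {
    x <- gsub("(^|\\s)\\p{N}+(?=\\s|$)", " ", x, perl = TRUE)
  }
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Split cleaned text into tokens
#'
#' Whitespace tokenization; empty tokens are discarded. Intended to run on
#' the output of [clean_text()].
#'
#' @param cleaned a single cleaned string.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(cleaned) {
  toks <- strsplit(trimws(cleaned), "\\s+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Remove stopwords from a token stream
#'
#' @param tokens character vector of lowercase tokens.
#' @param stopwords character vector (lowercase) of tokens to drop.
#' @return The surviving tokens, order preserved. Idempotent.
#' @export
remove_stopwords <- function(tokens, stopwords) {
  tokens[!tokens %in% stopwords]
}

#' Lemmatize a token stream through a pluggable lemmatizer
#'
#' The lemmatizer is either `NULL` (identity: synthetic corpora ship
#' pre-lemmatized vocabularies), a named character vector used as a
#' token-to-lemma dictionary (unknown tokens pass through unchanged), or a
#' function mapping a token vector to a lemma vector of equal length. This
#' is the adapter point for an external Italian morphological lemmatizer.
#'
#' @param tokens character vector of tokens.
#' @param lemmatizer `NULL`, a named character vector, or a function.
#' @return Character vector of lemmas, same length, lowercase.
#' @export
lemmatize <- function(tokens, lemmatizer = NULL) {
  if (is.null(lemmatizer)) return(tokens)
  if (is.function(lemmatizer)) {
    out <- lemmatizer(tokens)
    if (length(out) != length(tokens)) {
      stop("lemmatizer must preserve stream length")
    }
    return(tolower(out))
  }
  hit <- match(tokens, names(lemmatizer))
  out <- tokens
  out[!is.na(hit)] <- unname(lemmatizer[hit[!is.na(hit)]])
  tolower(out)
}

#' Read a stopword list file
#'
#' UTF-8 plain text, one token per line; `#` starts a comment; blank lines
#' ignored.
#'
#' @param path stopword file path.
#' @return Character vector of lowercase stopwords.
#' @export
read_stopwords <- function(path) {
  if (!file.exists(path)) stop("stopword file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(tolower(lines[nzchar(lines)]))
}

#' Default Italian stopword list
#'
#' The base Italian function-word list shipped with the package, optionally
#' merged with the domain "expansion" list (frequent but uninformative
#' corpus words), mirroring the practice of massively expanding a standard
#' stopword list for narrative-medicine text.
#'
#' @param expanded include the expansion list (default `TRUE`).
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function(expanded = TRUE) {
  base <- read_stopwords(system.file("extdata", "stopwords_it.txt",
                                     package = "narratopics", mustWork = TRUE))
  if (!expanded) return(base)
  extra <- read_stopwords(system.file("extdata", "stopwords_it_expansion.txt",
                                      package = "narratopics", mustWork = TRUE))
  unique(c(base, extra))
}

#' Build a vocabulary (token dictionary) from token streams
#'
#' Assigns indices `1..V` in order of first occurrence across the streams
#' and records each token's document frequency. Tokens appearing in fewer
#' than `min_df` documents, or in more than `max_df_fraction * n_docs`
#' documents, are excluded. Defaults perform no filtering.
#'
#' @param streams list of token character vectors (one per document).
#' @param min_df minimum document frequency (default 1).
#' @param max_df_fraction maximum document frequency as a fraction of the
#'   number of streams (default 1.0).
#' @return An `nt_vocab`: list with `terms` (character, index order), `df`
#'   (integer document frequencies, same order) and `n_docs`.
#' @export
build_vocabulary <- function(streams, min_df = 1L, max_df_fraction = 1.0) {
  stopifnot(is.list(streams), length(streams) > 0L)
  first_seen <- character(0)
  for (s in streams) first_seen <- c(first_seen, setdiff(unique(s), first_seen))
  if (length(first_seen) == 0L) stop("all streams are empty; no vocabulary")
  df <- integer(length(first_seen))
  names(df) <- first_seen
  for (s in streams) {
    u <- unique(s)
    df[u] <- df[u] + 1L
  }
  n <- length(streams)
  keep <- df >= min_df & df <= max_df_fraction * n
  if (!any(keep)) stop("vocabulary filtering removed every token")
  vocab <- list(terms = first_seen[keep], df = unname(df[keep]), n_docs = n)
  class(vocab) <- "nt_vocab"
  vocab
}

#' @export
print.nt_vocab <- function(x, ...) {
  cat(sprintf("<nt_vocab> %d terms over %d documents\n",
              length(x$terms), x$n_docs))
  invisible(x)
}

#' Sparse bag-of-words representation of one document
#'
#' Each in-vocabulary token type becomes a `(index, count)` pair; entries
#' are sorted by strictly increasing vocabulary index. Out-of-vocabulary
#' tokens are dropped. The sum of counts equals the number of surviving
#' tokens.
#'
#' @param tokens character vector of tokens for one document.
#' @param vocab an `nt_vocab` from [build_vocabulary()].
#' @return Integer matrix with columns `index` and `count` (possibly 0 rows).
#' @export
to_bag_of_words <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "nt_vocab"))
  idx <- match(tokens, vocab$terms)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("index", "count"))))
  }
  tab <- table(idx)
  out <- cbind(index = as.integer(names(tab)), count = as.integer(tab))
  out[order(out[, "index"]), , drop = FALSE]
}

#' Corpus-wide term-frequency table
#'
#' Total occurrence counts across all streams, sorted by decreasing count
#' with ties broken lexicographically — the data behind a word-cloud figure.
#'
#' @param streams list of token character vectors.
#' @param top_n number of terms to return (>= 1); all terms if larger than
#'   the vocabulary.
#' @return `data.frame` with columns `term` and `count`.
#' @export
term_frequency_table <- function(streams, top_n = 20L) {
  stopifnot(top_n >= 1L)
  all_tokens <- unlist(streams, use.names = FALSE)
  tab <- table(all_tokens)
  df <- data.frame(term = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$term), , drop = FALSE]
  rownames(df) <- NULL
  head(df, top_n)
}

#' Run the full preprocessing pipeline over a corpus
#'
#' clean -> tokenize -> stopword removal -> lemmatization, per document,
#' returning named token streams (names are `doc_id`s).
#'
#' @param corpus an `nt_corpus`.
#' @param stopwords character vector of stopwords (default: none).
#' @param lemmatizer see [lemmatize()].
#' @param keep_hyphens,remove_digits,url_removal cleaning flags, see
#'   [clean_text()].
#' @return Named list of token character vectors.
#' @export
preprocess_corpus <- function(corpus, stopwords = character(0),
                              lemmatizer = NULL, keep_hyphens = FALSE,
                              remove_digits = TRUE, url_removal = TRUE) {
  stopifnot(inherits(corpus, "nt_corpus"))
  cleaned <- clean_text(corpus$text, keep_hyphens = keep_hyphens,
                        remove_digits = remove_digits, url_removal = url_removal)
  streams <- lapply(cleaned, function(x) {
    lemmatize(remove_stopwords(tokenize(x), stopwords), lemmatizer)
  })
  names(streams) <- corpus$doc_id
  streams
}
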