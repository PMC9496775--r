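#' Configuration for an end-to-end pipeline run
#'
#' Exactly one input source must be given: a corpus CSV path or a synthetic
#' generator configuration. One global `seed` is expanded into per-stage
#' seeds by a fixed splitting rule (see [stage_seed()]), so adding or
#' skipping a stage never perturbs the randomness of the others.
#'
#' @param input_csv path to a labeled corpus CSV, or `NULL`.
#' @param synthetic an [synthetic_config()] object, or `NULL`.
#' @param track `"both"`, `"lda"` or `"cluster"`.
#' @param stopwords stopword vector (e.g. [default_stopwords()]); default
#'   none, which is correct for synthetic corpora.
#' @param lemmatizer see [lemmatize()].
#' @param keep_hyphens,remove_digits,url_removal cleaning flags.
#' @param k_grid LDA topic-count sweep grid (a single value skips model
#'   selection).
#' @param alpha,eta,n_iterations LDA hyperparameters ([fit_lda()] defaults).
#' @param embedder,reducer,n_components,min_cluster_size,min_samples,metric
#'   clustering-track settings (see [embed_documents()],
#'   [reduce_dimensions()], [hdbscan_cluster()]).
#' @param outdir output directory for tables, metrics and the log.
#' @param seed global RNG seed.
#' @param quiet suppress progress messages.
#' @return An `nt_run_config` list.
#' @export
run_config <- function(input_csv = NULL, synthetic = NULL,
                       track = c("both", "lda", "cluster"),
                       stopwords = character(0), lemmatizer = NULL,
                       keep_hyphens = FALSE, remove_digits = TRUE,
                       url_removal = TRUE,
                       k_grid = c(3L, 5L, 7L, 10L), alpha = NULL, eta = 0.01,
                       n_iterations = 1000L,
                       embedder = "tfidf", reducer = "pca", n_components = 5L,
                       min_cluster_size = 10L, min_samples = NULL,
                       metric = "euclidean",
                       outdir = tempfile("narratopics_run_"), seed = 1L,
                       quiet = FALSE) {
  track <- match.arg(track)
  if (is.null(input_csv) == is.null(synthetic)) {
    stop("exactly one input source required: input_csv or synthetic")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "nt_synth_config"))
  cfg <- list(input_csv = input_csv, synthetic = synthetic, track = track,
              stopwords = stopwords, lemmatizer = lemmatizer,
              keep_hyphens = keep_hyphens, remove_digits = remove_digits,
              url_removal = url_removal,
              k_grid = as.integer(k_grid), alpha = alpha, eta = eta,
              n_iterations = as.integer(n_iterations),
              embedder = embedder, reducer = reducer,
              n_components = as.integer(n_components),
              min_cluster_size = as.integer(min_cluster_size),
              min_samples = if (is.null(min_samples)) NULL
                            else as.integer(min_samples),
              metric = metric, outdir = outdir, seed = as.integer(seed),
              quiet = isTRUE(quiet))
  class(cfg) <- "nt_run_config"
  cfg
}

#' Per-stage seed splitting
#'
#' Deterministically expands one global seed into independent per-stage
#' seeds: `(31 * seed + 104729 * stage_index) mod (2^31 - 1)`. Stage
#' indices are fixed (`generate` = 1, `lda` = 2, `embed` = 3, `reduce` = 4),
#' so the LDA chain does not move when the clustering track is toggled.
#'
#' @param seed global integer seed.
#' @param stage one of `"generate"`, `"lda"`, `"embed"`, `"reduce"`.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("generate", "lda", "embed", "reduce"))
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer((31 * as.numeric(seed) + 104729 * idx) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Generate-or-load corpus, preprocess, run the selected topic-modeling
#' track(s), evaluate semi-supervised accuracy, and write all artifacts:
#' the corpus CSV (for synthetic input), per-track contingency TSVs and
#' keyword TSVs, a `metrics.json`, and a plain-text log recording every
#' decision parameter. Identical configuration and seed yield a
#' byte-identical `metrics.json`.
#'
#' @param config an [run_config()] object.
#' @return A run manifest: list with `outputs` (named file paths),
#'   `metrics` (per-track evaluation lists), `corpus`, and per-track model
#'   objects. Any stage error is re-thrown with the stage name in context.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nt_run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!config$quiet) message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  outputs <- list()
  note("seed: %d (stages: generate=%d lda=%d embed=%d reduce=%d)",
       config$seed, stage_seed(config$seed, "generate"),
       stage_seed(config$seed, "lda"), stage_seed(config$seed, "embed"),
       stage_seed(config$seed, "reduce"))

  # ---- input ----
  truth <- NULL
  corp <- run_stage("input", {
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$seed <- stage_seed(config$seed, "generate")
      gen <- generate_corpus(cfg)
      truth <- gen$truth
      path <- file.path(config$outdir, "corpus.csv")
      write_corpus_csv(gen$corpus, path)
      outputs$corpus_csv <- path
      gen$corpus
    } else {
      read_corpus_csv(config$input_csv, quiet = config$quiet)
    }
  })
  note("corpus: %d documents (%s)", n_docs(corp),
       paste(sprintf("%s=%d", names(label_counts(corp)), label_counts(corp)),
             collapse = ", "))

  # ---- preprocessing ----
  streams <- run_stage("preprocess", {
    preprocess_corpus(corp, stopwords = config$stopwords,
                      lemmatizer = config$lemmatizer,
                      keep_hyphens = config$keep_hyphens,
                      remove_digits = config$remove_digits,
                      url_removal = config$url_removal)
  })
  note("preprocess: %d stopwords, %d total tokens", length(config$stopwords),
       sum(lengths(streams)))

  fp <- corpus_fingerprint(corp)
  metrics <- list()
  models <- list()

  # ---- LDA track ----
  if (config$track %in% c("both", "lda")) {
    res <- run_stage("lda", {
      vocab <- build_vocabulary(streams)
      bows <- lapply(streams, to_bag_of_words, vocab = vocab)
      sel <- select_k(bows, vocab, k_grid = config$k_grid,
                      alpha = config$alpha, eta = config$eta,
                      n_iterations = config$n_iterations,
                      seed = stage_seed(config$seed, "lda"))
      model <- sel$models[[as.character(sel$k)]]
      topics <- dominant_topic(model$theta)
      tab <- contingency_table(topics, corp$label)
      ev <- semi_supervised_accuracy(tab)
      list(sel = sel, model = model, tab = tab, ev = ev,
           keywords = topic_keywords(model))
    })
    note("lda: k grid {%s} -> k=%d; positive topic %d, negative topic %d; accuracy %.2f%%",
         paste(config$k_grid, collapse = ","), res$sel$k,
         res$ev$positive_topic, res$ev$negative_topic, res$ev$accuracy_pct)
    outputs$lda_contingency <- write_contingency_tsv(
      res$tab, file.path(config$outdir, "lda_contingency.tsv"))
    outputs$lda_keywords <- write_keywords_tsv(
      res$keywords, file.path(config$outdir, "lda_keywords.tsv"))
    metrics$lda <- evaluation_metrics(res$ev, fp,
                                      extra = list(k = res$sel$k,
                                                   records = res$sel$records))
    models$lda <- res
  }

  # ---- clustering track ----
  if (config$track %in% c("both", "cluster")) {
    res <- run_stage("cluster", {
      emb <- embed_documents(streams, embedder = config$embedder,
                             seed = stage_seed(config$seed, "embed"))
      red <- reduce_dimensions(emb, n_components = config$n_components,
                               method = config$reducer,
                               seed = stage_seed(config$seed, "reduce"))
      cl <- hdbscan_cluster(
        red, min_cluster_size = config$min_cluster_size,
        min_samples = if (is.null(config$min_samples)) config$min_cluster_size
                      else config$min_samples,
        metric = config$metric)
      topics <- assign_topics(cl)
      tab <- contingency_table(topics, corp$label)
      ev <- semi_supervised_accuracy(tab)
      kw <- class_tfidf_keywords(group_streams_by_cluster(streams, topics))
      list(clustering = cl, tab = tab, ev = ev, keywords = kw)
    })
    note("cluster: %d clusters + %d noise docs; positive topic %d, negative topic %d; accuracy %.2f%%",
         length(res$clustering$sizes), res$clustering$n_noise,
         res$ev$positive_topic, res$ev$negative_topic, res$ev$accuracy_pct)
    outputs$cluster_contingency <- write_contingency_tsv(
      res$tab, file.path(config$outdir, "cluster_contingency.tsv"))
    outputs$cluster_keywords <- write_keywords_tsv(
      res$keywords, file.path(config$outdir, "cluster_keywords.tsv"))
    metrics$cluster <- evaluation_metrics(
      res$ev, fp, extra = list(n_clusters = length(res$clustering$sizes),
                               n_noise = res$clustering$n_noise))
    models$cluster <- res
  }

  # ---- reports ----
  metrics_path <- file.path(config$outdir, "metrics.json")
  jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs$metrics_json <- metrics_path
  log_path <- file.path(config$outdir, "log.txt")
  writeLines(log_lines, log_path)
  outputs$log <- log_path

  list(outputs = outputs, metrics = metrics, corpus = corp, truth = truth,
       models = models)
}

evaluation_metrics <- function(ev, fingerprint, extra = list()) {
  c(list(fingerprint = fingerprint,
         positive_topic = ev$positive_topic,
         negative_topic = ev$negative_topic,
         tp = ev$tp, tn = ev$tn, n = ev$n,
         accuracy = ev$accuracy, accuracy_pct = ev$accuracy_pct,
         grouped_fraction = as.list(ev$grouped_fraction),
         n_unassigned = as.list(ev$n_unassigned)),
    extra)
}

#' Compare the two tracks' evaluation metrics
#'
#' @param metrics_lda,metrics_cluster per-track entries of a
#'   [run_pipeline()] manifest's `metrics` (must describe the same corpus:
#'   fingerprints are checked).
#' @return List with a side-by-side `table` (accuracy and grouped
#'   fractions) and `better` (`"lda"`, `"cluster"` or `"tie"`).
#' @export
compare_tracks <- function(metrics_lda, metrics_cluster) {
  if (!identical(metrics_lda$fingerprint, metrics_cluster$fingerprint)) {
    stop("metrics were computed on different corpora (fingerprint mismatch)")
  }
  tab <- data.frame(
    track = c("lda", "cluster"),
    accuracy = c(metrics_lda$accuracy, metrics_cluster$accuracy),
    accuracy_pct = c(metrics_lda$accuracy_pct, metrics_cluster$accuracy_pct),
    grouped_pasc = c(metrics_lda$grouped_fraction$PASC,
                     metrics_cluster$grouped_fraction$PASC),
    grouped_non_pasc = c(metrics_lda$grouped_fraction$NON_PASC,
                         metrics_cluster$grouped_fraction$NON_PASC))
  better <- if (metrics_lda$accuracy > metrics_cluster$accuracy) "lda"
            else if (metrics_cluster$accuracy > metrics_lda$accuracy) "cluster"
            else "tie"
  list(table = tab, better = better)
}

#' Cheap deterministic corpus fingerprint
#'
#' Used to guard against comparing metrics from different corpora; not a
#' cryptographic hash.
#'
#' @param corpus an `nt_corpus`.
#' @return A character fingerprint.
#' @export
corpus_fingerprint <- function(corpus) {
  sums <- vapply(corpus$text, function(t) sum(utf8ToInt(t)), numeric(1),
                 USE.NAMES = FALSE)
  mix <- sum(sums * seq_along(sums)) %% 2147483647
  sprintf("%d-%d-%.0f", nrow(corpus), sum(nchar(corpus$text)), mix)
}

write_contingency_tsv <- function(tab, path) {
  long <- distribution_report(tab)$distribution
  utils::write.table(long, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

write_keywords_tsv <- function(keywords, path) {
  rows <- do.call(rbind, lapply(names(keywords), function(nm) {
    kw <- keywords[[nm]]
    if (is.null(kw) || nrow(kw) == 0L) return(NULL)
    data.frame(topic = nm, rank = seq_len(nrow(kw)), term = kw$term,
               weight = kw$weight, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}
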