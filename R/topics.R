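#' LDA configuration
#'
#' Defaults: five topics with symmetric Dirichlet priors `alpha = eta =
#' 1/M`, up to 50 variational passes (with early stopping on the evidence
#' lower bound), and vocabulary pruning that removes k-mers seen fewer
#' than twice in the whole corpus.
#'
#' @param num_topics number of topics M (>= 2).
#' @param alpha symmetric document-topic Dirichlet parameter; default 1/M.
#' @param eta symmetric topic-word Dirichlet parameter; default 1/M.
#' @param passes maximum variational EM passes over the corpus.
#' @param seed integer seed for reproducible fits, or `NULL`.
#' @param min_corpus_freq minimum total corpus count for a k-mer to enter
#'   the vocabulary.
#' @param min_doc_freq minimum number of documents a k-mer must occur in.
#' @return a list of class `lda_config`.
#' @export
lda_config <- function(num_topics = 5, alpha = NULL, eta = NULL,
                       passes = 50, seed = NULL,
                       min_corpus_freq = 2, min_doc_freq = 1) {
  num_topics <- as.integer(num_topics)
  if (num_topics < 2) stop("num_topics must be >= 2")
  if (is.null(alpha)) alpha <- 1 / num_topics
  if (is.null(eta)) eta <- 1 / num_topics
  stopifnot(alpha > 0, eta > 0, passes >= 1)
  structure(list(num_topics = num_topics, alpha = alpha, eta = eta,
                 passes = as.integer(passes), seed = seed,
                 min_corpus_freq = min_corpus_freq,
                 min_doc_freq = min_doc_freq),
            class = "lda_config")
}

#' Build a pruned vocabulary from a k-mer corpus
#'
#' k-mers below the frequency thresholds are removed (low-frequency words
#' mostly contribute noise to the topic-word distributions); ids are dense
#' `0..V-1` in order of first occurrence across documents.
#'
#' @param corpus a `kmer_corpus` from [decompose()].
#' @param min_corpus_freq minimum total count across the corpus.
#' @param min_doc_freq minimum number of documents containing the k-mer.
#' @return an object of class `kmer_vocab`: list with `locus_id`, `kmer`
#'   (character vector in id order), `corpus_freq`, `doc_freq`.
#' @export
build_vocabulary <- function(corpus, min_corpus_freq = 2, min_doc_freq = 1) {
  stopifnot(inherits(corpus, "kmer_corpus"))
  all_tokens <- unlist(corpus$docs, use.names = FALSE)
  if (!length(all_tokens)) stop("corpus ", corpus$locus_id, " has no tokens")
  words <- unique(all_tokens)                      # first-occurrence order
  cf <- tabulate(match(all_tokens, words), nbins = length(words))
  df <- integer(length(words))
  for (d in corpus$docs) {
    hit <- unique(match(d, words))
    df[hit] <- df[hit] + 1L
  }
  keep <- cf >= min_corpus_freq & df >= min_doc_freq
  if (!any(keep))
    stop("vocabulary of locus '", corpus$locus_id, "' is empty after ",
         "pruning; lower min_corpus_freq/min_doc_freq or use a smaller k")
  structure(list(locus_id = corpus$locus_id, kmer = words[keep],
                 corpus_freq = cf[keep], doc_freq = df[keep]),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat("<kmer_vocab> ", x$locus_id, ": ", length(x$kmer), " k-mers\n",
      sep = "")
  invisible(x)
}

.corpus_bow <- function(corpus, vocab) {
  # bag-of-words: per document, 0-based vocabulary ids and counts
  lapply(corpus$docs, function(toks) {
    idx <- match(toks, vocab$kmer)
    idx <- idx[!is.na(idx)]
    if (!length(idx))
      return(list(ids = integer(0), counts = numeric(0)))
    tab <- tabulate(idx, nbins = length(vocab$kmer))
    ids <- which(tab > 0L)
    list(ids = ids - 1L, counts = as.numeric(tab[ids]))
  })
}

#' Fit a latent Dirichlet allocation model to one locus
#'
#' Batch variational Bayes (document-topic Dirichlet `gamma`, topic-word
#' Dirichlet `lambda`) maximizing a lower bound on the corpus likelihood.
#' With a fixed `seed` in the configuration the fit is bit-reproducible.
#' Documents left with zero in-vocabulary tokens receive a uniform topic
#' frequency vector and a warning, so the downstream character matrix
#' stays rectangular.
#'
#' @param corpus a `kmer_corpus`.
#' @param config an [lda_config()].
#' @param vocab optional [build_vocabulary()] result; built from `corpus`
#'   with the config's thresholds when `NULL`.
#' @return an object of class `topic_fit`: list with `locus_id`, `theta`
#'   (documents x topics frequency matrix, rows sum to 1), `beta` (topics
#'   x vocabulary word distributions, rows sum to 1), `bound` (final
#'   evidence lower bound), `vocab`, and the `config` used.
#' @export
fit_lda <- function(corpus, config = lda_config(), vocab = NULL) {
  stopifnot(inherits(corpus, "kmer_corpus"), inherits(config, "lda_config"))
  if (length(corpus$docs) < 2) stop("need at least 2 documents")
  if (is.null(vocab))
    vocab <- build_vocabulary(corpus,
                              min_corpus_freq = config$min_corpus_freq,
                              min_doc_freq = config$min_doc_freq)
  V <- length(vocab$kmer)
  M <- config$num_topics
  if (V < M)
    warning("vocabulary size (", V, ") is below the number of topics (",
            M, ") for locus '", corpus$locus_id, "'")
  bow <- .corpus_bow(corpus, vocab)
  empty <- vapply(bow, function(b) length(b$ids) == 0L, logical(1))
  if (any(empty))
    warning("document(s) with no in-vocabulary k-mers get uniform topic ",
            "frequencies in locus '", corpus$locus_id, "': ",
            paste(names(bow)[empty], collapse = ", "))
  res <- with_seed(config$seed,
                   .lda_vb_cpp(lapply(bow, `[[`, "ids"),
                               lapply(bow, `[[`, "counts"),
                               V, M, config$alpha, config$eta,
                               config$passes))
  theta <- res$theta
  theta[empty, ] <- 1 / M
  dimnames(theta) <- list(names(corpus$docs), paste0("topic", seq_len(M)))
  beta <- res$beta
  dimnames(beta) <- list(paste0("topic", seq_len(M)), vocab$kmer)
  structure(list(locus_id = corpus$locus_id, theta = theta, beta = beta,
                 bound = res$bound, passes = res$passes, vocab = vocab,
                 config = config),
            class = "topic_fit")
}

#' @export
print.topic_fit <- function(x, ...) {
  cat("<topic_fit> ", x$locus_id, ": ", nrow(x$theta), " documents, ",
      ncol(x$theta), " topics, V = ", ncol(x$beta),
      ", bound = ", format(x$bound), "\n", sep = "")
  invisible(x)
}

#' Per-document topic frequencies as a tibble
#'
#' @param x a `topic_fit`.
#' @param ... unused.
#' @return tibble with columns `document`, `topic`, `frequency`.
#' @export
tidy_topics <- function(x, ...) {
  stopifnot(inherits(x, "topic_fit"))
  tibble::tibble(
    document = rep(rownames(x$theta), ncol(x$theta)),
    topic = rep(colnames(x$theta), each = nrow(x$theta)),
    frequency = as.vector(x$theta))
}

#' UMass topic coherence
#'
#' For each topic, the `top_n` most probable words are taken in decreasing
#' probability order and the coherence is the mean over ordered pairs
#' (w_i, w_j), i < j, of `log((D(w_i, w_j) + 1) / D(w_j))`, where D counts
#' the corpus documents containing the word(s).  Values are <= 0; higher
#' (closer to 0) means the topic's top words co-occur more.
#'
#' @param fit a `topic_fit`.
#' @param corpus the `kmer_corpus` the model was fitted to.
#' @param top_n number of top words per topic (>= 2).
#' @return numeric vector of per-topic coherences, with the model-level
#'   mean in attribute `"score"`.
#' @export
umass_coherence <- function(fit, corpus, top_n = 10) {
  stopifnot(inherits(fit, "topic_fit"), inherits(corpus, "kmer_corpus"),
            top_n >= 2)
  doc_sets <- lapply(corpus$docs, unique)
  D_single <- function(w) sum(vapply(doc_sets, function(s) w %in% s,
                                     logical(1)))
  D_joint <- function(wi, wj)
    sum(vapply(doc_sets, function(s) (wi %in% s) && (wj %in% s),
               logical(1)))
  words <- colnames(fit$beta)
  out <- apply(fit$beta, 1L, function(b) {
    ord <- order(-b, seq_along(b))          # ties broken by word id
    top <- words[ord[seq_len(min(top_n, length(words)))]]
    if (length(top) < top_n)
      warning("topic has fewer than top_n distinct words; using ",
              length(top))
    if (length(top) < 2) return(NA_real_)
    terms <- c()
    for (i in seq_len(length(top) - 1L))
      for (j in seq.int(i + 1L, length(top)))
        terms <- c(terms, log((D_joint(top[i], top[j]) + 1) /
                                D_single(top[j])))
    mean(terms)
  })
  structure(out, score = mean(out))
}

#' Select the number of topics by coherence
#'
#' Fits the model for each candidate topic count and returns the one with
#' the highest mean UMass coherence (ties go to the smallest count).  A
#' single candidate is returned without fitting.
#'
#' @param corpus a `kmer_corpus`.
#' @param candidates integer vector of topic counts to try.
#' @param config an [lda_config()]; its `num_topics` is overridden.
#' @param top_n top words per topic for the coherence score.
#' @return the selected topic count, with the per-candidate scores in
#'   attribute `"coherence"`.
#' @export
select_num_topics <- function(corpus, candidates, config = lda_config(),
                              top_n = 10) {
  candidates <- sort(unique(as.integer(candidates)))
  if (length(candidates) == 1L)
    return(structure(candidates, coherence = NULL))
  scores <- vapply(candidates, function(M) {
    cfg <- config
    cfg$num_topics <- M
    cfg$alpha <- config$alpha * config$num_topics / M
    cfg$eta <- config$eta * config$num_topics / M
    fit <- fit_lda(corpus, cfg)
    attr(umass_coherence(fit, corpus, top_n = top_n), "score")
  }, numeric(1))
  best <- candidates[which.max(scores)]   # which.max takes the first tie
  structure(best, coherence = setNames(scores, candidates))
}
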