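test_that("vocabulary pruning removes low-frequency k-mers", {
  corp <- toy_corpus(list(d1 = c("AA", "AA", "AA", "AC"),
                          d2 = c("AA", "AA")))
  v <- build_vocabulary(corp, min_corpus_freq = 2)
  expect_equal(v$kmer, "AA")
  expect_equal(v$corpus_freq, 5L)
  expect_equal(v$doc_freq, 2L)
  v2 <- build_vocabulary(corp, min_corpus_freq = 1)
  expect_equal(v2$kmer, c("AA", "AC"))   # first-occurrence order
  corp3 <- toy_corpus(list(d1 = c("AA", "AC"), d2 = c("GG", "GT")))
  expect_error(build_vocabulary(corp3, min_corpus_freq = 2), "empty")
})

test_that("LDA separates documents with disjoint k-mer sets", {
  corp <- toy_corpus(list(a = rep(c("AAAA", "AAAC", "AACA"), 20),
                          b = rep(c("TTTT", "TTTG", "TTGG"), 20)), k = 4)
  fit <- fit_lda(corp, lda_config(num_topics = 2, seed = 7,
                                  min_corpus_freq = 1))
  tv <- 0.5 * sum(abs(fit$theta[1, ] - fit$theta[2, ]))
  expect_gte(tv, 0.9)
})

test_that("identical documents get identical topic frequencies", {
  corp <- toy_corpus(list(a = rep(c("AA", "AC"), 15),
                          b = rep(c("AA", "AC"), 15)), k = 2)
  fit <- suppressWarnings(fit_lda(corp, lda_config(num_topics = 3, seed = 1,
                                                   min_corpus_freq = 1)))
  expect_lt(max(abs(fit$theta[1, ] - fit$theta[2, ])), 1e-6)
})

test_that("theta and beta rows are normalized and fits are seeded", {
  set.seed(30)
  docs <- lapply(1:6, function(i) sample(rand_dna(12, 4), 50, TRUE))
  names(docs) <- paste0("d", 1:6)
  corp <- toy_corpus(docs, k = 4)
  cfg <- lda_config(num_topics = 5, seed = 123, min_corpus_freq = 1)
  fit <- fit_lda(corp, cfg)
  expect_lt(max(abs(rowSums(fit$theta) - 1)), 1e-8)
  expect_lt(max(abs(rowSums(fit$beta) - 1)), 1e-8)
  expect_true(all(fit$theta >= 0), all(fit$beta >= 0))
  expect_identical(fit$theta, fit_lda(corp, cfg)$theta)
  expect_identical(fit$beta, fit_lda(corp, cfg)$beta)
  # default shape: 5 topics per document
  expect_equal(dim(fit$theta), c(6L, 5L))
})

test_that("documents with no surviving tokens get uniform theta", {
  corp <- toy_corpus(list(a = rep("AA", 10), b = rep("AA", 10),
                          c = "ZZ"))  # "ZZ" is pruned (corpus freq 1)
  expect_warning(
    expect_warning(fit <- fit_lda(corp, lda_config(num_topics = 2,
                                                   seed = 2)),
                   "uniform"),
    "below the number of topics")
  expect_equal(unname(fit$theta["c", ]), c(0.5, 0.5))
})

test_that("umass coherence equals a brute-force recomputation", {
  set.seed(31)
  docs <- lapply(1:5, function(i) sample(c("AA", "AC", "AG", "AT",
                                           "CA", "CC"), 30, TRUE))
  names(docs) <- paste0("d", 1:5)
  corp <- toy_corpus(docs, k = 2)
  fit <- fit_lda(corp, lda_config(num_topics = 3, seed = 3,
                                  min_corpus_freq = 1))
  got <- umass_coherence(fit, corp, top_n = 4)
  # independent recomputation straight from the definition
  sets <- lapply(corp$docs, unique)
  Dw <- function(w) sum(vapply(sets, function(s) w %in% s, logical(1)))
  Dww <- function(a, b) sum(vapply(sets, function(s)
    a %in% s && b %in% s, logical(1)))
  want <- vapply(seq_len(nrow(fit$beta)), function(m) {
    b <- fit$beta[m, ]
    top <- colnames(fit$beta)[order(-b, seq_along(b))][1:4]
    vals <- c()
    for (i in 1:3) for (j in (i + 1):4)
      vals <- c(vals, log((Dww(top[i], top[j]) + 1) / Dw(top[j])))
    mean(vals)
  }, numeric(1))
  expect_equal(unname(got), want, ignore_attr = TRUE)
})

test_that("coherence limits: perfect co-occurrence and never co-occur", {
  # all top words in every document -> pair terms log((D+1)/D), near 0
  corp <- toy_corpus(list(d1 = c("AA", "AC"), d2 = c("AA", "AC"),
                          d3 = c("AA", "AC"), d4 = c("AA", "AC")), k = 2)
  fit <- fit_lda(corp, lda_config(num_topics = 2, seed = 5,
                                  min_corpus_freq = 1))
  co <- suppressWarnings(umass_coherence(fit, corp, top_n = 2))
  expect_equal(unname(co), rep(log(5 / 4), 2), ignore_attr = TRUE)
  # two words that never co-occur, D(w_j) = 4 -> pair term log(1/4)
  corp2 <- toy_corpus(list(d1 = "AA", d2 = "AC", d3 = "AC", d4 = "AC",
                           d5 = "AC"), k = 2)
  sets <- lapply(corp2$docs, unique)
  expect_equal(log((0 + 1) / 4), log(1 / 4))  # formula anchor
  fit2 <- suppressWarnings(
    fit_lda(corp2, lda_config(num_topics = 2, seed = 5,
                              min_corpus_freq = 1)))
  co2 <- suppressWarnings(umass_coherence(fit2, corp2, top_n = 2))
  ord <- order(-fit2$beta[1, ], seq_len(2))
  wj <- colnames(fit2$beta)[ord[2]]
  Dj <- sum(vapply(sets, function(s) wj %in% s, logical(1)))
  expect_equal(unname(co2[1]), log(1 / Dj), ignore_attr = TRUE)
})

test_that("topic-count selection favors the generating structure", {
  set.seed(33)
  # corpus drawn from two well-separated topics
  words1 <- sprintf("A%02d", 1:8); words2 <- sprintf("T%02d", 1:8)
  docs <- lapply(1:10, function(d) {
    w <- if (d %% 2) words1 else words2
    sample(w, 60, TRUE)
  })
  names(docs) <- paste0("d", 1:10)
  corp <- toy_corpus(docs, k = 3)
  sel <- select_num_topics(corp, c(2, 5),
                           lda_config(seed = 9, min_corpus_freq = 1))
  expect_equal(as.integer(sel), 2L)
  expect_named(attr(sel, "coherence"), c("2", "5"))
  # single candidate: returned without any fitting
  expect_equal(as.integer(select_num_topics(corp, 5)), 5L)
})

test_that("permuting topic labels leaves the tree invariant", {
  set.seed(34)
  tr <- sim_guide_tree(7)
  sim <- simulate_dataset(tr, n_loci = 30, indel_rate = 0, seed = 77)
  fits <- lapply(sim$aligned$loci, function(lc)
    fit_lda(decompose(lc, k = 9), lda_config(seed = 11)))
  perm <- c(3, 1, 5, 2, 4)
  fits_p <- lapply(fits, function(f) {
    f$theta <- f$theta[, perm]
    colnames(f$theta) <- paste0("topic", 1:5)
    f
  })
  # without dropping a topic the characters are the same set, so the
  # likelihood surface and the search result are identical
  x1 <- assemble_matrix(fits, drop_last = FALSE, transform = "sqrt")
  x2 <- assemble_matrix(fits_p, drop_last = FALSE, transform = "sqrt")
  t1 <- search_tree(x1); t2 <- search_tree(x2)
  expect_equal(rf_distance(t1, t2), 0)
  expect_equal(attr(t1, "loglik"), attr(t2, "loglik"), tolerance = 1e-9)
})
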