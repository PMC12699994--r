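#' Run the full alignment-free pipeline on a dataset
#'
#' For each locus: pick a k-mer length, tokenize, fit the per-locus LDA
#' topic model; then assemble the topic-frequency character matrix and
#' search for the restricted-maximum-likelihood tree.  Optionally run a
#' bootstrap and summarize it into a majority-rule consensus.
#'
#' @param bundle a [dataset_bundle()].
#' @param k k-mer length(s); `NULL` estimates per locus ([locus_k()]).
#' @param q random k-mer probability for the k estimate.
#' @param gap_mode,drop_ambiguous passed to [decompose()].
#' @param config an [lda_config()]; per-locus fitting seeds are derived
#'   from `seed`.
#' @param transform,drop_last,missing passed to [assemble_matrix()].
#' @param global_rearrangements passed to [search_tree()].
#' @param bootstrap number of bootstrap replicates, or `NULL` for none.
#' @param bootstrap_mode `"sites"` or `"kmers"`.
#' @param seed master seed driving every stochastic stage.
#' @return an object of class `topic_phylogeny`: list with `tree`
#'   (`phylo`), `consensus` (`phylo` with % supports, or `NULL`),
#'   `matrix` (the assembled `freq_matrix`), `fits` (per-locus
#'   `topic_fit`s) and `report` (per-locus k, vocabulary size, bound,
#'   final log-likelihood, seed).
#' @export
infer_topic_tree <- function(bundle, k = NULL, q = 0.01,
                             gap_mode = "keep_all", drop_ambiguous = FALSE,
                             config = lda_config(), transform = "sqrt",
                             drop_last = TRUE, missing = "error",
                             global_rearrangements = TRUE,
                             bootstrap = NULL, bootstrap_mode = "sites",
                             seed = NULL) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  loci <- bundle$loci
  fits <- vector("list", length(loci))
  ks <- integer(length(loci))
  vsize <- integer(length(loci))
  bounds <- numeric(length(loci))
  for (i in seq_along(loci)) {
    corp <- decompose(loci[[i]], k = k, gap_mode = gap_mode,
                      drop_ambiguous = drop_ambiguous, q = q)
    cfg <- config
    cfg$seed <- .seed_stream(seed, i)
    fit <- fit_lda(corp, cfg)
    fits[[i]] <- fit
    ks[i] <- max(corp$k)
    vsize[i] <- ncol(fit$beta)
    bounds[i] <- fit$bound
  }
  xm <- assemble_matrix(fits, group_order = bundle$group_order,
                        transform = transform, drop_last = drop_last,
                        missing = missing)
  tree <- search_tree(xm, global_rearrangements = global_rearrangements)
  consensus <- NULL
  if (!is.null(bootstrap) && bootstrap >= 1) {
    reps <- run_bootstrap(bundle, replicates = bootstrap,
                          mode = bootstrap_mode,
                          seed = .seed_stream(seed, 999983L),
                          k = k, gap_mode = gap_mode,
                          drop_ambiguous = drop_ambiguous, config = config,
                          transform = transform, drop_last = drop_last,
                          global_rearrangements = global_rearrangements)
    consensus <- majority_consensus(reps)
    attr(consensus, "replicates") <- reps
  }
  structure(list(
    tree = tree, consensus = consensus, matrix = xm, fits = fits,
    report = list(locus_id = names(loci), k = ks,
                  vocabulary_size = vsize, lda_bound = bounds,
                  loglik = attr(tree, "loglik"), seed = seed,
                  num_topics = config$num_topics, gap_mode = gap_mode)),
    class = "topic_phylogeny")
}

#' @export
print.topic_phylogeny <- function(x, ...) {
  r <- x$report
  cat("<topic_phylogeny> ", length(r$locus_id), " loci, ",
      nrow(x$matrix), " tips, ", ncol(x$matrix), " characters; logL = ",
      format(r$loglik), "\n", sep = "")
  if (!is.null(x$consensus))
    cat("  consensus over bootstrap replicates included\n")
  invisible(x)
}

#' Per-locus summary of a fitted pipeline run
#'
#' @param x a `topic_phylogeny`.
#' @return tibble with one row per locus: k, vocabulary size, LDA bound.
#' @export
pipeline_report <- function(x) {
  stopifnot(inherits(x, "topic_phylogeny"))
  r <- x$report
  tibble::tibble(locus = r$locus_id, k = r$k,
                 vocabulary_size = r$vocabulary_size,
                 lda_bound = r$lda_bound)
}

.apply_treatment <- function(sim, treatment) {
  switch(treatment,
         aligned = list(bundle = sim$aligned, gap_mode = "keep_all"),
         unaligned = list(bundle = sim$unaligned, gap_mode = "strip_gaps"),
         no_gap_kmer = list(bundle = sim$aligned,
                            gap_mode = "drop_gap_kmers"),
         stop("unknown treatment: ", treatment))
}

#' Simulation study over loci counts and gap treatments
#'
#' For each number of loci and each replicate, a dataset is simulated on
#' the guide tree and analyzed under the requested treatments:
#' `"aligned"` (gaps kept as symbols), `"unaligned"` (gaps excised before
#' tokenization) and `"no_gap_kmer"` (gap-containing k-mers dropped after
#' tokenization).  Each estimate is scored against the generating tree
#' with the closeness criterion and the weighted RF distance.  The same
#' simulated data are reused across treatments within a replicate.
#'
#' @param tree guide tree (e.g. [sim_guide_tree()]).
#' @param loci vector of loci counts.
#' @param treatments subset of `c("aligned", "unaligned", "no_gap_kmer")`.
#' @param replicates replicates per cell.
#' @param indel_rate,mean_indel_length,root_length,model passed to
#'   [simulate_dataset()].
#' @param config an [lda_config()].
#' @param seed master seed.
#' @param max_rf closeness threshold (see [is_close()]).
#' @return tibble with columns `n_species`, `indel_rate`, `loci`,
#'   `treatment`, `C`, `wRF`, `replicates`.
#' @export
run_simulation_study <- function(tree, loci = c(10, 100),
                                 treatments = c("aligned", "unaligned",
                                                "no_gap_kmer"),
                                 replicates = 10, indel_rate = 0.02,
                                 mean_indel_length = 12, root_length = 1000,
                                 model = "JC", config = lda_config(),
                                 seed = NULL, max_rf = 4) {
  stopifnot(replicates >= 1)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  rows <- list()
  for (L in loci) {
    est <- lapply(treatments, function(t) vector("list", replicates))
    names(est) <- treatments
    for (r in seq_len(replicates)) {
      sim <- simulate_dataset(tree, n_loci = L, root_length = root_length,
                              indel_rate = indel_rate,
                              mean_indel_length = mean_indel_length,
                              model = model,
                              seed = .seed_stream(seed, L, r))
      for (t in treatments) {
        tr <- .apply_treatment(sim, t)
        run <- infer_topic_tree(tr$bundle, gap_mode = tr$gap_mode,
                                config = config,
                                seed = .seed_stream(seed, L, r,
                                                    match(t, treatments)))
        est[[t]][[r]] <- run$tree
      }
    }
    for (t in treatments) {
      sc <- score_simulation(est[[t]], tree, max_rf = max_rf)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_species = length(tree$tip.label), indel_rate = indel_rate,
        loci = L, treatment = t, C = sc$C, wRF = sc$wRF,
        replicates = replicates)
    }
  }
  do.call(rbind, rows)
}
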