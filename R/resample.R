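#' Site bootstrap for an aligned locus
#'
#' Draws alignment columns with replacement (the same resampled column
#' set applied to every row) and returns the rebuilt locus.  Each locus is
#' resampled independently in a multilocus bootstrap.  Uses the current R
#' RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param locus an aligned [locus_data()] object.
#' @return a resampled [locus_data()].
#' @export
bootstrap_sites <- function(locus) {
  stopifnot(inherits(locus, "locus_data"))
  if (!locus$aligned) stop("site bootstrap requires an aligned locus")
  L <- nchar(locus$sequences[[1]])
  cols <- sample.int(L, L, replace = TRUE)
  mat <- do.call(rbind, strsplit(locus$sequences, "", fixed = TRUE))
  res <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
  names(res) <- locus$labels
  locus_data(res, locus_id = locus$locus_id, aligned = TRUE)
}

#' k-mer bootstrap for an unaligned corpus
#'
#' Within each document, draws as many k-mers with replacement as the
#' document holds, so per-document token totals are conserved exactly.
#' Resampling is per document rather than pooled across documents:
#' pooling would shuffle k-mers between taxa and erase the tip-specific
#' signal the tree is built from.
#'
#' @param corpus a `kmer_corpus` from [decompose()].
#' @return a resampled `kmer_corpus`.
#' @export
bootstrap_kmers <- function(corpus) {
  stopifnot(inherits(corpus, "kmer_corpus"))
  docs <- lapply(corpus$docs, function(toks) {
    if (!length(toks)) return(toks)
    toks[sample.int(length(toks), length(toks), replace = TRUE)]
  })
  if (any(lengths(corpus$docs) == 0L))
    warning("empty document(s) left empty by the bootstrap")
  names(docs) <- names(corpus$docs)
  structure(list(locus_id = corpus$locus_id, docs = docs, k = corpus$k),
            class = "kmer_corpus")
}

#' Bootstrap replicate trees for a dataset
#'
#' Runs the full pipeline (resample, tokenize, per-locus LDA, matrix
#' assembly, tree search) once per replicate.  `mode = "sites"` resamples
#' alignment columns per locus (aligned data); `mode = "kmers"` resamples
#' each document's k-mer multiset (any data).  Replicate seeds are derived
#' deterministically from `seed`.
#'
#' @param bundle a [dataset_bundle()].
#' @param replicates number of bootstrap replicates R.
#' @param mode `"sites"` or `"kmers"`.
#' @param seed master seed.
#' @param k k-mer length(s) or `NULL` to estimate per locus; the estimate
#'   is made once on the original data and reused across replicates.
#' @param gap_mode,drop_ambiguous passed to [decompose()].
#' @param config an [lda_config()].
#' @param transform,drop_last passed to [assemble_matrix()].
#' @param global_rearrangements passed to [search_tree()].
#' @return list of `phylo` trees of class `multiPhylo`.
#' @export
run_bootstrap <- function(bundle, replicates, mode = c("sites", "kmers"),
                          seed = NULL, k = NULL, gap_mode = "keep_all",
                          drop_ambiguous = FALSE, config = lda_config(),
                          transform = "sqrt", drop_last = TRUE,
                          global_rearrangements = TRUE) {
  stopifnot(inherits(bundle, "dataset_bundle"), replicates >= 1)
  mode <- match.arg(mode)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1)
  corpora <- NULL
  if (mode == "kmers")
    corpora <- lapply(bundle$loci, decompose, k = k, gap_mode = gap_mode,
                      drop_ambiguous = drop_ambiguous)
  trees <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rep_trees <- tryCatch({
      fits <- vector("list", length(bundle$loci))
      for (i in seq_along(bundle$loci)) {
        rs <- .seed_stream(seed, r, i)
        corp <- with_seed(rs, {
          if (mode == "sites")
            decompose(bootstrap_sites(bundle$loci[[i]]), k = k,
                      gap_mode = gap_mode,
                      drop_ambiguous = drop_ambiguous)
          else bootstrap_kmers(corpora[[i]])
        })
        cfg <- config
        cfg$seed <- .seed_stream(seed, r, i, 7L)
        fits[[i]] <- fit_lda(corp, cfg)
      }
      xm <- assemble_matrix(fits, group_order = bundle$group_order,
                            transform = transform, drop_last = drop_last,
                            missing = "impute_uniform")
      search_tree(xm, global_rearrangements = global_rearrangements)
    }, error = function(e)
      stop("bootstrap replicate ", r, " (seed ", .seed_stream(seed, r, 1L),
           ") failed: ", conditionMessage(e)))
    trees[[r]] <- rep_trees
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Majority-rule consensus tree with support values
#'
#' Bipartitions occurring in strictly more than half of the trees are
#' retained (a mutually compatible set by construction) and annotated
#' with their percentage occurrence, rounded to integers, as internal
#' node labels.
#'
#' @param trees list / `multiPhylo` of trees on a common tip set.
#' @return a `phylo` tree; internal node labels hold the support
#'   percentages (the root label is empty).
#' @export
majority_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("no trees")
  tipsets <- lapply(trees, `[[`, "tip.label")
  u <- sort(tipsets[[1L]])
  if (!all(vapply(tipsets, setequal, logical(1), y = u)))
    stop("trees have differing tip sets")
  R <- length(trees)
  n <- length(u)
  counts <- new.env(hash = TRUE)
  for (tr in trees) {
    for (key in .tree_splits(tr, u)$key) {
      prev <- if (is.null(counts[[key]])) 0L else counts[[key]]
      counts[[key]] <- prev + 1L
    }
  }
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  keep <- cnt > R / 2
  keys <- keys[keep]
  support <- round(100 * cnt[keep] / R)
  clades <- lapply(strsplit(keys, ",", fixed = TRUE), as.integer)
  ord <- order(-lengths(clades))
  clades <- clades[ord]; support <- support[ord]
  sizes <- lengths(clades)

  # build rooted-at-anchor topology: parent of each clade (and tip) is the
  # smallest retained clade strictly containing it, else the root
  n_clade <- length(clades)
  root <- n + 1L
  parent <- integer(n_clade)                 # 0 = root
  for (i in seq_len(n_clade)) {
    for (j in seq_len(n_clade)) {
      if (j == i || sizes[j] <= sizes[i]) next
      if (all(clades[[i]] %in% clades[[j]]) &&
          (parent[i] == 0L || sizes[parent[i]] > sizes[j]))
        parent[i] <- j
    }
  }
  tip_parent <- rep(root, n)
  for (t in seq_len(n)[-1L]) {               # tip 1 is the anchor: at root
    best <- 0L
    for (i in seq_len(n_clade))
      if ((t %in% clades[[i]]) && (best == 0L || sizes[i] < sizes[best]))
        best <- i
    if (best > 0L) tip_parent[t] <- n + 1L + best
  }
  edge <- if (n_clade)
    rbind(cbind(ifelse(parent == 0L, root, n + 1L + parent),
                n + 1L + seq_len(n_clade)),
          cbind(tip_parent, seq_len(n)))
  else cbind(tip_parent, seq_len(n))
  st <- .search_state(edge, rep(1, nrow(edge)), n)
  tr <- .state_to_phylo(st, u)
  tr$edge.length <- NULL
  tr$node.label <- .consensus_labels(tr, u, clades, support)
  tr
}

.consensus_labels <- function(tr, universe, clades, support) {
  n <- length(tr$tip.label)
  lab <- rep("", tr$Nnode)
  if (!length(clades)) return(lab)
  keymap <- setNames(support, vapply(clades, paste, character(1),
                                     collapse = ","))
  post <- ape::reorder.phylo(tr, "postorder")
  below <- matrix(FALSE, n + tr$Nnode, n)
  below[cbind(seq_len(n), match(tr$tip.label, universe))] <- TRUE
  for (j in seq_len(nrow(post$edge)))
    below[post$edge[j, 1], ] <- below[post$edge[j, 1], ] |
      below[post$edge[j, 2], ]
  for (j in seq_len(nrow(post$edge))) {
    node <- post$edge[j, 2]
    if (node <= n) next
    side <- below[node, ]
    if (side[1L]) side <- !side
    key <- paste(which(side), collapse = ",")
    if (!is.na(keymap[key])) lab[node - n] <- as.character(keymap[key])
  }
  lab
}
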