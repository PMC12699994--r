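# shared fixtures and independent oracles used across the test files

# random DNA string(s)
rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# build a kmer_corpus directly from token lists (bypasses decompose)
toy_corpus <- function(docs, k = 2L, locus_id = "toy") {
  structure(list(locus_id = locus_id, docs = docs, k = as.integer(k)),
            class = "kmer_corpus")
}

# simulate Brownian-motion characters down a phylo tree
sim_bm <- function(tree, p, sd_scale = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  val <- vector("list", n + tr$Nnode)
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])
  val[[root]] <- rep(0, p)
  for (j in rev(seq_len(nrow(tr$edge)))) {
    par <- tr$edge[j, 1]; ch <- tr$edge[j, 2]
    val[[ch]] <- val[[par]] +
      rnorm(p, 0, sd_scale * sqrt(tr$edge.length[j]))
  }
  x <- do.call(rbind, val[seq_len(n)])
  rownames(x) <- tr$tip.label
  x
}

# independent REML oracle: multivariate-normal likelihood of the data with
# one tip differenced out, from the full tree covariance matrix
reml_oracle <- function(tree, x) {
  V <- ape::vcv(ape::root(tree, node = length(tree$tip.label) + 1,
                          resolve.root = FALSE))
  V <- V[rownames(x), rownames(x)]
  n <- nrow(x); p <- ncol(x)
  C <- cbind(diag(n - 1), -1)
  W <- C %*% V %*% t(C)
  S <- tcrossprod(x)
  as.numeric(-0.5 * ((n - 1) * p * log(2 * pi) +
                       p * determinant(W)$modulus +
                       sum(diag(solve(W, C %*% S %*% t(C))))))
}

# enumerate all unrooted binary topologies on the given labels (use only
# for <= 6 tips: 15 or 105 trees) by sequential addition over all edges
all_topologies <- function(labels) {
  base <- ape::read.tree(text = sprintf("(%s,%s,%s);",
                                        labels[1], labels[2], labels[3]))
  base$edge.length <- rep(0.1, 3)
  trees <- list(base)
  for (tip in seq_along(labels)[-(1:3)]) {
    nxt <- list()
    for (tr in trees) {
      for (j in seq_len(nrow(tr$edge))) {
        n <- length(tr$tip.label)
        st <- topictree:::.search_state(tr$edge, tr$edge.length, n)
        # renumber tips: new tip must get id n+1 in ape convention; easier
        # to insert via newick surgery using the internal helpers
        new_node <- max(tr$edge) + 1L
        # shift internal ids up by one to make room for the new tip id
        e <- st$edge
        e[e > n] <- e[e > n] + 1L
        st2 <- topictree:::.search_state(e, st$elen, n + 1L)
        st2 <- topictree:::.insert_tip(st2, n + 1L, j, max(e) + 1L, 0.1)
        tr2 <- topictree:::.state_to_phylo(st2, c(tr$tip.label, labels[tip]))
        nxt[[length(nxt) + 1L]] <- tr2
      }
    }
    trees <- nxt
  }
  trees
}

# 9-tip guide tree with population-study-like branch lengths
guide_tree_9 <- function() {
  tr <- ape::read.tree(text = paste0(
    "(((p1,p2),(p3,p4)),((p5,p6),p7),(p8,p9));"))
  tr$edge.length <- ifelse(tr$edge[, 2] <= 9, 0.05, 0.02)
  tr
}
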