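#' @title Tree comparison metrics
#' @description Robinson-Foulds (RF) distance, the branch-length weighted
#'   variant, and the "close to true tree" criterion used to score
#'   simulation studies.
#' @name tree-metrics
NULL

# canonical bipartition keys for an unrooted tree: for each edge, the tip
# set on the child side, flipped to the side NOT containing the anchor
# (first label of the sorted tip universe); keys are sorted label strings
.tree_splits <- function(tree, universe = NULL, trivial = FALSE) {
  labs <- tree$tip.label
  if (is.null(universe)) universe <- sort(labs)
  anchor <- universe[1L]
  n <- length(labs)
  e <- tree$edge
  nnode <- n + tree$Nnode
  below <- matrix(FALSE, nnode, n)  # node x tip membership
  below[cbind(seq_len(n), match(labs, universe))] <- TRUE
  tr <- ape::reorder.phylo(tree, "postorder")
  e <- tr$edge
  lens <- tr$edge.length
  for (j in seq_len(nrow(e)))
    below[e[j, 1], ] <- below[e[j, 1], ] | below[e[j, 2], ]
  keys <- character(nrow(e))
  sizes <- integer(nrow(e))
  for (j in seq_len(nrow(e))) {
    side <- below[e[j, 2], ]
    if (side[1L]) side <- !side      # anchor is universe[1]
    keys[j] <- paste(which(side), collapse = ",")
    sizes[j] <- sum(side)
  }
  keep <- if (trivial) sizes >= 1 & sizes <= n - 1
          else sizes >= 2 & sizes <= n - 2
  data.frame(key = keys[keep],
             length = if (is.null(lens)) rep(NA_real_, sum(keep))
                      else lens[keep],
             stringsAsFactors = FALSE)
}

.check_same_tips <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have different tip sets")
}

#' Robinson-Foulds distance
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees.  Zero for identical topologies; at most `2(n - 3)` for
#' two binary trees on `n` tips.  Multifurcating trees are compared on
#' their bipartition sets as-is.
#'
#' @param a,b `phylo` trees on the same tip set.
#' @return even non-negative integer (for binary trees).
#' @rdname tree-metrics
#' @export
rf_distance <- function(a, b) {
  .check_same_tips(a, b)
  u <- sort(a$tip.label)
  sa <- .tree_splits(a, u)$key
  sb <- .tree_splits(b, u)$key
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Weighted Robinson-Foulds distance
#'
#' Sum over the union of bipartitions (trivial ones included, since every
#' pendant edge carries a length) of the absolute branch-length
#' difference; a bipartition absent from one tree contributes its full
#' length.
#'
#' @rdname tree-metrics
#' @export
weighted_rf <- function(a, b) {
  .check_same_tips(a, b)
  if (is.null(a$edge.length) || is.null(b$edge.length))
    stop("both trees need branch lengths")
  u <- sort(a$tip.label)
  sa <- .tree_splits(a, u, trivial = TRUE)
  sb <- .tree_splits(b, u, trivial = TRUE)
  la <- tapply(sa$length, sa$key, sum)   # duplicate keys (unresolved) pool
  lb <- tapply(sb$length, sb$key, sum)
  keys <- union(names(la), names(lb))
  va <- ifelse(keys %in% names(la), la[keys], 0)
  vb <- ifelse(keys %in% names(lb), lb[keys], 0)
  sum(abs(va - vb))
}

#' Closeness criterion
#'
#' A reconstruction counts as close when it is the true topology or at
#' most two NNI-style rearrangements away; since one NNI changes the
#' bipartition set by at most one split on each side, this is
#' operationalized as RF distance <= `max_rf` (default 4).
#'
#' @param max_rf RF threshold for "close".
#' @rdname tree-metrics
#' @export
is_close <- function(a, b, max_rf = 4) {
  rf_distance(a, b) <= max_rf
}

#' Uniform random unrooted binary tree
#'
#' Sequential addition: starting from the unique 3-tip tree, each further
#' tip is attached to an edge drawn uniformly at random, which yields the
#' uniform distribution over labeled unrooted binary topologies.  Branch
#' lengths are set to 1.
#'
#' @param tips character vector of tip labels (>= 3).
#' @return an unrooted `phylo` tree.
#' @export
random_binary_tree <- function(tips) {
  n <- length(tips)
  if (n < 3) stop("need at least 3 tips")
  nedge_final <- 2L * n - 3L
  edge <- matrix(0L, nedge_final, 2L)
  edge[1:3, ] <- cbind(rep(n + 1L, 3L), 1:3)
  m <- 3L
  new_node <- n + 2L
  if (n > 3) for (tip in 4:n) {
    j <- sample.int(m, 1L)
    u <- edge[j, 1L]; v <- edge[j, 2L]
    edge[j, ] <- c(u, new_node)
    edge[m + 1L, ] <- c(new_node, v)
    edge[m + 2L, ] <- c(new_node, tip)
    m <- m + 2L
    new_node <- new_node + 1L
  }
  st <- .search_state(edge, rep(1, nedge_final), n)
  .state_to_phylo(st, tips)
}

#' Score a simulation study cell
#'
#' @param estimated list of estimated `phylo` trees (one per replicate).
#' @param truth the generating tree.
#' @param max_rf closeness threshold, see [is_close()].
#' @return a list with `C` (proportion of close replicates), `wRF` (mean
#'   weighted RF distance) and `n` (number of replicates).
#' @export
score_simulation <- function(estimated, truth, max_rf = 4) {
  if (inherits(estimated, "phylo")) estimated <- list(estimated)
  if (!length(estimated)) stop("no estimated trees")
  close <- vapply(estimated, is_close, logical(1), b = truth,
                  max_rf = max_rf)
  wrf <- vapply(estimated, weighted_rf, numeric(1), b = truth)
  list(C = mean(close), wRF = mean(wrf), n = length(estimated))
}
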