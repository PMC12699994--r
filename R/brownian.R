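#' Assemble the tips-by-characters topic frequency matrix
#'
#' Per locus, the topic frequency vectors are treated like allele
#' frequencies: the last topic column is dropped (its value is implied by
#' the sum-to-one constraint, the usual gene-frequency convention) and the
#' remaining entries are square-root transformed, the standard
#' variance-stabilizing map for drifting frequencies.  Blocks are
#' concatenated in locus order, giving a matrix of dimension
#' tips x sum over loci of (M_l - 1).  `transform = "none"` together with
#' `drop_last = FALSE` gives the plain continuous-characters mode.
#'
#' @param fits list of `topic_fit` objects (one per locus).
#' @param group_order tip order for the rows; defaults to first appearance
#'   across fits.
#' @param drop_last drop the last topic column of every locus.
#' @param transform `"sqrt"` or `"none"`.
#' @param missing what to do when a tip is absent from a locus:
#'   `"error"` (default) or `"impute_uniform"` (fill with uniform topic
#'   frequencies and warn).
#' @return a numeric matrix of class `freq_matrix` with attributes `loci`
#'   (locus ids), `topics` (per-locus topic count) and `transform`.
#' @export
assemble_matrix <- function(fits, group_order = NULL, drop_last = TRUE,
                            transform = c("sqrt", "none"),
                            missing = c("error", "impute_uniform")) {
  transform <- match.arg(transform)
  missing <- match.arg(missing)
  if (inherits(fits, "topic_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "topic_fit")))
  if (is.null(group_order))
    group_order <- unique(unlist(lapply(fits, function(f)
      rownames(f$theta))))
  blocks <- lapply(fits, function(f) {
    M <- ncol(f$theta)
    absent <- setdiff(group_order, rownames(f$theta))
    th <- f$theta
    if (length(absent)) {
      if (missing == "error")
        stop("tip(s) missing from locus '", f$locus_id, "': ",
             paste(absent, collapse = ", "),
             " (use missing = \"impute_uniform\" to fill)")
      warning("imputing uniform topic frequencies for ",
              paste(absent, collapse = ", "), " in locus '", f$locus_id,
              "'")
      fill <- matrix(1 / M, length(absent), M,
                     dimnames = list(absent, colnames(th)))
      th <- rbind(th, fill)
    }
    th <- th[group_order, , drop = FALSE]
    if (drop_last) th <- th[, -M, drop = FALSE]
    colnames(th) <- paste0(f$locus_id, ".", colnames(th))
    th
  })
  x <- do.call(cbind, blocks)
  if (transform == "sqrt") x <- sqrt(x)
  structure(x,
            loci = vapply(fits, `[[`, character(1), "locus_id"),
            topics = vapply(fits, function(f) ncol(f$theta), integer(1)),
            transform = transform,
            class = c("freq_matrix", class(x)))
}

#' Square-root transform a frequency matrix
#'
#' Entry-wise square root; the variance-stabilizing transform for
#' frequencies evolving by drift-like Brownian motion.
#'
#' @param x numeric matrix with entries in \[0, 1\].
#' @return the transformed matrix, with the `transform` attribute set.
#' @export
sqrt_transform <- function(x) {
  if (any(x < 0)) stop("negative entries; frequencies expected in [0, 1]")
  if (any(x > 1)) stop("entries above 1; frequencies expected in [0, 1]")
  out <- sqrt(x)
  attr(out, "transform") <- "sqrt"
  out
}

# --- internal light-weight tree representation for likelihood work -------
# list(edge = m x 2 integer (parent, child), elen, tip_row = node -> data
# row (0 for internal), nnode)

.phylo_to_internal <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"))
  labs <- rownames(x)
  if (is.null(labs)) stop("data matrix needs row names matching tip labels")
  if (!setequal(tree$tip.label, labs))
    stop("tree tips and matrix rows disagree: ",
         paste(union(setdiff(tree$tip.label, labs),
                     setdiff(labs, tree$tip.label)), collapse = ", "))
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  tip_row <- integer(nnode)
  tip_row[seq_len(n)] <- match(tree$tip.label, labs)
  elen <- tree$edge.length
  if (is.null(elen)) stop("tree has no branch lengths")
  list(edge = tree$edge, elen = elen, tip_row = tip_row, nnode = nnode)
}

.reduce_data <- function(x) {
  # n x p data enters the REML likelihood only through its scatter S = XX';
  # replace X by an n x n square root of S and remember p for the
  # determinant term.  Exact, and makes likelihood evaluations O(n^2).
  x <- unclass(x)
  n <- nrow(x)
  p <- ncol(x)
  if (p <= n) return(list(X = x, p = p))
  S <- tcrossprod(x)
  ev <- eigen(S, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  Xt <- ev$vectors %*% diag(sqrt(vals), n)
  rownames(Xt) <- rownames(x)
  list(X = Xt, p = p)
}

#' Restricted log-likelihood of a tree under Brownian motion
#'
#' Characters evolve independently by Brownian motion with variance `t`
#' per branch of length `t` (the rate constant is absorbed into the branch
#' lengths).  The restricted likelihood is the joint density of the n - 1
#' independent contrasts obtained by pruning: for contrast vectors `u_i`
#' (over the p characters) with variances `v_i`,
#' `logL = -(p/2) sum_i log(2 pi v_i) - (1/2) sum_i ||u_i||^2 / v_i`.
#' The value is invariant to root placement and to the input order of the
#' tips.  Branch lengths of zero are floored at 1e-8 during evaluation.
#'
#' @param tree a `phylo` tree (rooted or unrooted) whose tips match
#'   `rownames(x)`.
#' @param x numeric tips-by-characters matrix (e.g. a `freq_matrix`).
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(tree, x) {
  if (!is.matrix(x)) stop("x must be a matrix")
  if (length(tree$tip.label) < 3) stop("need at least 3 tips")
  it <- .phylo_to_internal(tree, x)
  .reml_loglik_cpp(it$edge, it$elen, unclass(x)[, , drop = FALSE],
                   it$tip_row, ncol(x))
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate ascent: each branch in turn is optimized by golden-section
#' search on the restricted likelihood, sweeping until the gain falls
#' below `tol` (or `max_sweeps`).  Lengths are constrained to be
#' non-negative; degenerate characters simply drive branches to zero.
#' The returned log-likelihood never decreases relative to the input.
#'
#' @param tree a `phylo` with starting branch lengths (missing lengths are
#'   initialized at 0.05).
#' @param x tips-by-characters matrix.
#' @param tol log-likelihood improvement threshold per sweep.
#' @param max_sweeps sweep cap.
#' @return the tree with optimized `edge.length` and the final restricted
#'   log-likelihood in attribute `"loglik"`.
#' @export
optimize_branch_lengths <- function(tree, x, tol = 1e-6, max_sweeps = 1000) {
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.05, nrow(tree$edge))
  it <- .phylo_to_internal(tree, x)
  red <- .reduce_data(x[, , drop = FALSE])
  res <- .optimize_bl_cpp(it$edge, it$elen, red$X, it$tip_row, red$p,
                          tol = tol, max_sweeps = max_sweeps)
  tree$edge.length <- res$edge_length
  attr(tree, "loglik") <- res$loglik
  tree
}

# --- search-internal edge-list utilities ---------------------------------

.search_state <- function(edge, elen, ntip) {
  list(edge = edge, elen = elen, ntip = ntip)
}

.state_loglik <- function(st, X, p, tip_row, tol = 1e-4, max_sweeps = 50,
                          golden_iter = 40) {
  res <- .optimize_bl_cpp(st$edge, st$elen, X, tip_row, p,
                          tol = tol, max_sweeps = max_sweeps,
                          golden_iter = golden_iter)
  list(st = .search_state(st$edge, res$edge_length, st$ntip),
       loglik = res$loglik)
}

.insert_tip <- function(st, tip, edge_idx, new_node, init_len = 0.02) {
  # subdivide edge edge_idx with new_node and hang tip off it
  e <- st$edge
  len <- st$elen
  u <- e[edge_idx, 1]; v <- e[edge_idx, 2]
  half <- len[edge_idx] / 2
  e[edge_idx, ] <- c(u, new_node)
  len[edge_idx] <- half
  e <- rbind(e, c(new_node, v), c(new_node, tip))
  len <- c(len, half, init_len)
  .search_state(e, len, st$ntip)
}

.nni_swaps <- function(st) {
  # list of candidate (row_a, row_b) pairs whose (child, length) entries
  # are exchanged; two per internal edge
  e <- st$edge
  is_internal <- tabulate(e[, 1], nbins = max(e)) > 0
  root <- setdiff(unique(e[, 1]), e[, 2])
  out <- list()
  for (j in seq_len(nrow(e))) {
    v <- e[j, 2]
    if (!is_internal[v]) next            # pendant edge
    u <- e[j, 1]
    vkids <- which(e[, 1] == v)
    if (u == root) {
      others <- setdiff(which(e[, 1] == u), j)
      # swapping v's first child with each of the root's other children
      out[[length(out) + 1L]] <- c(others[1L], vkids[1L])
      out[[length(out) + 1L]] <- c(others[2L], vkids[1L])
    } else {
      b <- setdiff(which(e[, 1] == u), j)[1L]
      out[[length(out) + 1L]] <- c(b, vkids[1L])
      out[[length(out) + 1L]] <- c(b, vkids[2L])
    }
  }
  out
}

.apply_swap <- function(st, swap) {
  e <- st$edge; len <- st$elen
  a <- swap[1]; b <- swap[2]
  tmp_child <- e[a, 2]; tmp_len <- len[a]
  e[a, 2] <- e[b, 2]; len[a] <- len[b]
  e[b, 2] <- tmp_child; len[b] <- tmp_len
  .search_state(e, len, st$ntip)
}

.state_to_phylo <- function(st, labels) {
  # renumber internal nodes to ape convention (root = ntip + 1, preorder)
  e <- st$edge
  n <- st$ntip
  nodes <- sort(unique(as.vector(e)))
  internal <- nodes[nodes > n]
  root <- setdiff(e[, 1], e[, 2])
  map <- integer(max(nodes))
  map[seq_len(n)] <- seq_len(n)
  nxt <- n + 1L
  stack <- root
  order_rows <- integer(0)
  kids <- split(seq_len(nrow(e)), e[, 1])
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    map[v] <- nxt; nxt <- nxt + 1L
    rows <- kids[[as.character(v)]]
    order_rows <- c(order_rows, rows)
    ch <- e[rows, 2]
    stack <- c(ch[ch > n], stack)
  }
  e2 <- cbind(map[e[order_rows, 1]], map[e[order_rows, 2]])
  tr <- list(edge = e2, edge.length = st$elen[order_rows],
             tip.label = labels, Nnode = length(internal))
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

.phylo_to_state <- function(tree) {
  .search_state(tree$edge, tree$edge.length, length(tree$tip.label))
}

#' Estimate an unrooted tree from a frequency matrix
#'
#' Stepwise addition in row order (each candidate insertion point is
#' scored by restricted maximum likelihood after branch-length
#' optimization) followed by nearest-neighbor-interchange rearrangements.
#' With `global_rearrangements = TRUE` (default) the NNI sweeps repeat
#' over all internal edges until no swap improves the likelihood.  The
#' search is deterministic given the row order; ties keep the first
#' candidate encountered.
#'
#' @param x tips-by-characters matrix with row names (a `freq_matrix`).
#' @param global_rearrangements repeat NNI sweeps to convergence instead
#'   of a single pass.
#' @param tol final branch-length optimization tolerance.
#' @param jumble_seed optional integer; permutes the tip insertion order
#'   randomly (by default tips are added in row order).
#' @return an unrooted `phylo` tree with optimized branch lengths and the
#'   restricted log-likelihood in attribute `"loglik"`.
#' @export
search_tree <- function(x, global_rearrangements = TRUE, tol = 1e-6,
                        jumble_seed = NULL) {
  x <- unclass(x)
  if (!is.null(jumble_seed))
    x <- with_seed(jumble_seed, x[sample.int(nrow(x)), , drop = FALSE])
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("t", seq_len(n))
  if (n < 3) stop("need at least 3 tips")
  labels <- rownames(x)
  red <- .reduce_data(x)
  X <- red$X; p <- red$p

  new_id <- n + 2L   # n+1 is the root join of the first three tips
  st <- .search_state(rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)),
                      rep(0.05, 3), n)
  nnode_max <- 2L * n

  score <- function(state, tips_now, coarse = TRUE) {
    # rows of the reduced X subset to the present tips still satisfy
    # Xs Xs' = S[tips, tips], so the reduction remains exact mid-search
    Xs <- X[tips_now, , drop = FALSE]
    tr <- integer(nnode_max)
    tr[tips_now] <- seq_along(tips_now)
    .state_loglik(state, Xs, p, tr,
                  tol = if (coarse) 1e-2 else tol,
                  max_sweeps = if (coarse) 6 else 1000,
                  golden_iter = if (coarse) 20 else 40)
  }

  cur <- score(st, 1:3, coarse = FALSE)
  if (n > 3) {
    for (tip in 4:n) {
      best <- NULL
      for (j in seq_len(nrow(cur$st$edge))) {
        cand <- .insert_tip(cur$st, tip, j, new_id)
        sc <- score(cand, 1:tip)
        if (is.null(best) || sc$loglik > best$loglik + 1e-9) best <- sc
      }
      new_id <- new_id + 1L
      cur <- best
    }
  }
  cur <- score(cur$st, 1:n, coarse = FALSE)

  repeat {
    improved <- FALSE
    swaps <- .nni_swaps(cur$st)
    for (sw in swaps) {
      cand <- score(.apply_swap(cur$st, sw), 1:n)
      if (cand$loglik > cur$loglik + 1e-7) {
        cur <- cand
        improved <- TRUE
        if (global_rearrangements) break  # restart sweep on new topology
      }
    }
    if (!improved || !global_rearrangements) break
  }
  cur <- score(cur$st, 1:n, coarse = FALSE)
  tr <- .state_to_phylo(cur$st, labels)
  attr(tr, "loglik") <- cur$loglik
  tr
}
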