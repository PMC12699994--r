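#' Guide trees for simulation studies
#'
#' Fixed 7- and 14-species shapes used throughout the package's
#' simulation experiments: a mildly unbalanced 7-tip topology, and a
#' 14-tip topology formed by joining two such subtrees.  Branch lengths
#' default to 0.05 substitutions/site on external and 0.02 on internal
#' branches, which keeps simulated ~1000-bp loci inside a realistic
#' width band once indels accumulate.
#'
#' @param n_species 7 or 14.
#' @param external,internal branch lengths (substitutions per site).
#' @return a `phylo` tree with tip labels `s1`, `s2`, ...
#' @export
sim_guide_tree <- function(n_species = 7, external = 0.05,
                           internal = 0.02) {
  shape7 <- "((((%s,%s)I,%s)I,((%s,%s)I,%s)I)I,%s)R;"
  if (n_species == 7) {
    nwk <- sprintf(shape7, "s1", "s2", "s3", "s4", "s5", "s6", "s7")
  } else if (n_species == 14) {
    half <- function(off) sprintf("(((%s,%s)I,%s)I,((%s,%s)I,%s)I)I",
                                  paste0("s", off + 1), paste0("s", off + 2),
                                  paste0("s", off + 3), paste0("s", off + 4),
                                  paste0("s", off + 5), paste0("s", off + 6))
    nwk <- sprintf("((%s,%s)I,(%s,%s)I)R;", half(0), "s7", half(7), "s14")
  } else stop("n_species must be 7 or 14")
  tr <- ape::unroot(ape::read.tree(text = nwk))
  n <- length(tr$tip.label)
  tr$edge.length <- ifelse(tr$edge[, 2] <= n, external, internal)
  tr$node.label <- NULL
  tr
}

.BASES <- c("A", "C", "G", "T")

.subst_matrix <- function(t, model = c("JC", "HKY"), kappa = 2,
                          base_freq = rep(0.25, 4)) {
  model <- match.arg(model)
  if (model == "JC") {
    same <- 0.25 + 0.75 * exp(-4 * t / 3)
    P <- matrix((1 - same) / 3, 4, 4)
    diag(P) <- same
    return(P)
  }
  # HKY85 via the eigendecomposition of the rate matrix, normalized to
  # one expected substitution per unit branch length
  f <- base_freq / sum(base_freq)
  Q <- matrix(0, 4, 4)
  transition <- matrix(c(0, 0, 1, 0,  0, 0, 0, 1,
                         1, 0, 0, 0,  0, 1, 0, 0), 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- f[j] * if (transition[i, j]) kappa else 1
  diag(Q) <- -rowSums(Q)
  scale <- -sum(f * diag(Q))
  Q <- Q / scale
  ev <- eigen(Q)
  P <- Re(ev$vectors %*% diag(exp(ev$values * t)) %*% solve(ev$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
}

.rindel_len <- function(n, mean_len) {
  # geometric on {1, 2, ...} with the requested mean
  1L + rgeom(n, prob = 1 / mean_len)
}

#' Simulate one locus with substitutions and indels along a tree
#'
#' A root sequence of `root_length` bases is drawn from `base_freq` and
#' evolved down every branch: insertion and deletion event counts are
#' Poisson with mean `indel_rate * t` per site (each process separately),
#' event lengths are geometric with mean `mean_indel_length`, insertion
#' positions and deletion start sites are uniform, inserted residues are
#' drawn from `base_freq`; substitutions are then applied site-wise from
#' the model's transition probabilities for the branch length.  Column
#' identity is tracked through the event history, so the true multiple
#' alignment (with "-" gaps) is returned alongside the gap-free
#' sequences.
#'
#' @param tree guide tree (`phylo` with branch lengths in expected
#'   substitutions per site).
#' @param root_length root sequence length in bp.
#' @param indel_rate insertion rate per site per unit branch length; the
#'   deletion rate is equal.
#' @param mean_indel_length expected indel tract length (bp).
#' @param model `"JC"` or `"HKY"`.
#' @param kappa HKY transition/transversion parameter.
#' @param base_freq root/insertion base frequencies (A, C, G, T).
#' @param locus_id identifier for the resulting locus.
#' @return an object of class `simulated_locus`: list with `alignment`
#'   (a [locus_data()], aligned, gaps as "-"), `sequences` (a
#'   [locus_data()] of the gap-free sequences) and `width` (alignment
#'   width).  Removing the gaps from an alignment row reproduces that
#'   tip's sequence exactly.
#' @export
simulate_locus <- function(tree, root_length = 1000, indel_rate = 0.02,
                           mean_indel_length = 12,
                           model = "JC", kappa = 2,
                           base_freq = rep(0.25, 4), locus_id = "locus") {
  stopifnot(inherits(tree, "phylo"), root_length >= 1, indel_rate >= 0,
            mean_indel_length >= 1)
  n <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  edge <- post$edge
  elen <- post$edge.length
  root <- setdiff(edge[, 1], edge[, 2])

  master <- seq_len(root_length)          # ordered global column ids
  next_id <- root_length + 1L
  env <- environment()

  evolve <- function(ids, bases, t) {
    L <- length(ids)
    if (L > 0L && indel_rate > 0) {
      n_ins <- rpois(1L, indel_rate * t * L)
      n_del <- rpois(1L, indel_rate * t * L)
      events <- sample(rep(c("I", "D"), c(n_ins, n_del)))
      for (ev in events) {
        L <- length(ids)
        if (L == 0L) break
        w <- .rindel_len(1L, mean_indel_length)
        if (ev == "I") {
          pos <- sample.int(L + 1L, 1L) - 1L    # insert after pos (0 = front)
          new_ids <- seq.int(env$next_id, length.out = w)
          env$next_id <- env$next_id + w
          new_bases <- sample.int(4L, w, replace = TRUE, prob = base_freq)
          anchor <- if (pos == 0L) {
            # before this sequence's first surviving column
            match(ids[1L], env$master) - 1L
          } else match(ids[pos], env$master)
          env$master <- append(env$master, new_ids, after = anchor)
          ids <- append(ids, new_ids, after = pos)
          bases <- append(bases, new_bases, after = pos)
        } else {
          s <- sample.int(L, 1L)
          idx <- s:min(L, s + w - 1L)
          ids <- ids[-idx]
          bases <- bases[-idx]
        }
      }
    }
    L <- length(bases)
    if (L > 0L && t > 0) {
      P <- .subst_matrix(t, model, kappa, base_freq)
      for (g in 1:4) {
        at <- which(bases == g)
        if (length(at))
          bases[at] <- sample.int(4L, length(at), replace = TRUE,
                                  prob = P[g, ])
      }
    }
    list(ids = ids, bases = bases)
  }

  # preorder traversal from the root
  nnode <- max(edge)
  seq_ids <- vector("list", nnode)
  seq_bases <- vector("list", nnode)
  seq_ids[[root]] <- master
  seq_bases[[root]] <- sample.int(4L, root_length, replace = TRUE,
                                  prob = base_freq)
  for (j in rev(seq_len(nrow(edge)))) {     # reverse postorder = preorder
    par <- edge[j, 1]; ch <- edge[j, 2]
    res <- evolve(seq_ids[[par]], seq_bases[[par]], elen[j])
    seq_ids[[ch]] <- res$ids
    seq_bases[[ch]] <- res$bases
  }

  tips <- seq_len(n)
  used <- sort(unique(unlist(seq_ids[tips])))
  cols <- master[master %in% used]          # master order, all-gap dropped
  W <- length(cols)
  aln <- character(n)
  raw <- character(n)
  for (i in tips) {
    row <- rep("-", W)
    pos <- match(seq_ids[[i]], cols)
    row[pos] <- .BASES[seq_bases[[i]]]
    aln[i] <- paste(row, collapse = "")
    raw[i] <- paste(.BASES[seq_bases[[i]]], collapse = "")
  }
  names(aln) <- names(raw) <- tree$tip.label
  structure(list(
    alignment = locus_data(aln, locus_id = locus_id, aligned = TRUE),
    sequences = locus_data(raw, locus_id = locus_id, aligned = FALSE),
    width = W), class = "simulated_locus")
}

#' Simulate a multilocus dataset
#'
#' Independent loci on a common guide tree.  Returns the two views the
#' downstream gap treatments need: the true alignments (gaps kept) and
#' the gap-free sequences; tokenizing the aligned view with
#' `gap_mode = "drop_gap_kmers"` gives the third treatment.
#'
#' @param tree guide tree.
#' @param n_loci number of loci (>= 1).
#' @param seed optional seed; per-locus seeds are derived from it.
#' @inheritParams simulate_locus
#' @return list with `aligned` and `unaligned` [dataset_bundle()]s and
#'   `tree` (the generating tree).
#' @export
simulate_dataset <- function(tree, n_loci, root_length = 1000,
                             indel_rate = 0.02, mean_indel_length = 12,
                             model = "JC", kappa = 2,
                             base_freq = rep(0.25, 4), seed = NULL) {
  stopifnot(n_loci >= 1)
  sims <- lapply(seq_len(n_loci), function(i) {
    with_seed(if (is.null(seed)) NULL else .seed_stream(seed, i),
              simulate_locus(tree, root_length = root_length,
                             indel_rate = indel_rate,
                             mean_indel_length = mean_indel_length,
                             model = model, kappa = kappa,
                             base_freq = base_freq,
                             locus_id = sprintf("locus%04d", i)))
  })
  list(aligned = dataset_bundle(lapply(sims, `[[`, "alignment"),
                                group_order = tree$tip.label),
       unaligned = dataset_bundle(lapply(sims, `[[`, "sequences"),
                                  group_order = tree$tip.label),
       tree = tree)
}
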