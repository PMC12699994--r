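fake_fit <- function(labels, M, locus_id) {
  th <- matrix(rgamma(length(labels) * M, 1), length(labels), M)
  th <- th / rowSums(th)
  dimnames(th) <- list(labels, paste0("topic", seq_len(M)))
  structure(list(locus_id = locus_id, theta = th,
                 beta = matrix(1, M, 1), bound = 0),
            class = "topic_fit")
}

test_that("matrix assembly follows the gene-frequency convention", {
  set.seed(40)
  tips9 <- paste0("p", 1:9)
  fits <- lapply(1:14, function(i) fake_fit(tips9, 5, paste0("l", i)))
  x <- assemble_matrix(fits)
  expect_equal(dim(x), c(9L, 14L * 4L))        # tips x loci (M - 1)
  expect_equal(attr(x, "transform"), "sqrt")
  tips12 <- paste0("s", 1:12)
  x2 <- assemble_matrix(lapply(1:100, function(i)
    fake_fit(tips12, 5, paste0("l", i))))
  expect_equal(dim(x2), c(12L, 400L))
  x3 <- assemble_matrix(fake_fit(c("a", "b"), 2, "solo"))
  expect_equal(dim(x3), c(2L, 1L))
  # sqrt applied: entries are square roots of the retained frequencies
  f <- fits[[1]]
  expect_equal(unname(x[, 1]), unname(sqrt(f$theta[, 1])))
  xn <- assemble_matrix(fits, transform = "none")
  expect_true(all(xn >= 0 & xn <= 1))
})

test_that("missing tips are an error unless imputation is requested", {
  set.seed(41)
  f1 <- fake_fit(c("a", "b", "c"), 3, "l1")
  f2 <- fake_fit(c("a", "b"), 3, "l2")
  expect_error(assemble_matrix(list(f1, f2)), "missing from locus 'l2'.*c")
  expect_warning(x <- assemble_matrix(list(f1, f2),
                                      missing = "impute_uniform"),
                 "imputing")
  expect_equal(unname(unclass(x)["c", 3:4]), sqrt(c(1 / 3, 1 / 3)))
})

test_that("sqrt transform fixes endpoints and rejects bad input", {
  expect_equal(unclass(sqrt_transform(matrix(c(0, 1, 0.25, 0.49), 2)))[, 1],
               c(0, 1))
  expect_equal(sqrt_transform(matrix(0.25))[1, 1], 0.5)
  expect_error(sqrt_transform(matrix(-0.1)), "negative")
})

test_that("pruning REML equals the covariance-matrix oracle", {
  set.seed(42)
  for (n in 4:8) {
    tr <- ape::unroot(ape::rtree(n))
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    x <- matrix(rnorm(n * 5), n,
                dimnames = list(tr$tip.label, NULL))
    expect_equal(reml_loglik(tr, x), reml_oracle(tr, x), tolerance = 1e-9)
  }
})

test_that("REML has the documented closed form on zero data", {
  tr <- ape::read.tree(text = "(a:1,b:1,c:1);")
  x <- matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  # contrasts: v1 = 2 (a vs b), v2 = 1 + 1/2 (joined node vs c)
  expect_equal(reml_loglik(tr, x),
               -0.5 * log(2 * pi * 2) - 0.5 * log(2 * pi * 1.5))
})

test_that("REML is invariant to root placement and tip order", {
  set.seed(43)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  x <- matrix(rnorm(6 * 3), 6, dimnames = list(tr$tip.label, NULL))
  ll <- reml_loglik(tr, x)
  rooted <- ape::root(tr, outgroup = tr$tip.label[3], resolve.root = TRUE)
  expect_equal(reml_loglik(rooted, x), ll, tolerance = 1e-8)
  perm <- sample(6)
  expect_equal(reml_loglik(tr, x[perm, , drop = FALSE]), ll,
               tolerance = 1e-10)
})

test_that("consistent rescaling shifts only the determinant term", {
  set.seed(44)
  tr <- ape::unroot(ape::rtree(5))
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  x <- matrix(rnorm(5 * 4), 5, dimnames = list(tr$tip.label, NULL))
  a <- 3.7
  tr2 <- tr; tr2$edge.length <- a * tr$edge.length
  ll1 <- reml_loglik(tr, x)
  ll2 <- reml_loglik(tr2, sqrt(a) * x)
  # quadratic terms match; log-det differs by (n-1) p/2 log(a) exactly
  expect_equal(ll2, ll1 - (5 - 1) * 4 / 2 * log(a), tolerance = 1e-8)
})

test_that("branch-length optimization ascends and recovers the truth", {
  set.seed(45)
  tr <- ape::unroot(ape::rtree(5))
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 1)
  x <- sim_bm(tr, 5000)
  ll0 <- reml_loglik(tr, x)
  opt <- optimize_branch_lengths(tr, x)
  expect_gte(attr(opt, "loglik"), ll0)
  expect_gte(attr(opt, "loglik"), reml_loglik(opt, x) - 1e-6)
  rel <- abs(opt$edge.length - tr$edge.length) / tr$edge.length
  expect_lt(mean(rel), 0.1)
  # identical rows leave no signal: internal branches collapse to zero
  x0 <- matrix(rep(rnorm(4), each = 5), 5,
               dimnames = list(tr$tip.label, NULL))
  o0 <- optimize_branch_lengths(tr, x0)
  internal <- o0$edge[, 2] > 5
  expect_lt(max(o0$edge.length[internal]), 1e-6)
})

test_that("tree search attains the exhaustive 5-tip optimum", {
  set.seed(46)
  labels <- letters[1:5]
  gen <- all_topologies(labels)[[7]]
  gen$edge.length <- runif(7, 0.2, 0.8)
  x <- sim_bm(gen, 60)
  x <- x[labels, ]
  best <- -Inf
  for (tp in all_topologies(labels)) {
    o <- optimize_branch_lengths(tp, x)
    best <- max(best, attr(o, "loglik"))
  }
  est <- search_tree(x)
  expect_equal(attr(est, "loglik"), best, tolerance = 1e-4)
  # row permutation changes the search path, not the optimum reached
  est2 <- search_tree(x[c(3, 5, 1, 2, 4), ])
  expect_equal(attr(est2, "loglik"), best, tolerance = 1e-4)
  expect_equal(rf_distance(est, est2), 0)
  est3 <- search_tree(x, jumble_seed = 11)
  expect_equal(attr(est3, "loglik"), best, tolerance = 1e-4)
})

test_that("three tips yield the unique topology", {
  set.seed(47)
  x <- matrix(rnorm(9), 3, dimnames = list(c("a", "b", "c"), NULL))
  tr <- search_tree(x)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 1L)
  expect_error(search_tree(x[1:2, ]), "3 tips")
})

test_that("search recovers the generating topology from clean BM data", {
  set.seed(48)
  tr <- sim_guide_tree(7)
  x <- sim_bm(tr, 400, sd_scale = 1)
  est <- search_tree(x)
  expect_equal(rf_distance(est, tr), 0)
})
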