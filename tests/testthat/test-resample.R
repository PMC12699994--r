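test_that("site bootstrap resamples columns jointly across rows", {
  lc <- locus_data(c(a = "A", b = "C"), aligned = TRUE)
  expect_equal(bootstrap_sites(lc)$sequences, lc$sequences)  # L = 1
  lc2 <- locus_data(c(a = "ACGTAC", b = "TGCATG"), aligned = TRUE)
  set.seed(60); r1 <- bootstrap_sites(lc2)
  set.seed(60); r2 <- bootstrap_sites(lc2)
  expect_identical(r1$sequences, r2$sequences)
  # columns stay intact: every resampled column is one of the originals
  cols <- function(l) {
    m <- do.call(rbind, strsplit(l$sequences, ""))
    apply(m, 2, paste, collapse = "")
  }
  expect_true(all(cols(r1) %in% cols(lc2)))
  un <- locus_data(c(a = "ACG", b = "ACGT"))
  expect_error(bootstrap_sites(un), "aligned")
})

test_that("each column appears once on average across replicates", {
  set.seed(61)
  L <- 10; reps <- 4000
  counts <- replicate(reps, sum(sample.int(L, L, replace = TRUE) == 1L))
  se <- sqrt(1 * (1 - 1 / L) / reps)   # multinomial count, mean 1
  expect_lt(abs(mean(counts) - 1), 3 * se)
  # and through the exported interface
  lc <- locus_data(c(a = "ACGTACGTAC", b = "ACGTACGTAC"), aligned = TRUE)
  set.seed(62)
  first <- replicate(500, {
    b <- bootstrap_sites(lc)
    substr(b$sequences[[1]], 1, 1)
  })
  expect_true(all(first %in% c("A", "C", "G", "T")))
})

test_that("k-mer bootstrap conserves per-document token totals", {
  corp <- toy_corpus(list(a = rep("AA", 3)))
  set.seed(63)
  expect_equal(bootstrap_kmers(corp)$docs$a, rep("AA", 3))
  set.seed(64)
  docs <- lapply(1:5, function(i)
    sample(c("AA", "AC", "CA", "CC"), sample(5:40, 1), TRUE))
  names(docs) <- paste0("d", 1:5)
  corp2 <- toy_corpus(docs)
  for (i in 1:10) {
    b <- bootstrap_kmers(corp2)
    expect_equal(lengths(b$docs), lengths(corp2$docs))
    expect_true(all(unlist(b$docs) %in% unlist(corp2$docs)))
  }
  empty <- toy_corpus(list(a = character(0), b = c("AA")))
  expect_warning(be <- bootstrap_kmers(empty), "empty")
  expect_length(be$docs$a, 0L)
})

test_that("two-kmer document resamples with binomial probabilities", {
  set.seed(65)
  corp <- toy_corpus(list(a = c("AA", "CC")))
  reps <- 4000
  both_aa <- mean(replicate(reps, {
    all(bootstrap_kmers(corp)$docs$a == "AA")
  }))
  se <- sqrt(0.25 * 0.75 / reps)
  expect_lt(abs(both_aa - 0.25), 3 * se)
})

test_that("majority consensus keeps >50% bipartitions with % supports", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  cons <- majority_consensus(list(t1, t1, t1))
  expect_equal(rf_distance(cons, t1), 0)
  expect_setequal(setdiff(cons$node.label, ""), "100")
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  cons2 <- majority_consensus(list(t1, t1, t2))
  # clade {a,b} and {c,d} appear in 2 of 3 trees -> kept with support 67
  expect_setequal(setdiff(cons2$node.label, ""), "67")
  expect_equal(rf_distance(cons2, t1), 0)
  t3 <- ape::read.tree(text = "((a,d),(b,c),e);")
  star <- majority_consensus(list(t1, t2, t3))
  expect_equal(star$Nnode, 1L)               # full conflict -> star
  expect_error(majority_consensus(list(t1, ape::rtree(4))), "tip sets")
})

test_that("consensus topology matches ape and ignores list order", {
  set.seed(66)
  trees <- replicate(9, ape::unroot(ape::rtree(8, tip.label = letters[1:8])),
                     simplify = FALSE)
  trees <- c(trees, trees[rep(1, 4)])        # weight one topology up
  mine <- majority_consensus(trees)
  ref <- ape::consensus(trees, p = 0.5)
  expect_equal(rf_distance(mine, ref), 0)
  perm <- majority_consensus(trees[sample(length(trees))])
  expect_equal(rf_distance(mine, perm), 0)
  expect_setequal(setdiff(perm$node.label, ""),
                  setdiff(mine$node.label, ""))
})

test_that("bootstrap pipeline: one replicate gives that tree at 100%", {
  set.seed(67)
  tr <- sim_guide_tree(7)
  sim <- simulate_dataset(tr, n_loci = 6, indel_rate = 0.02, seed = 5)
  reps <- run_bootstrap(sim$aligned, replicates = 1, mode = "sites",
                        seed = 99)
  expect_length(reps, 1L)
  cons <- majority_consensus(reps)
  expect_equal(rf_distance(cons, reps[[1]]), 0)
  expect_setequal(setdiff(cons$node.label, ""), "100")
  # deterministic under the master seed
  reps2 <- run_bootstrap(sim$aligned, replicates = 1, mode = "sites",
                         seed = 99)
  expect_equal(ape::write.tree(reps[[1]]), ape::write.tree(reps2[[1]]))
  # k-mer mode runs on the same bundle
  repk <- run_bootstrap(sim$unaligned, replicates = 2, mode = "kmers",
                        seed = 100)
  expect_length(repk, 2L)
  expect_s3_class(repk[[1]], "phylo")
})
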