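test_that("K2P distances follow the closed form", {
  rows <- c(a = "ACGTACGT", b = "ACGTACGT")
  k <- k2p_distance_matrix(rows)
  expect_equal(k$d["a", "b"], 0)
  expect_equal(k$P["a", "b"], 0)

  # 100 columns: 10 transitions (A<->G), 5 transversions (A<->C)
  base <- strsplit(paste(rep("A", 100), collapse = ""), "")[[1]]
  other <- base
  other[1:10] <- "G"
  other[11:15] <- "C"
  rows2 <- c(x = paste(base, collapse = ""), y = paste(other, collapse = ""))
  k2 <- k2p_distance_matrix(rows2)
  expect_equal(k2$P["x", "y"], 0.10)
  expect_equal(k2$Q["x", "y"], 0.05)
  expect_equal(k2$d["x", "y"], -0.5 * log(0.75 * sqrt(0.9)), tolerance = 1e-12)
  expect_equal(round(k2$d["x", "y"], 4), 0.1702)

  # d increases with P at fixed Q over the valid domain
  dvals <- sapply(seq(0, 30, by = 5), function(nts) {
    o <- base; if (nts > 0) o[seq_len(nts)] <- "G"; o[31:35] <- "C"
    unname(k2p_distance_matrix(c(x = paste(base, collapse = ""),
                                 y = paste(o, collapse = "")))$d[1, 2])
  })
  expect_true(all(diff(dvals) > 0))
})

test_that("saturated pairs are capped with a warning, gaps use pairwise deletion", {
  sat <- c(a = paste(rep("A", 40), collapse = ""),
           b = paste(rep(c("G", "C"), 20), collapse = ""))
  expect_warning(k <- k2p_distance_matrix(sat), "capped")
  expect_equal(unname(k$d[1, 2]), 10)

  gapped <- c(a = "AC--ACGT", b = "ACGTAC-T")
  k2 <- k2p_distance_matrix(gapped)
  expect_equal(unname(k2$d[1, 2]), 0) # the 5 shared columns are identical
  expect_error(k2p_distance_matrix(c(a = "----", b = "ACGT")), "share no")
})

test_that("NJ reproduces the closed form on three taxa", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(el["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(el["c"]), (9 + 10 - 5) / 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive matrices exactly", {
  set.seed(71)
  for (i in 1:25) {
    tr <- ape::rtree(6)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    d <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE)
    d2 <- ape::cophenetic.phylo(nj)[rownames(d), colnames(d)]
    expect_lt(max(abs(d2 - d)), 1e-9)
  }
})

test_that("NJ topology is invariant under taxon reordering", {
  set.seed(72)
  tr <- ape::rtree(7)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  d <- ape::cophenetic.phylo(tr)
  nj1 <- neighbor_joining(d)
  perm <- sample(rownames(d))
  nj2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(nj1, nj2), 0, ignore_attr = TRUE)
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  set.seed(73)
  for (i in 1:10) {
    d <- as.matrix(dist(matrix(rnorm(6 * 4), 6)))
    dimnames(d) <- list(letters[1:6], letters[1:6])
    mine <- neighbor_joining(d)
    ref <- ape::nj(d)
    expect_equal(ape::dist.topo(mine, ref), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports behave at the degenerate ends", {
  tr <- make_species_tree(six_taxa)
  seqs <- evolve_sequences(tr, 4000, scale = 0.05, seed = 74)
  al <- progressive_align(seqs)
  bs <- bootstrap_support(al, B = 30, seed = 75)
  expect_true(all(bs$support == 1)) # unambiguous, long alignment

  bs1 <- bootstrap_support(al, B = 1, seed = 76)
  expect_true(all(bs1$support %in% c(0, 1)))

  bs_a <- bootstrap_support(al, B = 20, seed = 77)
  bs_b <- bootstrap_support(al, B = 20, seed = 77)
  expect_identical(bs_a$support, bs_b$support)
})

test_that("bootstrap support for true clades grows with alignment length", {
  tr <- make_species_tree(six_taxa)
  mean_support <- sapply(c(100, 1000, 10000), function(L) {
    seqs <- evolve_sequences(tr, L, scale = 0.01, seed = 78)
    mean(bootstrap_support(progressive_align(seqs), B = 25, seed = 79)$support)
  })
  expect_true(all(diff(mean_support) >= 0))
  expect_gt(mean_support[3], mean_support[1])
})

test_that("majority consensus contains exactly the majority bipartitions", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  cons <- majority_consensus(list(t1, t1, t1))
  expect_equal(ape::dist.topo(cons, t1), 0, ignore_attr = TRUE)
  expect_setequal(pkg_splits(cons), pkg_splits(t1))

  # T2 differs from T1 by one NNI: the disputed splits keep frequency 2/3
  # (canonical split keys name the side not containing taxon "a")
  t2 <- ape::read.tree(text = "((a,c),(b,d),(e,f));")
  cons2 <- majority_consensus(list(t1, t1, t2))
  expect_true(.split_key_test(c("c", "d", "e", "f")) %in% pkg_splits(cons2))
  expect_true(.split_key_test(c("c", "d")) %in% pkg_splits(cons2))
  lab <- cons2$node.label
  expect_true(any(grepl("0.6667", lab)))

  expect_equal(ape::dist.topo(majority_consensus(list(t1)), t1), 0,
               ignore_attr = TRUE)
  t_bad <- ape::read.tree(text = "((a,b),(c,d),(e,g));")
  expect_error(majority_consensus(list(t1, t_bad)), "share one leaf set")
})

test_that("majority consensus agrees with the reference implementation", {
  set.seed(81)
  for (rep in 1:10) {
    trees <- ape::rmtree(9, 6)
    mine <- majority_consensus(trees, 0.5)
    ref <- ape::consensus(trees, p = 0.5)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bipartition extraction matches enumeration on all 6-leaf trees", {
  trs <- phangorn::allTrees(6, rooted = FALSE, tip.label = letters[1:6])
  for (i in seq_along(trs)) {
    tr <- trs[[i]]
    expect_identical(pkg_splits(tr), oracle_splits(tr))
  }
})
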