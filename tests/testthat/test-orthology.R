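mk_hits <- function(q, s, bit = 100, id = 0.9) {
  data.frame(query_id = q, subject_id = s, score = bit, bit_score = bit,
             evalue = 1e-20, identity = id, aln_length = 150L,
             mismatches = 0L, gap_opens = 0L, q_start = 0L, q_end = 150L,
             s_start = 0L, s_end = 150L, subject_strand = "+",
             stringsAsFactors = FALSE)
}

test_that("reciprocal uniqueness requires exactly one hit both ways", {
  h12 <- mk_hits("a1", "b1"); h21 <- mk_hits("b1", "a1")
  expect_equal(reciprocal_unique_pairs(h12, h21),
               data.frame(ref1_id = "a1", ref2_id = "b1",
                          stringsAsFactors = FALSE))
  # a non-unique forward hit removes the pair
  h12b <- rbind(h12, mk_hits("a1", "b2"))
  expect_equal(nrow(reciprocal_unique_pairs(h12b, h21)), 0L)
  # and so does a non-unique reverse hit
  h21b <- rbind(h21, mk_hits("b1", "a2"))
  expect_equal(nrow(reciprocal_unique_pairs(h12, h21b)), 0L)
})

test_that("a planted duplicate removes exactly its own pair", {
  genes <- sprintf("g%03d", 1:100)
  h12 <- do.call(rbind, lapply(genes, function(g) {
    mk_hits(paste0("a_", g), paste0("b_", g))
  }))
  h21 <- do.call(rbind, lapply(genes, function(g) {
    mk_hits(paste0("b_", g), paste0("a_", g))
  }))
  expect_equal(nrow(reciprocal_unique_pairs(h12, h21)), 100L)
  # duplicate gene in reference 2: a_g050 now hits two subjects
  h12_dup <- rbind(h12, mk_hits("a_g050", "b_g050_dup"))
  pairs <- reciprocal_unique_pairs(h12_dup, h21)
  expect_equal(nrow(pairs), 99L)
  expect_false("a_g050" %in% pairs$ref1_id)
  # matching property: ids occur at most once
  expect_equal(anyDuplicated(pairs$ref1_id), 0L)
  expect_equal(anyDuplicated(pairs$ref2_id), 0L)
})

test_that("best hits are selected by bit score with documented tie-breaks", {
  tabs <- list(tax1 = rbind(mk_hits("a1", "s_low", bit = 120),
                            mk_hits("a1", "s_high", bit = 140)))
  b <- best_bamboo_hits("a1", tabs)
  expect_equal(b$subject_id, "s_high")

  tabs2 <- list(tax1 = rbind(mk_hits("a1", "s_less", bit = 130, id = 0.8),
                             mk_hits("a1", "s_more", bit = 130, id = 0.9)))
  b2 <- best_bamboo_hits("a1", tabs2)
  expect_equal(b2$subject_id, "s_more")

  tabs3 <- list(tax1 = rbind(mk_hits("a1", "s_b", bit = 130, id = 0.9),
                             mk_hits("a1", "s_a", bit = 130, id = 0.9)))
  expect_equal(best_bamboo_hits("a1", tabs3)$subject_id, "s_a")

  # a taxon with no hits contributes no entry
  b3 <- best_bamboo_hits("a2", tabs)
  expect_equal(nrow(b3), 0L)
})

test_that("homologous regions are extracted and co-oriented", {
  seqs <- c(s1 = "ACGTT")
  hit_full <- list(subject_id = "s1", s_start = 0L, s_end = 5L,
                   subject_strand = "+")
  expect_equal(extract_homologous_region(hit_full, seqs), "ACGTT")
  hit_minus <- list(subject_id = "s1", s_start = 0L, s_end = 5L,
                    subject_strand = "-")
  expect_equal(extract_homologous_region(hit_minus, seqs), "AACGT")
  hit_bad <- list(subject_id = "s1", s_start = 0L, s_end = 9L,
                  subject_strand = "+")
  expect_error(extract_homologous_region(hit_bad, seqs), "out of range")
})

test_that("extracted minus-strand regions re-align to the query faithfully", {
  set.seed(31)
  q <- random_dna(400)
  s <- reverse_complement(.mutate_dna_for_test(q, 0.05))
  hits <- seeded_search(setNames(q, "q"), setNames(s, "s"))
  expect_equal(hits$subject_strand, "-")
  region <- extract_homologous_region(hits[1, ], c(s = s))
  re <- score_local_alignment(q, region)
  expect_equal(re$score, hits$score[1])
  expect_equal(re$identity, hits$identity[1], tolerance = 1e-9)
})

test_that("cluster assembly enforces taxon completeness", {
  pairs <- data.frame(ref1_id = c("a1", "a2"), ref2_id = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  taxa <- c("ref2", "t1", "t2", "t3")
  best <- do.call(rbind, c(
    lapply(taxa, function(tx) {
      h <- mk_hits("a1", paste0(tx, "_x"))
      cbind(data.frame(taxon = tx, anchor = "a1"), h)
    }),
    lapply(taxa[1:3], function(tx) { # a2 misses t3
      h <- mk_hits("a2", paste0(tx, "_y"))
      cbind(data.frame(taxon = tx, anchor = "a2"), h)
    })))
  seqs <- setNames(lapply(taxa, function(tx) {
    v <- c(paste(rep("ACGT", 50), collapse = ""),
           paste(rep("TGCA", 50), collapse = ""))
    setNames(v, paste0(tx, c("_x", "_y")))
  }), taxa)
  anchors <- c(a1 = paste(rep("ACGT", 50), collapse = ""),
               a2 = paste(rep("ACGT", 50), collapse = ""))
  cl <- assemble_clusters(pairs, best, seqs, anchors, require_taxa = taxa)
  expect_length(cl, 1L)
  expect_equal(cl[["a1"]]$anchor, "a1")
  expect_equal(nrow(cl[["a1"]]$members), 5L) # anchor + ref2 + 3 bamboo
})

test_that("retained clusters equal direct truth-table enumeration under dropout", {
  set.seed(41)
  n_genes <- 60
  taxa <- c("ref2", "t1", "t2", "t3")
  genes <- sprintf("g%03d", seq_len(n_genes))
  pairs <- data.frame(ref1_id = paste0("a_", genes),
                      ref2_id = paste0("b_", genes), stringsAsFactors = FALSE)
  present <- matrix(runif(n_genes * length(taxa)) > 0.1, n_genes,
                    dimnames = list(genes, taxa))
  rows <- list()
  for (g in genes) for (tx in taxa) {
    if (present[g, tx]) {
      h <- mk_hits(paste0("a_", g), paste0(tx, "_", g))
      rows[[paste(g, tx)]] <- cbind(
        data.frame(taxon = tx, anchor = paste0("a_", g)), h)
    }
  }
  best <- do.call(rbind, rows)
  seq_of <- paste(rep("ACGT", 50), collapse = "")
  seqs <- setNames(lapply(taxa, function(tx) {
    setNames(rep(seq_of, n_genes), paste0(tx, "_", genes))
  }), taxa)
  anchors <- setNames(rep(seq_of, n_genes), paste0("a_", genes))
  cl <- assemble_clusters(pairs, best, seqs, anchors, require_taxa = taxa)
  expect_length(cl, sum(rowSums(present) == length(taxa)))

  # raising dropout never increases the retained count
  present2 <- present & (matrix(runif(length(present)), nrow(present)) > 0.2)
  best2 <- best[unlist(Map(function(a, t) present2[sub("^a_", "", a), t],
                           best$anchor, best$taxon)), ]
  cl2 <- assemble_clusters(pairs, best2, seqs, anchors, require_taxa = taxa)
  expect_lte(length(cl2), length(cl))
})

test_that("noise-free simulation yields one correct cluster per gene", {
  cfg <- sim_config(seed = 51, n_genes = 15, paralogue_rate = 0,
                    variant_rate = 0)
  sim <- make_transcript_sets(cfg)
  res <- run_ortho_pipeline(sim)
  expect_length(res$clusters, 15L)
  for (cl in res$clusters) {
    gene <- sub("^Osativa_", "", cl$anchor)
    expect_true(all(grepl(gene, cl$members$id, fixed = TRUE)))
  }
})
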