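test_that("the longest-ORF translation helper finds forward and reverse ORFs", {
  pep <- paste(rep("MKTAYIAKQR", 15), collapse = "")  # 150 aa
  codon_of <- function(aa) {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[match(aa, gc)]
  }
  nt <- paste(vapply(strsplit(pep, "")[[1]], codon_of, character(1)),
              collapse = "")
  orf <- paste0("GG", nt, "TAA", "CC")
  expect_equal(translate_longest_orf(orf), pep)
  expect_equal(translate_longest_orf(reverse_complement(orf)), pep)
  expect_true(is.na(translate_longest_orf("ATGAAATAA")))
})

test_that("homologue candidates require a filtered hit and length over 100 aa", {
  set.seed(101)
  ref <- setNames(random_protein(150), "ref_A")
  exact <- setNames(unname(ref), "hit_150")
  short <- setNames(substr(ref, 1, 100), "hit_100")
  decoy <- setNames(random_protein(200), "decoy")
  found <- find_homologues(ref, c(exact, short, decoy))
  expect_equal(names(found$candidates), "hit_150")
})

test_that("planted family members are all recovered and decoys rejected", {
  counts <- matrix(2L, 2, 2, dimnames = list(c("A", "B"), c("t1", "t2")))
  ms <- make_mads_truth_set(classes = c("A", "B"), copies_per_taxon = counts,
                            seed = 7, n_decoys = 10)
  pool <- c(ms$copies, ms$decoys)
  found <- find_homologues(ms$refs, pool)
  expect_setequal(names(found$candidates), names(ms$copies))
})

test_that("conspecific merging collapses only long high-identity pairs", {
  set.seed(103)
  base <- random_protein(180)
  near <- .mutate_protein_for_test(base, 0.04) # ~96% identical
  two <- c(c1 = base, c2 = near)
  m <- merge_conspecific_copies(two)
  expect_length(m$copies, 1L)
  expect_gte(nchar(m$copies[[1]]), max(nchar(two)))
  expect_setequal(m$merged_from[[1]], c("c1", "c2"))

  far <- .mutate_protein_for_test(base, 0.10) # ~90%: both retained
  m2 <- merge_conspecific_copies(c(c1 = base, c3 = far))
  expect_length(m2$copies, 2L)

  # partial overlap: merged copy spans the union of covered regions
  left <- substr(base, 1, 120)
  right <- substr(base, 41, 180)
  m3 <- merge_conspecific_copies(c(l = left, r = right))
  expect_length(m3$copies, 1L)
  expect_equal(nchar(m3$copies[[1]]), 180L)

  # idempotence and monotonicity
  m4 <- merge_conspecific_copies(m$copies)
  expect_identical(unname(m4$copies), unname(m$copies))
  expect_lte(length(m$copies), length(two))
})

test_that("family assignment follows the smallest single-family clade", {
  counts <- matrix(c(2L, 2L), 2, 1, dimnames = list(c("A", "E"), "t1"))
  ms <- make_mads_truth_set(classes = c("A", "E"), copies_per_taxon = counts,
                            seed = 11, n_decoys = 0)
  # a copy identical to the E anchor is assigned E
  e_anchor <- ms$refs[grep("_E_ref", names(ms$refs))[1]]
  copies <- c(ms$copies, setNames(unname(e_anchor), "t1_clone"))
  af <- assign_families(copies, ms$refs, ms$ref_families)
  got <- setNames(af$assignments$family, af$assignments$copy_id)
  expect_equal(unname(got["t1_clone"]), "E")
  truth <- setNames(ms$truth$label, ms$truth$copy_id)
  expect_true(all(got[names(ms$copies)] == truth[names(ms$copies)]))
  expect_error(assign_families(copies, character(0), character(0)),
               "at least one")
})

test_that("copies inside mixed-family clades stay unassigned", {
  set.seed(107)
  anc <- random_protein(160)
  # anchors of two different families form a tight cherry; the copy is
  # equidistant outside it, so its smallest enclosing clade mixes families
  refA <- .mutate_protein_for_test(anc, 0.005)
  refs <- c(Osativa_A_ref = refA,
            Bdistachyon_B_ref = .mutate_protein_for_test(refA, 0.01),
            Osativa_E_ref = random_protein(160),
            Bdistachyon_E_ref2 = random_protein(160))
  fams <- c(Osativa_A_ref = "A", Bdistachyon_B_ref = "B",
            Osativa_E_ref = "E", Bdistachyon_E_ref2 = "E")
  copy <- setNames(.mutate_protein_for_test(anc, 0.10), "t1_x")
  af <- assign_families(copy, refs, fams)
  expect_equal(af$assignments$family, "unassigned")
})

test_that("copy-count tables satisfy the marginal identities", {
  counts <- mads_reference_counts()
  rows <- do.call(rbind, lapply(rownames(counts), function(f) {
    do.call(rbind, lapply(colnames(counts), function(tx) {
      n <- counts[f, tx]
      if (n == 0) return(NULL)
      data.frame(copy_id = sprintf("%s_%s_%d", tx, f, seq_len(n)),
                 family = f, taxon = tx, stringsAsFactors = FALSE)
    }))
  }))
  tab <- copy_count_table(rows, taxa = colnames(counts),
                          families = rownames(counts))
  expect_equal(tab$grand_total, sum(counts))
  expect_equal(unname(tab$row_totals), unname(rowSums(counts)))
  expect_equal(unname(tab$col_totals), unname(colSums(counts)))
  expect_equal(sum(tab$row_totals), sum(tab$col_totals))

  empty <- copy_count_table(rows[0, ], taxa = colnames(counts),
                            families = rownames(counts))
  expect_equal(empty$grand_total, 0L)

  set.seed(109)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    a <- data.frame(copy_id = paste0("c", 1:n),
                    family = sample(rownames(counts), n, TRUE),
                    taxon = sample(colnames(counts), n, TRUE))
    tb <- copy_count_table(a, colnames(counts), rownames(counts))
    expect_equal(sum(tb$counts), tb$grand_total)
    expect_equal(unname(rowSums(tb$counts)), unname(tb$row_totals))
    expect_equal(unname(colSums(tb$counts)), unname(tb$col_totals))
  }
})

test_that("sister-bamboo fractions match hand enumeration", {
  taxa_of <- c(lp1 = "Lp", lp2 = "Lp", lp3 = "Lp", lp4 = "Lp",
               gi1 = "Gi", oa1 = "Oa", os1 = "Os", bd1 = "Bd")
  bam <- c("Lp", "Gi", "Oa", "Pa")
  # lp1 sister to gi1 (bamboo), lp2 sister to os1 (reference),
  # lp3 sister to (lp4, bd1) clade (mixed) and lp4 sister to bd1
  tr <- ape::read.tree(text = "(((lp1,gi1),(lp2,os1)),((lp3,(lp4,bd1)),oa1));")
  sb <- sister_bamboo_fraction(list(fam = tr), "Lp", taxa_of, bam)
  expect_equal(sb$n_copies, 4L)
  expect_equal(sb$n_bamboo_sister, 1L)
  expect_equal(sb$percent, 25.00)

  tr0 <- ape::read.tree(text = "((lp1,os1),(lp2,bd1));")
  sb0 <- sister_bamboo_fraction(list(fam = tr0), "Lp",
                                taxa_of, bam)
  expect_equal(sb0$percent, 0.00)
  expect_error(sister_bamboo_fraction(list(fam = tr0), "Pa", taxa_of, bam),
               "absent")
})
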