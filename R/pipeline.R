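# End-to-end pipelines: simulate -> search -> cluster -> align -> tree ->
# classify, and the MADS-box identification/classification chain.

#' Default tribe-level hypotheses for a simulated taxon set
#'
#' For taxa ordered (outgroup1, outgroup2, herbaceous, tropical1, tropical2,
#' temperate1\[, temperate2\]): monophyly of all bamboos, monophyly of the
#' woody bamboos, the tropical pair, the temperate pair (7-taxon case), and
#' the plastid-hypothesis clade (herbaceous + tropical).
#'
#' @param taxa Taxon labels as in [make_species_tree()].
#' @return Named list of [hypothesis()] objects.
#' @export
default_hypotheses <- function(taxa) {
  stopifnot(length(taxa) %in% c(6L, 7L))
  bamboo <- taxa[3:length(taxa)]
  woody <- taxa[4:length(taxa)]
  hyps <- list(
    bambusoideae_monophyly = hypothesis("bambusoideae_monophyly", bamboo),
    woody_monophyly = hypothesis("woody_monophyly", woody),
    tropical_pair = hypothesis("tropical_pair", taxa[4:5]),
    plastid_topology = hypothesis("plastid_topology", taxa[3:5]))
  if (length(taxa) == 7L) {
    hyps$temperate_pair <- hypothesis("temperate_pair", taxa[6:7])
  }
  hyps
}

#' Run the orthologue phylogenomics pipeline on a transcript simulation
#'
#' The full chain: seeded search between the two reference gene sets,
#' reciprocal-unique anchor pairing, per-taxon best-bit-score hits of the
#' anchors against each bamboo transcript set, taxon-complete cluster
#' assembly, per-cluster progressive alignment, per-gene NJ trees (K2P
#' distances), rooting at the first reference taxon and hypothesis counting,
#' plus the concatenated gap-stripped supermatrix tree and the majority-rule
#' consensus of the gene trees.
#'
#' @param sim A `"transcript_sim"` from [make_transcript_sets()].
#' @param scheme Nucleotide [scoring_scheme()].
#' @param policy [filter_policy()] applied to every hit table.
#' @param word_size Seed word length for the searches (default 13; a larger
#'   word than the scheme default trades a little seeding sensitivity for
#'   far fewer chance seed matches, which the high-identity simulated
#'   homologues never miss).
#' @param hypotheses List of [hypothesis()] objects (default
#'   [default_hypotheses()] on the simulation's taxa).
#' @param consensus_threshold Majority-rule threshold (default 0.5).
#' @return List with `report` (a [support_report()]), `counts`, `clusters`,
#'   `gene_trees`, `consensus`, `supermatrix` (gap-stripped), and
#'   `concat_tree` (rooted NJ tree of the supermatrix).
#' @export
run_ortho_pipeline <- function(sim, scheme = scoring_scheme(),
                               policy = filter_policy(),
                               word_size = 13L,
                               hypotheses = NULL,
                               consensus_threshold = 0.5) {
  stopifnot(inherits(sim, "transcript_sim"))
  taxa <- sim$config$taxa
  ref1_taxon <- taxa[1]; ref2_taxon <- taxa[2]
  bamboo <- taxa[-(1:2)]
  if (is.null(hypotheses)) hypotheses <- default_hypotheses(taxa)

  hits12 <- filter_hits(seeded_search(sim$ref1, sim$ref2, scheme, word_size,
                                      max_evalue = policy$max_evalue), policy)
  hits21 <- filter_hits(seeded_search(sim$ref2, sim$ref1, scheme, word_size,
                                      max_evalue = policy$max_evalue), policy)
  anchor_pairs <- reciprocal_unique_pairs(hits12, hits21)

  subject_sets <- c(setNames(list(sim$ref2), ref2_taxon), sim$transcripts)
  hit_tables <- lapply(names(subject_sets), function(tx) {
    if (tx == ref2_taxon) return(hits12)
    filter_hits(seeded_search(sim$ref1, subject_sets[[tx]], scheme, word_size,
                              max_evalue = policy$max_evalue), policy)
  })
  names(hit_tables) <- names(subject_sets)
  best <- best_bamboo_hits(anchor_pairs$ref1_id, hit_tables)

  clusters <- assemble_clusters(
    anchor_pairs, best, subject_sets, sim$ref1,
    require_taxa = c(ref2_taxon, bamboo),
    anchor_taxon = ref1_taxon, min_region = policy$min_aln_length)

  alignments <- lapply(clusters, function(cl) {
    seqs <- setNames(cl$members$sequence, cl$members$taxon)
    progressive_align(seqs, scheme, source = cl$anchor)
  })
  gene_trees <- lapply(alignments, function(al) {
    neighbor_joining(k2p_distance_matrix(al))
  })

  counts <- classify_trees(gene_trees, ref1_taxon, hypotheses)
  report <- support_report(counts, length(gene_trees))
  consensus <- majority_consensus(unname(gene_trees), consensus_threshold)

  sm <- strip_gap_columns(concatenate_supermatrix(unname(alignments)))
  concat_tree <- root_tree(neighbor_joining(k2p_distance_matrix(sm$rows)),
                           ref1_taxon)

  list(report = report, counts = counts, clusters = clusters,
       gene_trees = gene_trees, consensus = consensus,
       supermatrix = sm, concat_tree = concat_tree)
}

#' Run the MADS-box identification and classification pipeline
#'
#' Per taxon: homologue candidates ([find_homologues()]) from the labeled
#' reference anchors, conspecific redundancy merging
#' ([merge_conspecific_copies()]); then family assignment on the anchored NJ
#' tree ([assign_families()]) and tabulation ([copy_count_table()]).
#'
#' @param proteins_by_taxon Named list, taxon -> named protein vector
#'   (transcript translations).
#' @param refs Named reference protein vector.
#' @param ref_families Named character vector: reference id -> family.
#' @param scheme Protein [scoring_scheme()].
#' @param policy [filter_policy()] for the homologue search.
#' @param merge_threshold Conspecific identity threshold (default 0.95).
#' @param B Bootstrap pseudoreplicates for per-family trees (default 0).
#' @param seed Seed for the bootstrap.
#' @return List with `table` (a [copy_count_table()]), `assignments` (data
#'   frame with `copy_id`, `taxon`, `family`, `merged_from`), `tree`,
#'   `family_trees`, and `taxa_of` (leaf -> taxon map over copies and refs).
#' @export
run_mads_pipeline <- function(proteins_by_taxon, refs, ref_families,
                              scheme = scoring_scheme("protein"),
                              policy = filter_policy(min_aln_length = 50),
                              merge_threshold = 0.95, B = 0L, seed = 1L) {
  stopifnot(!is.null(names(proteins_by_taxon)))
  copies <- character(0)
  taxon_of <- character(0)
  merged_from <- list()
  for (tx in names(proteins_by_taxon)) {
    found <- find_homologues(refs, proteins_by_taxon[[tx]], scheme, policy)
    if (!length(found$candidates)) next
    merged <- merge_conspecific_copies(found$candidates, merge_threshold,
                                       scheme)
    copies <- c(copies, merged$copies)
    taxon_of <- c(taxon_of, setNames(rep(tx, length(merged$copies)),
                                     names(merged$copies)))
    merged_from <- c(merged_from, merged$merged_from)
  }
  af <- assign_families(copies, refs, ref_families, scheme, B = B, seed = seed)
  assignments <- af$assignments
  assignments$taxon <- unname(taxon_of[assignments$copy_id])
  assignments$merged_from <- vapply(assignments$copy_id, function(id) {
    paste(merged_from[[id]], collapse = ",")
  }, character(1))
  tab <- copy_count_table(assignments,
                          taxa = names(proteins_by_taxon),
                          families = unique(ref_families))
  ref_taxon_of <- setNames(sub("_.*$", "", names(refs)), names(refs))
  list(table = tab, assignments = assignments, tree = af$tree,
       family_trees = af$family_trees,
       taxa_of = c(taxon_of, ref_taxon_of))
}
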