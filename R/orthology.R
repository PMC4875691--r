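# Single-copy orthologue clusters anchored on two reference gene sets:
# reciprocal uniqueness between the references, best-bit-score membership
# per taxon, and taxon-completeness filtering.

#' Reciprocal-unique anchor pairs between two reference gene sets
#'
#' Given filtered hit tables in both directions, returns the pairs `(a, b)`
#' where `b` is the only subject `a` hits and `a` is the only subject `b`
#' hits. "Exactly one hit" counts distinct subjects after filtering (segment
#' collapsing is the search's job). The result is a one-to-one partial
#' matching.
#'
#' @param hits12,hits21 Filtered hit tables (see [filter_hits()]) of
#'   reference 1 vs reference 2 and vice versa.
#' @return Data frame with columns `ref1_id`, `ref2_id`.
#' @export
reciprocal_unique_pairs <- function(hits12, hits21) {
  unique_map <- function(h) {
    pairs <- unique(h[, c("query_id", "subject_id")])
    n_subj <- table(pairs$query_id)
    ok <- names(n_subj)[n_subj == 1L]
    pairs <- pairs[pairs$query_id %in% ok, , drop = FALSE]
    setNames(pairs$subject_id, pairs$query_id)
  }
  fwd <- unique_map(hits12)
  rev <- unique_map(hits21)
  keep <- names(fwd)[!is.na(match(fwd, names(rev))) &
                       rev[fwd] == names(fwd)]
  keep <- sort(keep)
  data.frame(ref1_id = keep, ref2_id = unname(fwd[keep]),
             stringsAsFactors = FALSE)
}

#' Best hit per (anchor, taxon) by bit score
#'
#' For each anchor gene and each taxon keeps the single filtered hit with the
#' highest bit score; ties are broken by higher identity, then lexicographic
#' subject id. Taxa with no hit for an anchor get no entry (the cluster later
#' fails the completeness rule).
#'
#' @param anchor_ids Character vector of anchor (reference 1) gene ids.
#' @param hit_tables Named list, taxon -> filtered hit table whose queries
#'   are anchor ids and subjects are that taxon's transcripts.
#' @return Data frame with columns `taxon`, `anchor` plus the winning hit's
#'   fields.
#' @export
best_bamboo_hits <- function(anchor_ids, hit_tables) {
  stopifnot(!is.null(names(hit_tables)))
  out <- list()
  for (tx in names(hit_tables)) {
    h <- hit_tables[[tx]]
    h <- h[h$query_id %in% anchor_ids, , drop = FALSE]
    if (!nrow(h)) next
    h <- h[order(h$query_id, -h$bit_score, -h$identity, h$subject_id), ,
           drop = FALSE]
    h <- h[!duplicated(h$query_id), , drop = FALSE]
    out[[tx]] <- cbind(data.frame(taxon = tx, anchor = h$query_id,
                                  stringsAsFactors = FALSE), h)
  }
  if (!length(out)) {
    return(cbind(data.frame(taxon = character(0), anchor = character(0)),
                 .empty_hits()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract the homologous region a hit covers on its subject
#'
#' Returns `subject[s_start:s_end)` (0-based half-open coordinates),
#' reverse-complemented when the hit is on the minus strand, so all cluster
#' members are co-oriented with the anchor.
#'
#' @param hit One hit (list or single-row data frame with `subject_id`,
#'   `s_start`, `s_end`, `subject_strand`).
#' @param subject_seqs Named character vector containing the subject.
#' @return The extracted sequence (character scalar).
#' @export
extract_homologous_region <- function(hit, subject_seqs) {
  s <- subject_seqs[[hit$subject_id]]
  if (is.null(s)) stop("subject sequence not found: ", hit$subject_id,
                       call. = FALSE)
  if (hit$s_start < 0 || hit$s_end > nchar(s) || hit$s_start >= hit$s_end) {
    stop("hit coordinates out of range for subject ", hit$subject_id,
         call. = FALSE)
  }
  region <- substr(s, hit$s_start + 1L, hit$s_end)
  if (identical(hit$subject_strand, "-")) reverse_complement(region) else region
}

#' Assemble taxon-complete orthologue clusters
#'
#' One cluster per anchor pair: the anchor's full reference-1 sequence plus
#' the extracted homologous region of the best hit from every taxon in
#' `hit_tables` (the second reference joins the same way when its hit table
#' is supplied). Clusters missing any taxon in `require_taxa`, or whose
#' extracted region is shorter than `min_region`, are discarded.
#'
#' @param anchor_pairs Data frame from [reciprocal_unique_pairs()].
#' @param best_hits Data frame from [best_bamboo_hits()] (all taxa stacked).
#' @param sequences Named list, taxon -> named sequence vector for that
#'   taxon's subjects.
#' @param anchor_seqs Named character vector of reference-1 sequences.
#' @param require_taxa Taxa that must all be present for a cluster to be
#'   retained (default: every taxon in `best_hits`).
#' @param anchor_taxon Label used for the anchor row (default `"ref1"`).
#' @param min_region Minimum extracted-region length (default 100, the
#'   nucleotide alignment-length floor).
#' @return List of `"ortho_cluster"` objects, each with `anchor`, `ref2_id`
#'   and a `members` data frame (taxon, id, bit_score, sequence).
#' @export
assemble_clusters <- function(anchor_pairs, best_hits, sequences, anchor_seqs,
                              require_taxa = unique(best_hits$taxon),
                              anchor_taxon = "ref1", min_region = 100) {
  clusters <- list()
  for (i in seq_len(nrow(anchor_pairs))) {
    a <- anchor_pairs$ref1_id[i]
    hits_a <- best_hits[best_hits$anchor == a, , drop = FALSE]
    members <- data.frame(taxon = anchor_taxon, id = a, bit_score = NA_real_,
                          sequence = unname(anchor_seqs[[a]]),
                          stringsAsFactors = FALSE)
    ok <- TRUE
    for (j in seq_len(nrow(hits_a))) {
      h <- hits_a[j, ]
      region <- extract_homologous_region(h, sequences[[h$taxon]])
      if (nchar(region) < min_region) next
      members <- rbind(members, data.frame(
        taxon = h$taxon, id = h$subject_id, bit_score = h$bit_score,
        sequence = region, stringsAsFactors = FALSE))
    }
    if (!all(require_taxa %in% members$taxon)) next
    clusters[[a]] <- structure(
      list(anchor = a, ref2_id = anchor_pairs$ref2_id[i], members = members),
      class = "ortho_cluster")
  }
  clusters
}

#' Write orthologue clusters to disk
#'
#' One FASTA per cluster (`cluster_<anchor>.fasta`) plus a tab-separated
#' manifest (anchor, taxon, member id, bit score).
#'
#' @param clusters List of `"ortho_cluster"` objects.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_clusters <- function(clusters, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (cl in clusters) {
    seqs <- setNames(cl$members$sequence, cl$members$id)
    safe <- gsub("[^A-Za-z0-9_.-]", "_", cl$anchor)
    write_fasta(seqs, file.path(dir, sprintf("cluster_%s.fasta", safe)))
    manifest[[cl$anchor]] <- data.frame(
      anchor = cl$anchor, taxon = cl$members$taxon, member = cl$members$id,
      bit_score = cl$members$bit_score, stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, manifest), file.path(dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
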