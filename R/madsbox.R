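# MADS-box floral gene identification and classification: homologue search
# against labeled reference proteins, conspecific redundancy merging, family
# assignment via anchored gene trees, copy-count tabulation and sister-group
# summaries.

.GENETIC_CODE_STOP <- c("TAA", "TAG", "TGA")

#' Translate the longest open reading frame of a transcript
#'
#' Scans all six frames for the longest ATG-to-stop open reading frame and
#' returns its translation when it reaches `min_aa` residues (stop excluded).
#'
#' @param nt Nucleotide sequence.
#' @param min_aa Minimum peptide length to report (default 101, i.e. over
#'   100 aa).
#' @return The peptide string, or `NA_character_` if no ORF is long enough.
#' @export
translate_longest_orf <- function(nt, min_aa = 101L) {
  gc <- Biostrings::GENETIC_CODE
  best <- ""
  for (s in c(toupper(nt), reverse_complement(toupper(nt)))) {
    n <- nchar(s)
    for (frame in 0:2) {
      starts <- seq(1L + frame, n - 2L, by = 3L)
      if (!length(starts)) next
      codons <- substring(s, starts, starts + 2L)
      aa <- unname(gc[codons])
      aa[is.na(aa)] <- "X"
      is_start <- codons == "ATG"
      is_stop <- aa == "*"
      orf_open <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(orf_open) && is_start[i]) orf_open <- i
        if (!is.na(orf_open) && is_stop[i]) {
          pep_len <- i - orf_open
          if (pep_len > nchar(best)) {
            best <- paste(aa[orf_open:(i - 1L)], collapse = "")
          }
          orf_open <- NA_integer_
        }
      }
    }
  }
  if (nchar(best) >= min_aa) best else NA_character_
}

#' Find MADS-box homologue candidates in translated transcripts
#'
#' Protein-mode seeded search of the labeled reference proteins against the
#' supplied translations; candidates are the subjects with at least one hit
#' surviving the filter policy and a length strictly over 100 amino acids,
#' deduplicated by id.
#'
#' @param refs Named reference protein vector.
#' @param translations Named protein vector (transcript translations).
#' @param scheme Protein [scoring_scheme()].
#' @param policy [filter_policy()]; the default uses the protein convention
#'   of a 50-aa alignment-length floor with the usual E-value and identity
#'   thresholds.
#' @param min_length Minimum candidate length (strict; default 100 means
#'   "over 100 aa").
#' @return List with `candidates` (named protein vector) and `hits` (the
#'   filtered hit table).
#' @export
find_homologues <- function(refs, translations,
                            scheme = scoring_scheme("protein"),
                            policy = filter_policy(min_aln_length = 50),
                            min_length = 100L) {
  if (!length(translations)) {
    return(list(candidates = character(0), hits = .empty_hits()))
  }
  hits <- seeded_search(refs, translations, scheme,
                        max_evalue = policy$max_evalue)
  hits <- filter_hits(hits, policy)
  ids <- unique(hits$subject_id)
  ids <- ids[nchar(translations[ids]) > min_length]
  list(candidates = translations[ids], hits = hits)
}

# single-linkage grouping by pairwise predicate (union-find)
.single_linkage <- function(ids, linked) {
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(linked))) {
    a <- find(linked[k, 1]); b <- find(linked[k, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_along(ids), find, integer(1))
}

#' Merge conspecific near-duplicate copies
#'
#' Groups copies of one taxon by single linkage at pairwise identity above
#' `threshold` (identity measured on the optimal local alignment, i.e. over
#' the overlapping region) and collapses each group to one copy: sources are
#' taken longest-first and a consensus is built over the union of aligned
#' positions, earlier (longer) sources winning disagreements and filling
#' positions the shorter sources do not cover. `merged_from` records the
#' sources of every surviving copy. Idempotent; never increases copy count.
#'
#' Identity alone is not a sufficient linkage criterion: unrelated proteins
#' routinely share short perfect local matches, so a pair is linked only
#' when its optimal local alignment also spans at least `min_overlap`
#' columns.
#'
#' @param copies Named protein vector, all from one taxon.
#' @param threshold Identity threshold (strict >; default 0.95).
#' @param scheme Protein [scoring_scheme()].
#' @param min_overlap Minimum alignment columns for a pair to be linked
#'   (default 50 aa, matching the protein alignment-length floor).
#' @return List with `copies` (named vector) and `merged_from` (named list
#'   of source-id vectors).
#' @export
merge_conspecific_copies <- function(copies, threshold = 0.95,
                                     scheme = scoring_scheme("protein"),
                                     min_overlap = 50L) {
  n <- length(copies)
  if (n <= 1L) {
    return(list(copies = copies,
                merged_from = setNames(as.list(names(copies)), names(copies))))
  }
  pairs <- t(combn(n, 2L))
  linked <- pairs[apply(pairs, 1, function(ij) {
    a <- score_local_alignment(copies[[ij[1]]], copies[[ij[2]]], scheme)
    a$identity > threshold && a$aln_length >= min_overlap
  }), , drop = FALSE]
  grp <- .single_linkage(names(copies), linked)
  out <- character(0); from <- list()
  for (g in unique(grp)) {
    members <- copies[grp == g]
    ord <- order(-nchar(members), names(members))
    members <- members[ord]
    cons <- members[[1]]
    if (length(members) > 1L) {
      for (i in 2:length(members)) {
        al <- global_align(cons, members[[i]], scheme)
        ca <- .chars(al$q_aln); cb <- .chars(al$s_aln)
        merged <- ifelse(ca == "-", cb, ca)
        cons <- paste(merged[merged != "-"], collapse = "")
      }
    }
    id <- names(members)[1]
    out[[id]] <- cons
    from[[id]] <- names(members)
  }
  list(copies = unlist(out), merged_from = from)
}

#' Pairwise p-distance matrix from a protein (or nucleotide) alignment
#'
#' Per pair, the fraction of differing residues over columns where both rows
#' are ungapped.
#'
#' @param aln An `"ophy_alignment"` or named vector of equal-length rows.
#' @return Symmetric distance matrix with dimnames.
#' @export
p_distance_matrix <- function(aln) {
  rows <- if (inherits(aln, "ophy_alignment")) aln$rows else aln
  m <- do.call(rbind, strsplit(toupper(unname(rows)), "", fixed = TRUE))
  rownames(m) <- names(rows)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  ungapped <- m != "-"
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mask <- ungapped[i, ] & ungapped[j, ]
      L <- sum(mask)
      if (L < 1L) {
        stop("rows share no ungapped columns", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(mask & m[i, ] != m[j, ]) / L
    }
  }
  d
}

#' Assign gene copies to families via an anchored NJ tree
#'
#' Builds one NJ tree (distances: 1 minus global-alignment identity) over all
#' copies plus the labeled reference anchors. Each copy takes the family of
#' the smallest clade (split side) containing it together with labeled
#' references of exactly one family; copies whose smallest such clade mixes
#' families are `"unassigned"`. Per-family subtrees are then re-estimated
#' separately from a progressive protein alignment of the family's members,
#' rooted at the family's first reference anchor, optionally with bootstrap
#' support.
#'
#' @param copies Named protein vector (the merged bamboo copies).
#' @param refs Named protein vector of reference anchors.
#' @param ref_families Named character vector mapping each reference id to
#'   its family.
#' @param scheme Protein [scoring_scheme()].
#' @param B Bootstrap pseudoreplicates for the per-family trees (0 = none).
#' @param seed Seed for the bootstrap.
#' @return List with `assignments` (data frame: `copy_id`, `family`),
#'   `tree` (the global anchored NJ `phylo`), and `family_trees` (named list
#'   of rooted `phylo`, bootstrap supports as node labels when `B > 0`).
#' @export
assign_families <- function(copies, refs, ref_families,
                            scheme = scoring_scheme("protein"),
                            B = 0L, seed = 1L) {
  if (!length(refs)) stop("need at least one labeled reference", call. = FALSE)
  stopifnot(all(names(refs) %in% names(ref_families)))
  all_seqs <- c(copies, refs)
  n <- length(all_seqs)
  d <- matrix(0, n, n, dimnames = list(names(all_seqs), names(all_seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- global_align(all_seqs[[i]], all_seqs[[j]], scheme)
      d[i, j] <- d[j, i] <- 1 - al$identity
    }
  }
  tree <- neighbor_joining(d)
  tips <- tree$tip.label
  ntip <- length(tips)
  sets <- .node_desc_sets(tree)
  # both orientations of every split, ordered by side size
  sides <- list()
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    s <- sets[[nd]]
    if (length(s) >= 2L && length(s) <= ntip - 2L) {
      sides[[length(sides) + 1L]] <- s
      sides[[length(sides) + 1L]] <- setdiff(sort(tips), s)
    }
  }
  sides <- unique(sides)
  sides <- sides[order(lengths(sides),
                       vapply(sides, .split_key, character(1)))]
  fam_of_side <- function(s) {
    rf <- ref_families[intersect(s, names(refs))]
    if (!length(rf)) return(NA_character_)
    if (length(unique(rf)) == 1L) unique(rf) else "mixed"
  }
  assign_one <- function(id) {
    for (s in sides) {
      if (!(id %in% s)) next
      f <- fam_of_side(s)
      if (is.na(f)) next
      return(if (f == "mixed") "unassigned" else f)
    }
    "unassigned"
  }
  assignments <- data.frame(
    copy_id = names(copies),
    family = vapply(names(copies), assign_one, character(1)),
    stringsAsFactors = FALSE)
  # per-family subtree re-estimation
  family_trees <- list()
  for (fam in unique(ref_families)) {
    ids <- c(assignments$copy_id[assignments$family == fam],
             names(refs)[ref_families[names(refs)] == fam])
    if (length(ids) < 3L) next
    fam_aln <- progressive_align(all_seqs[ids], scheme, guide_k = 3L,
                                 source = fam)
    ftree <- if (B > 0) {
      bs <- bootstrap_support(fam_aln, B = B,
                              seed = .derive_seed(seed, match(fam, unique(ref_families))),
                              dist_fun = p_distance_matrix)
      bs$tree
    } else {
      neighbor_joining(p_distance_matrix(fam_aln))
    }
    anchor <- sort(names(refs)[ref_families[names(refs)] == fam])[1]
    family_trees[[fam]] <- root_tree(ftree, anchor)
  }
  list(assignments = assignments, tree = tree, family_trees = family_trees)
}

#' Copy-count table by family and taxon
#'
#' Counts assigned copies per family x taxon with row, column and grand
#' totals. Unassigned copies are excluded from the table and reported via
#' the `"n_unassigned"` attribute.
#'
#' @param assignments Data frame with `copy_id`, `family` and `taxon`.
#' @param taxa,families Column and row orders (defaults: as encountered).
#' @return An object of class `"copy_count_table"`: list with `counts`
#'   (matrix), `row_totals`, `col_totals`, `grand_total`.
#' @export
copy_count_table <- function(assignments,
                             taxa = unique(assignments$taxon),
                             families = setdiff(unique(assignments$family),
                                                "unassigned")) {
  keep <- assignments$family != "unassigned"
  a <- assignments[keep, , drop = FALSE]
  counts <- matrix(0L, length(families), length(taxa),
                   dimnames = list(families, taxa))
  for (i in seq_len(nrow(a))) {
    if (a$family[i] %in% families && a$taxon[i] %in% taxa) {
      counts[a$family[i], a$taxon[i]] <- counts[a$family[i], a$taxon[i]] + 1L
    }
  }
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand_total = sum(counts)),
            class = "copy_count_table",
            n_unassigned = sum(!keep))
}

#' @export
print.copy_count_table <- function(x, ...) {
  m <- cbind(x$counts, Total = x$row_totals)
  m <- rbind(m, Total = c(x$col_totals, x$grand_total))
  print(m)
  un <- attr(x, "n_unassigned")
  if (!is.null(un) && un > 0) cat(sprintf("(%d unassigned copies)\n", un))
  invisible(x)
}

#' Fraction of a taxon's copies sister to other-bamboo copies
#'
#' For every copy of `taxon` across the per-family trees, examines its
#' sister group: the copy counts as "bamboo-sister" iff the sister group's
#' leaves are all bamboo copies from other species. The fraction over all
#' the taxon's copies is returned as a percentage truncated to two decimals.
#'
#' @param family_trees Named list of rooted `phylo` gene-family trees.
#' @param taxon Taxon whose copies are examined.
#' @param taxa_of Named character vector mapping leaf ids to taxa.
#' @param bamboo_taxa Taxa counted as bamboo.
#' @return List with `percent` (floored, e.g. 25.00), `n_copies`,
#'   `n_bamboo_sister`.
#' @export
sister_bamboo_fraction <- function(family_trees, taxon, taxa_of, bamboo_taxa) {
  n_copies <- 0L; n_sister <- 0L
  for (tr in family_trees) {
    sets <- .node_desc_sets(tr)
    focal <- which(tr$tip.label %in%
                     names(taxa_of)[taxa_of == taxon &
                                      names(taxa_of) %in% tr$tip.label])
    for (leaf in focal) {
      n_copies <- n_copies + 1L
      p <- tr$edge[tr$edge[, 2] == leaf, 1]
      if (!length(p)) next
      sibs <- tr$edge[tr$edge[, 1] == p & tr$edge[, 2] != leaf, 2]
      sib_tips <- unlist(sets[sibs])
      sib_taxa <- taxa_of[sib_tips]
      if (length(sib_taxa) && all(sib_taxa %in% setdiff(bamboo_taxa, taxon))) {
        n_sister <- n_sister + 1L
      }
    }
  }
  if (n_copies == 0L) {
    stop("taxon `", taxon, "` absent from all family trees", call. = FALSE)
  }
  list(percent = floor(n_sister / n_copies * 1e4) / 1e2,
       n_copies = n_copies, n_bamboo_sister = n_sister)
}
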