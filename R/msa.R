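# Per-cluster multiple alignment (deterministic progressive alignment with a
# k-mer-distance guide tree), supermatrix concatenation, and gap-column
# stripping.

#' Construct an alignment object
#'
#' @param rows Named character vector of equal-length gapped sequences.
#' @param source Optional cluster anchor id the alignment came from.
#' @return An object of class `"ophy_alignment"`.
#' @export
alignment <- function(rows, source = NA_character_) {
  stopifnot(!is.null(names(rows)), length(rows) >= 1L)
  if (length(unique(nchar(rows))) != 1L) {
    stop("all alignment rows must have equal length", call. = FALSE)
  }
  structure(list(rows = rows, taxa = names(rows),
                 columns = nchar(rows[[1]]), source = source),
            class = "ophy_alignment")
}

#' @export
print.ophy_alignment <- function(x, ...) {
  cat(sprintf("alignment: %d rows x %d columns (source: %s)\n",
              length(x$rows), x$columns, x$source))
  invisible(x)
}

# character matrix view of an alignment (rows x columns)
.aln_matrix <- function(aln) {
  do.call(rbind, lapply(aln$rows, .chars))
}

.matrix_to_rows <- function(m) {
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

# frequency profile (states x columns) of a block of gapped rows
.profile_of <- function(block, states) {
  m <- do.call(rbind, strsplit(block, "", fixed = TRUE))
  nr <- nrow(m)
  prof <- vapply(seq_len(ncol(m)), function(j) {
    tabulate(match(m[, j], states), nbins = length(states))
  }, numeric(length(states)))
  matrix(prof, nrow = length(states)) / nr
}

# apply a profile-alignment path to a block of rows: -1 entries become gaps
.apply_path <- function(block, path) {
  m <- do.call(rbind, strsplit(block, "", fixed = TRUE))
  out <- matrix("-", nrow = nrow(m), ncol = length(path))
  keep <- path >= 0L
  out[, keep] <- m[, path[keep] + 1L, drop = FALSE]
  rownames(out) <- names(block)
  setNames(apply(out, 1, paste, collapse = ""), names(block))
}

#' Deterministic progressive multiple alignment
#'
#' Builds a guide tree from pairwise shared-k-mer distances (average-linkage
#' clustering) and aligns profiles progressively with affine-gap global
#' dynamic programming. Joins and DP ties are resolved by input order, so the
#' result is deterministic for a fixed input order. Ungapping any output row
#' reproduces the corresponding input sequence exactly.
#'
#' @param seqs Named character vector of >= 2 co-oriented nucleotide
#'   sequences.
#' @param scheme Nucleotide [scoring_scheme()] used for the profile DP.
#' @param guide_k Word length of the guide-tree k-mer distance (default 6).
#' @param source Optional anchor id recorded on the alignment.
#' @return An `"ophy_alignment"` with rows in the input order.
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme(), guide_k = 6L,
                              source = NA_character_) {
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  stopifnot(!is.null(names(seqs)))
  seqs <- toupper(seqs)
  for (s in seqs) .encode_seq(s, scheme$states, "sequence")
  n <- length(seqs)
  # guide tree from k-mer distances
  km <- lapply(seqs, .kmer_set, k = guide_k)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(km[[i]], km[[j]]))
      d[i, j] <- d[j, i] <- 1 - shared / max(1L, min(length(km[[i]]),
                                                     length(km[[j]])))
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  blocks <- lapply(seq_len(n), function(i) seqs[i])
  merged <- vector("list", n - 1L)
  for (step in seq_len(nrow(hc$merge))) {
    pick <- function(k) if (k < 0) blocks[[-k]] else merged[[k]]
    a <- pick(hc$merge[step, 1]); b <- pick(hc$merge[step, 2])
    pa <- .profile_of(a, scheme$states)
    pb <- .profile_of(b, scheme$states)
    al <- profile_align_cpp(pa, pb, scheme$sub, scheme$gap_open,
                            scheme$gap_extend)
    merged[[step]] <- c(.apply_path(a, al$a_path), .apply_path(b, al$b_path))
  }
  rows <- merged[[n - 1L]][names(seqs)]
  alignment(rows, source = source)
}

#' Concatenate per-cluster alignments into a supermatrix
#'
#' Row-wise concatenation over a shared taxon set, with a partition table
#' recording the provenance of every column range (0-based half-open).
#'
#' @param alignments List of `"ophy_alignment"` objects over exactly the
#'   same taxon set (rows named by taxon).
#' @param taxon_order Optional row order of the supermatrix.
#' @return An object of class `"ophy_supermatrix"`: list with `rows`,
#'   `taxa`, and `partitions` (data frame: `anchor`, `start`, `end`).
#' @export
concatenate_supermatrix <- function(alignments, taxon_order = NULL) {
  stopifnot(length(alignments) >= 1L)
  taxa <- sort(alignments[[1]]$taxa)
  for (al in alignments) {
    if (!identical(sort(al$taxa), taxa)) {
      stop("all alignments must contain exactly the same taxon set",
           call. = FALSE)
    }
  }
  if (is.null(taxon_order)) taxon_order <- alignments[[1]]$taxa
  stopifnot(identical(sort(taxon_order), taxa))
  parts <- data.frame(anchor = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  rows <- setNames(rep("", length(taxon_order)), taxon_order)
  pos <- 0L
  for (al in alignments) {
    rows <- paste0(rows, al$rows[taxon_order])
    parts <- rbind(parts, data.frame(
      anchor = al$source, start = pos, end = pos + al$columns,
      stringsAsFactors = FALSE))
    pos <- pos + al$columns
  }
  names(rows) <- taxon_order
  structure(list(rows = rows, taxa = taxon_order, columns = pos,
                 partitions = parts), class = "ophy_supermatrix")
}

#' @export
print.ophy_supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d columns, %d partitions\n",
              length(x$taxa), x$columns, nrow(x$partitions)))
  invisible(x)
}

#' Remove every column containing at least one gap
#'
#' Drops all columns in which any row has a `"-"`; remaining columns keep
#' their relative order and partition boundaries are remapped to surviving
#' columns. Ambiguity codes such as `N` are ordinary states and are kept.
#' Idempotent.
#'
#' @param sm An `"ophy_supermatrix"` (or `"ophy_alignment"`, treated as a
#'   single-partition matrix).
#' @return The gap-stripped `"ophy_supermatrix"`.
#' @export
strip_gap_columns <- function(sm) {
  if (inherits(sm, "ophy_alignment")) {
    sm <- concatenate_supermatrix(list(sm))
  }
  stopifnot(inherits(sm, "ophy_supermatrix"))
  m <- do.call(rbind, strsplit(unname(sm$rows), "", fixed = TRUE))
  gap_col <- apply(m == "-", 2, any)
  keep <- which(!gap_col)
  new_rows <- setNames(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""),
                       sm$taxa)
  # remap partition boundaries: new coordinate = surviving columns before it
  surv_before <- c(0L, cumsum(!gap_col))
  parts <- sm$partitions
  parts$start <- surv_before[parts$start + 1L]
  parts$end <- surv_before[parts$end + 1L]
  structure(list(rows = new_rows, taxa = sm$taxa, columns = length(keep),
                 partitions = parts), class = "ophy_supermatrix")
}

#' Write a supermatrix as FASTA, partitions, and relaxed PHYLIP
#'
#' @param sm An `"ophy_supermatrix"`.
#' @param fasta,partitions,phylip Output paths (any may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_supermatrix <- function(sm, fasta = NULL, partitions = NULL,
                              phylip = NULL) {
  if (!is.null(fasta)) write_fasta(sm$rows, fasta)
  if (!is.null(partitions)) {
    write.table(sm$partitions, partitions, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(phylip)) {
    con <- file(phylip, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", length(sm$taxa), sm$columns), con)
    writeLines(sprintf("%s  %s", sm$taxa, sm$rows[sm$taxa]), con)
  }
  invisible(c(fasta = fasta, partitions = partitions, phylip = phylip))
}
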