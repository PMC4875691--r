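# Rooting, monophyly testing, hypothesis classification and the support
# report with truncated two-decimal percentages.

#' Root a tree at a designated outgroup leaf
#'
#' Roots on the edge subtending the outgroup leaf, preserving the ingroup
#' topology. Re-rooting at the same leaf is idempotent.
#'
#' @param tree A `phylo` tree (rooted or unrooted).
#' @param outgroup A leaf label of `tree`.
#' @return A rooted `phylo` tree with the outgroup as one child of the root.
#' @export
root_tree <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!(outgroup %in% tree$tip.label)) {
    stop("outgroup `", outgroup, "` is not a leaf of the tree", call. = FALSE)
  }
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ape::root(utree, outgroup = outgroup, resolve.root = TRUE)
}

#' Is a set of taxa monophyletic in a rooted tree?
#'
#' True iff some node's descendant leaf set equals `taxa` exactly. Polytomies
#' get no soft credit: only an exact descendant-set match counts. Singletons
#' are trivially monophyletic.
#'
#' @param tree A rooted `phylo` tree.
#' @param taxa Character vector of leaf labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (length(taxa) <= 1L) return(TRUE)
  want <- sort(unique(taxa))
  sets <- .node_desc_sets(tree)
  for (s in sets) if (identical(s, want)) return(TRUE)
  FALSE
}

#' Phylogenetic hypothesis
#'
#' A named set of clades that must each be monophyletic (after rooting) for
#' a gene tree to support the hypothesis.
#'
#' @param name Hypothesis name.
#' @param ... One or more character vectors, each a required clade.
#' @return An object of class `"phylo_hypothesis"`.
#' @export
hypothesis <- function(name, ...) {
  clades <- list(...)
  stopifnot(length(clades) >= 1L,
            all(vapply(clades, is.character, logical(1))))
  structure(list(name = name, required_clades = clades),
            class = "phylo_hypothesis")
}

#' Classify gene trees against competing hypotheses
#'
#' Each tree is rooted at the outgroup and tested against every hypothesis
#' independently (a tree may support several). A hypothesis is supported when
#' all its required clades are monophyletic in the rooted tree.
#'
#' @param trees List of `phylo` trees, each containing the outgroup.
#' @param outgroup Outgroup leaf label used for rooting.
#' @param hypotheses List of [hypothesis()] objects (or bare character
#'   vectors, treated as single-clade hypotheses named by position).
#' @return Named integer vector of per-hypothesis support counts.
#' @export
classify_trees <- function(trees, outgroup, hypotheses) {
  hypotheses <- lapply(seq_along(hypotheses), function(i) {
    h <- hypotheses[[i]]
    if (inherits(h, "phylo_hypothesis")) return(h)
    nm <- names(hypotheses)[i]
    hypothesis(if (is.null(nm) || !nzchar(nm)) paste0("h", i) else nm, h)
  })
  counts <- setNames(integer(length(hypotheses)),
                     vapply(hypotheses, `[[`, character(1), "name"))
  for (tr in trees) {
    rt <- root_tree(tr, outgroup)
    for (h in hypotheses) {
      ok <- all(vapply(h$required_clades, function(cl) {
        is_monophyletic(rt, cl)
      }, logical(1)))
      if (ok) counts[h$name] <- counts[h$name] + 1L
    }
  }
  counts
}

#' Support report with truncated two-decimal percentages
#'
#' Percentages are floored (truncated) to two decimals, never rounded:
#' `percent = floor(count / total * 10^4) / 10^2`. This is the report's
#' contract; e.g. 2374/3878 prints 61.21 even though the exact value is
#' 61.2171...%.
#'
#' @param counts Named integer vector of per-hypothesis counts.
#' @param total Total number of trees (>= 1).
#' @return An object of class `"support_report"`: data frame with
#'   `hypothesis`, `count`, `percent`.
#' @export
support_report <- function(counts, total) {
  stopifnot(total >= 1)
  if (any(counts > total)) stop("count exceeds total", call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  out <- data.frame(hypothesis = names(counts) %||% paste0("h", seq_along(counts)),
                    count = as.integer(counts),
                    percent = floor(counts / total * 1e4) / 1e2,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "total") <- as.integer(total)
  class(out) <- c("support_report", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.support_report <- function(x, ...) {
  cat(sprintf("gene-tree support over %d trees\n", attr(x, "total")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s %6d (%.2f %%)\n",
                x$hypothesis[i], x$count[i], x$percent[i]))
  }
  invisible(x)
}

#' Write a support report as tab-separated values
#'
#' @param report A `"support_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_support_report <- function(report, path) {
  df <- as.data.frame(report)
  df$total <- attr(report, "total")
  df$percent <- sprintf("%.2f", df$percent)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify the reference relationship of a bamboo subtree
#'
#' For a rooted gene-family tree whose leaves are gene copies, tests the
#' relationship between the (monophyletic) bamboo copies and the copies from
#' the two reference taxa: category 1 when the bamboo clade is sister to a
#' clade of reference copies from both reference taxa; category 2 when
#' reference-2 copies are sister to the bamboo clade and that combined clade
#' is sister to reference-1 copies; category 3 symmetrically with the
#' references swapped; `"none"` otherwise (including non-monophyletic bamboo
#' copies).
#'
#' @param tree Rooted `phylo` tree of gene copies.
#' @param taxa_of Named character vector mapping every leaf to its taxon.
#' @param bamboo_taxa Taxa counted as bamboo.
#' @param ref1_taxon,ref2_taxon The two reference taxa.
#' @return `"1"`, `"2"`, `"3"`, or `"none"`.
#' @export
subtree_category <- function(tree, taxa_of, bamboo_taxa,
                             ref1_taxon, ref2_taxon) {
  stopifnot(inherits(tree, "phylo"), all(tree$tip.label %in% names(taxa_of)))
  tips <- tree$tip.label
  bamboo_tips <- sort(tips[taxa_of[tips] %in% bamboo_taxa])
  if (!length(bamboo_tips)) stop("tree has no bamboo copies", call. = FALSE)
  ntip <- length(tips)
  sets <- .node_desc_sets(tree)
  node <- NULL
  for (nd in seq_along(sets)) {
    if (identical(sets[[nd]], bamboo_tips)) { node <- nd; break }
  }
  if (is.null(node)) return("none")
  parent_of <- function(nd) {
    e <- tree$edge[tree$edge[, 2] == nd, 1]
    if (length(e)) e else NA_integer_
  }
  sister_taxa <- function(nd) {
    p <- parent_of(nd)
    if (is.na(p)) return(NULL)
    sibs <- tree$edge[tree$edge[, 1] == p & tree$edge[, 2] != nd, 2]
    unique(taxa_of[unlist(sets[sibs])])
  }
  sis <- sister_taxa(node)
  if (is.null(sis)) return("none") # bamboo clade is the whole tree
  p <- parent_of(node)
  psis <- sister_taxa(p)
  only <- function(x, what) length(x) > 0 && all(x %in% what)
  if (only(sis, ref2_taxon) && !is.null(psis) && only(psis, ref1_taxon)) {
    return("2")
  }
  if (only(sis, ref1_taxon) && !is.null(psis) && only(psis, ref2_taxon)) {
    return("3")
  }
  if (only(sis, c(ref1_taxon, ref2_taxon)) &&
      all(c(ref1_taxon, ref2_taxon) %in% sis)) {
    return("1")
  }
  "none"
}
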