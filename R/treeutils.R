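# Internal tree helpers: descendant leaf sets, canonical bipartitions.

# list of descendant tip-label sets for every node (tips + internals)
.node_desc_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")$edge
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; ch <- po[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

.split_key <- function(labels) paste(sort(labels), collapse = "|")

# canonical non-trivial bipartitions of a tree (rooted or unrooted), as
# sorted label strings of the side NOT containing the alphabetically first
# tip; names are the internal node numbers that induced them
.tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  n <- length(tips)
  ntip <- length(tree$tip.label)
  sets <- .node_desc_sets(tree)
  out <- character(0)
  nodes <- integer(0)
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    s <- sets[[nd]]
    if (length(s) < 2L || length(s) > n - 2L) next
    side <- if (anchor %in% s) setdiff(tips, s) else s
    key <- .split_key(side)
    if (!(key %in% out)) {
      out <- c(out, key)
      nodes <- c(nodes, nd)
    }
  }
  names(out) <- nodes
  out
}
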