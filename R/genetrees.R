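# Distance-based tree estimation: K2P distances, classical neighbor joining,
# nonparametric bootstrap support, and majority-rule consensus.

#' Kimura two-parameter distance matrix
#'
#' Per pair of rows, transition (`P`) and transversion (`Q`) proportions are
#' computed over the columns where both rows carry an ungapped A/C/G/T
#' (pairwise deletion), and `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`.
#' Saturated pairs (log argument <= 0) are capped at `d = 10` with a warning.
#'
#' @param aln An `"ophy_alignment"` or named character vector of equal-length
#'   gapped sequences.
#' @return An object of class `"k2p_dist"`: list with the symmetric distance
#'   matrix `d` and the per-pair proportions `P` and `Q`.
#' @export
k2p_distance_matrix <- function(aln) {
  rows <- if (inherits(aln, "ophy_alignment")) aln$rows else aln
  stopifnot(!is.null(names(rows)), length(unique(nchar(rows))) == 1L)
  m <- do.call(rbind, strsplit(toupper(unname(rows)), "", fixed = TRUE))
  rownames(m) <- names(rows)
  good <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  n <- nrow(m)
  d <- P <- Q <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  purine <- matrix(m %in% c("A", "G"), nrow = n)
  capped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mask <- good[i, ] & good[j, ]
      L <- sum(mask)
      if (L < 1L) {
        stop(sprintf("rows %s and %s share no ungapped A/C/G/T columns",
                     names(rows)[i], names(rows)[j]), call. = FALSE)
      }
      diffc <- mask & (m[i, ] != m[j, ])
      ts <- sum(diffc & (purine[i, ] == purine[j, ]))
      tv <- sum(diffc) - ts
      p <- ts / L; q <- tv / L
      a1 <- 1 - 2 * p - q; a2 <- 1 - 2 * q
      dij <- if (a1 <= 0 || a2 <= 0) {
        capped <- TRUE
        10
      } else -0.5 * log(a1 * sqrt(a2))
      d[i, j] <- d[j, i] <- dij
      P[i, j] <- P[j, i] <- p
      Q[i, j] <- Q[j, i] <- q
    }
  }
  if (capped) warning("saturated distance(s) capped at 10.0")
  structure(list(taxa = names(rows), d = d, P = P, Q = Q),
            class = "k2p_dist")
}

#' Classical neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion and branch-length
#' formulas. Negative branch-length estimates are clamped to 0; ties in Q are
#' broken by the lexicographically smallest pair of subtree representative
#' labels, so the result is independent of input row order.
#'
#' @param d A `"k2p_dist"`, `dist`, or symmetric matrix with dimnames
#'   (>= 3 taxa).
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "k2p_dist")) d <- d$d
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs dimnames", call. = FALSE)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  frag <- rownames(d) # newick fragment per active node
  rep_lab <- rownames(d) # representative label for deterministic tie-breaks
  while (nrow(d) > 3L) {
    n <- nrow(d)
    r <- rowSums(d)
    Qm <- (n - 2) * d - outer(r, r, "+")
    diag(Qm) <- Inf
    mn <- min(Qm)
    cand <- which(Qm == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1L) {
      key <- apply(cand, 1L, function(ij) {
        paste(sort(c(rep_lab[ij[1]], rep_lab[ij[2]])), collapse = "\r")
      })
      cand <- cand[order(key), , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    vi <- max(0, vi); vj <- max(0, vj)
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], vi, frag[j], vj)
    newlab <- min(rep_lab[i], rep_lab[j])
    keep <- setdiff(seq_len(n), c(i, j))
    dnew <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew), c(dnew, 0))
    nm <- c(rep_lab[keep], newlab)
    rownames(d) <- colnames(d) <- nm
    frag <- c(frag[keep], newfrag)
    rep_lab <- nm
  }
  v1 <- max(0, (d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- max(0, (d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- max(0, (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], v1, frag[2], v2, frag[3], v3)
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `B` times, re-estimates the
#' NJ tree from K2P distances on each pseudo-alignment, and annotates each
#' internal edge of the point-estimate tree with the fraction of
#' pseudoreplicates containing the same bipartition. A fixed seed gives
#' identical supports.
#'
#' @param aln An `"ophy_alignment"` or named character vector.
#' @param B Number of bootstrap pseudoreplicates (>= 1).
#' @param seed Integer seed.
#' @param dist_fun Distance function applied to each pseudo-alignment
#'   (default [k2p_distance_matrix()]; use [p_distance_matrix()] for
#'   proteins).
#' @return An object of class `"tree_with_support"`: list with `tree` (the
#'   point-estimate `phylo`, supports as node labels), `support` (named
#'   fractions by bipartition), and `B`.
#' @export
bootstrap_support <- function(aln, B = 1000L, seed = 1L,
                              dist_fun = k2p_distance_matrix) {
  stopifnot(B >= 1)
  rows <- if (inherits(aln, "ophy_alignment")) aln$rows else aln
  m <- do.call(rbind, strsplit(toupper(unname(rows)), "", fixed = TRUE))
  rownames(m) <- names(rows)
  point <- neighbor_joining(dist_fun(rows))
  splits <- .tree_splits(point)
  counts <- setNames(numeric(length(splits)), splits)
  set.seed(seed)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    res <- setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                    rownames(m))
    bt <- neighbor_joining(dist_fun(res))
    bs <- .tree_splits(bt)
    present <- splits %in% bs
    counts[present] <- counts[present] + 1
  }
  support <- counts / B
  ntip <- length(point$tip.label)
  labs <- rep(NA_character_, point$Nnode)
  node_of <- as.integer(names(splits))
  labs[node_of - ntip] <- sprintf("%.4g", support)
  point$node.label <- labs
  structure(list(tree = point, support = support, B = as.integer(B)),
            class = "tree_with_support")
}

#' @export
print.tree_with_support <- function(x, ...) {
  cat(sprintf("NJ tree with %d leaves; %d internal edges; B = %d\n",
              length(x$tree$tip.label), length(x$support), x$B))
  invisible(x)
}

#' Majority-rule consensus tree
#'
#' Returns the (possibly multifurcating) tree containing exactly the
#' bipartitions present in more than `threshold` of the input trees; for
#' `threshold >= 0.5` those are mutually compatible. Each retained
#' bipartition is annotated with its frequency as a node label.
#'
#' @param trees List of `phylo` trees over one shared leaf set.
#' @param threshold Frequency threshold in `[0.5, 1)`.
#' @return A `phylo` tree (no branch lengths), node labels = frequencies.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1L, threshold >= 0.5, threshold < 1)
  tips <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), tips)) {
      stop("all trees must share one leaf set", call. = FALSE)
    }
  }
  counts <- table(unlist(lapply(trees, function(tr) unname(.tree_splits(tr)))))
  freq <- as.numeric(counts) / length(trees)
  keep <- freq > threshold
  clusters <- strsplit(names(counts)[keep], "|", fixed = TRUE)
  cfreq <- freq[keep]
  # clusters exclude the anchor taxon by construction -> laminar family
  ord <- order(lengths(clusters), decreasing = TRUE)
  clusters <- clusters[ord]; cfreq <- cfreq[ord]
  nc <- length(clusters)
  parent <- rep(0L, nc) # 0 = root
  if (nc > 1) {
    for (i in seq_len(nc)) {
      for (j in seq_len(i - 1L)) { # j larger or equal size
        if (all(clusters[[i]] %in% clusters[[j]]) &&
            length(clusters[[j]]) > length(clusters[[i]])) {
          parent[i] <- j # last (smallest) containing cluster wins
        }
      }
    }
  }
  build <- function(node_id, members) {
    kids <- which(parent == node_id)
    if (node_id > 0L) kids <- kids[lengths(clusters[kids]) <
                                     length(clusters[[node_id]])]
    covered <- unlist(clusters[kids])
    parts <- c(
      vapply(kids, function(k) {
        sprintf("%s%s", build(k, clusters[[k]]), sprintf("%.4g", cfreq[k]))
      }, character(1)),
      setdiff(members, covered))
    sprintf("(%s)", paste(sort(parts), collapse = ","))
  }
  nwk <- paste0(build(0L, tips), ";")
  ape::read.tree(text = nwk)
}
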