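# Seeded synthetic-data generator: species trees, concordant/discordant gene
# trees, HKY-evolved coding sequences, transcript sets with paralogue and
# near-duplicate noise, and a labeled MADS-like protein family.

.MADS_CLASSES <- c("A", "B", "C/D", "E", "SOC-like", "SVP-like")

#' Six- or seven-taxon species tree under the nuclear hypothesis
#'
#' Builds the rooted topology in which the woody bamboos (tropical +
#' temperate tribes) are monophyletic and the herbaceous lineage is their
#' sister, with the two reference taxa as successive outgroups:
#' `(out1,(out2,(herb,((trop1,trop2),(temp1,temp2)))))`. All branch lengths
#' are 1.
#'
#' @param taxa Character vector of 6 or 7 labels in the order
#'   (outgroup1, outgroup2, herbaceous, tropical1, tropical2,
#'   temperate1\[, temperate2\]).
#' @return A rooted `phylo` tree with unit branch lengths.
#' @export
make_species_tree <- function(taxa) {
  if (!is.character(taxa) || !(length(taxa) %in% c(6L, 7L))) {
    stop("`taxa` must name 6 or 7 taxa", call. = FALSE)
  }
  temperate <- if (length(taxa) == 7L) {
    sprintf("(%s,%s)", taxa[6], taxa[7])
  } else taxa[6]
  nwk <- sprintf("(%s,(%s,(%s,((%s,%s),%s))));",
                 taxa[1], taxa[2], taxa[3], taxa[4], taxa[5], temperate)
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Species topology under the plastid hypothesis
#'
#' The competing rearrangement in which the herbaceous lineage is sister to
#' the tropical woody clade, making the woody bamboos paraphyletic:
#' `(out1,(out2,((herb,(trop1,trop2)),temperate)))`.
#'
#' @inheritParams make_species_tree
#' @return A rooted `phylo` tree with unit branch lengths.
#' @export
make_plastid_tree <- function(taxa) {
  if (!is.character(taxa) || !(length(taxa) %in% c(6L, 7L))) {
    stop("`taxa` must name 6 or 7 taxa", call. = FALSE)
  }
  temperate <- if (length(taxa) == 7L) {
    sprintf("(%s,%s)", taxa[6], taxa[7])
  } else taxa[6]
  nwk <- sprintf("(%s,(%s,((%s,(%s,%s)),%s)));",
                 taxa[1], taxa[2], taxa[3], taxa[4], taxa[5], temperate)
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the study conditions the rest of the package is tested
#' under: six taxa (two outgroup references, one herbaceous and three woody
#' bamboos), 500 genes, gene-tree concordance 0.62 with the plastid
#' rearrangement as the single discordant alternative, HKY substitution with
#' kappa = 2 and mildly AT-rich frequencies, 0.03 expected substitutions per
#' site per unit branch, and light paralogue/near-duplicate noise.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param taxa Ordered taxon labels (see [make_species_tree()]).
#' @param species_topology Newick string of the species tree; default the
#'   nuclear-hypothesis topology for `taxa`.
#' @param n_genes Number of genes to simulate.
#' @param concordance Probability a gene tree matches the species topology.
#' @param alt_topologies List of `list(newick=, prob=)` for discordant draws;
#'   probabilities plus `concordance` must sum to 1. Default: the plastid
#'   rearrangement with all remaining probability.
#' @param gene_length_range Integer (min, max) gene length in bp, min >= 3.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param base_freqs Stationary base frequencies (A, C, G, T), summing to 1.
#' @param branch_scale Expected substitutions/site per unit branch length.
#' @param paralogue_rate Expected extra (diverged, truncated) copies per gene
#'   per taxon.
#' @param variant_rate Probability a copy is emitted twice with < 5% mutual
#'   divergence (conspecific near-duplicate).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       taxa = c("Osativa", "Bdistachyon", "Lpauciflora",
                                "Ginermis", "Oacuminata", "Paurea"),
                       species_topology = NULL,
                       n_genes = 500L,
                       concordance = 0.62,
                       alt_topologies = NULL,
                       gene_length_range = c(300L, 900L),
                       kappa = 2,
                       base_freqs = c(0.3, 0.2, 0.2, 0.3),
                       branch_scale = 0.03,
                       paralogue_rate = 0.05,
                       variant_rate = 0.05) {
  if (is.null(species_topology)) {
    species_topology <- ape::write.tree(make_species_tree(taxa))
  }
  if (is.null(alt_topologies)) {
    alt_topologies <- list(list(newick = ape::write.tree(make_plastid_tree(taxa)),
                                prob = 1 - concordance))
  }
  probs <- vapply(alt_topologies, `[[`, numeric(1), "prob")
  if (abs(concordance + sum(probs) - 1) > 1e-12) {
    stop("concordance plus alternative-topology probabilities must sum to 1",
         call. = FALSE)
  }
  if (abs(sum(base_freqs) - 1) > 1e-12 || length(base_freqs) != 4L ||
      any(base_freqs <= 0)) {
    stop("base_freqs must be 4 positive probabilities summing to 1",
         call. = FALSE)
  }
  stopifnot(kappa > 0, concordance >= 0, concordance <= 1,
            length(gene_length_range) == 2L, gene_length_range[1] >= 3,
            gene_length_range[2] >= gene_length_range[1],
            n_genes >= 1, branch_scale >= 0,
            paralogue_rate >= 0, variant_rate >= 0, variant_rate <= 1)
  structure(list(seed = as.integer(seed), taxa = taxa,
                 species_topology = species_topology,
                 n_genes = as.integer(n_genes), concordance = concordance,
                 alt_topologies = alt_topologies,
                 gene_length_range = as.integer(gene_length_range),
                 kappa = kappa, base_freqs = base_freqs,
                 branch_scale = branch_scale,
                 paralogue_rate = paralogue_rate,
                 variant_rate = variant_rate),
            class = "sim_config")
}

# --- HKY substitution process ------------------------------------------------

# Eigen-decomposition of the HKY rate matrix, normalised to one expected
# substitution per site per unit time. Returned closure maps t to P(t).
.hky_pfun <- function(kappa, freqs) {
  pur <- matrix(1, 4, 4)
  pur[1, 3] <- pur[3, 1] <- kappa # A<->G
  pur[2, 4] <- pur[4, 2] <- kappa # C<->T
  Q <- pur * rep(freqs, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  left <- diag(1 / d) %*% e$vectors
  right <- t(e$vectors) %*% diag(d)
  function(t) {
    P <- left %*% diag(exp(e$values * t)) %*% right
    P[P < 0] <- 0
    P / rowSums(P)
  }
}

# Apply P once to an integer state vector (states 1..4), vectorised by state.
.mutate_states <- function(x, P) {
  out <- x
  for (a in 1:4) {
    idx <- which(x == a)
    if (length(idx)) {
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[a, ])
    }
  }
  out
}

.states_to_seq <- function(x) paste(c("A", "C", "G", "T")[x], collapse = "")

# Core sequence evolution along a rooted tree; assumes the RNG state is
# already set by the caller.
.evolve_impl <- function(tree, length, pfun, freqs, scale) {
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  seqs[[root]] <- sample.int(4L, length, replace = TRUE, prob = freqs)
  # preorder traversal: ape edge matrices from read.tree are parent-first,
  # but reorder defensively
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lens <- ape::reorder.phylo(tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1]; ch <- edges[i, 2]
    t <- scale * lens[i]
    seqs[[ch]] <- if (t == 0) seqs[[p]] else .mutate_states(seqs[[p]], pfun(t))
  }
  out <- vapply(seqs[seq_len(ntip)], .states_to_seq, character(1))
  names(out) <- tree$tip.label
  out
}

#' Evolve sequences along a rooted tree under an HKY process
#'
#' Draws the root sequence from the stationary frequencies and applies the
#' HKY transition kernel independently per site along each branch, with
#' `scale * branch length` expected substitutions per site. Indels are not
#' simulated. Identical seeds give identical output.
#'
#' @param tree Rooted `phylo` tree with nonnegative branch lengths.
#' @param length Sequence length in bp (>= 3).
#' @param kappa Transition/transversion ratio.
#' @param base_freqs Stationary base frequencies (A, C, G, T).
#' @param scale Expected substitutions/site multiplier.
#' @param seed Integer seed.
#' @return Named character vector, one sequence per leaf.
#' @export
evolve_sequences <- function(tree, length, kappa = 2,
                             base_freqs = c(0.25, 0.25, 0.25, 0.25),
                             scale = 1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), length >= 3)
  set.seed(seed)
  pfun <- .hky_pfun(kappa, base_freqs)
  .evolve_impl(tree, as.integer(length), pfun, base_freqs, scale)
}

# Gene-tree sampling; assumes RNG state set by caller.
.sample_gene_trees_impl <- function(config) {
  topos <- c(config$species_topology,
             vapply(config$alt_topologies, `[[`, character(1), "newick"))
  topo_names <- c("species", paste0("alt", seq_along(config$alt_topologies)))
  probs <- c(config$concordance,
             vapply(config$alt_topologies, `[[`, numeric(1), "prob"))
  base_trees <- lapply(topos, function(t) ape::read.tree(text = t))
  trees <- vector("list", config$n_genes)
  which_topo <- integer(config$n_genes)
  for (g in seq_len(config$n_genes)) {
    k <- sample.int(length(topos), 1L, prob = probs)
    tr <- base_trees[[k]]
    ne <- nrow(tr$edge)
    base <- if (is.null(tr$edge.length)) rep(1, ne) else tr$edge.length
    # lognormal multiplicative jitter with mean 1, sigma = 0.3
    tr$edge.length <- base * stats::rlnorm(ne, meanlog = -0.3^2 / 2, sdlog = 0.3)
    trees[[g]] <- tr
    which_topo[g] <- k
  }
  list(trees = trees,
       truth = data.frame(gene_id = sprintf("g%04d", seq_len(config$n_genes)),
                          topology = topo_names[which_topo],
                          concordant = which_topo == 1L,
                          stringsAsFactors = FALSE))
}

#' Sample gene trees with a controlled concordance proportion
#'
#' Each gene tree independently equals the species topology with probability
#' `config$concordance`, otherwise one of the alternative topologies by its
#' weight. Branch lengths receive a positive multiplicative lognormal jitter
#' (mean 1, sigma 0.3). The seed fully determines the output.
#'
#' @param config A [sim_config()].
#' @return List with `trees` (list of `phylo`) and `truth` (data frame with
#'   `gene_id`, `topology`, `concordant`).
#' @export
sample_gene_trees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .sample_gene_trees_impl(config)
}

#' Generate per-taxon transcript sets with paralogue and variant noise
#'
#' Simulates `n_genes` gene trees ([sample_gene_trees()]), evolves one coding
#' sequence per taxon along each ([evolve_sequences()]), and emits transcript
#' sets. The first two taxa are treated as the two clean reference (anchor)
#' gene sets; the remaining (bamboo) taxa additionally receive, per gene,
#' a Poisson(`paralogue_rate`) number of further-diverged truncated paralogue
#' copies (0.35 extra substitutions/site, truncated to a uniform 50-100%
#' window) and with probability `variant_rate` a conspecific near-duplicate
#' (2% divergence, > 95% identity to its source) mimicking redundant
#' assembly variants.
#'
#' @param config A [sim_config()].
#' @return An object of class `"transcript_sim"`: list with `transcripts`
#'   (per-bamboo-taxon named sequence vectors), `ref1`, `ref2` (anchor gene
#'   sets), `truth` (gene trees as newick plus a `copy_labels` table), and
#'   the `config`.
#' @export
make_transcript_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gt <- .sample_gene_trees_impl(config)
  pfun <- .hky_pfun(config$kappa, config$base_freqs)
  ref_taxa <- config$taxa[1:2]
  bamboo <- config$taxa[-(1:2)]
  ref1 <- character(0); ref2 <- character(0)
  transcripts <- setNames(vector("list", length(bamboo)), bamboo)
  for (tx in bamboo) transcripts[[tx]] <- character(0)
  labels <- list()
  add_label <- function(id, taxon, gene, label) {
    labels[[length(labels) + 1L]] <<- data.frame(
      copy_id = id, taxon = taxon, gene_id = gene, label = label,
      stringsAsFactors = FALSE)
  }
  lr <- config$gene_length_range
  for (g in seq_len(config$n_genes)) {
    gene <- sprintf("g%04d", g)
    len <- if (lr[1] == lr[2]) lr[1] else sample(lr[1]:lr[2], 1L)
    leaf <- .evolve_impl(gt$trees[[g]], len, pfun, config$base_freqs,
                         config$branch_scale)
    id1 <- sprintf("%s_%s", ref_taxa[1], gene)
    id2 <- sprintf("%s_%s", ref_taxa[2], gene)
    ref1[[id1]] <- leaf[[ref_taxa[1]]]
    ref2[[id2]] <- leaf[[ref_taxa[2]]]
    add_label(id1, ref_taxa[1], gene, "ortholog")
    add_label(id2, ref_taxa[2], gene, "ortholog")
    for (tx in bamboo) {
      id <- sprintf("%s_%s", tx, gene)
      base_seq <- leaf[[tx]]
      transcripts[[tx]][[id]] <- base_seq
      add_label(id, tx, gene, "ortholog")
      npar <- stats::rpois(1L, config$paralogue_rate)
      if (npar > 0) {
        st <- match(.chars(base_seq), c("A", "C", "G", "T"))
        for (p in seq_len(npar)) {
          par_states <- .mutate_states(st, pfun(0.35))
          keep <- max(3L, round(len * runif(1, 0.5, 1)))
          off <- sample.int(len - keep + 1L, 1L)
          pid <- sprintf("%s_p%d", id, p)
          transcripts[[tx]][[pid]] <-
            .states_to_seq(par_states[off:(off + keep - 1L)])
          add_label(pid, tx, gene, "paralogue")
        }
      }
      if (runif(1) < config$variant_rate) {
        st <- match(.chars(base_seq), c("A", "C", "G", "T"))
        vid <- sprintf("%s_v1", id)
        transcripts[[tx]][[vid]] <- .states_to_seq(.mutate_states(st, pfun(0.02)))
        add_label(vid, tx, gene, "variant")
      }
    }
  }
  structure(list(
    transcripts = transcripts, ref1 = unlist(ref1), ref2 = unlist(ref2),
    truth = list(gene_trees = vapply(gt$trees, ape::write.tree, character(1)),
                 gene_truth = gt$truth,
                 copy_labels = do.call(rbind, labels)),
    config = config), class = "transcript_sim")
}

#' Write a transcript simulation to disk
#'
#' Emits one multi-FASTA per taxon, the two anchor gene sets, the true gene
#' trees (newick), the truth table (TSV) and the configuration as a
#' `key: value` text file.
#'
#' @param sim A `"transcript_sim"` from [make_transcript_sets()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_transcript_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "transcript_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tx in names(sim$transcripts)) {
    write_fasta(sim$transcripts[[tx]], file.path(dir, paste0(tx, ".fasta")))
  }
  write_fasta(sim$ref1, file.path(dir, "ref1.fasta"))
  write_fasta(sim$ref2, file.path(dir, "ref2.fasta"))
  writeLines(sim$truth$gene_trees, file.path(dir, "gene_trees.nwk"))
  write.table(sim$truth$copy_labels, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  keys <- c(seed = cfg$seed, taxa = paste(cfg$taxa, collapse = ","),
            species_topology = cfg$species_topology,
            n_genes = cfg$n_genes, concordance = cfg$concordance,
            gene_length_range = paste(cfg$gene_length_range, collapse = ","),
            kappa = cfg$kappa,
            base_freqs = paste(cfg$base_freqs, collapse = ","),
            branch_scale = cfg$branch_scale,
            paralogue_rate = cfg$paralogue_rate,
            variant_rate = cfg$variant_rate)
  writeLines(sprintf("%s: %s", names(keys), keys), file.path(dir, "config.txt"))
  invisible(dir)
}

# --- MADS-like protein family ------------------------------------------------

.random_protein <- function(len) {
  paste(sample(.AA_STATES, len, replace = TRUE), collapse = "")
}

.mutate_protein <- function(s, p) {
  ch <- .chars(s)
  hit <- which(runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(.AA_STATES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate a labeled MADS-like protein family with anchors and decoys
#'
#' Simulates one ancestral protein per gene class, diversifies it into the
#' requested number of copies per taxon, and emits labeled reference anchor
#' copies per class (for the two reference taxa) plus unrelated decoy
#' proteins. Class ancestors are mutually unrelated; within-class copies
#' diverge ~10% from their ancestor and anchors ~8%, so copies share high
#' identity with their own class only. All family members are at least
#' 101 aa long; decoys are random proteins with no homology to any class,
#' so they fall below any sensible score cutoff.
#'
#' @param classes Gene classes to simulate; subset of
#'   A, B, C/D, E, SOC-like, SVP-like.
#' @param copies_per_taxon Integer matrix of requested copy numbers with
#'   classes as rows and taxa as columns (dimnames required).
#' @param seed Integer seed.
#' @param ref_taxa Labels of the two reference taxa providing anchors.
#' @param n_decoys Number of unrelated decoy proteins.
#' @param copy_divergence,ref_divergence Per-site substitution probability
#'   from the class ancestor for bamboo copies and reference anchors.
#' @return An object of class `"mads_sim"`: list with `copies`, `refs`,
#'   `decoys` (named protein vectors), `ref_families` (named class labels for
#'   the anchors), and `truth` (per-copy table of taxon and class).
#' @export
make_mads_truth_set <- function(classes = .MADS_CLASSES, copies_per_taxon,
                                seed = 1L,
                                ref_taxa = c("Osativa", "Bdistachyon"),
                                n_decoys = 20L,
                                copy_divergence = 0.10,
                                ref_divergence = 0.08) {
  stopifnot(all(classes %in% .MADS_CLASSES), is.matrix(copies_per_taxon),
            !is.null(rownames(copies_per_taxon)),
            !is.null(colnames(copies_per_taxon)),
            all(rownames(copies_per_taxon) %in% classes))
  set.seed(seed)
  taxa <- colnames(copies_per_taxon)
  copies <- character(0); refs <- character(0); ref_families <- character(0)
  truth <- list()
  class_tag <- function(cl) gsub("[^A-Za-z]", "", cl)
  for (cl in classes) {
    anc <- .random_protein(sample(150:300, 1L))
    for (rt in ref_taxa) {
      rid <- sprintf("%s_%s_ref", rt, class_tag(cl))
      refs[[rid]] <- .mutate_protein(anc, ref_divergence)
      ref_families[[rid]] <- cl
      truth[[length(truth) + 1L]] <- data.frame(
        copy_id = rid, taxon = rt, label = cl, stringsAsFactors = FALSE)
    }
    if (cl %in% rownames(copies_per_taxon)) {
      for (tx in taxa) {
        ncp <- copies_per_taxon[cl, tx]
        for (i in seq_len(ncp)) {
          cid <- sprintf("%s_%s_c%d", tx, class_tag(cl), i)
          copies[[cid]] <- .mutate_protein(anc, copy_divergence)
          truth[[length(truth) + 1L]] <- data.frame(
            copy_id = cid, taxon = tx, label = cl, stringsAsFactors = FALSE)
        }
      }
    }
  }
  decoys <- character(0)
  for (i in seq_len(n_decoys)) {
    did <- sprintf("decoy_%02d", i)
    decoys[[did]] <- .random_protein(sample(120:300, 1L))
    truth[[length(truth) + 1L]] <- data.frame(
      copy_id = did, taxon = NA_character_, label = "decoy",
      stringsAsFactors = FALSE)
  }
  structure(list(copies = unlist(copies), refs = unlist(refs),
                 decoys = unlist(decoys),
                 ref_families = unlist(ref_families),
                 truth = do.call(rbind, truth),
                 classes = classes, taxa = taxa, ref_taxa = ref_taxa),
            class = "mads_sim")
}

#' Bundled MADS-box copy-count reference table
#'
#' Published per-family, per-taxon copy counts for four flowering bamboo
#' taxa, used to parameterise [make_mads_truth_set()] in examples and tests.
#'
#' @return Integer matrix, families x taxa.
#' @export
mads_reference_counts <- function() {
  path <- system.file("extdata", "mads_copy_counts.tsv",
                      package = "orthophylo", mustWork = TRUE)
  x <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "integer"
  m
}
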