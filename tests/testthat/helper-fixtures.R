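# Shared fixtures and small oracles used across the suite.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_protein <- function(n) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, n, TRUE), collapse = "")
}

# independent oracle for local alignment scores (Biostrings DP engine);
# gap of length L costs gapOpening + L * gapExtension, as in the package
oracle_local_score <- function(q, s, match = 1, mismatch = -2,
                               gap_open = 5, gap_ext = 2) {
  states <- c("A", "C", "G", "T", "N")
  sub <- matrix(mismatch, 5, 5, dimnames = list(states, states))
  diag(sub)[1:4] <- match
  max(0, Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE))
}

# point-mutate a protein string at per-site probability p
.mutate_protein_for_test <- function(s, p) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste(ch, collapse = "")
}

# point-mutate a DNA string at per-site probability p
.mutate_dna_for_test <- function(s, p) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

six_taxa <- c("Osativa", "Bdistachyon", "Lpauciflora",
              "Ginermis", "Oacuminata", "Paurea")
seven_taxa <- c("Osativa", "Bdistachyon", "Lpauciflora",
                "Ginermis", "Oacuminata", "Paurea", "Pheterocycla")

# canonical split strings derived from ape::prop.part, used as the
# enumeration oracle for bipartition extraction
oracle_splits <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- sort(labs)[1]
  out <- unlist(lapply(pp, function(ix) {
    s <- sort(labs[ix])
    if (length(s) < 2 || length(s) > length(labs) - 2) return(NULL)
    if (anchor %in% s) s <- sort(setdiff(labs, s))
    paste(s, collapse = "|")
  }))
  sort(unique(out))
}

pkg_splits <- function(tree) sort(unname(orthophylo:::.tree_splits(tree)))

.split_key_test <- function(labels) paste(sort(labels), collapse = "|")
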