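# Local-alignment homology search with bit-score/E-value statistics and
# threshold-based hit filtering, in nucleotide and protein modes.

#' Scoring scheme for local-alignment search
#'
#' Bundles the substitution scores, affine gap penalties, Karlin-Altschul
#' statistical constants and seeding word size for one search mode. A gap of
#' length L costs `gap_open + L * gap_extend`.
#'
#' Defaults follow common practice for the two modes: nucleotide match +1 /
#' mismatch -2 with gap 5/2 and an 11-bp seed word; protein BLOSUM62 with gap
#' 11/1 and a 3-aa seed word. `lambda` and `K` are scheme constants (per
#' raw-score unit) supplied with the scheme, not estimated from data: the
#' pipeline's decisions depend only on threshold crossings, which the
#' constants merely scale.
#'
#' @param mode `"nucleotide"` or `"protein"`.
#' @param match,mismatch Integer match reward and mismatch penalty
#'   (nucleotide mode; mismatch is negative).
#' @param substitution_table 20x20 integer score matrix with amino-acid
#'   dimnames (protein mode). Default: BLOSUM62.
#' @param gap_open,gap_extend Nonnegative gap penalties.
#' @param lambda,K Karlin-Altschul constants.
#' @param word_size Exact-word seed length for [seeded_search()].
#' @return An object of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(mode = c("nucleotide", "protein"),
                           match = 1L, mismatch = -2L,
                           substitution_table = NULL,
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL,
                           word_size = NULL) {
  mode <- match.arg(mode)
  if (mode == "nucleotide") {
    stopifnot(match > 0, mismatch < 0)
    if (is.null(gap_open)) gap_open <- 5
    if (is.null(gap_extend)) gap_extend <- 2
    if (is.null(lambda)) lambda <- 1.28
    if (is.null(K)) K <- 0.46
    if (is.null(word_size)) word_size <- 11L
    states <- .NUC_STATES
    # N mismatches everything, including itself
    sub <- matrix(as.numeric(mismatch), 5, 5, dimnames = list(states, states))
    diag(sub)[1:4] <- match
    sub["N", "N"] <- mismatch
  } else {
    if (is.null(substitution_table)) substitution_table <- blosum62()
    stopifnot(is.matrix(substitution_table),
              all(.AA_STATES %in% rownames(substitution_table)))
    if (is.null(gap_open)) gap_open <- 11
    if (is.null(gap_extend)) gap_extend <- 1
    if (is.null(lambda)) lambda <- 0.267
    if (is.null(K)) K <- 0.041
    if (is.null(word_size)) word_size <- 3L
    states <- .AA_STATES
    sub <- substitution_table[states, states]
  }
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0)
  structure(list(mode = mode, match = match, mismatch = mismatch,
                 sub = sub, states = states,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, word_size = as.integer(word_size)),
            class = "scoring_scheme")
}

#' BLOSUM62 substitution scores for the 20 standard amino acids
#'
#' The canonical matrix as distributed with Biostrings, restricted to the
#' 20 standard residues.
#'
#' @return 20x20 integer matrix with amino-acid dimnames.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62[.AA_STATES, .AA_STATES]
}

#' Hit filter policy
#'
#' The three-way hit filter: maximum E-value, minimum alignment length and
#' minimum identity. All comparisons are inclusive at the stated values.
#' The default alignment-length floor of 100 applies to nucleotide searches
#' (bp); protein searches conventionally use a lower floor, supplied by the
#' caller.
#'
#' @param max_evalue Maximum E-value (default `1e-5`).
#' @param min_aln_length Minimum alignment columns (default 100).
#' @param min_identity Minimum identity fraction (default 0.70).
#' @return An object of class `"filter_policy"`.
#' @export
filter_policy <- function(max_evalue = 1e-5, min_aln_length = 100,
                          min_identity = 0.70) {
  stopifnot(is.finite(max_evalue), max_evalue > 0,
            is.finite(min_aln_length), min_aln_length > 0,
            is.finite(min_identity), min_identity > 0)
  structure(list(max_evalue = max_evalue,
                 min_aln_length = min_aln_length,
                 min_identity = min_identity),
            class = "filter_policy")
}

#' Bit score and E-value from a raw alignment score
#'
#' Karlin-Altschul statistics: `S' = (lambda * S - ln K) / ln 2` and
#' `E = m * n * 2^-S'`, with search space `m * n` (query length times total
#' subject/database length) and no edge-effect correction.
#'
#' @param S Raw alignment score(s).
#' @param scheme A [scoring_scheme()].
#' @param m Query length (>= 1).
#' @param n Total subject length (>= 1).
#' @return List with numeric vectors `bit_score` and `evalue`.
#' @export
bit_score_evalue <- function(S, scheme, m, n) {
  if (!(m >= 1) || !(n >= 1)) {
    stop("search-space lengths m and n must be positive", call. = FALSE)
  }
  bits <- (scheme$lambda * S - log(scheme$K)) / log(2)
  list(bit_score = bits, evalue = m * n * 2^(-bits))
}

#' Percent identity of an aligned pair
#'
#' Identical-residue columns divided by total alignment columns. Columns with
#' a gap in either row count in the denominator and never in the numerator,
#' the convention of tabular search output. Symmetric in its arguments.
#'
#' @param a,b Equal-length gapped rows (strings, gap character `"-"`).
#' @return Identity fraction in `[0, 1]`.
#' @export
percent_identity <- function(a, b) {
  ca <- .chars(a); cb <- .chars(b)
  if (length(ca) != length(cb)) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  sum(ca == cb & ca != "-" & cb != "-") / length(ca)
}

# Build a hit record from a traceback result. Coordinates are 0-based
# half-open on the forward strands.
.hit_from_aln <- function(aln, q, s, scheme, query_id, subject_id,
                          m, n, strand = "+", s_len = nchar(s)) {
  qp <- aln$q_path; sp <- aln$s_path
  cols <- length(qp)
  qs <- .chars(q); ss <- .chars(s)
  both <- qp >= 0L & sp >= 0L
  qres <- ifelse(qp >= 0L, qs[pmax(qp, 0L) + 1L], "-")
  sres <- ifelse(sp >= 0L, ss[pmax(sp, 0L) + 1L], "-")
  ident <- sum(both & qres == sres)
  mism <- sum(both & qres != sres)
  gap_opens <- sum(diff(c(0L, as.integer(qp < 0L))) == 1L) +
    sum(diff(c(0L, as.integer(sp < 0L))) == 1L)
  st <- bit_score_evalue(aln$score, scheme, m, n)
  s_start <- aln$s_start; s_end <- aln$s_end
  if (strand == "-") {
    tmp <- s_len - s_end
    s_end <- s_len - s_start
    s_start <- tmp
  }
  list(query_id = query_id, subject_id = subject_id,
       score = aln$score, bit_score = st$bit_score, evalue = st$evalue,
       identity = if (cols) ident / cols else 0,
       aln_length = cols, mismatches = mism, gap_opens = gap_opens,
       q_start = aln$q_start, q_end = aln$q_end,
       s_start = s_start, s_end = s_end,
       subject_strand = strand,
       q_aln = paste(qres, collapse = ""),
       s_aln = paste(sres, collapse = ""))
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman with affine gaps: returns the maximal-scoring local
#' alignment with a traceback-consistent score, coordinates (0-based
#' half-open), identity and gap statistics. E-value statistics use the
#' pairwise search space `nchar(q) * nchar(s)`.
#'
#' @param q,s Nonempty sequences in the scheme's alphabet.
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Optional identifiers recorded in the hit.
#' @return An object of class `"local_alignment"`: a list with the hit fields
#'   (`score`, `bit_score`, `evalue`, `identity`, `aln_length`, coordinates)
#'   plus the aligned rows `q_aln`/`s_aln`.
#' @export
score_local_alignment <- function(q, s, scheme = scoring_scheme(),
                                  query_id = "query", subject_id = "subject") {
  if (!nzchar(q) || !nzchar(s)) stop("sequences must be nonempty", call. = FALSE)
  qi <- .encode_seq(q, scheme$states, "query")
  si <- .encode_seq(s, scheme$states, "subject")
  aln <- pair_align_cpp(qi, si, scheme$sub, scheme$gap_open, scheme$gap_extend,
                        local = TRUE, score_only = FALSE)
  hit <- .hit_from_aln(aln, toupper(q), toupper(s), scheme,
                       query_id, subject_id, nchar(q), nchar(s))
  structure(hit, class = "local_alignment")
}

#' Global (end-to-end) pairwise alignment
#'
#' Needleman-Wunsch with affine gaps under the same scoring scheme. Used for
#' full-length identity comparisons (e.g. protein distances).
#'
#' @inheritParams score_local_alignment
#' @return List with `score`, `q_aln`, `s_aln` and `identity`.
#' @export
global_align <- function(q, s, scheme = scoring_scheme()) {
  if (!nzchar(q) || !nzchar(s)) stop("sequences must be nonempty", call. = FALSE)
  qi <- .encode_seq(q, scheme$states, "query")
  si <- .encode_seq(s, scheme$states, "subject")
  aln <- pair_align_cpp(qi, si, scheme$sub, scheme$gap_open, scheme$gap_extend,
                        local = FALSE, score_only = FALSE)
  qs <- .chars(toupper(q)); ss <- .chars(toupper(s))
  qres <- ifelse(aln$q_path >= 0L, qs[pmax(aln$q_path, 0L) + 1L], "-")
  sres <- ifelse(aln$s_path >= 0L, ss[pmax(aln$s_path, 0L) + 1L], "-")
  qa <- paste(qres, collapse = ""); sa <- paste(sres, collapse = "")
  list(score = aln$score, q_aln = qa, s_aln = sa,
       identity = percent_identity(qa, sa))
}

.kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

.empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             score = numeric(0), bit_score = numeric(0), evalue = numeric(0),
             identity = numeric(0), aln_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             subject_strand = character(0), stringsAsFactors = FALSE)
}

#' Seeded local-alignment search of queries against a subject database
#'
#' For every query/subject pair sharing at least one exact `word_size`-mer
#' (on either strand in nucleotide mode) the full optimal local alignment is
#' computed, so any alignment containing an exact shared word and scoring at
#' least `score_cutoff` is reported. Multiple high-scoring segments per pair
#' are collapsed to the single best alignment by raw score (downstream
#' orthology logic counts subjects, not segments). E-values use search space
#' `m * n` with `n` the summed subject length.
#'
#' @param queries,subjects Named character vectors of sequences.
#' @param scheme A [scoring_scheme()].
#' @param word_size Seed word length; defaults to the scheme's.
#' @param score_cutoff Minimum raw score to report (default 1, i.e. any
#'   positive-scoring alignment).
#' @param max_evalue Optional E-value ceiling applied while searching; the
#'   result equals post-filtering on E-value, computed early to skip
#'   tracebacks of chance seed matches.
#' @return Hit table (`data.frame`), one row per (query, subject) pair,
#'   ordered by query then decreasing bit score.
#' @export
seeded_search <- function(queries, subjects, scheme = scoring_scheme(),
                          word_size = scheme$word_size, score_cutoff = 1,
                          max_evalue = Inf) {
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  k <- as.integer(word_size)
  min_k <- if (scheme$mode == "nucleotide") 4L else 2L
  stopifnot(k >= min_k)
  queries <- toupper(queries); subjects <- toupper(subjects)
  n_db <- sum(nchar(subjects))
  strands <- if (scheme$mode == "nucleotide") c("+", "-") else "+"

  # per-strand k-word index of the subjects
  index_for <- function(seqs) {
    km <- lapply(seqs, .kmer_set, k = k)
    split(rep(names(seqs), lengths(km)), unlist(km, use.names = FALSE))
  }
  subj_oriented <- list("+" = subjects)
  if ("-" %in% strands) {
    subj_oriented[["-"]] <- vapply(subjects, reverse_complement, character(1))
  }
  idx <- lapply(subj_oriented, index_for)

  rows <- list()
  for (qn in names(queries)) {
    q <- queries[[qn]]
    qk <- .kmer_set(q, k)
    if (!length(qk)) next
    qi <- .encode_seq(q, scheme$states, "query")
    m <- nchar(q)
    best <- list() # per subject id: best hit across strands
    for (strand in strands) {
      pos <- match(qk, names(idx[[strand]]))
      cand <- unique(unlist(idx[[strand]][pos[!is.na(pos)]], use.names = FALSE))
      for (sn in cand) {
        s_or <- subj_oriented[[strand]][[sn]]
        si <- .encode_seq(s_or, scheme$states, "subject")
        sc <- pair_align_cpp(qi, si, scheme$sub, scheme$gap_open,
                             scheme$gap_extend, local = TRUE,
                             score_only = TRUE)
        if (sc$score < score_cutoff) next
        ev <- bit_score_evalue(sc$score, scheme, m, n_db)$evalue
        if (ev > max_evalue) next
        prev <- best[[sn]]
        if (!is.null(prev) && prev$score >= sc$score) next
        aln <- pair_align_cpp(qi, si, scheme$sub, scheme$gap_open,
                              scheme$gap_extend, local = TRUE,
                              score_only = FALSE)
        best[[sn]] <- .hit_from_aln(aln, q, s_or, scheme, qn, sn, m, n_db,
                                    strand = strand,
                                    s_len = nchar(subjects[[sn]]))
      }
    }
    if (length(best)) {
      ord <- order(-vapply(best, `[[`, numeric(1), "bit_score"),
                   names(best))
      rows <- c(rows, best[ord])
    }
  }
  if (!length(rows)) return(.empty_hits())
  out <- do.call(rbind, lapply(rows, function(h) {
    as.data.frame(h[setdiff(names(h), c("q_aln", "s_aln"))],
                  stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Filter a hit table by E-value, alignment length and identity
#'
#' Keeps exactly the hits with `evalue <= max_evalue`,
#' `aln_length >= min_aln_length` and `identity >= min_identity`
#' (inclusive comparisons). Row order is preserved; filtering is idempotent.
#'
#' @param hits Hit table from [seeded_search()].
#' @param policy A [filter_policy()].
#' @return The filtered hit table.
#' @export
filter_hits <- function(hits, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"),
            all(c("evalue", "aln_length", "identity") %in% names(hits)))
  keep <- hits$evalue <= policy$max_evalue &
    hits$aln_length >= policy$min_aln_length &
    hits$identity >= policy$min_identity
  hits[keep, , drop = FALSE]
}

#' Write a hit table in 12-column tabular format
#'
#' Columns: query, subject, identity percent, alignment length, mismatches,
#' gap opens, q. start, q. end, s. start, s. end, E-value, bit score, with
#' 1-based inclusive coordinates; minus-strand hits have subject start >
#' subject end, the usual tabular dialect.
#'
#' @param hits Hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  minus <- hits$subject_strand == "-"
  ss <- ifelse(minus, hits$s_end, hits$s_start + 1L)
  se <- ifelse(minus, hits$s_start + 1L, hits$s_end)
  out <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.3f", hits$identity * 100),
                    hits$aln_length, hits$mismatches, hits$gap_opens,
                    hits$q_start + 1L, hits$q_end, ss, se,
                    format(hits$evalue, digits = 3),
                    sprintf("%.1f", hits$bit_score))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular hit table
#'
#' Inverse of [write_hit_table()]; restores 0-based half-open coordinates and
#' infers the subject strand from coordinate order. Raw scores are not stored
#' in the tabular dialect and are recovered from the bit score when a scheme
#' is supplied.
#'
#' @param path Input path.
#' @param scheme Optional [scoring_scheme()] for raw-score recovery.
#' @return Hit table (`data.frame`).
#' @export
read_hit_table <- function(path, scheme = NULL) {
  x <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  minus <- x$V9 > x$V10
  s_start <- ifelse(minus, x$V10, x$V9) - 1L
  s_end <- ifelse(minus, x$V9, x$V10)
  score <- if (!is.null(scheme)) {
    (x$V12 * log(2) + log(scheme$K)) / scheme$lambda
  } else NA_real_
  data.frame(query_id = x$V1, subject_id = x$V2, score = score,
             bit_score = x$V12, evalue = x$V11,
             identity = x$V3 / 100, aln_length = x$V4,
             mismatches = x$V5, gap_opens = x$V6,
             q_start = x$V7 - 1L, q_end = x$V8,
             s_start = s_start, s_end = s_end,
             subject_strand = ifelse(minus, "-", "+"),
             stringsAsFactors = FALSE)
}
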