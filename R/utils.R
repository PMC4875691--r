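# Shared low-level helpers: alphabets, encoding, FASTA I/O.

.NUC_STATES <- c("A", "C", "G", "T", "N")
.AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.encode_seq <- function(s, states, what = "sequence") {
  idx <- match(.chars(toupper(s)), states)
  if (anyNA(idx)) {
    bad <- unique(.chars(toupper(s))[is.na(idx)])
    stop(sprintf("%s contains characters outside the expected alphabet: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  idx - 1L
}

#' Reverse complement of a nucleotide sequence
#'
#' @param s A nucleotide string over A/C/G/T/N.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
  paste(rev(.chars(comp)), collapse = "")
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around Biostrings returning a plain named character vector,
#' the container the rest of the package works with.
#'
#' @param path Path to a FASTA file.
#' @param type `"nucleotide"` or `"protein"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("nucleotide", "protein")) {
  type <- match.arg(type)
  x <- if (type == "nucleotide") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param type `"nucleotide"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("nucleotide", "protein")) {
  type <- match.arg(type)
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- if (type == "nucleotide") Biostrings::DNAStringSet(seqs)
       else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

# Deterministic sub-seed derivation: keeps every derived seed a valid
# 32-bit integer whatever the user passes.
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1664525 * offset) %% .Machine$integer.max)
}
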