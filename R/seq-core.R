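# Nucleotide-sequence primitives: the IUPAC alphabet, reverse complement,
# canonical k-mers and k-mer extraction. Sequences are plain uppercase
# character vectors over {A,C,G,T,N} plus the IUPAC ambiguity codes.

.IUPAC_ALPHABET <- c("A", "C", "G", "T", "N",
                     "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# base sets of every single-letter code
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# sorted-set key -> code (inverse of .IUPAC_SETS)
.IUPAC_FROM_SET <- local({
  keys <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  setNames(names(keys), keys)
})

.COMP_FROM <- "ACGTRYSWKMBDHVN"
.COMP_TO   <- "TGCAYRSWMKVHDBN"

.check_alphabet <- function(x, what = "sequence") {
  bad <- regexpr(sprintf("[^%s]", paste(.IUPAC_ALPHABET, collapse = "")), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d of %s %d",
                 substr(x[i], bad[i], bad[i]), bad[i], what, i), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of nucleotide sequences
#'
#' IUPAC ambiguity codes map to their complements (R/Y, K/M, B/V, D/H swap;
#' S, W and N are self-complementary). Input is uppercased first, so
#' soft-masked (lowercase) bases are treated like their uppercase form.
#'
#' @param x Character vector of sequences over the IUPAC alphabet.
#' @return Character vector of reverse complements, same length as `x`.
#' @examples
#' revcomp("ACGT")
#' revcomp("RN")
#' @export
revcomp <- function(x) {
  x <- toupper(as.character(x))
  .check_alphabet(x)
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(chartr(.COMP_FROM, .COMP_TO, s))))
  }, "", USE.NAMES = FALSE)
}

#' Canonical form of k-mers
#'
#' The canonical form is the lexicographically smaller of a k-mer and its
#' reverse complement -- a strand-neutral identity used throughout the
#' k-mer graph, so that both strands of double-stranded sequence data index
#' the same graph node.
#'
#' @param x Character vector of ACGT-only k-mers.
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_kmer(c("TTT", "AAA", "ACGT"))
#' @export
canonical_kmer <- function(x) {
  canonical_cpp(toupper(as.character(x)))
}

#' Extract clean k-mers from a sequence
#'
#' Yields every length-`k` window that contains only A, C, G or T, left to
#' right, in forward (non-canonical) orientation. Windows overlapping `N` or
#' any ambiguity code are skipped: ambiguous bases are not solid sequence.
#'
#' @param x A single sequence (character scalar).
#' @param k K-mer length (>= 1).
#' @return Character vector of k-mers; empty when `k > nchar(x)`.
#' @examples
#' extract_kmers("ACGTA", 4)
#' extract_kmers("ACNGT", 2)
#' @export
extract_kmers <- function(x, k) {
  stopifnot(length(x) == 1L, is.numeric(k), k >= 1)
  k <- as.integer(k)
  x <- toupper(as.character(x))
  n <- nchar(x)
  if (k > n) return(character(0))
  w <- substring(x, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  w[grepl("^[ACGT]+$", w)]
}

#' Merge a set of bases into one IUPAC code
#'
#' Maps every non-empty subset of \{A,C,G,T\} to the unique single-letter
#' IUPAC code with exactly that base set; used when alternate assembly paths
#' disagree at a consensus column.
#'
#' @param bases Character vector of bases from \{A,C,G,T\} (duplicates
#'   allowed).
#' @return A single character: the IUPAC code for the set.
#' @examples
#' iupac_merge(c("A", "G"))
#' iupac_merge(c("A", "C", "G", "T"))
#' @export
iupac_merge <- function(bases) {
  bases <- unique(toupper(as.character(bases)))
  if (length(bases) == 0L) stop("empty base set")
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("bases must be from {A,C,G,T}")
  unname(.IUPAC_FROM_SET[paste(sort(bases), collapse = "")])
}

#' Base set of an IUPAC code
#'
#' @param code A single IUPAC letter.
#' @return Character vector of the A/C/G/T bases the code stands for.
#' @examples
#' iupac_bases("R")
#' @export
iupac_bases <- function(code) {
  code <- toupper(as.character(code))
  stopifnot(length(code) == 1L, code %in% .IUPAC_ALPHABET)
  .IUPAC_SETS[[code]]
}
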