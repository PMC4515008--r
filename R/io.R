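# FASTA/FASTQ input and output, via Biostrings. Sequences cross the package
# boundary as named uppercase character vectors; Biostrings containers and
# file paths are accepted everywhere and coerced on entry.

.guess_format <- function(path) {
  p <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
  if (grepl("\\.(fq|fastq)$", p, ignore.case = TRUE)) "fastq" else "fasta"
}

#' Read sequences from a FASTA or FASTQ file
#'
#' Format is chosen from the file extension (`.fq`/`.fastq` vs anything
#' else); gzip-compressed files are handled transparently. Sequences are
#' uppercased on ingestion, discarding soft-masking.
#'
#' @param path Path to a FASTA or FASTQ file, optionally gzipped.
#' @param format `"auto"` (default), `"fasta"` or `"fastq"`.
#' @return Named character vector of uppercase sequences. Names are the
#'   first whitespace-delimited token of each record header.
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: '", path, "'")
  if (format == "auto") format <- .guess_format(path)
  ss <- Biostrings::readDNAStringSet(path, format = format)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss) %||% character(0))
  out
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector (or `DNAStringSet`) of sequences.
#' @param path Output path; a `.gz` extension triggers compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ss <- if (is(x, "XStringSet")) x else Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write reads to a FASTQ file
#'
#' Writes fixed quality characters (the simulator does not model qualities).
#'
#' @param x Named character vector of reads.
#' @param path Output path; a `.gz` extension triggers compression.
#' @param qual Single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path, qual = "I") {
  ss <- Biostrings::DNAStringSet(x)
  q <- Biostrings::BStringSet(strrep(qual, nchar(x)))
  Biostrings::writeXStringSet(ss, path, compress = grepl("\\.gz$", path),
                              format = "fastq", qualities = q)
  invisible(path)
}

# Coerce scaffolds-like input (file path, XStringSet, or character vector)
# to a named uppercase character vector.
as_named_seqs <- function(x, default_prefix = "seq") {
  if (is(x, "XStringSet")) {
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x) %||% character(0))
  } else if (is.character(x) && length(x) == 1L && !grepl("^[ACGTNacgtn]*$", x) &&
             file.exists(x)) {
    out <- read_seqs(x)
  } else {
    out <- toupper(as.character(x))
    if (is.null(names(x))) {
      names(out) <- sprintf("%s_%d", default_prefix, seq_along(out))
    } else {
      names(out) <- names(x)
    }
  }
  if (anyNA(out)) stop("sequences contain NA")
  out
}

# Reads-like input: file path(s), XStringSet, the list returned by
# simulate_reads(), or a plain character vector of sequences.
load_reads <- function(x) {
  if (is.list(x) && !is.null(x$read1) && !is.null(x$read2))
    return(toupper(c(x$read1, x$read2)))
  if (is(x, "XStringSet")) return(toupper(as.character(x)))
  if (is.character(x) && length(x) >= 1L &&
      all(grepl("\\.(fa|fasta|fq|fastq)(\\.gz)?$", x, ignore.case = TRUE))) {
    bad <- x[!file.exists(x) | file.access(x, 4L) != 0L]
    if (length(bad) > 0)
      stop("cannot read input reads file(s): ", paste(bad, collapse = ", "))
    return(unlist(lapply(x, read_seqs), use.names = FALSE))
  }
  toupper(as.character(x))
}
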