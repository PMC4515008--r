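# The multiplicity-thresholded Bloom filter over canonical k-mers, exposed
# as an implicit de Bruijn graph. The filter holds `threshold` stacked bit
# arrays ("cascading" levels): each occurrence of a k-mer advances it by one
# level, and a k-mer is "solid" -- a graph node -- once present in every
# level. Membership errors are one-sided: no false negatives, and a false
# positive rate governed by the per-level fill ratio.

#' Build a k-mer Bloom filter from reads
#'
#' Streams every clean (ACGT-only) k-mer of the reads, in canonical form,
#' into a cascading Bloom filter with `threshold` levels. K-mers observed
#' fewer than `threshold` times are not solid, which removes most
#' sequencing-error k-mers before graph traversal. Duplicate k-mers within
#' one read count as separate occurrences.
#'
#' @param reads Reads as a character vector, `DNAStringSet`, FASTA/FASTQ
#'   file path(s) (optionally gzipped), or the list returned by
#'   [simulate_reads()].
#' @param k K-mer length in bp.
#' @param threshold Multiplicity threshold (number of cascade levels);
#'   default 2.
#' @param size_bits Bit capacity of each level. Too small a filter is not an
#'   error, but a warning is emitted when the estimated top-level false
#'   positive rate exceeds 5 percent.
#' @param num_hashes Hash functions per level (double hashing).
#' @param hash_seed Fixed integer seed for the hash functions; recorded in
#'   the filter so runs are reproducible across sessions and platforms.
#' @return An object of class `kmer_bloom`. The filter lives in native
#'   memory and does not survive an R session; use [bloom_save()] /
#'   [bloom_load()] to persist it.
#' @examples
#' b <- kmer_bloom(c("ACGTA", "ACGTA"), k = 5, threshold = 2,
#'                 size_bits = 2^16)
#' bloom_solid(b, "ACGTA")
#' @export
kmer_bloom <- function(reads, k, threshold = 2, size_bits = 2^26,
                       num_hashes = 4, hash_seed = 1) {
  stopifnot(k >= 1, threshold >= 1, num_hashes >= 1, size_bits >= 8 * num_hashes)
  ptr <- bloom_new_cpp(as.integer(k), as.integer(threshold),
                       as.numeric(size_bits), as.integer(num_hashes),
                       as.numeric(hash_seed))
  b <- structure(
    list(ptr = ptr, k = as.integer(k), threshold = as.integer(threshold),
         size_bits = as.numeric(size_bits), num_hashes = as.integer(num_hashes),
         hash_seed = as.numeric(hash_seed)),
    class = "kmer_bloom")
  if (!is.null(reads)) {
    bloom_insert_reads_cpp(b$ptr, load_reads(reads))
    est <- bloom_fpr(b)
    if (est$per_level[b$threshold] > 0.05)
      warning(sprintf(
        "estimated top-level false positive rate %.1f%% exceeds 5%%; increase size_bits",
        100 * est$per_level[b$threshold]))
  }
  b
}

.check_bloom <- function(b) {
  if (!inherits(b, "kmer_bloom")) stop("not a kmer_bloom object")
  b
}

#' Query k-mer solidity
#'
#' A k-mer is solid when its canonical form is present in every cascade
#' level, i.e. it was observed at least `threshold` times in the reads (up
#' to Bloom false positives; there are no false negatives). Queries are
#' strand-neutral.
#'
#' @param b A [kmer_bloom()] filter.
#' @param kmers Character vector of ACGT-only k-mers of length `b$k`.
#' @return Logical vector.
#' @export
bloom_solid <- function(b, kmers) {
  .check_bloom(b)
  bloom_solid_cpp(b$ptr, toupper(as.character(kmers)))
}

#' Solid graph neighbors of a k-mer
#'
#' The implicit de Bruijn graph: right neighbors are the solid k-mers
#' `x[2:k] + c` and left neighbors `c + x[1:k-1]`, for `c` in A, C, G, T in
#' that fixed order.
#'
#' @param b A [kmer_bloom()] filter.
#' @param kmer A single k-mer.
#' @param direction `"right"` or `"left"`.
#' @return Named character vector of at most 4 neighbor k-mers; names are
#'   the extension bases.
#' @export
bloom_neighbors <- function(b, kmer, direction = c("right", "left")) {
  .check_bloom(b)
  direction <- match.arg(direction)
  bloom_neighbors_cpp(b$ptr, toupper(as.character(kmer)),
                      direction == "right")
}

#' Per-level fill ratio of a Bloom filter
#'
#' @param b A [kmer_bloom()] filter.
#' @return Numeric vector: fraction of set bits in each level.
#' @export
bloom_fill <- function(b) {
  .check_bloom(b)
  bloom_fill_cpp(b$ptr)
}

#' Estimated false positive rates of a Bloom filter
#'
#' Per level, the chance a never-inserted k-mer queries present is
#' `fill_ratio ^ num_hashes`; a spurious solid call needs a hit in every
#' level, so the solid-query estimate is the product over levels.
#'
#' @param b A [kmer_bloom()] filter.
#' @return List with `per_level` (numeric vector) and `solid` (scalar).
#' @export
bloom_fpr <- function(b) {
  f <- bloom_fill(b) ^ .check_bloom(b)$num_hashes
  list(per_level = f, solid = prod(f))
}

#' Filter summary counters
#'
#' @param b A [kmer_bloom()] filter.
#' @return List with the filter parameters, the number of k-mer occurrences
#'   processed and the approximate number of distinct solid k-mers.
#' @export
bloom_info <- function(b) {
  .check_bloom(b)
  bloom_info_cpp(b$ptr)
}

#' Save / load a Bloom filter
#'
#' Flat binary format: an 8-byte magic, a header (k, levels, per-level bits,
#' hash count, hash seed, counters), then the level bit arrays. Round trips
#' are bit-exact.
#'
#' @param b A [kmer_bloom()] filter.
#' @param path File path.
#' @return `bloom_save()` returns `path` invisibly; `bloom_load()` returns a
#'   `kmer_bloom` object.
#' @export
bloom_save <- function(b, path) {
  .check_bloom(b)
  bloom_save_cpp(b$ptr, path.expand(path))
  invisible(path)
}

#' @rdname bloom_save
#' @export
bloom_load <- function(path) {
  ptr <- bloom_load_cpp(path.expand(path))
  info <- bloom_info_cpp(ptr)
  structure(
    list(ptr = ptr, k = as.integer(info$k),
         threshold = as.integer(info$threshold),
         size_bits = as.numeric(info$size_bits),
         num_hashes = as.integer(info$num_hashes),
         hash_seed = as.numeric(info$hash_seed)),
    class = "kmer_bloom")
}

#' @export
print.kmer_bloom <- function(x, ...) {
  info <- bloom_info(x)
  fpr <- bloom_fpr(x)
  cat(sprintf(
    "k-mer Bloom filter (implicit de Bruijn graph)\n  k = %d, multiplicity threshold = %d, %d hash functions, %s bits/level\n",
    info$k, info$threshold, info$num_hashes,
    format(info$size_bits, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  occurrences inserted: %s; ~distinct solid k-mers: %s\n",
              format(info$n_occurrences, big.mark = ","),
              format(info$n_solid, big.mark = ",")))
  cat(sprintf("  fill ratio per level: %s; est. solid-query FPR: %.3g\n",
              paste(sprintf("%.3f", bloom_fill(x)), collapse = ", "),
              fpr$solid))
  invisible(x)
}
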