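# End-to-end pipeline: gap discovery, the subtractive k sweep of connection
# attempts (one Bloom filter in memory at a time), 3'-to-5' scaffold
# rewriting, and the output files. Coordinates are 0-based, half-open
# throughout; file outputs state this in a header comment.

#' Pipeline configuration
#'
#' @param k Ordered vector of k-mer lengths for the sweep. Large k first is
#'   the default: with sufficient coverage, long k-mers disambiguate
#'   repeats, while the later small-k passes rescue low-coverage gaps.
#'   Every k must be at most `min_flank`.
#' @param threshold K-mer multiplicity threshold for the Bloom filter
#'   (default 2).
#' @param min_flank Required N-free flank length `L` in bp on each side of
#'   a gap (default 100); also the amount of flank extracted.
#' @param bloom_size Total Bloom filter memory as bytes or a string with a
#'   K/M/G suffix (e.g. `"500M"`), split equally across the `threshold`
#'   cascade levels.
#' @param num_hashes,hash_seed Bloom filter hashing; see [kmer_bloom()].
#' @param max_paths,max_branches,max_frag,max_flank_scan Connection search
#'   limits; see [search_params()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(k = c(90, 80, 70, 60, 50, 40), threshold = 2,
                       min_flank = 100, bloom_size = "16M", num_hashes = 4,
                       hash_seed = 1, max_paths = 2, max_branches = 3000,
                       max_frag = 5000, max_flank_scan = NULL) {
  k <- as.integer(k)
  if (length(k) == 0L) stop("k list must be non-empty")
  if (any(k < 1L)) stop("k must be positive")
  if (any(k > min_flank))
    stop("every k must be <= min_flank (", min_flank, "); got k = ",
         paste(k[k > min_flank], collapse = ", "))
  structure(list(
    k = k, threshold = as.integer(threshold),
    min_flank = as.integer(min_flank),
    bloom_size = bloom_size, num_hashes = as.integer(num_hashes),
    hash_seed = as.numeric(hash_seed),
    params = search_params(max_paths = max_paths, max_branches = max_branches,
                           max_frag = max_frag,
                           max_flank_scan = max_flank_scan)),
    class = "run_config")
}

.bits_per_level <- function(cfg) {
  max(8 * cfg$num_hashes, floor(parse_size(cfg$bloom_size) * 8 / cfg$threshold))
}

#' Find N-gaps and their flanks in scaffolds
#'
#' A gap is a maximal run of N characters. A gap qualifies for closing only
#' when it has at least `min_flank` clean (ACGT-only) bases on both sides
#' before hitting another N-run, an ambiguity code, or the scaffold end;
#' the flanks recorded are exactly the `min_flank` bases adjacent to the
#' gap. Gaps at scaffold termini are skipped.
#'
#' @param scaffolds FASTA path, `DNAStringSet`, or named character vector.
#' @param min_flank Required flank length in bp.
#' @return `data.frame` with columns `scaffold_id`, `start`, `end` (0-based
#'   half-open coordinates of the N-run), `gap_len`, `left_flank`,
#'   `right_flank`, sorted by (scaffold_id, start).
#' @examples
#' find_gaps(c(sc1 = "ACGTNNNACGT"), min_flank = 4)
#' @export
find_gaps <- function(scaffolds, min_flank = 100) {
  stopifnot(min_flank >= 1)
  scaffolds <- as_named_seqs(scaffolds, default_prefix = "scaffold")
  rows <- lapply(names(scaffolds), function(sid) {
    s <- scaffolds[[sid]]
    n <- nchar(s)
    m <- gregexpr("N+", s)[[1L]]
    if (m[1L] == -1L) return(NULL)
    start0 <- as.integer(m) - 1L
    end0 <- start0 + attr(m, "match.length")
    lf <- substring(s, start0 - min_flank + 1L, start0)
    rf <- substring(s, end0 + 1L, end0 + min_flank)
    ok <- start0 >= min_flank & end0 + min_flank <= n &
      grepl("^[ACGT]+$", lf) & grepl("^[ACGT]+$", rf)
    if (!any(ok)) return(NULL)
    data.frame(scaffold_id = sid, start = start0[ok], end = end0[ok],
               gap_len = end0[ok] - start0[ok], left_flank = lf[ok],
               right_flank = rf[ok], stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(scaffold_id = character(0), start = integer(0),
                       end = integer(0), gap_len = integer(0),
                       left_flank = character(0), right_flank = character(0),
                       stringsAsFactors = FALSE)
  rows <- rows[order(rows$scaffold_id, rows$start), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Run the subtractive k sweep of connection attempts
#'
#' For each k in `cfg$k`, in order: build one Bloom filter from the reads,
#' attempt to connect every still-open gap, record successful closures
#' (status `unique` or `consensus`), remove them from the open set, and
#' release the filter before the next k -- so only one filter is in memory
#' at a time and closed gaps are never re-attempted.
#'
#' @param scaffolds Scaffolds (path, `DNAStringSet`, or named character).
#' @param reads Reads (see [kmer_bloom()]); file paths are re-read for each
#'   k rather than cached.
#' @param cfg A [run_config()].
#' @param gaps Optional precomputed [find_gaps()] table.
#' @param verbose Print a per-k progress line.
#' @return List with `closures` (one row per closed gap: the gap columns
#'   plus `replacement`, `left_trim`, `right_trim`, `flank_len`, `k_used`,
#'   `status`, `num_paths`), `sweep_log` (per-k attempt/closure/status
#'   counts), `gap_log` (per gap and k attempted: status), and `gaps`.
#' @export
run_sweep <- function(scaffolds, reads, cfg = run_config(), gaps = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  scaffolds <- as_named_seqs(scaffolds, default_prefix = "scaffold")
  if (is.null(gaps)) gaps <- find_gaps(scaffolds, cfg$min_flank)
  statuses <- c("unique", "consensus", "no_path", "too_many_paths",
                "branch_limit", "length_limit", "no_anchor")
  open <- seq_len(nrow(gaps))
  closure_rows <- list()
  gap_log <- list()
  sweep_log <- list()
  bits <- .bits_per_level(cfg)
  for (k in cfg$k) {
    b <- kmer_bloom(reads, k = k, threshold = cfg$threshold,
                    size_bits = bits, num_hashes = cfg$num_hashes,
                    hash_seed = cfg$hash_seed)
    counts <- setNames(integer(length(statuses)), statuses)
    closed_now <- integer(0)
    for (gi in open) {
      res <- connect_flanks(gaps$left_flank[gi], gaps$right_flank[gi], b,
                            cfg$params)
      counts[res$status] <- counts[res$status] + 1L
      gap_log[[length(gap_log) + 1L]] <- data.frame(
        gap_id = gi, scaffold_id = gaps$scaffold_id[gi],
        start = gaps$start[gi], end = gaps$end[gi], k = k,
        status = res$status, num_paths = res$num_paths,
        stringsAsFactors = FALSE)
      if (res$status %in% c("unique", "consensus")) {
        closed_now <- c(closed_now, gi)
        closure_rows[[length(closure_rows) + 1L]] <- data.frame(
          gap_id = gi, scaffold_id = gaps$scaffold_id[gi],
          start = gaps$start[gi], end = gaps$end[gi],
          gap_len = gaps$gap_len[gi], flank_len = cfg$min_flank,
          replacement = res$sequence, left_trim = res$left_trim,
          right_trim = res$right_trim, k_used = k, status = res$status,
          num_paths = res$num_paths, stringsAsFactors = FALSE)
      }
    }
    sweep_log[[length(sweep_log) + 1L]] <- data.frame(
      k = k, attempted = length(open), closed = length(closed_now),
      as.list(counts), stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("k=%d: attempted %d, closed %d (open now %d)", k,
                      length(open), length(closed_now),
                      length(open) - length(closed_now)))
    open <- setdiff(open, closed_now)
    rm(b)
  }
  empty_closures <- data.frame(
    gap_id = integer(0), scaffold_id = character(0), start = integer(0),
    end = integer(0), gap_len = integer(0), flank_len = integer(0),
    replacement = character(0), left_trim = integer(0),
    right_trim = integer(0), k_used = integer(0), status = character(0),
    num_paths = integer(0), stringsAsFactors = FALSE)
  list(closures = if (length(closure_rows)) do.call(rbind, closure_rows)
                  else empty_closures,
       sweep_log = do.call(rbind, sweep_log),
       gap_log = do.call(rbind, gap_log) %||% data.frame(
         gap_id = integer(0), scaffold_id = character(0), start = integer(0),
         end = integer(0), k = integer(0), status = character(0),
         num_paths = integer(0), stringsAsFactors = FALSE),
       gaps = gaps)
}

#' Splice closures back into scaffolds
#'
#' Per scaffold, closures are applied from 3' to 5' (descending start), so
#' that length changes introduced by a replacement never shift the
#' coordinates of gaps still to be processed on its left. Each closure
#' replaces the window spanning the gap and both extracted flanks with its
#' replacement product; size discrepancies between the N-run and the new
#' sequence are ignored by design, since assembler gap sizes are estimates.
#' When two closures' windows overlap (gaps closer than two flank
#' lengths), the right-most wins and the conflicting closure is dropped and
#' reported.
#'
#' @param scaffolds Scaffolds (path, `DNAStringSet`, or named character).
#' @param closures Closure table from [run_sweep()].
#' @return Named character vector of rewritten scaffolds, with an attribute
#'   `dropped` holding the closures skipped due to window conflicts.
#' @export
apply_closures <- function(scaffolds, closures) {
  out <- as_named_seqs(scaffolds, default_prefix = "scaffold")
  dropped <- list()
  if (nrow(closures) > 0) {
    for (sid in unique(closures$scaffold_id)) {
      if (!sid %in% names(out))
        stop("closure references unknown scaffold '", sid, "'")
      rows <- closures[closures$scaffold_id == sid, , drop = FALSE]
      rows <- rows[order(-rows$start), , drop = FALSE]
      s <- out[[sid]]
      applied_min_start <- nchar(s) + 1L
      for (i in seq_len(nrow(rows))) {
        wstart <- rows$start[i] - rows$flank_len[i]   # 0-based
        wend <- rows$end[i] + rows$flank_len[i]
        if (wend > applied_min_start) {               # overlaps a window to the right
          dropped[[length(dropped) + 1L]] <- rows[i, , drop = FALSE]
          next
        }
        s <- paste0(substr(s, 1L, wstart), rows$replacement[i],
                    substr(s, wend + 1L, nchar(s)))
        applied_min_start <- wstart
      }
      out[[sid]] <- s
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped)
             else closures[0, , drop = FALSE]
  if (nrow(dropped) > 0)
    warning(nrow(dropped),
            " closure(s) dropped due to overlapping replacement windows")
  attr(out, "dropped") <- dropped
  out
}

#' Close gaps in scaffolds end to end
#'
#' Runs [find_gaps()], [run_sweep()] and [apply_closures()], optionally
#' writing the output files (see [write_outputs()]).
#'
#' @inheritParams run_sweep
#' @param out_prefix If non-`NULL`, write output files with this path
#'   prefix.
#' @param print_flanks Also write the gap-flank pairs FASTA.
#' @param verbose Print per-k progress.
#' @return An object of class `gapfill_result`: list with `scaffolds`
#'   (gap-filled, named character), `gaps`, `closures`, `applied` (closures
#'   actually spliced), `dropped`, `sweep_log`, `gap_log`, `config`, and
#'   `files` (written paths, when `out_prefix` is given).
#' @export
close_gaps <- function(scaffolds, reads, cfg = run_config(),
                       out_prefix = NULL, print_flanks = FALSE,
                       verbose = FALSE) {
  scaffolds <- as_named_seqs(scaffolds, default_prefix = "scaffold")
  if (!is.null(out_prefix)) .check_writable(out_prefix)
  sw <- run_sweep(scaffolds, reads, cfg, verbose = verbose)
  filled <- apply_closures(scaffolds, sw$closures)
  dropped <- attr(filled, "dropped")
  attr(filled, "dropped") <- NULL
  applied <- if (nrow(dropped) > 0)
    sw$closures[!(sw$closures$gap_id %in% dropped$gap_id), , drop = FALSE]
  else sw$closures
  res <- structure(list(scaffolds = filled, gaps = sw$gaps,
                        closures = sw$closures, applied = applied,
                        dropped = dropped, sweep_log = sw$sweep_log,
                        gap_log = sw$gap_log, config = cfg, files = NULL),
                   class = "gapfill_result")
  if (!is.null(out_prefix))
    res$files <- write_outputs(res, out_prefix, print_flanks = print_flanks)
  res
}

.check_writable <- function(out_prefix) {
  d <- dirname(out_prefix)
  if (!dir.exists(d)) stop("output directory does not exist: '", d, "'")
  if (file.access(d, 2L) != 0L) stop("output directory not writable: '", d, "'")
  invisible(TRUE)
}

#' Write pipeline output files
#'
#' Writes: `<prefix>_scaffolds.fa` (gap-filled scaffolds),
#' `<prefix>_merged.fa` (every replacement product, headers
#' `<scaffold_id>_<gap_start>_<gap_end> k=<k> status=<status>`),
#' `<prefix>_sweep.tsv` and `<prefix>_gaps.tsv` (machine-parsable per-k and
#' per-gap logs; coordinates 0-based half-open, stated in a `#` header
#' line), and optionally `<prefix>_flanks.fa` with the gap-flank pairs as
#' records suffixed `/1` (left) and `/2` (right).
#'
#' @param res A `gapfill_result` from [close_gaps()], or a list with the
#'   same fields.
#' @param out_prefix Path prefix for all files.
#' @param print_flanks Write the flank-pair FASTA too.
#' @return Named character vector of written paths, invisibly.
#' @export
write_outputs <- function(res, out_prefix, print_flanks = FALSE) {
  .check_writable(out_prefix)
  files <- c(scaffolds = paste0(out_prefix, "_scaffolds.fa"),
             merged = paste0(out_prefix, "_merged.fa"),
             sweep_log = paste0(out_prefix, "_sweep.tsv"),
             gap_log = paste0(out_prefix, "_gaps.tsv"))
  write_fasta(res$scaffolds, files[["scaffolds"]])
  applied <- res$applied %||% res$closures
  merged <- setNames(applied$replacement,
                     sprintf("%s_%d_%d k=%d status=%s", applied$scaffold_id,
                             applied$start, applied$end, applied$k_used,
                             applied$status))
  write_fasta(merged, files[["merged"]])
  .write_tsv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# coordinates are 0-based, half-open", con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .write_tsv(res$sweep_log, files[["sweep_log"]])
  .write_tsv(res$gap_log, files[["gap_log"]])
  if (print_flanks) {
    files <- c(files, flanks = paste0(out_prefix, "_flanks.fa"))
    g <- res$gaps
    fl <- character(2L * nrow(g))
    nm <- character(2L * nrow(g))
    if (nrow(g) > 0) {
      fl[seq(1L, length(fl), by = 2L)] <- g$left_flank
      fl[seq(2L, length(fl), by = 2L)] <- g$right_flank
      nm[seq(1L, length(nm), by = 2L)] <-
        sprintf("%s_%d_%d/1", g$scaffold_id, g$start, g$end)
      nm[seq(2L, length(nm), by = 2L)] <-
        sprintf("%s_%d_%d/2", g$scaffold_id, g$start, g$end)
    }
    write_fasta(setNames(fl, nm), files[["flanks"]])
  }
  invisible(files)
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat(sprintf("gap closing run: %d scaffold(s), %d gap(s), %d closed (%d applied)\n",
              length(x$scaffolds), nrow(x$gaps), nrow(x$closures),
              nrow(x$applied)))
  cat(sprintf("  k sweep: %s; threshold %d; flank %d bp\n",
              paste(x$config$k, collapse = ","), x$config$threshold,
              x$config$min_flank))
  if (nrow(x$sweep_log) > 0) {
    cat("  per-k closures: ",
        paste(sprintf("k%d=%d", x$sweep_log$k, x$sweep_log$closed),
              collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
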