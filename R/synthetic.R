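# Desk-scale synthetic fixtures with the statistical structure the method
# assumes: a random reference genome (optionally with planted exact
# repeats), paired-end shotgun reads at a stated coverage and substitution
# error rate, and a gapped draft whose N-run lengths may deliberately
# mis-estimate the true masked lengths. Every operation draws from its own
# RNG stream derived from (seed, operation name), so outputs are
# individually reproducible.

#' Simulation configuration
#'
#' Defaults describe the package's reference validation scenario: a 100 kbp
#' non-repetitive genome, 2 x 100 bp pairs at 50-fold coverage with no
#' sequencing errors, and 20 gaps of 50-500 bp whose written N-run lengths
#' mis-estimate the truth by a uniform factor in +/- 20 percent (assembler
#' gap sizes come from fragment-library distributions and are routinely
#' off by that much).
#'
#' @param genome_len Genome length in bp.
#' @param gc GC fraction of the random background sequence.
#' @param repeat_spec Optional list of `c(unit_len, copies)` pairs: each
#'   plants a randomly chosen unit verbatim at `copies` total positions.
#' @param read_len Read length in bp.
#' @param frag_len_mean,frag_len_sd Gaussian fragment length in bp (clamped
#'   to at least `read_len`).
#' @param coverage Fold sequence coverage; pair count is
#'   `ceiling(coverage * genome_len / (2 * read_len))`.
#' @param sub_error_rate Per-base substitution probability (no indels: the
#'   multiplicity filter is what substitution errors exercise).
#' @param n_gaps Number of gaps to mask in the draft.
#' @param gap_len_range `c(min, max)` true gap length in bp.
#' @param gap_size_error Signed fraction by which the written N-run length
#'   misstates the true masked length; a scalar applies to every gap, a
#'   length-2 range draws one factor per gap uniformly.
#' @param min_flank Minimum clean spacing kept around gaps (twice this
#'   between gaps, once to scaffold ends).
#' @param gaps_in_repeats Allow gap windows inside planted repeats (off by
#'   default; turn on to exercise repeat resolution at large k).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 100000, gc = 0.5, repeat_spec = NULL,
                       read_len = 100, frag_len_mean = 400, frag_len_sd = 40,
                       coverage = 50, sub_error_rate = 0, n_gaps = 20,
                       gap_len_range = c(50, 500),
                       gap_size_error = c(-0.2, 0.2), min_flank = 100,
                       gaps_in_repeats = FALSE, seed = 1) {
  stopifnot(genome_len > 0, gc >= 0, gc <= 1, read_len > 0, coverage > 0,
            frag_len_mean >= read_len, frag_len_sd >= 0, sub_error_rate >= 0,
            sub_error_rate < 1, n_gaps >= 0, length(gap_len_range) == 2L,
            gap_len_range[1] >= 1, gap_len_range[2] >= gap_len_range[1],
            length(gap_size_error) %in% 1:2, min_flank >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a reference genome
#'
#' I.i.d. bases at the configured GC fraction; then, for each entry of
#' `repeat_spec`, a randomly located unit is copied verbatim to additional
#' non-overlapping positions so it occurs (at least) `copies` times as an
#' exact substring.
#'
#' @param cfg A [sim_config()].
#' @return A single uppercase sequence (character scalar) with attribute
#'   `repeats`: a `data.frame` of the planted repeat windows (0-based,
#'   half-open).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "genome"), {
    p <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
    g <- paste(sample(c("A", "C", "G", "T"), cfg$genome_len, replace = TRUE,
                      prob = p), collapse = "")
    rep_rows <- list()
    for (spec in cfg$repeat_spec) {
      unit_len <- as.integer(spec[1])
      copies <- as.integer(spec[2])
      if (unit_len > cfg$genome_len)
        stop("repeat unit longer than the genome")
      if (unit_len * copies > cfg$genome_len)
        stop("planted repeats exceed genome length")
      # pick 'copies' pairwise non-overlapping windows; first is the source
      starts <- integer(0)
      tries <- 0L
      while (length(starts) < copies && tries < 10000L) {
        cand <- sample.int(cfg$genome_len - unit_len + 1L, 1L)
        if (all(abs(cand - starts) >= unit_len)) starts <- c(starts, cand)
        tries <- tries + 1L
      }
      if (length(starts) < copies)
        stop("could not place ", copies, " non-overlapping repeat copies")
      unit <- substr(g, starts[1L], starts[1L] + unit_len - 1L)
      for (s in starts[-1L])
        substr(g, s, s + unit_len - 1L) <- unit
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(start = sort(starts) - 1L,
                   end = sort(starts) - 1L + unit_len)
    }
    attr(g, "repeats") <- if (length(rep_rows)) do.call(rbind, rep_rows)
                          else data.frame(start = integer(0), end = integer(0))
    g
  })
}

#' Simulate paired-end reads
#'
#' Fragments are drawn uniformly along the genome with Gaussian lengths;
#' read 1 is the fragment 5' prefix and read 2 the reverse complement of
#' the fragment 3' suffix. Substitution errors are applied i.i.d. per base.
#'
#' @param genome Genome sequence (character scalar).
#' @param cfg A [sim_config()].
#' @return List with `read1`, `read2` (named character vectors, pair `i`
#'   named `read<i>/1` and `read<i>/2`) and `meta` (`data.frame` of
#'   fragment start and length, 1-based, for downstream checks).
#' @export
simulate_reads <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genome <- toupper(as.character(genome))
  G <- nchar(genome)
  rl <- cfg$read_len
  if (G < rl) stop("genome shorter than the read length")
  with_seed(derive_seed(cfg$seed, "reads"), {
    n_pairs <- ceiling(cfg$coverage * G / (2 * rl))
    frag <- pmin(G, pmax(rl, round(rnorm(n_pairs, cfg$frag_len_mean,
                                         cfg$frag_len_sd))))
    start <- floor(runif(n_pairs) * (G - frag + 1)) + 1L
    r1 <- substring(genome, start, start + rl - 1L)
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      substring(genome, start + frag - rl, start + frag - 1L))))
    if (cfg$sub_error_rate > 0) {
      r1 <- mutate_seqs_cpp(r1, cfg$sub_error_rate)
      r2 <- mutate_seqs_cpp(r2, cfg$sub_error_rate)
    }
    list(read1 = setNames(r1, sprintf("read%d/1", seq_len(n_pairs))),
         read2 = setNames(r2, sprintf("read%d/2", seq_len(n_pairs))),
         meta = data.frame(start = as.integer(start),
                           frag_len = as.integer(frag)))
  })
}

#' Mask gaps into a draft scaffold with known truth
#'
#' Chooses `n_gaps` windows (pairwise separated by at least
#' `2 * min_flank`, at least `min_flank` from the ends, and outside planted
#' repeats unless `gaps_in_repeats`), records the masked bases as truth,
#' and replaces each window with an N-run of length
#' `round(true_len * (1 + gap_size_error))` (minimum 1).
#'
#' @param genome Genome sequence, as from [simulate_genome()].
#' @param cfg A [sim_config()].
#' @param scaffold_id Name of the single draft scaffold.
#' @return List with `draft` (named character vector of one scaffold) and
#'   `truth` (`data.frame`: `scaffold_id`, `start`, `end` as written in the
#'   draft, 0-based half-open, `true_len`, `true_sequence`).
#' @export
make_gapped_draft <- function(genome, cfg, scaffold_id = "scaffold_1") {
  stopifnot(inherits(cfg, "sim_config"))
  g <- toupper(as.character(genome))
  G <- nchar(g)
  reps <- attr(genome, "repeats") %||%
    data.frame(start = integer(0), end = integer(0))
  with_seed(derive_seed(cfg$seed, "draft"), {
    n <- cfg$n_gaps
    if (n == 0L) {
      return(list(draft = setNames(g, scaffold_id),
                  truth = data.frame(scaffold_id = character(0),
                                     start = integer(0), end = integer(0),
                                     true_len = integer(0),
                                     true_sequence = character(0),
                                     stringsAsFactors = FALSE)))
    }
    lens <- floor(runif(n, cfg$gap_len_range[1], cfg$gap_len_range[2] + 1))
    starts <- integer(0)   # 1-based window starts, placed one by one
    placed_len <- integer(0)
    tries <- 0L
    i <- 1L
    while (i <= n && tries < 20000L) {
      tries <- tries + 1L
      len <- lens[i]
      lo <- cfg$min_flank + 1L
      hi <- G - len - cfg$min_flank + 1L
      if (hi < lo) break
      cand <- floor(runif(1) * (hi - lo + 1)) + lo
      sep_ok <- all(cand + len + 2L * cfg$min_flank <= starts |
                    starts + placed_len + 2L * cfg$min_flank <= cand)
      rep_ok <- cfg$gaps_in_repeats || nrow(reps) == 0L ||
        all(cand + len - 1L <= reps$start | cand > reps$end)
      if (sep_ok && rep_ok) {
        starts <- c(starts, cand)
        placed_len <- c(placed_len, len)
        i <- i + 1L
      }
    }
    if (length(starts) < n)
      stop("could only place ", length(starts), " of ", n,
           " non-conflicting gap windows")
    ord <- order(starts)
    starts <- starts[ord]
    placed_len <- placed_len[ord]
    err <- if (length(cfg$gap_size_error) == 2L) {
      runif(n, cfg$gap_size_error[1], cfg$gap_size_error[2])
    } else {
      rep(cfg$gap_size_error, n)
    }
    written <- pmax(1L, as.integer(round(placed_len * (1 + err))))
    truth_seq <- substring(g, starts, starts + placed_len - 1L)
    # build the draft left to right, tracking the coordinate shift
    pieces <- character(0)
    draft_starts <- integer(n)
    prev_end <- 1L
    offset <- 0L
    for (j in seq_len(n)) {
      pieces <- c(pieces, substr(g, prev_end, starts[j] - 1L),
                  strrep("N", written[j]))
      draft_starts[j] <- starts[j] - 1L + offset
      offset <- offset + written[j] - placed_len[j]
      prev_end <- starts[j] + placed_len[j]
    }
    pieces <- c(pieces, substr(g, prev_end, G))
    draft <- paste(pieces, collapse = "")
    list(draft = setNames(draft, scaffold_id),
         truth = data.frame(scaffold_id = scaffold_id, start = draft_starts,
                            end = draft_starts + written,
                            true_len = placed_len,
                            true_sequence = truth_seq,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a full dataset: genome, reads, gapped draft and truth
#'
#' @param cfg A [sim_config()].
#' @return List with `genome`, `reads` (see [simulate_reads()]), `draft`
#'   and `truth` (see [make_gapped_draft()]).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  genome <- simulate_genome(cfg)
  reads <- simulate_reads(genome, cfg)
  gd <- make_gapped_draft(genome, cfg)
  list(genome = genome, reads = reads, draft = gd$draft, truth = gd$truth)
}

#' Write / read a gap truth table
#'
#' Tab-separated with a header; coordinates 0-based half-open.
#'
#' @param truth Truth `data.frame` from [make_gapped_draft()].
#' @param path File path.
#' @return `path` (write) or the truth `data.frame` (read).
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(scaffold_id = "character",
                            true_sequence = "character"))
}
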