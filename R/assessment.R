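# Assessment of gap closing: counting N-runs, recovering the inserted
# sequence of each gap by anchoring its original flanks in the filled
# assembly, and similarity scoring that does not penalize IUPAC ambiguity
# codes.

#' Count N-gaps in an assembly
#'
#' A gap is one or a contiguous group of N bases. Ambiguity codes are not
#' N and are not counted; terminal runs count.
#'
#' @param x FASTA path, `DNAStringSet`, or (named) character vector.
#' @return List with `total` and `per_scaffold` (`data.frame` of
#'   `scaffold_id`, `n_gaps`).
#' @examples
#' count_gaps(c(s1 = "NNAAN", s2 = "ACGRYT"))$total
#' @export
count_gaps <- function(x) {
  s <- as_named_seqs(x, default_prefix = "scaffold")
  if (length(s) == 0L) {
    warning("no sequences found; zero gaps")
    return(list(total = 0L,
                per_scaffold = data.frame(scaffold_id = character(0),
                                          n_gaps = integer(0))))
  }
  n <- vapply(s, function(seq) {
    m <- gregexpr("N+", seq)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1))
  list(total = sum(n),
       per_scaffold = data.frame(scaffold_id = names(s), n_gaps = unname(n),
                                 stringsAsFactors = FALSE, row.names = NULL))
}

# All match starts (1-based) of a probe in a scaffold; integer(0) if none.
.find_all <- function(probe, filled) {
  m <- gregexpr(probe, filled, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Anchor one gap's flanks in the filled scaffold and return the bases
# strictly between them, or NULL when anchoring is ambiguous/impossible.
# Strategy: (1) exact flanks at the expected (draft) coordinates; (2)
# scaffold-wide exact search, allowing progressively more gap-facing bases
# of the flanks to have been corrected by the closure; a unique valid
# (left end < right start) pairing is required -- multiple pairings are
# ambiguous.
.anchor_gap <- function(lf, rf, filled, le_exp, rs_exp, max_trim) {
  fl <- nchar(lf)
  if (substr(filled, le_exp - fl + 1L, le_exp) == lf &&
      substr(filled, rs_exp, rs_exp + nchar(rf) - 1L) == rf &&
      le_exp < rs_exp)
    return(substr(filled, le_exp + 1L, rs_exp - 1L))
  for (t in 0:(2L * max_trim)) {
    pairs <- list()
    for (trL in max(0L, t - max_trim):min(t, max_trim)) {
      trR <- t - trL
      pl <- substr(lf, 1L, fl - trL)            # trim the 3' (gap) end
      pr <- substr(rf, trR + 1L, nchar(rf))     # trim the 5' (gap) end
      if (nchar(pl) == 0L || nchar(pr) == 0L) next
      le <- .find_all(pl, filled) + nchar(pl) - 1L
      rs <- .find_all(pr, filled)
      for (a in le) for (b in rs)
        if (b > a) pairs[[length(pairs) + 1L]] <- c(a, b)
    }
    if (length(pairs) == 1L)
      return(substr(filled, pairs[[1L]][1L] + 1L, pairs[[1L]][2L] - 1L))
    if (length(pairs) > 1L) return(NULL)        # ambiguous anchoring
  }
  NULL
}

#' Recover inserted gap sequences by flank anchoring
#'
#' For every gap of the original draft, takes the `flank_len` bases on each
#' side, locates them in the corresponding filled scaffold (exact match
#' first, then with up to `flank_len / 2` gap-facing bases trimmed, since
#' closing may correct bases at the flank tip), and reports the bases
#' strictly between the two matches. A gap whose flanks cannot be anchored
#' uniquely is marked unassessable.
#'
#' @param draft,filled Original and gap-filled assemblies (path,
#'   `DNAStringSet`, or named character); scaffold IDs must correspond.
#' @param flank_len Flank length in bp used for anchoring (default 100).
#' @return `data.frame` with one row per draft gap: `scaffold_id`,
#'   `gap_id`, `start`, `end` (0-based half-open, draft coordinates),
#'   `assessable`, `inserted`, `closed`.
#' @export
extract_inserted <- function(draft, filled, flank_len = 100) {
  draft <- as_named_seqs(draft, default_prefix = "scaffold")
  filled <- as_named_seqs(filled, default_prefix = "scaffold")
  missing_ids <- setdiff(names(draft), names(filled))
  if (length(missing_ids) > 0)
    stop("scaffold IDs missing from the filled assembly: ",
         paste(missing_ids, collapse = ", "))
  rows <- list()
  for (sid in names(draft)) {
    s <- draft[[sid]]
    f <- filled[[sid]]
    m <- gregexpr("N+", s)[[1L]]
    if (m[1L] == -1L) next
    start0 <- as.integer(m) - 1L
    end0 <- start0 + attr(m, "match.length")
    for (i in seq_along(start0)) {
      row <- data.frame(scaffold_id = sid, gap_id = i, start = start0[i],
                        end = end0[i], assessable = FALSE,
                        inserted = NA_character_, closed = FALSE,
                        stringsAsFactors = FALSE)
      lf <- if (start0[i] >= flank_len)
        substr(s, start0[i] - flank_len + 1L, start0[i]) else ""
      rf <- if (end0[i] + flank_len <= nchar(s))
        substr(s, end0[i] + 1L, end0[i] + flank_len) else ""
      if (nchar(lf) == flank_len && nchar(rf) == flank_len &&
          !grepl("N", lf) && !grepl("N", rf)) {
        ins <- .anchor_gap(lf, rf, f, le_exp = start0[i], rs_exp = end0[i] + 1L,
                           max_trim = flank_len %/% 2L)
        if (!is.null(ins)) {
          row$assessable <- TRUE
          row$inserted <- ins
          row$closed <- !grepl("N", ins)
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(scaffold_id = character(0), gap_id = integer(0),
               start = integer(0), end = integer(0), assessable = logical(0),
               inserted = character(0), closed = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# 0/1 substitution matrix: 1 when the two IUPAC base sets are compatible.
# Built on first use and cached (seq-core tables are not yet defined at
# file load time).
.sim_matrix_cache <- new.env(parent = emptyenv())
.sim_matrix <- function() {
  if (is.null(.sim_matrix_cache$m)) {
    letters <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")
    m <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
    for (a in letters) for (b in letters) {
      if (length(intersect(.IUPAC_SETS[[a]], .IUPAC_SETS[[b]])) > 0)
        m[a, b] <- 1
    }
    .sim_matrix_cache$m <- m
  }
  .sim_matrix_cache$m
}

#' Percent similarity of a query to a truth sequence
#'
#' Global alignment with unit scoring: each aligned column scores 1 when
#' the two base sets are compatible and 0 otherwise, and gaps cost
#' nothing, so the optimal score is the maximum number of matching bases.
#' A query ambiguity code aligned to any base of its IUPAC set counts as a
#' match -- ambiguity codes are not penalized. The result is
#' `100 * matches / nchar(query)`.
#'
#' @param query,truth Non-empty sequences (character scalars); `query` may
#'   contain ambiguity codes.
#' @return Percent similarity in `[0, 100]`.
#' @examples
#' seq_similarity("ACGR", "ACGA")
#' seq_similarity("ACGT", "ACCT")
#' @export
seq_similarity <- function(query, truth) {
  query <- toupper(as.character(query))
  truth <- toupper(as.character(truth))
  stopifnot(length(query) == 1L, length(truth) == 1L)
  if (nchar(query) == 0L) stop("empty query")
  if (nchar(truth) == 0L) stop("empty truth")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(truth),
    type = "global", substitutionMatrix = .sim_matrix(),
    gapOpening = 0, gapExtension = 0)
  100 * BiocGenerics::score(al) / nchar(query)
}

# TRUE when some IUPAC-consistent resolution of `query` equals `truth`.
.exact_under_ambiguity <- function(query, truth) {
  if (nchar(query) != nchar(truth)) return(FALSE)
  q <- strsplit(query, "", fixed = TRUE)[[1L]]
  t <- strsplit(truth, "", fixed = TRUE)[[1L]]
  all(mapply(function(a, b) b %in% .IUPAC_SETS[[a]], q, t))
}

#' Evaluate a gap-filled assembly against the draft (and optional truth)
#'
#' Runs [extract_inserted()], joins ground truth by gap coordinates when
#' provided, and summarizes closure success and insertion accuracy.
#'
#' @param draft,filled Original and gap-filled assemblies.
#' @param truth Optional truth: a `data.frame` as from
#'   [make_gapped_draft()], or a TSV path readable by [read_truth()];
#'   without it only closure counts are reported.
#' @param flank_len Anchoring flank length in bp.
#' @param similarity_threshold Optional percent threshold; when set, the
#'   summary also reports the fraction of closed gaps at or above it.
#' @return Object of class `gap_evaluation`: list with `rows` (per-gap
#'   table, with `percent_similarity` and `exact_match` where truth is
#'   available) and `summary` (gaps, closed, percent success, mean
#'   similarity, exact-match fraction).
#' @export
evaluate_closure <- function(draft, filled, truth = NULL, flank_len = 100,
                             similarity_threshold = NULL) {
  rows <- extract_inserted(draft, filled, flank_len = flank_len)
  rows$truth_sequence <- NA_character_
  rows$percent_similarity <- NA_real_
  rows$exact_match <- NA
  if (!is.null(truth)) {
    if (is.character(truth) && length(truth) == 1L) truth <- read_truth(truth)
    bad <- setdiff(unique(truth$scaffold_id), unique(rows$scaffold_id))
    if (length(bad) > 0 && nrow(truth) > 0)
      stop("truth scaffold IDs not present in the draft: ",
           paste(bad, collapse = ", "))
    key <- paste(rows$scaffold_id, rows$start, rows$end)
    tkey <- paste(truth$scaffold_id, truth$start, truth$end)
    idx <- match(key, tkey)
    rows$truth_sequence <- truth$true_sequence[idx]
    for (i in which(rows$closed & !is.na(rows$truth_sequence))) {
      rows$percent_similarity[i] <-
        seq_similarity(rows$inserted[i], rows$truth_sequence[i])
      rows$exact_match[i] <-
        .exact_under_ambiguity(rows$inserted[i], rows$truth_sequence[i])
    }
  }
  n <- nrow(rows)
  closed <- sum(rows$closed)
  summ <- list(
    gaps = n, closed = closed,
    pct_success = if (n > 0) 100 * closed / n else NA_real_,
    unassessable = sum(!rows$assessable),
    mean_similarity = if (any(!is.na(rows$percent_similarity)))
      mean(rows$percent_similarity, na.rm = TRUE) else NA_real_,
    exact_match_fraction = if (any(!is.na(rows$exact_match)))
      mean(rows$exact_match, na.rm = TRUE) else NA_real_)
  if (!is.null(similarity_threshold))
    summ$frac_above_threshold <-
      mean(rows$percent_similarity[rows$closed] >= similarity_threshold,
           na.rm = TRUE)
  structure(list(rows = rows, summary = summ), class = "gap_evaluation")
}

#' @export
print.gap_evaluation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("gaps: %d, closed: %d (%.1f%% success), unassessable: %d\n",
              s$gaps, s$closed, s$pct_success, s$unassessable))
  if (!is.na(s$mean_similarity))
    cat(sprintf("mean similarity of closed insertions: %.2f%%; exact-match fraction: %.3f\n",
                s$mean_similarity, s$exact_match_fraction))
  invisible(x)
}
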