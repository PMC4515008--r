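# The connection engine: anchor a k-mer in each gap flank, enumerate every
# path between the anchors through the implicit de Bruijn graph with a
# depth-limited bidirectional breadth-first search, and emit one consensus
# sequence. Connections are all-or-none: a gap is reported only when the
# path set is unambiguous enough to spell a single (possibly
# ambiguity-coded) product.

#' Search parameters for flank connection
#'
#' @param max_paths Maximum number of distinct paths reported as a
#'   successful connection (`-P`); unique traversals and path sets of
#'   multiplicity up to this limit are merged into a consensus. Default 2.
#' @param max_branches Cap on simultaneously live search branches summed
#'   over both frontiers (`-B`); exceeding it aborts the gap, fail-closed.
#' @param max_frag Cap in bp on the full assembled product, flank anchor to
#'   flank anchor inclusive (`-F`).
#' @param max_flank_scan How many positions inward from the gap edge to
#'   scan for a solid anchor k-mer; `NULL` scans the whole flank.
#' @return A list of class `search_params`.
#' @export
search_params <- function(max_paths = 2, max_branches = 3000,
                          max_frag = 5000, max_flank_scan = NULL) {
  stopifnot(max_paths >= 1, max_branches >= 1, max_frag >= 1)
  structure(list(max_paths = as.integer(max_paths),
                 max_branches = as.integer(max_branches),
                 max_frag = as.integer(max_frag),
                 max_flank_scan = if (is.null(max_flank_scan)) NULL
                                  else as.integer(max_flank_scan)),
            class = "search_params")
}

#' Find a solid anchor k-mer in a gap flank
#'
#' Scans candidate k-mers from the gap edge inward (offset 0, 1, ...) and
#' returns the first that is solid in the filter. The bases between the
#' anchor and the gap edge (`trim`) are later replaced by assembled
#' sequence, which lets the connection correct micro-misassemblies at the
#' flank tip.
#'
#' @param flank N-free flank sequence (character scalar).
#' @param side `"left"` (scan from the 3' end) or `"right"` (from the 5'
#'   end).
#' @param b A [kmer_bloom()] filter.
#' @param max_flank_scan Maximum offset to scan; `NULL` scans the whole
#'   flank.
#' @return `list(kmer =, trim =)`, or `NULL` when no anchor is found
#'   (including flanks shorter than k).
#' @export
find_anchor <- function(flank, side = c("left", "right"), b,
                        max_flank_scan = NULL) {
  side <- match.arg(side)
  .check_bloom(b)
  flank <- toupper(as.character(flank))
  stopifnot(length(flank) == 1L)
  L <- nchar(flank)
  k <- b$k
  if (L < k) return(NULL)
  max_scan <- min(max_flank_scan %||% (L - k), L - k)
  offs <- 0:max_scan
  cand <- if (side == "left") {
    substring(flank, L - k - offs + 1L, L - offs)
  } else {
    substring(flank, offs + 1L, offs + k)
  }
  ok <- grepl("^[ACGT]+$", cand)
  if (!any(ok)) return(NULL)
  hit <- which(ok)[bloom_solid(b, cand[ok])]
  if (length(hit) == 0L) return(NULL)
  list(kmer = cand[hit[1L]], trim = offs[hit[1L]])
}

#' Enumerate all graph paths between two anchor k-mers
#'
#' Bidirectional breadth-first search: one frontier extends rightward from
#' `start`, the other leftward from `goal`, alternating one level at a time
#' (left first); complete paths are assembled wherever the two search
#' regions share a k-mer at compatible depths. All distinct paths within
#' the depth limit are returned, or a limit status. A path never visits the
#' same k-mer twice in the same orientation, which bounds walks through
#' repeats while still allowing inverted-repeat traversal.
#'
#' @param b A [kmer_bloom()] filter.
#' @param start,goal Anchor k-mers (forward orientation).
#' @param max_edges Depth limit: maximum number of graph edges in a path.
#' @param max_branches,max_paths See [search_params()].
#' @return List with `status` (`"ok"`, `"no_path"`, `"too_many_paths"`,
#'   `"branch_limit"`, `"length_limit"`), `paths` (character vector of
#'   spelled sequences when `status == "ok"`), and `num_paths`.
#' @export
enumerate_paths <- function(b, start, goal, max_edges,
                            max_branches = 3000, max_paths = 2) {
  .check_bloom(b)
  r <- enumerate_paths_cpp(b$ptr, toupper(as.character(start)),
                           toupper(as.character(goal)),
                           as.integer(max_edges), as.integer(max_branches),
                           as.integer(max_paths))
  list(status = r$status, paths = r$paths, num_paths = r$n_paths)
}

#' Column-wise consensus of equal-length path spellings
#'
#' A single path is returned verbatim. Multiple paths of equal length are
#' merged position by position, writing the IUPAC code of the observed base
#' set at mismatching columns. Path sets of unequal lengths cannot be
#' merged column-wise and return `NA` (the gap is left open).
#'
#' @param paths Character vector of spelled path sequences (ACGT-only).
#' @return A single consensus sequence, or `NA_character_` for unequal
#'   lengths.
#' @examples
#' consensus_paths(c("ACGGTAGCCA", "ACGGTTGCCA"))
#' @export
consensus_paths <- function(paths) {
  paths <- toupper(as.character(paths))
  if (length(paths) == 0L) stop("empty path list")
  if (length(paths) == 1L) return(paths)
  if (length(unique(nchar(paths))) > 1L) return(NA_character_)
  m <- do.call(rbind, strsplit(paths, "", fixed = TRUE))
  merged <- apply(m, 2L, function(col) {
    u <- unique(col)
    if (length(u) == 1L) u else iupac_merge(u)
  })
  paste(merged, collapse = "")
}

#' Connect a pair of gap flanks through the de Bruijn graph
#'
#' Composes [find_anchor()] on both flanks, [enumerate_paths()] between the
#' anchors, and [consensus_paths()]. On success the returned sequence is
#' the full replacement product: the kept left flank (up to and including
#' its anchor), the assembled interior, and the kept right flank (from its
#' anchor on). The depth limit is derived from `max_frag` so the product
#' never exceeds it.
#'
#' @param left_flank,right_flank N-free flank sequences, each at least k
#'   bp.
#' @param b A [kmer_bloom()] filter.
#' @param params A [search_params()] object.
#' @return An object of class `connection_result`: list with `status`
#'   (`"unique"`, `"consensus"`, or a failure code), `sequence` (`NULL`
#'   unless successful), `num_paths`, `left_trim`, `right_trim`.
#' @export
connect_flanks <- function(left_flank, right_flank, b,
                           params = search_params()) {
  .check_bloom(b)
  stopifnot(inherits(params, "search_params"))
  k <- b$k
  fail <- function(status, num_paths = 0L, lt = NA_integer_, rt = NA_integer_) {
    structure(list(status = status, sequence = NULL,
                   num_paths = as.integer(num_paths),
                   left_trim = lt, right_trim = rt),
              class = "connection_result")
  }
  left_flank <- toupper(as.character(left_flank))
  right_flank <- toupper(as.character(right_flank))
  aL <- find_anchor(left_flank, "left", b, params$max_flank_scan)
  aR <- find_anchor(right_flank, "right", b, params$max_flank_scan)
  if (is.null(aL) || is.null(aR)) return(fail("no_anchor"))
  kept_l <- nchar(left_flank) - aL$trim
  kept_r <- nchar(right_flank) - aR$trim
  max_edges <- params$max_frag - kept_l - kept_r + k
  if (max_edges < 0L) return(fail("length_limit", 0L, aL$trim, aR$trim))
  er <- enumerate_paths(b, aL$kmer, aR$kmer, max_edges,
                        params$max_branches, params$max_paths)
  if (er$status != "ok")
    return(fail(er$status, er$num_paths, aL$trim, aR$trim))
  merged <- consensus_paths(er$paths)
  if (is.na(merged))  # unequal-length path set: too ambiguous to merge
    return(fail("too_many_paths", er$num_paths, aL$trim, aR$trim))
  seq <- paste0(substr(left_flank, 1L, kept_l - k), merged,
                substr(right_flank, aR$trim + k + 1L, nchar(right_flank)))
  structure(list(status = if (er$num_paths == 1L) "unique" else "consensus",
                 sequence = seq, num_paths = as.integer(er$num_paths),
                 left_trim = aL$trim, right_trim = aR$trim),
            class = "connection_result")
}

#' @export
print.connection_result <- function(x, ...) {
  cat(sprintf("flank connection: status = %s, paths = %d", x$status,
              x$num_paths))
  if (!is.null(x$sequence))
    cat(sprintf(", product = %d bp (trims %d/%d)", nchar(x$sequence),
                x$left_trim, x$right_trim))
  cat("\n")
  invisible(x)
}
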