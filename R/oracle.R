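# Reference path enumerator for validation: an exact (hash-set) de Bruijn
# graph built by literal k-mer counting, traversed by exhaustive
# depth-first search. Deliberately independent of the Bloom filter and the
# bidirectional search so the two routes can be compared on the same
# inputs; intended for small fixtures, not production data.

#' Exact solid k-mer set from reads
#'
#' Counts every canonical k-mer occurrence literally and returns the set at
#' or above the multiplicity threshold, stored in a hashed environment.
#'
#' @param reads Character vector of read sequences.
#' @param k K-mer length.
#' @param threshold Multiplicity threshold.
#' @return Environment whose keys are the solid canonical k-mers, with
#'   attributes `k` and `threshold`.
#' @export
exact_solid_kmers <- function(reads, k, threshold = 2) {
  reads <- toupper(as.character(reads))
  km <- unlist(lapply(reads, extract_kmers, k = k), use.names = FALSE)
  ct <- table(canonical_kmer(km))
  solid <- names(ct[ct >= threshold])
  env <- new.env(hash = TRUE, parent = emptyenv(), size = length(solid) + 1L)
  for (s in solid) assign(s, TRUE, envir = env)
  attr(env, "k") <- as.integer(k)
  attr(env, "threshold") <- as.integer(threshold)
  env
}

#' Exhaustive DFS path enumeration over an exact k-mer set
#'
#' Enumerates every path from `start` to `goal` of at most `max_edges`
#' graph edges by depth-first search over the exact solid set, with the
#' same path rule as the production search: a path never visits the same
#' k-mer twice in the same orientation. Enumeration stops once more than
#' `max_paths` distinct paths are found.
#'
#' @param solid Environment from [exact_solid_kmers()] (or a character
#'   vector of solid canonical k-mers).
#' @param start,goal Anchor k-mers in forward orientation.
#' @param max_edges Depth limit in edges.
#' @param max_paths Stop after this many paths plus one.
#' @return List with `paths` (spelled sequences, in discovery order) and
#'   `truncated` (`TRUE` when more than `max_paths` paths exist).
#' @export
exact_dbg_paths <- function(solid, start, goal, max_edges,
                            max_paths = Inf) {
  if (is.character(solid)) {
    v <- solid
    solid <- new.env(hash = TRUE, parent = emptyenv(), size = length(v) + 1L)
    for (s in v) assign(s, TRUE, envir = solid)
  }
  start <- toupper(start)
  goal <- toupper(goal)
  k <- nchar(start)
  stopifnot(nchar(goal) == k)
  has <- function(x) exists(canonical_kmer(x), envir = solid, inherits = FALSE)
  paths <- character(0)
  truncated <- FALSE
  if (start == goal)
    return(list(paths = start, truncated = FALSE))
  # explicit-stack DFS (paths can be hundreds of edges deep)
  BASES <- c("A", "C", "G", "T")
  nodes <- character(max_edges + 1L)  # nodes[d]: k-mer at depth d (d-1 edges)
  ext <- character(max_edges + 1L)    # ext[d]: base appended to reach depth d
  nexti <- integer(max_edges + 1L)    # next untried extension per depth
  nodes[1L] <- start
  nexti[1L] <- 1L
  depth <- 1L
  while (depth >= 1L) {
    if (depth - 1L >= max_edges || nexti[depth] > 4L) {
      depth <- depth - 1L
      next
    }
    i <- nexti[depth]
    nexti[depth] <- i + 1L
    nxt <- paste0(substr(nodes[depth], 2L, k), BASES[i])
    if (!has(nxt)) next
    if (any(nodes[seq_len(depth)] == nxt)) next  # same k-mer, same orientation
    if (nxt == goal) {
      spelled <- paste0(start,
                        paste(ext[seq_len(depth)][-1L], collapse = ""),
                        BASES[i])
      paths <- c(paths, spelled)
      if (length(paths) > max_paths) {
        truncated <- TRUE
        break
      }
      next  # revisiting the goal is barred by the path rule
    }
    depth <- depth + 1L
    nodes[depth] <- nxt
    ext[depth] <- BASES[i]
    nexti[depth] <- 1L
  }
  list(paths = paths, truncated = truncated)
}
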