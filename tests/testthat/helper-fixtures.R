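# Shared fixture builders. Everything is generated in code under fixed
# seeds; no stored data.

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

# minimal local stand-in for withr::with_seed (withr not a test dependency)
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Bloom filter holding exactly the k-mers of `seqs`, each seen `times`
# times (FPR negligible at these sizes).
bloom_of <- function(seqs, k, times = 2, threshold = 2, size_bits = 2^22,
                     ...) {
  kmer_bloom(rep(seqs, times), k = k, threshold = threshold,
             size_bits = size_bits, ...)
}

# Two-haplotype fixture: identical arms, one substitution in the middle,
# variant at least k from both anchor k-mers. Returns the haplotypes and
# the draft flanks around a gap that covers the variant.
snp_fixture <- function(k = 21, arm = 60, mid = 41, seed = 7) {
  withr_seed(seed, {
    L <- rand_dna(arm)
    R <- rand_dna(arm)
    M <- rand_dna(mid)
    M2 <- M
    pos <- (mid + 1) %/% 2
    substr(M2, pos, pos) <- if (substr(M, pos, pos) == "A") "T" else "A"
    list(hap1 = paste0(L, M, R), hap2 = paste0(L, M2, R),
         left_flank = L, right_flank = R, mid1 = M, mid2 = M2,
         variant_col = arm + pos)
  })
}

# Splice truth sequences back into a draft (brute force, right to left);
# the generator's consistency oracle.
splice_truth <- function(draft, truth) {
  for (sid in names(draft)) {
    rows <- truth[truth$scaffold_id == sid, , drop = FALSE]
    rows <- rows[order(-rows$start), , drop = FALSE]
    s <- draft[[sid]]
    for (i in seq_len(nrow(rows))) {
      s <- paste0(substr(s, 1, rows$start[i]), rows$true_sequence[i],
                  substr(s, rows$end[i] + 1, nchar(s)))
    }
    draft[[sid]] <- s
  }
  draft
}

# Brute-force application of closure windows by plain string splicing,
# right to left; independent of apply_closures().
splice_closures_by_hand <- function(scaffolds, closures) {
  for (sid in unique(closures$scaffold_id)) {
    rows <- closures[closures$scaffold_id == sid, , drop = FALSE]
    rows <- rows[order(-rows$start), , drop = FALSE]
    s <- scaffolds[[sid]]
    for (i in seq_len(nrow(rows))) {
      ws <- rows$start[i] - rows$flank_len[i]
      we <- rows$end[i] + rows$flank_len[i]
      s <- paste0(substr(s, 1, ws), rows$replacement[i],
                  substr(s, we + 1, nchar(s)))
    }
    scaffolds[[sid]] <- s
  }
  scaffolds
}

# lengths of every maximal N-run in a sequence
n_run_lengths <- function(s) {
  m <- gregexpr("N+", s)[[1]]
  if (m[1] == -1) integer(0) else as.integer(attr(m, "match.length"))
}
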