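test_that("anchor search scans inward from the gap edge", {
  # filter holding exactly CGTAC, GTACG, TACGT
  b <- bloom_of(c("CGTAC", "GTACG", "TACGT"), k = 5)
  a <- find_anchor("ACGTACGT", "left", b)
  expect_equal(a, list(kmer = "TACGT", trim = 0L))

  # without TACGT the scan must step inward by one
  b2 <- bloom_of(c("CGTAC", "GTACG"), k = 5)
  a2 <- find_anchor("ACGTACGT", "left", b2)
  expect_equal(a2, list(kmer = "GTACG", trim = 1L))
  # right side is symmetric from the 5' end
  a3 <- find_anchor("CGTACGTT", "right", b2)
  expect_equal(a3, list(kmer = "CGTAC", trim = 0L))

  empty <- kmer_bloom(NULL, 5, size_bits = 2^16)
  expect_null(find_anchor("ACGTACGT", "left", empty))
  expect_null(find_anchor("ACG", "left", b))  # flank shorter than k
  # scan window respected
  expect_null(find_anchor("GTACGTTT", "left", b2, max_flank_scan = 0))
})

test_that("path enumeration handles chains, identity and branch points", {
  S <- "ACGGTAGCCA"
  b <- bloom_of(S, k = 5)
  er <- enumerate_paths(b, "ACGGT", "AGCCA", max_edges = 20)
  expect_equal(er$status, "ok")
  expect_equal(er$paths, S)

  id <- enumerate_paths(b, "ACGGT", "ACGGT", max_edges = 20)
  expect_equal(id$status, "ok")
  expect_equal(id$paths, "ACGGT")  # zero-length interior: the k-mer itself

  empty <- kmer_bloom(NULL, 5, size_bits = 2^16)
  expect_equal(enumerate_paths(empty, "ACGGT", "AGCCA", 20)$status, "no_path")
})

test_that("a one-SNP pair yields exactly the two variant paths (vs DFS oracle)", {
  fx <- snp_fixture(k = 21)
  reads <- c(fx$hap1, fx$hap1, fx$hap2, fx$hap2)
  b <- kmer_bloom(reads, k = 21, threshold = 2, size_bits = 2^22)
  start <- substr(fx$hap1, 40, 60)          # inside the shared left arm
  goal <- substr(fx$hap1, 102, 122)         # inside the shared right arm
  er <- enumerate_paths(b, start, goal, max_edges = 200, max_paths = 10)
  expect_equal(er$status, "ok")
  expect_equal(er$num_paths, 2L)
  oracle <- exact_dbg_paths(exact_solid_kmers(reads, 21, 2), start, goal,
                            max_edges = 200, max_paths = 10)
  expect_false(oracle$truncated)
  expect_setequal(er$paths, oracle$paths)

  er1 <- enumerate_paths(b, start, goal, max_edges = 200, max_paths = 1)
  expect_equal(er1$status, "too_many_paths")
})

test_that("consensus merging is column-wise with IUPAC codes, equal lengths only", {
  expect_equal(consensus_paths("ACGGTAGCCA"), "ACGGTAGCCA")
  expect_equal(consensus_paths(c("ACGGTAGCCA", "ACGGTTGCCA")), "ACGGTWGCCA")
  expect_equal(consensus_paths(c("AAAA", "ATAA", "AGAA")), "ADAA")
  expect_identical(consensus_paths(c(strrep("A", 30), strrep("A", 32))),
                   NA_character_)
  expect_error(consensus_paths(character(0)))
})

test_that("connect reconstructs a unique product spanning both flanks", {
  S <- "ACGGTAGCCATTGCA"
  # precondition of the fixture: all canonical 5-mers of S are distinct
  expect_false(any(duplicated(canonical_kmer(extract_kmers(S, 5)))))
  b <- bloom_of(S, k = 5)
  res <- connect_flanks(substr(S, 1, 7), substr(S, 9, 15), b,
                        search_params(max_paths = 2, max_branches = 100,
                                      max_frag = 100))
  expect_s3_class(res, "connection_result")
  expect_equal(res$status, "unique")
  expect_equal(res$num_paths, 1L)
  expect_identical(res$sequence, S)
  expect_equal(res$left_trim, 0L)
  expect_equal(res$right_trim, 0L)

  # every k-mer of a unique product is solid (soundness)
  expect_true(all(bloom_solid(b, extract_kmers(res$sequence, 5))))

  empty <- kmer_bloom(NULL, 5, size_bits = 2^16)
  rese <- connect_flanks(substr(S, 1, 7), substr(S, 9, 15), empty,
                         search_params())
  expect_true(rese$status %in% c("no_anchor", "no_path"))
  expect_null(rese$sequence)
})

test_that("SNP pair connects to a consensus under P >= 2 and fails under P = 1", {
  fx <- snp_fixture(k = 21)
  reads <- c(fx$hap1, fx$hap1, fx$hap2, fx$hap2)
  b <- kmer_bloom(reads, k = 21, threshold = 2, size_bits = 2^22)
  res <- connect_flanks(fx$left_flank, fx$right_flank, b,
                        search_params(max_paths = 2, max_frag = 400))
  expect_equal(res$status, "consensus")
  expect_equal(res$num_paths, 2L)
  # exactly one ambiguity code, at the variant column
  amb <- gregexpr("[^ACGT]", res$sequence)[[1]]
  expect_length(amb, 1L)
  expect_equal(as.integer(amb), fx$variant_col)
  expect_equal(substr(res$sequence, amb, amb),
               iupac_merge(c(substr(fx$hap1, fx$variant_col, fx$variant_col),
                             substr(fx$hap2, fx$variant_col, fx$variant_col))))

  res1 <- connect_flanks(fx$left_flank, fx$right_flank, b,
                         search_params(max_paths = 1, max_frag = 400))
  expect_equal(res1$status, "too_many_paths")
  expect_null(res1$sequence)
})

test_that("the fragment cap bounds the product and reports length_limit", {
  g <- rand_dna(2000, seed = 31)
  b <- kmer_bloom(c(g, g), k = 21, threshold = 2, size_bits = 2^22)
  lf <- substr(g, 101, 200)
  rf <- substr(g, 601, 700)
  ok <- connect_flanks(lf, rf, b, search_params(max_frag = 1000))
  expect_equal(ok$status, "unique")
  expect_identical(ok$sequence, substr(g, 101, 700))
  expect_lte(nchar(ok$sequence), 1000)

  short <- connect_flanks(lf, rf, b, search_params(max_frag = 300))
  expect_equal(short$status, "length_limit")
  tiny <- connect_flanks(lf, rf, b, search_params(max_frag = 150))
  expect_equal(tiny$status, "length_limit")  # flanks alone exceed the cap
})

test_that("a tight branch cap aborts the whole search fail-closed", {
  fx <- snp_fixture(k = 21)
  reads <- c(fx$hap1, fx$hap1, fx$hap2, fx$hap2)
  b <- kmer_bloom(reads, k = 21, threshold = 2, size_bits = 2^22)
  res <- connect_flanks(fx$left_flank, fx$right_flank, b,
                        search_params(max_paths = 5, max_branches = 1,
                                      max_frag = 400))
  expect_equal(res$status, "branch_limit")
  expect_null(res$sequence)
})

test_that("connection agrees with the exhaustive DFS oracle on random genomes", {
  withr_seed(32, {
    for (rep in 1:4) {
      G <- sample(1500:3000, 1)
      g <- rand_dna(G)
      reads <- c(g, g)
      k <- 21
      b <- kmer_bloom(reads, k = k, threshold = 2, size_bits = 2^23)
      solid <- exact_solid_kmers(reads, k, 2)
      for (j in 1:5) {
        a <- sample(1:(G - 700), 1)
        d <- sample(80:300, 1)
        start <- substr(g, a + 40 - k, a + 39)
        goal <- substr(g, a + 40 + d, a + 40 + d + k - 1)
        max_edges <- 500
        er <- enumerate_paths(b, start, goal, max_edges, 2000, 10)
        or <- exact_dbg_paths(solid, start, goal, max_edges, 10)
        if (er$status == "ok") {
          expect_false(or$truncated)
          expect_setequal(er$paths, or$paths)
        } else if (er$status == "too_many_paths") {
          expect_true(or$truncated)
        } else {
          expect_length(or$paths, 0L)
        }
      }
    }
  })
})

test_that("identical inputs give identical connections (determinism)", {
  g <- rand_dna(1500, seed = 33)
  mk <- function() {
    b <- kmer_bloom(c(g, g), k = 21, threshold = 2, size_bits = 2^22,
                    hash_seed = 5)
    connect_flanks(substr(g, 51, 150), substr(g, 401, 500), b,
                   search_params(max_frag = 800))
  }
  expect_identical(mk(), mk())
})
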