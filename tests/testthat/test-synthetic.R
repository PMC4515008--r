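test_that("genome simulation is seed-deterministic and honours GC", {
  cfg <- sim_config(genome_len = 1000, gc = 0.5, seed = 3)
  expect_identical(simulate_genome(cfg), simulate_genome(cfg))
  cfg2 <- sim_config(genome_len = 1000, gc = 0.5, seed = 4)
  expect_false(identical(as.character(simulate_genome(cfg)),
                         as.character(simulate_genome(cfg2))))

  gonly <- simulate_genome(sim_config(genome_len = 500, gc = 1, seed = 3))
  expect_true(grepl("^[GC]+$", gonly))
  at <- simulate_genome(sim_config(genome_len = 2000, gc = 0.3, seed = 3))
  gc_obs <- mean(strsplit(as.character(at), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.3), 0.05)
})

test_that("planted repeats occur as exact copies", {
  cfg <- sim_config(genome_len = 5000, repeat_spec = list(c(200, 3)),
                    seed = 8)
  g <- simulate_genome(cfg)
  reps <- attr(g, "repeats")
  expect_equal(nrow(reps), 3L)
  unit <- substr(g, reps$start[1] + 1, reps$end[1])
  hits <- gregexpr(unit, g, fixed = TRUE)[[1]]
  expect_gte(length(hits), 3L)
})

test_that("read pairs tile the genome at the requested coverage", {
  cfg <- sim_config(genome_len = 10000, coverage = 50, read_len = 100,
                    seed = 5)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(g, cfg)
  expect_length(rd$read1, 2500L)  # ceiling(50 * 10000 / 200)
  expect_length(rd$read2, 2500L)
  total <- sum(nchar(rd$read1)) + sum(nchar(rd$read2))
  expect_lt(abs(total / 10000 - 50) / 50, 0.01)

  # error-free reads are exact substrings of the genome or its complement
  grc <- revcomp(as.character(g))
  idx <- seq(1, 2500, by = 50)
  expect_true(all(vapply(rd$read1[idx], function(r)
    grepl(r, g, fixed = TRUE) || grepl(r, grc, fixed = TRUE), TRUE)))
  expect_true(all(vapply(rd$read2[idx], function(r)
    grepl(r, g, fixed = TRUE) || grepl(r, grc, fixed = TRUE), TRUE)))
  # read 2 is the reverse complement of the fragment 3' suffix
  m <- rd$meta[1, ]
  expect_identical(rd$read2[[1]],
                   revcomp(substr(g, m$start + m$frag_len - 100,
                                  m$start + m$frag_len - 1)))
  expect_error(simulate_reads(rand_dna(50, seed = 1), cfg), "shorter")
})

test_that("substitution errors hit at the configured rate", {
  cfg <- sim_config(genome_len = 5000, coverage = 20, read_len = 100,
                    sub_error_rate = 0.01, seed = 6)
  g <- simulate_genome(cfg)
  rd <- simulate_reads(g, cfg)
  truth1 <- substring(g, rd$meta$start, rd$meta$start + 99)
  obs <- strsplit(paste(rd$read1, collapse = ""), "")[[1]]
  tru <- strsplit(paste(truth1, collapse = ""), "")[[1]]
  n <- length(obs)
  expect_gte(n, 50000L)
  rate <- mean(obs != tru)
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(rate - 0.01), 3 * se)
})

test_that("gapped drafts mask truth with the configured size error", {
  base <- sim_config(genome_len = 20000, n_gaps = 8,
                     gap_len_range = c(100, 100), gap_size_error = 0.5,
                     seed = 10)
  g <- simulate_genome(base)
  gd <- make_gapped_draft(g, base)
  expect_equal(n_run_lengths(gd$draft[[1]]), rep(150L, 8))  # 100 * 1.5
  expect_equal(gd$truth$true_len, rep(100L, 8))
  expect_equal(count_gaps(gd$draft)$total, 8L)

  # size error 0: every N-run equals its true length; splice-back identity
  exact <- sim_config(genome_len = 20000, n_gaps = 8,
                      gap_len_range = c(50, 300), gap_size_error = 0,
                      seed = 10)
  gd0 <- make_gapped_draft(g, exact)
  expect_equal(n_run_lengths(gd0$draft[[1]]), gd0$truth$true_len)
  expect_identical(unname(splice_truth(gd0$draft, gd0$truth)[[1]]),
                   as.character(g))
  # splice-back also restores the genome when lengths are mis-stated
  expect_identical(unname(splice_truth(gd$draft, gd$truth)[[1]]),
                   as.character(g))
  # coordinates in the truth table are draft coordinates
  for (i in seq_len(nrow(gd$truth)))
    expect_true(grepl("^N+$", substr(gd$draft[[1]], gd$truth$start[i] + 1,
                                     gd$truth$end[i])))

  none <- make_gapped_draft(g, sim_config(genome_len = 20000, n_gaps = 0,
                                          seed = 10))
  expect_identical(unname(none$draft[[1]]), as.character(g))
  expect_equal(nrow(none$truth), 0L)

  # impossible placements are rejected with the achievable count
  expect_error(
    make_gapped_draft(rand_dna(600, seed = 2),
                      sim_config(genome_len = 600, n_gaps = 10,
                                 gap_len_range = c(100, 100), seed = 2)),
    "place")
})

test_that("truth tables round-trip through TSV", {
  cfg <- sim_config(genome_len = 5000, n_gaps = 3, seed = 12,
                    gap_len_range = c(50, 100))
  gd <- make_gapped_draft(simulate_genome(cfg), cfg)
  f <- tempfile(fileext = ".tsv")
  write_truth(gd$truth, f)
  expect_equal(read_truth(f), gd$truth)
})
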