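test_that("gap counting sees maximal N-runs only", {
  expect_equal(count_gaps(c(s = "NNAAN"))$total, 2L)  # terminal runs count
  expect_equal(count_gaps(c(s = "ACGT"))$total, 0L)
  expect_equal(count_gaps(c(s = "ACGRYT"))$total, 0L)  # ambiguity is not N
  ct <- count_gaps(c(a = "NNAAN", b = "ANNA", c = "ACGT"))
  expect_equal(ct$total, 3L)
  expect_equal(ct$per_scaffold$n_gaps, c(2L, 1L, 0L))
  expect_warning(empty <- count_gaps(character(0)), "no sequences")
  expect_equal(empty$total, 0L)
})

test_that("inserted sequences are recovered by flank anchoring", {
  ins <- extract_inserted(c(sc = "ACGTNNNACGT"), c(sc = "ACGTTTTACGT"),
                          flank_len = 4)
  expect_equal(nrow(ins), 1L)
  expect_true(ins$assessable)
  expect_equal(ins$inserted, "TTT")
  expect_true(ins$closed)

  # unfilled gap: the inserted region still contains the Ns
  un <- extract_inserted(c(sc = "ACGTNNNACGT"), c(sc = "ACGTNNNACGT"),
                         flank_len = 4)
  expect_equal(un$inserted, "NNN")
  expect_false(un$closed)

  # corrected base at the flank tip: recovered by trimming the probe;
  # brute-force expectation: "ACG" anchors at 1, right "ACGT" at 8,
  # so the inserted bases are positions 4..7 = "ATTT"
  cor <- extract_inserted(c(sc = "ACGTNNNACGT"), c(sc = "ACGATTTACGT"),
                          flank_len = 4)
  expect_true(cor$assessable)
  expect_equal(cor$inserted, "ATTT")
  expect_true(cor$closed)

  # ambiguous anchoring (flank occurs twice) is unassessable, not fatal
  amb <- extract_inserted(c(sc = "ACGCACGCNNNTTTT"),
                          c(sc = "ACGCACGCAATTTTGGACGCACGCAATTTT"),
                          flank_len = 4)
  expect_false(amb$assessable)

  expect_error(extract_inserted(c(x = "ANNA"), c(y = "AAAA")), "missing")
})

test_that("similarity scoring does not penalize ambiguity codes", {
  s <- rand_dna(100, seed = 41)
  expect_equal(seq_similarity(s, s), 100)
  expect_equal(seq_similarity("ACGR", "ACGA"), 100)  # R covers A
  expect_equal(seq_similarity("ACGT", "ACCT"), 75)
  expect_equal(seq_similarity("ACGT", "TGCA"), 25)   # only one base can align
  expect_error(seq_similarity("", "ACGT"), "empty")
  # symmetric for plain equal-length sequences
  withr_seed(42, {
    for (i in 1:10) {
      a <- rand_dna(30)
      b <- rand_dna(30)
      expect_equal(seq_similarity(a, b), seq_similarity(b, a))
    }
  })
})

test_that("evaluation summarizes closure and accuracy against truth", {
  # 10 gaps in one scaffold; fill 9 correctly, leave one open
  withr_seed(43, {
    seg <- replicate(11, rand_dna(30))
    mids <- replicate(10, rand_dna(12))
  })
  draft <- paste0(paste0(seg[1:10], "NNNNNNNNNNNN", collapse = ""), seg[11])
  filled_mids <- mids
  filled_mids[4] <- strrep("N", 12)          # gap 4 stays open
  filled <- paste0(paste0(seg[1:10], filled_mids, collapse = ""), seg[11])
  truth <- data.frame(
    scaffold_id = "sc",
    start = (seq_len(10) - 1) * 42 + 30,
    end = (seq_len(10) - 1) * 42 + 42,
    true_len = 12L, true_sequence = mids, stringsAsFactors = FALSE)

  ev <- evaluate_closure(c(sc = draft), c(sc = filled), truth,
                         flank_len = 20)
  expect_equal(ev$summary$gaps, 10L)
  expect_equal(ev$summary$closed, 9L)
  expect_equal(ev$summary$pct_success, 90)
  expect_equal(ev$summary$mean_similarity, 100)
  expect_equal(ev$summary$exact_match_fraction, 1)
  expect_equal(sum(ev$rows$closed), ev$summary$closed)  # totals match rows

  # an ambiguity code that covers the truth base still counts as exact
  filled_amb <- filled_mids
  substr(filled_amb[1], 5, 5) <- "N"
  filled2 <- paste0(paste0(seg[1:10], filled_amb, collapse = ""), seg[11])
  # N in the insert means the gap is not closed; use a non-N ambiguity code
  substr(filled_amb[1], 5, 5) <-
    iupac_merge(c(substr(mids[1], 5, 5),
                  setdiff(c("A", "C", "G", "T"), substr(mids[1], 5, 5))[1]))
  filled2 <- paste0(paste0(seg[1:10], filled_amb, collapse = ""), seg[11])
  ev2 <- evaluate_closure(c(sc = draft), c(sc = filled2), truth,
                          flank_len = 20)
  expect_equal(ev2$summary$closed, 9L)
  expect_true(ev2$rows$exact_match[1])
  expect_equal(ev2$rows$percent_similarity[1], 100)

  # no truth: only closure counts
  ev3 <- evaluate_closure(c(sc = draft), c(sc = filled), flank_len = 20)
  expect_equal(ev3$summary$closed, 9L)
  expect_true(is.na(ev3$summary$mean_similarity))

  # draft vs draft: nothing closed
  ev4 <- evaluate_closure(c(sc = draft), c(sc = draft), flank_len = 20)
  expect_equal(ev4$summary$closed, 0L)

  # truth naming a scaffold the draft lacks is an error
  bad <- truth
  bad$scaffold_id <- "other"
  expect_error(evaluate_closure(c(sc = draft), c(sc = filled), bad,
                                flank_len = 20), "other")
})
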