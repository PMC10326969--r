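test_that("canonicalize agrees with the brute-force minimal-shift oracle", {
  # the worked 11-mer: every equivalent window found by enumeration
  s <- "AATCGATCGTT"
  oc <- brute_canonical(s, 3, 7)
  got <- canonicalize(s, indel(3, 7))
  expect_identical(got$del_start, as.integer(oc$a))
  expect_identical(got$del_end, as.integer(oc$b))
  # idempotence on the representative
  expect_identical(format_indel(canonicalize(s, got)), format_indel(got))

  # insertion at the 3' end of a run repositions to its 5' end
  s2 <- "ACGTTTACGT"
  oc2 <- brute_canonical(s2, 6, 6, "T")
  got2 <- canonicalize(s2, indel(6, 6, "T"))
  expect_identical(got2$del_start, as.integer(oc2$a))
  expect_identical(got2$insert_seq, oc2$ins)
  expect_lt(got2$del_start, 6L)
})

test_that("canonicalize is idempotent and class-consistent on random edits", {
  set.seed(101)
  for (i in 1:60) {
    s <- random_seq(60)
    kind <- i %% 3
    if (kind == 0) {          # deletion
      a <- sample(0:50, 1); b <- a + sample(1:9, 1)
      ins <- ""
    } else if (kind == 1) {   # insertion
      a <- b <- sample(0:59, 1)
      ins <- random_seq(sample(1:3, 1))
    } else {                  # compound
      a <- sample(0:50, 1); b <- a + sample(1:5, 1)
      ins <- random_seq(sample(1:3, 1))
    }
    got <- canonicalize(s, indel(a, b, ins))
    oc <- brute_canonical(s, a, b, ins)
    expect_identical(got$del_start, as.integer(oc$a))
    expect_identical(got$insert_seq, oc$ins)
    # mutated sequence is preserved
    expect_identical(apply_edit(s, got$del_start, got$del_end,
                                got$insert_seq),
                     apply_edit(s, a, b, ins))
    # idempotent
    expect_identical(format_indel(canonicalize(s, got)), format_indel(got))
  }
})

test_that("mh_length equals brute-force window degeneracy minus one", {
  expect_identical(mh_length("ACGT", indel(1, 2)), 0L)
  expect_identical(mh_length("AAAA", indel(0, 2)), 2L)
  set.seed(7)
  for (i in 1:40) {
    s <- random_seq(60)
    for (j in 1:15) {
      a <- sample(0:48, 1); b <- a + sample(1:12, 1)
      expect_identical(mh_length(s, indel(a, b)) + 1L,
                       as.integer(brute_window_count(s, a, b)),
                       info = paste(s, a, b))
    }
  }
})

test_that("mh_length rejects non-deletions", {
  expect_error(mh_length("ACGTACGT", indel(2, 2, "T")), "pure deletion")
  expect_error(mh_length("ACGTACGT", indel(2, 4, "T")), "pure deletion")
})

test_that("insertion flank match reads the cut-site flanks", {
  ts <- toy_target("T", "C")
  expect_identical(insertion_flank_match(ts, indel(17, 17, "T")),
                   "DISTAL_ONLY")
  expect_identical(insertion_flank_match(ts, indel(17, 17, "C")),
                   "PROXIMAL_ONLY")
  expect_identical(insertion_flank_match(ts, indel(17, 17, "G")),
                   "NEITHER")
  tsb <- toy_target("T", "T")
  expect_identical(insertion_flank_match(tsb, indel(17, 17, "T")), "BOTH")
  # 2bp inserts compare to the 2bp flanks
  ts2 <- toy_target("T", "C")  # distal 2-mer "CT", proximal "CT"... read off
  distal2 <- substr(ts2$sequence, 16, 17)
  expect_identical(insertion_flank_match(ts2, indel(17, 17, distal2)),
                   if (distal2 == substr(ts2$sequence, 18, 19)) "BOTH"
                   else "DISTAL_ONLY")
  # longer inserts and off-cut insertions are NA
  expect_true(is.na(insertion_flank_match(ts, indel(17, 17, "TTT"))))
  expect_true(is.na(insertion_flank_match(ts, indel(3, 3, "G"))))
})

test_that("cut-adjacent insertions in a repeat run still match via shifting", {
  # insertion physically placed away from the cut but equivalent to a
  # cut-site insertion through the run
  ts <- toy_target("T", "T")  # ...TCATT -> run of T around the cut
  run_start <- 17L
  while (substr(ts$sequence, run_start, run_start) == "T")
    run_start <- run_start - 1L
  x <- indel(run_start, run_start, "T")  # 5'-most placement
  expect_identical(insertion_flank_match(ts, x), "BOTH")
})

test_that("templated insertions are detected in the 10bp flanks", {
  s <- paste0(strrep("A", 10), "GGCAT", "TTTTTGGCCX")  # X placeholder
  s <- sub("X", "A", s)
  # insert CAT right after ...GGCAT
  expect_true(templated_insertion(s, indel(15, 15, "CAT")))
  expect_false(templated_insertion(s, indel(15, 15, "GGG")))
  expect_false(templated_insertion(s, indel(15, 15, "A")))  # length-1 rule
  expect_error(templated_insertion(s, indel(2, 5)), "insert")
})

test_that("directionality follows max(L,R)/(L+R) with boundary value 1", {
  ts <- toy_target()
  cc <- ts$cut_index
  expect_identical(directionality(ts, indel(cc - 1, cc)), 1)
  expect_identical(directionality(ts, indel(cc, cc + 1)), 1)
  expect_identical(directionality(ts, indel(cc - 3, cc + 3)), 0.5)
  expect_identical(directionality(ts, indel(cc - 4, cc + 1)), 0.8)
  expect_error(directionality(ts, indel(2, 2, "A")), "pure deletion")
})

test_that("classification is total and matches the category definitions", {
  ts <- target_site("t", "AATCGATCGTAGGTACGATCGT", 0L, 10L)
  expect_identical(classify_outcome(ts, indel(2, 6))$category, "D3_9_MH")
  # 1bp deletions are never MH-split
  for (a in 3:6)
    expect_identical(classify_outcome(ts, indel(a, a + 1))$category, "D1")
  # untemplated compound goes to the catch-all
  expect_identical(classify_outcome(toy_target(), indel(15, 17, "GGG"))$category,
                   "OTHER_I")
  # totality over a full candidate space
  wt <- wide_target(3)
  cs <- enumerate_candidates(wt)
  cats <- cs$annotations$category
  expect_true(all(cats %in% outcome_categories()))
  expect_identical(length(cats), length(cs$outcomes))
})

test_that("frame status is invariant under canonicalization", {
  set.seed(11)
  wt <- wide_target(5)
  for (i in 1:30) {
    a <- sample(30:60, 1); b <- a + sample(0:6, 1)
    ins <- if (b == a || runif(1) < 0.5) random_seq(sample(1:4, 1)) else ""
    if (b == a && ins == "") next
    raw_frame <- ((nchar(ins) - (b - a)) %% 3) == 0
    expect_identical(classify_outcome(wt, indel(a, b, ins))$in_frame,
                     raw_frame)
  }
})

test_that("indel serialization round-trips and rejects malformed strings", {
  for (x in list(indel(2, 6), indel(17, 17, "T"), indel(3, 5, "GGA"))) {
    expect_identical(format_indel(parse_indel(format_indel(x))),
                     format_indel(x))
  }
  expect_error(parse_indel("DEL:17-16"), "malformed")
  expect_error(parse_indel("DEL:2"), "malformed")
  expect_error(parse_indel("INS:5:"), "malformed")
  expect_error(parse_indel("XYZ:1-2"), "malformed")
})

test_that("classified mh is capped at deletion size inside homopolymers", {
  s <- paste0(strrep("C", 13), "A", "TTT", "AGG", "ACGTACGTAAA")
  ts <- target_site("h", s, 0L, 17L)
  # deleting one T of the TTT run: window degeneracy 3 exceeds the size,
  # so the raw MH (2) is capped at the deletion size (1)
  expect_identical(mh_length(ts, indel(14, 15)), 2L)
  cl <- classify_outcome(ts, indel(14, 15))
  expect_identical(cl$mh_len, 1L)
  expect_identical(cl$category, "D1")
})
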