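test_that("block submatrix over identical subsequences is the diagonal", {
  set.seed(201)
  s <- rand_seq(60)
  b <- block_submatrix(s, s, 50, 50, fx_scheme)
  expect_equal(b$consumed_q, 40)
  expect_equal(b$consumed_g, 40)
  expect_equal(b$cigar, "40M")
  expect_equal(b$score, 200)
})

test_that("block submatrix recovers the planted insertion (CG > CAAG)", {
  set.seed(202)
  g <- paste0(rand_seq(30), "CG", rand_seq(20))
  q <- paste0(substr(g, 1, 31), "AA", substr(g, 32, 52))  # CG -> CAAG
  # corner sits 3' of the edit; block covers it
  b <- block_submatrix(q, g, 50, 48, fx_scheme)
  ops <- cigar_ops(b$cigar)
  expect_equal(ops$length[ops$op == "I"], 2)
  # oracle equality on the identical block window
  qb <- substr(q, 50 - b$consumed_q + 1, 50)
  gb <- substr(g, 48 - b$consumed_g + 1, 48)
  expect_equal(b$score, oracle_dp(qb, gb, fx_scheme, "anchored")$score)
})

test_that("block submatrix recovers the planted deletion (TC > --)", {
  set.seed(203)
  g <- paste0(rand_seq(30), "TC", rand_seq(20))
  q <- paste0(substr(g, 1, 30), substr(g, 33, 52))  # TC deleted
  b <- block_submatrix(q, g, 48, 50, fx_scheme)
  ops <- cigar_ops(b$cigar)
  expect_equal(ops$length[ops$op == "D"], 2)
})

test_that("backwards walk over identical prefixes is all matches", {
  set.seed(204)
  s <- rand_seq(50)
  a <- approx_backwards_align(s, s, 50, 50, fx_scheme)
  expect_equal(a$score, 250)
  expect_equal(a$cigar, "50M")
  expect_equal(a$query_interval, c(0, 50))
  f <- full_overlap_dp(s, s, fx_scheme)
  expect_equal(a$score, f$score)
})

test_that("a single substitution upstream of the anchor matches the full DP", {
  set.seed(205)
  g <- rand_seq(60)
  qc <- strsplit(g, "")[[1]]
  qc[40] <- sample(setdiff(c("A", "C", "G", "T"), qc[40]), 1)
  q <- paste(qc, collapse = "")
  a <- approx_backwards_align(q, g, 60, 60, fx_scheme)
  expect_equal(sum(cigar_ops(a$cigar)$op == "X"), 1)
  expect_equal(a$score, full_overlap_dp(q, g, fx_scheme)$score)
})

test_that("an isolated length-3 insertion matches the full DP", {
  set.seed(206)
  pair <- make_isolated_edit_pair(120, n_subst = 0,
                                  indel = list(type = "ins", len = 3))
  a <- approx_backwards_align(pair$q, pair$g, nchar(pair$q), nchar(pair$g),
                              fx_scheme)
  f <- full_overlap_dp(pair$q, pair$g, fx_scheme)
  expect_gt(sum(cigar_ops(a$cigar)$op == "I"), 0)
  expect_equal(a$score, f$score)
})

test_that("approximate walk equals exhaustive DP when edits are isolated", {
  set.seed(207)
  for (k in 1:60) {
    len <- sample(100:300, 1)
    indel <- if (k %% 2 == 0)
      list(type = sample(c("ins", "del"), 1), len = sample(1:10, 1))
    pair <- make_isolated_edit_pair(len, n_subst = sample(0:3, 1),
                                    indel = indel)
    a <- approx_backwards_align(pair$q, pair$g, nchar(pair$q),
                                nchar(pair$g), fx_scheme)
    f <- full_overlap_dp(pair$q, pair$g, fx_scheme)
    expect_equal(a$score, f$score)
  }
})

test_that("the approximation never beats the exhaustive DP", {
  set.seed(208)
  for (p in c(0.1, 0.3, 0.5)) {
    for (k in 1:10) {
      g <- rand_seq(150)
      q <- mutate_seq(g, p)
      a <- approx_backwards_align(q, g, 150, 150, fx_scheme)
      f <- full_overlap_dp(q, g, fx_scheme)
      expect_lte(a$score, f$score)
      expect_equal(score_ops(a, fx_scheme), a$score)
    }
  }
})

test_that("anchors out of range are rejected", {
  expect_error(approx_backwards_align("ACGT", "ACGT", 5, 4), "out of range")
  expect_error(approx_backwards_align("ACGT", "ACGT", 4, -1), "out of range")
})

test_that("QC realignment is skipped for indel-free alignments", {
  s <- rand_seq(40)
  a <- approx_backwards_align(s, s, 40, 40, fx_scheme)
  qc <- qc_realign(s, s, a, fx_scheme)
  expect_true(qc$consistent)
  expect_false(qc$invoked)
})

test_that("an isolated deletion realigns consistently in both directions", {
  set.seed(209)
  g <- rand_seq(140)
  q <- paste0(substr(g, 1, 70), substr(g, 73, 140))  # 2-base deletion
  a <- approx_backwards_align(q, g, nchar(q), nchar(g), fx_scheme)
  expect_equal(sum(cigar_ops(a$cigar)$op == "D"), 1)
  qc <- qc_realign(q, g, a, fx_scheme)
  expect_true(qc$invoked)
  expect_true(qc$consistent)
  expect_identical(qc$revised$cigar, a$cigar)
})

test_that("direction disagreement in a repeat region is flagged", {
  # tandem repeat around the indel: many equal-scoring placements, the two
  # walk directions break ties differently
  set.seed(210)
  flank5 <- rand_seq(60)
  flank3 <- rand_seq(60)
  rep_unit <- "ACGT"
  g <- paste0(flank5, strrep(rep_unit, 8), flank3)
  q <- paste0(flank5, strrep(rep_unit, 8), "ACATGCA",
              substr(flank3, 2, 60))
  a <- approx_backwards_align(q, g, nchar(q), nchar(g), fx_scheme)
  qc <- qc_realign(q, g, a, fx_scheme)
  if (qc$invoked && !qc$consistent) {
    expect_gte(qc$revised$score, min(a$score, qc$forward$score))
  }
  # construct guaranteed-disagreeing case: insertion of a repeat copy
  g2 <- paste0(flank5, strrep("AC", 12), flank3)
  q2 <- paste0(flank5, strrep("AC", 14), flank3)
  a2 <- approx_backwards_align(q2, g2, nchar(q2), nchar(g2), fx_scheme)
  qc2 <- qc_realign(q2, g2, a2, fx_scheme)
  expect_true(qc2$invoked)
  # whatever the verdict, the revised alignment is the better-scoring one
  expect_gte(qc2$revised$score, max(a2$score, qc2$forward$score) - 1e-9)
})
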