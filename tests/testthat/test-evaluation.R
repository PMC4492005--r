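make_parts_truth <- function() {
  parts <- tibble::tibble(
    query = c("r1", "r2", "r3", "r4"),
    v_allele_list = c("IGHV1-S1*01", "IGHV1-S1*02",
                      "IGHV1-S1*01,IGHV1-S2*01", NA),
    d_allele_list = c("IGHD1-S1*01", NA, "IGHD1-S2*01", "IGHD1-S1*01"),
    j_allele_list = c("IGHJ1*01", "IGHJ1*01,IGHJ2*01,IGHJ3*01",
                      "IGHJ2*01", "IGHJ1*01"),
    v_score = c(1400, 1300, 1200, NA),
    v_score_per_base = c(5, 4.6, 4.2, NA),
    d_score = c(12, NA, 9, 10),
    j_score = c(150, 140, 130, 120),
    flags = "")
  truth <- tibble::tibble(
    id = c("r1", "r2", "r3", "r4"),
    v_gene = c("IGHV1-S1", "IGHV1-S1", "IGHV1-S2", "IGHV1-S1"),
    d_gene = c("IGHD1-S1", "IGHD1-S1", "IGHD1-S1", "IGHD1-S2"),
    j_gene = c("IGHJ1", "IGHJ2", "IGHJ2", "IGHJ1"))
  list(parts = parts, truth = truth)
}

test_that("success is gene-level and honours tie sets", {
  x <- make_parts_truth()
  ev <- evaluate_success(x$parts, x$truth)
  g <- glance(ev)
  # r2: correct gene, different allele -> success; r3: truth in tie set
  expect_equal(ev$by_record$v_success, c(TRUE, TRUE, TRUE, FALSE))
  # r2 unassigned D -> failure; r3/r4 wrong gene
  expect_equal(ev$by_record$d_success, c(TRUE, FALSE, FALSE, FALSE))
  # r2: truth J in 3-way tie
  expect_equal(ev$by_record$j_success, c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(g$v_success, 0.75)
  expect_equal(g$d_success, 0.25)
  expect_equal(g$all_success, 0.25)
  expect_equal(ev$rates$n_unassigned[ev$rates$segment == "V"], 1L)
})

test_that("mismatched record ids raise an error naming offenders", {
  x <- make_parts_truth()
  bad <- x$truth
  bad$id[2] <- "zz"
  expect_error(evaluate_success(x$parts, bad), "zz")
})

test_that("all-correct partitions give rate 1 everywhere", {
  params <- simulation_params(mutation_probability = 0,
                              indels_enabled = FALSE)
  sim <- simulate_rearrangements(fx_db, params, 15, seed = 31)
  parts <- partition_sequences(sim, fx_db, fx_scheme)
  ev <- evaluate_success(parts, sim)
  g <- glance(ev)
  expect_equal(g$v_success, 1)
  expect_equal(g$j_success, 1)
})

test_that("outside-genotype rates distinguish alleles from genes", {
  parts <- tibble::tibble(
    query = c("r1", "r2"),
    v_allele_list = c("IGHV1-S1*01", "IGHV1-S1*02"),
    d_allele_list = c("IGHD1-S1*01", "IGHD1-S1*01"),
    j_allele_list = c("IGHJ1*01", "IGHJ2*01"))
  geno <- c("IGHV1-S1*01", "IGHD1-S1*01", "IGHJ1*01", "IGHJ2*01")
  out <- outside_genotype_rate(parts, geno)
  # r2's V allele *02 is outside, but its gene is inside
  expect_equal(out$allele_rate[out$segment == "V"], 0.5)
  expect_equal(out$gene_rate[out$segment == "V"], 0)
  expect_equal(out$allele_rate[out$segment == "D"], 0)
  expect_equal(out$allele_rate[out$segment == "J"], 0)
  expect_error(outside_genotype_rate(parts, character(0)))
})

test_that("a genotype excluding one used gene recovers the planted rate", {
  params <- simulation_params(mutation_probability = 0,
                              indels_enabled = FALSE)
  sim <- simulate_rearrangements(fx_db, params, 40, seed = 32)
  parts <- partition_sequences(sim, fx_db, fx_scheme)
  excluded <- fx_db$gene[fx_db$segment == "V"][1]
  geno <- fx_db$name[fx_db$gene != excluded]
  out <- outside_genotype_rate(parts, geno)
  planted <- mean(sim$v_gene == excluded)
  expect_equal(out$gene_rate[out$segment == "V"], planted)
})

test_that("score differences vanish at zero mutation", {
  params <- simulation_params(mutation_probability = 0,
                              indels_enabled = FALSE)
  sim <- simulate_rearrangements(fx_db, params, 10, seed = 33)
  diffs <- score_difference(sim, fx_db, fx_scheme)
  expect_true(all(diffs$diff == 0))
})

test_that("a block spanning both sequences degenerates to exhaustive DP", {
  # with block_size >= sequence length the walk solves one all-covering
  # block, i.e. the full anchored (corner-pinned) DP; compare against the
  # anchored engine run on the reversed pair, which computes exactly that
  # dense mutation in the middle third defeats a 40-wide block but not an
  # all-covering one; exact-matching ends make the pinned and free-ended
  # optima coincide, so the giant-block walk must equal full overlap DP
  set.seed(34)
  big <- scoring_scheme(block_size = 400, step_back = 10)
  for (k in 1:10) {
    g <- rand_seq(180)
    q <- paste0(substr(g, 1, 60), mutate_seq(substr(g, 61, 120), 0.3),
                substr(g, 121, 180))
    a <- approx_backwards_align(q, g, nchar(q), nchar(g), big)
    f <- full_overlap_dp(q, g, fx_scheme)
    expect_equal(a$score, f$score)
  }
})

test_that("a motif at the query 5' terminus yields an empty-prefix diff", {
  v <- fx_v(1)
  anchor <- fx_db$motif_anchor[fx_db$segment == "V"][1]
  q <- paste0(substr(v, anchor + 1, nchar(v)), "GCA", fx_j(1))
  diffs <- score_difference(q, fx_db, fx_scheme)
  expect_equal(diffs$diff, 0)
  expect_equal(diffs$approx_score, 0)
})

test_that("success rates trend downwards with the mutation probability", {
  probs <- c(0, 0.3, 0.6, 0.85)
  v <- j <- numeric(length(probs))
  for (k in seq_along(probs)) {
    params <- simulation_params(mutation_probability = probs[k],
                                indels_enabled = TRUE)
    sim <- simulate_rearrangements(fx_db, params, 50, seed = 36 + k)
    parts <- partition_sequences(sim, fx_db, fx_scheme)
    g <- glance(evaluate_success(parts, sim))
    v[k] <- g$v_success; j[k] <- g$j_success
  }
  expect_lt(stats::cor(probs, v, method = "spearman"), 0)
  expect_lt(stats::cor(probs, j, method = "spearman"), 0)
  expect_lt(v[4], v[1])
  expect_lt(j[4], j[1])
})

test_that("score differences are never positive and peak at zero", {
  params <- simulation_params(mutation_probability = 0.2,
                              indels_enabled = FALSE)
  sim <- simulate_rearrangements(fx_db, params, 40, seed = 35)
  diffs <- score_difference(sim, fx_db, fx_scheme)
  d <- diffs$diff[!is.na(diffs$diff)]
  expect_true(all(d <= 0))
  tab <- table(d)
  expect_equal(names(tab)[which.max(tab)], "0")
})
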