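test_that("find_motif reports exact and single-mutation hits", {
  hits <- find_motif("NNNNNTATTACTGTNN", "TATTACTGT")
  expect_equal(hits$position, 5L)
  expect_equal(hits$n_mutations, 0L)
  # mutated motif found only when one mutation is allowed
  m <- find_motif("AAAAATATTACTGGAAAAA", "TATTACTGT", max_mutations = 1)
  expect_equal(m$position, 5L)
  expect_equal(m$n_mutations, 1L)
  expect_equal(nrow(find_motif("AAAAATATTACTGGAAAAA", "TATTACTGT")), 0)
  expect_equal(nrow(find_motif("ACGTACGTACGT", "TATTACTGT", 0)), 0)
  # exact hits suppress mutated ones
  both <- find_motif("TATTACTGTAAATATTACTGG", "TATTACTGT", 1)
  expect_equal(both$position, 0L)
})

test_that("clean rearrangements recover V and J genes and N regions", {
  params <- simulation_params(mutation_probability = 0,
                              indels_enabled = FALSE)
  sim <- simulate_rearrangements(fx_db, params, 30, seed = 21)
  parts <- partition_sequences(sim, fx_db, fx_scheme)
  truth_v <- sim$v_gene; truth_j <- sim$j_gene
  expect_true(all(mapply(function(tv, al)
    tv %in% vdjpartition:::strip_allele(strsplit(al, ",")[[1]]),
    truth_v, parts$v_allele_list)))
  expect_true(all(mapply(function(tj, al)
    tj %in% vdjpartition:::strip_allele(strsplit(al, ",")[[1]]),
    truth_j, parts$j_allele_list)))
  # V end called exactly on the truth boundary for most records, and the
  # VD junction sequence matches the simulator ground truth when it is
  # the V end may overshoot by a few bases when excised germline tail
  # bases chance-match the junction (max-anywhere end rule); it never
  # undershoots on clean sequences
  dv <- parts$v_end - sim$v_end
  expect_gte(mean(dv == 0), 0.5)
  expect_true(all(dv >= 0 & dv <= 8))
  exact <- which(parts$v_end == sim$v_end & parts$j_start == sim$j_start &
                   !is.na(parts$d_start) & parts$d_start == sim$d_start &
                   parts$d_end == sim$d_end)
  for (i in exact) {
    expect_equal(parts$vd_n_seq[i],
                 substr(sim$sequence[i], sim$vd_start[i] + 1,
                        sim$vd_end[i]))
    expect_equal(parts$dj_n_seq[i],
                 substr(sim$sequence[i], sim$dj_start[i] + 1,
                        sim$dj_end[i]))
  }
})

test_that("a planted V insertion is recovered at its position", {
  set.seed(22)
  found <- 0L
  params <- simulation_params(mutation_probability = 0,
                              indels_enabled = TRUE)
  sim <- simulate_rearrangements(fx_db, params, 20, seed = 22)
  one_ins <- which(sim$n_indels == 1 &
                     vapply(sim$indels, function(x) x$type[1] == "ins",
                            TRUE))
  for (i in one_ins) {
    p <- partition_sequence(sim$sequence[i], fx_db, fx_scheme)
    expect_equal(p$v$gene, sim$v_gene[i])
    ops <- tidy(p$v$alignment5)
    ins <- dplyr::filter(ops, op == "I")
    if (nrow(ins) == 1 && ins$length == sim$indels[[i]]$length[1]) {
      found <- found + 1L
      # planted insert position (alignment may shift within equal bases)
      expect_lt(abs(ins$q_pos - sim$indels[[i]]$pos[1]), 6)
    }
  }
  expect_gt(found, length(one_ins) / 2)
})

test_that("a bare V germline gets no J and carries the fallback flag", {
  p <- partition_sequence(fx_v(1), fx_db, fx_scheme, query_name = "bareV")
  expect_equal(p$v$gene, fx_db$gene[fx_db$segment == "V"][1])
  expect_null(p$j)
  expect_true("fallback_j" %in% p$flags)
  expect_null(p$d)
})

test_that("two motif mutations are rescued by the anchor-gene rung", {
  set.seed(23)
  v <- fx_v(2)
  anchor <- fx_db$motif_anchor[fx_db$segment == "V"][2]
  chars <- strsplit(v, "")[[1]]
  # mutate motif bases 2 and 6 (invisible to the 1-mutation search)
  for (off in c(1, 5)) {
    chars[anchor + 1 + off] <-
      sample(setdiff(c("A", "C", "G", "T"), chars[anchor + 1 + off]), 1)
  }
  q <- paste0(paste(chars, collapse = ""), "GGCAT", fx_j(1))
  p <- partition_sequence(q, fx_db, fx_scheme)
  expect_true(any(c("v_motif_inferred", "fallback_v") %in% p$flags))
  expect_equal(p$v$gene, fx_db$gene[fx_db$segment == "V"][2])
})

test_that("a deletion through the motif falls back to exhaustive DP", {
  v <- fx_v(3)
  anchor <- fx_db$motif_anchor[fx_db$segment == "V"][3]
  # delete the central 5 bases of the motif
  q <- paste0(substr(v, 1, anchor + 2), substr(v, anchor + 8, nchar(v)),
              "ACGGA", fx_j(2))
  p <- partition_sequence(q, fx_db, fx_scheme)
  expect_true(any(c("fallback_v", "v_motif_inferred") %in% p$flags))
  expect_equal(p$v$gene, fx_db$gene[fx_db$segment == "V"][3])
})

test_that("well-formed queries never invoke the ladder", {
  params <- simulation_params(mutation_probability = 0,
                              indels_enabled = FALSE)
  sim <- simulate_rearrangements(fx_db, params, 10, seed = 24)
  parts <- partition_sequences(sim, fx_db, fx_scheme)
  expect_false(any(grepl("fallback_v|v_motif_inferred", parts$flags)))
  expect_true(all(parts$v_score_per_base >= 3.1))
})

test_that("segment and N-region intervals tile without overlap", {
  params <- simulation_params(mutation_probability = 0.05,
                              indels_enabled = TRUE)
  sim <- simulate_rearrangements(fx_db, params, 25, seed = 25)
  parts <- partition_sequences(sim, fx_db, fx_scheme)
  for (i in seq_len(nrow(parts))) {
    r <- parts[i, ]
    if (is.na(r$v_end) || is.na(r$j_start)) next
    if (!is.na(r$d_start)) {
      expect_true(r$v_end <= r$d_start)
      expect_true(r$d_start <= r$d_end)
      expect_true(r$d_end <= r$j_start)
      expect_equal(nchar(r$vd_n_seq), r$d_start - r$v_end)
      expect_equal(nchar(r$dj_n_seq), r$j_start - r$d_end)
    } else {
      expect_equal(nchar(r$vd_n_seq), r$j_start - r$v_end)
      expect_equal(nchar(r$dj_n_seq), 0L)
    }
  }
})

test_that("unrelated decoy germlines never change an existing best score", {
  params <- simulation_params(mutation_probability = 0.05,
                              indels_enabled = FALSE)
  sim <- simulate_rearrangements(fx_db, params, 8, seed = 26)
  base_parts <- partition_sequences(sim, fx_db, fx_scheme)
  decoys <- make_fixture_db(2, 1, 1, seed = 99)
  decoys$name <- sub("IGH([VDJ])1?-?S?", "IGH\\19-X", decoys$name)
  decoys$gene <- vdjpartition:::strip_allele(decoys$name)
  combined <- vdjpartition:::new_germline_db(
    dplyr::bind_rows(tibble::as_tibble(fx_db), tibble::as_tibble(decoys)))
  new_parts <- partition_sequences(sim, combined, fx_scheme)
  expect_equal(new_parts$v_score, base_parts$v_score)
  expect_equal(new_parts$j_score, base_parts$j_score)
})

test_that("degenerate inputs are rejected cleanly", {
  expect_error(partition_sequence("ACGT", fx_db), "shorter than")
  expect_error(partition_sequence(strrep("Z", 30), fx_db), "outside")
  only_dj <- vdjpartition:::new_germline_db(
    dplyr::filter(tibble::as_tibble(fx_db), segment != "V"))
  expect_error(partition_sequence(paste0(rand_seq(100), "TATTACTGT",
                                         rand_seq(30)), only_dj),
               "no V genes")
})

test_that("reverse-strand queries are recovered when enabled", {
  params <- simulation_params(mutation_probability = 0,
                              indels_enabled = FALSE)
  sim <- simulate_rearrangements(fx_db, params, 3, seed = 27)
  rc <- vdjpartition:::revcomp(sim$sequence[1])
  p <- partition_sequence(rc, fx_db, fx_scheme,
                          partition_options(try_reverse = TRUE))
  expect_equal(p$strand, "-")
  expect_equal(p$v$gene, sim$v_gene[1])
})
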