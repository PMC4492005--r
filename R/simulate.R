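#' Simulation parameters
#'
#' Defaults follow the simulation model for artificial VDJ rearrangements:
#' excision amounts at each germline terminus and the number of N-addition
#' nucleotides at each junction are drawn from normal distributions (rounded,
#' clipped at zero); every base is substituted independently with
#' `mutation_probability`; the number of indels follows
#' \eqn{P(n) = c n e^{-s(n-1)}} with \eqn{s} = `indel_rate_scale` and
#' \eqn{c = (1 - e^{-s})^2}, which places ~90% of the mass on a single
#' indel for s = 3; indel lengths are zero-truncated Poisson with mean
#' parameter `indel_mean_length`.
#'
#' @param mutation_probability Per-base substitution probability in
#'   \[0, 0.95\].
#' @param excision Named list of `c(mu, sigma)` pairs for the six germline
#'   termini: `v5`, `d5`, `j5` (5' ends) and `v3`, `d3`, `j3` (3' ends).
#' @param junction Named list of `c(mu, sigma)` pairs `vd` and `dj` for the
#'   N-addition lengths.
#' @param indel_rate_scale Exponent constant s of the indel-count
#'   distribution. Default 3.
#' @param indel_mean_length Poisson mean of the (zero-truncated) indel length
#'   distribution. Default 4.
#' @param indels_enabled Plant indels. Default TRUE.
#' @param indel_region `"v"` (default) restricts indel positions to the V
#'   segment; `"whole"` allows them anywhere in the sequence.
#' @param seed Optional integer seed recorded in the parameter set.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(mutation_probability = 0,
                              excision = list(v5 = c(8, 2), d5 = c(5, 1),
                                              j5 = c(7, 2), v3 = c(2, 1),
                                              d3 = c(2, 1), j3 = c(13, 3)),
                              junction = list(vd = c(2, 1), dj = c(2, 1)),
                              indel_rate_scale = 3,
                              indel_mean_length = 4,
                              indels_enabled = TRUE,
                              indel_region = c("v", "whole"),
                              seed = NULL) {
  indel_region <- match.arg(indel_region)
  stopifnot(mutation_probability >= 0, mutation_probability <= 0.95)
  stopifnot(setequal(names(excision), c("v5", "d5", "j5", "v3", "d3", "j3")))
  stopifnot(setequal(names(junction), c("vd", "dj")))
  for (p in c(excision, junction)) {
    stopifnot(length(p) == 2, p[2] >= 0)
  }
  structure(
    list(mutation_probability = mutation_probability, excision = excision,
         junction = junction, indel_rate_scale = indel_rate_scale,
         indel_mean_length = indel_mean_length,
         indels_enabled = indels_enabled, indel_region = indel_region,
         seed = seed),
    class = "simulation_params")
}

#' Sample the number of indels per sequence
#'
#' Draws from \eqn{P(n) = c n e^{-s(n-1)}}, \eqn{n \ge 1}, with
#' normalization \eqn{c = (1-e^{-s})^2} (so that
#' \eqn{\sum_n n x^{n-1} = 1/(1-x)^2} with \eqn{x = e^{-s}}). With the
#' default s = 3, \eqn{P(1) = (1-e^{-3})^2 \approx 0.9029}.
#'
#' @param n Number of draws.
#' @param rate_scale Exponent constant s. Default 3.
#' @return Integer vector of counts >= 1.
#' @export
sample_indel_count <- function(n = 1, rate_scale = 3) {
  support <- 1:60
  x <- exp(-rate_scale)
  pmf <- (1 - x)^2 * support * x^(support - 1)
  sample(support, n, replace = TRUE, prob = pmf)
}

#' Sample an indel length (zero-truncated Poisson)
#'
#' Poisson draws with the given mean parameter; zeros are rejected and
#' redrawn. The mean of the returned values is
#' \eqn{\lambda / (1 - e^{-\lambda})}.
#'
#' @param n Number of draws.
#' @param mean Poisson mean parameter. Default 4.
#' @return Integer vector of lengths >= 1.
#' @export
sample_indel_length <- function(n = 1, mean = 4) {
  out <- rpois(n, mean)
  while (any(out == 0)) {
    zero <- out == 0
    out[zero] <- rpois(sum(zero), mean)
  }
  out
}

draw_count <- function(mu_sigma) {
  as.integer(round(max(0, rnorm(1, mu_sigma[1], mu_sigma[2]))))
}

substitute_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1)
}

#' Simulate artificial VDJ rearrangements with ground truth
#'
#' Each record uniformly picks one V, D and J allele, excises a random
#' number of bases from each germline terminus, inserts uniform-random
#' N-addition bases at the VD and DJ junctions, applies iid per-base
#' substitution (never reproducing the original base), and optionally plants
#' indels (insertion or deletion with probability 1/2 each) whose positions
#' default to the V segment. The ground truth carried with every record is
#' sufficient to reconstruct the final sequence byte-exactly (see
#' [reconstruct_rearrangement()]).
#'
#' @param db A [germline_db] with at least one gene per class.
#' @param params A [simulation_params()].
#' @param n Number of rearrangements.
#' @param seed Integer seed (defaults to `params$seed`); the output is fully
#'   deterministic per seed.
#' @return A tibble with one row per record: `id`, `sequence`, the chosen
#'   allele and gene names, the segment and N-region intervals in final
#'   0-based half-open coordinates, `n_substitutions`, and list-columns
#'   `substitutions` (position in pre-indel coordinates, new base),
#'   `indels` (type, application-time position, length, inserted bases) and
#'   `truth` (everything needed for reconstruction).
#' @export
simulate_rearrangements <- function(db, params = simulation_params(), n,
                                    seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  vg <- dplyr::filter(db, .data$segment == "V")
  dg <- dplyr::filter(db, .data$segment == "D")
  jg <- dplyr::filter(db, .data$segment == "J")
  if (nrow(vg) == 0 || nrow(dg) == 0 || nrow(jg) == 0)
    stop("germline database must contain V, D and J genes", call. = FALSE)
  with_seed(seed, function() {
    rows <- vector("list", n)
    for (r in seq_len(n)) {
      rows[[r]] <- simulate_one(vg, dg, jg, params, r)
    }
    dplyr::bind_rows(rows)
  })
}

simulate_one <- function(vg, dg, jg, params, r) {
  vi <- sample(nrow(vg), 1); di <- sample(nrow(dg), 1)
  ji <- sample(nrow(jg), 1)
  vseq <- vg$sequence[vi]; dseq <- dg$sequence[di]; jseq <- jg$sequence[ji]

  clip2 <- function(len, e5, e3) {
    clipped <- FALSE
    if (e5 > len - 1) { e5 <- len - 1L; clipped <- TRUE }
    if (e3 > len - 1 - e5) { e3 <- len - 1L - e5; clipped <- TRUE }
    list(e5 = as.integer(e5), e3 = as.integer(e3), clipped = clipped)
  }
  ex <- params$excision
  ev <- clip2(nchar(vseq), draw_count(ex$v5), draw_count(ex$v3))
  ed <- clip2(nchar(dseq), draw_count(ex$d5), draw_count(ex$d3))
  ej <- clip2(nchar(jseq), draw_count(ex$j5), draw_count(ex$j3))
  clipped <- ev$clipped || ed$clipped || ej$clipped

  vpart <- substr(vseq, ev$e5 + 1, nchar(vseq) - ev$e3)
  dpart <- substr(dseq, ed$e5 + 1, nchar(dseq) - ed$e3)
  jpart <- substr(jseq, ej$e5 + 1, nchar(jseq) - ej$e3)
  n_vd <- draw_count(params$junction$vd)
  n_dj <- draw_count(params$junction$dj)
  vd_seq <- rand_dna(n_vd)
  dj_seq <- rand_dna(n_dj)

  s0 <- paste0(vpart, vd_seq, dpart, dj_seq, jpart)
  lv <- nchar(vpart); ld <- nchar(dpart); lj <- nchar(jpart)
  # pre-indel interval boundaries (0-based half-open)
  b <- cumsum(c(lv, n_vd, ld, n_dj, lj))
  iv <- c(0L, b[1]); ivd <- c(b[1], b[2]); id_ <- c(b[2], b[3])
  idj <- c(b[3], b[4]); ij <- c(b[4], b[5])

  # substitutions (uniform over the whole rearrangement)
  chars <- strsplit(s0, "")[[1]]
  hit <- which(runif(length(chars)) < params$mutation_probability)
  new_bases <- vapply(chars[hit], substitute_base, "", USE.NAMES = FALSE)
  chars[hit] <- new_bases
  s1 <- paste(chars, collapse = "")
  subs <- tibble(pos = as.integer(hit - 1L), base = new_bases)

  # indels
  seq_cur <- s1
  bounds <- c(iv[2], ivd[2], id_[2], idj[2], ij[2]) # shifting boundaries
  indels <- tibble(type = character(), pos = integer(), length = integer(),
                   bases = character())
  if (params$indels_enabled) {
    n_ind <- sample_indel_count(1, params$indel_rate_scale)
    for (k in seq_len(n_ind)) {
      type <- sample(c("ins", "del"), 1)
      len <- sample_indel_length(1, params$indel_mean_length)
      lo <- 0L
      hi <- if (params$indel_region == "v") bounds[1] else nchar(seq_cur)
      if (hi <= lo) break # V segment fully eroded; nowhere to plant
      pick_pos <- function() { # sample() misbehaves on length-1 ranges
        if (hi - lo == 1L) lo else sample(lo:(hi - 1L), 1)
      }
      if (type == "ins") {
        pos <- pick_pos() + 1L # insert after >=1 segment base
        ins <- rand_dna(len)
        seq_cur <- paste0(substr(seq_cur, 1, pos), ins,
                          substr(seq_cur, pos + 1, nchar(seq_cur)))
        bounds <- ifelse(bounds >= pos, bounds + len, bounds)
        indels <- dplyr::bind_rows(indels, tibble(
          type = "ins", pos = as.integer(pos), length = as.integer(len),
          bases = ins))
      } else {
        pos <- pick_pos()
        len_eff <- min(len, hi - pos)
        seq_cur <- paste0(substr(seq_cur, 1, pos),
                          substr(seq_cur, pos + len_eff + 1,
                                 nchar(seq_cur)))
        bounds <- ifelse(bounds >= pos + len_eff, bounds - len_eff,
                         ifelse(bounds > pos, pos, bounds))
        indels <- dplyr::bind_rows(indels, tibble(
          type = "del", pos = as.integer(pos),
          length = as.integer(len_eff), bases = ""))
      }
    }
  }

  truth_list <- list(
    v_name = vg$name[vi], d_name = dg$name[di], j_name = jg$name[ji],
    e_v5 = ev$e5, e_v3 = ev$e3, e_d5 = ed$e5, e_d3 = ed$e3,
    e_j5 = ej$e5, e_j3 = ej$e3,
    vd_seq = vd_seq, dj_seq = dj_seq,
    substitutions = subs, indels = indels)

  tibble(
    id = sprintf("sim%06d", r),
    sequence = seq_cur,
    v_name = vg$name[vi], d_name = dg$name[di], j_name = jg$name[ji],
    v_gene = vg$gene[vi], d_gene = dg$gene[di], j_gene = jg$gene[ji],
    v_start = 0L, v_end = as.integer(bounds[1]),
    vd_start = as.integer(bounds[1]), vd_end = as.integer(bounds[2]),
    d_start = as.integer(bounds[2]), d_end = as.integer(bounds[3]),
    dj_start = as.integer(bounds[3]), dj_end = as.integer(bounds[4]),
    j_start = as.integer(bounds[4]), j_end = as.integer(bounds[5]),
    n_substitutions = nrow(subs),
    n_indels = nrow(indels),
    excision_clipped = clipped,
    substitutions = list(subs),
    indels = list(indels),
    truth = list(truth_list))
}

#' Reconstruct a simulated sequence from its ground truth
#'
#' Re-applies the recorded excisions, N additions, substitutions and indels
#' to the named germline alleles; the result must equal the record's
#' `sequence` byte-exactly.
#'
#' @param record One row of the tibble from [simulate_rearrangements()].
#' @param db The [germline_db] used for the simulation.
#' @return The reconstructed sequence string.
#' @export
reconstruct_rearrangement <- function(record, db) {
  tr <- record$truth[[1]]
  gseq <- function(nm) db$sequence[match(nm, db$name)]
  vseq <- gseq(tr$v_name); dseq <- gseq(tr$d_name); jseq <- gseq(tr$j_name)
  s0 <- paste0(
    substr(vseq, tr$e_v5 + 1, nchar(vseq) - tr$e_v3), tr$vd_seq,
    substr(dseq, tr$e_d5 + 1, nchar(dseq) - tr$e_d3), tr$dj_seq,
    substr(jseq, tr$e_j5 + 1, nchar(jseq) - tr$e_j3))
  chars <- strsplit(s0, "")[[1]]
  if (nrow(tr$substitutions) > 0) {
    chars[tr$substitutions$pos + 1] <- tr$substitutions$base
  }
  s <- paste(chars, collapse = "")
  ind <- tr$indels
  for (k in seq_len(nrow(ind))) {
    if (ind$type[k] == "ins") {
      s <- paste0(substr(s, 1, ind$pos[k]), ind$bases[k],
                  substr(s, ind$pos[k] + 1, nchar(s)))
    } else {
      s <- paste0(substr(s, 1, ind$pos[k]),
                  substr(s, ind$pos[k] + ind$length[k] + 1, nchar(s)))
    }
  }
  s
}

#' Write simulated records as FASTA plus a truth table
#'
#' @param sim Tibble from [simulate_rearrangements()].
#' @param fasta_path,truth_path Output paths.
#' @return `truth_path`, invisibly.
#' @export
write_simulation <- function(sim, fasta_path, truth_path) {
  set <- Biostrings::BStringSet(setNames(sim$sequence, sim$id))
  Biostrings::writeXStringSet(set, fasta_path, width = 70)
  flat <- sim |>
    dplyr::mutate(
      substitution_list = purrr::map_chr(
        .data$substitutions,
        ~ paste(.x$pos, .x$base, sep = ":", collapse = ";")),
      indel_list = purrr::map_chr(
        .data$indels,
        ~ paste(.x$type, .x$pos, .x$length, .x$bases, sep = ":",
                collapse = ";"))) |>
    dplyr::select(-"substitutions", -"indels", -"truth")
  readr::write_tsv(flat, truth_path)
  invisible(truth_path)
}

#' Read a truth table written by [write_simulation()]
#'
#' @param truth_path Path to the TSV.
#' @return A tibble.
#' @export
read_truth <- function(truth_path) {
  readr::read_tsv(truth_path, show_col_types = FALSE)
}
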