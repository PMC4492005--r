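#' Gene-level assignment success rates
#'
#' A record's segment assignment is a success when the true gene
#' (allele-stripped) appears in the tie set of best germlines reported for
#' that segment; the exact allele is not required. A record with no reported
#' assignment for a segment counts as a failure. "All" success requires V, D
#' and J simultaneously.
#'
#' V scores are normalised per aligned base for score binning (bin width
#' 0.1); D and J use raw scores (bin width 1). The `shown` column marks bins
#' with more than 100 records, the conventional display cut-off; it affects
#' reporting only, not computation.
#'
#' @param partitions Tibble from [partition_sequences()].
#' @param truth Tibble from [simulate_rearrangements()] (or a truth TSV read
#'   back with [read_truth()]), with `id` and `v_gene`/`d_gene`/`j_gene`
#'   columns.
#' @return A `vdj_evaluation` list: `rates` (per-segment tibble),
#'   `score_bins` (success vs score-bin tibble), `by_record`, `n_records`.
#' @export
evaluate_success <- function(partitions, truth) {
  missing_ids <- setdiff(truth$id, partitions$query)
  extra_ids <- setdiff(partitions$query, truth$id)
  if (length(missing_ids) > 0 || length(extra_ids) > 0)
    stop("record ids do not match; offenders: ",
         paste(head(c(missing_ids, extra_ids), 10), collapse = ", "),
         call. = FALSE)
  joined <- dplyr::inner_join(
    partitions,
    dplyr::select(truth, "id", truth_v = "v_gene", truth_d = "d_gene",
                  truth_j = "j_gene"),
    by = c(query = "id"))

  in_ties <- function(truth_gene, allele_list) {
    if (is.na(allele_list)) return(FALSE)
    genes <- strip_allele(strsplit(allele_list, ",", fixed = TRUE)[[1]])
    truth_gene %in% genes
  }
  by_record <- joined |>
    dplyr::mutate(
      v_success = purrr::map2_lgl(.data$truth_v, .data$v_allele_list,
                                  in_ties),
      d_success = purrr::map2_lgl(.data$truth_d, .data$d_allele_list,
                                  in_ties),
      j_success = purrr::map2_lgl(.data$truth_j, .data$j_allele_list,
                                  in_ties),
      all_success = .data$v_success & .data$d_success & .data$j_success,
      v_bin = floor(.data$v_score_per_base / 0.1) * 0.1,
      d_bin = floor(.data$d_score),
      j_bin = floor(.data$j_score)) |>
    dplyr::select("query", dplyr::starts_with("truth_"),
                  dplyr::ends_with("_success"), dplyr::ends_with("_bin"),
                  "v_score", "v_score_per_base", "d_score", "j_score",
                  "flags")

  rates <- tibble(
    segment = c("V", "D", "J", "all"),
    n = nrow(by_record),
    n_success = c(sum(by_record$v_success), sum(by_record$d_success),
                  sum(by_record$j_success), sum(by_record$all_success)),
    n_unassigned = c(sum(is.na(joined$v_allele_list)),
                     sum(is.na(joined$d_allele_list)),
                     sum(is.na(joined$j_allele_list)), NA_integer_)) |>
    dplyr::mutate(rate = .data$n_success / .data$n)

  bin_table <- function(bin_col, success_col, segment) {
    by_record |>
      dplyr::filter(!is.na(.data[[bin_col]])) |>
      dplyr::group_by(bin = .data[[bin_col]]) |>
      dplyr::summarise(n = dplyr::n(),
                       success_rate = mean(.data[[success_col]]),
                       .groups = "drop") |>
      dplyr::mutate(segment = segment, shown = .data$n > 100) |>
      dplyr::select("segment", "bin", "n", "success_rate", "shown")
  }
  score_bins <- dplyr::bind_rows(
    bin_table("v_bin", "v_success", "V"),
    bin_table("d_bin", "d_success", "D"),
    bin_table("j_bin", "j_success", "J"))

  structure(list(rates = rates, score_bins = score_bins,
                 by_record = by_record, n_records = nrow(by_record)),
            class = "vdj_evaluation")
}

#' @export
print.vdj_evaluation <- function(x, ...) {
  cat(sprintf("<vdj_evaluation: %d records>\n", x$n_records))
  print(x$rates)
  invisible(x)
}

#' @describeIn evaluate_success One-row summary of the success rates.
#' @param x A `vdj_evaluation`.
#' @param ... Unused.
#' @export
glance.vdj_evaluation <- function(x, ...) {
  r <- setNames(x$rates$rate, x$rates$segment)
  tibble(v_success = r[["V"]], d_success = r[["D"]], j_success = r[["J"]],
         all_success = r[["all"]], n_records = x$n_records)
}

#' Approximate-vs-exhaustive score differences
#'
#' For each query, finds the best motif-anchored V germline with the
#' approximate backwards algorithm and re-aligns the identical anchored
#' prefix pair with exhaustive overlap DP; the reported difference is
#' (approximate score - overlap DP score), which is <= 0 by construction
#' since the approximation explores a subset of alignment paths. Queries
#' in which no V-motif anchoring is found are skipped.
#'
#' @param queries Character vector of sequences, or a tibble with `sequence`
#'   (and optionally `id`).
#' @param db A [germline_db].
#' @param scheme A [scoring_scheme()].
#' @return A tibble with `id`, `germline`, `approx_score`, `full_score`,
#'   `diff`; skipped queries carry `NA`.
#' @param max_motif_mutations Motif-search tolerance used for anchoring,
#'   mirroring the partitioning pipeline (exact occurrences first, then
#'   single-substitution variants). Default 1.
#' @export
score_difference <- function(queries, db, scheme = scoring_scheme(),
                             max_motif_mutations = 1) {
  scheme <- as_scheme(scheme)
  if (is.data.frame(queries)) {
    ids <- if ("id" %in% names(queries)) queries$id
           else paste0("query", seq_len(nrow(queries)))
    seqs <- queries$sequence
  } else {
    ids <- if (!is.null(names(queries))) names(queries)
           else paste0("query", seq_along(queries))
    seqs <- queries
  }
  vg <- dplyr::filter(db, .data$segment == "V", !is.na(.data$motif_anchor))
  rows <- purrr::map(seq_along(seqs), function(i) {
    q <- clean_dna(seqs[i], "query")
    hits <- find_motif(q, V_MOTIF, max_motif_mutations)
    if (nrow(hits) == 0 || nrow(vg) == 0) {
      return(tibble(id = ids[i], germline = NA_character_,
                    approx_score = NA_real_, full_score = NA_real_,
                    diff = NA_real_))
    }
    tab <- anchored_v_table(q, vg, hits$position, scheme)
    best <- pick_best(tab)[1, ]
    # an anchor at either 5' terminus leaves an empty prefix pair, whose
    # alignment (approximate or exhaustive) is empty with score 0
    full_score <- if (best$p > 0 && best$g_anchor > 0) {
      full_overlap_dp(substr(q, 1, best$p),
                      substr(vg$sequence[match(best$name, vg$name)],
                             1, best$g_anchor),
                      scheme, best$name)$score
    } else 0
    tibble(id = ids[i], germline = best$name,
           approx_score = best$score5, full_score = full_score,
           diff = best$score5 - full_score)
  })
  dplyr::bind_rows(rows)
}

#' Fraction of assignments outside a predetermined genotype
#'
#' For each segment, the fraction of records whose primary assignment (the
#' lexicographically smallest allele in the tie set) is an allele -- or, at
#' gene level, a gene -- absent from the given genotype. Records with no
#' assignment for a segment are excluded from that segment's denominator.
#' Whether sub-threshold D assignments are included is controlled upstream by
#' [partition_options()]`$all_d`.
#'
#' @param partitions Tibble from [partition_sequences()].
#' @param genotype Non-empty character vector of allele names.
#' @return A tibble with `segment`, `n`, `allele_rate`, `gene_rate`.
#' @export
outside_genotype_rate <- function(partitions, genotype) {
  stopifnot(length(genotype) > 0)
  geno_genes <- unique(strip_allele(genotype))
  one <- function(allele_list, segment) {
    assigned <- !is.na(allele_list)
    primary <- purrr::map_chr(allele_list[assigned], function(al) {
      sort(strsplit(al, ",", fixed = TRUE)[[1]])[1]
    })
    tibble(segment = segment, n = sum(assigned),
           allele_rate = if (sum(assigned) == 0) NA_real_
                         else mean(!(primary %in% genotype)),
           gene_rate = if (sum(assigned) == 0) NA_real_
                       else mean(!(strip_allele(primary) %in% geno_genes)))
  }
  dplyr::bind_rows(
    one(partitions$v_allele_list, "V"),
    one(partitions$d_allele_list, "D"),
    one(partitions$j_allele_list, "J"))
}
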