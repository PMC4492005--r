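#' Locate a conserved motif, optionally tolerating one mutation
#'
#' Returns all exact occurrences of `motif` in `seq`; if there are none and
#' `max_mutations = 1`, all occurrences of any single-substitution variant
#' are returned instead. `N` in the query never matches a motif base.
#'
#' @param seq DNA string.
#' @param motif Motif (length >= 6).
#' @param max_mutations 0 or 1.
#' @return A tibble with columns `position` (0-based, ascending) and
#'   `n_mutations`.
#' @examples
#' find_motif("NNNNNTATTACTGTNN", "TATTACTGT")
#' @export
find_motif <- function(seq, motif, max_mutations = 0) {
  stopifnot(nchar(motif) >= 6, max_mutations %in% c(0, 1))
  seq <- clean_dna(seq, "seq")
  hits <- stringr::str_locate_all(seq, stringr::fixed(motif))[[1]]
  if (nrow(hits) > 0) {
    return(tibble(position = as.integer(hits[, "start"] - 1L),
                  n_mutations = 0L))
  }
  if (max_mutations == 0 || nchar(seq) < nchar(motif)) {
    return(tibble(position = integer(), n_mutations = integer()))
  }
  k <- nchar(motif)
  qs <- strsplit(seq, "")[[1]]
  ms <- strsplit(motif, "")[[1]]
  npos <- nchar(seq) - k + 1
  mm <- vapply(seq_len(npos), function(i) {
    w <- qs[i:(i + k - 1)]
    sum(w != ms | w == "N")
  }, integer(1))
  pos <- which(mm == 1) - 1L
  tibble(position = as.integer(pos), n_mutations = rep(1L, length(pos)))
}

#' Partitioner options
#'
#' @param all_d Report the best D germline even when its score is below
#'   `scheme$d_min_score` (the below-threshold state is still flagged).
#' @param try_reverse If no V motif is found (even with one mutation) on the
#'   forward strand, try the reverse complement before the fallback ladder.
#' @return A list of class `partition_options`.
#' @export
partition_options <- function(all_d = FALSE, try_reverse = FALSE) {
  structure(list(all_d = all_d, try_reverse = try_reverse),
            class = "partition_options")
}

revcomp <- function(x) {
  reverse_chars(chartr("ACGTN", "TGCAN", x))
}

# score every (candidate anchor position, motif-bearing V germline) pair:
# approximate backwards 5' alignment + anchored 3' V-end alignment.
anchored_v_table <- function(query, vg, positions, scheme) {
  n <- nchar(query)
  rows <- list()
  for (p in positions) {
    q3 <- substr(query, p + 1, n)
    for (i in seq_len(nrow(vg))) {
      ga <- vg$motif_anchor[i]
      gseq <- vg$sequence[i]
      a5 <- approx_backwards_align(query, gseq, p, ga, scheme, vg$name[i])
      a3 <- v_end_align(q3, substr(gseq, ga + 1, nchar(gseq)), scheme,
                        vg$name[i])
      total <- a5$score + a3$score
      span <- (p + a3$query_interval[2]) - a5$query_interval[1]
      rows[[length(rows) + 1]] <- tibble(
        name = vg$name[i], gene = vg$gene[i], p = p,
        score = total, score5 = a5$score, score3 = a3$score,
        per_base = if (span > 0) total / span else -Inf,
        q_start = a5$query_interval[1],
        q_end = p + a3$query_interval[2],
        g_anchor = ga,
        a5 = list(a5), a3 = list(a3))
    }
  }
  dplyr::bind_rows(rows)
}

# collapse a scored table to a segment assignment (tie set at max score)
pick_best <- function(tab) {
  if (is.null(tab) || nrow(tab) == 0) return(NULL)
  top <- max(tab$score)
  tied <- tab |>
    dplyr::filter(.data$score == top) |>
    dplyr::arrange(.data$name, .data$p) |>
    dplyr::distinct(.data$name, .keep_all = TRUE) |>
    dplyr::arrange(.data$name)
  tied
}

#' The V fallback ladder
#'
#' Invoked when the motif-anchored V score per base falls below the scheme
#' threshold or no V motif was found. Rung 1 aligns the query to a fixed
#' anchor gene (`IGHV1-18*01` when present, otherwise the first V gene) with
#' exhaustive overlap DP, infers the query motif position from where the
#' anchor gene's motif maps through that alignment, and repeats the
#' motif-anchored scoring there. Rung 2 (if the score is still below
#' threshold) runs overlap DP against every V gene with the segment end at
#' the maximum score anywhere.
#'
#' @inheritParams partition_sequence
#' @return A list: `assignment` (tibble of tied best rows or `NULL`) and
#'   `flags` (character).
#' @export
fallback_ladder <- function(query, db, scheme = scoring_scheme()) {
  scheme <- as_scheme(scheme)
  vg_all <- dplyr::filter(db, .data$segment == "V")
  if (nrow(vg_all) == 0)
    stop("germline database has no V genes", call. = FALSE)
  flags <- character()

  # rung 1: infer the motif position through a fixed anchor gene
  anchor_idx <- match("IGHV1-18*01", vg_all$name)
  if (is.na(anchor_idx)) anchor_idx <- 1L
  anchor <- vg_all[anchor_idx, ]
  vg_motif <- dplyr::filter(vg_all, !is.na(.data$motif_anchor))
  if (!is.na(anchor$motif_anchor) && nrow(vg_motif) > 0) {
    fa <- full_overlap_dp(query, anchor$sequence, scheme, anchor$name)
    q_anchor_inf <- map_g_to_q(fa, anchor$motif_anchor)
    if (!is.na(q_anchor_inf)) {
      tab <- anchored_v_table(query, vg_motif, q_anchor_inf, scheme)
      best <- pick_best(tab)
      if (!is.null(best) && best$per_base[1] >=
            scheme$v_score_per_base_threshold) {
        return(list(assignment = best, flags = "v_motif_inferred"))
      }
    }
  }

  # rung 2: exhaustive overlap DP against every V gene
  tab <- purrr::map(seq_len(nrow(vg_all)), function(i) {
    al <- full_overlap_dp(query, vg_all$sequence[i], scheme, vg_all$name[i])
    span <- al$query_interval[2] - al$query_interval[1]
    tibble(name = vg_all$name[i], gene = vg_all$gene[i], p = NA_integer_,
           score = al$score, score5 = al$score, score3 = 0,
           per_base = if (span > 0) al$score / span else -Inf,
           q_start = al$query_interval[1], q_end = al$query_interval[2],
           g_anchor = NA_integer_, a5 = list(al), a3 = list(NULL))
  }) |> dplyr::bind_rows()
  best <- pick_best(tab)
  if (!is.null(best) && best$score[1] <= 0) best <- NULL
  flags <- if (is.null(best)) "v_unassigned" else "fallback_v"
  list(assignment = best, flags = flags)
}

# map a germline coordinate to the query coordinate aligned to it (NA when
# the coordinate is outside the aligned germline interval or inside a gap)
map_g_to_q <- function(alignment, g_coord) {
  ops <- tidy.vdj_alignment(alignment)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$length[i]
    if (op %in% c("M", "X")) {
      if (g_coord >= ops$g_pos[i] && g_coord < ops$g_pos[i] + len) {
        return(ops$q_pos[i] + (g_coord - ops$g_pos[i]))
      }
    } else if (op == "D") {
      if (g_coord >= ops$g_pos[i] && g_coord < ops$g_pos[i] + len) {
        return(NA_integer_)
      }
    }
  }
  NA_integer_
}

assign_j <- function(query, region_start, db, scheme, options) {
  jg <- dplyr::filter(db, .data$segment == "J", !is.na(.data$motif_anchor))
  n <- nchar(query)
  flags <- character()
  if (region_start < n && nrow(jg) > 0) {
    tail_seq <- substr(query, region_start + 1, n)
    hits <- find_motif(tail_seq, J_MOTIF, 0)
    positions <- hits$position + region_start
    if (length(positions) > 0) {
      rows <- list()
      for (p in positions) {
        for (i in seq_len(nrow(jg))) {
          ga <- jg$motif_anchor[i]
          gseq <- jg$sequence[i]
          pre_q <- substr(query, region_start + 1, p)
          pre_g <- substr(gseq, 1, ga)
          a5 <- j_start_align(pre_q, pre_g, scheme, jg$name[i])
          a3 <- v_end_align(substr(query, p + 1, n),
                            substr(gseq, ga + 1, nchar(gseq)), scheme,
                            jg$name[i])
          total <- a5$score + a3$score
          j_start <- region_start + a5$query_interval[1]
          j_end <- p + a3$query_interval[2]
          rows[[length(rows) + 1]] <- tibble(
            name = jg$name[i], gene = jg$gene[i], p = p,
            score = total, score5 = a5$score, score3 = a3$score,
            per_base = if (j_end > j_start) total / (j_end - j_start)
                       else -Inf,
            q_start = j_start, q_end = j_end, g_anchor = ga,
            a5 = list(a5), a3 = list(a3))
        }
      }
      best <- pick_best(dplyr::bind_rows(rows))
      if (!is.null(best) &&
            best$per_base[1] >= scheme$v_score_per_base_threshold) {
        return(list(assignment = best, flags = flags))
      }
    }
  }
  # fallback: Smith-Waterman over the post-V region
  flags <- c(flags, "fallback_j")
  jg_all <- dplyr::filter(db, .data$segment == "J")
  if (region_start >= n || nrow(jg_all) == 0)
    return(list(assignment = NULL, flags = flags))
  tail_seq <- substr(query, region_start + 1, n)
  tab <- purrr::map(seq_len(nrow(jg_all)), function(i) {
    al <- smith_waterman(tail_seq, jg_all$sequence[i], scheme,
                         jg_all$name[i])
    al$query_interval <- al$query_interval + region_start
    span <- al$query_interval[2] - al$query_interval[1]
    tibble(name = jg_all$name[i], gene = jg_all$gene[i], p = NA_integer_,
           score = al$score, score5 = al$score, score3 = 0,
           per_base = if (span > 0) al$score / span else -Inf,
           q_start = al$query_interval[1], q_end = al$query_interval[2],
           g_anchor = NA_integer_, a5 = list(al), a3 = list(NULL))
  }) |> dplyr::bind_rows()
  best <- pick_best(tab)
  if (is.null(best) ||
        best$per_base[1] < scheme$v_score_per_base_threshold) {
    return(list(assignment = NULL, flags = flags))
  }
  list(assignment = best, flags = flags)
}

assign_d <- function(query, junction_start, junction_end, db, scheme,
                     options) {
  dg <- dplyr::filter(db, .data$segment == "D")
  flags <- character()
  if (junction_end <= junction_start || nrow(dg) == 0)
    return(list(assignment = NULL, flags = flags))
  junction <- substr(query, junction_start + 1, junction_end)
  tab <- purrr::map(seq_len(nrow(dg)), function(i) {
    al <- d_match(junction, dg$sequence[i], scheme, dg$name[i])
    al$query_interval <- al$query_interval + junction_start
    tibble(name = dg$name[i], gene = dg$gene[i], p = NA_integer_,
           score = al$score, score5 = al$score, score3 = 0,
           per_base = NA_real_,
           q_start = al$query_interval[1], q_end = al$query_interval[2],
           g_anchor = NA_integer_, a5 = list(al), a3 = list(NULL))
  }) |> dplyr::bind_rows()
  best <- pick_best(tab)
  if (is.null(best) || best$score[1] <= 0)
    return(list(assignment = NULL, flags = flags))
  if (best$score[1] < scheme$d_min_score) {
    flags <- c(flags, "d_below_min")
    if (!options$all_d) return(list(assignment = NULL, flags = flags))
  }
  list(assignment = best, flags = flags)
}

segment_assignment <- function(best, segment) {
  if (is.null(best)) return(NULL)
  list(best_germlines = best$name,
       gene = strip_allele(best$name[1]),
       genes = sort(unique(strip_allele(best$name))),
       score = best$score[1],
       score_per_base = best$per_base[1],
       interval = c(best$q_start[1], best$q_end[1]),
       q_anchor = best$p[1],
       g_anchor = best$g_anchor[1],
       alignment5 = best$a5[[1]],
       alignment3 = best$a3[[1]],
       segment = segment)
}

#' Partition one VDJ rearrangement
#'
#' Runs the full motif-anchored partitioning pipeline on a single query: V
#' motif search (exact, then one mutation), approximate backwards 5' V
#' alignment against every motif-bearing V germline, anchored 3' V-end
#' alignment, quality-control realignment of V indels, the fallback ladder
#' when the V score per base falls below threshold, exact J motif search
#' with J-start/J-end alignment (Smith-Waterman fallback), run-length D
#' matching of the junction, and N-region assignment from the untagged
#' bases between segments.
#'
#' @param query DNA string (>= 20 nt).
#' @param db A [germline_db].
#' @param scheme A [scoring_scheme()].
#' @param options A [partition_options()].
#' @param query_name Name recorded in the result.
#' @return A `vdj_partition` object; see [tidy.vdj_partition()] for the
#'   tabular form.
#' @export
partition_sequence <- function(query, db, scheme = scoring_scheme(),
                               options = partition_options(),
                               query_name = "query") {
  scheme <- as_scheme(scheme)
  query <- clean_dna(query, "query")
  if (nchar(query) < 20)
    stop("query shorter than minimum length (20 nt)", call. = FALSE)
  n <- nchar(query)
  flags <- character()
  strand <- "+"

  vg <- dplyr::filter(db, .data$segment == "V", !is.na(.data$motif_anchor))
  cands <- find_motif(query, V_MOTIF, 0)
  if (nrow(cands) == 0) {
    cands <- find_motif(query, V_MOTIF, 1)
    if (nrow(cands) > 0) flags <- c(flags, "v_motif_mutated")
  }
  if (nrow(cands) == 0 && options$try_reverse) {
    rc <- revcomp(query)
    rc_hits <- find_motif(rc, V_MOTIF, 1)
    if (nrow(rc_hits) > 0) {
      query <- rc
      strand <- "-"
      cands <- rc_hits
      if (any(rc_hits$n_mutations > 0)) flags <- c(flags, "v_motif_mutated")
    }
  }

  v_best <- NULL
  if (nrow(cands) > 0 && nrow(vg) > 0) {
    v_best <- pick_best(anchored_v_table(query, vg, cands$position, scheme))
  }
  if (is.null(v_best) ||
        v_best$per_base[1] < scheme$v_score_per_base_threshold) {
    fb <- fallback_ladder(query, db, scheme)
    if (!is.null(fb$assignment)) v_best <- fb$assignment
    flags <- c(flags, fb$flags)
  } else {
    # QC: realign V indels in the opposite direction
    a5 <- v_best$a5[[1]]
    if (n_indels(a5) > 0 && a5$method == "approx_backwards") {
      gseq <- db$sequence[match(v_best$name[1], db$name)]
      qc <- qc_realign(query, gseq, a5, scheme)
      if (!qc$consistent) {
        flags <- c(flags, "qc_inconsistent")
        # retry the 5' part once with exhaustive overlap DP
        redo <- v_best
        for (k in seq_len(nrow(redo))) {
          gs <- db$sequence[match(redo$name[k], db$name)]
          al <- full_overlap_dp(substr(query, 1, redo$p[k]),
                                substr(gs, 1, redo$g_anchor[k]),
                                scheme, redo$name[k])
          redo$a5[[k]] <- al
          redo$score5[k] <- al$score
          redo$score[k] <- al$score + redo$score3[k]
          redo$q_start[k] <- al$query_interval[1]
          span <- redo$q_end[k] - redo$q_start[k]
          redo$per_base[k] <- if (span > 0) redo$score[k] / span else -Inf
        }
        v_best <- pick_best(redo)
      }
    }
  }

  v <- segment_assignment(v_best, "V")
  v_end <- if (is.null(v)) 0L else v$interval[2]

  jres <- assign_j(query, v_end, db, scheme, options)
  flags <- c(flags, jres$flags)
  j <- segment_assignment(jres$assignment, "J")
  j_start <- if (is.null(j)) n else j$interval[1]

  dres <- assign_d(query, v_end, j_start, db, scheme, options)
  flags <- c(flags, dres$flags)
  d <- segment_assignment(dres$assignment, "D")

  if (!is.null(d)) {
    vd_n <- c(v_end, d$interval[1])
    dj_n <- c(d$interval[2], j_start)
  } else {
    vd_n <- c(v_end, j_start)
    dj_n <- c(j_start, j_start)
  }

  for (seg in list(v, d, j)) {
    if (!is.null(seg) && length(seg$best_germlines) > 1) {
      flags <- c(flags, paste0("tie_", tolower(seg$segment)))
    }
  }
  if (is.null(v)) flags <- c(flags, "v_unassigned")

  structure(
    list(query_name = query_name, sequence = query, strand = strand,
         v = v, d = d, j = j,
         vd_n_region = list(interval = vd_n,
                            sequence = substr(query, vd_n[1] + 1, vd_n[2])),
         dj_n_region = list(interval = dj_n,
                            sequence = substr(query, dj_n[1] + 1, dj_n[2])),
         flags = sort(unique(flags))),
    class = "vdj_partition")
}

#' @export
print.vdj_partition <- function(x, ...) {
  cat(sprintf("<vdj_partition: %s (%d nt, strand %s)>\n", x$query_name,
              nchar(x$sequence), x$strand))
  seg_line <- function(s, label) {
    if (is.null(s)) {
      cat(sprintf("  %s: unassigned\n", label))
    } else {
      cat(sprintf("  %s: %s [%d, %d) score %g%s\n", label,
                  paste(s$best_germlines, collapse = ","),
                  s$interval[1], s$interval[2], s$score,
                  if (!is.na(s$score_per_base))
                    sprintf(" (%.2f/base)", s$score_per_base) else ""))
    }
  }
  seg_line(x$v, "V"); seg_line(x$d, "D"); seg_line(x$j, "J")
  cat(sprintf("  VD N: '%s'  DJ N: '%s'\n", x$vd_n_region$sequence,
              x$dj_n_region$sequence))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

# plain-list representation for JSON-lines dumps
partition_to_list <- function(x) {
  al <- function(a) if (is.null(a)) NULL else as.list(glance(a))
  seg <- function(s) {
    if (is.null(s)) return(NULL)
    list(best_germlines = s$best_germlines, gene = s$gene,
         score = s$score, score_per_base = s$score_per_base,
         interval = s$interval, q_anchor = s$q_anchor,
         g_anchor = s$g_anchor, alignment5 = al(s$alignment5),
         alignment3 = al(s$alignment3))
  }
  list(query_name = x$query_name, strand = x$strand,
       v = seg(x$v), d = seg(x$d), j = seg(x$j),
       vd_n_region = x$vd_n_region, dj_n_region = x$dj_n_region,
       flags = x$flags)
}

#' Tidy a partition into one row
#'
#' @param x A `vdj_partition`.
#' @param ... Unused.
#' @return A one-row tibble with gene assignments, tie lists
#'   (comma-separated allele names), scores, intervals (0-based half-open),
#'   N-region sequences and flags.
#' @export
tidy.vdj_partition <- function(x, ...) {
  seg_cols <- function(s, prefix) {
    if (is.null(s)) {
      out <- list(NA_character_, NA_character_, NA_real_, NA_integer_,
                  NA_integer_)
    } else {
      out <- list(s$gene, paste(s$best_germlines, collapse = ","),
                  s$score, as.integer(s$interval[1]),
                  as.integer(s$interval[2]))
    }
    setNames(out, paste0(prefix, c("_gene", "_allele_list", "_score",
                                   "_start", "_end")))
  }
  v_extra <- list(
    v_score_per_base = if (is.null(x$v)) NA_real_ else x$v$score_per_base,
    v_cigar = if (is.null(x$v)) NA_character_ else {
      c5 <- x$v$alignment5$cigar
      c3 <- if (is.null(x$v$alignment3)) "" else x$v$alignment3$cigar
      paste0(c5, c3)
    })
  as_tibble(c(
    list(query = x$query_name, strand = x$strand),
    seg_cols(x$v, "v"), v_extra, seg_cols(x$d, "d"), seg_cols(x$j, "j"),
    list(vd_n_seq = x$vd_n_region$sequence,
         dj_n_seq = x$dj_n_region$sequence,
         flags = paste(x$flags, collapse = ","))))
}

#' Partition many sequences
#'
#' Maps [partition_sequence()] over a set of queries and binds the tidied
#' rows. Queries may be a named character vector, a tibble with `name` and
#' `sequence` columns, or a path to a FASTA file.
#'
#' @param queries Queries (see above).
#' @inheritParams partition_sequence
#' @param keep_partitions Attach the full `vdj_partition` objects as a
#'   `partition` list-column.
#' @return A tibble with one row per query.
#' @export
partition_sequences <- function(queries, db, scheme = scoring_scheme(),
                                options = partition_options(),
                                keep_partitions = FALSE) {
  queries <- as_query_set(queries)
  parts <- purrr::map(seq_len(nrow(queries)), function(i) {
    partition_sequence(queries$sequence[i], db, scheme, options,
                       query_name = queries$name[i])
  })
  out <- dplyr::bind_rows(purrr::map(parts, tidy))
  if (keep_partitions) out$partition <- parts
  out
}

as_query_set <- function(queries) {
  if (is.character(queries) && length(queries) == 1 &&
        file.exists(queries) && !dir.exists(queries)) {
    seqs <- Biostrings::readBStringSet(queries)
    nm <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
    return(tibble(name = nm, sequence = toupper(as.character(seqs))))
  }
  if (is.character(queries)) {
    nm <- names(queries)
    if (is.null(nm)) nm <- paste0("query", seq_along(queries))
    return(tibble(name = nm, sequence = unname(queries)))
  }
  if (is.data.frame(queries)) {
    if (!"name" %in% names(queries) && "id" %in% names(queries))
      queries <- dplyr::rename(queries, name = "id")
    stopifnot(all(c("name", "sequence") %in% names(queries)))
    return(as_tibble(queries)[, c("name", "sequence")])
  }
  stop("unsupported query input", call. = FALSE)
}
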