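#' Overlap dynamic programming alignment
#'
#' Global alignment with free end gaps (affine-gap Gotoh recurrences),
#' terminating at the maximum score anywhere in the matrix. This is the
#' exhaustive engine the approximate backwards algorithm is measured against,
#' and the final rung of the V fallback ladder.
#'
#' @param query,germline DNA strings over \{A,C,G,T,N\}.
#' @param scheme A [scoring_scheme()].
#' @param germline_name Optional name recorded in the result.
#' @return A [vdj_alignment].
#' @examples
#' full_overlap_dp("ACGTACGT", "ACGTACGT")$score  # 40
#' @export
full_overlap_dp <- function(query, germline, scheme = scoring_scheme(),
                            germline_name = NA_character_) {
  scheme <- as_scheme(scheme)
  query <- clean_dna(query, "query")
  germline <- clean_dna(germline, "germline")
  if (nchar(query) == 0 || nchar(germline) == 0)
    stop("sequences must be non-empty", call. = FALSE)
  r <- cpp_align(query, germline, scheme$match, scheme$mismatch,
                 scheme$gap_open, scheme$gap_extend, "overlap")
  new_alignment(r, "full_overlap_dp", germline_name)
}

#' Smith-Waterman local alignment
#'
#' Standard local alignment under the same affine scoring constants; the
#' empty alignment (score 0) is allowed. Used as the J fallback when the J
#' motif is absent.
#'
#' @inheritParams full_overlap_dp
#' @return A [vdj_alignment].
#' @examples
#' smith_waterman("AAAA", "GGGG")$score  # 0
#' @export
smith_waterman <- function(query, germline, scheme = scoring_scheme(),
                           germline_name = NA_character_) {
  scheme <- as_scheme(scheme)
  query <- clean_dna(query, "query")
  germline <- clean_dna(germline, "germline")
  r <- cpp_align(query, germline, scheme$match, scheme$mismatch,
                 scheme$gap_open, scheme$gap_extend, "local")
  new_alignment(r, "smith_waterman", germline_name)
}

#' Block submatrix of the approximate backwards walk
#'
#' When the diagonal walk meets a mismatch it steps forward `step_back` bases
#' and solves a square block of side up to `block_size` whose 3' corner is
#' `(q_pos, g_pos)` (0-based, exclusive). The block is initialised from the
#' corner assuming insertions along one edge and deletions along the other,
#' filled Needleman-Wunsch style, and the best entry restricted to the
#' block's 5' boundary (first row or first column) is returned together with
#' the traceback operations from the corner to that entry. The block shrinks
#' rather than pads when fewer than `block_size` bases remain before a 5'
#' end.
#'
#' @inheritParams full_overlap_dp
#' @param q_pos,g_pos 0-based exclusive 3' corner of the block.
#' @return A list: `q_entry`/`g_entry` (0-based coordinates of the selected
#'   boundary entry), `consumed_q`/`consumed_g`, `score` (DP value at the
#'   entry), and `cigar` (5'->3' operations from the entry to the corner).
#' @export
block_submatrix <- function(query, germline, q_pos, g_pos,
                            scheme = scoring_scheme()) {
  scheme <- as_scheme(scheme)
  query <- clean_dna(query, "query")
  germline <- clean_dna(germline, "germline")
  if (q_pos == 0 && g_pos == 0)
    stop("reached sequence start", call. = FALSE)
  cpp_block_submatrix(query, germline, q_pos, g_pos, scheme$match,
                      scheme$mismatch, scheme$gap_open, scheme$gap_extend,
                      scheme$block_size)
}

#' Approximate backwards alignment
#'
#' Aligns the query and germline 5' of a shared anchor (the first base of the
#' conserved V motif in each sequence) by walking the DP diagonal 3'->5'.
#' While bases match the walk steps along the diagonal; on a mismatch it
#' steps `step_back` bases forward and solves a [block_submatrix()], resuming
#' the diagonal from the block's best boundary entry. The walk terminates
#' when either sequence's 5' end is consumed; the shorter 5' overhang is left
#' unaligned and unpenalised, matching the free-end-gap convention of
#' [full_overlap_dp()].
#'
#' The returned alignment covers `query[q_start, q_anchor)` and
#' `germline[g_start, g_anchor)`; the motif itself belongs to the 3'-side
#' alignment (see [v_end_align()]).
#'
#' @inheritParams full_overlap_dp
#' @param q_anchor,g_anchor 0-based index of the motif's first base in the
#'   query and germline.
#' @return A [vdj_alignment].
#' @export
approx_backwards_align <- function(query, germline, q_anchor, g_anchor,
                                   scheme = scoring_scheme(),
                                   germline_name = NA_character_) {
  scheme <- as_scheme(scheme)
  query <- clean_dna(query, "query")
  germline <- clean_dna(germline, "germline")
  if (q_anchor < 0 || q_anchor > nchar(query))
    stop("q_anchor out of range", call. = FALSE)
  if (g_anchor < 0 || g_anchor > nchar(germline))
    stop("g_anchor out of range", call. = FALSE)
  r <- cpp_approx_backwards(query, germline, q_anchor, g_anchor,
                            scheme$match, scheme$mismatch, scheme$gap_open,
                            scheme$gap_extend, scheme$block_size,
                            scheme$step_back)
  new_alignment(r, "approx_backwards", germline_name)
}

#' 3' end alignment from a shared motif anchor
#'
#' Full small-matrix DP over the sequence tails that both begin at the first
#' base of the conserved motif (`T` of the V motif, or `C` of the J motif
#' when locating the 3' J end). The alignment is pinned at the motif start
#' and the segment end is the query coordinate of the maximum-scoring cell,
#' which may fall anywhere in the matrix (ties: smallest query index, then
#' smallest germline index).
#'
#' @param query_3prime,germline_3prime Sequence tails starting at the motif's
#'   first base.
#' @inheritParams full_overlap_dp
#' @return A [vdj_alignment]; `query_interval[2]` is the segment end relative
#'   to the start of `query_3prime`.
#' @export
v_end_align <- function(query_3prime, germline_3prime,
                        scheme = scoring_scheme(),
                        germline_name = NA_character_) {
  scheme <- as_scheme(scheme)
  q <- clean_dna(query_3prime, "query_3prime")
  g <- clean_dna(germline_3prime, "germline_3prime")
  r <- cpp_align(q, g, scheme$match, scheme$mismatch, scheme$gap_open,
                 scheme$gap_extend, "anchored")
  new_alignment(r, "v_end_overlap", germline_name)
}

#' 5' J start alignment backwards from the J motif
#'
#' Needleman-Wunsch-style DP run backwards from the J motif: the inputs end
#' where the motif begins (exclusive), the alignment is pinned at the
#' motif-adjacent ends, and the maximum score anywhere in the matrix defines
#' the 5' start of the J segment in the query.
#'
#' @param query_pre_motif,germline_pre_motif Sequences ending immediately
#'   before the J motif.
#' @inheritParams full_overlap_dp
#' @return A [vdj_alignment]; `query_interval[1]` is the J start relative to
#'   the start of `query_pre_motif`.
#' @export
j_start_align <- function(query_pre_motif, germline_pre_motif,
                          scheme = scoring_scheme(),
                          germline_name = NA_character_) {
  scheme <- as_scheme(scheme)
  q <- clean_dna(query_pre_motif, "query_pre_motif")
  g <- clean_dna(germline_pre_motif, "germline_pre_motif")
  nq <- nchar(q); ng <- nchar(g)
  if (nq == 0 || ng == 0) {
    r <- list(score = 0, q_start = nq, q_end = nq, g_start = ng, g_end = ng,
              cigar = "", n_match = 0L)
    return(new_alignment(r, "j_start", germline_name))
  }
  qr <- reverse_chars(q)
  gr <- reverse_chars(g)
  r <- cpp_align(qr, gr, scheme$match, scheme$mismatch, scheme$gap_open,
                 scheme$gap_extend, "anchored")
  ops <- cigar_ops(r$cigar)
  mapped <- list(score = r$score,
                 q_start = nq - r$q_end, q_end = nq - r$q_start,
                 g_start = ng - r$g_end, g_end = ng - r$g_start,
                 cigar = ops_cigar(ops[rev(seq_len(nrow(ops))), , drop = FALSE]),
                 n_match = r$n_match)
  new_alignment(mapped, "j_start", germline_name)
}

#' Run-length D segment matcher
#'
#' Local, gapless DP over the junction and a D germline with the
#' classical consecutive-match D scoring: +1 per match, a
#' mismatch resets the run to 0. When a new run reaches
#' `d_lookback - 1` matches the matcher looks back across the mismatch; if
#' the run score immediately before it exceeded `d_bridge_min_prev` the
#' previous score is added, so a mismatch is recognised as a somatic mutation
#' only when flanked by at least 3 consecutive matches on both sides.
#' Terminates at the maximum score anywhere. `N` never matches and never
#' seeds or extends a run.
#'
#' @param junction DNA between the V end and the J start (may be empty).
#' @param d_germline A D germline sequence.
#' @inheritParams full_overlap_dp
#' @return A [vdj_alignment] with `method = "d_local"`; its score is the
#'   run-length D score (compare against `scheme$d_min_score`).
#' @examples
#' d_match("ACGTACGTA", "ACGTACGTA")$score       # 9
#' d_match("GGGTCCC", "GGGACCC")$score           # 3: flanks too short to bridge
#' d_match("GGGGTCCCC", "GGGGACCCC")$score       # 8: mismatch bridged
#' @export
d_match <- function(junction, d_germline, scheme = scoring_scheme(),
                    germline_name = NA_character_) {
  scheme <- as_scheme(scheme)
  if (nchar(junction) > 0) junction <- clean_dna(junction, "junction")
  d_germline <- clean_dna(d_germline, "d_germline")
  r <- cpp_d_match(junction, d_germline, scheme$d_lookback - 1L,
                   scheme$d_bridge_min_prev)
  new_alignment(r, "d_local", germline_name)
}

#' Quality control realignment of an approximate V alignment
#'
#' Alignments containing indels are re-aligned in the opposite direction
#' (5'->3' from the alignment's 5' terminus back towards the motif) and the
#' two direction's indel calls are compared. Agreement in indel type,
#' length and position marks the alignment consistent; on disagreement the
#' higher-scoring of the two is returned and the result is flagged so the
#' caller can fall back to exhaustive DP.
#'
#' @inheritParams full_overlap_dp
#' @param alignment A [vdj_alignment] from [approx_backwards_align()].
#' @return A list: `consistent` (logical), `revised` (a [vdj_alignment]),
#'   `invoked` (FALSE when the alignment had no indels and the check was
#'   skipped), `forward`, `backward`.
#' @export
qc_realign <- function(query, germline, alignment,
                       scheme = scoring_scheme()) {
  scheme <- as_scheme(scheme)
  query <- clean_dna(query, "query")
  germline <- clean_dna(germline, "germline")
  if (n_indels(alignment) == 0) {
    return(list(consistent = TRUE, revised = alignment, invoked = FALSE,
                forward = alignment, backward = NULL))
  }
  qs <- alignment$query_interval[1]; qe <- alignment$query_interval[2]
  gs <- alignment$germline_interval[1]; ge <- alignment$germline_interval[2]
  qseg <- substr(query, qs + 1, qe)
  gseg <- substr(germline, gs + 1, ge)
  lq <- nchar(qseg); lg <- nchar(gseg)
  r <- cpp_approx_backwards(reverse_chars(qseg), reverse_chars(gseg),
                            lq, lg, scheme$match, scheme$mismatch,
                            scheme$gap_open, scheme$gap_extend,
                            scheme$block_size, scheme$step_back)
  # map the reversed-frame walk back onto original coordinates
  ops <- cigar_ops(r$cigar)
  fwd <- list(score = r$score,
              q_start = qs + (lq - r$q_end), q_end = qs + (lq - r$q_start),
              g_start = gs + (lg - r$g_end), g_end = gs + (lg - r$g_start),
              cigar = ops_cigar(ops[rev(seq_len(nrow(ops))), , drop = FALSE]),
              n_match = r$n_match)
  forward <- new_alignment(fwd, "approx_backwards", alignment$germline_name)
  key <- function(a) {
    tb <- indel_table(a)
    paste(tb$op, tb$length, ifelse(tb$op == "I", tb$q_pos, tb$g_pos),
          sep = ":", collapse = ";")
  }
  consistent <- identical(key(alignment), key(forward))
  revised <- if (consistent || alignment$score >= forward$score) alignment
             else forward
  list(consistent = consistent, revised = revised, invoked = TRUE,
       forward = forward, backward = alignment)
}

reverse_chars <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}
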