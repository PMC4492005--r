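#' Alignment objects
#'
#' Every alignment engine returns a `vdj_alignment`: the aligned intervals on
#' the query and germline (0-based, half-open, 5'->3'), the score, the edit
#' operations as a CIGAR-like string and a provenance tag naming the engine
#' that produced it.
#'
#' Operation codes: `M` match, `X` mismatch, `I` insertion (consumes query),
#' `D` deletion (consumes germline).
#'
#' @name vdj_alignment
NULL

new_alignment <- function(cpp, method, germline_name = NA_character_,
                          q_offset = 0L, g_offset = 0L) {
  structure(
    list(germline_name = germline_name,
         score = cpp$score,
         query_interval = c(cpp$q_start + q_offset, cpp$q_end + q_offset),
         germline_interval = c(cpp$g_start + g_offset, cpp$g_end + g_offset),
         cigar = cpp$cigar,
         n_match = cpp$n_match,
         method = method),
    class = "vdj_alignment")
}

#' @export
print.vdj_alignment <- function(x, ...) {
  cat(sprintf("<vdj_alignment: %s>\n", x$method))
  cat(sprintf("  germline %s  score %g\n",
              ifelse(is.na(x$germline_name), "<unnamed>", x$germline_name),
              x$score))
  cat(sprintf("  query [%d, %d)  germline [%d, %d)\n",
              x$query_interval[1], x$query_interval[2],
              x$germline_interval[1], x$germline_interval[2]))
  cat(sprintf("  cigar %s\n", x$cigar))
  invisible(x)
}

#' Parse a CIGAR-like operation string
#'
#' Expands `"50M1X2I30M"` into a run-length tibble. With `q_start`/`g_start`
#' the 0-based start coordinates of each run on query and germline are added.
#'
#' @param cigar A CIGAR-like string over the ops `M`, `X`, `I`, `D`.
#' @param q_start,g_start 0-based coordinates of the alignment start.
#' @return A tibble with columns `op`, `length`, `q_pos`, `g_pos`.
#' @examples
#' cigar_ops("5M1X2I3M")
#' @export
cigar_ops <- function(cigar, q_start = 0L, g_start = 0L) {
  if (is.na(cigar) || cigar == "") {
    return(tibble(op = character(), length = integer(),
                  q_pos = integer(), g_pos = integer()))
  }
  lens <- as.integer(stringr::str_extract_all(cigar, "[0-9]+")[[1]])
  ops <- stringr::str_extract_all(cigar, "[MXID]")[[1]]
  if (length(lens) != length(ops))
    stop("malformed cigar: ", cigar, call. = FALSE)
  dq <- ifelse(ops %in% c("M", "X", "I"), lens, 0L)
  dg <- ifelse(ops %in% c("M", "X", "D"), lens, 0L)
  tibble(op = ops, length = lens,
         q_pos = q_start + cumsum(dq) - dq,
         g_pos = g_start + cumsum(dg) - dg)
}

ops_cigar <- function(ops) {
  if (nrow(ops) == 0) return("")
  paste0(ops$length, ops$op, collapse = "")
}

#' Re-score edit operations under a scoring scheme
#'
#' Computes the score of an alignment from its edit operations alone. For the
#' affine engines the score is
#' `match * n_match + mismatch * n_mismatch + sum over gaps of
#' (gap_open + (L - 1) * gap_extend)`. The D matcher uses run-length scoring
#' in which every reported operation window scores +1 per matching base
#' (bridged mismatches contribute nothing), so `method = "d_local"` re-scores
#' as the number of matched bases.
#'
#' @param ops A `vdj_alignment`, a CIGAR string, or a tibble from
#'   [cigar_ops()].
#' @param scheme A [scoring_scheme()].
#' @param method Scoring convention; `"affine"` (default) or `"d_local"`.
#'   When `ops` is a `vdj_alignment` the method is taken from the object.
#' @return The numeric score.
#' @examples
#' score_ops("4M", scoring_scheme())          # 20
#' score_ops("9M1X", scoring_scheme())        # 41
#' score_ops("10M2I", scoring_scheme())       # 50 - 31 = 19
#' @export
score_ops <- function(ops, scheme = scoring_scheme(), method = "affine") {
  scheme <- as_scheme(scheme)
  if (inherits(ops, "vdj_alignment")) {
    method <- if (ops$method == "d_local") "d_local" else "affine"
    ops <- ops$cigar
  }
  if (is.character(ops)) ops <- cigar_ops(ops)
  if (identical(method, "d_local")) {
    return(sum(ops$length[ops$op == "M"]))
  }
  s <- sum(ops$length[ops$op == "M"]) * scheme$match +
    sum(ops$length[ops$op == "X"]) * scheme$mismatch
  gaps <- ops$length[ops$op %in% c("I", "D")]
  if (length(gaps) > 0) {
    s <- s + sum(scheme$gap_open + (gaps - 1) * scheme$gap_extend)
  }
  s
}

#' @describeIn vdj_alignment Edit operations of an alignment as a tibble.
#' @param x A `vdj_alignment`.
#' @param ... Unused.
#' @export
tidy.vdj_alignment <- function(x, ...) {
  cigar_ops(x$cigar, x$query_interval[1], x$germline_interval[1])
}

#' @describeIn vdj_alignment One-row summary of an alignment.
#' @export
glance.vdj_alignment <- function(x, ...) {
  tibble(germline_name = x$germline_name,
         score = x$score,
         q_start = x$query_interval[1], q_end = x$query_interval[2],
         g_start = x$germline_interval[1], g_end = x$germline_interval[2],
         n_match = x$n_match,
         cigar = x$cigar,
         method = x$method)
}

# number of indel events (gap runs) in an alignment
n_indels <- function(alignment) {
  ops <- cigar_ops(alignment$cigar)
  sum(ops$op %in% c("I", "D"))
}

# indel descriptors (type, length, absolute q/g position) for QC comparison
indel_table <- function(alignment) {
  ops <- tidy.vdj_alignment(alignment)
  dplyr::filter(ops, .data$op %in% c("I", "D"))
}
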