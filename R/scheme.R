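#' Alignment scoring scheme
#'
#' Bundles every constant used by the alignment engines: the affine-gap
#' substitution scores, the block-submatrix geometry of the approximate
#' backwards algorithm, the per-base V score threshold that triggers the
#' fallback ladder, and the run-length D-matcher constants.
#'
#' A gap of length \eqn{L} costs \code{gap_open + (L - 1) * gap_extend}
#' (both negative): the opening penalty is charged on the first gap base and
#' the extension penalty on each additional base.
#'
#' @param match Match score (> 0). Default +5.
#' @param mismatch Mismatch score (< 0). Default -4. `N` never matches and
#'   always scores as a mismatch.
#' @param gap_open Score of the first base of a gap. Default -30.
#' @param gap_extend Score of each additional gap base. Default -1.
#' @param block_size Side of the square submatrix solved when the backwards
#'   walk meets a mismatch. Default 40.
#' @param step_back Number of bases the walk steps forward (3') before
#'   solving the block. Default 10.
#' @param v_score_per_base_threshold Minimum acceptable V alignment score per
#'   aligned query base; below it the fallback ladder is invoked. Default 3.1.
#' @param d_min_score Minimum run-length D score for a D assignment to be
#'   reported. Default 9.
#' @param d_lookback How far the D matcher looks back after a mismatch when a
#'   new run reaches `d_lookback - 1` matches. Default 4.
#' @param d_bridge_min_prev The run score before the mismatch must exceed this
#'   for the mismatch to be bridged as a mutation. Default 3.
#'
#' @return A list of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme(block_size = 60)
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap_open = -30,
                           gap_extend = -1, block_size = 40, step_back = 10,
                           v_score_per_base_threshold = 3.1, d_min_score = 9,
                           d_lookback = 4, d_bridge_min_prev = 3) {
  stopifnot(match > 0, mismatch < 0)
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("gap_open <= gap_extend <= 0 is required", call. = FALSE)
  if (!(block_size > step_back && step_back > 0))
    stop("block_size > step_back > 0 is required", call. = FALSE)
  structure(
    list(match = match, mismatch = mismatch, gap_open = gap_open,
         gap_extend = gap_extend, block_size = block_size,
         step_back = step_back,
         v_score_per_base_threshold = v_score_per_base_threshold,
         d_min_score = d_min_score, d_lookback = d_lookback,
         d_bridge_min_prev = d_bridge_min_prev),
    class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme>\n")
  cat(sprintf("  match %+g  mismatch %+g  gap open %+g  gap extend %+g\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend))
  cat(sprintf("  block %d x %d, step back %d\n",
              x$block_size, x$block_size, x$step_back))
  cat(sprintf("  V threshold %.2f/base, D min score %d (lookback %d, bridge > %d)\n",
              x$v_score_per_base_threshold, x$d_min_score, x$d_lookback,
              x$d_bridge_min_prev))
  invisible(x)
}

as_scheme <- function(x) {
  if (inherits(x, "scoring_scheme")) return(x)
  stop("`scheme` must be a scoring_scheme object", call. = FALSE)
}
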