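#' Scoring and acceptance parameters for graph merging
#'
#' The alignment scheme follows the short-read mapper convention: +1 match,
#' -4 mismatch, affine gaps costing \code{gap_open + len * gap_extend}
#' (-6, -1: a 1-base gap scores -7). Terminal-edge alignments are accepted
#' for merging when the score and the aligned query length reach the
#' thresholds (inclusive) and the edge's open end is not clipped.
#'
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @param min_score Minimum accepted alignment score (default 45).
#' @param min_aln_len Minimum aligned query length in bases (default 100).
#' @param max_query_tail Only this many bases at the open end of a terminal
#'   edge are aligned (the rest cannot influence a junction); keeps the
#'   dynamic program small on long unitigs.
#' @return A validated parameter list of class \code{MergeParams}.
#' @export
MergeParams <- function(match = 1, mismatch = -4, gap_open = -6,
                        gap_extend = -1, min_score = 45, min_aln_len = 100L,
                        max_query_tail = 400L) {
    stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
              min_score > 0, min_aln_len > 0, max_query_tail >= min_aln_len)
    structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                   gap_extend = gap_extend, min_score = min_score,
                   min_aln_len = as.integer(min_aln_len),
                   max_query_tail = as.integer(max_query_tail)),
              class = "MergeParams")
}

#' Optimal local alignment under the merge scoring scheme
#'
#' Smith-Waterman dynamic programming with affine gaps; with
#' \code{both_strands} the reverse complement of the query is also tried and
#' the better orientation returned. Spans are 0-based half-open; the query
#' span is reported on the *oriented* query (the strand that aligned).
#' Clipping flags record unaligned query overhangs at either end.
#'
#' @param query,target Nucleotide strings.
#' @param params A [MergeParams()] list (thresholds are not applied here).
#' @param both_strands Try both query orientations.
#' @return List of class \code{LocalAlignment}: \code{score},
#'   \code{query_span}, \code{target_span}, \code{query_len},
#'   \code{target_len}, \code{clipped_head}, \code{clipped_tail},
#'   \code{orientation}.
#' @examples
#' a <- localAlign(strrep("ACGT", 25), strrep("ACGT", 25))
#' a$score  # 100
#' @export
localAlign <- function(query, target, params = MergeParams(),
                       both_strands = TRUE) {
    stopifnot(nchar(query) > 0L, nchar(target) > 0L)
    query <- toupper(query); target <- toupper(target)
    run <- function(q, orient) {
        r <- cpp_local_align(q, target, params$match, params$mismatch,
                             params$gap_open, params$gap_extend)
        list(score = r$score,
             query_span = c(r$query_start, r$query_end),
             target_span = c(r$target_start, r$target_end),
             query_len = nchar(q), target_len = nchar(target),
             clipped_head = r$query_start > 0L,
             clipped_tail = r$query_end < nchar(q),
             orientation = orient)
    }
    best <- run(query, "+")
    if (both_strands) {
        alt <- run(revComp(query), "-")
        if (alt$score > best$score) best <- alt
    }
    structure(best, class = "LocalAlignment")
}
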