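# Deterministic pairwise alignment used for primer localisation, clustering
# identity, tandem-window comparison and evaluation.  The engine is a native
# affine-gap (Gotoh) DP with IUPAC-degenerate-aware scoring; see src/.

#' Alignment scoring scheme
#'
#' Affine gap model: a gap of length \eqn{k} scores
#' `gap_open + k * gap_extend`.  With `degenerate_aware = TRUE` two symbols
#' score as a match whenever their IUPAC expansion sets intersect, so the
#' degenerate primer bases (R/M/W) match their targets.
#'
#' The defaults (+2 / -1 / -2 / -1) are tolerant enough to localise a 20-mer
#' primer in a read carrying 2-3% errors while penalising spurious hits.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (<= 0).
#' @param gap_open gap opening score (<= 0).
#' @param gap_extend gap extension score per base (<= 0).
#' @param degenerate_aware treat intersecting IUPAC codes as matches.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap_open = -2,
                           gap_extend = -1, degenerate_aware = TRUE) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend,
                 degenerate_aware = isTRUE(degenerate_aware)),
            class = "scoring_scheme")
}

.aln_result <- function(raw) {
  structure(list(
    score = raw$score,
    query_span = c(raw$q_start, raw$q_end),
    target_span = c(raw$t_start, raw$t_end),
    query_aln = raw$q_aln,
    target_aln = raw$t_aln,
    matches = raw$matches,
    mismatches = raw$mismatches,
    gap_cols = raw$gap_cols,
    columns = raw$columns,
    identity_pct = raw$identity_pct,
    empty = raw$empty
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment> score %.1f, identity %.2f%% (%d/%d cols), q %d-%d, t %d-%d\n",
              x$score, x$identity_pct, x$matches, x$columns,
              x$query_span[1], x$query_span[2],
              x$target_span[1], x$target_span[2]))
  invisible(x)
}

#' Optimal local (Smith-Waterman) alignment
#'
#' @param query,target nucleotide strings.
#' @param scheme a [scoring_scheme()].
#' @param band optional band half-width around the length-scaled diagonal
#'   (0 = full dynamic programming).
#' @return an `alignment_result`: score, 1-based inclusive query/target spans,
#'   gapped alignment strings, match/mismatch/gap column counts and
#'   `identity_pct` = 100 * matches / columns over the aligned region.
#' @export
align_local <- function(query, target, scheme = scoring_scheme(), band = 0L) {
  .aln_result(cpp_pairwise_align(query, target, 0L, scheme$match,
                                 scheme$mismatch, scheme$gap_open,
                                 scheme$gap_extend, scheme$degenerate_aware,
                                 as.integer(band)))
}

#' Optimal global (Needleman-Wunsch) alignment
#'
#' With `end_gap_free = TRUE` terminal gaps in either sequence are free and
#' the reported alignment (and its identity columns) covers only the anchored
#' overlap region.
#'
#' @inheritParams align_local
#' @param end_gap_free leave terminal gaps unpenalised (ends-free / overlap
#'   alignment).
#' @return an `alignment_result`; see [align_local()].
#' @export
align_global <- function(query, target, scheme = scoring_scheme(),
                         end_gap_free = FALSE, band = 0L) {
  .aln_result(cpp_pairwise_align(query, target, if (end_gap_free) 2L else 1L,
                                 scheme$match, scheme$mismatch,
                                 scheme$gap_open, scheme$gap_extend,
                                 scheme$degenerate_aware, as.integer(band)))
}

#' Identity between two co-occurring segments
#'
#' Percent identity of the global alignment of `a` against `b`, counted over
#' all alignment columns.  This is the comparison the tandem-repeat scanner
#' applies to adjacent windows; penalised end gaps keep short random windows
#' from scoring as spurious high-identity partial overlaps.
#'
#' @param a,b non-empty nucleotide strings.
#' @param scheme a [scoring_scheme()].
#' @return identity percentage in `[0, 100]`.
#' @export
window_identity <- function(a, b, scheme = scoring_scheme()) {
  align_global(a, b, scheme)$identity_pct
}

#' Scoring scheme tuned for clustering deletion-noisy reads
#'
#' Gaps are cheaper than mismatches (`mismatch = -2`, `gap_open = -0.5`,
#' `gap_extend = -1`), so nearby opposite-strand indels align as gap columns
#' instead of runs of spurious mismatches, while an isolated true
#' substitution still aligns as a mismatch (one mismatch costs 2, the
#' gap-pair alternative 3).  Used as the default for [cluster_identity()]
#' consumers in the OTU stage.
#'
#' @return a [scoring_scheme()].
#' @export
clustering_scheme <- function() {
  scoring_scheme(match = 2, mismatch = -2, gap_open = -0.5, gap_extend = -1)
}

#' Substitution-only identity used for OTU clustering
#'
#' Identity of the ends-free alignment counted as
#' `matches / (matches + mismatches)`: gap columns are excluded, so the
#' platform's deletion-dominated residual noise does not dilute the
#' substitution signal that separates species at the 97% threshold.
#'
#' @inheritParams window_identity
#' @param band band half-width (0 = full DP).
#' @return identity percentage in `[0, 100]`.
#' @export
cluster_identity <- function(a, b, scheme = scoring_scheme(), band = 0L) {
  cpp_cluster_identity(a, b, scheme$match, scheme$mismatch, scheme$gap_open,
                       scheme$gap_extend, scheme$degenerate_aware,
                       as.integer(band))
}
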