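# chopSeq: orientation correction of concatemer-consensus reads via primer
# localisation, tandem-repeat removal, split merging and size selection.

#' Parameters for chopSeq read correction
#'
#' @param forward_primer forward primer sequence (IUPAC codes allowed);
#'   default is the near-full-length 16S primer 8F.
#' @param reverse_primer reverse primer sequence; default 1387R.
#' @param min_len,max_len retained length window in bp after correction
#'   (defaults 1300 and 1450).
#' @param tr_min_window,tr_max_window tandem-repeat window size range in bp
#'   (defaults 10 and 350).
#' @param tr_threshold_at_min,tr_threshold_at_max percent-identity threshold
#'   at the smallest and largest window; the threshold diminishes linearly
#'   with window size between the two.
#' @param primer_accept_fraction a primer hit is accepted when its local
#'   alignment score reaches this fraction of the maximal score
#'   (`match * primer length`).
#' @param scheme a [scoring_scheme()] for all alignments.
#' @return an object of class `chop_params`.
#' @export
chop_params <- function(forward_primer = "AGRGTTTGATCMTGGCTCAG",
                        reverse_primer = "GGGCGGWGTGTACAAG",
                        min_len = 1300L, max_len = 1450L,
                        tr_min_window = 10L, tr_max_window = 350L,
                        tr_threshold_at_min = 92, tr_threshold_at_max = 70,
                        primer_accept_fraction = 0.6,
                        scheme = scoring_scheme()) {
  stopifnot(min_len > 0, min_len < max_len,
            tr_min_window >= 2, tr_min_window < tr_max_window,
            tr_threshold_at_min > 0, tr_threshold_at_min <= 100,
            tr_threshold_at_max > 0, tr_threshold_at_max <= 100,
            tr_threshold_at_min >= tr_threshold_at_max,
            primer_accept_fraction > 0, primer_accept_fraction <= 1)
  fp <- normalize_seq(forward_primer, warn = FALSE)
  rp <- normalize_seq(reverse_primer, warn = FALSE)
  structure(list(forward_primer = fp, reverse_primer = rp,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 tr_min_window = as.integer(tr_min_window),
                 tr_max_window = as.integer(tr_max_window),
                 tr_threshold_at_min = tr_threshold_at_min,
                 tr_threshold_at_max = tr_threshold_at_max,
                 primer_accept_fraction = primer_accept_fraction,
                 scheme = scheme),
            class = "chop_params")
}

#' Similarity threshold for a tandem-repeat window size
#'
#' Linear interpolation between the thresholds at the smallest and largest
#' window: longer tandem repeats tend to have lower similarity between
#' copies, so the required identity diminishes with window size.
#'
#' @param window window size in bp, within
#'   `[tr_min_window, tr_max_window]`.
#' @param params a [chop_params()].
#' @return identity threshold in percent.
#' @export
threshold_for_window <- function(window, params = chop_params()) {
  if (any(window < params$tr_min_window) || any(window > params$tr_max_window))
    stop("window outside [", params$tr_min_window, ", ", params$tr_max_window, "]")
  params$tr_threshold_at_min +
    (params$tr_threshold_at_max - params$tr_threshold_at_min) *
      (window - params$tr_min_window) /
      (params$tr_max_window - params$tr_min_window)
}

#' Locate primers on a read in both orientations
#'
#' Aligns the forward primer and the reverse complement of the reverse primer
#' locally against the read (plus-strand hypothesis) and against the
#' reverse-complemented read (minus-strand hypothesis; by reverse-complement
#' symmetry this is equivalent to aligning the reverse-complemented forward
#' primer and the reverse primer on the read itself).  The hypothesis with the
#' highest mean accepted-hit score wins; a hypothesis missing a primer scores
#' `-Inf`.
#'
#' @param read a single nucleotide string.
#' @param params a [chop_params()].
#' @return an `orientation_report`: chosen `strand` (`"plus"`/`"minus"`),
#'   per-hypothesis mean scores, `found_forward`/`found_reverse` flags,
#'   `rotation_point` (1-based start of the forward-primer hit on the
#'   re-oriented read) and the accepted hits on the re-oriented read.
#' @export
locate_primers <- function(read, params = chop_params()) {
  fwd <- params$forward_primer
  rcr <- reverse_complement(params$reverse_primer)
  sc <- params$scheme
  accept_f <- params$primer_accept_fraction * sc$match * nchar(fwd)
  accept_r <- params$primer_accept_fraction * sc$match * nchar(rcr)
  read_rc <- reverse_complement(read)

  hyp <- function(target) {
    f <- align_local(fwd, target, sc)
    r <- align_local(rcr, target, sc)
    okf <- !f$empty && f$score >= accept_f
    okr <- !r$empty && r$score >= accept_r
    list(f = f, r = r, okf = okf, okr = okr,
         mean_score = if (okf && okr) (f$score + r$score) / 2 else -Inf)
  }
  plus <- hyp(read)
  minus <- hyp(read_rc)

  strand <- if (minus$mean_score > plus$mean_score) "minus" else "plus"
  chosen <- if (strand == "minus") minus else plus
  structure(list(
    strand = strand,
    mean_score_plus = plus$mean_score,
    mean_score_minus = minus$mean_score,
    found_forward = chosen$okf,
    found_reverse = chosen$okr,
    rotation_point = if (chosen$okf) chosen$f$target_span[1] else NA_integer_,
    forward_hit = chosen$f,
    reverse_hit = chosen$r
  ), class = "orientation_report")
}

#' Split a read at the forward-primer site and re-orient
#'
#' On the re-oriented (plus-strand) read the forward split starts at the
#' forward-primer hit and runs to the read end; the reverse split is the
#' prefix before it, trimmed so that it ends at the reverse-primer hit (any
#' overhang beyond the primer is removed).  Concatenating
#' `forward + reverse` restores primer-flanked amplicon orientation.
#'
#' @param read a single nucleotide string.
#' @param report the [locate_primers()] result for `read`.
#' @return list with `forward`, `reverse` (possibly empty) split strings and
#'   `trimmed_overhang_bp`.
#' @export
split_and_reorient <- function(read, report) {
  if (!report$found_forward || !report$found_reverse)
    stop("both primers must be located before splitting")
  oriented <- if (report$strand == "minus") reverse_complement(read) else read
  rp <- report$rotation_point
  fwd_split <- substring(oriented, rp)
  trimmed <- 0L
  if (rp > 1L) {
    rev_split <- substring(oriented, 1L, rp - 1L)
    r_end <- report$reverse_hit$target_span[2]
    if (!report$reverse_hit$empty && r_end < rp - 1L) {
      rev_split <- substring(oriented, 1L, r_end)
      trimmed <- (rp - 1L) - r_end
    }
  } else {
    rev_split <- ""
  }
  list(forward = fwd_split, reverse = rev_split, trimmed_overhang_bp = trimmed)
}

#' Scan a sequence for tandem repeats
#'
#' Windowed scan from `tr_max_window` down to `tr_min_window`: a position
#' carries a repeat of period `w` when the identity between the co-occurring
#' segments `seq[i, i+w)` and `seq[i+w, i+2w)` meets
#' [threshold_for_window()]; hits are extended over consecutive copies and
#' larger windows claim their spans first, so maximal repeats are reported
#' without overlap.
#'
#' @param seq a nucleotide string.
#' @param params a [chop_params()].
#' @return data frame with 1-based `start` of the first copy, `window` (bp),
#'   `n_copies` (>= 2) and `identity_pct` between the first pair of copies.
#' @export
scan_tandem_repeats <- function(seq, params = chop_params()) {
  stopifnot(nzchar(seq))
  sc <- params$scheme
  raw <- cpp_tandem_scan(seq, params$tr_min_window, params$tr_max_window,
                         params$tr_threshold_at_min, params$tr_threshold_at_max,
                         sc$match, sc$mismatch, sc$gap_open, sc$gap_extend)
  data.frame(start = raw$start0 + 1L, window = raw$window,
             n_copies = raw$n_copies, identity_pct = raw$identity_pct)
}

#' Excise tandem-repeat copies, retaining one copy each
#'
#' @param seq a nucleotide string.
#' @param repeats data frame as returned by [scan_tandem_repeats()];
#'   repeats must not overlap.
#' @return list with the collapsed `seq` and `removed_bp`
#'   (`sum((n_copies - 1) * window)`).
#' @export
collapse_repeats <- function(seq, repeats) {
  if (is.null(repeats) || nrow(repeats) == 0)
    return(list(seq = seq, removed_bp = 0L))
  o <- order(repeats$start)
  repeats <- repeats[o, , drop = FALSE]
  ends <- repeats$start + repeats$n_copies * repeats$window - 1L
  if (any(repeats$start[-1] <= ends[-length(ends)]))
    stop("overlapping repeats")
  removed <- 0L
  # right-to-left so earlier coordinates stay valid
  for (i in rev(seq_len(nrow(repeats)))) {
    cut_from <- repeats$start[i] + repeats$window[i]          # start of copy 2
    cut_to <- repeats$start[i] + repeats$n_copies[i] * repeats$window[i] - 1L
    seq <- paste0(substring(seq, 1L, cut_from - 1L), substring(seq, cut_to + 1L))
    removed <- removed + (repeats$n_copies[i] - 1L) * repeats$window[i]
  }
  list(seq = seq, removed_bp = as.integer(removed))
}

#' Run chopSeq correction over a set of reads
#'
#' Per read: locate primers in both orientations, re-orient and split at the
#' forward-primer site, detect and collapse tandem repeats within the forward
#' and reverse splits independently, merge the splits, and keep the result
#' only when its length falls inside `[min_len, max_len]`.
#'
#' @param reads named character vector of reads.
#' @param params a [chop_params()].
#' @param verbose emit a per-read trace of primer hits and repeat removals.
#' @return list with `corrected` (named character vector) and `outcomes`
#'   (data frame: `read_id`, `status` in `corrected` /
#'   `discarded_no_primers` / `discarded_length`, `strand`, `rotation_point`,
#'   `removed_repeat_bp`, `trimmed_overhang_bp`, `final_len`).
#' @export
run_chopseq <- function(reads, params = chop_params(), verbose = FALSE) {
  n <- length(reads)
  ids <- names(reads)
  if (n > 0) validate_seqset(reads)
  status <- character(n); strand <- character(n)
  rotation <- integer(n); removed <- integer(n); trimmed <- integer(n)
  final_len <- integer(n)
  corrected <- character(0)

  minimum_read <- max(nchar(params$forward_primer), nchar(params$reverse_primer))
  for (i in seq_len(n)) {
    read <- reads[[i]]
    if (nchar(read) < minimum_read) {
      status[i] <- "discarded_no_primers"; strand[i] <- NA_character_
      rotation[i] <- NA_integer_; final_len[i] <- NA_integer_
      next
    }
    rep_ <- locate_primers(read, params)
    strand[i] <- rep_$strand
    if (!rep_$found_forward || !rep_$found_reverse) {
      status[i] <- "discarded_no_primers"
      rotation[i] <- NA_integer_; final_len[i] <- NA_integer_
      if (verbose)
        message(ids[i], ": primers not found (forward=", rep_$found_forward,
                ", reverse=", rep_$found_reverse, ")")
      next
    }
    rotation[i] <- rep_$rotation_point
    splits <- split_and_reorient(read, rep_)
    trimmed[i] <- splits$trimmed_overhang_bp
    merged <- character(2)
    for (k in 1:2) {
      s <- c(splits$forward, splits$reverse)[k]
      if (nchar(s) >= 2 * params$tr_min_window) {
        reps <- scan_tandem_repeats(s, params)
        if (verbose && nrow(reps) > 0)
          message(ids[i], ": ", c("forward", "reverse")[k], " split: removed ",
                  sum((reps$n_copies - 1) * reps$window), " bp of tandem repeat (",
                  paste0(reps$window, "bp x", reps$n_copies, collapse = ", "), ")")
        cr <- collapse_repeats(s, reps)
        merged[k] <- cr$seq
        removed[i] <- removed[i] + cr$removed_bp
      } else {
        merged[k] <- s
      }
    }
    out_seq <- paste0(merged[1], merged[2])
    final_len[i] <- nchar(out_seq)
    if (final_len[i] >= params$min_len && final_len[i] <= params$max_len) {
      status[i] <- "corrected"
      corrected[[ids[i]]] <- out_seq
      if (verbose)
        message(ids[i], ": corrected (", rep_$strand, ", rotation ",
                rotation[i], ", ", final_len[i], " bp)")
    } else {
      status[i] <- "discarded_length"
      if (verbose)
        message(ids[i], ": discarded, length ", final_len[i], " outside [",
                params$min_len, ", ", params$max_len, "]")
    }
  }
  outcomes <- data.frame(
    read_id = if (n > 0) ids else character(0),
    status = status, strand = strand, rotation_point = rotation,
    removed_repeat_bp = removed, trimmed_overhang_bp = trimmed,
    final_len = final_len, stringsAsFactors = FALSE)
  list(corrected = corrected, outcomes = outcomes)
}
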