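# Reference-based accuracy and OTU-recovery metrics.

# Per-position homopolymer run length of a sequence.
.run_lengths <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  rep.int(r$lengths, r$lengths)
}

#' Classify alignment errors against the reference
#'
#' Walks the aligned strings of a query-vs-reference alignment and counts
#' mismatches, insertions (gap in the reference) and deletions (gap in the
#' query); a deletion whose reference base lies inside a homopolymer run
#' longer than 4 bp is counted separately as `homopolymer_deletion`.
#'
#' @param aln an `alignment_result` of query vs reference.
#' @param ref the full reference string the alignment targeted.
#' @return named integer vector: `mismatch`, `insertion`, `deletion`,
#'   `homopolymer_deletion`.  The four counts sum to
#'   `columns - matches` of the alignment.
#' @export
classify_errors <- function(aln, ref) {
  runs <- .run_lengths(ref)
  q <- strsplit(aln$query_aln, "")[[1]]
  t <- strsplit(aln$target_aln, "")[[1]]
  tpos <- aln$target_span[1] - 1L
  mm <- ins <- del <- hp <- 0L
  for (k in seq_along(q)) {
    if (t[k] != "-") tpos <- tpos + 1L
    if (q[k] == "-") {
      if (runs[tpos] > 4L) hp <- hp + 1L else del <- del + 1L
    } else if (t[k] == "-") {
      ins <- ins + 1L
    } else if (!degenerate_match_chr(q[k], t[k])) {
      mm <- mm + 1L
    }
  }
  c(mismatch = mm, insertion = ins, deletion = del, homopolymer_deletion = hp)
}

# scalar IUPAC compatibility without input validation (hot path)
degenerate_match_chr <- function(a, b) {
  ea <- IUPAC_EXPANSION[[a]]; eb <- IUPAC_EXPANSION[[b]]
  if (is.null(ea) || is.null(eb)) return(FALSE)
  any(ea %in% eb)
}

#' Align queries to their best references and report accuracy metrics
#'
#' Each query is aligned ends-free (terminal gaps unpenalised) against every
#' reference and assigned to the best-scoring one; identity, the fraction of
#' the query covered by the alignment, the query/reference aligned-length
#' ratio (below 1 when deletions dominate) and typed error counts are
#' reported per query, with mean +/- sd summaries.
#'
#' @param queries named character vector of query sequences.
#' @param refs named character vector of reference sequences.
#' @param scheme a [scoring_scheme()].
#' @param band band half-width for the alignments (0 = full DP; use 0 when
#'   queries may be rotated or otherwise non-collinear with the reference).
#' @return list with `per_query` (data frame) and `summary` (list of means
#'   and sds).
#' @export
reference_accuracy <- function(queries, refs, scheme = scoring_scheme(),
                               band = 0L) {
  stopifnot(length(queries) > 0, length(refs) > 0)
  rows <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    best <- NULL; best_ref <- NA_character_
    for (rn in names(refs)) {
      a <- align_global(q, refs[[rn]], scheme, end_gap_free = TRUE, band = band)
      if (is.null(best) || a$score > best$score) { best <- a; best_ref <- rn }
    }
    errs <- classify_errors(best, refs[[best_ref]])
    qspan <- best$query_span[2] - best$query_span[1] + 1L
    tspan <- best$target_span[2] - best$target_span[1] + 1L
    rows[[i]] <- data.frame(
      query_id = names(queries)[i], ref_id = best_ref,
      identity_pct = best$identity_pct,
      aligned_fraction = qspan / nchar(q),
      alignment_length_ratio = qspan / tspan,
      mismatch = errs[["mismatch"]], insertion = errs[["insertion"]],
      deletion = errs[["deletion"]],
      homopolymer_deletion = errs[["homopolymer_deletion"]],
      stringsAsFactors = FALSE)
  }
  per_query <- do.call(rbind, rows)
  summary <- list(
    mean_identity = mean(per_query$identity_pct),
    sd_identity = sd(per_query$identity_pct),
    mean_aligned_fraction = mean(per_query$aligned_fraction),
    sd_aligned_fraction = sd(per_query$aligned_fraction),
    mean_alignment_length_ratio = mean(per_query$alignment_length_ratio),
    total_errors = colSums(per_query[, c("mismatch", "insertion", "deletion",
                                         "homopolymer_deletion")]))
  list(per_query = per_query, summary = summary)
}

#' Score OTU recovery against the truth references
#'
#' Each consensus is assigned to its best reference; a reference with at
#' least one consensus at `match_threshold` identity counts as detected,
#' consensuses below the threshold against every reference (or duplicate
#' assignments beyond the first per reference) count as spurious, and
#' references with none are missed.
#'
#' @param consensus named character vector of OTU consensus sequences.
#' @param truth_refs named character vector of reference amplicons
#'   (mutually below `match_threshold` identity).
#' @param match_threshold identity threshold as a fraction (default 0.97).
#' @param scheme a [scoring_scheme()].
#' @param band band half-width for alignments (consensuses are full-length
#'   and collinear with the references).
#' @return list with `detected`, `spurious`, `missed` counts and a
#'   `per_otu` data frame (`otu_id`, `best_ref`, `identity_pct`, `status`).
#' @export
otu_recovery <- function(consensus, truth_refs, match_threshold = 0.97,
                         scheme = scoring_scheme(), band = 150L) {
  if (length(consensus) == 0) {
    return(list(detected = 0L, spurious = 0L, missed = length(truth_refs),
                per_otu = data.frame(otu_id = character(0),
                                     best_ref = character(0),
                                     identity_pct = numeric(0),
                                     status = character(0))))
  }
  best_ref <- character(length(consensus))
  best_id <- numeric(length(consensus))
  for (i in seq_along(consensus)) {
    ids <- vapply(truth_refs, function(r)
      align_global(consensus[[i]], r, scheme, end_gap_free = TRUE,
                   band = band)$identity_pct, numeric(1))
    best_ref[i] <- names(truth_refs)[which.max(ids)]
    best_id[i] <- max(ids)
  }
  thr <- 100 * match_threshold
  status <- character(length(consensus))
  seen <- character(0)
  for (i in order(-best_id)) {
    if (best_id[i] < thr) {
      status[i] <- "spurious"
    } else if (best_ref[i] %in% seen) {
      status[i] <- "duplicate"
    } else {
      status[i] <- "detected"
      seen <- c(seen, best_ref[i])
    }
  }
  list(detected = sum(status == "detected"),
       spurious = sum(status != "detected"),
       missed = length(setdiff(names(truth_refs), seen)),
       per_otu = data.frame(otu_id = names(consensus), best_ref = best_ref,
                            identity_pct = best_id, status = status,
                            stringsAsFactors = FALSE))
}
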