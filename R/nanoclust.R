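# nanoClust: read-partitioning de novo OTU clustering, best-partition
# selection, full-length read recruitment and within-OTU consensus calling.

#' Parse partition size limits
#'
#' The limits come as a flat comma-separated list of coordinate pairs, e.g.
#' `"0,450,451,900,901,1300"` for the default three partitions.  The slice
#' for a pair `(a, b)` covers 1-based positions `max(a, 1) .. b` inclusive,
#' so the default scheme splits a 1,300 bp read into 450, 450 and 400 bp.
#'
#' @param raw comma-separated integers (even count, non-overlapping,
#'   ascending), or an integer vector.
#' @return object of class `partition_scheme`: list of `(start, end)` pairs.
#' @export
parse_partition_limits <- function(raw = "0,450,451,900,901,1300") {
  vals <- if (is.character(raw)) {
    suppressWarnings(as.integer(strsplit(raw, ",")[[1]]))
  } else as.integer(raw)
  if (any(is.na(vals))) stop("partition limits must be integers")
  if (length(vals) == 0 || length(vals) %% 2 != 0)
    stop("partition limits require an even number of values")
  if (any(vals < 0)) stop("partition limits must be non-negative")
  starts <- vals[seq(1, length(vals), by = 2)]
  ends <- vals[seq(2, length(vals), by = 2)]
  if (any(ends <= starts)) stop("each partition end must exceed its start")
  if (length(starts) > 1 && any(starts[-1] <= ends[-length(ends)]))
    stop("partitions must be ascending and non-overlapping")
  structure(list(limits = Map(c, starts, ends)), class = "partition_scheme")
}

#' Equal-width partition limits over a read length
#'
#' Convenience constructor for partition-count sweeps: `n` contiguous
#' near-equal slices of `1..len`.
#'
#' @param n number of partitions.
#' @param len total length covered (default 1300 bp).
#' @return a `partition_scheme`.
#' @export
equal_partitions <- function(n, len = 1300L) {
  cuts <- round(seq(0, len, length.out = n + 1))
  starts <- head(cuts, -1)
  ends <- cuts[-1]
  parse_partition_limits(as.integer(rbind(starts + c(0, rep(1, n - 1)), ends)))
}

#' Slice reads into coordinate partitions
#'
#' @param reads named character vector (size-selected corrected reads).
#' @param scheme a `partition_scheme`.
#' @return list of partitions; each is a list with `index` and `seqs`
#'   (named character vector of slices, source read ids retained).  A read
#'   shorter than a pair's start contributes nothing to that partition; a
#'   read shorter than its end contributes the available suffix.
#' @export
partition_reads <- function(reads, scheme) {
  stopifnot(inherits(scheme, "partition_scheme"))
  lens <- nchar(reads)
  lapply(seq_along(scheme$limits), function(i) {
    a <- max(scheme$limits[[i]][1], 1L)
    b <- scheme$limits[[i]][2]
    keep <- lens >= a
    slices <- substring(reads[keep], a, pmin(b, lens[keep]))
    names(slices) <- names(reads)[keep]
    list(index = i, seqs = slices)
  })
}

#' Dereplicate identical sequences
#'
#' Exact full-length string grouping, sorted by abundance descending with
#' ties in first-seen order.
#'
#' @param seqs named character vector.
#' @return data frame with `seq`, `abundance` and a `member_ids`
#'   list-column.
#' @export
dereplicate <- function(seqs) {
  if (length(seqs) == 0)
    return(data.frame(seq = character(0), abundance = integer(0),
                      member_ids = I(list())))
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  grp <- match(seqs, uniq)
  members <- split(names(seqs), grp)
  ab <- lengths(members)
  o <- order(-ab, seq_along(uniq))
  data.frame(seq = unname(uniq[o]), abundance = as.integer(ab[o]),
             member_ids = I(unname(members[o])), stringsAsFactors = FALSE)
}

#' Flag and remove two-parent chimeras among dereplicated sequences
#'
#' De novo screen in abundance order: a candidate is chimeric when a prefix
#' aligns to one more-abundant sequence and the complementary suffix to
#' another (both parents at >= 2x the candidate's abundance), the best
#' split's combined substitution identity reaches `threshold` and exceeds
#' the best single-parent identity by at least `margin` percentage points.
#'
#' @param uniques data frame from [dereplicate()].
#' @param threshold combined-identity threshold in percent (default 99).
#' @param margin required improvement over the best single parent (default 2).
#' @param scheme a [scoring_scheme()].
#' @return list with `kept` and `removed` data frames (same columns as
#'   `uniques`).
#' @export
flag_chimeras <- function(uniques, threshold = 99, margin = 2,
                          scheme = clustering_scheme()) {
  n <- nrow(uniques)
  if (n == 0) return(list(kept = uniques, removed = uniques[0, ]))
  chim <- logical(n)
  for (i in seq_len(n)) {
    parents <- which(!chim & uniques$abundance >= 2 * uniques$abundance[i] &
                       seq_len(n) < i)
    if (length(parents) < 2) next
    cand <- uniques$seq[i]
    L <- nchar(cand)
    single <- vapply(parents, function(p)
      cluster_identity(cand, uniques$seq[p], scheme), numeric(1))
    best_single <- max(single)
    # prefix/suffix identities against every parent over a split grid
    splits <- unique(pmax(20L, pmin(L - 20L, round(seq(0.15, 0.85, by = 0.1) * L))))
    if (length(splits) == 0) next
    best_comb <- -Inf
    for (s in splits) {
      pre <- substring(cand, 1, s); suf <- substring(cand, s + 1, L)
      idp <- vapply(parents, function(p)
        cluster_identity(pre, uniques$seq[p], scheme), numeric(1))
      ids <- vapply(parents, function(p)
        cluster_identity(suf, uniques$seq[p], scheme), numeric(1))
      for (a in seq_along(parents)) for (b in seq_along(parents)) {
        if (a == b) next
        comb <- (idp[a] * s + ids[b] * (L - s)) / L
        if (comb > best_comb) best_comb <- comb
      }
    }
    if (best_comb >= threshold && best_comb >= best_single + margin)
      chim[i] <- TRUE
  }
  list(kept = uniques[!chim, , drop = FALSE],
       removed = uniques[chim, , drop = FALSE])
}

#' Greedy clustering of dereplicated sequences
#'
#' Abundance-ordered greedy clustering: clusters are scanned in founding
#' order (members in joining order) and a sequence joins the first cluster
#' holding a member at or above `threshold` identity, otherwise it founds a
#' new cluster.  Deciding membership against the nearest existing member
#' rather than the founder alone keeps an atypically error-rich founder from
#' splitting its species, while species separated by several times the
#' noise rate cannot chain together.  Identity is the substitution-only
#' [cluster_identity()] under the indel-tolerant [clustering_scheme()].
#'
#' @param uniques data frame from [dereplicate()] (chimera-filtered).
#' @param threshold identity threshold as a fraction (default 0.97).
#' @param scheme a [scoring_scheme()].
#' @param partition_index bookkeeping index carried into the result.
#' @return object of class `clustering_result`: `clusters` (list with
#'   `centroid_seq`, `member_ids`, `n_reads`), `n_otus_nonsingleton`,
#'   `reads_nonsingleton`, `partition_index`.
#' @export
greedy_cluster <- function(uniques, threshold = 0.97,
                           scheme = clustering_scheme(), partition_index = 1L) {
  if (nrow(uniques) == 0) {
    return(structure(list(clusters = list(), n_otus_nonsingleton = 0L,
                          reads_nonsingleton = 0L,
                          partition_index = partition_index),
                     class = "clustering_result"))
  }
  res <- cpp_greedy_cluster(uniques$seq, threshold * 100,
                            scheme$match, scheme$mismatch, scheme$gap_open,
                            scheme$gap_extend, scheme$degenerate_aware,
                            30L, 0.08)
  nclust <- length(res$centroids)
  clusters <- lapply(seq_len(nclust), function(ci) {
    members <- which(res$assignment == ci)
    ids <- unlist(uniques$member_ids[members], use.names = FALSE)
    list(centroid_seq = uniques$seq[res$centroids[ci]],
         member_ids = ids, n_reads = length(ids))
  })
  sizes <- vapply(clusters, `[[`, integer(1), "n_reads")
  structure(list(clusters = clusters,
                 n_otus_nonsingleton = sum(sizes >= 2L),
                 reads_nonsingleton = sum(sizes[sizes >= 2L]),
                 partition_index = partition_index),
            class = "clustering_result")
}

#' Select the best-performing partition
#'
#' The partition with the maximum number of non-singleton OTUs wins;
#' ties break towards the most reads retained in non-singleton clusters,
#' then the lowest partition index.
#'
#' @param results list of `clustering_result` objects.
#' @return the winning `clustering_result`.
#' @export
pick_best_partition <- function(results) {
  stopifnot(length(results) >= 1)
  n_otus <- vapply(results, `[[`, integer(1), "n_otus_nonsingleton")
  retained <- vapply(results, `[[`, integer(1), "reads_nonsingleton")
  idx <- vapply(results, `[[`, integer(1), "partition_index")
  o <- order(-n_otus, -retained, idx)
  results[[o[1]]]
}

#' Recruit full-length reads for each OTU bin
#'
#' Read ids from the best partition's non-singleton clusters pull the
#' corresponding full-length corrected reads; each bin computes its local
#' mean read length and gates members to within +/-10% of it.
#'
#' @param best a `clustering_result` (the winning partition).
#' @param corrected_reads named character vector of full-length corrected
#'   reads (every member id must resolve).
#' @param size_tolerance length gate as a fraction of the bin mean
#'   (default 0.10).
#' @return list of OTU bins: `otu_id`, `member_ids`, `mean_len`,
#'   `gated_ids`, `gated_seqs` (in corrected-reads order), `n_reads`.
#' @export
recruit_full_length <- function(best, corrected_reads, size_tolerance = 0.10) {
  keep <- Filter(function(cl) cl$n_reads >= 2L, best$clusters)
  bins <- list()
  for (k in seq_along(keep)) {
    cl <- keep[[k]]
    missing <- setdiff(cl$member_ids, names(corrected_reads))
    if (length(missing) > 0)
      stop("member id(s) not found among corrected reads: ",
           paste(head(missing, 3), collapse = ", "))
    # keep input-file order
    ids <- names(corrected_reads)[names(corrected_reads) %in% cl$member_ids]
    seqs <- corrected_reads[ids]
    mean_len <- mean(nchar(seqs))
    ok <- abs(nchar(seqs) - mean_len) <= size_tolerance * mean_len
    if (sum(ok) < 2L) {
      warning("OTU bin ", k, " has fewer than 2 reads after length gating; dropped")
      next
    }
    bins[[length(bins) + 1L]] <- list(
      otu_id = sprintf("OTU_%d", length(bins) + 1L),
      member_ids = ids, mean_len = mean_len,
      gated_ids = ids[ok], gated_seqs = seqs[ok], n_reads = length(ids))
  }
  bins
}

#' Build the consensus sequence for one OTU bin
#'
#' The first `max_reads` length-gated reads (input-file order) are aligned
#' with [progressive_msa()] and collapsed with [majority_consensus()].
#'
#' @param bin an OTU bin from [recruit_full_length()].
#' @param max_reads maximum reads used for the consensus (default 50).
#' @param scheme a [scoring_scheme()].
#' @param backend alignment backend passed to [progressive_msa()].
#' @return list with `otu_id`, `consensus` (string) and `n_reads_used`.
#' @export
build_otu_consensus <- function(bin, max_reads = 50L,
                                scheme = scoring_scheme(),
                                backend = "internal") {
  if (length(bin$gated_seqs) < 2)
    stop("consensus requires at least 2 gated reads")
  use <- head(bin$gated_seqs, max_reads)
  aln <- progressive_msa(use, scheme = scheme, backend = backend)
  list(otu_id = bin$otu_id, consensus = majority_consensus(aln),
       n_reads_used = length(use))
}

#' Run the full nanoClust stage
#'
#' Pipeline per partition: slice, dereplicate, screen chimeras, greedy-cluster
#' at `threshold`; then pick the partition with the most non-singleton OTUs,
#' recruit full-length reads per OTU, gate to +/-10% of the bin mean length
#' and call a majority consensus from the first `max_reads` reads.
#' Singleton OTUs are discarded.
#'
#' @param corrected_reads named character vector from [run_chopseq()].
#' @param scheme_limits a `partition_scheme` (default: the three-partition
#'   `0,450,451,900,901,1300`).
#' @param threshold clustering identity threshold as a fraction (default
#'   0.97).
#' @param max_reads reads per OTU used for consensus (default 50).
#' @param chimera_check run the de novo chimera screen (default TRUE).
#' @param align_scheme a [scoring_scheme()] for clustering identities
#'   (default [clustering_scheme()]).
#' @param backend MSA backend, `"internal"` or `"mafft"`.
#' @param verbose print per-partition OTU counts.
#' @return list with `otu_table` (data frame: `otu_id`, `count`,
#'   `consensus_id`), `consensus` (named character vector), `membership`
#'   (data frame `read_id` -> `otu_id`), `partition_counts` (data frame of
#'   per-partition non-singleton OTU counts) and `best_partition` index.
#' @export
run_nanoclust <- function(corrected_reads,
                          scheme_limits = parse_partition_limits(),
                          threshold = 0.97, max_reads = 50L,
                          chimera_check = TRUE,
                          align_scheme = clustering_scheme(),
                          backend = "internal", verbose = FALSE) {
  parts <- partition_reads(corrected_reads, scheme_limits)
  results <- lapply(parts, function(p) {
    uni <- dereplicate(p$seqs)
    removed <- 0L
    if (chimera_check && nrow(uni) > 0) {
      fc <- flag_chimeras(uni, scheme = align_scheme)
      removed <- nrow(fc$removed)
      uni <- fc$kept
    }
    r <- greedy_cluster(uni, threshold = threshold, scheme = align_scheme,
                        partition_index = p$index)
    r$chimeras_removed <- removed
    r
  })
  partition_counts <- data.frame(
    partition = vapply(results, `[[`, integer(1), "partition_index"),
    n_otus_nonsingleton = vapply(results, `[[`, integer(1), "n_otus_nonsingleton"),
    reads_nonsingleton = vapply(results, `[[`, integer(1), "reads_nonsingleton"),
    chimeras_removed = vapply(results, function(r) as.integer(r$chimeras_removed), integer(1)))
  if (verbose) {
    for (i in seq_len(nrow(partition_counts)))
      message("partition ", partition_counts$partition[i], ": ",
              partition_counts$n_otus_nonsingleton[i], " non-singleton OTUs, ",
              partition_counts$reads_nonsingleton[i], " reads retained")
  }
  best <- pick_best_partition(results)
  bins <- recruit_full_length(best, corrected_reads)
  if (length(bins) == 0) {
    warning("no non-singleton OTU found")
    return(list(otu_table = data.frame(otu_id = character(0), count = integer(0),
                                       consensus_id = character(0)),
                consensus = character(0),
                membership = data.frame(read_id = character(0), otu_id = character(0)),
                partition_counts = partition_counts,
                best_partition = best$partition_index))
  }
  cons <- lapply(bins, build_otu_consensus, max_reads = max_reads,
                 scheme = align_scheme, backend = backend)
  # order OTUs by read count (descending), ties by bin order
  counts <- vapply(bins, `[[`, integer(1), "n_reads")
  o <- order(-counts, seq_along(bins))
  otu_ids <- sprintf("OTU_%d", seq_along(o))
  consensus <- setNames(vapply(cons[o], `[[`, character(1), "consensus"), otu_ids)
  otu_table <- data.frame(
    otu_id = otu_ids,
    count = counts[o],
    consensus_id = otu_ids,
    n_reads_used = vapply(cons[o], `[[`, integer(1), "n_reads_used"),
    stringsAsFactors = FALSE)
  membership <- data.frame(
    read_id = unlist(lapply(bins[o], `[[`, "member_ids"), use.names = FALSE),
    otu_id = rep(otu_ids, counts[o]),
    stringsAsFactors = FALSE)
  list(otu_table = otu_table, consensus = consensus, membership = membership,
       partition_counts = partition_counts,
       best_partition = best$partition_index)
}
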