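# Multiple sequence alignment of within-OTU reads and majority consensus.

#' Progressive multiple sequence alignment
#'
#' Guide order comes from average-linkage clustering of pairwise 6-mer
#' distances (fraction of shared 6-mers); profiles are merged by banded
#' global alignment of their column profiles under the default scoring
#' scheme.  Deterministic.  When `backend = "mafft"` and the `mafft`
#' executable is on the PATH, the external aligner (G-INS-i style global
#' pairwise mode) is invoked instead and parsed into the same structure.
#'
#' @param seqs named character vector of >= 2 non-empty sequences.
#' @param scheme a [scoring_scheme()] for profile merging.
#' @param backend `"internal"` (default) or `"mafft"`.
#' @param k k-mer size for the guide distances.
#' @return object of class `multiple_alignment`: list with `rows` (named
#'   character vector of equal-length gapped strings, in input order) and
#'   `width`.  Removing the gaps of row i restores input sequence i exactly.
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme(),
                            backend = c("internal", "mafft"), k = 6L) {
  backend <- match.arg(backend)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (any(!nzchar(seqs))) stop("zero-length sequence at position ",
                               which(!nzchar(seqs))[1])
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))

  if (backend == "mafft") return(.mafft_msa(seqs))

  n <- length(seqs)
  if (n == 2) {
    rows <- cpp_merge_profiles(seqs[[1]], seqs[[2]], scheme$match,
                               scheme$mismatch, scheme$gap_open,
                               scheme$gap_extend, 0L)
    rows <- setNames(rows, names(seqs))
    return(structure(list(rows = rows, width = nchar(rows[[1]])),
                     class = "multiple_alignment"))
  }

  d <- cpp_kmer_dist(unname(seqs), as.integer(k))
  hc <- hclust(as.dist(d), method = "average")
  profiles <- vector("list", nrow(hc$merge))
  prof_ids <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    pick <- function(x) {
      if (x < 0) list(rows = unname(seqs[-x]), ids = -x)
      else list(rows = profiles[[x]], ids = prof_ids[[x]])
    }
    a <- pick(hc$merge[m, 1]); b <- pick(hc$merge[m, 2])
    profiles[[m]] <- cpp_merge_profiles(a$rows, b$rows, scheme$match,
                                        scheme$mismatch, scheme$gap_open,
                                        scheme$gap_extend, 0L)
    prof_ids[[m]] <- c(a$ids, b$ids)
  }
  rows <- profiles[[nrow(hc$merge)]]
  ord <- order(prof_ids[[nrow(hc$merge)]])
  rows <- setNames(rows[ord], names(seqs))
  structure(list(rows = rows, width = nchar(rows[[1]])),
            class = "multiple_alignment")
}

.mafft_msa <- function(seqs) {
  if (Sys.which("mafft") == "")
    stop("mafft executable not found on PATH")
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(setNames(unname(seqs), paste0("s", seq_along(seqs))), fin)
  res <- system2("mafft", c("--globalpair", "--maxiterate", "2", "--quiet", fin),
                 stdout = fout, stderr = FALSE)
  if (res != 0) stop("mafft failed with exit status ", res)
  aln <- Biostrings::readBStringSet(fout)
  rows <- toupper(as.character(aln))
  rows <- rows[order(as.integer(sub("^s", "", sub("\\s.*$", "", names(aln)))))]
  rows <- setNames(rows, names(seqs))
  structure(list(rows = rows, width = nchar(rows[[1]])),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d rows x %d columns\n",
              length(x$rows), x$width))
  invisible(x)
}

#' Column-wise majority consensus of a multiple alignment
#'
#' Per column the most frequent symbol wins.  A column whose strict majority
#' is the gap is dropped (this is how a deletion shared by most reads
#' propagates into the consensus); a base-vs-gap tie retains the base, since
#' the platform's dominant error mode is deletion and gap-favouring ties
#' would compound it.  Base-vs-base ties resolve lexicographically
#' (A < C < G < T) and N never wins over a concrete base.
#'
#' @param aln a `multiple_alignment` (or list with a `rows` element).
#' @return consensus sequence string (gap columns removed).
#' @export
majority_consensus <- function(aln) {
  rows <- if (is.list(aln)) aln$rows else aln
  if (length(rows) < 2) stop("need at least 2 rows")
  mat <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  syms <- c("A", "C", "G", "T", "N", "-")
  counts <- vapply(syms, function(s) colSums(mat == s), numeric(ncol(mat)))
  if (ncol(mat) == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, syms))
  gap <- counts[, "-"]
  base_max <- apply(counts[, c("A", "C", "G", "T"), drop = FALSE], 1, max)
  other_max <- pmax(base_max, counts[, "N"])
  drop_col <- gap > other_max                   # gap strictly most frequent
  pick <- character(nrow(counts))
  has_base <- base_max > 0
  base_idx <- apply(counts[, c("A", "C", "G", "T"), drop = FALSE], 1, which.max)
  pick[has_base] <- c("A", "C", "G", "T")[base_idx[has_base]]
  pick[!has_base] <- "N"
  paste(pick[!drop_col], collapse = "")
}
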