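# Sequence primitives: IUPAC handling, normalization, FASTA/FASTQ I/O.
#
# Sequence collections are represented as named character vectors (names are
# read ids, values are uppercase sequences over A/C/G/T/N).  An optional
# "description" attribute carries the remainder of each FASTA header.

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Does a concrete base fall within an IUPAC code's expansion?
#'
#' @param base single concrete base, one of `A`, `C`, `G`, `T` (vectorised).
#' @param code single IUPAC nucleotide code (vectorised).
#' @return logical, `TRUE` when `base` belongs to the expansion set of `code`.
#' @examples
#' degenerate_match("A", "R")  # TRUE: R = A/G
#' degenerate_match("C", "R")  # FALSE
#' @export
degenerate_match <- function(base, code) {
  base <- toupper(base)
  code <- toupper(code)
  if (any(!base %in% c("A", "C", "G", "T")))
    stop("'base' must be a concrete nucleotide (A/C/G/T)")
  if (any(!code %in% names(IUPAC_EXPANSION)))
    stop("invalid IUPAC code: ", paste(setdiff(code, names(IUPAC_EXPANSION)), collapse = ", "))
  mapply(function(b, k) b %in% IUPAC_EXPANSION[[k]], base, code, USE.NAMES = FALSE)
}

#' Reverse complement of nucleotide sequences
#'
#' Length-preserving involution over the full IUPAC alphabet (R<->Y, M<->K,
#' W and S self-complementary, N fixed).
#'
#' @param seq character vector of sequences.
#' @return character vector of reverse complements; names are preserved.
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0) return(character(0))
  bad <- !grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvnuU]*$", seq)
  if (any(bad))
    stop("non-IUPAC character in sequence ", which(bad)[1])
  comp <- chartr("ACGTURYSWKMBDHVN", "TGCAAYRSWMKVHDBN",
                 toupper(seq))
  out <- vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
                USE.NAMES = FALSE)
  names(out) <- names(seq)
  out
}

# Normalise raw sequence text: uppercase, U -> T, anything outside the IUPAC
# alphabet becomes N (real basecaller output occasionally carries stray
# symbols and a hard error would drop the whole file).
normalize_seq <- function(seq, warn = TRUE) {
  out <- chartr("U", "T", toupper(seq))
  stray <- grepl("[^ACGTRYSWKMBDHVN]", out)
  if (any(stray)) {
    if (warn)
      warning(sum(stray), " sequence(s) contained non-IUPAC characters; replaced with N")
    out[stray] <- gsub("[^ACGTRYSWKMBDHVN]", "N", out[stray])
  }
  out
}

# Validate a named sequence collection (unique non-empty ids, non-empty seqs).
validate_seqset <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("every sequence needs a non-empty id")
  dup <- duplicated(ids)
  if (any(dup)) stop("duplicate id: ", ids[which(dup)[1]])
  empty <- !nzchar(seqs)
  if (any(empty)) stop("empty sequence at record ", which(empty)[1])
  invisible(seqs)
}

#' Read a FASTA file into a named sequence vector
#'
#' Multi-line records are folded, sequences are normalised to uppercase
#' A/C/G/T/N plus IUPAC ambiguity codes (U is mapped to T, stray characters
#' to N with a warning), and ids must be unique.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences; the part of each header after
#'   the first whitespace is kept in the `"description"` attribute.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  seqs <- as.character(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence at record ", which(empty)[1], " ('", ids[which(empty)[1]], "')")
  if (any(!nzchar(ids)))
    stop("malformed header at record ", which(!nzchar(ids))[1])
  dup <- duplicated(ids)
  if (any(dup)) stop("duplicate id: ", ids[which(dup)[1]])
  out <- setNames(normalize_seq(seqs), ids)
  attr(out, "description") <- desc
  validate_seqset(out)
  out
}

#' Read a FASTQ file, discarding qualities
#'
#' Convenience mirror of the workflow's FASTQ-to-FASTA conversion step.
#'
#' @param path path to a FASTQ file.
#' @return named character vector of sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(set))
  out <- setNames(normalize_seq(as.character(set)), ids)
  validate_seqset(out)
  out
}

#' Write sequences to FASTA
#'
#' Round-trips through [read_fasta()]: `read_fasta(write_fasta(x, f))` equals
#' `x` for any valid collection.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param wrap line width for sequence folding (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, wrap = 70L) {
  if (length(seqs) > 0) validate_seqset(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  desc <- attr(seqs, "description")
  for (i in seq_along(seqs)) {
    header <- names(seqs)[i]
    if (!is.null(desc) && nzchar(desc[i])) header <- paste(header, desc[i])
    writeLines(paste0(">", header), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}
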