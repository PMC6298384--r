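# Simulator of concatemer-consensus amplicon reads: per-base errors with a
# homopolymer deletion bias, tandem-repeat insertions, circular permutation
# and strand flips, with a per-read ground-truth ledger.

#' Mock community specification
#'
#' @param n_species number of community members.
#' @param amplicon_len amplicon length in bp including both primer sites
#'   (default 1400, near-full-length 16S).
#' @param min_pairwise_divergence minimum pairwise divergence between species
#'   references as a fraction (default 0.05, i.e. all pairwise identities
#'   below 95%).
#' @param abundances per-species relative abundances summing to 1 (default
#'   equimolar).
#' @param reads_total total reads to draw.
#' @param seed RNG seed; the whole run is deterministic given the seed.
#' @return object of class `mock_spec`.
#' @export
mock_spec <- function(n_species = 10L, amplicon_len = 1400L,
                      min_pairwise_divergence = 0.05, abundances = NULL,
                      reads_total = 1000L, seed = 1L) {
  if (is.null(abundances)) abundances <- rep(1 / n_species, n_species)
  stopifnot(length(abundances) == n_species,
            abs(sum(abundances) - 1) < 1e-9,
            n_species >= 1, amplicon_len >= 200, reads_total >= 1)
  structure(list(n_species = as.integer(n_species),
                 amplicon_len = as.integer(amplicon_len),
                 min_pairwise_divergence = min_pairwise_divergence,
                 abundances = abundances,
                 reads_total = as.integer(reads_total),
                 seed = as.integer(seed)),
            class = "mock_spec")
}

#' Concatemer-consensus error model
#'
#' Defaults emulate the documented phenomenology of consensus reads from
#' rolling-circle concatemers: ~2.5% residual error dominated by deletions
#' (`p_sub:p_ins:p_del = 0.5:0.5:1.5` x 1e-2), an extra deletion probability
#' inside homopolymer runs longer than 4 bp, a 70% chance of carrying a
#' tandem-repeat insertion whose length is log-normal with median 30 bp
#' (observed medians range 12-62 bp) truncated at the 10 bp observability
#' floor, a 1% heavy tail reaching 1,500 bp, and a 50% strand flip.
#' The `"1d2"` chemistry preset adds a second, longer repeat-length mode,
#' giving the bimodal shape seen for that chemistry.
#'
#' @param p_sub,p_ins,p_del per-base substitution/insertion/deletion
#'   probabilities.
#' @param homopolymer_del_boost extra per-base deletion probability within
#'   homopolymer runs > 4 bp.
#' @param p_tandem probability a read carries a tandem-repeat insertion.
#' @param tandem_median,tandem_sdlog log-normal parameters of the repeat
#'   length sampler.
#' @param tandem_min_len smallest insert length generated (default 10 bp).
#' @param tandem_heavy_p,tandem_heavy_max heavy-tail mixture weight and
#'   maximum length.
#' @param copies_prob probabilities of 2 and 3 tandem copies.
#' @param p_revcomp probability of emitting the reverse-complement strand.
#' @param chemistry `"2d"` (unimodal repeat lengths) or `"1d2"` (bimodal).
#' @return object of class `error_model`.
#' @export
error_model <- function(p_sub = 0.005, p_ins = 0.005, p_del = 0.015,
                        homopolymer_del_boost = 0.05, p_tandem = 0.7,
                        tandem_median = 30, tandem_sdlog = 0.55,
                        tandem_min_len = 10L, tandem_heavy_p = 0.01,
                        tandem_heavy_max = 1500L, copies_prob = c(0.7, 0.3),
                        p_revcomp = 0.5, chemistry = c("2d", "1d2")) {
  chemistry <- match.arg(chemistry)
  probs <- c(p_sub, p_ins, p_del, homopolymer_del_boost, p_tandem, p_revcomp,
             tandem_heavy_p)
  stopifnot(all(probs >= 0), all(probs <= 1), p_sub + p_ins + p_del <= 1,
            length(copies_prob) == 2, abs(sum(copies_prob) - 1) < 1e-9)
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 homopolymer_del_boost = homopolymer_del_boost,
                 p_tandem = p_tandem, tandem_median = tandem_median,
                 tandem_sdlog = tandem_sdlog,
                 tandem_min_len = as.integer(tandem_min_len),
                 tandem_heavy_p = tandem_heavy_p,
                 tandem_heavy_max = as.integer(tandem_heavy_max),
                 copies_prob = copies_prob, p_revcomp = p_revcomp,
                 chemistry = chemistry),
            class = "error_model")
}

.random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

.instantiate_primer <- function(primer) {
  chars <- strsplit(primer, "")[[1]]
  paste(vapply(chars, function(c) {
    exp <- IUPAC_EXPANSION[[c]]
    if (length(exp) == 1) exp else sample(exp, 1)
  }, character(1)), collapse = "")
}

#' Synthesise species reference amplicons
#'
#' One random ancestor of `amplicon_len` is flanked by a concrete
#' instantiation of the forward primer and the reverse complement of the
#' reverse primer; each species is derived by at least
#' `min_pairwise_divergence * amplicon_len` substitutions in the core
#' (primers untouched), and all pairwise identities are verified below
#' `1 - min_pairwise_divergence` by alignment.
#'
#' @param spec a [mock_spec()].
#' @param forward_primer,reverse_primer primer sequences (IUPAC codes
#'   allowed).
#' @param max_tries retries of the whole construction before giving up.
#' @return named character vector of reference sequences
#'   (`species_01`, ...).
#' @export
synth_references <- function(spec,
                             forward_primer = "AGRGTTTGATCMTGGCTCAG",
                             reverse_primer = "GGGCGGWGTGTACAAG",
                             max_tries = 20L) {
  fwd <- .instantiate_primer(normalize_seq(forward_primer, warn = FALSE))
  rev_rc <- reverse_complement(.instantiate_primer(normalize_seq(reverse_primer, warn = FALSE)))
  core_len <- spec$amplicon_len - nchar(fwd) - nchar(rev_rc)
  stopifnot(core_len > 0)
  n_mut <- ceiling(spec$min_pairwise_divergence * spec$amplicon_len)
  target_id <- 100 * (1 - spec$min_pairwise_divergence)
  for (try in seq_len(max_tries)) {
    ancestor <- .random_seq(core_len)
    refs <- vapply(seq_len(spec$n_species), function(s) {
      chars <- strsplit(ancestor, "")[[1]]
      pos <- sample(core_len, n_mut)
      chars[pos] <- vapply(chars[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      paste0(fwd, paste(chars, collapse = ""), rev_rc)
    }, character(1))
    names(refs) <- sprintf("species_%02d", seq_len(spec$n_species))
    ok <- TRUE
    if (spec$n_species > 1) {
      for (i in seq_len(spec$n_species - 1)) {
        for (j in (i + 1):spec$n_species) {
          id <- align_global(refs[[i]], refs[[j]], end_gap_free = TRUE,
                             band = 40L)$identity_pct
          if (id >= target_id) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) return(refs)
  }
  stop("could not satisfy the pairwise divergence constraint after ",
       max_tries, " tries")
}

#' Apply per-base sequencing errors
#'
#' Per-base sampling of substitution, insertion (after the base) and
#' deletion; within homopolymer runs longer than 4 bp the deletion
#' probability is raised by `homopolymer_del_boost`.
#'
#' @param seq reference sequence string.
#' @param model an [error_model()].
#' @return list with the errored `seq` and an `edits` data frame
#'   (`pos` on the reference, `op` in sub/ins/del, `base`); replaying the
#'   edits on the reference reproduces `seq` exactly.
#' @export
apply_errors <- function(seq, model) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  pdel <- rep(model$p_del, L)
  r <- rle(chars)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$lengths > 4))
    pdel[starts[k]:ends[k]] <- model$p_del + model$homopolymer_del_boost
  u <- runif(L)
  op <- rep.int("none", L)
  op[u < model$p_sub] <- "sub"
  op[u >= model$p_sub & u < model$p_sub + model$p_ins] <- "ins"
  op[u >= model$p_sub + model$p_ins &
       u < model$p_sub + model$p_ins + pdel] <- "del"

  pieces <- as.list(chars)
  edits <- list()
  bases <- c("A", "C", "G", "T")
  for (i in which(op == "sub")) {
    nb <- sample(bases[bases != chars[i]], 1)
    pieces[[i]] <- nb
    edits[[length(edits) + 1L]] <- list(pos = i, op = "sub", base = nb)
  }
  for (i in which(op == "ins")) {
    nb <- sample(bases, 1)
    pieces[[i]] <- c(pieces[[i]], nb)
    edits[[length(edits) + 1L]] <- list(pos = i, op = "ins", base = nb)
  }
  for (i in which(op == "del")) {
    pieces[[i]] <- character(0)
    edits[[length(edits) + 1L]] <- list(pos = i, op = "del", base = NA_character_)
  }
  ed <- if (length(edits) == 0) {
    data.frame(pos = integer(0), op = character(0), base = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = vapply(edits, `[[`, integer(1), "pos"),
               op = vapply(edits, `[[`, character(1), "op"),
               base = vapply(edits, `[[`, character(1), "base"),
               stringsAsFactors = FALSE)
  }
  ed <- ed[order(ed$pos, ed$op), , drop = FALSE]
  rownames(ed) <- NULL
  list(seq = paste(unlist(pieces), collapse = ""), edits = ed)
}

#' Replay an edit list on a reference
#'
#' Independent reconstruction used to check the ground-truth ledger:
#' substitutions replace the reference base, insertions add their base after
#' it, deletions drop it.  Edits at the same position apply substitution
#' before insertion (a deletion is exclusive of both).
#'
#' @param ref reference sequence string.
#' @param edits edit data frame from [apply_errors()].
#' @return the edited sequence string.
#' @export
replay_edits <- function(ref, edits) {
  chars <- strsplit(ref, "")[[1]]
  out <- vector("list", length(chars))
  for (i in seq_along(chars)) out[[i]] <- chars[i]
  for (k in seq_len(nrow(edits))) {
    p <- edits$pos[k]
    if (edits$op[k] == "sub") out[[p]][1] <- edits$base[k]
    else if (edits$op[k] == "del") out[[p]] <- character(0)
    else out[[p]] <- c(out[[p]], edits$base[k])
  }
  paste(unlist(out), collapse = "")
}

.sample_tandem_len <- function(model, max_len) {
  for (i in 1:200) {
    if (runif(1) < model$tandem_heavy_p) {
      len <- round(runif(1, 100, model$tandem_heavy_max))
    } else if (model$chemistry == "1d2" && runif(1) < 0.25) {
      len <- round(rlnorm(1, log(model$tandem_median * 5), 0.4))
    } else {
      len <- round(rlnorm(1, log(model$tandem_median), model$tandem_sdlog))
    }
    if (len >= model$tandem_min_len && len <= max_len) return(as.integer(len))
  }
  model$tandem_min_len
}

.rotate <- function(s, r) {
  if (r == 0L) s else paste0(substring(s, r + 1L), substring(s, 1L, r))
}

#' Simulate one concatemer-consensus read
#'
#' Pipeline: [apply_errors()], then with probability `p_tandem` an in-place
#' tandem duplication of a local segment (2-3 adjacent copies), then a
#' circular permutation at a junction-safe breakpoint, then a strand flip
#' with probability `p_revcomp`.  The breakpoint is sampled uniformly over
#' positions outside the inserted repeat copies and outside the two primer
#' sites: observed repeats sit within the forward/reverse splits rather than
#' straddling the junction, and a junction inside a primer destroys the very
#' anchors the consensus process needs.
#'
#' @param ref reference amplicon string (primer-flanked).
#' @param model an [error_model()].
#' @param primer_len_f,primer_len_r lengths of the primer sites at the two
#'   ends of `ref`.
#' @return list with `seq` (the read) and `truth` (rotation, strand,
#'   tandem-repeat position/window/copies or NA, and the edit list).
#' @export
make_read <- function(ref, model, primer_len_f = 20L, primer_len_r = 16L) {
  er <- apply_errors(ref, model)
  s <- er$seq
  tandem <- c(start = NA_integer_, window = NA_integer_, copies = NA_integer_)
  if (runif(1) < model$p_tandem && nchar(s) > 4 * model$tandem_min_len) {
    w <- .sample_tandem_len(model, nchar(s) - 2L)
    copies <- sample(2:3, 1, prob = model$copies_prob)
    start <- sample.int(nchar(s) - w + 1L, 1)
    seg <- substring(s, start, start + w - 1L)
    s <- paste0(substring(s, 1L, start + w - 1L),
                strrep(seg, copies - 1L),
                substring(s, start + w))
    tandem <- c(start = start, window = w, copies = copies)
  }
  L <- nchar(s)
  bad <- rep(FALSE, L)                     # disallowed junction positions
  bad[seq_len(min(L, primer_len_f + 2L))] <- TRUE
  bad[max(1L, L - primer_len_r - 2L):L] <- TRUE
  if (!is.na(tandem["start"])) {
    span_end <- tandem["start"] + tandem["copies"] * tandem["window"] - 1L
    bad[tandem["start"]:min(L, span_end)] <- TRUE
  }
  allowed <- c(0L, which(!bad))            # 0 = no rotation
  r <- allowed[sample.int(length(allowed), 1)]
  s <- .rotate(s, r)
  flip <- runif(1) < model$p_revcomp
  if (flip) s <- reverse_complement(s)
  list(seq = unname(s),
       truth = list(rotation = r, strand = if (flip) "minus" else "plus",
                    tandem_start = unname(tandem["start"]),
                    tandem_window = unname(tandem["window"]),
                    tandem_copies = unname(tandem["copies"]),
                    edits = er$edits))
}

#' Simulate a full sequencing run
#'
#' Draws `reads_total` reads by species abundance and runs [make_read()] on
#' each; deterministic given `spec$seed`.
#'
#' @param spec a [mock_spec()].
#' @param model an [error_model()].
#' @param forward_primer,reverse_primer primers used to flank the references.
#' @return list with `reads` (named character vector), `refs`, `truth`
#'   (data frame with per-read provenance and an `edits` list-column),
#'   `spec` and `model`.
#' @export
simulate_run <- function(spec = mock_spec(), model = error_model(),
                         forward_primer = "AGRGTTTGATCMTGGCTCAG",
                         reverse_primer = "GGGCGGWGTGTACAAG") {
  set.seed(spec$seed)
  refs <- synth_references(spec, forward_primer, reverse_primer)
  species <- sample.int(spec$n_species, spec$reads_total, replace = TRUE,
                        prob = spec$abundances)
  plf <- nchar(normalize_seq(forward_primer, warn = FALSE))
  plr <- nchar(normalize_seq(reverse_primer, warn = FALSE))
  reads <- character(spec$reads_total)
  truth_rows <- vector("list", spec$reads_total)
  for (i in seq_len(spec$reads_total)) {
    mr <- make_read(refs[[species[i]]], model, plf, plr)
    reads[i] <- mr$seq
    truth_rows[[i]] <- mr$truth
  }
  ids <- sprintf("read_%05d", seq_len(spec$reads_total))
  names(reads) <- ids
  truth <- data.frame(
    read_id = ids,
    species = names(refs)[species],
    rotation = vapply(truth_rows, `[[`, integer(1), "rotation"),
    strand = vapply(truth_rows, `[[`, character(1), "strand"),
    tandem_start = vapply(truth_rows, `[[`, integer(1), "tandem_start"),
    tandem_window = vapply(truth_rows, `[[`, integer(1), "tandem_window"),
    tandem_copies = vapply(truth_rows, `[[`, integer(1), "tandem_copies"),
    stringsAsFactors = FALSE)
  truth$edits <- lapply(truth_rows, `[[`, "edits")
  list(reads = reads, refs = refs, truth = truth, spec = spec, model = model)
}

#' Reconstruct a read from its ground-truth entry
#'
#' Replays the edit list, re-inserts the tandem duplication, re-applies the
#' rotation and the strand flip; the result must equal the emitted read
#' byte-for-byte.
#'
#' @param ref the read's species reference.
#' @param truth_row one row of the `truth` data frame from
#'   [simulate_run()] (with its `edits` entry).
#' @return the reconstructed read string.
#' @export
replay_truth <- function(ref, truth_row) {
  s <- replay_edits(ref, truth_row$edits[[1]])
  if (!is.na(truth_row$tandem_start)) {
    st <- truth_row$tandem_start; w <- truth_row$tandem_window
    seg <- substring(s, st, st + w - 1L)
    s <- paste0(substring(s, 1L, st + w - 1L),
                strrep(seg, truth_row$tandem_copies - 1L),
                substring(s, st + w))
  }
  s <- .rotate(s, truth_row$rotation)
  if (truth_row$strand == "minus") s <- reverse_complement(s)
  unname(s)
}
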