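test_that("partition limits parse into the documented slices", {
  sc <- parse_partition_limits("0,450,451,900,901,1300")
  read <- setNames(rand_seq(1300), "r1")
  parts <- partition_reads(read, sc)
  expect_equal(vapply(parts, function(p) nchar(p$seqs[[1]]), integer(1)),
               c(450L, 450L, 400L))

  # a 1,450 bp read: the third pair still ends at 1300, trailing bases unused
  long <- setNames(rand_seq(1450), "r1")
  p3 <- partition_reads(long, sc)[[3]]
  expect_equal(nchar(p3$seqs[[1]]), 400L)
  expect_equal(p3$seqs[[1]], unname(substring(long, 901, 1300)))

  whole <- parse_partition_limits("0,1300")
  expect_length(whole$limits, 1)

  expect_error(parse_partition_limits("0,450,400,900"), "non-overlapping")
  expect_error(parse_partition_limits("0,450,451"), "even number")
  expect_error(parse_partition_limits("100,50"), "exceed")
})

test_that("short reads contribute suffixes or nothing, ids retained", {
  sc <- parse_partition_limits("0,450,451,900")
  reads <- setNames(c(rand_seq(500), rand_seq(300)), c("a", "b"))
  parts <- partition_reads(reads, sc)
  expect_equal(names(parts[[1]]$seqs), c("a", "b"))
  expect_equal(nchar(parts[[1]]$seqs[["b"]]), 300L)
  expect_equal(names(parts[[2]]$seqs), "a")  # b shorter than pair start
  expect_equal(nchar(parts[[2]]$seqs[["a"]]), 50L)
  expect_length(partition_reads(setNames(character(0), character(0)), sc)[[1]]$seqs, 0)
})

test_that("dereplication groups exact duplicates, abundance-sorted", {
  u <- dereplicate(setNames(c("ACGT", "ACGT", "ACGA"), c("x", "y", "z")))
  expect_equal(u$seq, c("ACGT", "ACGA"))
  expect_equal(u$abundance, c(2L, 1L))
  expect_equal(u$member_ids[[1]], c("x", "y"))

  distinct <- dereplicate(setNames(c("AA", "CC", "GG"), c("a", "b", "c")))
  expect_equal(distinct$abundance, rep(1L, 3))
  expect_equal(distinct$seq, c("AA", "CC", "GG"))  # first-seen order kept

  # brute-force pairwise-equality oracle
  set.seed(201)
  seqs <- setNames(sample(c("ACGT", "AGGT", "ACGA"), 20, replace = TRUE),
                   paste0("s", 1:20))
  u2 <- dereplicate(seqs)
  for (k in seq_len(nrow(u2))) {
    expected <- names(seqs)[vapply(seqs, identical, logical(1), u2$seq[k])]
    expect_setequal(u2$member_ids[[k]], expected)
  }
  expect_equal(sum(u2$abundance), 20L)
})

test_that("constructed two-parent chimeras are flagged, legitimate reads kept", {
  set.seed(202)
  pa <- rand_seq(400); pb <- mutate_seq(pa, 0.10)
  chim <- paste0(substring(pa, 1, 200), substring(pb, 201, 400))
  u <- data.frame(seq = c(pa, pb, chim), abundance = c(10L, 10L, 1L),
                  member_ids = I(list(paste0("a", 1:10), paste0("b", 1:10), "c1")),
                  stringsAsFactors = FALSE)
  fc <- flag_chimeras(u)
  expect_equal(fc$removed$seq, chim)
  expect_equal(nrow(fc$kept), 2)

  # identical to a parent: single-parent identity is already 100, never flagged
  u2 <- u; u2$seq[3] <- pa
  expect_equal(nrow(flag_chimeras(u2)$removed), 0)

  # no parents at >= 2x abundance: nothing flagged
  u3 <- u; u3$abundance <- c(1L, 1L, 1L)
  expect_equal(nrow(flag_chimeras(u3)$removed), 0)
})

test_that("greedy clustering separates diverged groups and joins noisy kin", {
  set.seed(203)
  a <- rand_seq(300); b <- mutate_seq(a, 0.10)
  seqs <- c(replicate(5, mutate_seq(a, 0.005)), replicate(5, mutate_seq(b, 0.005)))
  u <- dereplicate(setNames(seqs, paste0("r", 1:10)))
  cl <- greedy_cluster(u)
  expect_equal(cl$n_otus_nonsingleton, 2L)
  expect_equal(length(cl$clusters), 2L)

  # threshold 1.0 reproduces dereplication for interior variation (a strict
  # substring scores 100 under the ends-free identity, so terminal-only
  # variants are the documented exception)
  dup <- dereplicate(setNames(c("ACGTTACGT", "ACGTTACGT", "ACGTAACGT"), paste0("d", 1:3)))
  cl1 <- greedy_cluster(dup, threshold = 1.0)
  expect_equal(length(cl1$clusters), 2L)
  expect_equal(cl1$n_otus_nonsingleton, 1L)
})

test_that("greedy clustering matches the independent member-linkage oracle", {
  set.seed(204)
  for (trial in 1:15) {
    seqs <- make_separable_instance(9, 3, len = 60, thr = 90)
    u <- dereplicate(setNames(seqs, paste0("s", 1:9)))
    mine <- cpp_greedy_cluster(u$seq, 90, 2, -2, -0.5, -1, TRUE, 100L, 0.08)
    orac <- oracle_greedy(u$seq, 90)  # same rule, plain R, unbanded DP
    expect_equal(as.integer(mine$assignment), orac)
  }
})

test_that("best-partition selection follows count, retention, then index", {
  mk <- function(idx, n, reads) structure(
    list(clusters = list(), n_otus_nonsingleton = n, reads_nonsingleton = reads,
         partition_index = as.integer(idx)), class = "clustering_result")
  expect_equal(pick_best_partition(list(mk(1, 3L, 100L), mk(2, 5L, 100L),
                                        mk(3, 4L, 100L)))$partition_index, 2)
  expect_equal(pick_best_partition(list(mk(1, 5L, 400L), mk(2, 5L, 500L)))$partition_index, 2)
  expect_equal(pick_best_partition(list(mk(2, 5L, 400L), mk(1, 5L, 400L)))$partition_index, 1)
  expect_equal(pick_best_partition(list(mk(1, 2L, 10L)))$partition_index, 1)
})

test_that("full-length recruitment gates members to 10% of the bin mean", {
  set.seed(205)
  reads <- c(setNames(replicate(9, rand_seq(1400)), paste0("k", 1:9)),
             setNames(rand_seq(1200), "short"))
  best <- structure(list(clusters = list(list(centroid_seq = "x",
                                              member_ids = names(reads),
                                              n_reads = 10L)),
                         n_otus_nonsingleton = 1L, reads_nonsingleton = 10L,
                         partition_index = 1L), class = "clustering_result")
  bins <- recruit_full_length(best, reads)
  expect_equal(bins[[1]]$mean_len, 1380)
  expect_false("short" %in% bins[[1]]$gated_ids)  # 1200 < 0.9 * 1380
  expect_length(bins[[1]]$gated_ids, 9)

  best$clusters[[1]]$member_ids <- c("k1", "missing_read")
  expect_error(recruit_full_length(best, reads), "not found")
})

test_that("run_nanoclust recovers a small mock community end to end", {
  set.seed(206)
  refs <- replicate(3, rand_seq(1350))
  reads <- setNames(unlist(lapply(refs, function(r)
    replicate(8, mutate_seq(r, 0.004)))), sprintf("read_%02d", 1:24))
  res <- run_nanoclust(reads)
  expect_equal(nrow(res$otu_table), 3)
  expect_equal(sort(res$otu_table$count), c(8L, 8L, 8L))
  # every read id appears exactly once; table total <= input count
  expect_false(any(duplicated(res$membership$read_id)))
  expect_lte(sum(res$otu_table$count), length(reads))
  expect_equal(length(res$consensus), 3)
  # consensus of each OTU is essentially its reference
  ids <- vapply(seq_len(3), function(i)
    max(vapply(refs, function(r)
      align_global(res$consensus[[i]], r, end_gap_free = TRUE,
                   band = 80L)$identity_pct, numeric(1))), numeric(1))
  expect_true(all(ids > 99.5))
})

test_that("OTU counts never decrease as partitions narrow", {
  # under-partitioning can only merge; over-partitioning can only inflate
  sc3 <- equal_partitions(3)
  expect_equal(vapply(sc3$limits, `[[`, numeric(1), 2) -
                 pmax(vapply(sc3$limits, `[[`, numeric(1), 1), 1) + 1,
               c(433, 434, 433))
  sim <- simulate_run(mock_spec(n_species = 5, reads_total = 200, seed = 208),
                      error_model())
  cc <- run_chopseq(sim$reads)
  counts <- vapply(c(1L, 3L, 7L), function(np) {
    nrow(run_nanoclust(cc$corrected, equal_partitions(np))$otu_table)
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_gte(counts[2], 5L)  # the recommended regime recovers every species
})

test_that("degenerate inputs give empty results with warnings, not errors", {
  set.seed(207)
  lone <- setNames(c(rand_seq(1300), rand_seq(1300)), c("a", "b"))  # unrelated
  expect_warning(res <- run_nanoclust(lone), "no non-singleton OTU")
  expect_equal(nrow(res$otu_table), 0)
})
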