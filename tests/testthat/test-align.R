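test_that("local alignment finds exact and degenerate-aware matches", {
  a <- align_local("ACGT", "TTACGTTT")
  expect_equal(a$score, 4 * 2)
  expect_equal(a$target_span, c(3, 6))

  d <- align_local("AGRG", "AGAG")
  expect_equal(d$matches, 4)  # R matches A when degenerate-aware
  expect_equal(d$identity_pct, 100)

  nd <- align_local("AGRG", "AGAG", scoring_scheme(degenerate_aware = FALSE))
  expect_lt(nd$matches, 4)
})

test_that("global alignment identity follows the forced single-indel optimum", {
  g <- align_global("ACGT", "ACGT")
  expect_equal(g$identity_pct, 100)
  g2 <- align_global("ACGT", "ACT")
  expect_equal(g2$columns, 4)
  expect_equal(g2$identity_pct, 75)
})

test_that("window identity satisfies its worked examples and symmetry", {
  expect_equal(window_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(window_identity("AAAA", "TTTT"), 0)
  set.seed(3)
  for (i in 1:25) {
    a <- rand_seq(sample(5:30, 1)); b <- rand_seq(sample(5:30, 1))
    expect_equal(window_identity(a, b), window_identity(b, a))
  }
})

test_that("local score is invariant under joint reverse-complement", {
  set.seed(11)
  for (i in 1:25) {
    q <- rand_seq(sample(4:15, 1)); t <- rand_seq(sample(10:40, 1))
    expect_equal(align_local(q, t)$score,
                 align_local(reverse_complement(q), reverse_complement(t))$score)
  }
})

test_that("all three alignment modes match the exhaustive DP oracle", {
  set.seed(19)
  schemes <- list(scoring_scheme(), clustering_scheme(),
                  scoring_scheme(match = 3, mismatch = -2, gap_open = -4,
                                 gap_extend = -2))
  for (i in 1:60) {
    q <- rand_seq(sample(1:12, 1)); t <- rand_seq(sample(1:12, 1))
    sc <- schemes[[1 + i %% length(schemes)]]
    expect_equal(align_global(q, t, sc)$score,
                 oracle_align_score(q, t, sc, "global"))
    expect_equal(align_local(q, t, sc)$score,
                 oracle_align_score(q, t, sc, "local"))
    expect_equal(align_global(q, t, sc, end_gap_free = TRUE)$score,
                 oracle_align_score(q, t, sc, "overlap"))
  }
})

test_that("native aligner agrees with Biostrings on global scores", {
  bases <- c("A", "C", "G", "T")
  mat <- matrix(-1, 4, 4, dimnames = list(bases, bases)); diag(mat) <- 2
  set.seed(23)
  for (i in 1:20) {
    q <- rand_seq(sample(6:25, 1)); t <- rand_seq(sample(6:25, 1))
    bs <- Biostrings::pairwiseAlignment(q, t, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 2, gapExtension = 1)
    expect_equal(align_global(q, t)$score, Biostrings::score(bs))
  }
})

test_that("clustering identity agrees with a Biostrings route on kin pairs", {
  # co-optimal alignments can split matches/mismatches differently between
  # engines, so the cross-check allows a small tolerance on collinear,
  # near-identical pairs (the regime the OTU stage operates in)
  set.seed(37)
  for (i in 1:15) {
    a <- rand_seq(300)
    b <- mutate_seq(a, 0.02)
    expect_equal(cluster_identity(a, b, clustering_scheme(), band = 40L),
                 oracle_cluster_identity(a, b), tolerance = 0.02)
  }
})

test_that("banded alignment equals full DP when the band covers the problem", {
  set.seed(31)
  for (i in 1:10) {
    q <- rand_seq(200)
    t <- mutate_seq(q, 0.05)
    expect_equal(align_global(q, t, band = 60L)$score, align_global(q, t)$score)
  }
})

test_that("alignment results are internally consistent and reproducible", {
  set.seed(7)
  q <- rand_seq(80); t <- mutate_seq(q, 0.1)
  a1 <- align_global(q, t, end_gap_free = TRUE)
  a2 <- align_global(q, t, end_gap_free = TRUE)
  expect_identical(a1, a2)
  expect_equal(a1$matches + a1$mismatches + a1$gap_cols, a1$columns)
  expect_equal(a1$identity_pct, 100 * a1$matches / a1$columns)
  expect_equal(gsub("-", "", a1$query_aln),
               substring(q, a1$query_span[1], a1$query_span[2]))
  expect_equal(gsub("-", "", a1$target_aln),
               substring(t, a1$target_span[1], a1$target_span[2]))
})
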