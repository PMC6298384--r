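test_that("synthesised references carry primers and verified divergence", {
  set.seed(401)
  spec <- mock_spec(n_species = 6, amplicon_len = 600, reads_total = 1)
  refs <- synth_references(spec)
  expect_length(refs, 6)
  expect_true(all(nchar(refs) == 600))
  # every reference begins with a concrete match of the degenerate 8F primer
  fwd <- "AGRGTTTGATCMTGGCTCAG"
  for (r in refs) {
    head_bases <- strsplit(substring(r, 1, nchar(fwd)), "")[[1]]
    codes <- strsplit(fwd, "")[[1]]
    expect_true(all(mapply(degenerate_match, head_bases, codes)))
  }
  # all pairwise identities below 1 - divergence
  for (i in 1:5) for (j in (i + 1):6)
    expect_lt(align_global(refs[[i]], refs[[j]], end_gap_free = TRUE,
                           band = 40L)$identity_pct, 95)
})

test_that("apply_errors spans its limit cases and honest edit ledger", {
  set.seed(402)
  ref <- rand_seq(500)
  clean <- apply_errors(ref, error_model(p_sub = 0, p_ins = 0, p_del = 0,
                                         homopolymer_del_boost = 0))
  expect_equal(clean$seq, ref)
  expect_equal(nrow(clean$edits), 0)

  gone <- apply_errors(ref, error_model(p_sub = 0, p_ins = 0, p_del = 1,
                                        homopolymer_del_boost = 0))
  expect_equal(gone$seq, "")

  for (i in 1:10) {
    er <- apply_errors(ref, error_model())
    expect_equal(replay_edits(ref, er$edits), er$seq)
  }
})

test_that("homopolymer boost concentrates deletions inside long runs", {
  set.seed(403)
  ref <- paste0(rand_seq(100), strrep("A", 30), rand_seq(100))
  m <- error_model(p_sub = 0, p_ins = 0, p_del = 0.01,
                   homopolymer_del_boost = 0.2)
  dels_in_run <- dels_out <- 0
  for (i in 1:50) {
    ed <- apply_errors(ref, m)$edits
    d <- ed$pos[ed$op == "del"]
    dels_in_run <- dels_in_run + sum(d > 100 & d <= 130)
    dels_out <- dels_out + sum(d <= 100 | d > 130)
  }
  # run covers 13% of positions but a ~21x higher per-base rate
  expect_gt(dels_in_run, dels_out)
})

test_that("make_read plants recoverable rotations and exact tandem copies", {
  set.seed(404)
  spec <- mock_spec(n_species = 1, amplicon_len = 700, reads_total = 1)
  ref <- synth_references(spec)[[1]]
  model0 <- error_model(p_sub = 0, p_ins = 0, p_del = 0,
                        homopolymer_del_boost = 0, p_tandem = 1)
  for (i in 1:10) {
    mr <- make_read(ref, model0)
    tr <- mr$truth
    expect_false(is.na(tr$tandem_start))
    # replay reproduces the read byte-exactly
    row <- data.frame(rotation = tr$rotation, strand = tr$strand,
                      tandem_start = tr$tandem_start,
                      tandem_window = tr$tandem_window,
                      tandem_copies = tr$tandem_copies)
    row$edits <- list(tr$edits)
    expect_equal(replay_truth(ref, row), mr$seq)
  }
})

test_that("simulate_run is byte-deterministic and respects abundances", {
  s1 <- simulate_run(mock_spec(n_species = 3, amplicon_len = 500,
                               reads_total = 40, seed = 9))
  s2 <- simulate_run(mock_spec(n_species = 3, amplicon_len = 500,
                               reads_total = 40, seed = 9))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$refs, s2$refs)
  expect_identical(s1$truth$rotation, s2$truth$rotation)

  sk <- simulate_run(mock_spec(n_species = 2, amplicon_len = 500,
                               reads_total = 400, seed = 10,
                               abundances = c(0.9, 0.1)))
  counts <- table(sk$truth$species)
  # multinomial 3 sigma around 360/40
  expect_gt(counts[["species_01"]], 360 - 3 * sqrt(400 * 0.9 * 0.1))
  expect_lt(counts[["species_02"]], 40 + 3 * sqrt(400 * 0.9 * 0.1))
})

test_that("tandem-repeat length sampler stays in the documented band", {
  set.seed(405)
  m <- error_model()
  lens <- vapply(1:500, function(i) nanoamplikit:::.sample_tandem_len(m, 1500L),
                 integer(1))
  expect_gte(min(lens), 10L)
  expect_gte(median(lens), 12)
  expect_lte(median(lens), 62)
  m2 <- error_model(chemistry = "1d2")
  lens2 <- vapply(1:500, function(i) nanoamplikit:::.sample_tandem_len(m2, 1500L),
                  integer(1))
  expect_gt(mean(lens2), mean(lens))  # the 1d2 preset adds a longer mode
})

test_that("error-free reads round-trip through chopSeq to their references", {
  set.seed(406)
  spec <- mock_spec(n_species = 2, amplicon_len = 700, reads_total = 20, seed = 5)
  model0 <- error_model(p_sub = 0, p_ins = 0, p_del = 0,
                        homopolymer_del_boost = 0)
  sim <- simulate_run(spec, model0)
  out <- run_chopseq(sim$reads, chop_params(min_len = 600, max_len = 800))
  expect_equal(unname(out$outcomes$status), rep("corrected", 20))
  for (id in names(out$corrected)) {
    sp <- sim$truth$species[sim$truth$read_id == id]
    expect_identical(unname(out$corrected[[id]]), unname(sim$refs[[sp]]))
  }
})
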