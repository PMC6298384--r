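# Fixtures: a primer-flanked amplicon with controlled rotation/flip/repeats.
make_amplicon <- function(core_len = 360, params = chop_params()) {
  paste0(nanoamplikit:::.instantiate_primer(params$forward_primer),
         rand_seq(core_len),
         reverse_complement(nanoamplikit:::.instantiate_primer(params$reverse_primer)))
}
rotate <- nanoamplikit:::.rotate

test_that("threshold_for_window interpolates linearly between the endpoints", {
  p <- chop_params(tr_threshold_at_min = 90, tr_threshold_at_max = 70)
  expect_equal(threshold_for_window(10, p), 90)
  expect_equal(threshold_for_window(350, p), 70)
  expect_equal(threshold_for_window(180, p), 90 - 20 * (180 - 10) / 340)
  expect_error(threshold_for_window(5, p), "outside")
  expect_error(threshold_for_window(351, p), "outside")
})

test_that("locate_primers resolves strand and rotation point", {
  set.seed(101)
  p <- chop_params()
  amp <- make_amplicon()
  r <- locate_primers(amp, p)
  expect_equal(r$strand, "plus")
  expect_true(r$found_forward && r$found_reverse)
  expect_equal(r$rotation_point, 1L)

  rm <- locate_primers(reverse_complement(amp), p)
  expect_equal(rm$strand, "minus")
  expect_equal(rm$rotation_point, 1L)

  rot <- rotate(amp, 150L)
  rr <- locate_primers(rot, p)
  expect_equal(rr$rotation_point, nchar(amp) - 150L + 1L)

  none <- locate_primers(rand_seq(300), p)
  expect_false(none$found_forward && none$found_reverse)
})

test_that("split_and_reorient reconstructs the amplicon and trims overhangs", {
  set.seed(102)
  p <- chop_params()
  amp <- make_amplicon()
  rep0 <- locate_primers(amp, p)
  sp <- split_and_reorient(amp, rep0)
  expect_equal(sp$forward, amp)
  expect_equal(sp$reverse, "")

  rot <- rotate(amp, 200L)
  spr <- split_and_reorient(rot, locate_primers(rot, p))
  expect_equal(paste0(spr$forward, spr$reverse), amp)

  # planted junk between the reverse-primer end and the junction is removed
  junk <- "GGGTT"
  rot2 <- paste0(substring(amp, 201), junk, substring(amp, 1, 200))
  sp2 <- split_and_reorient(rot2, locate_primers(rot2, p))
  expect_equal(paste0(sp2$forward, sp2$reverse), amp)
  expect_equal(sp2$trimmed_overhang_bp, nchar(junk))
})

test_that("scan_tandem_repeats finds exact repeats and extends copies", {
  p4 <- chop_params(tr_min_window = 4, tr_max_window = 6)
  r <- scan_tandem_repeats("ACGTACGTACGT", p4)
  expect_equal(nrow(r), 1)
  expect_equal(r$window, 4)
  expect_equal(r$n_copies, 3)

  set.seed(103)
  s <- rand_seq(600)
  seg <- substring(s, 561, 600)
  planted <- paste0(s, strrep(seg, 2))  # 3 adjacent copies at 561
  hit <- scan_tandem_repeats(planted, chop_params())
  expect_equal(nrow(hit), 1)
  expect_equal(hit$window, 40)
  expect_gte(hit$n_copies, 3)
  expect_equal(collapse_repeats(planted, hit)$seq, s)
})

test_that("repeat-free random sequence yields no detections", {
  set.seed(104)
  for (i in 1:20) {
    hits <- scan_tandem_repeats(rand_seq(500), chop_params())
    expect_equal(nrow(hits), 0)
  }
})

test_that("collapse_repeats retains one copy and conserves the remainder", {
  r <- data.frame(start = 1L, window = 4L, n_copies = 3L, identity_pct = 100)
  out <- collapse_repeats("ACGTACGTACGT", r)
  expect_equal(out$seq, "ACGT")
  expect_equal(out$removed_bp, 8L)
  expect_equal(collapse_repeats("ACGT", r[0, ]), list(seq = "ACGT", removed_bp = 0L))
  bad <- data.frame(start = c(1L, 5L), window = c(4L, 4L),
                    n_copies = c(3L, 2L), identity_pct = 100)
  expect_error(collapse_repeats("ACGTACGTACGTACGT", bad), "overlap")
})

test_that("run_chopseq restores rotated, flipped, repeat-carrying reads", {
  set.seed(105)
  p <- chop_params(min_len = 350, max_len = 450)
  amp <- make_amplicon(core_len = 364)  # 400 bp total
  reads <- character(20)
  for (i in 1:20) {
    s <- amp
    if (i %% 2 == 0) {  # plant an exact 25 bp duplication mid-core
      st <- 150 + i
      s <- paste0(substring(s, 1, st + 24), substring(s, st, st + 24),
                  substring(s, st + 25))
    }
    s <- rotate(s, 40 + 3 * i)
    if (i %% 3 == 0) s <- reverse_complement(s)
    reads[i] <- s
  }
  names(reads) <- sprintf("r%02d", 1:20)
  out <- run_chopseq(reads, p)
  expect_equal(unname(out$outcomes$status), rep("corrected", 20))
  expect_true(all(vapply(out$corrected, identical, logical(1), amp)))

  # idempotence on corrected output
  again <- run_chopseq(out$corrected, p)
  expect_identical(again$corrected, out$corrected)

  # mass conservation: input length = output + removed repeats + trimmed overhang
  oc <- out$outcomes
  expect_equal(nchar(reads[oc$read_id]) - oc$removed_repeat_bp - oc$trimmed_overhang_bp,
               setNames(oc$final_len, oc$read_id))
})

test_that("length selection discards out-of-range reads and empty input works", {
  set.seed(106)
  short <- make_amplicon(core_len = 200)  # 236 bp, below the 350 floor
  out <- run_chopseq(setNames(short, "s1"), chop_params(min_len = 350, max_len = 450))
  expect_equal(out$outcomes$status, "discarded_length")
  expect_length(out$corrected, 0)

  empty <- run_chopseq(setNames(character(0), character(0)))
  expect_equal(nrow(empty$outcomes), 0)
  expect_length(empty$corrected, 0)
})
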