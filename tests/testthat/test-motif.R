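test_that("SMO-like H8 window yields the mapped strict and gapped matches", {
  h8 <- make_smo_like_h8()
  strict <- scan_motif(h8, bbs_motif("strict"))
  expect_equal(nrow(strict), 1)
  expect_equal(strict$start, 549)
  expect_equal(strict$end, 550)
  expect_equal(strict$matched_text, "WR")

  gapped <- scan_motif(h8, bbs_motif("gapped"))
  expect_equal(nrow(gapped), 1)
  expect_equal(gapped$start, 553)
  expect_equal(gapped$end, 555)
  expect_equal(gapped$matched_text, "WCR")

  relaxed <- scan_motif(h8, bbs_motif("relaxed"))
  expect_equal(relaxed$start, 549)
})

test_that("PIP-motif scan finds Kx_n[K/R]xR with the gap reported by span", {
  loop <- make_bbs5_ph1_like_loop()
  m <- scan_pip_motif(loop)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 41)
  expect_equal(m$end, 49)

  toy <- sequence_record("toy", "KAAAARAR")
  mt <- scan_pip_motif(toy)
  expect_equal(nrow(mt), 1)
  expect_equal(c(mt$start, mt$end), c(1, 8))

  nok <- sequence_record("nok", "AAAARAR")
  expect_equal(nrow(scan_pip_motif(nok)), 0)
  empty <- sequence_record("e", "")
  expect_equal(nrow(scan_motif(empty, bbs_motif("strict"))), 0)
})

test_that("windowed scanning keeps only matches fully inside the window", {
  # W at 548 pairs with R at 549 across the window edge: excluded
  s <- sequence_record("w", "AAWRAAWR", offset = 546)
  inwin <- scan_motif(s, bbs_motif("strict"), window = c(549, 552))
  expect_equal(nrow(inwin), 0)
  wide <- scan_motif(s, bbs_motif("strict"), window = c(548, 553))
  expect_equal(wide$start, c(548, 552))
})

test_that("X never matches a residue class", {
  s <- sequence_record("x", "WXRWRX")
  m <- scan_motif(s, bbs_motif("strict"))
  expect_equal(m$start, 4)
  expect_equal(nrow(scan_motif(sequence_record("x2", "XXXX"),
                               bbs_motif("strict"))), 0)
})

test_that("scanner equals the brute-force regex oracle on random sequences", {
  set.seed(131)
  pats <- list(bbs_motif("strict"), bbs_motif("gapped"), pip_motif())
  for (i in 1:200) {
    rec <- sequence_record(paste0("r", i), random_aa_string(sample(5:40, 1)),
                           offset = sample(1:500, 1))
    for (p in pats) {
      spans <- regex_scan_spans(rec$residues, p)
      expect_spans_equal(scan_motif(rec, p), spans, rec)
    }
  }
})

test_that("cohort censuses reproduce planted counts and pattern containment", {
  co <- make_gpcr_cohort(seed = 1)
  strict <- cohort_motif_census(co$records, bbs_motif("strict"), co$windows)
  relaxed <- cohort_motif_census(co$records, bbs_motif("relaxed"),
                                 co$windows)
  expect_equal(strict$n_with_match, 20)
  expect_equal(relaxed$n_with_match, 23)
  expect_equal(strict$n_total, 26)
  expect_lte(strict$n_with_match, relaxed$n_with_match)

  # census invariant under sequence order permutation
  set.seed(141)
  perm <- sample(names(co$records))
  shuffled <- cohort_motif_census(co$records[perm], bbs_motif("strict"),
                                  co$windows)
  expect_equal(shuffled$n_with_match, strict$n_with_match)

  # per-sequence table agrees with the planted labels
  expect_equal(strict$table$n_matches > 0,
               co$truth[match(strict$table$sequence_id,
                              co$truth$sequence_id), "has_strict"])
})

test_that("census requires a window annotation for every sequence", {
  co <- make_gpcr_cohort(n_sequences = 4, seed = 2)
  expect_error(cohort_motif_census(co$records, bbs_motif("strict"),
                                   co$windows[-1]), "missing window")
})
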