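test_that("hydrophobic moment matches the geometric-series closed form", {
  sc <- hydrophobicity_scale()
  for (aa in c("L", "A", "S", "R")) {
    for (n in c(3, 7, 12, 18)) {
      s <- strrep(aa, n)
      delta <- 100 * pi / 180
      expected <- abs(sc[aa]) * abs(sin(n * delta / 2) / sin(delta / 2)) / n
      expect_lt(abs(hydrophobic_moment(s, sc) - expected), 1e-9)
    }
  }
})

test_that("single-residue moment is the absolute hydrophobicity", {
  sc <- hydrophobicity_scale()
  for (aa in c("W", "K", "G", "D")) {
    expect_equal(hydrophobic_moment(aa, sc), abs(unname(sc[aa])))
  }
  expect_error(hydrophobic_moment(""), "empty")
})

test_that("period-matched alternation maximizes the moment over permutations", {
  # twist 180 deg: period-2 helical wheel; the perfectly alternating
  # arrangement of 4 hydrophobic + 4 polar residues must beat every other
  # permutation of the same composition
  sc <- hydrophobicity_scale()
  best <- hydrophobic_moment("LSLSLSLS", sc, twist = 180)
  slots <- utils::combn(8, 4)
  mu <- apply(slots, 2, function(ii) {
    s <- rep("S", 8); s[ii] <- "L"
    hydrophobic_moment(paste(s, collapse = ""), sc, twist = 180)
  })
  expect_lt(max(mu) - best, 1e-12)
})

test_that("moment is non-negative and reversal/twist-flip invariant", {
  set.seed(91)
  for (i in 1:20) {
    s <- random_aa_string(sample(2:25, 1))
    mu <- hydrophobic_moment(s)
    expect_gte(mu, 0)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_lt(abs(hydrophobic_moment(rev_s, twist = -100) - mu), 1e-12)
  }
})

test_that("annotate_helix8 places the window after TM7 with truncation flags", {
  smo_tail <- sequence_record("smo", strrep("A", 251), offset = 543)
  ann <- annotate_helix8(smo_tail, tm7_end = 542)
  expect_equal(ann$window, c(543, 559))
  expect_equal(ann$source, "config")
  expect_false(ann$truncated)

  short <- sequence_record("s", "AAAAAAAAAA", offset = 543)
  expect_true(annotate_helix8(short, tm7_end = 542)$truncated)
  expect_true(annotate_helix8(short, tm7_end = 552)$empty)
})

test_that("heuristic window finder recovers planted amphipathic windows", {
  co <- make_gpcr_cohort(seed = 20)
  hits <- vapply(names(co$records), function(id) {
    ann <- annotate_helix8(co$records[[id]])
    abs(ann$window[1] - co$windows[[id]][1]) <= 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("sequence properties: tail span length, acidity, pI self-consistency", {
  # synthetic stand-in for an 85-residue highly acidic disordered tail
  # (30 D/E over the author-numbered interval 329..413)
  set.seed(101)
  n <- 413 - 329 + 1
  tail_seq <- rep("S", n)
  tail_seq[sample(n, 30)] <- sample(c("D", "E"), 30, replace = TRUE)
  tail_seq[sample(which(tail_seq == "S"), 20)] <-
    sample(c("G", "T", "A", "P", "N"), 20, replace = TRUE)
  rec <- sequence_record("ift38_tail_like_synthetic",
                         paste(tail_seq, collapse = ""), offset = 329)
  props <- sequence_properties(rec)
  expect_equal(props$length, 85)
  expect_equal(props$n_acidic, 30)
  expect_lt(props$theoretical_pI, 5)
  expect_lt(abs(net_charge(rec, props$theoretical_pI)), 1e-4)

  expect_lt(sequence_properties("EEEE")$theoretical_pI, 7)
})

test_that("pI is monotone under adding acidic or basic residues", {
  set.seed(111)
  for (i in 1:10) {
    s <- random_aa_string(sample(5:30, 1), with_x = FALSE)
    base <- sequence_properties(s)$theoretical_pI
    expect_lte(sequence_properties(paste0(s, "D"))$theoretical_pI,
               base + 1e-6)
    expect_gte(sequence_properties(paste0(s, "K"))$theoretical_pI,
               base - 1e-6)
  }
})
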