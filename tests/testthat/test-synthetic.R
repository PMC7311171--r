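test_that("ideal helix geometry follows the closed forms", {
  one <- make_ideal_helix(1)
  expect_equal(n_atoms(one), 1)
  expect_equal(sqrt(sum(coords(one)[1, 1:2]^2)), 2.3)

  h7 <- make_ideal_helix(7)
  z <- coords(h7)[, 3]
  expect_equal(max(z) - min(z), 9.0)   # (7 - 1) x 1.5

  ca <- coords(make_ideal_helix(20))
  d <- sqrt(rowSums((ca[-1, ] - ca[-20, ])^2))
  expected <- sqrt(1.5^2 + (2 * 2.3 * sin(50 * pi / 180))^2)
  expect_true(all(abs(d - expected) < 1e-6))
  expect_equal(expected, 3.8, tolerance = 0.02)
})

test_that("extended chain end-to-end distance is (n-1) x rise", {
  c7 <- coords(make_extended_chain(7))
  expect_equal(sqrt(sum((c7[7, ] - c7[1, ])^2)), 21.0)
  expect_equal(nrow(coords(make_extended_chain(1))), 1)
  set.seed(81)
  for (n in sample(2:100, 10)) {
    cc <- coords(make_extended_chain(n))
    expect_equal(sqrt(sum((cc[n, ] - cc[1, ])^2)), (n - 1) * 3.5)
  }
})

test_that("membrane fixture plants a parallel anchor and is seed-deterministic", {
  fx <- make_membrane_complex_fixture(seed = 7)
  ax <- helix_axis(ca_coords(fx$model, chain = "A"))
  expect_lt(abs(sum(ax * fx$plane$normal)), 1e-6)
  # anchor centroid at headgroup depth below the planted plane
  cen <- colMeans(ca_coords(fx$model, chain = "A"))
  expect_equal(signed_plane_distance(cen, fx$plane), -3, tolerance = 1e-9)
  # body entirely cytoplasmic
  body <- fx$model$atoms[fx$model$atoms$chain == "B", ]
  expect_true(all(signed_plane_distance(as.matrix(body[, c("x", "y", "z")]),
                                        fx$plane) < 0))
  fx2 <- make_membrane_complex_fixture(seed = 7)
  expect_equal(fx2$model$atoms, fx$model$atoms)
  fx3 <- make_membrane_complex_fixture(seed = 8)
  expect_false(isTRUE(all.equal(fx3$model$atoms$x, fx$model$atoms$x)))
})

test_that("cohort generator plants motif carriers at the requested counts", {
  co <- make_gpcr_cohort(seed = 5)
  expect_equal(sum(co$truth$has_strict), 20)
  expect_equal(sum(co$truth$has_relaxed), 23)
  expect_equal(nrow(co$truth), 26)

  none <- make_gpcr_cohort(n_sequences = 12, motif_fraction = 0,
                           strict_fraction = 0, seed = 5)
  expect_equal(
    cohort_motif_census(none$records, bbs_motif("relaxed"),
                        none$windows)$n_with_match, 0)
  all_hit <- make_gpcr_cohort(n_sequences = 12, motif_fraction = 1,
                              strict_fraction = 1, seed = 5)
  expect_equal(
    cohort_motif_census(all_hit$records, bbs_motif("relaxed"),
                        all_hit$windows)$n_with_match, 12)

  co2 <- make_gpcr_cohort(seed = 5)
  expect_identical(vapply(co2$records, function(r) r$residues, character(1)),
                   vapply(co$records, function(r) r$residues, character(1)))
})

test_that("cohort FASTA + sidecar round trip preserves planted truth", {
  co <- make_gpcr_cohort(seed = 9)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_cohort(co, f)
  back <- read_fasta_records(f)
  expect_equal(length(back), 26)
  expect_equal(back[[1]]$residues, co$records[[1]]$residues)
  truth <- jsonlite::read_json(paste0(f, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$sequence_id, co$truth$sequence_id)
  expect_equal(sum(truth$has_strict), sum(co$truth$has_strict))
})

test_that("PH-site fixture plants exactly the requested clash count", {
  fx <- make_ph_site_fixture(12, seed = 3)
  cl <- count_clashes(fx$truth$ligand, fx$environment, cutoff = 3.0)
  expect_equal(cl$count, 12L)
  expect_equal(cl$nearest_blocker, "E")

  fx0 <- make_ph_site_fixture(0, seed = 3)
  expect_equal(count_clashes(fx0$truth$ligand, fx0$environment,
                             cutoff = 3.0)$count, 0L)

  # tightening the cutoff can only lose clashes
  fx3 <- make_ph_site_fixture(3, seed = 4)
  tight <- count_clashes(fx3$truth$ligand, fx3$environment,
                         cutoff = 2.5)$count
  expect_lte(tight, 3L)
})
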