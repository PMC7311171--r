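test_that("a template superposed onto itself leaves the ligand unchanged", {
  tmpl <- make_ph_site_fixture(0, seed = 2)$template
  placed <- place_template_ligand(tmpl$ph, tmpl)
  expect_lt(placed$rmsd, 1e-9)
  expect_lt(max(abs(placed$ligand - tmpl$ligand)), 1e-9)
})

test_that("a planted transform is recovered exactly by ligand placement", {
  for (s in c(1, 9)) {
    fx <- make_ph_site_fixture(5, seed = s)
    placed <- place_template_ligand(fx$query_ph, fx$template)
    expect_lt(max(abs(placed$ligand - fx$truth$ligand)), 1e-6)
    expect_lt(placed$rmsd, 1e-9)
  }
})

test_that("placement refuses too few alignable pairs", {
  fx <- make_ph_site_fixture(0, seed = 2)
  short <- structure_model(fx$query_ph$atoms[1:10, ])
  expect_error(place_template_ligand(short, fx$template), "alignable")
})

test_that("clash counting is exact on planted fixtures and monotone in cutoff", {
  fx <- make_ph_site_fixture(12, seed = 5)
  placed <- place_template_ligand(fx$query_ph, fx$template)
  counts <- vapply(c(1.5, 2.0, 2.5, 3.0, 4.0, 8.0), function(ct)
    count_clashes(placed$ligand, fx$environment, cutoff = ct)$count,
    integer(1))
  expect_equal(counts[4], 12L)
  expect_true(all(diff(counts) >= 0))

  # excluding the clashing chain empties the count
  excl <- count_clashes(placed$ligand, fx$environment,
                        exclude = c("E", "F"), cutoff = 3.0)
  expect_equal(excl$count, 0L)
  expect_true(is.na(excl$nearest_blocker))
})

test_that("site assessment verdicts: open, distant and blocked", {
  fx0 <- make_ph_site_fixture(0, seed = 3)
  lig_cen <- colMeans(fx0$truth$ligand)
  # plane 4 A from the ligand centroid -> open
  nrm <- c(0, 0, 1)
  near_plane <- plane_model(nrm, sum(nrm * lig_cen) + 4)
  open <- assess_site(fx0$query_ph, "canonical", list(fx0$template),
                      fx0$environment, plane = near_plane)
  expect_equal(open$verdict, "open")
  expect_equal(open$clash_count, 0)

  # plane 12 A away with a 10 A threshold -> distant (the 1 nm rule)
  far_plane <- plane_model(nrm, sum(nrm * lig_cen) + 12)
  distant <- assess_site(fx0$query_ph, "atypical", list(fx0$template),
                         fx0$environment, plane = far_plane,
                         distance_threshold = 10)
  expect_equal(distant$verdict, "distant")
  expect_equal(distant$membrane_distance, 12, tolerance = 1e-6)

  fx12 <- make_ph_site_fixture(12, seed = 3)
  blocked <- assess_site(fx12$query_ph, "canonical", list(fx12$template),
                         fx12$environment, plane = near_plane,
                         domain_map = c(E = "blocking_loop"))
  expect_equal(blocked$verdict, "blocked")
  expect_equal(blocked$nearest_blocker, "blocking_loop")
})

test_that("nine templates place the ligand consistently; median is stable", {
  fx <- make_ph_site_fixture(4, seed = 6)
  lib <- make_ph_template_library(9, seed = 7)
  res <- assess_site(fx$query_ph, "canonical", lib, fx$environment)
  cen <- as.matrix(res$per_template[, c("centroid_x", "centroid_y",
                                        "centroid_z")])
  spread <- max(dist(cen))
  dom_size <- max(dist(coords(fx$query_ph)))
  expect_lt(spread, 0.1 * dom_size)

  counts <- res$per_template$clash_count
  med_all <- stats::median(counts)
  for (k in seq_along(counts)) {
    expect_lte(abs(stats::median(counts[-k]) - med_all),
               max(counts) - min(counts) + 1e-9)
  }
})

test_that("assessment is invariant under a joint rigid transform", {
  fx <- make_ph_site_fixture(7, seed = 8)
  nrm <- c(0, 0, 1)
  plane <- plane_model(nrm, sum(nrm * colMeans(fx$truth$ligand)) + 6)
  base <- assess_site(fx$query_ph, "canonical", list(fx$template),
                      fx$environment, plane = plane)
  set.seed(15)
  tr <- random_transform()
  moved <- assess_site(transform_structure(fx$query_ph, tr), "canonical",
                       list(fx$template),
                       transform_structure(fx$environment, tr),
                       plane = transform_plane(tr, plane))
  expect_equal(moved$clash_count, base$clash_count)
  expect_equal(moved$verdict, base$verdict)
  expect_equal(moved$membrane_distance, base$membrane_distance,
               tolerance = 1e-6)
})
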