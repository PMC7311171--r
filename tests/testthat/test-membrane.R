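test_that("place_membrane recovers a planted plane from the amphipathic anchor", {
  for (s in c(2, 12, 22)) {
    fx <- make_membrane_complex_fixture(seed = s)
    pl <- place_membrane(fx$model, fx$anchor)
    expect_true(pl$feasible)
    expect_lt(angle_between(pl$plane$normal, fx$plane$normal), 5)
    expect_lt(abs(pl$plane$offset - fx$plane$offset), 2)
  }
  # and for a tilted planted plane
  fx <- make_membrane_complex_fixture(
    plane = plane_model(c(1, 1, 2), offset = 10, 3), seed = 3)
  pl <- place_membrane(fx$model, fx$anchor)
  expect_lt(angle_between(pl$plane$normal, fx$plane$normal), 5)
  expect_lt(abs(pl$plane$offset - fx$plane$offset), 2)
})

test_that("an ideal helix as its own anchor yields a plane parallel to its axis", {
  h <- make_ideal_helix(18)
  pl <- place_membrane(h, anchor_spec("A", 18, c(1, 18)))
  expect_true(pl$feasible)
  expect_lt(abs(90 - angle_between(pl$plane$normal, c(0, 0, 1))), 1e-3)
})

test_that("membrane placement is equivariant under rigid motion of the model", {
  fx <- make_membrane_complex_fixture(seed = 6)
  pl0 <- place_membrane(fx$model, fx$anchor)
  set.seed(14)
  tr <- random_transform()
  pl1 <- place_membrane(transform_structure(fx$model, tr), fx$anchor)
  expected <- transform_plane(tr, pl0$plane)
  expect_lt(angle_between(pl1$plane$normal, expected$normal), 1e-6)
  expect_lt(abs(pl1$plane$offset - expected$offset), 1e-6)
})

test_that("place_membrane reports infeasibility when the body surrounds the anchor", {
  h <- make_ideal_helix(18)
  # enclose the helix in a shell of atoms so no clearance direction exists
  set.seed(4)
  dirs <- matrix(rnorm(900), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cen <- colMeans(ca_coords(h))
  shell <- sweep(dirs * 12, 2, cen, "+")
  cage <- data.frame(element = "C", name = "CA", x = shell[, 1],
                     y = shell[, 2], z = shell[, 3],
                     resno = seq_len(nrow(shell)), insert = "",
                     resid = "GLY", chain = "B", het = FALSE)
  model <- structure_model(rbind(h$atoms[, names(cage)], cage))
  pl <- place_membrane(model, anchor_spec("A", 18, c(1, 18)))
  expect_false(pl$feasible)
  expect_gt(pl$n_penetrating, 0)
})

test_that("min_patch_distance: the anchor itself sits in the headgroup layer", {
  fx <- make_membrane_complex_fixture(seed = 2)
  anchor_ca_xyz <- ca_coords(fx$model, chain = "A")
  md <- min_patch_distance(fx$model, fx$anchor, anchor_ca_xyz)
  expect_true(md$feasible)
  expect_lte(md$min_distance, fx$anchor$headgroup_depth)
})

test_that("coarse-grid minimum matches a dense 0.5-degree oracle within 0.5 A", {
  fx <- make_membrane_complex_fixture(seed = 13, n_body = 120L)
  coarse <- min_patch_distance(fx$model, fx$anchor, "P", theta_step = 2)
  dense <- min_patch_distance(fx$model, fx$anchor, "P", theta_step = 0.5,
                              tilt_step = 0.5)
  expect_lt(abs(coarse$min_distance - dense$min_distance), 0.5)
  expect_lte(dense$min_distance, coarse$min_distance + 1e-9)
})

test_that("min distance is non-increasing on nested angular grids", {
  fx <- make_membrane_complex_fixture(seed = 17, n_body = 120L)
  d <- vapply(c(8, 4, 2), function(s)
    min_patch_distance(fx$model, fx$anchor, "P", theta_step = s)$min_distance,
    numeric(1))
  expect_true(all(diff(d) <= 1e-9))
})

test_that("charge census counts planted in-slab charges and nothing else", {
  polyk <- make_ideal_helix(10, sequence = strrep("K", 10))
  plane_above <- plane_model(c(0, 0, 1), max(coords(polyk)[, 3]) + 1)
  cc <- membrane_facing_charge_census(polyk, plane_above, slab_depth = 30)
  expect_equal(cc$positive_count, 10)
  expect_equal(cc$negative_count, 0)

  fx <- make_membrane_complex_fixture(seed = 3, plant_positive = 7,
                                      plant_negative = 2)
  cen <- membrane_facing_charge_census(fx$model, fx$plane, slab_depth = 8)
  expect_equal(cen$positive_count, 7)
  expect_equal(cen$negative_count, 2)
  expect_equal(cen$net, 5)
})

test_that("charge census is monotone in slab depth and bounded by residue counts", {
  fx <- make_membrane_complex_fixture(seed = 3, plant_positive = 5,
                                      plant_negative = 3)
  prev_pos <- -1; prev_neg <- -1
  for (depth in c(2, 5, 10, 40, 120)) {
    cc <- membrane_facing_charge_census(fx$model, fx$plane,
                                        slab_depth = depth)
    expect_gte(cc$positive_count, prev_pos)
    expect_gte(cc$negative_count, prev_neg)
    expect_lte(cc$positive_count + cc$negative_count,
               n_residues(fx$model))
    prev_pos <- cc$positive_count; prev_neg <- cc$negative_count
  }
})

test_that("curvature: a 1250 A cylinder is flat at complex scale", {
  fx <- make_membrane_complex_fixture(seed = 5)
  pl <- place_membrane(fx$model, fx$anchor)
  curv <- curvature_compatibility(fx$model, pl$plane, radius = 1250)
  flat_count <- sum(signed_plane_distance(
    coords(fx$model, heavy_only = TRUE), pl$plane) > 2)
  expect_lte(abs(curv$penetration_count - flat_count), 1)
})

test_that("curvature separates convex-matched from concave-up surfaces", {
  r <- 50
  pl <- plane_model(c(0, 0, 1), 0)
  x <- seq(-30, 30, by = 1.5)
  convex_z <- sqrt((r - 0.5)^2 - pmin(x^2, (r - 0.5)^2)) - r
  concave_z <- -(20 - x^2 / 45)
  mk <- function(z) structure_model(data.frame(
    element = "C", name = "CA", x = x, y = 0, z = z,
    resno = seq_along(x), insert = "", resid = "GLY", chain = "A",
    het = FALSE))
  convex <- curvature_compatibility(mk(convex_z), pl, radius = r,
                                    axis_direction = c(0, 1, 0),
                                    slab_depth = 30)
  expect_equal(convex$penetration_count, 0)
  expect_gt(convex$contact_fraction, 0.9)
  concave <- curvature_compatibility(mk(concave_z), pl, radius = r,
                                     axis_direction = c(0, 1, 0),
                                     slab_depth = 30)
  expect_gt(concave$penetration_count, 0)
})
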