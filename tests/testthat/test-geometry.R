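test_that("superpose recovers identity and constructed rotations exactly", {
  set.seed(11)
  p <- matrix(rnorm(30), ncol = 3)
  selfFit <- superpose(p, p)
  expect_lt(selfFit$rmsd, 1e-9)
  expect_equal(selfFit$transform$rotation, diag(3), tolerance = 1e-9)

  r37 <- rotation_about_axis(c(0, 0, 1), 37)
  moved <- sweep(p %*% t(r37), 2, c(3, -2, 7), "+")
  fit <- superpose(p, moved)
  expect_lt(abs(rotation_angle(fit$transform) - 37), 1e-6)
  expect_lt(fit$rmsd, 1e-6)
})

test_that("superpose rmsd matches the quaternion-method oracle on random clouds", {
  set.seed(21)
  for (i in 1:20) {
    a <- matrix(rnorm(150), ncol = 3)
    b <- matrix(rnorm(150), ncol = 3)
    expect_lt(abs(superpose(a, b)$rmsd - horn_rmsd(a, b)), 1e-6)
  }
})

test_that("superpose rmsd is invariant under pre-applied rigid transforms", {
  set.seed(31)
  a <- matrix(rnorm(90), ncol = 3)
  b <- matrix(rnorm(90), ncol = 3)
  base <- superpose(a, b)$rmsd
  for (i in 1:5) {
    expect_lt(abs(superpose(apply_transform(random_transform(), a), b)$rmsd -
                    base), 1e-6)
    expect_lt(abs(superpose(a, apply_transform(random_transform(), b))$rmsd -
                    base), 1e-6)
  }
})

test_that("superpose rejects degenerate inputs", {
  expect_error(superpose(matrix(rnorm(6), ncol = 3),
                         matrix(rnorm(6), ncol = 3)), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("rotation_angle reads back constructed rotations and compositions", {
  expect_equal(rotation_angle(rigid_transform()), 0)
  set.seed(41)
  for (ang in c(0.5, 20, 37, 120, 179)) {
    ax <- rnorm(3)
    t1 <- rigid_transform(rotation_about_axis(ax, ang), rnorm(3))
    expect_lt(abs(rotation_angle(t1) - ang), 1e-6)
    expect_lt(rotation_angle(compose_transform(t1, invert_transform(t1))),
              1e-6)
  }
})

test_that("signed plane distance is signed, zero on the plane, rigid-invariant", {
  pl <- plane_model(c(0, 0, 1), 0)
  expect_equal(signed_plane_distance(c(5, 5, 0), pl), 0)
  expect_equal(signed_plane_distance(c(5, 5, 7), pl), 7)
  set.seed(51)
  for (i in 1:10) {
    pl2 <- plane_model(rnorm(3), rnorm(1) * 5)
    x <- rnorm(3) * 10
    tr <- random_transform()
    d0 <- signed_plane_distance(x, pl2)
    d1 <- signed_plane_distance(apply_transform(tr, x),
                                transform_plane(tr, pl2))
    expect_lt(abs(d1 - d0), 1e-9)
  }
})

test_that("cylinder surface distance is signed and converges to the plane limit", {
  cyl <- cylinder_model(c(0, 0, 100), c(0, 1, 0), 100)
  expect_equal(cylinder_surface_distance(c(0, 0, 100), cyl), -100)
  expect_equal(cylinder_surface_distance(c(0, 0, 0), cyl), 0)
  # flat limit: radius 100x the patch size, wall tangent to z = 0 from above;
  # inside-wall distance approaches minus the plane height
  r <- 1000
  cylBig <- cylinder_model(c(0, 0, r), c(0, 1, 0), r)
  pl <- plane_model(c(0, 0, 1), 0)
  set.seed(61)
  pts <- cbind(runif(50, -5, 5), runif(50, -5, 5), runif(50, 3, 8))
  dc <- cylinder_surface_distance(pts, cylBig)
  dp <- signed_plane_distance(pts, pl)
  expect_true(all(abs(-dc - dp) <= 0.01 * abs(dp)))
})

test_that("helix_axis is exact for ideal helices in any frame", {
  h <- make_ideal_helix(11)
  expect_lt(angle_between(helix_axis(ca_coords(h)), c(0, 0, 1)), 1e-6)
  set.seed(71)
  tr <- random_transform()
  h2 <- transform_structure(h, tr)
  expect_lt(angle_between(helix_axis(ca_coords(h2)),
                          as.numeric(tr$rotation %*% c(0, 0, 1))), 1e-6)
})
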