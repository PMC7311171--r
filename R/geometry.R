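#' Rigid-body transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1
#' @param translation length-3 numeric vector (Angstrom)
#' @return object of class `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation matrix is not orthonormal within 1e-8")
  }
  if (det(rotation) < 0) stop("rotation has determinant -1 (reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`
#' @param points n x 3 matrix or length-3 vector
#' @return transformed points, same shape as input
#' @export
apply_transform <- function(transform, points) {
  if (is.null(dim(points))) {
    return(as.numeric(transform$rotation %*% points + transform$translation))
  }
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms (apply `second` after `first`)
#' @param second,first `rigid_transform` objects
#' @return their composition as a `rigid_transform`
#' @export
compose_transform <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation + translation minimizing the RMSD between paired point
#' sets, with a reflection guard (determinant forced to +1 so chirality is
#' preserved).
#'
#' @param moving,fixed n x 3 matrices of paired points, n >= 3, not collinear
#' @return list with `transform` (a `rigid_transform` mapping `moving` onto
#'   `fixed`) and `rmsd` (the minimized value, Angstrom)
#' @export
superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)) || ncol(moving) != 3) {
    stop("point sets must be equal-sized n x 3 matrices")
  }
  n <- nrow(moving)
  if (n < 3) stop("need at least 3 points for superposition")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  pm <- sweep(moving, 2, cm); pf <- sweep(fixed, 2, cf)
  # collinearity check: rank of the centered configuration
  if (sum(svd(pm)$d > 1e-8 * max(1, max(abs(pm)))) < 2) {
    stop("degenerate (collinear) point configuration")
  }
  h <- crossprod(pm, pf)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cf - as.numeric(r %*% cm)
  moved <- sweep(moving %*% t(r), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((moved - fixed)^2)))
  list(transform = rigid_transform(r, tr), rmsd = rmsd)
}

#' Rotation angle of a rigid transform
#'
#' Angle of the axis-angle decomposition of the rotation part, the scalar
#' used to quantify domain rotations between conformations.
#'
#' @param transform a `rigid_transform`
#' @return angle in degrees, in [0, 180]
#' @export
rotation_angle <- function(transform) {
  r <- transform$rotation
  # atan2 form: accurate near 0 where acos((tr-1)/2) loses precision
  v <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])
  atan2(sqrt(sum(v^2)) / 2, (sum(diag(r)) - 1) / 2) * 180 / pi
}

#' Rotation axis of a rigid transform
#' @param transform a `rigid_transform`
#' @return unit 3-vector (arbitrary for the identity)
#' @export
rotation_axis <- function(transform) {
  r <- transform$rotation
  v <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) {
    # angle 0 or 180; fall back to eigen decomposition
    e <- eigen(r)
    i <- which.min(abs(Re(e$values) - 1))
    v <- Re(e$vectors[, i])
    nv <- sqrt(sum(v^2))
  }
  v / nv
}

#' Rotation about an axis
#' @param axis 3-vector (normalized internally)
#' @param angle_deg angle in degrees
#' @return 3x3 rotation matrix (Rodrigues formula)
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  k <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' Oriented membrane plane
#'
#' The plane `{x : normal . x = offset}` with the unit normal pointing from
#' the cytoplasm into the membrane; `headgroup_half_thickness` records the
#' half-thickness of the lipid-headgroup layer the plane represents.
#'
#' @param normal 3-vector (normalized internally; must be non-zero)
#' @param offset scalar, Angstrom
#' @param headgroup_half_thickness Angstrom, >= 0
#' @return object of class `plane_model`
#' @export
plane_model <- function(normal, offset = 0, headgroup_half_thickness = 0) {
  nv <- sqrt(sum(normal^2))
  if (nv < 1e-12) stop("plane normal must be non-zero")
  stopifnot(headgroup_half_thickness >= 0)
  structure(list(normal = as.numeric(normal) / nv, offset = as.numeric(offset),
                 headgroup_half_thickness = headgroup_half_thickness),
            class = "plane_model")
}

#' Signed distance from points to a plane
#'
#' Positive on the normal side (inside the membrane for a placed plane),
#' zero on the plane, negative on the cytoplasmic side.
#'
#' @param point length-3 vector or n x 3 matrix
#' @param plane a `plane_model`
#' @return numeric scalar or vector, Angstrom
#' @export
signed_plane_distance <- function(point, plane) {
  if (is.null(dim(point))) {
    return(sum(plane$normal * point) - plane$offset)
  }
  as.numeric(point %*% plane$normal) - plane$offset
}

#' Apply a rigid transform to a plane
#' @param transform a `rigid_transform`
#' @param plane a `plane_model`
#' @return transformed `plane_model`
#' @export
transform_plane <- function(transform, plane) {
  n2 <- as.numeric(transform$rotation %*% plane$normal)
  plane_model(n2, plane$offset + sum(n2 * transform$translation),
              plane$headgroup_half_thickness)
}

#' Cylinder surface (curved-membrane model)
#'
#' The ciliary membrane is modelled as a cylinder; by default downstream
#' code uses a 250 nm diameter cilium, i.e. radius 1250 Angstrom.
#'
#' @param axis_point point on the axis (3-vector, Angstrom)
#' @param axis_direction axis direction (normalized internally)
#' @param radius cylinder radius, Angstrom, > 0
#' @return object of class `cylinder_model`
#' @export
cylinder_model <- function(axis_point, axis_direction, radius) {
  stopifnot(radius > 0)
  nv <- sqrt(sum(axis_direction^2))
  if (nv < 1e-12) stop("axis direction must be non-zero")
  structure(list(axis_point = as.numeric(axis_point),
                 axis_direction = as.numeric(axis_direction) / nv,
                 radius = radius),
            class = "cylinder_model")
}

#' Signed distance from points to a cylinder surface
#'
#' Radial distance to the axis minus the radius: negative inside the wall
#' (the lumenal/cytoplasmic side for a membrane cylinder), zero on the
#' surface, positive beyond it.
#'
#' @param point length-3 vector or n x 3 matrix
#' @param cyl a `cylinder_model`
#' @return numeric scalar or vector, Angstrom
#' @export
cylinder_surface_distance <- function(point, cyl) {
  pts <- if (is.null(dim(point))) matrix(point, 1, 3) else as.matrix(point)
  d <- sweep(pts, 2, cyl$axis_point)
  along <- as.numeric(d %*% cyl$axis_direction)
  perp <- d - outer(along, cyl$axis_direction)
  out <- sqrt(rowSums(perp^2)) - cyl$radius
  if (is.null(dim(point))) out[1] else out
}

#' Helix axis by self-superposition screw fit
#'
#' Superposes the CA trace onto itself shifted by one residue; for a helix
#' the residual rotation axis is the helix axis (exact for an ideal helix,
#' least-squares for a distorted one). The axis is oriented from the first
#' toward the last residue.
#'
#' @param ca n x 3 matrix of consecutive CA positions, n >= 4
#' @return unit 3-vector
#' @export
helix_axis <- function(ca) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 4) stop("need at least 4 CA atoms to fit a helix axis")
  fit <- superpose(ca[1:(n - 1), , drop = FALSE], ca[2:n, , drop = FALSE])
  ax <- rotation_axis(fit$transform)
  if (sum(ax * (ca[n, ] - ca[1, ])) < 0) ax <- -ax
  ax
}

#' Angle between two directions
#' @param a,b 3-vectors
#' @param undirected if TRUE (default), treat a and -a as the same direction
#' @return angle in degrees
#' @export
angle_between <- function(a, b, undirected = TRUE) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  if (undirected) ca <- abs(ca)
  acos(max(-1, min(1, ca))) * 180 / pi
}
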