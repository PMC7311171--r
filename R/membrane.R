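#' Amphipathic-anchor specification
#'
#' Describes the amphipathic helix that anchors a complex in the lipid
#' headgroup layer (for the BBSome-ARL6 complex: the ARL6 N-terminal helix,
#' whose core GTPase domain starts at Ser15). The helix axis must lie
#' membrane-parallel within `parallelism_tolerance` and its CA centroid at
#' `headgroup_depth` below the headgroup plane.
#'
#' @param chain chain id carrying the anchor helix
#' @param anchor_residue author number of the residue marking the end of the
#'   anchor (e.g. 15 for ARL6 Ser15); must lie within or adjacent to
#'   `anchor_helix_range`
#' @param anchor_helix_range inclusive author-numbered interval of the
#'   anchor helix (needs >= 4 CA atoms)
#' @param parallelism_tolerance allowed tilt of the helix axis out of the
#'   membrane plane, degrees
#' @param headgroup_depth depth of the helix centroid below the headgroup
#'   plane, Angstrom
#' @return object of class `anchor_spec`
#' @export
anchor_spec <- function(chain, anchor_residue, anchor_helix_range,
                        parallelism_tolerance = 5, headgroup_depth = 3) {
  stopifnot(length(anchor_helix_range) == 2,
            anchor_helix_range[1] <= anchor_helix_range[2])
  if (anchor_residue < anchor_helix_range[1] - 1 ||
      anchor_residue > anchor_helix_range[2] + 1) {
    stop("anchor residue must lie within or adjacent to the helix range")
  }
  structure(list(chain = chain, anchor_residue = as.integer(anchor_residue),
                 anchor_helix_range = as.integer(anchor_helix_range),
                 parallelism_tolerance = parallelism_tolerance,
                 headgroup_depth = headgroup_depth),
            class = "anchor_spec")
}

anchor_ca <- function(model, anchor) {
  sel <- select_domain(model, domain_selection(anchor$chain, "anchor",
                                               anchor$anchor_helix_range))
  ca <- ca_coords(sel)
  if (nrow(ca) < 4) stop("anchor helix resolves to fewer than 4 CA atoms")
  list(ca = ca, model = sel)
}

# hydrophobic-face direction of an anchor helix: hydrophobicity-weighted sum
# of unit radial CA vectors, projected perpendicular to the axis
hydrophobic_face <- function(sel_model, ca, axis,
                             scale = hydrophobicity_scale()) {
  seqrec <- extract_sequence(sel_model, sel_model$atoms$chain[1])
  h <- unname(scale[seq_letters(seqrec)])
  h[is.na(h)] <- 0
  centroid <- colMeans(ca)
  rel <- sweep(ca, 2, centroid)
  perp <- rel - outer(as.numeric(rel %*% axis), axis)
  nr <- sqrt(rowSums(perp^2))
  ok <- nr > 1e-9
  f <- colSums(perp[ok, , drop = FALSE] / nr[ok] * h[ok])
  f <- f - sum(f * axis) * axis
  nf <- sqrt(sum(f^2))
  if (nf < 1e-6) return(NULL)
  f / nf
}

candidate_normals <- function(axis, face, theta) {
  w1 <- face
  w2 <- c(axis[2] * w1[3] - axis[3] * w1[2],
          axis[3] * w1[1] - axis[1] * w1[3],
          axis[1] * w1[2] - axis[2] * w1[1])
  th <- theta * pi / 180
  cbind(cos(th)) %*% rbind(w1) + cbind(sin(th)) %*% rbind(w2)
}

#' Place a membrane plane from an amphipathic anchor
#'
#' Returns a headgroup plane satisfying: (a) the anchor-helix axis is
#' parallel to the plane (exact, by construction: the normal is chosen
#' perpendicular to the fitted axis); (b) the anchor-helix CA centroid lies
#' `headgroup_depth` below the plane; (c) no heavy atom of the model rises
#' above the plane by more than `penetration_tolerance`. Among directions
#' around the helix axis that satisfy (c), the one closest to the anchor's
#' hydrophobic-face direction is taken (amphipathic helices bury their
#' hydrophobic face in the membrane). If no direction satisfies (c), an
#' infeasibility report is returned (`feasible = FALSE`) carrying the
#' least-violating plane.
#'
#' @param model a `structure_model`
#' @param anchor an [anchor_spec()]
#' @param penetration_tolerance allowed protrusion beyond the plane,
#'   Angstrom
#' @param theta_step angular grid step around the helix axis, degrees
#' @param scale hydrophobicity scale for the face direction
#' @return list of class `membrane_placement`: `plane`, `feasible`,
#'   `n_penetrating`, `axis`, `face`
#' @export
place_membrane <- function(model, anchor, penetration_tolerance = 2,
                           theta_step = 2, scale = hydrophobicity_scale()) {
  ac <- anchor_ca(model, anchor)
  axis <- helix_axis(ac$ca)
  centroid <- colMeans(ac$ca)
  face <- hydrophobic_face(ac$model, ac$ca, axis, scale)
  if (is.null(face)) {
    # no amphipathic signal (e.g. a homopolymer helix): any perpendicular
    e <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    face <- e - sum(e * axis) * axis
    face <- face / sqrt(sum(face^2))
  }
  theta <- seq(-180, 180 - theta_step, by = theta_step)
  normals <- candidate_normals(axis, face, theta)
  xyz <- coords(model, heavy_only = TRUE)
  proj <- normals %*% t(xyz)                       # n_theta x n_atoms
  cen_proj <- as.numeric(normals %*% centroid)
  offsets <- cen_proj + anchor$headgroup_depth
  heights <- proj - offsets                        # signed distances
  n_pen <- rowSums(heights > penetration_tolerance)
  feasible <- n_pen == 0
  pick <- if (any(feasible)) {
    cand <- which(feasible)
    cand[which.min(abs(theta[cand]))]
  } else which.min(n_pen)
  plane <- plane_model(normals[pick, ], offsets[pick],
                       headgroup_half_thickness = anchor$headgroup_depth)
  structure(list(plane = plane, feasible = any(feasible),
                 n_penetrating = n_pen[pick], axis = axis, face = face,
                 theta = theta[pick]),
            class = "membrane_placement")
}

#' Minimum cargo-patch/membrane distance over anchored orientations
#'
#' Searches all membrane-plane orientations compatible with the amphipathic
#' anchor (rotations about the helix axis on a deterministic angular grid,
#' plus tilts within the parallelism tolerance) and the non-penetration
#' constraint, and reports the minimum over orientations of the smallest
#' distance from any patch heavy atom to the plane, with the achieving
#' plane. This is the quantity behind the bound "no anchored orientation
#' brings the cargo-binding surface within less than 15 Angstrom of the
#' membrane".
#'
#' @param model a `structure_model`
#' @param anchor an [anchor_spec()]
#' @param patch patch atoms: a chain id, a `domain_selection`, or an n x 3
#'   coordinate matrix
#' @param theta_step rotation grid step about the helix axis, degrees
#'   (<= 15)
#' @param tilt_step tilt grid step, degrees
#' @param penetration_tolerance allowed protrusion beyond the plane,
#'   Angstrom
#' @param scale hydrophobicity scale for the reference face direction
#' @return list of class `patch_distance`: `min_distance` (Angstrom),
#'   `plane` (achieving orientation), `feasible`, `n_feasible`
#' @export
min_patch_distance <- function(model, anchor, patch, theta_step = 2,
                               tilt_step = 1, penetration_tolerance = 2,
                               scale = hydrophobicity_scale()) {
  stopifnot(theta_step <= 15, theta_step > 0)
  patch_xyz <- if (is.matrix(patch)) patch
    else if (inherits(patch, "domain_selection"))
      coords(select_domain(model, patch), heavy_only = TRUE)
    else coords(structure_model(
      model$atoms[model$atoms$chain == patch, , drop = FALSE]),
      heavy_only = TRUE)
  if (nrow(patch_xyz) == 0) stop("empty patch")
  ac <- anchor_ca(model, anchor)
  axis <- helix_axis(ac$ca)
  centroid <- colMeans(ac$ca)
  face <- hydrophobic_face(ac$model, ac$ca, axis, scale)
  if (is.null(face)) {
    e <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    face <- e - sum(e * axis) * axis
    face <- face / sqrt(sum(face^2))
  }
  theta <- seq(-180, 180 - theta_step, by = theta_step)
  tmax <- anchor$parallelism_tolerance
  tilts <- if (tmax > 0) seq(-tmax, tmax, by = tilt_step) else 0
  base <- candidate_normals(axis, face, theta)     # n_theta x 3
  grid <- do.call(rbind, lapply(tilts, function(phi) {
    cp <- cos(phi * pi / 180); sp <- sin(phi * pi / 180)
    cp * base + matrix(sp * axis, nrow(base), 3, byrow = TRUE)
  }))
  xyz <- coords(model, heavy_only = TRUE)
  proj <- grid %*% t(xyz)
  offsets <- as.numeric(grid %*% centroid) + anchor$headgroup_depth
  heights <- proj - offsets
  feasible <- rowSums(heights > penetration_tolerance) == 0
  if (!any(feasible)) {
    return(structure(list(min_distance = NA_real_, plane = NULL,
                          feasible = FALSE, n_feasible = 0L),
                     class = "patch_distance"))
  }
  pproj <- grid %*% t(patch_xyz)
  pdist <- offsets - pproj                         # depth below the plane
  mind <- apply(pdist, 1, min)
  mind[!feasible] <- Inf
  pick <- which.min(mind)
  plane <- plane_model(grid[pick, ], offsets[pick],
                       headgroup_half_thickness = anchor$headgroup_depth)
  structure(list(min_distance = mind[pick], plane = plane, feasible = TRUE,
                 n_feasible = sum(feasible)),
            class = "patch_distance")
}

#' Curvature compatibility with a cylindrical membrane
#'
#' Positions the membrane cylinder tangent to the placed headgroup plane at
#' the projection of the membrane-facing centroid, with its axis along the
#' supplied in-plane direction (default: the dominant in-plane direction of
#' the membrane-facing atoms), and counts heavy atoms penetrating the
#' curved wall; also reports the fraction of membrane-facing residues whose
#' CA lies within `shell` of the wall (the contact fraction). The default
#' radius, 1250 Angstrom, models a 250 nm diameter cilium.
#'
#' @param model a `structure_model` (already oriented against `plane`)
#' @param plane the placed `plane_model`
#' @param radius cylinder radius, Angstrom
#' @param axis_direction optional in-plane axis direction for the cylinder
#' @param slab_depth depth below the plane defining "membrane-facing"
#'   atoms/residues, Angstrom
#' @param shell contact-shell thickness, Angstrom
#' @param penetration_tolerance allowed protrusion beyond the wall,
#'   Angstrom
#' @return list of class `curvature_assessment`: `penetration_count`,
#'   `contact_fraction`, `cylinder`
#' @export
curvature_compatibility <- function(model, plane, radius = 1250,
                                    axis_direction = NULL, slab_depth = 10,
                                    shell = 5, penetration_tolerance = 2) {
  xyz <- coords(model, heavy_only = TRUE)
  depth <- -signed_plane_distance(xyz, plane)      # below-plane depth
  facing <- depth <= slab_depth
  if (!any(facing)) stop("no membrane-facing atoms within slab_depth")
  cen <- colMeans(xyz[facing, , drop = FALSE])
  tangent <- cen - signed_plane_distance(cen, plane) * plane$normal
  if (is.null(axis_direction)) {
    rel <- sweep(xyz[facing, , drop = FALSE], 2, cen)
    rel_in <- rel - outer(as.numeric(rel %*% plane$normal), plane$normal)
    axis_direction <- if (sum(facing) >= 2 && max(abs(rel_in)) > 1e-9) {
      svd(rel_in)$v[, 1]
    } else plane_frame(plane$normal)$u
  }
  axis_direction <- axis_direction -
    sum(axis_direction * plane$normal) * plane$normal
  # the complex lies inside the membrane cylinder: the axis is on the
  # cytoplasmic side of the tangent plane, the wall curves away from it
  cyl <- cylinder_model(tangent - radius * plane$normal, axis_direction,
                        radius)
  sd_all <- cylinder_surface_distance(xyz, cyl)
  pen <- sum(sd_all > penetration_tolerance)
  ca <- ca_coords(model)
  ca_depth <- -signed_plane_distance(ca, plane)
  ca_facing <- ca_depth <= slab_depth
  contact <- if (any(ca_facing)) {
    mean(abs(cylinder_surface_distance(ca[ca_facing, , drop = FALSE],
                                       cyl)) <= shell)
  } else NA_real_
  structure(list(penetration_count = pen, contact_fraction = contact,
                 cylinder = cyl),
            class = "curvature_assessment")
}

charge_rep_atom <- c(LYS = "NZ", ARG = "CZ", ASP = "CG", GLU = "CD",
                     HIS = "NE2")
residue_charge <- c(LYS = 1, ARG = 1, ASP = -1, GLU = -1)

#' Membrane-facing charge census
#'
#' Tallies charged residues whose side-chain representative atom lies
#' within `slab_depth` of the placed plane: K/R count +1, D/E count -1, H
#' counts `his_charge` (0 by default). The representative atom is the
#' terminal charged-group atom when present, else CB, else CA (robust to
#' CA-only models).
#'
#' @param model a `structure_model`
#' @param plane the placed `plane_model`
#' @param slab_depth slab half-width around the plane, Angstrom
#' @param his_charge charge assigned to histidine
#' @return list of class `charge_census`: `slab_depth`, `positive_count`,
#'   `negative_count`, `net`, `per_residue_table` (residue, charge,
#'   distance to plane)
#' @export
membrane_facing_charge_census <- function(model, plane, slab_depth = 8,
                                          his_charge = 0) {
  a <- model$atoms[!model$atoms$het, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert, sep = ":")
  rows <- lapply(split(seq_len(nrow(a)), key), function(ii) {
    sub <- a[ii, , drop = FALSE]
    resid <- sub$resid[1]
    want <- charge_rep_atom[resid]
    j <- if (!is.na(want) && any(sub$name == want)) which(sub$name == want)[1]
      else if (any(sub$name == "CB")) which(sub$name == "CB")[1]
      else if (any(sub$name == "CA")) which(sub$name == "CA")[1]
      else 1L
    q <- if (resid == "HIS") his_charge
      else if (!is.na(residue_charge[resid])) unname(residue_charge[resid])
      else 0
    data.frame(chain = sub$chain[1], resno = sub$resno[1], resid = resid,
               charge = q,
               distance = signed_plane_distance(
                 c(sub$x[j], sub$y[j], sub$z[j]), plane),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  in_slab <- tab[abs(tab$distance) <= slab_depth & tab$charge != 0, ,
                 drop = FALSE]
  structure(list(slab_depth = slab_depth,
                 positive_count = sum(in_slab$charge > 0),
                 negative_count = sum(in_slab$charge < 0),
                 net = sum(in_slab$charge),
                 per_residue_table = tab),
            class = "charge_census")
}

#' @export
print.charge_census <- function(x, ...) {
  cat(sprintf("charge_census (slab %.1f A): +%d / -%d, net %+d\n",
              x$slab_depth, x$positive_count, x$negative_count, x$net))
  invisible(x)
}
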