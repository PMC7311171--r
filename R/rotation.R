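#' Domain rotation between two conformations
#'
#' Quantifies how far a domain rotates between two conformations of a
#' multi-subunit complex: the models are first superposed on a stable
#' reference selection (for the BBSome, the base/corkscrew lower-lobe
#' subunits), then the domain of interest (e.g. the BBS1 beta-propeller) is
#' superposed separately, and the rotation angle of that residual transform
#' is reported. CA atoms of residues common to both models are used
#' throughout.
#'
#' @param model_ref,model_alt the two conformations (`structure_model`s)
#' @param align_chains chain id(s) of the stable reference selection
#' @param domain either a chain id or a `domain_selection` naming the
#'   moving domain
#' @return list of class `domain_rotation`: `angle` (degrees),
#'   `align_rmsd`, `domain_rmsd`, `axis` (rotation axis of the residual
#'   transform)
#' @export
domain_rotation <- function(model_ref, model_alt, align_chains, domain) {
  sub <- function(model, chains) structure_model(
    model$atoms[model$atoms$chain %in% chains, , drop = FALSE])
  pick_domain <- function(model) {
    if (inherits(domain, "domain_selection")) select_domain(model, domain)
    else sub(model, domain)
  }
  ref_align <- sub(model_ref, align_chains)
  alt_align <- sub(model_alt, align_chains)
  mp <- matched_ca(alt_align, ref_align)
  if (nrow(mp$a) < 3) stop("fewer than 3 common CA atoms in the alignment set")
  fit1 <- superpose(mp$a, mp$b)
  alt_on_ref <- transform_structure(model_alt, fit1$transform)
  dp <- matched_ca(pick_domain(alt_on_ref), pick_domain(model_ref))
  if (nrow(dp$a) < 3) stop("fewer than 3 common CA atoms in the domain")
  fit2 <- superpose(dp$a, dp$b)
  structure(list(angle = rotation_angle(fit2$transform),
                 align_rmsd = fit1$rmsd, domain_rmsd = fit2$rmsd,
                 axis = rotation_axis(fit2$transform)),
            class = "domain_rotation")
}

#' Two-conformation complex fixture with a planted domain rotation
#'
#' Builds a toy multi-domain complex (a stable lower-lobe body plus a
#' moving-domain helix bundle) and a second conformation in which the
#' moving domain (chain "D") is rotated by `angle` degrees about an axis
#' through its centroid, after which the whole second model is placed in an
#' unrelated global frame. The planted angle is the ground truth for
#' [domain_rotation()].
#'
#' @param angle planted rotation, degrees (default 20, the activation-scale
#'   beta-propeller rotation)
#' @param seed RNG seed
#' @param n_body number of lower-lobe body atoms (chains "L1","L2")
#' @return list of class `rotation_fixture`: `model_ref`, `model_alt`,
#'   `align_chains`, `domain_chain`, `truth`
#' @export
make_rotation_fixture <- function(angle = 20, seed = 1L, n_body = 200L) {
  set.seed(seed)
  body_xyz <- matrix(stats::rnorm(3 * n_body, sd = 15), ncol = 3)
  half <- n_body %/% 2
  body <- data.frame(
    element = "C", name = "CA", x = body_xyz[, 1], y = body_xyz[, 2],
    z = body_xyz[, 3], resno = seq_len(n_body), insert = "", resid = "GLY",
    chain = rep(c("L1", "L2"), c(half, n_body - half)), het = FALSE,
    stringsAsFactors = FALSE)
  dom <- make_ideal_helix(40, chain = "D")
  dom$atoms$x <- dom$atoms$x + 30   # offset the domain from the body
  ref <- structure_model(rbind(body, dom$atoms[, names(body)]))

  a <- ref$atoms
  is_dom <- a$chain == "D"
  dc <- colMeans(as.matrix(a[is_dom, c("x", "y", "z")]))
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rot <- rotation_about_axis(ax, angle)
  xyz_dom <- as.matrix(a[is_dom, c("x", "y", "z")])
  xyz_dom <- sweep(sweep(xyz_dom, 2, dc) %*% t(rot), 2, dc, "+")
  a[is_dom, c("x", "y", "z")] <- xyz_dom
  alt <- structure_model(a)
  gax <- stats::rnorm(3); gax <- gax / sqrt(sum(gax^2))
  global <- rigid_transform(rotation_about_axis(gax, stats::runif(1, 0, 180)),
                            stats::runif(3, -50, 50))
  alt <- transform_structure(alt, global)
  structure(list(model_ref = ref, model_alt = alt,
                 align_chains = c("L1", "L2"), domain_chain = "D",
                 truth = list(angle = angle, axis = ax, seed = seed)),
            class = "rotation_fixture")
}
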