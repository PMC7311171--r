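#' Lipid-bound template complex
#'
#' A PH-domain/PIP co-structure used to transfer the bound ligand onto a
#' query PH domain by structural superposition.
#'
#' @param id template id (e.g. a PDB code, or a synthetic-fixture id)
#' @param ph the template PH-domain `structure_model`
#' @param ligand n x 3 matrix of ligand heavy-atom coordinates in the
#'   template frame
#' @param site_label `"canonical"` (the beta1-beta2-loop site) or
#'   `"atypical"` (the secondary A site)
#' @return object of class `template_complex`
#' @export
template_complex <- function(id, ph, ligand,
                             site_label = c("canonical", "atypical")) {
  site_label <- match.arg(site_label)
  stopifnot(inherits(ph, "structure_model"), ncol(as.matrix(ligand)) == 3)
  structure(list(id = id, ph = ph, ligand = as.matrix(ligand),
                 site_label = site_label),
            class = "template_complex")
}

# matched CA coordinate pairs between two models, by chain-agnostic author
# residue number (or by an explicit pairing of residue numbers)
matched_ca <- function(a, b, pairing = NULL) {
  ca_a <- ca_coords(a); ca_b <- ca_coords(b)
  num <- function(m) as.integer(sub("^[^:]*:([0-9-]+):.*$", "\\1",
                                    rownames(m)))
  na <- num(ca_a); nb <- num(ca_b)
  if (is.null(pairing)) {
    common <- intersect(na, nb)
    list(a = ca_a[match(common, na), , drop = FALSE],
         b = ca_b[match(common, nb), , drop = FALSE])
  } else {
    stopifnot(ncol(pairing) == 2)
    ia <- match(pairing[, 1], na); ib <- match(pairing[, 2], nb)
    ok <- !is.na(ia) & !is.na(ib)
    list(a = ca_a[ia[ok], , drop = FALSE], b = ca_b[ib[ok], , drop = FALSE])
  }
}

#' Place a template's bound ligand onto a query PH domain
#'
#' Superposes the template PH domain onto the query (CA correspondence by
#' author residue number, or an explicit residue pairing) and applies the
#' transform to the template's ligand atoms.
#'
#' @param query_ph the query PH-domain `structure_model`
#' @param template a [template_complex()]
#' @param pairing optional 2-column matrix of (template resno, query resno)
#'   pairs
#' @param min_pairs minimum alignable CA pairs required (default 20)
#' @return list: `ligand` (n x 3 in the query frame), `rmsd` (superposition
#'   RMSD, Angstrom), `transform`
#' @export
place_template_ligand <- function(query_ph, template, pairing = NULL,
                                  min_pairs = 20) {
  mp <- matched_ca(template$ph, query_ph, pairing)
  if (nrow(mp$a) < min_pairs) {
    stop(sprintf("only %d alignable CA pairs (need >= %d)", nrow(mp$a),
                 min_pairs))
  }
  fit <- superpose(mp$a, mp$b)
  list(ligand = apply_transform(fit$transform, template$ligand),
       rmsd = fit$rmsd, transform = fit$transform)
}

#' Count steric clashes of a placed ligand with its environment
#'
#' Number of environment heavy atoms (outside excluded selections, e.g. the
#' PH domain itself) within `cutoff` of any ligand heavy atom, plus the
#' identity of the nearest blocker.
#'
#' @param ligand n x 3 matrix of ligand heavy-atom coordinates
#' @param environment a `structure_model`
#' @param exclude chain ids (character) and/or `domain_selection`s to drop
#'   from the environment
#' @param cutoff heavy-atom clash cutoff, Angstrom (default 3.0)
#' @param domain_map optional named vector mapping chain ids to
#'   subunit/domain names for blocker reporting
#' @return list: `count`, `nearest_blocker` (chain or mapped domain name,
#'   NA when no clash), `min_distance`
#' @export
count_clashes <- function(ligand, environment, exclude = NULL, cutoff = 3.0,
                          domain_map = NULL) {
  ligand <- as.matrix(ligand)
  if (nrow(ligand) == 0) stop("empty ligand")
  a <- environment$atoms[environment$atoms$heavy, , drop = FALSE]
  if (!is.null(exclude)) {
    for (ex in if (is.list(exclude)) exclude else as.list(exclude)) {
      if (inherits(ex, "domain_selection")) {
        rng <- ex$residue_range
        a <- a[!(a$chain == ex$subunit & a$resno >= rng[1] &
                   a$resno <= rng[2]), , drop = FALSE]
      } else {
        a <- a[a$chain != ex, , drop = FALSE]
      }
    }
  }
  if (nrow(a) == 0) {
    return(list(count = 0L, nearest_blocker = NA_character_,
                min_distance = Inf))
  }
  env <- as.matrix(a[, c("x", "y", "z")])
  d2 <- outer(rowSums(env^2), rowSums(ligand^2), "+") -
    2 * env %*% t(ligand)
  mind <- sqrt(pmax(0, apply(d2, 1, min)))
  count <- sum(mind <= cutoff)
  j <- which.min(mind)
  blocker <- a$chain[j]
  if (!is.null(domain_map) && !is.na(domain_map[blocker])) {
    blocker <- unname(domain_map[blocker])
  }
  list(count = as.integer(count),
       nearest_blocker = if (count > 0) blocker else NA_character_,
       min_distance = mind[j])
}

#' Assess a PH-domain lipid-binding site in complex context
#'
#' Places each template's ligand onto the query PH domain, counts clashes
#' against the environment (median over templates), and, when a membrane
#' plane is supplied, measures the distance from the placed-ligand centroid
#' to the plane. Verdict: `"blocked"` when the median clash count exceeds
#' `clash_threshold` (default 0: any clash blocks), `"distant"` when open
#' but farther from the membrane than `distance_threshold` (default 10
#' Angstrom = 1 nm), else `"open"`.
#'
#' @param query_ph the query PH-domain `structure_model`
#' @param site_label `"canonical"` or `"atypical"`
#' @param templates list of [template_complex()]s for the site (>= 1)
#' @param environment a `structure_model` of the surrounding complex
#' @param plane optional placed `plane_model`
#' @param exclude environment exclusions (the PH domain itself, typically)
#' @param clash_cutoff heavy-atom clash cutoff, Angstrom
#' @param clash_threshold verdict threshold on the median clash count
#' @param distance_threshold membrane-distance threshold, Angstrom
#' @param domain_map optional chain-to-domain names for blocker reporting
#' @return list of class `site_assessment`: `site_label`, `clash_count`
#'   (median), `per_template` (data.frame), `nearest_blocker`,
#'   `membrane_distance` (Angstrom or NA), `verdict`
#' @export
assess_site <- function(query_ph, site_label, templates, environment,
                        plane = NULL, exclude = NULL, clash_cutoff = 3.0,
                        clash_threshold = 0, distance_threshold = 10,
                        domain_map = NULL) {
  if (length(templates) == 0) stop("need at least one template for the site")
  per <- lapply(templates, function(tmpl) {
    placed <- place_template_ligand(query_ph, tmpl)
    cl <- count_clashes(placed$ligand, environment, exclude, clash_cutoff,
                        domain_map)
    data.frame(template_id = tmpl$id, rmsd = placed$rmsd,
               clash_count = cl$count,
               nearest_blocker = ifelse(is.na(cl$nearest_blocker), "",
                                        cl$nearest_blocker),
               centroid_x = mean(placed$ligand[, 1]),
               centroid_y = mean(placed$ligand[, 2]),
               centroid_z = mean(placed$ligand[, 3]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  clash <- stats::median(per$clash_count)
  blockers <- per$nearest_blocker[per$nearest_blocker != ""]
  nearest <- if (length(blockers)) names(sort(table(blockers),
                                              decreasing = TRUE))[1]
    else NA_character_
  mem_d <- NA_real_
  if (!is.null(plane)) {
    cen <- colMeans(per[, c("centroid_x", "centroid_y", "centroid_z")])
    mem_d <- abs(signed_plane_distance(as.numeric(cen), plane))
  }
  verdict <- if (clash > clash_threshold) "blocked"
    else if (!is.na(mem_d) && mem_d > distance_threshold) "distant"
    else "open"
  structure(list(site_label = site_label, clash_count = clash,
                 per_template = per, nearest_blocker = nearest,
                 membrane_distance = mem_d, verdict = verdict),
            class = "site_assessment")
}

#' @export
print.site_assessment <- function(x, ...) {
  cat(sprintf("site_assessment [%s]: %s (median clashes %.1f%s%s)\n",
              x$site_label, x$verdict, x$clash_count,
              if (!is.na(x$nearest_blocker))
                paste0(", blocker ", x$nearest_blocker) else "",
              if (!is.na(x$membrane_distance))
                sprintf(", membrane %.1f A", x$membrane_distance) else ""))
  invisible(x)
}
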