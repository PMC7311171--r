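#' Ideal alpha-helix CA trace
#'
#' CA atoms placed on a circular helix with the canonical alpha-helix
#' parameters (rise 1.5 Angstrom per residue, twist 100 degrees, radius
#' 2.3 Angstrom); the axial extent of n residues is (n-1) x rise. The helix
#' axis is +z starting at the origin; the true axis is attached as the
#' `"axis"` attribute.
#'
#' @param n_residues number of residues (>= 1)
#' @param rise rise per residue, Angstrom (> 0)
#' @param twist twist per residue, degrees (0 < twist <= 180)
#' @param radius helix radius, Angstrom
#' @param sequence optional one-letter sequence (length `n_residues`);
#'   default poly-alanine
#' @param chain chain id
#' @param resno_start first author residue number
#' @return a `structure_model` CA trace
#' @export
make_ideal_helix <- function(n_residues, rise = 1.5, twist = 100,
                             radius = 2.3, sequence = NULL, chain = "A",
                             resno_start = 1L) {
  stopifnot(n_residues >= 1, rise > 0, twist > 0, twist <= 180)
  i <- 0:(n_residues - 1)
  delta <- twist * pi / 180
  xyz <- cbind(radius * cos(i * delta), radius * sin(i * delta), i * rise)
  resid <- if (is.null(sequence)) rep("ALA", n_residues)
    else bio3d::aa123(strsplit(toupper(sequence), "")[[1]])
  m <- structure_model(data.frame(
    element = "C", name = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    resno = resno_start + i, insert = "", resid = resid, chain = chain,
    het = FALSE, stringsAsFactors = FALSE))
  attr(m, "axis") <- c(0, 0, 1)
  m
}

#' Extended-chain CA trace
#'
#' Collinear CA atoms spaced by the extended-chain rise (default 3.5
#' Angstrom per residue), the geometry behind the extended-tether reach
#' bound (6 steps = 21 Angstrom).
#'
#' @param n number of residues (>= 1)
#' @param rise spacing, Angstrom
#' @param chain chain id
#' @param resno_start first author residue number
#' @return a `structure_model` CA trace along +z from the origin
#' @export
make_extended_chain <- function(n, rise = 3.5, chain = "A",
                                resno_start = 1L) {
  stopifnot(n >= 1, rise > 0)
  i <- 0:(n - 1)
  structure_model(data.frame(
    element = "C", name = "CA", x = 0, y = 0, z = i * rise,
    resno = resno_start + i, insert = "", resid = "ALA", chain = chain,
    het = FALSE, stringsAsFactors = FALSE))
}

plane_frame <- function(normal) {
  e <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- e - sum(e * normal) * normal
  u <- u / sqrt(sum(u^2))
  w2 <- c(u[2] * normal[3] - u[3] * normal[2],
          u[3] * normal[1] - u[1] * normal[3],
          u[1] * normal[2] - u[2] * normal[1])
  list(u = u, w2 = w2 / sqrt(sum(w2^2)))
}

#' Membrane-complex fixture with a planted plane
#'
#' Builds a toy peripheral membrane complex with known ground truth: an
#' amphipathic anchor helix (chain "A") whose axis is parallel to the
#' planted plane and whose CA centroid sits `headgroup_depth` below it,
#' with the hydrophobic face toward the membrane; a globular body (chain
#' "B") entirely on the cytoplasmic side with its top `body_clearance`
#' below the plane, most atoms on the spherical envelope (a protein surface
#' constrains plane orientations by its envelope, not its interior); a
#' small cargo-site patch (chain "P") recessed `patch_depth` below the
#' plane; and optional planted charged residues (chain "Q") at
#' `charge_depth` for the charge census. The 18-residue default anchor
#' spans exactly five helical turns, so its hydrophobic face is symmetric
#' about the planted normal. The default geometry (24-Angstrom recessed
#' patch on a 30-Angstrom body approaching the membrane to 5 Angstrom)
#' plants the regime of a coat complex whose cargo-binding surface stays
#' beyond helical tether reach in every anchored orientation.
#'
#' @param plane planted `plane_model` (ground truth)
#' @param seed RNG seed; fixtures are deterministic given the seed
#' @param n_anchor anchor-helix length in residues
#' @param headgroup_depth anchor centroid depth below the plane, Angstrom
#' @param body_radius radius of the body atom cloud, Angstrom
#' @param n_body number of body atoms
#' @param body_clearance depth of the top of the body below the plane
#' @param patch_depth planted depth of the cargo-site patch, Angstrom
#' @param n_patch number of patch atoms
#' @param plant_positive,plant_negative number of planted K / D residues at
#'   `charge_depth` below the plane (chain "Q")
#' @param charge_depth depth of planted charges, Angstrom
#' @return list of class `membrane_fixture`: `model`, `plane` (truth),
#'   `anchor` (an [anchor_spec()]), `patch_chain`, and `truth` (planted
#'   parameters)
#' @export
make_membrane_complex_fixture <- function(plane = plane_model(c(0, 0, 1), 0, 3),
                                          seed = 1L, n_anchor = 18L,
                                          headgroup_depth = 3,
                                          body_radius = 30, n_body = 400L,
                                          body_clearance = 5,
                                          patch_depth = 24, n_patch = 5L,
                                          plant_positive = 0L,
                                          plant_negative = 0L,
                                          charge_depth = 5) {
  set.seed(seed)
  nrm <- plane$normal
  fr <- plane_frame(nrm)
  u <- fr$u; w2 <- fr$w2
  p0 <- plane$offset * nrm   # point on the plane
  delta <- 100 * pi / 180
  i <- 0:(n_anchor - 1)
  radial <- outer(cos(i * delta), nrm) + outer(sin(i * delta), w2)
  centroid <- p0 - headgroup_depth * nrm
  base <- centroid - mean(i) * 1.5 * u
  ca <- sweep(outer(i * 1.5, u) + 2.3 * radial, 2, base, "+")
  # amphipathic sequence: hydrophobic residues on the membrane-facing side
  seq1 <- ifelse(cos(i * delta) > 0.25, "L", rep_len(c("S", "N"), n_anchor))
  anchor_atoms <- data.frame(
    element = "C", name = "CA", x = ca[, 1], y = ca[, 2], z = ca[, 3],
    resno = 1:n_anchor, insert = "", resid = bio3d::aa123(seq1),
    chain = "A", het = FALSE, stringsAsFactors = FALSE)

  # body fully below the plane: 80% of atoms on the spherical envelope
  # (the surface is what constrains plane orientations), 20% interior
  dirs <- matrix(stats::rnorm(3 * n_body), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  n_surf <- floor(0.8 * n_body)
  rad <- c(rep(body_radius, n_surf),
           body_radius * stats::runif(n_body - n_surf)^(1 / 3))
  c_body <- p0 - (body_clearance + body_radius) * nrm
  bxyz <- sweep(dirs * rad, 2, c_body, "+")
  body_atoms <- data.frame(
    element = "C", name = "CA", x = bxyz[, 1], y = bxyz[, 2], z = bxyz[, 3],
    resno = 1:n_body, insert = "", resid = "GLY", chain = "B", het = FALSE,
    stringsAsFactors = FALSE)

  # cargo-site patch at the planted depth, laterally near the anchor
  off_u <- stats::runif(n_patch, -2, 2)
  off_w <- stats::runif(n_patch, -2, 2)
  pxyz <- sweep(outer(off_u, u) + outer(off_w, w2), 2,
                p0 - patch_depth * nrm, "+")
  patch_atoms <- data.frame(
    element = "C", name = "CA", x = pxyz[, 1], y = pxyz[, 2], z = pxyz[, 3],
    resno = 1:n_patch, insert = "", resid = "GLY", chain = "P", het = FALSE,
    stringsAsFactors = FALSE)

  charge_atoms <- NULL
  n_q <- plant_positive + plant_negative
  if (n_q > 0) {
    qu <- stats::runif(n_q, -15, 15)
    qw <- stats::runif(n_q, -15, 15)
    qxyz <- sweep(outer(qu, u) + outer(qw, w2), 2,
                  p0 - charge_depth * nrm, "+")
    charge_atoms <- data.frame(
      element = "C", name = "CA", x = qxyz[, 1], y = qxyz[, 2],
      z = qxyz[, 3], resno = 1:n_q, insert = "",
      resid = c(rep("LYS", plant_positive), rep("ASP", plant_negative)),
      chain = "Q", het = FALSE, stringsAsFactors = FALSE)
  }

  model <- structure_model(rbind(anchor_atoms, body_atoms, patch_atoms,
                                 charge_atoms))
  structure(list(
    model = model,
    plane = plane,
    anchor = anchor_spec(chain = "A", anchor_residue = n_anchor,
                         anchor_helix_range = c(1L, n_anchor),
                         headgroup_depth = headgroup_depth),
    patch_chain = "P",
    truth = list(normal = nrm, offset = plane$offset,
                 patch_depth = patch_depth, axis = u,
                 plant_positive = plant_positive,
                 plant_negative = plant_negative, seed = seed)),
    class = "membrane_fixture")
}

#' Synthetic GPCR C-tail cohort with planted helix-8 motifs
#'
#' Generates C-tail-like sequences whose helix-8 window carries a planted
#' BBSome-binding motif at stated frequencies. Default composition matches
#' the ciliary-GPCR study conditions: 26 receptors, of which 20 carry a
#' strict [W/F/Y]R motif and 3 more carry only the relaxed [W/F/Y][K/R]
#' motif (aromatic followed by K), leaving 3 with none. The helix-8 window
#' is built with an amphipathic 100-degrees-per-residue periodicity
#' (hydrophobic face from L/I/V/M, polar face from S/T/N/Q/G), aromatics
#' appear only in the planted motif, and background flanks are sampled from
#' the supplied alphabet (uniform by default) - so in-window match counts
#' are exact by construction. Author numbering is chosen so the window is
#' always aa 543-559 (tm7_end = 542), mirroring SMO numbering.
#'
#' @param n_sequences cohort size
#' @param h8_window_length helix-8 window length, residues
#' @param motif_fraction fraction of sequences with a relaxed-motif match
#'   in-window (rounded to a count)
#' @param strict_fraction fraction with a strict-motif match (<= motif
#'   fraction; rounded)
#' @param alphabet_background named residue-frequency vector over the
#'   20-letter alphabet for flanking background (uniform when NULL; must
#'   sum to 1)
#' @param seed RNG seed
#' @param tail_length total sequence length
#' @return list of class `gpcr_cohort`: `records` (named list of
#'   `sequence_record`s), `truth` (per-sequence data.frame with planted
#'   class, window and motif position), `windows` (named list of
#'   author-numbered windows), `tm7_end`
#' @export
make_gpcr_cohort <- function(n_sequences = 26L, h8_window_length = 17L,
                             motif_fraction = 23 / 26,
                             strict_fraction = 20 / 26,
                             alphabet_background = NULL, seed = 1L,
                             tail_length = 60L) {
  stopifnot(n_sequences >= 1, h8_window_length >= 5,
            motif_fraction >= 0, motif_fraction <= 1)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (is.null(alphabet_background)) {
    alphabet_background <- stats::setNames(rep(1 / 20, 20), aa20)
  }
  if (abs(sum(alphabet_background) - 1) > 1e-9) {
    stop("background frequencies must sum to 1")
  }
  set.seed(seed)
  n_relaxed <- round(motif_fraction * n_sequences)
  n_strict <- min(round(strict_fraction * n_sequences), n_relaxed)
  classes <- sample(c(rep("strict", n_strict),
                      rep("relaxed_only", n_relaxed - n_strict),
                      rep("none", n_sequences - n_relaxed)))
  # face sets with a clear hydrophobicity contrast on the Eisenberg scale
  # (no aromatics, no K/R, so motif matches are exactly the planted ones)
  hydro <- c("L", "I", "V", "M")
  polar <- c("S", "N", "Q", "D", "E")
  delta <- 100 * pi / 180
  L <- as.integer(h8_window_length)
  max_start <- max(1L, min(25L - L + 1L, tail_length - L + 1L))
  records <- list()
  truth <- list()
  for (k in seq_len(n_sequences)) {
    s <- sample.int(max_start, 1)
    win <- vapply(0:(L - 1), function(j) {
      if (cos(j * delta) > 0.25) sample(hydro, 1) else sample(polar, 1)
    }, character(1))
    motif_start_idx <- NA_integer_
    if (classes[k] != "none") {
      # plant phase-aligned: the aromatic on the membrane-facing
      # (hydrophobic) side of the wheel, the basic residue off it, as in
      # membrane-embedded helix 8
      cand <- which(cos((0:(L - 2)) * delta) > 0.25 &
                      cos((1:(L - 1)) * delta) <= 0.25)
      pos_in <- if (length(cand)) cand[sample.int(length(cand), 1)]
        else sample.int(L - 1, 1)
      win[pos_in] <- sample(c("W", "F", "Y"), 1)
      win[pos_in + 1] <- if (classes[k] == "strict") "R" else "K"
      motif_start_idx <- pos_in
    }
    flank_n <- tail_length - L
    n_pre <- s - 1L
    flanks <- sample(names(alphabet_background), flank_n, replace = TRUE,
                     prob = alphabet_background)
    seq1 <- c(if (n_pre > 0) flanks[seq_len(n_pre)] else character(0), win,
              if (flank_n > n_pre) flanks[(n_pre + 1):flank_n] else character(0))
    id <- sprintf("gpcr%02d", k)
    offset <- 543L - (s - 1L)
    records[[id]] <- sequence_record(id, paste(seq1, collapse = ""),
                                     offset = offset)
    truth[[k]] <- data.frame(
      sequence_id = id, class = classes[k],
      window_start = 543L, window_end = 543L + L - 1L,
      window_start_idx = s,
      motif_start = if (is.na(motif_start_idx)) NA_integer_
        else 543L + motif_start_idx - 1L,
      has_strict = classes[k] == "strict",
      has_relaxed = classes[k] != "none",
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  windows <- stats::setNames(
    rep(list(c(543L, 543L + L - 1L)), n_sequences), truth$sequence_id)
  structure(list(records = records, truth = truth, windows = windows,
                 tm7_end = 542L, seed = seed),
            class = "gpcr_cohort")
}

#' Write a cohort to FASTA with a machine-readable truth sidecar
#'
#' @param cohort a [make_gpcr_cohort()] result
#' @param fasta_path output FASTA path
#' @param sidecar_path output JSON path for the planted ground truth
#'   (default: `fasta_path` with a `.truth.json` suffix)
#' @return `fasta_path`, invisibly
#' @export
write_cohort <- function(cohort, fasta_path,
                         sidecar_path = paste0(fasta_path, ".truth.json")) {
  write_fasta_records(cohort$records, fasta_path)
  jsonlite::write_json(cohort$truth, sidecar_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(fasta_path)
}

#' PH-domain lipid-site fixture with a planted clash count
#'
#' Builds a template PH-domain stand-in (a 30-residue CA helix, chain "T")
#' with a bound-ligand blob at a fixed site, a query copy displaced by a
#' random planted rigid transform, and an environment in the query frame in
#' which exactly `n_clashes` heavy atoms (chain "E") lie within `cutoff` of
#' the correctly placed ligand, at distances spread over [1.9, 2.9]
#' Angstrom; decoy atoms (chain "F") lie at least `cutoff` + 10 Angstrom
#' away.
#'
#' @param n_clashes planted number of clashing environment atoms (>= 0)
#' @param seed RNG seed
#' @param cutoff heavy-atom clash cutoff, Angstrom
#' @param n_far number of far decoy environment atoms
#' @param site_label `"canonical"` or `"atypical"`
#' @return list of class `ph_site_fixture`: `query_ph`, `template` (a
#'   [template_complex()]), `environment`, `truth` (planted transform,
#'   placed-ligand coordinates, clash count)
#' @export
make_ph_site_fixture <- function(n_clashes, seed = 1L, cutoff = 3.0,
                                 n_far = 20L, site_label = "canonical") {
  stopifnot(n_clashes >= 0)
  set.seed(seed)
  ph <- make_ideal_helix(30, chain = "T")
  lig_center <- c(10, 0, 22)
  offs <- rbind(c(0, 0, 0), c(1.2, 0, 0), c(-1.2, 0, 0), c(0, 1.2, 0),
                c(0, -1.2, 0), c(0, 0, 1.2), c(0, 0, -1.2), c(0.8, 0.8, 0.8))
  ligand <- sweep(offs, 2, lig_center, "+")
  rownames(ligand) <- NULL
  template <- template_complex("synthetic_template", ph, ligand, site_label)

  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  planted <- rigid_transform(rotation_about_axis(ax, stats::runif(1, 20, 160)),
                             stats::runif(3, -30, 30))
  query_ph <- transform_structure(ph, planted)
  query_ph$atoms$chain <- "Z"
  ligand_true <- apply_transform(planted, ligand)

  env_rows <- list()
  if (n_clashes > 0) {
    d <- seq(1.9, 2.9, length.out = n_clashes)
    for (j in seq_len(n_clashes)) {
      base <- ligand_true[((j - 1) %% nrow(ligand_true)) + 1, ]
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      p <- base + d[j] * dir
      env_rows[[length(env_rows) + 1]] <- data.frame(
        element = "C", name = "CA", x = p[1], y = p[2], z = p[3],
        resno = j, insert = "", resid = "GLY", chain = "E", het = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  lig_c_true <- colMeans(ligand_true)
  for (j in seq_len(n_far)) {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    p <- lig_c_true + (cutoff + 10 + 2.2 + stats::runif(1, 0, 20)) * dir
    env_rows[[length(env_rows) + 1]] <- data.frame(
      element = "C", name = "CA", x = p[1], y = p[2], z = p[3],
      resno = n_clashes + j, insert = "", resid = "GLY", chain = "F",
      het = FALSE, stringsAsFactors = FALSE)
  }
  environment <- structure_model(do.call(rbind, env_rows))
  structure(list(query_ph = query_ph, template = template,
                 environment = environment,
                 truth = list(transform = planted, ligand = ligand_true,
                              n_clashes = n_clashes, cutoff = cutoff,
                              seed = seed)),
            class = "ph_site_fixture")
}

#' Library of perturbed lipid-bound templates
#'
#' Emulates a set of distinct PH-domain/PIP co-structures: independent
#' noisy copies of one template (coordinate noise on the domain and the
#' ligand) so that ligands placed from different templates land at nearly
#' the same site on a query.
#'
#' @param n number of templates
#' @param seed RNG seed
#' @param noise coordinate noise s.d., Angstrom
#' @param site_label site label passed to each template
#' @return list of [template_complex()] objects
#' @export
make_ph_template_library <- function(n = 9L, seed = 1L, noise = 0.3,
                                     site_label = "canonical") {
  set.seed(seed)
  base <- make_ph_site_fixture(0, seed = seed)$template
  lapply(seq_len(n), function(k) {
    ph <- base$ph
    xyz <- coords(ph) + matrix(stats::rnorm(3 * n_atoms(ph), 0, noise),
                               ncol = 3)
    ph$atoms$x <- xyz[, 1]; ph$atoms$y <- xyz[, 2]; ph$atoms$z <- xyz[, 3]
    lig <- base$ligand + matrix(stats::rnorm(3 * nrow(base$ligand), 0, noise),
                                ncol = 3)
    template_complex(sprintf("synthetic_template_%02d", k), ph, lig,
                     site_label)
  })
}

#' Synthetic SMO-like helix-8 window sequence
#'
#' A synthetic 17-residue window numbered 543-559 (mouse SMO numbering)
#' carrying the experimentally mapped BBSome-binding determinants on a
#' synthetic backbone: the perfect motif 549WR550 and the looser candidate
#' 553WCR555, starting at Lys543 (the first residue after TM7). This is a
#' constructed stand-in, not the native SMO sequence.
#'
#' @return a `sequence_record` with offset 543
#' @export
make_smo_like_h8 <- function() {
  sequence_record("SMO_like_H8_synthetic", "KTLAHSWRSEWCRLKDS", offset = 543L)
}

#' Synthetic BBS5-PH1-like beta1-beta2 loop sequence
#'
#' A synthetic loop segment carrying the canonical PIP-binding motif at the
#' mapped positions K41...R47xR49 (one perfect Kx5[K/R]xR match and no
#' other), numbered 35-55. A constructed stand-in, not the native BBS5
#' sequence.
#'
#' @return a `sequence_record` with offset 35
#' @export
make_bbs5_ph1_like_loop <- function() {
  sequence_record("BBS5_PH1_like_synthetic", "GSTGLAKAPNSTRGRAGSLVE",
                  offset = 35L)
}
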