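#' Residue hydrophobicity scale
#'
#' The default is the Eisenberg consensus scale, the scale classically used
#' for hydrophobic-moment calculations. Moment values are scale-relative, so
#' report files always name the scale used.
#'
#' @param name `"eisenberg_consensus"` or `"kyte_doolittle"`
#' @return named numeric vector over the 20 one-letter codes, with class
#'   `hydrophobicity_scale` and a `"scale_name"` attribute
#' @export
hydrophobicity_scale <- function(name = c("eisenberg_consensus",
                                          "kyte_doolittle")) {
  name <- match.arg(name)
  v <- switch(name,
    eisenberg_consensus = c(
      A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85,
      E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
      M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
      Y = 0.26, V = 1.08),
    kyte_doolittle = c(
      A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
      E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
      M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
      Y = -1.3, V = 4.2))
  structure(v, class = "hydrophobicity_scale", scale_name = name)
}

seq_letters <- function(seq) {
  s <- if (inherits(seq, "sequence_record")) seq$residues else as.character(seq)
  strsplit(toupper(s), "")[[1]]
}

#' Mean hydrophobic moment of a sequence window
#'
#' The per-residue mean hydrophobic moment on an ideal helical wheel:
#' `muH = |sum_n H_n exp(i n delta)| / N` with `delta` the helical twist
#' (default 100 degrees per residue). High values mark amphipathic helices
#' such as GPCR helix 8 or the ARF-family N-terminal membrane anchor.
#' Unknown residues (X) contribute hydrophobicity 0.
#'
#' @param seq a `sequence_record` or plain string
#' @param scale a [hydrophobicity_scale()]
#' @param twist helical twist in degrees per residue
#' @return non-negative scalar, in the units of the scale
#' @export
hydrophobic_moment <- function(seq, scale = hydrophobicity_scale(),
                               twist = 100) {
  letters1 <- seq_letters(seq)
  n <- length(letters1)
  if (n == 0) stop("empty sequence")
  h <- unname(scale[letters1])
  h[is.na(h)] <- 0
  delta <- twist * pi / 180
  Mod(sum(h * exp(1i * (seq_len(n) - 1) * delta))) / n
}

#' Helix-8 window annotation
#'
#' When the last transmembrane-helix residue (`tm7_end`) is known, helix 8 is
#' the `window_length` residues that immediately follow (for SMO, tm7_end =
#' 542 gives the window 543-559 in mouse numbering). Without `tm7_end`, a
#' heuristic picks the window of length `window_length`, starting within the
#' first 25 residues of the supplied C-tail, that maximizes the hydrophobic
#' moment.
#'
#' @param seq a `sequence_record` (a C-tail sequence for heuristic mode)
#' @param tm7_end author residue number of the last TM7 residue, or NULL
#' @param window_length window length in residues (default 17, the length of
#'   the SMO helix 8, aa 543-559)
#' @param scale hydrophobicity scale for the heuristic
#' @param twist helical twist (degrees) for the heuristic
#' @return list of class `helix8_annotation` with `sequence_id`, `window`
#'   (inclusive author-numbered interval, or NULL when empty), `source`
#'   (`"config"` or `"heuristic"`), `truncated` and `empty` flags
#' @export
annotate_helix8 <- function(seq, tm7_end = NULL, window_length = 17,
                            scale = hydrophobicity_scale(), twist = 100) {
  stopifnot(inherits(seq, "sequence_record"))
  pos <- seq$positions
  n <- length(pos)
  if (!is.null(tm7_end)) {
    first <- tm7_end + 1L
    last <- tm7_end + as.integer(window_length)
    truncated <- FALSE
    empty <- first > pos[n]
    if (!empty && last > pos[n]) {
      last <- pos[n]
      truncated <- TRUE
    }
    window <- if (empty) NULL else c(first, last)
    return(structure(list(sequence_id = seq$id, window = window,
                          source = "config", truncated = truncated,
                          empty = empty),
                     class = "helix8_annotation"))
  }
  # window confined to the first 25 C-tail residues (helix 8 sits at the
  # start of the tail), clipped to the sequence
  max_start_idx <- min(25L - as.integer(window_length) + 1L,
                       n - as.integer(window_length) + 1L)
  if (max_start_idx < 1 && n >= window_length) max_start_idx <- 1L
  if (max_start_idx < 1) {
    return(structure(list(sequence_id = seq$id, window = NULL,
                          source = "heuristic", truncated = FALSE,
                          empty = TRUE),
                     class = "helix8_annotation"))
  }
  letters1 <- seq_letters(seq)
  mu <- vapply(seq_len(max_start_idx), function(i) {
    hydrophobic_moment(paste(letters1[i:(i + window_length - 1)],
                             collapse = ""), scale, twist)
  }, numeric(1))
  i <- which.max(mu)
  structure(list(sequence_id = seq$id,
                 window = c(pos[i], pos[i + window_length - 1]),
                 source = "heuristic", truncated = FALSE, empty = FALSE,
                 muH = mu[i]),
            class = "helix8_annotation")
}

#' pKa set for isoelectric-point calculation
#'
#' The default is a Bjellqvist-style set (the set behind common "theoretical
#' pI" calculators). Reported pI values are pKa-set-relative, so reports name
#' the set used.
#'
#' @param name currently `"bjellqvist"`
#' @return named numeric vector with terminal and side-chain pKa values and
#'   a `"set_name"` attribute
#' @export
pka_set <- function(name = "bjellqvist") {
  name <- match.arg(name, "bjellqvist")
  structure(c(Nterm = 7.5, Cterm = 3.55,
              K = 10.0, R = 12.0, H = 5.98,
              D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
            set_name = name)
}

#' Net protein charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N terminus, C terminus and ionizable
#' side chains (K, R, H positive; D, E, C, Y negative).
#'
#' @param seq a `sequence_record` or string
#' @param pH pH value(s)
#' @param pka a [pka_set()]
#' @return net charge (same length as `pH`)
#' @export
net_charge <- function(seq, pH, pka = pka_set()) {
  letters1 <- seq_letters(seq)
  counts <- table(factor(letters1, levels = c("K", "R", "H", "D", "E",
                                              "C", "Y")))
  vapply(pH, function(p) {
    pos <- 1 / (1 + 10^(p - pka["Nterm"])) +
      sum(counts[c("K", "R", "H")] /
            (1 + 10^(p - pka[c("K", "R", "H")])))
    neg <- 1 / (1 + 10^(pka["Cterm"] - p)) +
      sum(counts[c("D", "E", "C", "Y")] /
            (1 + 10^(pka[c("D", "E", "C", "Y")] - p)))
    unname(pos - neg)
  }, numeric(1))
}

#' Basic sequence properties: length, charge composition, theoretical pI
#'
#' The theoretical pI is solved by bisection on the Henderson-Hasselbalch
#' net-charge function under the configured pKa set (net charge at the
#' returned pI is zero within `tol`).
#'
#' @param seq a `sequence_record` or string
#' @param pka a [pka_set()]
#' @param tol bisection tolerance on net charge
#' @return list with `length`, `n_acidic` (D+E), `n_basic` (K+R),
#'   `theoretical_pI`, `pka_set`
#' @export
sequence_properties <- function(seq, pka = pka_set(), tol = 1e-6) {
  letters1 <- seq_letters(seq)
  if (length(letters1) == 0) stop("empty sequence")
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid, pka)
    if (abs(q) < tol) break
    if (q > 0) lo <- mid else hi <- mid
  }
  list(length = length(letters1),
       n_acidic = sum(letters1 %in% c("D", "E")),
       n_basic = sum(letters1 %in% c("K", "R")),
       theoretical_pI = mid,
       pka_set = attr(pka, "set_name"))
}
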