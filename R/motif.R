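#' Short-linear-motif pattern with bounded gaps
#'
#' A pattern is an ordered list of residue classes with optional bounded
#' gaps between consecutive classes, e.g. aromatic [WFY] followed directly
#' by R (the strict BBSome-binding motif), or K, gap of 3-8, [KR], gap of 1,
#' R (the canonical PH-domain PIP-binding motif Kx_n[K/R]xR).
#'
#' @param id pattern id used in reports
#' @param elements list of character vectors, each the allowed one-letter
#'   residues at that element
#' @param gaps list of length `length(elements) - 1`; each entry an integer
#'   pair `c(min, max)` of allowed gap lengths between consecutive elements
#'   (default zero gaps everywhere)
#' @return object of class `motif_pattern`
#' @export
motif_pattern <- function(id, elements, gaps = NULL) {
  stopifnot(length(elements) >= 1)
  elements <- lapply(elements, function(e) toupper(as.character(e)))
  if (is.null(gaps)) {
    gaps <- rep(list(c(0L, 0L)), max(0, length(elements) - 1))
  }
  stopifnot(length(gaps) == length(elements) - 1)
  gaps <- lapply(gaps, function(g) {
    g <- as.integer(g)
    if (length(g) == 1) g <- c(g, g)
    stopifnot(length(g) == 2, g[1] >= 0, g[1] <= g[2])
    g
  })
  structure(list(id = id, elements = elements, gaps = gaps),
            class = "motif_pattern")
}

#' BBSome-binding motif patterns
#'
#' Three variants, reported separately and never merged:
#' \describe{
#'   \item{strict}{aromatic followed directly by arginine, `[W/F/Y]R` (the
#'     pattern behind the 20-of-26 helix-8 census).}
#'   \item{relaxed}{aromatic followed directly by lysine or arginine,
#'     `[W/F/Y][K/R]` (the pattern behind the 23-of-26 census).}
#'   \item{gapped}{aromatic, one spacer, then K/R, `[W/F/Y]x[K/R]` (captures
#'     looser candidates such as WCR).}
#' }
#'
#' @param variant `"strict"`, `"relaxed"` or `"gapped"`
#' @return a `motif_pattern`
#' @export
bbs_motif <- function(variant = c("strict", "relaxed", "gapped")) {
  variant <- match.arg(variant)
  aro <- c("W", "F", "Y")
  switch(variant,
    strict = motif_pattern("bbs_strict", list(aro, "R")),
    relaxed = motif_pattern("bbs_relaxed", list(aro, c("K", "R"))),
    gapped = motif_pattern("bbs_gapped", list(aro, c("K", "R")),
                           gaps = list(c(1L, 1L))))
}

#' Canonical PH-domain PIP-binding motif
#'
#' `Kx_n[K/R]xR` with the first gap `n` bounded (default 3-8) and the second
#' gap exactly one residue, the beta1-beta2-loop signature of PIP-binding PH
#' domains (in BBS5 PH1: K41xxxxxR47xR49).
#'
#' @param gap_range integer pair, allowed lengths of the first gap
#' @return a `motif_pattern`
#' @export
pip_motif <- function(gap_range = c(3L, 8L)) {
  motif_pattern("pip_canonical", list("K", c("K", "R"), "R"),
                gaps = list(as.integer(gap_range), c(1L, 1L)))
}

#' Scan a sequence (or window) for a motif
#'
#' Reports every match whose full span lies inside the window, left to
#' right; overlapping matches are all reported, and matches with the same
#' span but different internal gap decompositions are reported once. X never
#' matches any residue class.
#'
#' @param seq a `sequence_record`
#' @param pattern a `motif_pattern`
#' @param window inclusive author-numbered interval `c(start, end)`, or NULL
#'   for the whole sequence
#' @return data.frame with `sequence_id`, `pattern_id`, `start`, `end`
#'   (author numbers), `matched_text`
#' @export
scan_motif <- function(seq, pattern, window = NULL) {
  stopifnot(inherits(seq, "sequence_record"), inherits(pattern, "motif_pattern"))
  letters1 <- seq_letters(seq)
  pos <- seq$positions
  n <- length(letters1)
  empty <- data.frame(sequence_id = character(0), pattern_id = character(0),
                      start = integer(0), end = integer(0),
                      matched_text = character(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  idx <- seq_len(n)
  if (!is.null(window)) {
    idx <- which(pos >= window[1] & pos <= window[2])
    if (length(idx) == 0) return(empty)
  }
  lo <- min(idx); hi <- max(idx)
  spans <- list()
  # depth-first enumeration over element placements and gap choices
  match_from <- function(i, elem) {
    if (elem > length(pattern$elements)) return(list(i - 1L))
    if (i > hi) return(list())
    if (!(letters1[i] %in% pattern$elements[[elem]])) return(list())
    if (elem == length(pattern$elements)) return(list(i))
    g <- pattern$gaps[[elem]]
    out <- list()
    for (gap in g[1]:g[2]) {
      out <- c(out, match_from(i + 1L + gap, elem + 1L))
    }
    out
  }
  for (s in lo:hi) {
    ends <- match_from(s, 1L)
    for (e in ends) spans[[length(spans) + 1L]] <- c(s, e)
  }
  if (length(spans) == 0) return(empty)
  sp <- unique(do.call(rbind, spans))
  sp <- sp[order(sp[, 1], sp[, 2]), , drop = FALSE]
  data.frame(sequence_id = seq$id, pattern_id = pattern$id,
             start = pos[sp[, 1]], end = pos[sp[, 2]],
             matched_text = vapply(seq_len(nrow(sp)), function(k)
               paste(letters1[sp[k, 1]:sp[k, 2]], collapse = ""),
               character(1)),
             stringsAsFactors = FALSE)
}

#' Scan for the canonical PIP-binding motif
#'
#' Convenience wrapper: [scan_motif()] with [pip_motif()].
#'
#' @param seq a `sequence_record`
#' @param gap_range allowed lengths of the K-to-[K/R] gap (default 3-8)
#' @param window optional author-numbered window
#' @return match data.frame as in [scan_motif()]
#' @export
scan_pip_motif <- function(seq, gap_range = c(3L, 8L), window = NULL) {
  scan_motif(seq, pip_motif(gap_range), window)
}

#' Cohort motif census over annotated helix-8 windows
#'
#' Counts how many sequences carry at least one in-window match of the
#' pattern (the census behind "motif within helix 8 in k of n ciliary
#' GPCRs").
#'
#' @param records named list of `sequence_record`s
#' @param pattern a `motif_pattern`
#' @param windows named list (by sequence id) of `helix8_annotation`s or
#'   inclusive author-numbered intervals `c(start, end)`; every sequence
#'   must have one
#' @return list of class `motif_census`: `n_with_match`, `n_total`,
#'   `pattern_id`, and `table` (one row per sequence with its match count)
#' @export
cohort_motif_census <- function(records, pattern, windows) {
  ids <- vapply(records, function(r) r$id, character(1))
  if (!all(ids %in% names(windows))) {
    stop("missing window annotation for: ",
         paste(setdiff(ids, names(windows)), collapse = ", "))
  }
  rows <- lapply(records, function(r) {
    w <- windows[[r$id]]
    if (inherits(w, "helix8_annotation")) w <- w$window
    m <- scan_motif(r, pattern, window = w)
    data.frame(sequence_id = r$id, window_start = w[1], window_end = w[2],
               n_matches = nrow(m), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(n_with_match = sum(tab$n_matches > 0),
                 n_total = nrow(tab), pattern_id = pattern$id, table = tab),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("motif_census [%s]: %d of %d sequences with an in-window match\n",
              x$pattern_id, x$n_with_match, x$n_total))
  invisible(x)
}
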