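# Independent oracles used across tests. These deliberately share no code
# with the package implementation paths they check.

# Horn's quaternion method for the optimal-superposition RMSD: the largest
# eigenvalue of the 4x4 quaternion matrix gives the minimized residual in
# closed form, independent of the SVD/Kabsch route.
horn_rmsd <- function(moving, fixed) {
  pm <- sweep(moving, 2, colMeans(moving))
  pf <- sweep(fixed, 2, colMeans(fixed))
  s <- crossprod(pm, pf)
  n4 <- matrix(c(
    s[1, 1] + s[2, 2] + s[3, 3], s[2, 3] - s[3, 2], s[3, 1] - s[1, 3], s[1, 2] - s[2, 1],
    s[2, 3] - s[3, 2], s[1, 1] - s[2, 2] - s[3, 3], s[1, 2] + s[2, 1], s[3, 1] + s[1, 3],
    s[3, 1] - s[1, 3], s[1, 2] + s[2, 1], -s[1, 1] + s[2, 2] - s[3, 3], s[2, 3] + s[3, 2],
    s[1, 2] - s[2, 1], s[3, 1] + s[1, 3], s[2, 3] + s[3, 2], -s[1, 1] - s[2, 2] + s[3, 3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(n4, symmetric = TRUE)$values)
  sqrt(max(0, sum(pm^2) + sum(pf^2) - 2 * lam) / nrow(moving))
}

# Brute-force motif matching through the regex engine: expand every concrete
# gap combination into a plain regex and find all (overlapping) matches with
# a lookahead. Returns a sorted matrix of index spans.
regex_scan_spans <- function(seq_string, pattern, window_idx = NULL) {
  n <- nchar(seq_string)
  lo <- 1L; hi <- n
  if (!is.null(window_idx)) { lo <- window_idx[1]; hi <- window_idx[2] }
  if (hi < lo || n == 0) return(matrix(integer(0), ncol = 2))
  sub <- substr(seq_string, lo, hi)
  combos <- expand.grid(lapply(pattern$gaps, function(g) g[1]:g[2]))
  if (nrow(combos) == 0) combos <- data.frame(row.names = 1)
  spans <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(combos))) {
    re <- ""
    for (e in seq_along(pattern$elements)) {
      re <- paste0(re, "[", paste(pattern$elements[[e]], collapse = ""), "]")
      if (e < length(pattern$elements)) {
        re <- paste0(re, sprintf(".{%d}", combos[r, e]))
      }
    }
    len <- length(pattern$elements) +
      if (ncol(combos)) sum(combos[r, ]) else 0
    m <- gregexpr(paste0("(?=", re, ")"), sub, perl = TRUE)[[1]]
    if (m[1] != -1) {
      starts <- as.integer(m) + lo - 1L
      spans <- rbind(spans, cbind(starts, starts + len - 1L))
    }
  }
  if (nrow(spans) == 0) return(spans)
  spans <- unique(spans)
  spans[order(spans[, 1], spans[, 2]), , drop = FALSE]
}

random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rotation_about_axis(ax, stats::runif(1, 0, 180))
}

random_transform <- function() {
  rigid_transform(random_rotation(), stats::runif(3, -20, 20))
}

random_aa_string <- function(len, with_x = TRUE) {
  ab <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prob <- rep(1, 20)
  if (with_x) { ab <- c(ab, "X"); prob <- c(prob, 1) }
  paste(sample(ab, len, replace = TRUE, prob = prob / sum(prob)),
        collapse = "")
}

expect_spans_equal <- function(matches, spans, record) {
  got <- if (nrow(matches) == 0) matrix(integer(0), ncol = 2) else
    cbind(match(matches$start, record$positions),
          match(matches$end, record$positions))
  expect_equal(unname(got), unname(spans))
}
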