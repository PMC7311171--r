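#' Tether reach model
#'
#' Per-residue rise constants for the two limiting conformations of a
#' peptide tether: fully extended chain (default 3.5 Angstrom per residue
#' step, so a 6-step tether reaches 21 Angstrom) and ideal alpha-helix
#' (default 1.5 Angstrom per residue step, so 6 steps reach 9 Angstrom).
#'
#' @param extended_rise Angstrom per residue step, extended state
#' @param helical_rise Angstrom per residue step, helical state
#' @return object of class `reach_model`
#' @export
reach_model <- function(extended_rise = 3.5, helical_rise = 1.5) {
  if (!(extended_rise > helical_rise && helical_rise > 0)) {
    stop("require extended_rise > helical_rise > 0")
  }
  structure(list(extended_rise = extended_rise, helical_rise = helical_rise),
            class = "reach_model")
}

#' Maximum tether reach for a residue count
#'
#' @param n_residues number of inter-residue steps in the tether (>= 0)
#' @param state `"extended"` or `"helical"`
#' @param model a [reach_model()]
#' @return reach in Angstrom (`n_residues` times the state's rise)
#' @export
max_reach <- function(n_residues, state = c("extended", "helical"),
                      model = reach_model()) {
  state <- match.arg(state)
  if (any(n_residues < 0)) stop("negative residue count")
  rise <- if (state == "extended") model$extended_rise else model$helical_rise
  n_residues * rise
}

#' Tether length from author numbering
#'
#' Counts inter-residue steps between a membrane-anchored residue and a
#' contact residue: `contact - anchor`. (Lys543 to Trp549 in the SMO C-tail
#' is 6 steps, which at 3.5 Angstrom per extended step gives the 21 Angstrom
#' reach bound.)
#'
#' @param anchor_residue author number of the membrane anchor residue
#' @param contact_residue author number of the binding-site contact residue
#'   (must be >= anchor)
#' @return integer step count
#' @export
tether_length_from_numbering <- function(anchor_residue, contact_residue) {
  if (any(contact_residue < anchor_residue)) {
    stop("contact residue precedes anchor residue")
  }
  as.integer(contact_residue - anchor_residue)
}

#' Conformational verdict for a tether and measured site distance
#'
#' A conformational state is compatible when the measured minimum
#' binding-site/membrane distance does not exceed the tether's reach in that
#' state. When only the extended state is compatible the verdict is
#' "must be unfolded": the tether cannot span the distance while helical, so
#' a helix-8 cargo must leave the membrane and unfold to be engaged.
#'
#' @param d_min measured minimum distance, Angstrom (>= 0)
#' @param n_residues tether step count
#' @param model a [reach_model()]
#' @return object of class `reach_verdict` with `d_min`, `n_residues`,
#'   `extended_reach`, `helical_reach`, `compatible_states`, `conclusion`
#' @export
conformational_verdict <- function(d_min, n_residues,
                                   model = reach_model()) {
  stopifnot(d_min >= 0)
  ext <- max_reach(n_residues, "extended", model)
  hel <- max_reach(n_residues, "helical", model)
  states <- c(if (d_min <= hel) "helical", if (d_min <= ext) "extended")
  conclusion <- if (length(states) == 0) "unreachable"
    else if (identical(states, "extended")) "must be unfolded"
    else "reachable in either state"
  structure(list(d_min = d_min, n_residues = n_residues,
                 extended_reach = ext, helical_reach = hel,
                 compatible_states = states, conclusion = conclusion),
            class = "reach_verdict")
}

#' @export
print.reach_verdict <- function(x, ...) {
  cat(sprintf(
    "reach_verdict: d_min %.1f A over %d steps (extended %.1f A, helical %.1f A)\n  compatible: {%s} -> %s\n",
    x$d_min, x$n_residues, x$extended_reach, x$helical_reach,
    paste(x$compatible_states, collapse = ", "), x$conclusion))
  invisible(x)
}

#' Reach table over a range of tether lengths
#'
#' @param n_max largest step count to tabulate
#' @param model a [reach_model()]
#' @return data.frame with `n_residues`, `extended_reach`, `helical_reach`
#' @export
reach_table <- function(n_max, model = reach_model()) {
  n <- 0:n_max
  data.frame(n_residues = n,
             extended_reach = max_reach(n, "extended", model),
             helical_reach = max_reach(n, "helical", model))
}
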