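# R surface over the compiled force-field kernel.

ff_args <- function(state, extF = NULL) {
  p <- state$params
  list(
    pos = state$pos, radius = state$radius, frozen = state$frozen,
    bonds = state$bonds, angles = state$angles, posres = state$posres,
    dirres = state$dirres, attach = state$attach, ljclass = state$ljclass,
    eps = p$eps_LJ, cutmult = 3,
    excl = if (is.null(state$excl)) {
      matrix(as.integer(excluded_pairs(state)), ncol = 2)
    } else state$excl,
    ellipse = if (is.null(state$ellipse)) numeric(0) else state$ellipse,
    K_mem = p$K_mem, extF = extF
  )
}

#' Total mechanical energy and its breakdown
#'
#' Evaluates the total potential energy of a mechanical state: harmonic
#' stretching and bending of microtubules and chromosome arms, the
#' centromere/corona springs, Ndc80 attachment springs, the repulsive
#' 12-power excluded-volume term, and the soft harmonic membrane repulsion.
#'
#' @param state a `mech_state`.
#' @param extF optional n-by-3 matrix of constant external forces (pN).
#' @return A list of class `energy_breakdown` with elements `U_MT`, `U_KT`,
#'   `U_CH`, `U_att`, `U_rep`, `U_mem`, `total` (pN nm).
#' @export
energy_total <- function(state, extF = NULL) {
  a <- ff_args(state, extF)
  a$want_forces <- FALSE
  out <- do.call(ff_eval_cpp, a)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  v <- unlist(x[c("U_MT", "U_KT", "U_CH", "U_att", "U_rep", "U_mem",
                  "total")])
  print(signif(v, 6))
  invisible(x)
}

#' Bonded (stretch + bend) energies grouped by component
#'
#' @param state a `mech_state`.
#' @return Named vector `c(U_MT, U_KT, U_CH)` in pN nm.
#' @export
energy_bonded <- function(state) {
  e <- energy_total(state)
  c(U_MT = e$U_MT, U_KT = e$U_KT, U_CH = e$U_CH)
}

#' Ndc80 attachment spring energy
#' @param state a `mech_state`.
#' @return `U_att` in pN nm.
#' @export
energy_attachment <- function(state) energy_total(state)$U_att

#' Excluded-volume (repulsive) energy
#' @param state a `mech_state`.
#' @return `U_rep` in pN nm.
#' @export
energy_repulsive <- function(state) energy_total(state)$U_rep

#' Membrane confinement energy
#' @param state a `mech_state`.
#' @param ellipse optional `c(a, b, c)` semi-axes in nm overriding the state's.
#' @return `U_mem` in pN nm.
#' @export
energy_membrane <- function(state, ellipse = NULL) {
  if (!is.null(ellipse)) state$ellipse <- ellipse
  energy_total(state)$U_mem
}

#' Deterministic forces on every bead
#'
#' Forces are the negative gradient of [energy_total()]; frozen beads
#' (centrosomes) report zero force.
#'
#' @param state a `mech_state`.
#' @param extF optional n-by-3 external force matrix (pN), added to the
#'   potential forces.
#' @return n-by-3 matrix of forces in pN.
#' @export
forces <- function(state, extF = NULL) {
  a <- ff_args(state, extF)
  a$want_forces <- TRUE
  do.call(ff_eval_cpp, a)$forces
}
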