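# MechState: flat bead-spring description of every mechanically active
# component, consumed directly by the compiled force/Langevin kernels.
#
# Interaction term groups (column `group` of bonds/angles): 1 = microtubule,
# 2 = kinetochore (centromere spring, corona grid, corona-to-KT), 3 =
# chromosome arms (stretch, bend, cohesin).  Excluded-volume classes
# (`ljclass`): 0 none, 1 MT bead, 2 bulky bead (KT center / arm); pairs
# (1,2) and (2,2) interact, bonded pairs are excluded.

GROUP_MT <- 1; GROUP_KT <- 2; GROUP_CH <- 3

#' Create an empty mechanical state
#'
#' @param params a `spindle_params` (normalized); stored for stiffness and
#'   temperature lookups.
#' @return A `mech_state` list with zero beads.
#' @export
mech_state <- function(params = validate_params()) {
  params <- validate_params(params)
  s <- list(
    pos    = matrix(numeric(0), 0, 3),
    radius = numeric(0),
    gamma  = numeric(0),
    tag    = character(0),
    frozen = logical(0),
    bonds  = matrix(numeric(0), 0, 5,
                    dimnames = list(NULL, c("i", "j", "k", "r0", "group"))),
    angles = matrix(numeric(0), 0, 6,
                    dimnames = list(NULL, c("i", "j", "k", "ktheta",
                                            "theta0", "group"))),
    posres = matrix(numeric(0), 0, 5,
                    dimnames = list(NULL, c("i", "x", "y", "z", "kr"))),
    dirres = matrix(numeric(0), 0, 6,
                    dimnames = list(NULL, c("im", "ib", "dx", "dy", "dz",
                                            "ktheta"))),
    attach = matrix(numeric(0), 0, 4,
                    dimnames = list(NULL, c("i_mt", "i_site", "k", "l0"))),
    ljclass = integer(0),
    ellipse = NULL,        # c(a, b, c) in nm, or NULL for no membrane
    params  = params
  )
  class(s) <- "mech_state"
  s
}

#' Number of beads in a mechanical state
#' @param state a `mech_state`.
#' @return integer bead count.
#' @export
n_beads <- function(state) nrow(state$pos)

#' @export
print.mech_state <- function(x, ...) {
  cat("<mech_state> ", n_beads(x), " beads, ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", nrow(x$attach), " attachments\n", sep = "")
  invisible(x)
}

#' Append beads to a mechanical state
#'
#' @param state a `mech_state`.
#' @param pos n-by-3 positions (nm).
#' @param radius,gamma,tag,frozen,ljclass per-bead attributes (recycled).
#' @return the updated state; the indices of the new beads are in
#'   `attr(state, "new_idx")`.
#' @export
add_beads <- function(state, pos, radius, gamma, tag, frozen = FALSE,
                      ljclass = 0L) {
  pos <- matrix(pos, ncol = 3)
  n <- nrow(pos)
  idx <- n_beads(state) + seq_len(n)
  state$pos    <- rbind(state$pos, pos)
  state$radius <- c(state$radius, rep_len(radius, n))
  state$gamma  <- c(state$gamma, rep_len(gamma, n))
  state$tag    <- c(state$tag, rep_len(tag, n))
  state$frozen <- c(state$frozen, rep_len(frozen, n))
  state$ljclass <- c(state$ljclass, rep_len(as.integer(ljclass), n))
  attr(state, "new_idx") <- idx
  state
}

#' Append harmonic bonds / angles to a mechanical state
#'
#' @param state a `mech_state`.
#' @param i,j,k bead indices (for angles, `j` is the vertex).
#' @param r0 bond rest length (nm).
#' @param ktheta,theta0 angular stiffness (pN nm/rad^2) and rest angle.
#' @param group energy-accounting group: 1 microtubule, 2 kinetochore,
#'   3 chromosome arms.
#' @return the updated state.
#' @export
add_bonds <- function(state, i, j, k, r0, group) {
  state$bonds <- rbind(state$bonds, cbind(i = i, j = j, k = k, r0 = r0,
                                          group = group))
  state
}

#' @rdname add_bonds
#' @export
add_angles <- function(state, i, j, k, ktheta, theta0 = pi, group = GROUP_MT) {
  state$angles <- rbind(state$angles,
                        cbind(i = i, j = j, k = k, ktheta = ktheta,
                              theta0 = theta0, group = group))
  state
}

#' Validate internal consistency of a mechanical state
#'
#' Checks that all bond/angle/attachment endpoints exist, rest lengths are
#' positive, and no bead carries a non-positive friction.
#'
#' @param state a `mech_state`.
#' @return `state`, invisibly; stops on inconsistency.
#' @export
validate_state <- function(state) {
  n <- n_beads(state)
  idx <- c(state$bonds[, c("i", "j")], state$angles[, c("i", "j", "k")],
           state$posres[, "i"], state$dirres[, c("im", "ib")],
           state$attach[, c("i_mt", "i_site")])
  if (length(idx) && (any(idx < 1) || any(idx > n))) {
    stop("interaction references a bead that does not exist")
  }
  if (nrow(state$bonds) && any(state$bonds[, "r0"] <= 0)) {
    stop("bond rest lengths must be positive")
  }
  if (n > 0 && any(state$gamma <= 0)) stop("bead frictions must be positive")
  invisible(state)
}

# Pairs excluded from excluded-volume interactions: everything bonded.
excluded_pairs <- function(state) {
  b <- state$bonds
  if (nrow(b) == 0) return(matrix(integer(0), 0, 2))
  cbind(pmin(b[, "i"], b[, "j"]), pmax(b[, "i"], b[, "j"]))
}
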