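# Overdamped Langevin dynamics: per-bead friction, Ermak-McCammon stepping,
# and T = 0 relaxation to mechanical equilibrium.

#' Friction coefficient for a bead
#'
#' Returns the quoted per-component friction where one exists (kinetochore /
#' chromosome-sized beads and microtubule beads) and the Stokes value
#' 6 pi eta R otherwise.
#'
#' @param radius bead radius in nm.
#' @param component_tag one of `"KT_center"`, `"CH_arm"`, `"CS"`,
#'   `"MT_minus"`, `"MT_body"`, `"MT_plus"`, `"corona"`, or `""` for the
#'   Stokes fallback.
#' @param params a `spindle_params`.
#' @return friction in pN ps/nm.
#' @export
friction_for <- function(radius, component_tag = "", params = validate_params()) {
  params <- validate_params(params)
  if (component_tag %in% c("KT_center", "CH_arm", "CS")) {
    return(params$gamma_KT)
  }
  if (component_tag %in% c("MT_minus", "MT_body", "MT_plus")) {
    return(params$gamma_MT)
  }
  if (!is.numeric(radius) || radius <= 0) {
    stop("no quoted friction for tag '", component_tag,
         "' and no usable radius")
  }
  6 * pi * params$eta * radius
}

#' Langevin-dynamics settings
#'
#' @param dt timestep in ps; reduced automatically below the overdamped
#'   stability bound dt < 2 gamma_min / k_max when stiff small beads are
#'   present.
#' @param temperature kelvin.
#' @param noise_on draw thermal noise (else T = 0 descent).
#' @param max_steps cap on relaxation steps.
#' @param ftol convergence force tolerance in pN.
#' @return `ld_settings` list.
#' @export
ld_settings <- function(dt = 50, temperature = 300, noise_on = FALSE,
                        max_steps = 20000, ftol = 0.1) {
  stopifnot(dt > 0, max_steps >= 1, ftol > 0)
  structure(list(dt = dt, temperature = temperature, noise_on = noise_on,
                 max_steps = max_steps, ftol = ftol),
            class = "ld_settings")
}

# Total stiffness felt by each bead (sum over its bonds, restraints,
# attachments, and an estimate for angular terms) sets the explicit-Euler
# stability bound dt_i < 2 gamma_i / ksum_i.
per_bead_stiffness <- function(state) {
  n <- n_beads(state)
  ks <- numeric(n)
  addk <- function(ks, idx, k) {
    for (q in seq_along(idx)) ks[idx[q]] <- ks[idx[q]] + k[q]
    ks
  }
  b <- state$bonds
  if (nrow(b)) {
    ks <- addk(ks, b[, "i"], b[, "k"]); ks <- addk(ks, b[, "j"], b[, "k"])
  }
  if (nrow(state$posres)) {
    ks <- addk(ks, state$posres[, "i"], state$posres[, "kr"])
  }
  at <- state$attach
  if (nrow(at)) {
    ks <- addk(ks, at[, "i_mt"], at[, "k"])
    ks <- addk(ks, at[, "i_site"], at[, "k"])
  }
  an <- state$angles
  if (nrow(an)) {
    # positional stiffness ~ ktheta / arm^2 on the flanks; microtubule arms
    # (group 1) are floored at the nucleation half-length so the bound is
    # position-independent and can be cached across length events
    la <- sqrt(rowSums((state$pos[an[, "i"], , drop = FALSE] -
                          state$pos[an[, "j"], , drop = FALSE])^2))
    lb <- sqrt(rowSums((state$pos[an[, "k"], , drop = FALSE] -
                          state$pos[an[, "j"], , drop = FALSE])^2))
    mtg <- an[, "group"] == 1
    la[mtg] <- 18; lb[mtg] <- 18
    kpos <- an[, "ktheta"] * (1 / pmax(la, 1)^2 + 1 / pmax(lb, 1)^2)
    ks <- addk(ks, an[, "i"], kpos); ks <- addk(ks, an[, "k"], kpos)
    ks <- addk(ks, an[, "j"], 2 * kpos)
  }
  dr <- state$dirres
  if (nrow(dr)) {
    kpos <- dr[, "ktheta"] / 18^2
    ks <- addk(ks, dr[, "im"], kpos); ks <- addk(ks, dr[, "ib"], kpos)
  }
  ks
}

# Global stability bound for uniform-dt (dynamical) stepping.
ld_stable_dt <- function(state) {
  ks <- per_bead_stiffness(state)
  if (n_beads(state) == 0 || all(ks == 0)) return(Inf)
  min(2 * state$gamma / pmax(ks, 1e-300))
}

ld_effective_dt <- function(state, dt) {
  bound <- ld_stable_dt(state)
  if (dt >= bound) {
    dt_new <- 0.4 * bound
    message(sprintf(
      "LD timestep %.3g ps exceeds stability bound %.3g ps; using %.3g ps",
      dt, bound, dt_new))
    return(dt_new)
  }
  dt
}

# Per-bead relaxation steps: each bead at a fixed fraction of its own bound.
per_bead_dt <- function(state, dt, safety = 0.25) {
  ks <- per_bead_stiffness(state)
  pmin(dt, ifelse(ks > 0, safety * 2 * state$gamma / ks, dt))
}

#' One (or more) Ermak-McCammon steps
#'
#' Advances r_i by (F_i / gamma_i) dt plus, when `noise_on`, a Gaussian
#' displacement with per-coordinate variance 2 k_B T dt / gamma_i. Frozen
#' beads do not move.
#'
#' @param state a `mech_state`.
#' @param settings an [ld_settings()].
#' @param n_steps number of steps.
#' @param extF optional constant external forces (n-by-3, pN).
#' @return the updated `mech_state`.
#' @export
ld_step <- function(state, settings = ld_settings(), n_steps = 1,
                    extF = NULL) {
  bound <- ld_stable_dt(state)
  if (settings$dt >= bound) {
    stop(sprintf("LD timestep %.3g ps is above the stability bound %.3g ps",
                 settings$dt, bound))
  }
  a <- ff_args(state, extF)
  a$want_forces <- NULL
  out <- do.call(ld_run_cpp, c(a, list(
    gamma = state$gamma, dt = settings$dt, n_steps = as.integer(n_steps),
    kT = kB_T(settings$temperature), noise = isTRUE(settings$noise_on),
    sample_every = 0L, sample_beads = integer(0))))
  state$pos <- out$pos
  state
}

#' Thermal LD trajectory with sampling
#'
#' @inheritParams ld_step
#' @param sample_every record every this many steps.
#' @param sample_beads bead indices to record.
#' @return list with final `state` and `samples` (rows = records, columns =
#'   x,y,z per sampled bead).
#' @export
ld_trajectory <- function(state, settings, n_steps, sample_every,
                          sample_beads, extF = NULL) {
  settings$dt <- ld_effective_dt(state, settings$dt)
  a <- ff_args(state, extF)
  out <- do.call(ld_run_cpp, c(a, list(
    gamma = state$gamma, dt = settings$dt, n_steps = as.integer(n_steps),
    kT = kB_T(settings$temperature), noise = isTRUE(settings$noise_on),
    sample_every = as.integer(sample_every),
    sample_beads = as.integer(sample_beads))))
  state$pos <- out$pos
  list(state = state, samples = out$samples, dt = settings$dt)
}

#' Relax a state to mechanical equilibrium (T = 0)
#'
#' Steepest-descent Langevin steps until the largest per-bead force drops
#' below `settings$ftol` or `settings$max_steps` is reached (in which case a
#' warning flag, not an error, is set on the result).
#'
#' @param state a `mech_state`.
#' @param settings an [ld_settings()].
#' @param extF optional constant external forces.
#' @param active optional bead indices: only these move and only interaction
#'   terms touching them are evaluated (local relaxation around an event).
#' @param dtv optional precomputed per-bead timestep vector (ps).
#' @return list: `state` (relaxed), `n_steps`, `max_force` (pN),
#'   `converged` (logical).
#' @export
relax_to_equilibrium <- function(state, settings = ld_settings(),
                                 extF = NULL, active = integer(0),
                                 dtv = NULL) {
  if (is.null(dtv)) dtv <- per_bead_dt(state, settings$dt)
  a <- ff_args(state, extF)
  out <- do.call(ld_relax_cpp, c(a, list(
    gamma = state$gamma, dt = dtv, ftol = settings$ftol,
    max_steps = as.integer(settings$max_steps),
    active = as.integer(active), max_disp = 5)))
  state$pos <- out$pos
  list(state = state, n_steps = out$n_steps, max_force = out$max_force,
       converged = out$converged)
}
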