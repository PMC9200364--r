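# The RDME <-> LD coupling loop: biological time advances by stochastic
# kinetic events (microtubule dynamics, attachment/detachment, Ndc80
# phosphorylation); events that change the mechanical state hand control to
# the T = 0 Langevin relaxation before kinetics resumes.

#' Default simulation configuration
#'
#' @param params named parameter overrides (see [default_params()]).
#' @param kt_offset initial kinetochore displacement from the spindle axis,
#'   nm.
#' @param orientation initial KT-axis orientation.
#' @param with_arms,flexible kinetochore variants.
#' @param n_corona corona beads (= Ndc80 sites) per sister.
#' @param mt_length_range initial MT lengths, nm.
#' @param bio_time biological duration, s.
#' @param output_interval frame spacing, s.
#' @param field_mode Aurora representation (`"field"` or `"explicit"`).
#' @param relax_max_steps,relax_ftol,dt Langevin relaxation controls
#'   (steps, pN, ps).
#' @param seed optional RNG seed applied at the start of [run_simulation()].
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(params = list(), kt_offset = 1500,
                              orientation = "perpendicular",
                              with_arms = FALSE, flexible = FALSE,
                              n_corona = NULL, mt_length_range = NULL,
                              bio_time = 60, output_interval = 1,
                              field_mode = "field", relax_max_steps = 100,
                              relax_ftol = 0.1, dt = 50, seed = NULL) {
  structure(list(params = params, kt_offset = kt_offset,
                 orientation = orientation, with_arms = with_arms,
                 flexible = flexible, n_corona = n_corona,
                 mt_length_range = mt_length_range, bio_time = bio_time,
                 output_interval = output_interval, field_mode = field_mode,
                 relax_max_steps = relax_max_steps, relax_ftol = relax_ftol,
                 dt = dt, seed = seed),
            class = "simulation_config")
}

#' A small spindle for desk-scale runs
#'
#' 20 microtubules per pole, 32 corona beads per kinetochore, a 5-um cell
#' with 3-um pole separation and a 750-nm initial kinetochore offset: the
#' full model at a size where minutes of biological time run in seconds to
#' minutes of wall time.
#'
#' @param ... overrides passed to [simulation_config()].
#' @export
mini_spindle_config <- function(...) {
  base <- simulation_config(
    params = list(ellipse_a = 2.5, ellipse_b = 2.0, ellipse_c = 2.0,
                  pole_separation = 3, n_MT_per_CS = 20L),
    kt_offset = 750, n_corona = 32L, mt_length_range = c(36, 500),
    bio_time = 60)
  over <- list(...)
  if (!is.null(over$params)) {
    base$params <- modifyList(base$params, over$params)
    over$params <- NULL
  }
  base[names(over)] <- over
  base
}

#' Assemble the full mechanical + lattice cell from a configuration
#'
#' Builds both centrosome asters, the kinetochore pair (placed at its
#' initial offset), the subcell lattice with enzyme fields, and merges them
#' into one `spindle_cell`.
#'
#' @param config a [simulation_config()].
#' @return a `spindle_cell`: `state`, `mts`, `kt`, `lattice`, `params`,
#'   plus run bookkeeping.
#' @export
build_spindle_cell <- function(config = simulation_config()) {
  p <- validate_params(config$params)
  ellipse <- c(p$ellipse_a, p$ellipse_b, p$ellipse_c) * 1000
  half_sep <- p$pole_separation * 1000 / 2

  astL <- build_aster(c(-half_sep, 0, 0), p$n_MT_per_CS, p,
                      length_range = config$mt_length_range)
  astR <- build_aster(c(half_sep, 0, 0), p$n_MT_per_CS, p,
                      length_range = config$mt_length_range)
  ktf <- build_kinetochore_pair(p, flexible = config$flexible,
                                with_arms = config$with_arms,
                                n_corona = config$n_corona)
  ktf <- place_initial_configuration(ktf, offset = config$kt_offset,
                                     orientation = config$orientation,
                                     ellipse = ellipse)

  state <- merge_states(astL$state, astR$state)
  offR <- attr(state, "offset")
  state <- merge_states(state, ktf$state)
  offK <- attr(state, "offset")
  state$ellipse <- ellipse

  mtsR <- astR$mts
  bcols <- c("i_minus", "i_body", "i_plus", "i_cs")
  mtsR[bcols] <- mtsR[bcols] + offR
  mtsR[c("bond1", "bond2")] <- mtsR[c("bond1", "bond2")] +
    nrow(astL$state$bonds)
  mtsR$angle_row <- mtsR$angle_row + nrow(astL$state$angles)
  mtsR$id <- mtsR$id + nrow(astL$mts)
  mts <- rbind(astL$mts, mtsR)
  mts$pole <- rep(c("L", "R"), c(nrow(astL$mts), nrow(mtsR)))

  kt <- ktf$kt
  kt$i_kt <- kt$i_kt + offK
  kt$sites$bead <- kt$sites$bead + offK
  kt$sites$mt <- 0L
  kt$arm_beads <- kt$arm_beads + offK
  # bond/angle row offsets for the KT fragment are irrelevant downstream

  lattice <- build_lattice(ellipse[1], ellipse[2], ellipse[3], p$l_SV)
  kt_centers <- state$pos[kt$i_kt, , drop = FALSE]
  cs_pos <- rbind(c(-half_sep, 0, 0), c(half_sep, 0, 0))
  lattice <- init_enzyme_fields(lattice, kt_centers, cs_pos, p,
                                mode = config$field_mode)

  cell <- list(state = state, mts = mts, kt = kt, lattice = lattice,
               params = p, cs_pos = cs_pos,
               assembly_beads = c(kt$i_kt, kt$sites$bead, kt$arm_beads),
               nucleation_length = if (is.null(config$mt_length_range))
                 3 * p$R_MT else config$mt_length_range[1],
               config = config, t = 0)
  class(cell) <- "spindle_cell"
  cell
}

#' @export
print.spindle_cell <- function(x, ...) {
  cat("<spindle_cell> ", nrow(x$mts), " MTs, ", nrow(x$kt$sites),
      " Ndc80 sites, ", n_beads(x$state), " beads, t = ", x$t, " s\n",
      sep = "")
  invisible(x)
}

#' Does a kinetic event change the mechanical state?
#'
#' True exactly for microtubule growth/shortening/catastrophe/rescue and
#' attachment formation/release; false for phosphorylation (which only
#' refreshes propensities) and diffusion hops.
#'
#' @param event event name, or a list with a `name` element.
#' @return logical.
#' @export
detect_mech_change <- function(event) {
  nm <- if (is.list(event)) event$name else event
  nm %in% c("grow", "shorten", "catastrophe", "rescue", "attach", "detach")
}

# Beads to relax after an event on microtubule ev_mt, with a kind tag:
# "free" (the filament interacts with nothing but its anchor and possibly
# the membrane), or "assembly" (it is attached to or pressing on the
# kinetochore assembly: relax the assembly plus every microtubule engaged
# with it).  Pressing means inside 1.7 sigma, where the excluded-volume
# force reaches the ~10 pN contact scale; weaker tail forces are picked up
# by the periodic whole-cell relaxation instead of per-event work.
active_set <- function(cell, ev_mt) {
  st <- cell$state
  mt_beads <- function(ids) {
    as.integer(rbind(cell$mts$i_minus[ids], cell$mts$i_body[ids],
                     cell$mts$i_plus[ids]))
  }
  mtb <- mt_beads(ev_mt)
  big <- c(cell$kt$i_kt, cell$kt$arm_beads)
  near <- function(ids) {
    px <- st$pos[ids, 1]; py <- st$pos[ids, 2]; pz <- st$pos[ids, 3]
    for (b in big) {
      lim <- 1.7 * (cell$params$R_MT + st$radius[b])
      d2 <- (px - st$pos[b, 1])^2 + (py - st$pos[b, 2])^2 +
        (pz - st$pos[b, 3])^2
      if (any(d2 < lim^2)) return(TRUE)
    }
    FALSE
  }
  involve <- cell$mts$attached_site[ev_mt] > 0 || near(mtb)
  if (!involve) return(list(act = mtb, kind = "free"))
  ids <- which(cell$mts$attached_site > 0)
  for (m in seq_len(nrow(cell$mts))) {
    if (m == ev_mt || m %in% ids) next
    if (near(c(cell$mts$i_body[m], cell$mts$i_plus[m]))) ids <- c(ids, m)
  }
  list(act = c(cell$assembly_beads, mt_beads(union(ids, ev_mt))),
       kind = "assembly")
}

# A free microtubule needs relaxing only when poking through the membrane.
outside_membrane <- function(state, beads) {
  e <- state$ellipse
  if (is.null(e)) return(FALSE)
  p <- state$pos[beads, , drop = FALSE]
  any((p[, 1] / e[1])^2 + (p[, 2] / e[2])^2 + (p[, 3] / e[3])^2 > 1)
}

# Per-site phosphorylation rates from the current geometry: up-rate from the
# kinase field at each site's subcell, down-rate from the explicit
# phosphatase count there.
site_phospho_rates <- function(cell) {
  p <- cell$params
  c_up <- convert_bimolecular_rate(p$k_phos)
  c_dn <- convert_bimolecular_rate(p$k_dephos)
  sc <- subcell_of(cell$lattice, cell$state$pos[cell$kt$sites$bead, ,
                                                drop = FALSE])
  kin <- kinase_counts(cell$lattice)
  ph <- phosphatase_counts(cell$lattice)
  ok <- !is.na(sc)
  up <- dn <- numeric(length(sc))
  up[ok] <- c_up * kin[sc[ok]]
  dn[ok] <- c_dn * ph[sc[ok]]
  list(up = up, dn = dn)
}

# Re-center the Aurora B gaussian on the current kinetochore midpoint
# (the kinase cloud is tethered to the centromere).
recenter_fields <- function(cell) {
  if (!identical(cell$lattice$fields$mode, "field")) return(cell)
  p <- cell$params
  kt_centers <- cell$state$pos[cell$kt$i_kt, , drop = FALSE]
  hood <- corona_neighborhood(cell$lattice, kt_centers, p)
  w <- gaussian_weights(cell$lattice, colMeans(kt_centers), p$sigma_AB, hood)
  if (sum(w) > 0) w <- w / sum(w)
  cell$lattice$fields$AB <- w * p$n_AB
  cell$lattice$fields$hood <- hood
  cell
}

make_frame <- function(cell, with_forces = TRUE) {
  list(time = cell$t,
       pos = cell$state$pos,
       forces = if (with_forces) forces(cell$state) else NULL,
       attach = cell$state$attach,
       p_sites = cell$kt$sites$p,
       phase = cell$mts$phase,
       attached = cell$mts$attached_site,
       lattice_totals = species_total(cell$lattice))
}

#' Run a full mechanochemical simulation
#'
#' The main loop: kinetic channels (per-MT growth/shortening/catastrophe/
#' rescue, per-candidate attachment formation, per-attachment
#' phospho-dependent release, per-site Ndc80 (de)phosphorylation) are
#' sampled exactly by the Gillespie/next-subvolume machinery; after every
#' mechanics-changing event the geometry is updated and relaxed to
#' mechanical equilibrium at T = 0. Biological time is advanced only by the
#' kinetic waiting times, never by Langevin steps. Frames are emitted every
#' `output_interval` seconds.
#'
#' @param config a [simulation_config()].
#' @return a `spindle_trajectory`: `frames` (list), `cell` (final state),
#'   `stats` (event counters, non-converged relaxations), `config`.
#' @export
run_simulation <- function(config = simulation_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cell <- build_spindle_cell(config)
  p <- cell$params
  k_att <- convert_bimolecular_rate(p$k_on_NdcMT)  # per candidate pair
  settings <- ld_settings(dt = config$dt, max_steps = config$relax_max_steps,
                          ftol = config$relax_ftol)

  # static caches: excluded pairs depend only on bond topology; the
  # per-bead stability bound is position-independent by construction and
  # changes only when attachments change
  cell$state$excl <- matrix(as.integer(excluded_pairs(cell$state)), ncol = 2)
  dtv <- per_bead_dt(cell$state, settings$dt)

  # settle any initial strain (arm lattices, corona vs membrane)
  rx <- relax_to_equilibrium(cell$state, ld_settings(
    dt = settings$dt, max_steps = 20 * settings$max_steps,
    ftol = settings$ftol), dtv = dtv)
  cell$state <- rx$state

  cand <- candidate_attachments(cell)
  ph_rates <- site_phospho_rates(cell)
  kt_ref <- colMeans(cell$state$pos[cell$kt$i_kt, , drop = FALSE])
  # periodic whole-cell relaxation mops up residuals left by local updates
  full_relax_interval <- 10
  next_full_relax <- full_relax_interval
  full_settings <- settings
  full_settings$max_steps <- 10 * settings$max_steps
  n_att_prev <- nrow(cell$state$attach)

  frames <- vector("list", floor(config$bio_time / config$output_interval) + 1)
  frames[[1]] <- make_frame(cell)
  nfr <- 1
  next_frame <- config$output_interval

  counters <- c(grow = 0, shorten = 0, catastrophe = 0, rescue = 0,
                attach = 0, detach = 0, phospho = 0, dephospho = 0,
                relax_nc = 0)
  repeat {
    growing <- cell$mts$phase == "growing"
    attached <- cell$mts$attached_site > 0
    # an attached filament at its minimum length is stalled: it can no
    # longer shorten (the kinetochore is parked) and waits for detachment
    can_shorten <- !growing &
      (!attached | cell$mts$length - p$delta_l >= 3 * p$R_MT)
    a_grow <- sum(growing) * p$k_gr
    a_shorten <- sum(can_shorten) * p$k_sh
    a_cat <- sum(growing & !attached) * p$w_cat
    a_res <- sum(!growing & !attached) * p$w_res
    a_att <- nrow(cand) * k_att
    det_rates <- if (any(attached)) {
      detachment_propensity(cell$kt$sites$p[cell$mts$attached_site[attached]],
                            p)
    } else numeric(0)
    a_det <- sum(det_rates)
    can_up <- cell$kt$sites$p < p$p_max
    can_dn <- cell$kt$sites$p > 0
    a_up <- sum(ph_rates$up[can_up])
    a_dn <- sum(ph_rates$dn[can_dn])
    a_tot <- a_grow + a_shorten + a_cat + a_res + a_att + a_det + a_up + a_dn
    if (a_tot <= 0) cell$t <- config$bio_time
    else cell$t <- min(cell$t + rexp(1) / a_tot, config$bio_time)

    # emit frames crossed by this waiting time
    while (next_frame <= cell$t + 1e-12 && next_frame <= config$bio_time) {
      nfr <- nfr + 1
      fr_cell <- cell; fr_cell$t <- next_frame
      frames[[nfr]] <- make_frame(fr_cell)
      next_frame <- next_frame + config$output_interval
    }
    if (cell$t >= config$bio_time) break

    u <- runif(1) * a_tot
    mech <- TRUE
    needs_relax <- TRUE
    ev_mt <- 0L
    if (u < a_grow) {
      ev_mt <- safe_sample(which(growing))
      cell <- apply_mt_length_event(cell, ev_mt, "grow")
      counters["grow"] <- counters["grow"] + 1
    } else if ((u <- u - a_grow) < a_shorten) {
      ev_mt <- safe_sample(which(can_shorten))
      cell <- apply_mt_length_event(cell, ev_mt, "shorten")
      counters["shorten"] <- counters["shorten"] + 1
    } else if ((u <- u - a_shorten) < a_cat) {
      ev_mt <- safe_sample(which(growing & !attached))
      cell <- switch_phase(cell, ev_mt, "catastrophe")
      counters["catastrophe"] <- counters["catastrophe"] + 1
      needs_relax <- FALSE  # phase flip: rates change, geometry does not
    } else if ((u <- u - a_cat) < a_res) {
      ev_mt <- safe_sample(which(!growing & !attached))
      cell <- switch_phase(cell, ev_mt, "rescue")
      counters["rescue"] <- counters["rescue"] + 1
      needs_relax <- FALSE
    } else if ((u <- u - a_res) < a_att) {
      q <- if (nrow(cand) == 1) 1L else sample.int(nrow(cand), 1)
      ev_mt <- cand[q, "mt"]
      cell <- form_attachment(cell, ev_mt, cand[q, "site"])
      counters["attach"] <- counters["attach"] + 1
    } else if ((u <- u - a_att) < a_det) {
      ids <- which(attached)
      ev_mt <- ids[safe_sample_prob(det_rates)]
      cell <- break_attachment(cell, ev_mt)
      counters["detach"] <- counters["detach"] + 1
    } else if ((u <- u - a_det) < a_up) {
      s <- which(can_up)[safe_sample_prob(ph_rates$up[can_up])]
      cell <- phospho_event(cell, s, +1)
      counters["phospho"] <- counters["phospho"] + 1
      mech <- FALSE
    } else {
      s <- which(can_dn)[safe_sample_prob(ph_rates$dn[can_dn])]
      cell <- phospho_event(cell, s, -1)
      counters["dephospho"] <- counters["dephospho"] + 1
      mech <- FALSE
    }

    if (mech) {
      asm_moved <- FALSE
      if (attach_changed(cell, n_att_prev)) {
        dtv <- per_bead_dt(cell$state, settings$dt)
        n_att_prev <- nrow(cell$state$attach)
      }
      if (needs_relax) {
        as_ <- active_set(cell, ev_mt)
        loc <- settings
        if (as_$kind == "free") {
          # untouched filament: relaxation only matters at the membrane
          if (!outside_membrane(cell$state, as_$act)) loc <- NULL
          else loc$max_steps <- min(loc$max_steps, 30L)
        } else {
          loc$max_steps <- min(loc$max_steps, 50L)
        }
        if (!is.null(loc)) {
          rx <- relax_to_equilibrium(cell$state, loc, active = as_$act,
                                     dtv = dtv)
          cell$state <- rx$state
          if (!rx$converged) {
            counters["relax_nc"] <- counters["relax_nc"] + 1
          }
          asm_moved <- as_$kind == "assembly"
        }
      }
      if (cell$t >= next_full_relax) {
        rx <- relax_to_equilibrium(cell$state, full_settings, dtv = dtv)
        cell$state <- rx$state
        next_full_relax <- next_full_relax + full_relax_interval
        asm_moved <- TRUE
      }
      cand <- candidate_attachments(cell)
      if (asm_moved) {
        kt_mid <- colMeans(cell$state$pos[cell$kt$i_kt, , drop = FALSE])
        if (sqrt(sum((kt_mid - kt_ref)^2)) > cell$lattice$l_SV / 2) {
          cell <- recenter_fields(cell)
          kt_ref <- kt_mid
        }
        ph_rates <- site_phospho_rates(cell)
      }
    }
  }
  frames <- frames[seq_len(nfr)]
  structure(list(frames = frames, cell = cell, stats = counters,
                 config = config),
            class = "spindle_trajectory")
}

attach_changed <- function(cell, n_prev) nrow(cell$state$attach) != n_prev

# sample() misbehaves on length-1 integer vectors; these do not.
safe_sample <- function(ids) if (length(ids) == 1) ids else sample(ids, 1)
safe_sample_prob <- function(w) {
  if (length(w) == 1) 1L else sample.int(length(w), 1, prob = w)
}

#' @export
print.spindle_trajectory <- function(x, ...) {
  cat("<spindle_trajectory> ", length(x$frames), " frames to t = ",
      x$cell$t, " s; events:\n", sep = "")
  print(x$stats)
  invisible(x)
}
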