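# Microtubule dynamic instability and Ndc80-mediated attachment kinetics:
# the mechanochemistry bridging RDME events to mechanics.
#
# These operations act on a `spindle_cell` (see build_spindle_cell): a
# mech_state plus per-MT and per-Ndc80-site bookkeeping.

#' Apply a growth or shortening event to one microtubule
#'
#' Changes the filament length by `delta_l`, resets the two segment rest
#' lengths to l/2, and repositions the body and plus-end beads along the
#' filament's current axis at the new rest geometry (any elastic strain is
#' resolved by the subsequent Langevin relaxation). A shortening event that
#' would take the filament below the minimum length re-nucleates it: length
#' resets to the nucleation length, the phase flips to growing, the anchor
#' direction is kept, and any attachment is released.
#'
#' @param cell a `spindle_cell`.
#' @param mt_id microtubule id.
#' @param kind `"grow"` or `"shorten"`.
#' @return the updated cell (fields `renucleated`, `released_site` on the
#'   attribute `event_info`).
#' @export
apply_mt_length_event <- function(cell, mt_id, kind = c("grow", "shorten")) {
  kind <- match.arg(kind)
  p <- cell$state$params
  mts <- cell$mts
  phase <- mts$phase[mt_id]
  if (kind == "grow" && phase != "growing") stop("grow event on a non-growing MT")
  if (kind == "shorten" && phase != "shortening") {
    stop("shorten event on a non-shortening MT")
  }
  info <- list(renucleated = FALSE, released_site = 0L)
  min_len <- 3 * p$R_MT
  if (kind == "grow") {
    new_len <- mts$length[mt_id] + p$delta_l
  } else {
    new_len <- mts$length[mt_id] - p$delta_l
    if (new_len < min_len) {
      new_len <- cell$nucleation_length
      cell$mts$phase[mt_id] <- "growing"
      info$renucleated <- TRUE
      if (mts$attached_site[mt_id] > 0) {
        info$released_site <- mts$attached_site[mt_id]
        cell <- break_attachment(cell, mt_id)
      }
    }
  }
  # current axis from minus to plus end; fall back to the anchor direction
  i_minus <- mts$i_minus[mt_id]; i_body <- mts$i_body[mt_id]
  i_plus <- mts$i_plus[mt_id]
  u <- cell$state$pos[i_plus, ] - cell$state$pos[i_minus, ]
  nu <- sqrt(sum(u^2))
  u <- if (nu > 1e-9) u / nu else
    c(mts$dx[mt_id], mts$dy[mt_id], mts$dz[mt_id])
  base <- cell$state$pos[i_minus, ]
  cell$state$pos[i_body, ] <- base + u * new_len / 2
  cell$state$pos[i_plus, ] <- base + u * new_len
  cell$state$bonds[c(mts$bond1[mt_id], mts$bond2[mt_id]), "r0"] <-
    new_len / 2
  cell$mts$length[mt_id] <- new_len
  attr(cell, "event_info") <- info
  cell
}

#' Switch a microtubule between growth and shortening
#'
#' @param cell a `spindle_cell`.
#' @param mt_id microtubule id.
#' @param kind `"catastrophe"` (growing -> shortening) or `"rescue"`.
#' @return the updated cell.
#' @export
switch_phase <- function(cell, mt_id, kind = c("catastrophe", "rescue")) {
  kind <- match.arg(kind)
  ph <- cell$mts$phase[mt_id]
  if (kind == "catastrophe" && ph != "growing") {
    stop("catastrophe requires a growing MT")
  }
  if (kind == "rescue" && ph != "shortening") stop("rescue requires a shortening MT")
  cell$mts$phase[mt_id] <- if (kind == "catastrophe") "shortening" else "growing"
  cell
}

#' Candidate microtubule-Ndc80 attachment pairs
#'
#' All (growing, unattached plus-end, free Ndc80 site) pairs within the
#' capture radius `l_Ndc`; each candidate carries the per-pair formation
#' propensity from the attachment rate constant.
#'
#' @param cell a `spindle_cell`.
#' @return matrix with columns `mt`, `site` (site row index in
#'   `cell$kt$sites`); zero rows when none.
#' @export
candidate_attachments <- function(cell) {
  p <- cell$state$params
  free_sites <- which(!cell$kt$sites$occupied)
  mt_ok <- which(cell$mts$phase == "growing" & cell$mts$attached_site == 0)
  out <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("mt", "site")))
  if (!length(free_sites) || !length(mt_ok)) return(out)
  pos <- cell$state$pos
  ip <- cell$mts$i_plus[mt_ok]
  px <- pos[ip, 1]; py <- pos[ip, 2]; pz <- pos[ip, 3]
  # prefilter: plus-ends within reach of either kinetochore sphere
  reach2 <- (p$R_CH + p$l_Ndc + 50)^2
  keep <- rep(FALSE, length(mt_ok))
  for (s in 1:2) {
    kp <- pos[cell$kt$i_kt[s], ]
    keep <- keep |
      ((px - kp[1])^2 + (py - kp[2])^2 + (pz - kp[3])^2 <= reach2)
  }
  mt_ok <- mt_ok[keep]
  if (!length(mt_ok)) return(out)
  sb <- cell$kt$sites$bead[free_sites]
  sx <- pos[sb, 1]; sy <- pos[sb, 2]; sz <- pos[sb, 3]
  for (m in mt_ok) {
    pp <- pos[cell$mts$i_plus[m], ]
    d2 <- (sx - pp[1])^2 + (sy - pp[2])^2 + (sz - pp[3])^2
    hit <- which(d2 <= p$l_Ndc^2)
    if (length(hit)) {
      out <- rbind(out, cbind(mt = m, site = free_sites[hit]))
    }
  }
  out
}

#' Form a microtubule-kinetochore attachment
#'
#' Creates the Ndc80 harmonic bond between the plus-end and the corona bead,
#' marks the site occupied, and triggers an immediate catastrophe: the
#' attached microtubule switches to shortening.
#'
#' @param cell a `spindle_cell`.
#' @param mt_id,site_id the candidate pair (site row index).
#' @return the updated cell; a no-op if the pair became invalid.
#' @export
form_attachment <- function(cell, mt_id, site_id) {
  if (cell$kt$sites$occupied[site_id] || cell$mts$attached_site[mt_id] > 0) {
    return(cell)  # raced by another event
  }
  p <- cell$state$params
  cell$state$attach <- rbind(
    cell$state$attach,
    cbind(i_mt = cell$mts$i_plus[mt_id],
          i_site = cell$kt$sites$bead[site_id],
          k = p$K_Ndc_r, l0 = p$l_Ndc))
  cell$kt$sites$occupied[site_id] <- TRUE
  cell$kt$sites$mt[site_id] <- mt_id
  cell$mts$attached_site[mt_id] <- site_id
  cell$mts$phase[mt_id] <- "shortening"  # immediate catastrophe
  cell
}

#' Release a microtubule-kinetochore attachment
#'
#' The microtubule keeps its current phase; the site keeps its
#' phosphorylation state.
#'
#' @param cell a `spindle_cell`.
#' @param mt_id attached microtubule id.
#' @return the updated cell.
#' @export
break_attachment <- function(cell, mt_id) {
  site_id <- cell$mts$attached_site[mt_id]
  if (site_id == 0) return(cell)
  row <- which(cell$state$attach[, "i_mt"] == cell$mts$i_plus[mt_id])
  cell$state$attach <- cell$state$attach[-row, , drop = FALSE]
  cell$kt$sites$occupied[site_id] <- FALSE
  cell$kt$sites$mt[site_id] <- 0L
  cell$mts$attached_site[mt_id] <- 0L
  cell
}

#' Phosphorylation-dependent detachment propensity
#'
#' @param p number of phosphorylated Ndc80 sites, 0..p_max.
#' @param params a `spindle_params`.
#' @return detachment rate (1.5 + 0.2 p) x 1e-3 1/s.
#' @examples
#' detachment_propensity(0)  # 1.5e-3: mean lifetime ~11.1 min
#' detachment_propensity(7)  # 2.9e-3: mean lifetime ~5.7 min
#' @export
detachment_propensity <- function(p, params = validate_params()) {
  params <- validate_params(params)
  if (any(p < 0 | p > params$p_max)) stop("p outside [0, p_max]")
  params$k_off_base + params$k_off_perP * p
}

#' Apply a (de)phosphorylation event to one Ndc80 site
#'
#' @param cell a `spindle_cell`.
#' @param site_id site row index.
#' @param direction `+1` (phosphorylation) or `-1`.
#' @return the updated cell.
#' @export
phospho_event <- function(cell, site_id, direction) {
  p <- cell$kt$sites$p[site_id]
  pm <- cell$state$params$p_max
  if (direction > 0 && p >= pm) stop("site already fully phosphorylated")
  if (direction < 0 && p <= 0) stop("site already fully dephosphorylated")
  cell$kt$sites$p[site_id] <- p + as.integer(sign(direction))
  cell
}

#' Pushing/pulling statistics from a trajectory
#'
#' Extracts contiguous episodes of microtubule-chromosome excluded-volume
#' contact (center separation below the repulsive length scale sigma plus a
#' margin) with their mean repulsive force magnitudes, and the Ndc80 spring
#' tensions on attached microtubules.
#'
#' @param frames list of trajectory frames (see [run_simulation()]); each
#'   frame holds `time`, `pos`, `attach`.
#' @param cell the `spindle_cell` the frames came from (for radii/indices).
#' @param contact_mult contact threshold in units of sigma = R_i + R_j.
#' @return list: `push_durations` (s), `push_forces` (pN),
#'   `pull_forces` (pN).
#' @export
pushing_interaction_stats <- function(frames, cell, contact_mult = 1.6) {
  p <- cell$state$params
  mt_beads <- which(cell$state$ljclass == 1L)
  big <- which(cell$state$ljclass == 2L)
  durations <- numeric(0)
  push_forces <- numeric(0)
  pull_forces <- numeric(0)
  if (length(mt_beads) && length(big) && length(frames) > 1) {
    dtf <- diff(vapply(frames, `[[`, numeric(1), "time"))
    key_open <- list()
    for (fi in seq_along(frames)) {
      pos <- frames[[fi]]$pos
      now <- character(0)
      for (b in big) {
        sig <- p$R_MT + cell$state$radius[b]
        d <- sqrt(colSums((t(pos[mt_beads, , drop = FALSE]) - pos[b, ])^2))
        hit <- which(d <= contact_mult * sig)
        for (h in hit) {
          kk <- paste(mt_beads[h], b)
          fmag <- 12 * p$eps_LJ * (sig / d[h])^12 / d[h]
          if (is.null(key_open[[kk]])) {
            key_open[[kk]] <- list(start = fi, f = fmag)
          } else {
            key_open[[kk]]$f <- c(key_open[[kk]]$f, fmag)
          }
          now <- c(now, kk)
        }
      }
      ended <- setdiff(names(key_open), now)
      if (fi == length(frames)) ended <- names(key_open)  # flush at the end
      for (kk in ended) {
        ep <- key_open[[kk]]
        durations <- c(durations,
                       sum(dtf[seq(ep$start, max(ep$start, fi - 1))]))
        push_forces <- c(push_forces, mean(ep$f))
        key_open[[kk]] <- NULL
      }
    }
  }
  for (fr in frames) {
    att <- fr$attach
    if (!is.null(att) && nrow(att)) {
      d <- sqrt(rowSums((fr$pos[att[, "i_mt"], , drop = FALSE] -
                           fr$pos[att[, "i_site"], , drop = FALSE])^2))
      pull_forces <- c(pull_forces, abs(att[, "k"] * (d - att[, "l0"])))
    }
  }
  list(push_durations = durations, push_forces = push_forces,
       pull_forces = pull_forces)
}
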