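# Readouts: attachment-error classification, spindle geometry metrics, and
# diffusion-coefficient estimation from trajectories.

#' Classify a kinetochore attachment configuration
#'
#' `L1`, `L2`, `R1`, `R2` count microtubules from the left/right pole
#' attached to sister 1/2. Merotelic: one sister holds microtubules from
#' both poles. Amphitelic: each sister is connected, to opposite poles.
#' Syntelic: both sisters to a single pole. Monotelic: exactly one sister
#' attached (to one pole). Otherwise unattached.
#'
#' @param L1,L2,R1,R2 non-negative attachment counts.
#' @return one of `"amphitelic"`, `"merotelic"`, `"monotelic"`,
#'   `"syntelic"`, `"unattached"`.
#' @examples
#' classify_attachment(5, 0, 0, 7)  # amphitelic
#' classify_attachment(3, 0, 1, 0)  # merotelic
#' @export
classify_attachment <- function(L1, L2, R1, R2) {
  if (any(c(L1, L2, R1, R2) < 0)) stop("attachment counts must be >= 0")
  if ((L1 > 0 && R1 > 0) || (L2 > 0 && R2 > 0)) return("merotelic")
  if ((L1 > 0 && R2 > 0) || (R1 > 0 && L2 > 0)) return("amphitelic")
  s1 <- L1 > 0 || R1 > 0
  s2 <- L2 > 0 || R2 > 0
  if (s1 && s2) return("syntelic")
  if (s1 || s2) return("monotelic")
  "unattached"
}

#' Attachment counts (L1, L2, R1, R2) of a spindle cell
#' @param cell a `spindle_cell`.
#' @return integer vector `c(L1, L2, R1, R2)`: microtubules from the
#'   left/right pole attached to sister 1/2.
#' @export
attachment_counts <- function(cell) {
  att <- cell$mts$attached_site > 0
  out <- c(L1 = 0L, L2 = 0L, R1 = 0L, R2 = 0L)
  if (any(att)) {
    sis <- cell$kt$sites$sister[cell$mts$attached_site[att]]
    pole <- cell$mts$pole[att]
    tab <- table(factor(paste0(pole, sis),
                        levels = c("L1", "L2", "R1", "R2")))
    out[] <- as.integer(tab)
  }
  out
}

#' Spindle geometry metrics for one frame
#'
#' @param frame a trajectory frame (or a `spindle_cell`).
#' @param cell the `spindle_cell` (for bead indices) when `frame` is a
#'   frame.
#' @return list: `angle_deg` (KT-KT axis vs pole-pole axis, folded to
#'   0..90), `kt_distance` (nm), `equator_distance` (nm, |x| of the KT
#'   midpoint), `counts` (L1, L2, R1, R2), `n_phos` (mean phosphostate).
#' @export
spindle_metrics <- function(frame, cell = NULL) {
  if (inherits(frame, "spindle_cell")) {
    cell <- frame
    pos <- cell$state$pos
    p_sites <- cell$kt$sites$p
    counts <- attachment_counts(cell)
  } else {
    pos <- frame$pos
    p_sites <- frame$p_sites
    tmp <- cell
    tmp$mts$attached_site <- frame$attached
    counts <- attachment_counts(tmp)
  }
  i_kt <- cell$kt$i_kt
  if (length(i_kt) != 2) stop("cell does not hold a kinetochore pair")
  kk <- pos[i_kt[2], ] - pos[i_kt[1], ]
  kt_dist <- sqrt(sum(kk^2))
  pole_axis <- cell$cs_pos[2, ] - cell$cs_pos[1, ]
  cosang <- abs(sum(kk * pole_axis)) / (kt_dist * sqrt(sum(pole_axis^2)))
  angle <- acos(pmin(1, cosang)) * 180 / pi
  mid <- (pos[i_kt[1], ] + pos[i_kt[2], ]) / 2
  list(angle_deg = angle,
       kt_distance = kt_dist,
       equator_distance = abs(mid[1]),
       counts = counts,
       n_phos = mean(p_sites))
}

#' Estimate diffusion coefficients from a sampled trajectory
#'
#' Least-squares slope of MSD(lag)/2 against lag time over the first decade
#' of lags (lags up to 10% of the trajectory length), per column.
#'
#' @param x numeric vector or matrix: uniformly sampled positions (nm or
#'   um) or unwrapped angles (rad), one column per coordinate.
#' @param dt sampling interval, s.
#' @param max_lag_frac largest lag as a fraction of the series length.
#' @return named vector of diffusion coefficients, units of `x`^2 per s.
#' @export
estimate_diffusion <- function(x, dt, max_lag_frac = 0.1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 100) stop("trajectory too short for MSD estimation")
  max_lag <- max(10L, floor(n * max_lag_frac))
  lags <- unique(pmax(1L, round(seq(1, min(max_lag, n - 1),
                                    length.out = 50))))
  apply(x, 2, function(col) {
    msd <- vapply(lags, function(L) mean((col[(1 + L):n] - col[1:(n - L)])^2),
                  numeric(1))
    fit <- lm(msd / 2 ~ I(lags * dt))
    unname(coef(fit)[2])
  })
}

#' Aggregate end-state attachment classes over runs
#'
#' @param trajectories list of `spindle_trajectory` objects.
#' @return table of class probabilities.
#' @export
attachment_class_table <- function(trajectories) {
  cls <- vapply(trajectories, function(tr) {
    co <- attachment_counts(tr$cell)
    classify_attachment(co["L1"], co["L2"], co["R1"], co["R2"])
  }, character(1))
  tab <- table(factor(cls, levels = c("amphitelic", "merotelic", "monotelic",
                                      "syntelic", "unattached")))
  tab / length(cls)
}
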