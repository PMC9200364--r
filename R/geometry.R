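# Construction of the mechanical cell: centrosome asters, kinetochore pair
# with corona grid and optional chromosome arms, initial placement.

#' Merge two mechanical-state fragments
#'
#' Bead indices of the second fragment are offset; the offset is returned in
#' `attr(result, "offset")`.
#'
#' @param s1,s2 `mech_state` objects built with the same parameters.
#' @return the combined `mech_state`.
#' @export
merge_states <- function(s1, s2) {
  off <- n_beads(s1)
  shift <- function(m, cols) {
    if (nrow(m)) m[, cols] <- m[, cols] + off
    m
  }
  s1$pos <- rbind(s1$pos, s2$pos)
  s1$radius <- c(s1$radius, s2$radius)
  s1$gamma <- c(s1$gamma, s2$gamma)
  s1$tag <- c(s1$tag, s2$tag)
  s1$frozen <- c(s1$frozen, s2$frozen)
  s1$ljclass <- c(s1$ljclass, s2$ljclass)
  s1$bonds <- rbind(s1$bonds, shift(s2$bonds, c("i", "j")))
  s1$angles <- rbind(s1$angles, shift(s2$angles, c("i", "j", "k")))
  s1$posres <- rbind(s1$posres, shift(s2$posres, "i"))
  s1$dirres <- rbind(s1$dirres, shift(s2$dirres, c("im", "ib")))
  s1$attach <- rbind(s1$attach, shift(s2$attach, c("i_mt", "i_site")))
  attr(s1, "offset") <- off
  s1
}

# Uniform random unit vectors (n x 3).
runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build a centrosome with its microtubule aster
#'
#' Creates one frozen centrosome bead and `n_MT` three-bead microtubules with
#' minus-ends on the centrosome surface, uniformly random outward directions,
#' growing phase, and initial lengths drawn uniformly on `length_range`.
#' Minus-ends are position-restrained to their anchor point and the first
#' segment is direction-restrained by a stiff angular spring.
#'
#' @param cs_center centrosome center, nm (length-3).
#' @param n_MT number of microtubules.
#' @param params a `spindle_params`.
#' @param length_range initial length range in nm (the nucleation length is
#'   `length_range[1]`, default 3 R_MT).
#' @return list: `state` (a `mech_state` fragment), `mts` (data.frame of
#'   per-MT bookkeeping: bead indices, anchor, direction, length, phase,
#'   interaction-row indices).
#' @export
build_aster <- function(cs_center, n_MT, params = validate_params(),
                        length_range = NULL) {
  params <- validate_params(params)
  if (n_MT < 1) stop("n_MT must be >= 1")
  if (is.null(length_range)) length_range <- c(3 * params$R_MT, 1000)
  st <- mech_state(params)
  st <- add_beads(st, matrix(cs_center, 1, 3), params$R_CS, params$gamma_KT,
                  "CS", frozen = TRUE, ljclass = 0L)
  i_cs <- attr(st, "new_idx")

  dirs <- runif_sphere(n_MT)
  lens <- runif(n_MT, length_range[1], length_range[2])
  anchors <- sweep(dirs * params$R_CS, 2, cs_center, "+")
  K_anchor_r <- params$K_KT_r          # stiff positional anchor
  K_anchor_theta <- params$K_MT_theta  # stiff angular anchor

  mts <- vector("list", n_MT)
  for (m in seq_len(n_MT)) {
    d <- dirs[m, ]; a <- anchors[m, ]; l <- lens[m]
    pos <- rbind(a, a + d * l / 2, a + d * l)
    st <- add_beads(st, pos, params$R_MT, params$gamma_MT,
                    c("MT_minus", "MT_body", "MT_plus"), ljclass = 1L)
    idx <- attr(st, "new_idx")
    b0 <- nrow(st$bonds)
    st <- add_bonds(st, i = c(idx[1], idx[2]), j = c(idx[2], idx[3]),
                    k = params$K_MT_r, r0 = l / 2, group = GROUP_MT)
    a0 <- nrow(st$angles)
    st <- add_angles(st, idx[1], idx[2], idx[3], params$K_MT_theta,
                     theta0 = pi, group = GROUP_MT)
    st$posres <- rbind(st$posres,
                       cbind(i = idx[1], x = a[1], y = a[2], z = a[3],
                             kr = K_anchor_r))
    st$dirres <- rbind(st$dirres,
                       cbind(im = idx[1], ib = idx[2], dx = d[1], dy = d[2],
                             dz = d[3], ktheta = K_anchor_theta))
    mts[[m]] <- data.frame(
      id = m, i_minus = idx[1], i_body = idx[2], i_plus = idx[3],
      ax = a[1], ay = a[2], az = a[3], dx = d[1], dy = d[2], dz = d[3],
      length = l, phase = "growing", bond1 = b0 + 1, bond2 = b0 + 2,
      angle_row = a0 + 1, attached_site = 0L, i_cs = i_cs,
      stringsAsFactors = FALSE)
  }
  list(state = st, mts = do.call(rbind, mts))
}

# Corona patch bead positions for one sister: cylinder of curvature
# (1 - chi)/R_CH tangent to the kinetochore sphere at its outward pole,
# extent L x L with L = sqrt(A_KT) so the patch area equals A_KT for every
# chi (chi = 0 hugs the sphere radius, chi = 1 is flat).
corona_patch <- function(kt_center, outward, n_beads, params) {
  L <- sqrt(params$A_KT) * 1000  # um^2 -> nm
  n1 <- max(1L, round(sqrt(n_beads)))
  n2 <- ceiling(n_beads / n1)
  u <- (seq_len(n1) - 0.5) / n1 * L - L / 2   # along the cylinder axis
  v <- (seq_len(n2) - 0.5) / n2 * L - L / 2   # arc length across
  g <- expand.grid(u = u, v = v)[seq_len(n_beads), ]
  # local frame
  nvec <- outward / sqrt(sum(outward^2))
  e1 <- if (abs(nvec[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * nvec) * nvec
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nvec[2] * e1[3] - nvec[3] * e1[2],
          nvec[3] * e1[1] - nvec[1] * e1[3],
          nvec[1] * e1[2] - nvec[2] * e1[1])
  kappa <- (1 - params$chi) / params$R_CH
  if (kappa > 0) {
    rho <- 1 / kappa
    phi <- g$v / rho
    height <- params$R_CH - rho * (1 - cos(phi))
    lateral <- rho * sin(phi)
  } else {
    height <- rep(params$R_CH, nrow(g))
    lateral <- g$v
  }
  pts <- outer(height, nvec) + outer(lateral, e2) + outer(g$u, e1)
  sweep(pts, 2, kt_center, "+")
}

#' Build a sister-kinetochore pair with corona grids and optional arms
#'
#' Two kinetochore beads `d_KT` apart along z (sister 1 at -z), each carrying
#' a curved-rectangle corona patch of area `A_KT` at curvature parameter
#' `chi`, facing outward along the KT-KT axis. Corona beads are
#' pairwise-bonded within `R_Ndc_bond` and every corona bead is bonded to its
#' KT center; each corona bead is one Ndc80 site. With `with_arms`, each
#' sister chromatid gains 8 arm beads (4 per side, 725-nm spacing) with
#' bending springs and inter-sister cohesin springs. The flexible-KT variant
#' softens the corona-to-KT springs 40-fold and shrinks the grid cutoff to
#' 50 nm.
#'
#' @param params a `spindle_params` (its `chi` is used).
#' @param flexible logical, soft-kinetochore variant.
#' @param with_arms logical, add chromosome arms.
#' @param n_corona corona beads (= Ndc80 sites) per sister; default from
#'   `params`.
#' @return list: `state` fragment (KT pair centered at the origin, axis z),
#'   `kt` bookkeeping (bead indices, `sites` data frame with phosphostate and
#'   occupancy).
#' @export
build_kinetochore_pair <- function(params = validate_params(),
                                   flexible = FALSE, with_arms = FALSE,
                                   n_corona = NULL) {
  params <- validate_params(params)
  if (is.null(n_corona)) n_corona <- params$n_corona_beads
  K_cor_kt <- if (flexible) params$K_KT_r_flex else params$K_KT_r
  bond_cut <- if (flexible) params$R_Ndc_bond_flex else params$R_Ndc_bond

  st <- mech_state(params)
  kt_pos <- rbind(c(0, 0, -params$d_KT / 2), c(0, 0, params$d_KT / 2))
  st <- add_beads(st, kt_pos, params$R_CH, params$gamma_KT, "KT_center",
                  ljclass = 2L)
  i_kt <- attr(st, "new_idx")
  st <- add_bonds(st, i_kt[1], i_kt[2], params$K_KT_r, params$d_KT, GROUP_KT)

  gamma_cor <- friction_for(params$R_Ndc, "corona", params)
  sites <- NULL
  for (s in 1:2) {
    outward <- c(0, 0, if (s == 1) -1 else 1)
    pts <- corona_patch(kt_pos[s, ], outward, n_corona, params)
    st <- add_beads(st, pts, params$R_Ndc, gamma_cor, "corona", ljclass = 0L)
    idx <- attr(st, "new_idx")
    # grid bonds within the cutoff
    dmat <- as.matrix(stats::dist(pts))
    pair <- which(upper.tri(dmat) & dmat <= bond_cut, arr.ind = TRUE)
    if (nrow(pair)) {
      st <- add_bonds(st, idx[pair[, 1]], idx[pair[, 2]], params$K_KT_r,
                      dmat[pair], GROUP_KT)
    }
    # corona-to-KT-center springs keep the patch shape
    d_ck <- sqrt(rowSums(sweep(pts, 2, kt_pos[s, ])^2))
    st <- add_bonds(st, idx, i_kt[s], K_cor_kt, d_ck, GROUP_KT)
    sites <- rbind(sites, data.frame(bead = idx, sister = s, p = 0L,
                                     occupied = FALSE))
  }

  arm_idx <- integer(0)
  if (with_arms) {
    arm_of <- list()
    for (s in 1:2) {
      beads <- NULL
      for (side in c(-1, 1)) {
        off <- outer((1:4) * params$d_KT * side, c(1, 0, 0))
        pts <- sweep(off, 2, kt_pos[s, ], "+")
        st <- add_beads(st, pts, params$R_CH, params$gamma_KT, "CH_arm",
                        ljclass = 2L)
        idx <- attr(st, "new_idx")
        chain <- c(i_kt[s], idx)
        st <- add_bonds(st, chain[-5], chain[-1], params$K_CH_r,
                        params$d_KT, GROUP_CH)
        st <- add_angles(st, chain[1:3], chain[2:4], chain[3:5],
                         params$K_CH_theta, pi, GROUP_CH)
        beads <- c(beads, idx)
      }
      # straight-through angle at the centromere
      st <- add_angles(st, beads[1], i_kt[s], beads[5],
                       params$K_CH_theta, pi, GROUP_CH)
      arm_of[[s]] <- beads
    }
    # cohesin springs between corresponding arm beads of the two sisters
    st <- add_bonds(st, arm_of[[1]], arm_of[[2]], params$K_coh_r,
                    params$d_KT, GROUP_CH)
    arm_idx <- c(arm_of[[1]], arm_of[[2]])
  }

  list(state = st,
       kt = list(i_kt = i_kt, sites = sites, arm_beads = arm_idx,
                 flexible = flexible, chi = params$chi,
                 with_arms = with_arms))
}

# Rotate positions (n x 3) about the origin by matrix R.
rotate_pos <- function(pos, R) pos %*% t(R)

#' Place the kinetochore pair in its initial configuration
#'
#' The kinetochore fragment (built about the origin with its axis along z) is
#' oriented and then displaced by `offset` along -z, i.e. perpendicular to
#' the spindle (x) axis, reproducing the unbiased starting geometry: spindle
#' angle 90 degrees, kinetochore midpoint on the equatorial plane x = 0.
#'
#' @param kt_fragment result of [build_kinetochore_pair()].
#' @param offset displacement in nm (default 1500).
#' @param orientation `"perpendicular"` (KT axis along z) or `"parallel"`
#'   (KT axis along the spindle axis x).
#' @param ellipse optional semi-axes (nm) to check that nothing crosses the
#'   membrane.
#' @return the fragment with transformed coordinates.
#' @export
place_initial_configuration <- function(kt_fragment, offset = 1500,
                                        orientation = c("perpendicular",
                                                        "parallel"),
                                        ellipse = NULL) {
  orientation <- match.arg(orientation)
  st <- kt_fragment$state
  if (orientation == "parallel") {
    Rz2x <- rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0))  # z -> x about y
    st$pos <- rotate_pos(st$pos, Rz2x)
    st$dirres[, c("dx", "dy", "dz")] <-
      st$dirres[, c("dx", "dy", "dz"), drop = FALSE] %*% t(Rz2x)
  }
  st$pos <- sweep(st$pos, 2, c(0, 0, -offset), "+")
  if (!is.null(ellipse)) {
    zeta <- (st$pos[, 1] / ellipse[1])^2 + (st$pos[, 2] / ellipse[2])^2 +
      (st$pos[, 3] / ellipse[3])^2
    if (any(zeta >= 1)) stop("placed component overlaps the membrane")
  }
  kt_fragment$state <- st
  kt_fragment
}
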