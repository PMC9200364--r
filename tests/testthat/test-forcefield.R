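test_that("single-term energies match hand calculations", {
  p <- validate_params()
  # MT segment stretched 1 nm: U = K/2 = 8.35 pN nm
  st <- two_bead_spring(101, p$K_MT_r, 100, group = 1)
  expect_equal(energy_bonded(st)[["U_MT"]], 0.5 * 16.7)
  # centromere spring stretched 10 nm
  st <- two_bead_spring(735, p$K_KT_r, 725, group = 2)
  expect_equal(energy_bonded(st)[["U_KT"]], 0.5 * 3.3e3 * 100)
  # everything at rest -> zero
  st <- two_bead_spring(100, 50, 100)
  expect_equal(unname(energy_bonded(st)), c(0, 0, 0))
})

test_that("attachment springs follow the Ndc80 rest length", {
  p <- validate_params()
  st <- mech_state(p)
  st <- add_beads(st, rbind(c(0, 0, 0), c(75, 0, 0)), 4, 1e5, "corona")
  st$attach <- cbind(i_mt = 1, i_site = 2, k = p$K_Ndc_r, l0 = p$l_Ndc)
  expect_equal(energy_attachment(st), 0.5 * 310 * 100)  # 1.55e4
  st$pos[2, 1] <- 65
  expect_equal(energy_attachment(st), 0)
  st$attach <- st$attach[0, , drop = FALSE]
  expect_equal(energy_attachment(st), 0)
})

test_that("excluded-volume repulsion has the printed scale and cutoff", {
  p <- validate_params()
  mk <- function(sep) {
    st <- mech_state(p)
    st <- add_beads(st, c(0, 0, 0), 12, 1e5, "MT_body", ljclass = 1L)
    st <- add_beads(st, c(sep, 0, 0), 362.5, 1e5, "KT_center", ljclass = 2L)
    st
  }
  sigma <- 12 + 362.5
  expect_rel(energy_repulsive(mk(sigma)), p$eps_LJ, 1e-9)
  expect_rel(energy_repulsive(mk(2 * sigma)), p$eps_LJ / 4096, 1e-9)
  expect_equal(energy_repulsive(mk(3 * sigma)), 0)        # at the cutoff
  expect_error(energy_repulsive(mk(1e-12)), "overlap")
})

test_that("membrane term activates only outside the ellipsoid", {
  p <- validate_params()
  mk <- function(pos) {
    st <- mech_state(p)
    st <- add_beads(st, pos, 10, 1e5, "CH_arm")
    st$ellipse <- c(4000, 3000, 3000)
    st
  }
  expect_equal(energy_membrane(mk(c(0, 0, 0))), 0)
  expect_equal(energy_membrane(mk(c(4000, 0, 0))), 0)
  expect_rel(energy_membrane(mk(c(4010, 0, 0))), 0.5 * 3.3e3 * 100, 1e-6)
  # off-axis exterior point: distance via the projected-Newton solve
  u <- energy_membrane(mk(c(2900, 2100, 50)))
  expect_gt(u, 0)
})

test_that("forces equal the negative numerical gradient", {
  st <- composite_state(seed = 1)
  f <- forces(st)
  h <- 1e-3
  idx <- sample(which(!st$frozen), 8)
  for (i in idx) {
    for (k in 1:3) {
      s1 <- st; s1$pos[i, k] <- s1$pos[i, k] + h
      s2 <- st; s2$pos[i, k] <- s2$pos[i, k] - h
      g <- -(energy_total(s1)$total - energy_total(s2)$total) / (2 * h)
      expect_lt(abs(g - f[i, k]) / max(abs(f)), 1e-6)
    }
  }
})

test_that("internal interactions exert no net force or torque", {
  # isolated cluster: no membrane, no anchors
  st <- composite_state(seed = 3)
  st$ellipse <- NULL
  st$posres <- st$posres[0, , drop = FALSE]
  st$dirres <- st$dirres[0, , drop = FALSE]
  st$frozen[] <- FALSE
  f <- forces(st)
  scale <- max(abs(f))
  expect_lt(max(abs(colSums(f))) / scale, 1e-9)
  tq <- colSums(cbind(
    st$pos[, 2] * f[, 3] - st$pos[, 3] * f[, 2],
    st$pos[, 3] * f[, 1] - st$pos[, 1] * f[, 3],
    st$pos[, 1] * f[, 2] - st$pos[, 2] * f[, 1]))
  expect_lt(max(abs(tq)) / (scale * max(abs(st$pos))), 1e-9)
})

test_that("energy is invariant under rigid motions without membrane/anchors", {
  st <- composite_state(seed = 4)
  st$ellipse <- NULL
  st$posres <- st$posres[0, , drop = FALSE]
  st$dirres <- st$dirres[0, , drop = FALSE]
  e0 <- energy_total(st)$total
  st2 <- st; st2$pos <- sweep(st$pos, 2, c(123, -77, 301), "+")
  expect_rel(energy_total(st2)$total, e0, 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  st3 <- st; st3$pos <- st$pos %*% t(R)
  expect_rel(energy_total(st3)$total, e0, 1e-9)
})
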