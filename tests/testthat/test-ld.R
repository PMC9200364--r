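test_that("frictions use the quoted values with a Stokes fallback", {
  p <- validate_params()
  expect_equal(friction_for(362.5, "KT_center", p), 6.8e6)
  expect_equal(friction_for(12, "MT_body", p), 4.5e5)
  g <- friction_for(2.9, "", p)
  expect_rel(p$kT / (g * 1e-12), p$D_aurora, 1e-6)  # Stokes-Einstein
  expect_error(friction_for(-1, ""), "radius")
})

test_that("a deterministic step moves F dt / gamma", {
  st <- mech_state()
  st <- add_beads(st, c(0, 0, 0), 362.5, 6.8e6, "KT_center")
  extF <- matrix(c(5, 0, 0), 1, 3)
  st2 <- ld_step(st, ld_settings(dt = 50), extF = extF)
  expect_rel(st2$pos[1, 1], 5 * 50 / 6.8e6, 1e-12)  # 3.68e-5 nm
  # zero force, T = 0: identity
  st3 <- ld_step(st, ld_settings(dt = 50))
  expect_identical(st3$pos, st$pos)
})

test_that("thermal noise has the Ermak-McCammon variance", {
  set.seed(10)
  n <- 3000
  st <- mech_state()
  st <- add_beads(st, matrix(0, n, 3), 362.5, 6.8e6, "KT_center")
  tr <- ld_trajectory(st, ld_settings(dt = 50, noise_on = TRUE), n_steps = 10,
                      sample_every = 10, sample_beads = seq_len(n))
  disp <- as.numeric(tr$samples)
  expect_rel(sd(disp), sqrt(10 * 2 * 4.142 * 50 / 6.8e6), 0.02)
})

test_that("free-bead MSD grows as 2 (kT/gamma) t", {
  set.seed(11)
  n <- 30000
  st <- mech_state()
  st <- add_beads(st, matrix(0, n, 3), 12, 4.5e5, "MT_body")
  nst <- 100
  tr <- ld_trajectory(st, ld_settings(dt = 50, noise_on = TRUE),
                      n_steps = nst, sample_every = nst,
                      sample_beads = seq_len(n))
  expect_rel(var(as.numeric(tr$samples)),
             2 * (4.142 / 4.5e5) * nst * 50, 0.02)
})

test_that("tethered bead satisfies fluctuation-dissipation", {
  set.seed(12)
  n <- 1500; k <- 1; gamma <- 4.5e5
  st <- mech_state()
  st <- add_beads(st, matrix(0, n, 3), 12, gamma, "MT_body")
  st$posres <- cbind(i = seq_len(n), x = 0, y = 0, z = 0, kr = k)
  tau_steps <- round(gamma / k / 50)
  tr <- ld_trajectory(st, ld_settings(dt = 50, noise_on = TRUE),
                      n_steps = 12 * tau_steps, sample_every = tau_steps,
                      sample_beads = seq_len(n))
  stat <- as.numeric(tr$samples[-(1:4), ])  # discard the transient
  expect_rel(var(stat), 4.142 / k, 0.03)
})

test_that("relaxation descends to mechanical equilibrium", {
  st <- two_bead_spring(140, 10, 100)
  rx <- relax_to_equilibrium(st, ld_settings(dt = 50))
  expect_true(rx$converged)
  expect_rel(unname(dist(rx$state$pos)[1]), 100, 0.001)
  expect_lt(rx$max_force, 0.1)
  # already-relaxed state returns without stepping
  rx2 <- relax_to_equilibrium(rx$state, ld_settings(dt = 50))
  expect_equal(rx2$n_steps, 0)
  # energy decreases monotonically along the descent
  st <- composite_state(seed = 6, jitter = 10)
  e <- energy_total(st)$total
  s <- ld_settings(dt = 50, max_steps = 1)
  for (q in 1:25) {
    rx <- relax_to_equilibrium(st, s)
    st <- rx$state
    e2 <- energy_total(st)$total
    expect_lte(e2, e + 1e-9 * abs(e))
    e <- e2
  }
})

test_that("unstable timesteps are refused for dynamics", {
  st <- two_bead_spring(100, 3.3e3, 100, gamma = 7.5e4)
  expect_error(ld_step(st, ld_settings(dt = 50)), "stability")
})
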