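test_that("three-bead drift matches the analytic spring solution", {
  set.seed(1)
  b5 <- three_bead_benchmark(force = 5)
  expect_true(b5$pass)
  expect_lt(max(b5$rel_errors), 0.015)
  b0 <- three_bead_benchmark(force = 0, n_steps = 2000)
  expect_lt(max(abs(b0$values)), 1e-9)
  # the drift solution is linear in the load
  b50 <- three_bead_benchmark(force = 50)
  expect_rel(b50$oracles["dx13"], 10 * b5$oracles["dx13"], 1e-12)
})

test_that("Brownian oscillator ensemble follows the exact response curve", {
  set.seed(2)
  ob <- oscillator_ensemble_benchmark(N = 2000)
  expect_lt(max(ob$rel_errors), 0.004)
  # asymptote is the spring equilibrium F/k
  expect_rel(ob$oracles[length(ob$oracles)], 50 * (1 - exp(-5)), 1e-9)
})

test_that("cylinder diffusion closed forms give the kinetochore-pair values", {
  ex <- cylinder_diffusion_exact(1450, 725)
  expect_rel(ex["D_x"], 0.152, 0.01)
  expect_rel(ex["D_theta"], 0.869, 0.01)
  # scaling: D_x ~ ln(L/d)/L
  ex2 <- cylinder_diffusion_exact(2900, 725)
  expect_rel(ex2["D_x"] / ex["D_x"], (log(4) / 2900) / (log(2) / 1450),
             1e-9)
  expect_error(cylinder_diffusion_exact(700, 725), "L > d")
})

test_that("rigid-dimer simulation recovers its input mobilities", {
  set.seed(3)
  db <- rigid_dimer_diffusion_benchmark(duration = 60)
  expect_lt(max(db$rel_errors), 0.10)
})

test_that("kinetic closed forms are correct at landmark points", {
  p <- kinetics_closed_forms("two_step", c(k1 = 1, k2 = 2), c(0, log(2)))
  expect_equal(unname(p[1, ]), c(1, 0, 0))
  expect_rel(p[2, ], c(0.5, 0.25, 0.25), 1e-12)
  r <- kinetics_closed_forms("reversible", c(k1 = 1, k_rev = 3), c(0, 50))
  expect_equal(unname(r[1, ]), c(1, 0))
  expect_rel(r[2, "p_A"], 0.75, 1e-12)
  expect_error(kinetics_closed_forms("two_step", c(k1 = 1, k2 = 1), 1),
               "degenerate")
})

test_that("phosphorylation benchmark responds to the enzyme balance", {
  set.seed(4)
  # no kinase: everything stays dephosphorylated
  r0 <- nphos_benchmark(P_count = 10, AB_count = 0, bio_time = 5,
                        n_runs = 2, burn_in = 1, n_corona = 100)
  expect_equal(r0$mean, 0)
  # kinase without phosphatase: sites saturate at p_max
  r7 <- nphos_benchmark(P_count = 0, AB_count = 100, bio_time = 60,
                        n_runs = 2, burn_in = 40, n_corona = 100)
  expect_gt(r7$mean, 6.5)
})
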