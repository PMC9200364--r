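test_that("mechanics-changing events are identified", {
  expect_true(all(vapply(c("grow", "shorten", "catastrophe", "rescue",
                           "attach", "detach"), detect_mech_change,
                         logical(1))))
  expect_false(detect_mech_change("phospho"))
  expect_false(detect_mech_change("dephospho"))
  expect_false(detect_mech_change(list(name = "diffusion_hop")))
})

test_that("seeded simulations replay bit-exactly", {
  t1 <- run_simulation(tiny_config(seed = 123))
  t2 <- run_simulation(tiny_config(seed = 123))
  expect_identical(t1$stats, t2$stats)
  expect_identical(t1$cell$state$pos, t2$cell$state$pos)
  expect_identical(vapply(t1$frames, `[[`, numeric(1), "time"),
                   vapply(t2$frames, `[[`, numeric(1), "time"))
})

test_that("trajectories emit time-ordered frames with consistent state", {
  tr <- run_simulation(tiny_config(seed = 42))
  # fencepost: 0..5 s at 1-s interval
  expect_equal(length(tr$frames), 6)
  times <- vapply(tr$frames, `[[`, numeric(1), "time")
  expect_true(all(diff(times) > 0))
  for (fr in tr$frames) {
    # attachment records consistent with the bond list
    expect_equal(sum(fr$attached > 0), nrow(fr$attach))
    # phosphostates within range
    expect_true(all(fr$p_sites >= 0 & fr$p_sites <= 7))
    # lattice totals preserved (phosphatase never created or destroyed)
    expect_equal(unname(fr$lattice_totals["PH"]),
                 unname(tr$frames[[1]]$lattice_totals["PH"]))
  }
})

test_that("biological time is advanced only by kinetic waiting times", {
  tr <- run_simulation(tiny_config(seed = 9, bio_time = 3))
  expect_equal(tr$cell$t, 3)
  # with no kinetics possible there are no events and time still completes
  cfg <- tiny_config(seed = 10, bio_time = 1)
  cfg$params$n_MT_per_CS <- 1L
  cfg$params$w_cat <- 1e-12
  tr2 <- run_simulation(cfg)
  expect_equal(tr2$cell$t, 1)
})
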