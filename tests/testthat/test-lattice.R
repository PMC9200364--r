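test_that("lattice discretizes the ellipsoid volume", {
  lat <- build_lattice(1000, 1000, 1000, 250)
  # (4/3) pi 4^3 = 268 subcells up to surface discretization
  expect_lt(abs(sum(lat$inside) - 268) / 268, 0.10)
  # origin subcell is a center and inside
  v0 <- subcell_of(lat, c(0, 0, 0))
  expect_true(lat$inside[v0])
  expect_equal(unname(lat$centers[v0, ]), c(0, 0, 0))
  expect_error(build_lattice(100, 1000, 1000, 250), "exceed")
})

test_that("default cell volume is about 850 um^3", {
  lat <- build_lattice(8000, 5040, 5040, 250)
  vol <- sum(lat$inside) * 0.25^3
  expect_lt(abs(vol - 850) / 850, 0.02)
})

test_that("molecule placement respects the mask and conserves totals", {
  set.seed(1)
  lat <- build_lattice(900, 900, 900, 250)
  lat <- add_species(lat, "X", D = 1e7)
  lat <- place_molecules(lat, "X", 500, rep(1, nrow(lat$centers)))
  expect_equal(species_total(lat, "X"), 500)
  expect_true(all(lat$counts[1, !lat$inside] == 0))
  # diffusion epochs conserve the total and stay inside the mask
  net <- reaction_network("X", D = c(X = 1e7))
  set.seed(2)
  lat2 <- mpd_diffusion_step(lat, net, tau = 5e-4, n_epochs = 200)
  expect_equal(species_total(lat2, "X"), 500)
  expect_true(all(lat2$counts[1, !lat2$inside] == 0))
})

test_that("subcell lookup is the inverse of the center grid", {
  lat <- build_lattice(1200, 900, 700, 250)
  idx <- sample(nrow(lat$centers), 50)
  expect_equal(subcell_of(lat, lat$centers[idx, ]), idx)
})
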