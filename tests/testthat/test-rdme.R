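one_subcell_lattice <- function(species, counts, D = NULL) {
  lat <- build_lattice(300, 300, 300, 250)
  for (s in species) lat <- add_species(lat, s, if (is.null(D)) 0 else D[s])
  v <- subcell_of(lat, c(0, 0, 0))
  lat$counts[, v] <- as.integer(counts)
  lat
}

test_that("propensities follow the mass-action rules", {
  net <- reaction_network(
    c("A", "B", "C"),
    reactions = list(
      list(name = "decay", c = 2.5e-3, reactants = c(A = 1),
           products = c(B = 1)),
      list(name = "bi", c = 1.5, reactants = c(A = 1, B = 1),
           products = c(C = 1, B = 1))))
  expect_equal(reaction_propensity(net, "decay", c(A = 1, B = 0, C = 0)),
               2.5e-3)
  expect_equal(reaction_propensity(net, "bi", c(A = 2, B = 3, C = 0)),
               1.5 * 2 * 3)
  expect_equal(reaction_propensity(net, "bi", c(A = 0, B = 5, C = 0)), 0)
  expect_error(reaction_propensity(net, "nope", c(1, 1, 1)), "unknown")
  expect_error(reaction_network("A", reactions = list(
    list(name = "x", c = 1, reactants = c(Z = 1), products = c(A = 1)))),
    "undefined")
})

test_that("NSM sampling reproduces two-step irreversible kinetics", {
  set.seed(21)
  n0 <- 1500
  lat <- one_subcell_lattice(c("A", "B", "C"), c(n0, 0, 0))
  net <- reaction_network(c("A", "B", "C"), reactions = list(
    list(name = "s1", c = 1, reactants = c(A = 1), products = c(B = 1)),
    list(name = "s2", c = 2, reactants = c(B = 1), products = c(C = 1))))
  tt <- c(0.25, log(2), 1.5)
  out <- run_rdme(lat, net, bio_time = 2, record_times = tt)
  sim <- t(out$records) / n0
  ex <- kinetics_closed_forms("two_step", c(k1 = 1, k2 = 2), tt)
  expect_lt(max(abs(sim - ex)), 3 / sqrt(n0))
  # molecule number is conserved by isomerization chains
  expect_equal(sum(out$lattice$counts), n0)
})

test_that("NSM sampling reaches the reversible equilibrium", {
  set.seed(22)
  n0 <- 1500
  lat <- one_subcell_lattice(c("A", "B"), c(n0, 0))
  net <- reaction_network(c("A", "B"), reactions = list(
    list(name = "f", c = 1, reactants = c(A = 1), products = c(B = 1)),
    list(name = "b", c = 3, reactants = c(B = 1), products = c(A = 1))))
  out <- run_rdme(lat, net, bio_time = 6, record_times = c(4, 5, 6))
  pA <- mean(out$records["A", ]) / n0
  expect_lt(abs(pA - 0.75), 3 / sqrt(n0))
})

test_that("seeded RDME runs replay bit-exactly", {
  lat <- one_subcell_lattice(c("A", "B"), c(200, 0))
  net <- reaction_network(c("A", "B"), reactions = list(
    list(name = "f", c = 1, reactants = c(A = 1), products = c(B = 1))))
  set.seed(5); o1 <- run_rdme(lat, net, bio_time = 2)
  set.seed(5); o2 <- run_rdme(lat, net, bio_time = 2)
  expect_identical(o1$events, o2$events)
  expect_identical(o1$lattice$counts, o2$lattice$counts)
})

test_that("an empty network just advances time", {
  lat <- one_subcell_lattice("A", 100)
  net <- reaction_network("A")
  out <- run_rdme(lat, net, bio_time = 1)
  expect_equal(out$n_events, 0L)
  expect_equal(species_total(out$lattice, "A"), 100)
})

test_that("MPD hopping obeys the stability bound and free-diffusion law", {
  net <- reaction_network("A", D = c(A = 7.3e7))
  lat <- one_subcell_lattice("A", 50, D = c(A = 7.3e7))
  expect_error(mpd_diffusion_step(lat, net, tau = 4.3e-4), "6 D tau")
  # zero-D species: lattice unchanged
  net0 <- reaction_network("A")
  expect_identical(mpd_diffusion_step(lat, net0, tau = 1e-4)$counts,
                   lat$counts)
  # displacement variance ~ 2 D t (unbounded lattice sampler)
  set.seed(30)
  rep <- gaussian_spread_benchmark(n_molecules = 1e4, times = c(0.5, 1))
  expect_lt(max(rep$rel_errors), 0.03)
})

test_that("timescale separation violations are flagged", {
  lat <- one_subcell_lattice(c("A", "B"), c(10, 0), D = c(A = 7.3e7, B = 0))
  net <- reaction_network(c("A", "B"), D = c(A = 7.3e7), reactions = list(
    list(name = "fast", c = 1e6, reactants = c(A = 1), products = c(B = 1))))
  expect_warning(run_rdme(lat, net, bio_time = 1e-5), "diffusion epoch")
})

test_that("hooks fire on flagged reaction events", {
  set.seed(33)
  lat <- one_subcell_lattice(c("A", "B"), c(50, 0))
  net <- reaction_network(c("A", "B"), reactions = list(
    list(name = "f", c = 1, reactants = c(A = 1), products = c(B = 1))))
  seen <- 0L
  out <- run_rdme(lat, net, bio_time = 5,
                  hooks = function(ev, t, lattice) seen <<- seen + 1L,
                  mech_events = "f")
  expect_equal(seen, out$n_events)
  set.seed(33)
  out2 <- run_rdme(lat, net, bio_time = 5, mech_events = character(0))
  expect_equal(out2$n_events, out$n_events)  # hooks do not perturb sampling
})
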