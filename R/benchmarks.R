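# Verification benchmark suite: small systems with closed-form oracles that
# exercise the Langevin integrator, the lattice diffusion sampler, and the
# kinetic sampler.

bench_report <- function(name, values, oracles, tol) {
  err <- abs(values - oracles) / abs(oracles)
  structure(list(name = name, values = values, oracles = oracles,
                 rel_errors = err, tol = tol,
                 pass = all(err[is.finite(err)] < tol)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark '", x$name, "': ", if (x$pass) "PASS" else "FAIL",
      " (max rel err ", signif(max(x$rel_errors, na.rm = TRUE), 3),
      " vs tol ", x$tol, ")\n", sep = "")
  invisible(x)
}

#' Three-bead chain under a constant load (T = 0)
#'
#' Three beads joined by two harmonic springs, constant force F on bead 3
#' along the chain. In steady drift every bead moves at F/(3 gamma) and the
#' asymptotic relative displacements are Delta x13 = F (1/(3 k1) + 2/(3 k2))
#' and Delta x23 = 2 F/(3 k2); the simulation is compared against this
#' closed-form solution of the same spring network.
#'
#' @param force load on bead 3, pN.
#' @param dt timestep, ps.
#' @param n_steps integration steps.
#' @param k1,k2 spring constants, pN/nm.
#' @param gamma per-bead friction, pN ps/nm.
#' @param rest rest length, nm.
#' @return a `benchmark_report` with `dx13`, `dx23` vs exact.
#' @export
three_bead_benchmark <- function(force = 5, dt = 50, n_steps = 20000,
                                 k1 = 16.7, k2 = 16.7, gamma = 4.5e5,
                                 rest = 500) {
  st <- mech_state()
  st <- add_beads(st, rbind(c(0, 0, 0), c(rest, 0, 0), c(2 * rest, 0, 0)),
                  radius = 12, gamma = gamma, tag = "MT_body")
  st <- add_bonds(st, c(1, 2), c(2, 3), c(k1, k2), rest, GROUP_MT)
  extF <- matrix(0, 3, 3); extF[3, 1] <- force
  tr <- ld_trajectory(st, ld_settings(dt = dt, noise_on = FALSE), n_steps,
                      sample_every = n_steps, sample_beads = 1:3,
                      extF = extF)
  xs <- tr$samples[1, c(1, 4, 7)]
  dx13 <- (xs[3] - xs[1]) - 2 * rest
  dx23 <- (xs[3] - xs[2]) - rest
  exact13 <- force * (1 / (3 * k1) + 2 / (3 * k2))
  exact23 <- 2 * force / (3 * k2)
  bench_report("three_bead", c(dx13 = dx13, dx23 = dx23),
               c(dx13 = exact13, dx23 = exact23), tol = 0.015)
}

#' Ensemble of Brownian oscillators under a step force
#'
#' N independent thermal beads, each tethered by a spring k, loaded by a
#' constant force F at t = 0. The exact mean displacement is
#' (F/k)(1 - exp(-k t / gamma)); the report carries the maximum relative
#' error over the requested times at or beyond the relaxation time gamma/k.
#'
#' @param N ensemble size.
#' @param k spring constant, pN/nm.
#' @param gamma friction, pN ps/nm.
#' @param force load, pN.
#' @param times in units of the relaxation time gamma/k.
#' @param dt timestep, ps.
#' @param temperature kelvin.
#' @return a `benchmark_report`.
#' @export
oscillator_ensemble_benchmark <- function(N = 100, k = 1, gamma = 4.5e5,
                                          force = 50, times = c(1, 2, 3, 5),
                                          dt = 50, temperature = 300) {
  st <- mech_state()
  st <- add_beads(st, matrix(0, N, 3), radius = 12, gamma = gamma,
                  tag = "MT_body")
  st$posres <- cbind(i = seq_len(N), x = 0, y = 0, z = 0, kr = k)
  extF <- cbind(rep(force, N), 0, 0)
  tau <- gamma / k                       # ps
  steps_per_tau <- round(tau / dt)
  n_steps <- max(times) * steps_per_tau
  tr <- ld_trajectory(st, ld_settings(dt = dt, temperature = temperature,
                                      noise_on = TRUE),
                      n_steps, sample_every = steps_per_tau,
                      sample_beads = seq_len(N), extF = extF)
  xcols <- seq(1, 3 * N, by = 3)
  t_rec <- seq_len(nrow(tr$samples)) * steps_per_tau * tr$dt / tau  # in tau
  sel <- vapply(times, function(tt) which.min(abs(t_rec - tt)), integer(1))
  sim <- rowMeans(tr$samples[sel, xcols, drop = FALSE])
  exact <- (force / k) * (1 - exp(-t_rec[sel]))
  bench_report("oscillators", setNames(sim, paste0("t", times)),
               setNames(exact, paste0("t", times)), tol = 0.004)
}

#' Closed-form diffusion coefficients of a rigid cylinder
#'
#' D_x = kT ln(L/d) / (4 pi eta L) and
#' D_theta = 3 kT ln(L/d) / (pi eta L^3).
#'
#' @param L cylinder length, nm.
#' @param d cylinder diameter, nm.
#' @param kT_over_eta kT/eta in nm^3/s; defaults to the value implied by the
#'   Aurora diffusion constant (Stokes-Einstein at 2.9 nm).
#' @param params a `spindle_params`.
#' @return c(D_x = um^2/s, D_theta = rad^2/s).
#' @examples
#' cylinder_diffusion_exact(1450, 725)  # ~0.152 um^2/s, ~0.87 rad^2/s
#' @export
cylinder_diffusion_exact <- function(L, d, kT_over_eta = NULL,
                                     params = validate_params()) {
  if (L <= d || d <= 0) stop("need L > d > 0")
  params <- validate_params(params)
  if (is.null(kT_over_eta)) {
    kT_over_eta <- params$kT / (params$eta * 1e-12)  # nm^3/s
  }
  Dx <- kT_over_eta * log(L / d) / (4 * pi * L)      # nm^2/s
  Dth <- kT_over_eta * 3 * log(L / d) / (pi * L^3)   # rad^2/s
  c(D_x = Dx * 1e-6, D_theta = Dth)                  # um^2/s, rad^2/s
}

#' Rigid-dimer (sister-kinetochore pair) diffusion benchmark
#'
#' The dimer is propagated as a rigid body with the cylinder mobilities of
#' [cylinder_diffusion_exact()] assigned directly (one translational, one
#' rotational; per-bead Stokes frictions cannot reproduce the cylinder
#' values, so the benchmark validates the integrator + estimator pair).
#' Translation along x and rotation about one axis are integrated as
#' independent Brownian coordinates and the coefficients re-estimated with
#' [estimate_diffusion()].
#'
#' @param L,d cylinder dimensions, nm.
#' @param n_runs number of independent runs averaged.
#' @param duration run length, s.
#' @param dt sampling interval, s.
#' @param max_lag_frac lag window passed to [estimate_diffusion()].
#' @param params a `spindle_params`.
#' @return a `benchmark_report` with `D_x` (um^2/s) and `D_theta` (rad^2/s).
#' @export
rigid_dimer_diffusion_benchmark <- function(L = 1450, d = 725, n_runs = 4,
                                            duration = 100, dt = 1e-3,
                                            max_lag_frac = 0.002,
                                            params = validate_params()) {
  ex <- cylinder_diffusion_exact(L, d, params = params)
  Dx_nm <- ex["D_x"] * 1e6
  n <- round(duration / dt)
  est <- vapply(seq_len(n_runs), function(run) {
    paths <- brownian_paths_cpp(c(2 * Dx_nm * dt, 2 * ex["D_theta"] * dt),
                                n_samples = n, steps_per_sample = 1L)
    c(estimate_diffusion(paths[, 1], dt, max_lag_frac) * 1e-6,
      estimate_diffusion(paths[, 2], dt, max_lag_frac))
  }, numeric(2))
  sim <- rowMeans(est)
  bench_report("dimer_diffusion",
               c(D_x = sim[1], D_theta = sim[2]),
               c(D_x = unname(ex["D_x"]), D_theta = unname(ex["D_theta"])),
               tol = 0.10)
}

#' Lattice-diffusion spread against the free-diffusion law
#'
#' Releases `n_molecules` in the central subcell of an unbounded lattice and
#' runs the multi-particle diffusion sampler; per-axis displacement variances
#' are compared with 2 D t at each requested time.
#'
#' @param n_molecules molecules released.
#' @param D diffusion constant, nm^2/s.
#' @param times measurement times, s.
#' @param l_SV subcell side, nm.
#' @param tau epoch length, s; default from the 6p = 0.5 stability rule.
#' @return a `benchmark_report`; values/oracles are variances (nm^2) at the
#'   requested times (x axis), with all three axes in `$per_axis`.
#' @export
gaussian_spread_benchmark <- function(n_molecules = 1e4, D = 7.3e7,
                                      times = c(1, 2, 5, 10, 20),
                                      l_SV = 250, tau = NULL) {
  if (is.null(tau)) tau <- 0.5 * l_SV^2 / (6 * D)
  p_hop <- D * tau / l_SV^2
  epochs <- as.integer(round(times / tau))
  vars <- mpd_free_variance_cpp(as.integer(n_molecules), p_hop,
                                epochs, max_cells = 100000L)
  vars_nm2 <- vars * l_SV^2
  exact <- 2 * D * epochs * tau
  rep <- bench_report("gaussian_spread",
                      setNames(vars_nm2[, 1], paste0("t", times)),
                      setNames(exact, paste0("t", times)), tol = 0.03)
  rep$per_axis <- vars_nm2
  rep$times <- epochs * tau
  rep
}

#' Closed-form populations of the kinetic test schemes
#'
#' Two-step irreversible kinetics A -> B -> C (rates k1, k2) or single-step
#' reversible kinetics A <-> B (rates k1, k_rev), from p_A(0) = 1.
#'
#' @param scheme `"two_step"` or `"reversible"`.
#' @param rates named: `k1`, `k2` (two-step) or `k1`, `k_rev`.
#' @param t time(s), s.
#' @return matrix of populations (rows = times).
#' @examples
#' kinetics_closed_forms("two_step", c(k1 = 1, k2 = 2), log(2))
#' @export
kinetics_closed_forms <- function(scheme = c("two_step", "reversible"),
                                  rates, t) {
  scheme <- match.arg(scheme)
  if (scheme == "two_step") {
    k1 <- rates[["k1"]]; k2 <- rates[["k2"]]
    if (k1 == k2) stop("degenerate two-step form (k1 = k2) not supported")
    pA <- exp(-k1 * t)
    pB <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
    cbind(p_A = pA, p_B = pB, p_C = 1 - pA - pB)
  } else {
    k1 <- rates[["k1"]]; km <- rates[["k_rev"]]
    pA <- (km + k1 * exp(-(k1 + km) * t)) / (k1 + km)
    cbind(p_A = pA, p_B = 1 - pA)
  }
}

#' Stationary Ndc80 phosphorylation under the enzyme fields
#'
#' Kinetics + diffusion only (mechanics off): the Ndc80 sites of one
#' kinetochore pair sit in their subcells; Aurora B is the gaussian field
#' about the centromere midpoint, phosphatase is placed as explicit immobile
#' molecules uniformly over the corona neighborhood. The
#' phospho/dephospho network is run by the next-subvolume sampler and the
#' time-averaged mean phosphostate after a burn-in is reported.
#'
#' @param P_count phosphatase molecules.
#' @param AB_count Aurora B molecules.
#' @param bio_time run length, s.
#' @param n_runs independent replicates (fresh enzyme placements).
#' @param burn_in discarded initial interval, s.
#' @param n_corona Ndc80 sites per sister.
#' @param params a `spindle_params`.
#' @return list: `mean` (grand mean N_phos), `sd` (across runs), `runs`.
#' @export
nphos_benchmark <- function(P_count = 10, AB_count = 100, bio_time = 100,
                            n_runs = 8, burn_in = 20, n_corona = NULL,
                            params = validate_params()) {
  params <- validate_params(params)
  params$n_PH <- as.integer(P_count)
  params$n_AB <- as.integer(AB_count)
  ktf <- build_kinetochore_pair(params, n_corona = n_corona)
  kt_centers <- ktf$state$pos[ktf$kt$i_kt, , drop = FALSE]
  site_pos <- ktf$state$pos[ktf$kt$sites$bead, , drop = FALSE]
  # lattice box just covering the corona neighborhood
  ext <- params$d_KT / 2 + params$R_CH + params$ab_spread + params$l_SV
  c_up <- convert_bimolecular_rate(params$k_phos)
  c_dn <- convert_bimolecular_rate(params$k_dephos)

  runs <- vapply(seq_len(n_runs), function(run) {
    lat <- build_lattice(ext, ext, ext, params$l_SV)
    lat <- init_enzyme_fields(lat, kt_centers, NULL, params, mode = "field")
    sc <- subcell_of(lat, site_pos)
    if (anyNA(sc)) stop("Ndc80 site outside the benchmark lattice")
    V <- ncol(lat$counts)
    x <- matrix(0L, params$p_max + 1, V)
    tab <- table(sc)
    x[1, as.integer(names(tab))] <- as.integer(tab)
    out <- nsm_phospho_cpp(x, kinase_counts(lat), phosphatase_counts(lat),
                           c_up, c_dn, bio_time, burn_in)
    out$mean_p
  }, numeric(1))
  list(mean = mean(runs), sd = sd(runs), runs = runs)
}
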