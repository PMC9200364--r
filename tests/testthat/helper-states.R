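# Shared fixtures, all built in code.

# Two beads joined by one spring; handy for single-term energy checks.
two_bead_spring <- function(sep, k, r0, gamma = 1e5, group = 1) {
  st <- mech_state()
  st <- add_beads(st, rbind(c(0, 0, 0), c(sep, 0, 0)), radius = 10,
                  gamma = gamma, tag = "MT_body")
  add_bonds(st, 1, 2, k, r0, group)
}

# A composite state exercising every energy term: a few microtubules, a
# kinetochore pair with arms, and the membrane.
composite_state <- function(seed = 42, n_corona = 24, jitter = 5) {
  set.seed(seed)
  p <- validate_params()
  ast <- build_aster(c(-3500, 1500, 0), 3, p)
  ktf <- build_kinetochore_pair(p, with_arms = TRUE, n_corona = n_corona)
  st <- merge_states(ast$state, ktf$state)
  st$ellipse <- c(4000, 3400, 3400)
  # one attachment so U_att is non-trivial
  st$attach <- cbind(i_mt = ast$mts$i_plus[1],
                     i_site = attr(st, "offset") + 3, k = p$K_Ndc_r,
                     l0 = p$l_Ndc)
  if (jitter > 0) {
    st$pos <- st$pos + matrix(rnorm(length(st$pos), 0, jitter), ncol = 3)
  }
  st
}

# Small cell for scheduler tests.
tiny_config <- function(...) {
  mini_spindle_config(
    params = list(n_MT_per_CS = 6L), n_corona = 16L, bio_time = 5,
    ...)
}

expect_rel <- function(x, target, tol) {
  expect_lt(max(abs(x - target) / abs(target)), tol)
}
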