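test_that("defaults validate and are unit-normalized correctly", {
  p <- validate_params()
  expect_s3_class(p, "spindle_params")
  # thermal energy at 300 K
  expect_rel(p$kT, 4.14, 0.001)
  # molar -> mechanical energy conversions
  expect_rel(p$eps_LJ, 3.49e5, 0.005)
  expect_rel(p$K_MT_theta, 7.7e5 * 1.66, 0.001)
  # viscosity consistent with the Aurora diffusion constant
  D_implied <- p$kT / (6 * pi * p$eta * 1e-12 * p$R_aurora)
  expect_rel(D_implied, p$D_aurora, 1e-6)
  # re-validating is idempotent (no double conversion)
  expect_equal(validate_params(p)$eps_LJ, p$eps_LJ)
})

test_that("unit round trips are exact", {
  x <- c(1e-3, 1, 7.7e5)
  expect_rel(pnnm_to_kjmol(kjmol_to_pnnm(x)), x, 1e-12)
})

test_that("invalid parameters are rejected", {
  expect_error(validate_params(list(chi = 1.5)), "chi")
  expect_error(validate_params(list(chi = -0.1)), "chi")
  expect_error(validate_params(list(k_gr = 0)), "positive")
  expect_error(validate_params(list(K_MT_r = -5)), "positive")
  expect_error(validate_params(list(no_such = 1)), "unknown")
  expect_error(validate_params(list(p_max = 6)), "p_max")
  expect_equal(
    validate_params(list(p_max = 6), allow_p_max_override = TRUE)$p_max, 6L)
})

test_that("bimolecular rate conversion matches the printed propensities", {
  expect_equal(convert_bimolecular_rate(1.5e7), 1.5)
  expect_equal(convert_bimolecular_rate(3.0e7), 3.0)
  expect_equal(convert_bimolecular_rate(3.8e9), 3.8e2)
  expect_rel(convert_bimolecular_rate(1.5e7, mode = "exact"), 1.594, 0.001)
  # the rounded convention differs from the exact conversion by < 7%
  for (k in c(1.5e7, 3.0e7, 3.8e9)) {
    r <- convert_bimolecular_rate(k)
    e <- convert_bimolecular_rate(k, mode = "exact")
    expect_lt(abs(r - e) / e, 0.07)
  }
  expect_error(convert_bimolecular_rate(-1), "positive")
})
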