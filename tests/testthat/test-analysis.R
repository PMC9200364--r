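test_that("attachment classification matches the standard definitions", {
  expect_equal(classify_attachment(5, 0, 0, 7), "amphitelic")
  expect_equal(classify_attachment(0, 3, 2, 0), "amphitelic")
  expect_equal(classify_attachment(3, 0, 1, 0), "merotelic")
  expect_equal(classify_attachment(2, 0, 0, 0), "monotelic")
  expect_equal(classify_attachment(2, 3, 0, 0), "syntelic")
  expect_equal(classify_attachment(0, 0, 0, 0), "unattached")
  # merotely dominates: one sister holding both poles is merotelic even if
  # the other sister is also attached
  expect_equal(classify_attachment(1, 1, 1, 0), "merotelic")
  expect_error(classify_attachment(-1, 0, 0, 0), ">= 0")
})

test_that("the classification truth table is total and deterministic", {
  classes <- c("amphitelic", "merotelic", "monotelic", "syntelic",
               "unattached")
  for (L1 in 0:1) for (L2 in 0:1) for (R1 in 0:1) for (R2 in 0:1) {
    c1 <- classify_attachment(L1, L2, R1, R2)
    c2 <- classify_attachment(3 * L1, 2 * L2, 5 * R1, 7 * R2)
    expect_true(c1 %in% classes)
    expect_identical(c1, c2)  # depends only on the sign pattern
  }
})

test_that("spindle metrics report angle, distances and phosphorylation", {
  set.seed(2)
  cell <- build_spindle_cell(tiny_config())
  m <- spindle_metrics(cell)
  expect_equal(m$angle_deg, 90)
  expect_rel(m$kt_distance, 725, 1e-9)
  expect_lt(m$equator_distance, 1e-9)
  expect_equal(sum(m$counts), 0)
  cell$kt$sites$p[] <- 7L
  expect_equal(spindle_metrics(cell)$n_phos, 7)
  # parallel orientation reads 0 degrees
  set.seed(2)
  cellp <- build_spindle_cell(tiny_config(orientation = "parallel"))
  expect_lt(spindle_metrics(cellp)$angle_deg, 1e-6)
})

test_that("metrics are invariant under global rotation", {
  set.seed(3)
  cell <- build_spindle_cell(tiny_config())
  m0 <- spindle_metrics(cell)
  th <- 0.35
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  cell$state$pos <- cell$state$pos %*% t(R)
  cell$cs_pos <- cell$cs_pos %*% t(R)
  m1 <- spindle_metrics(cell)
  expect_rel(m1$angle_deg, m0$angle_deg, 1e-9)
  expect_rel(m1$kt_distance, m0$kt_distance, 1e-9)
})

test_that("diffusion estimator closes the loop with the generator", {
  set.seed(77)
  D <- 0.152e6  # nm^2/s
  dt <- 1e-3
  est <- replicate(3, {
    x <- spindlesim:::brownian_paths_cpp(2 * D * dt, 1e5, 1L)
    estimate_diffusion(x[, 1], dt, max_lag_frac = 0.002)
  })
  expect_rel(mean(est), D, 0.05)
  # immobile particle
  expect_equal(unname(estimate_diffusion(rep(0, 500), dt)), 0)
  expect_error(estimate_diffusion(rnorm(10), dt), "too short")
})

test_that("class tables aggregate end states over runs", {
  trs <- lapply(c(51, 52), function(s) run_simulation(tiny_config(seed = s,
                                                                  bio_time = 2)))
  tab <- attachment_class_table(trs)
  expect_equal(sum(tab), 1)
  expect_named(tab, c("amphitelic", "merotelic", "monotelic", "syntelic",
                      "unattached"))
})
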