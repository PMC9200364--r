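make_cell <- function(seed = 5, ...) {
  set.seed(seed)
  build_spindle_cell(tiny_config(...))
}

test_that("length events step by delta_l and re-nucleate at the floor", {
  cell <- make_cell()
  l0 <- cell$mts$length[1]
  cell2 <- apply_mt_length_event(cell, 1, "grow")
  expect_equal(cell2$mts$length[1], l0 + 24)
  expect_equal(unname(cell2$state$bonds[cell2$mts$bond1[1], "r0"]),
               (l0 + 24) / 2)
  # beads sit at the rest geometry along the axis after the event
  m <- cell2$mts[1, ]
  d13 <- sqrt(sum((cell2$state$pos[m$i_plus, ] -
                     cell2$state$pos[m$i_minus, ])^2))
  expect_rel(d13, l0 + 24, 1e-9)
  expect_error(apply_mt_length_event(cell, 1, "shorten"), "non-shortening")
  # shortening at the floor re-nucleates as growing
  cell$mts$phase[1] <- "shortening"
  cell$mts$length[1] <- 40
  cell3 <- apply_mt_length_event(cell, 1, "shorten")
  expect_equal(cell3$mts$phase[1], "growing")
  expect_equal(cell3$mts$length[1], cell$nucleation_length)
})

test_that("phase switches respect the current phase", {
  cell <- make_cell()
  cell2 <- switch_phase(cell, 2, "catastrophe")
  expect_equal(cell2$mts$phase[2], "shortening")
  expect_error(switch_phase(cell2, 2, "catastrophe"), "growing")
  cell3 <- switch_phase(cell2, 2, "rescue")
  expect_equal(cell3$mts$phase[2], "growing")
  expect_error(switch_phase(cell3, 2, "rescue"), "shortening")
})

test_that("capture candidacy is gated by the 65-nm Ndc80 sphere", {
  cell <- make_cell()
  sb <- cell$kt$sites$bead[3]
  put <- function(cell, dist) {
    cell$state$pos[cell$mts$i_plus[1], ] <-
      cell$state$pos[sb, ] + c(0, 0, -dist)
    cell
  }
  expect_equal(nrow(candidate_attachments(put(cell, 64))), 1)
  expect_equal(nrow(candidate_attachments(put(cell, 66))), 0)
  # a shortening filament cannot capture
  c2 <- put(cell, 64); c2$mts$phase[1] <- "shortening"
  expect_equal(nrow(candidate_attachments(c2)), 0)
  # one plus-end near several free sites yields several candidates
  mid <- colMeans(cell$state$pos[cell$kt$sites$bead[1:4], ])
  c3 <- cell; c3$state$pos[c3$mts$i_plus[1], ] <- mid
  expect_gte(nrow(candidate_attachments(c3)), 2)
})

test_that("attachment formation triggers an immediate catastrophe", {
  cell <- make_cell()
  cell <- form_attachment(cell, 1, 5)
  expect_equal(cell$mts$phase[1], "shortening")
  expect_true(cell$kt$sites$occupied[5])
  expect_equal(nrow(cell$state$attach), 1)
  # occupied site: forming again is a no-op
  cell2 <- form_attachment(cell, 2, 5)
  expect_equal(cell2$mts$attached_site[2], 0L)
  # release frees the site, keeps the phase and the phosphostate
  cell$kt$sites$p[5] <- 4L
  cell3 <- break_attachment(cell, 1)
  expect_false(cell3$kt$sites$occupied[5])
  expect_equal(cell3$kt$sites$p[5], 4L)
  expect_equal(cell3$mts$phase[1], "shortening")
  expect_equal(nrow(cell3$state$attach), 0)
  # Ndc80 conservation: free + occupied is invariant
  expect_equal(sum(cell3$kt$sites$occupied) + sum(!cell3$kt$sites$occupied),
               nrow(cell$kt$sites))
})

test_that("detachment rate rises linearly with phosphorylation", {
  expect_equal(detachment_propensity(0), 1.5e-3)
  expect_equal(detachment_propensity(7), 2.9e-3)
  expect_equal(detachment_propensity(3), 2.1e-3)
  r <- detachment_propensity(0:7)
  expect_true(all(diff(r) > 0))
  # printed lifetime band: 5.7 to 11.1 minutes
  expect_rel(1 / detachment_propensity(0) / 60, 11.1, 0.01)
  expect_rel(1 / detachment_propensity(7) / 60, 5.75, 0.01)
  expect_error(detachment_propensity(8), "p outside")
})

test_that("phosphostates stay within 0..p_max", {
  cell <- make_cell()
  cell$kt$sites$p[1] <- 6L
  cell <- phospho_event(cell, 1, +1)
  expect_equal(cell$kt$sites$p[1], 7L)
  expect_error(phospho_event(cell, 1, +1), "fully")
  cell$kt$sites$p[2] <- 0L
  expect_error(phospho_event(cell, 2, -1), "fully")
})

test_that("dynamic instability occupies the growing phase ~92% of the time", {
  p <- validate_params()
  frac <- (1 / p$w_cat) / (1 / p$w_cat + 1 / p$w_res)
  expect_rel(frac, 400 / 433.3, 0.001)
  # Monte-Carlo renewal process agrees
  set.seed(40)
  g <- rexp(4000, p$w_cat); s <- rexp(4000, p$w_res)
  expect_lt(abs(sum(g) / sum(g + s) - frac), 0.01)
})

test_that("push/pull statistics read episodes off a trajectory", {
  cell <- make_cell()
  p <- cell$params
  # static stretched Ndc80 at 75 nm: tension K (75-65) = 3.1e3 pN
  sb <- cell$kt$sites$bead[1]
  cell$state$pos[cell$mts$i_plus[1], ] <-
    cell$state$pos[sb, ] + c(75, 0, 0)
  cell <- form_attachment(cell, 1, 1)
  fr <- list(time = 0, pos = cell$state$pos, attach = cell$state$attach)
  st <- pushing_interaction_stats(list(fr, fr), cell)
  expect_rel(st$pull_forces, 310 * 10, 1e-6)
  # nothing near the chromosome -> no pushing episodes
  far <- make_cell(mt_length_range = c(36, 36))
  fr2 <- list(time = 0, pos = far$state$pos, attach = far$state$attach)
  st2 <- pushing_interaction_stats(list(fr2, fr2), far)
  expect_equal(length(st2$push_durations), 0)
})
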