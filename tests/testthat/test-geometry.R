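test_that("asters anchor on the centrosome surface in uniform directions", {
  set.seed(1)
  p <- validate_params()
  a <- build_aster(c(100, -200, 300), 40, p)
  expect_equal(nrow(a$mts), 40)
  expect_equal(n_beads(a$state), 1 + 3 * 40)
  minus <- a$state$pos[a$mts$i_minus, ]
  d <- sqrt(rowSums(sweep(minus, 2, c(100, -200, 300))^2))
  expect_rel(d, p$R_CS, 1e-9)
  # single filament is collinear at creation
  a1 <- build_aster(c(0, 0, 0), 1, p)
  pts <- a1$state$pos[unlist(a1$mts[1, c("i_minus", "i_body", "i_plus")]), ]
  v1 <- pts[2, ] - pts[1, ]; v2 <- pts[3, ] - pts[2, ]
  expect_lt(sum(abs(v1 / sqrt(sum(v1^2)) - v2 / sqrt(sum(v2^2)))), 1e-9)
  # anchor directions are uniform on the sphere
  set.seed(7)
  dirs <- as.matrix(build_aster(c(0, 0, 0), 1e4, p)$mts[, c("dx", "dy", "dz")])
  expect_lt(sqrt(sum(colMeans(dirs)^2)), 3 / sqrt(1e4))
})

test_that("aster rebuild with the same seed is identical", {
  p <- validate_params()
  set.seed(99); a1 <- build_aster(c(0, 0, 0), 20, p)
  set.seed(99); a2 <- build_aster(c(0, 0, 0), 20, p)
  expect_identical(a1$state$pos, a2$state$pos)
  expect_identical(a1$mts, a2$mts)
})

corona_area_estimate <- function(pts, n1, n2, L) {
  # polyline length along each grid direction, extrapolated by half cells
  g <- expand.grid(i = seq_len(n1), j = seq_len(n2))[seq_len(nrow(pts)), ]
  col1 <- pts[g$j == 1, , drop = FALSE]         # varies along u
  row1 <- pts[g$i == 1, , drop = FALSE]         # varies along v (arc)
  plen <- function(m) sum(sqrt(rowSums(diff(m)^2)))
  ext_u <- plen(col1) * n1 / (n1 - 1)
  ext_v <- plen(row1) * n2 / (n2 - 1)
  ext_u * ext_v
}

test_that("corona patch area is fixed at A_KT for every curvature", {
  for (chi in c(0, 0.25, 0.5, 0.75, 1)) {
    p <- validate_params(list(chi = chi))
    ktf <- build_kinetochore_pair(p, n_corona = 900)  # 30 x 30 grid
    s1 <- ktf$kt$sites$bead[ktf$kt$sites$sister == 1]
    pts <- ktf$state$pos[s1, ]
    est <- corona_area_estimate(pts, 30, 30, sqrt(p$A_KT) * 1000)
    expect_lt(abs(est * 1e-6 - p$A_KT) / p$A_KT, 0.01)
  }
})

test_that("kinetochore pair has the advertised composition", {
  p <- validate_params()
  ktf <- build_kinetochore_pair(p)
  expect_equal(n_beads(ktf$state), 2 + 2 * 750)
  expect_equal(nrow(ktf$kt$sites), 1500)
  expect_equal(unname(dist(ktf$state$pos[ktf$kt$i_kt, ])[1]), p$d_KT)
  # corona-to-center rest lengths span the sphere radius up to the patch
  # rim (square-patch corners reach a little past 400 nm at chi = 0.5)
  ck <- ktf$state$bonds[ktf$state$bonds[, "j"] %in% ktf$kt$i_kt &
                          ktf$state$bonds[, "r0"] < 500, ]
  expect_true(all(ck[, "r0"] >= p$R_CH - 1 & ck[, "r0"] <= 440))
})

test_that("chromosome arms add 16 beads with ~6 um contour and cohesin", {
  p <- validate_params()
  ktf <- build_kinetochore_pair(p, with_arms = TRUE, n_corona = 10)
  expect_equal(length(ktf$kt$arm_beads), 16)
  # contour length through the centromere: 8 segments of 725 nm
  contour <- 8 * p$d_KT / 1000
  expect_lt(abs(contour - 6) / 6, 0.05)
  coh <- ktf$state$bonds[ktf$state$bonds[, "k"] == p$K_coh_r &
                           ktf$state$bonds[, "group"] == 3, , drop = FALSE]
  expect_gte(nrow(coh), 8)
})

test_that("flexible variant softens corona anchoring 40-fold", {
  p <- validate_params()
  rigid <- build_kinetochore_pair(p, n_corona = 20)
  flex <- build_kinetochore_pair(p, flexible = TRUE, n_corona = 20)
  kmin_r <- min(rigid$state$bonds[, "k"])
  kmin_f <- min(flex$state$bonds[, "k"])
  expect_equal(kmin_r / kmin_f, 40)
})

test_that("initial placement reproduces the unbiased starting geometry", {
  set.seed(5)
  cell <- build_spindle_cell(tiny_config())
  m <- spindle_metrics(cell)
  expect_equal(m$angle_deg, 90)
  expect_rel(m$kt_distance, 725, 1e-9)
  expect_lt(m$equator_distance, 1e-9)
  # zero offset puts the midpoint at the origin
  p <- validate_params()
  ktf <- build_kinetochore_pair(p, n_corona = 10)
  ktf0 <- place_initial_configuration(ktf, offset = 0)
  expect_lt(max(abs(colMeans(ktf0$state$pos[ktf0$kt$i_kt, ]))), 1e-9)
  # parallel orientation aligns the KT axis with the spindle axis
  ktfp <- place_initial_configuration(ktf, orientation = "parallel")
  kk <- ktfp$state$pos[ktfp$kt$i_kt[2], ] - ktfp$state$pos[ktfp$kt$i_kt[1], ]
  expect_lt(abs(abs(kk[1]) / sqrt(sum(kk^2)) - 1), 1e-9)
  # a placement through the membrane errors
  expect_error(place_initial_configuration(ktf, offset = 5000,
                                           ellipse = c(4000, 3000, 3000)),
               "membrane")
})

test_that("enzyme fields honor confinement and conserve counts", {
  set.seed(3)
  p <- validate_params(list(n_AA = 200L))
  lat <- build_lattice(3000, 3000, 3000, 250)
  ktc <- rbind(c(0, 0, -362.5), c(0, 0, 362.5))
  cs <- rbind(c(-1500, 0, 0), c(1500, 0, 0))
  lat <- init_enzyme_fields(lat, ktc, cs, p, mode = "explicit")
  expect_equal(species_total(lat, "PH"), p$n_PH)
  expect_equal(species_total(lat, "AB"), p$n_AB)
  expect_equal(species_total(lat, "AA"), p$n_AA)
  # all AB within 250 nm of the centromere surface
  occ <- which(lat$counts[match("AB", lat$species), ] > 0)
  d <- pmin(sqrt(colSums((t(lat$centers[occ, , drop = FALSE]) - ktc[1, ])^2)),
            sqrt(colSums((t(lat$centers[occ, , drop = FALSE]) - ktc[2, ])^2)))
  expect_true(all(d <= p$R_CH + p$ab_spread))
  # field mode: expected counts sum to the totals
  lat2 <- init_enzyme_fields(build_lattice(3000, 3000, 3000, 250),
                             ktc, cs, p, mode = "field")
  expect_rel(sum(lat2$fields$AB), p$n_AB, 1e-9)
  # twin Aurora A field is symmetric about the equatorial plane
  set.seed(11)
  lat3 <- init_enzyme_fields(build_lattice(3000, 3000, 3000, 250),
                             ktc, cs, p, mode = "explicit")
  aa <- lat3$counts[match("AA", lat3$species), ]
  xw <- sum(aa * lat3$centers[, 1]) / sum(aa)
  expect_lt(abs(xw), 3 * 1500 / sqrt(p$n_AA))
})
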