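test_that("radial coordinate matches the closed form on concentric disks", {
  n <- 81
  cell <- disk_mask(n, 30)
  nuc <- disk_mask(n, 10)
  dn <- normalized_radial_coordinate(cell, nuc)
  ctr <- (n + 1) / 2
  # pixel at radius 20 along the axis: (20 - 10) / (30 - 10) = 0.5
  expect_equal(dn[ctr, ctr + 20], 0.5, tolerance = 0.05)
  # boundary conditions
  expect_lt(dn[ctr, ctr + 11], 0.1)
  expect_gt(dn[ctr, ctr + 29], 0.9)
  expect_true(all(is.na(dn[nuc])))
  expect_true(all(is.na(dn[!cell])))
  # brute-force oracle: d_n at radius r is (r - 10)/20 within 1 px of
  # rasterization slack on the 20-px nucleus-to-edge span
  idx <- which(cell & !nuc, arr.ind = TRUE)
  r <- sqrt((idx[, 1] - ctr)^2 + (idx[, 2] - ctr)^2)
  expected <- (r - 10) / 20
  got <- dn[idx]
  expect_true(all(abs(got - expected) <= 1 / 20 + 1e-9))
})

test_that("radial coordinate rejects malformed mask pairs", {
  expect_error(normalized_radial_coordinate(disk_mask(41, 10), disk_mask(41, 15)),
               "not contained")
  expect_error(normalized_radial_coordinate(disk_mask(41, 10),
                                            matrix(FALSE, 41, 41)),
               "empty nucleus")
})

test_that("bands sit at fixed relative distances with analytic areas", {
  n <- 101
  cell <- disk_mask(n, 30); nuc <- disk_mask(n, 10)
  dn <- normalized_radial_coordinate(cell, nuc)
  part <- define_regions(dn, 0.25, 0.25)
  expect_true(part$valid)
  # PN = annulus (10, 15), PE = annulus (25, 30)
  a_pn <- pi * (15^2 - 10^2)
  a_pe <- pi * (30^2 - 25^2)
  expect_equal(part$n_pn, a_pn, tolerance = 0.03)
  expect_equal(part$n_pe, a_pe, tolerance = 0.03)
  expect_true(!any(part$pn & nuc))
  expect_true(!any(part$pn & part$pe))
})

test_that("band area fractions are invariant to isotropic cell scaling", {
  # the same cell drawn at 1x and 2x scale (radii doubled)
  frac <- function(n, r_cell, r_nuc) {
    cm <- disk_mask(n, r_cell); nm <- disk_mask(n, r_nuc)
    dn <- normalized_radial_coordinate(cm, nm)
    p <- define_regions(dn, 0.25, 0.25)
    c(p$n_pn, p$n_pe) / sum(cm & !nm)
  }
  f1 <- frac(81, 30, 10)
  f2 <- frac(161, 60, 20)
  expect_equal(f1, f2, tolerance = 0.02)
})

test_that("expansion ratio reproduces painted constants and invariances", {
  n <- 101
  cell <- disk_mask(n, 30); nuc <- disk_mask(n, 10)
  dn <- normalized_radial_coordinate(cell, nuc)
  part <- define_regions(dn, 0.25, 0.25)
  uniform <- matrix(500, n, n)
  expect_equal(as.numeric(expansion_ratio(uniform, part)), 1.0)
  painted <- matrix(0, n, n)
  painted[part$pn] <- 100; painted[part$pe] <- 50
  expect_identical(as.numeric(expansion_ratio(painted, part)), 0.5)
  # invariant under positive scaling of the ER channel
  for (c_scale in c(0.5, 3))
    expect_equal(as.numeric(expansion_ratio(painted * c_scale, part)), 0.5,
                 tolerance = 1e-12)
  # degenerate cases flagged, not errors
  zero <- matrix(0, n, n)
  expect_true(is.na(expansion_ratio(zero, part)))
  empty_part <- define_regions(matrix(NA_real_, n, n), 0.25, 0.25)
  expect_false(empty_part$valid)
  expect_true(is.na(expansion_ratio(uniform, empty_part)))
})

test_that("texture scores agree with a brute-force convolution oracle", {
  set.seed(8)
  n <- 64
  mask <- disk_mask(n, 26)
  k <- texture_kernels()
  # flat image scores exactly zero on both channels
  flat <- matrix(700, n, n)
  ts <- texture_scores(flat, mask)
  expect_equal(unname(ts), c(0, 0), tolerance = 1e-8)
  # 1-px bright horizontal lines spaced 8 px
  lines <- matrix(100, n, n)
  lines[seq(8, n - 8, by = 8), ] <- 1100
  ts_l <- texture_scores(lines, mask)
  resp <- lapply(k$ridges, function(kr) conv2_oracle(lines, kr))
  ridge_or <- Reduce(pmax, resp)
  hole_or <- conv2_oracle(lines, k$hole)
  expect_equal(unname(ts_l["ridge_score"]),
               mean(pmax(ridge_or[mask], 0)) / mean(lines[mask]),
               tolerance = 1e-6)
  expect_equal(unname(ts_l["hole_score"]),
               mean(pmax(hole_or[mask], 0)) / mean(lines[mask]),
               tolerance = 1e-6)
  expect_gt(ts_l["ridge_score"], ts_l["hole_score"])
  # 1-px dark pits on a bright background
  pits <- matrix(1000, n, n)
  pit_at <- cbind(seq(10, 54, by = 8), seq(12, 56, by = 8))
  pits[pit_at] <- 50
  ts_p <- texture_scores(pits, mask)
  expect_gt(ts_p["hole_score"], ts_p["ridge_score"])
  # intensity-scale invariance
  ts_s <- texture_scores(lines * 2.5, mask)
  expect_equal(unname(ts_s), unname(ts_l), tolerance = 1e-9)
})

test_that("shape features recover analytic descriptors", {
  rect <- matrix(FALSE, 60, 80)
  rect[20:39, 15:54] <- TRUE           # 20 x 40 rectangle
  s <- shape_features(rect)
  expect_equal(unname(s["area"]), 20 * 40)
  circ <- disk_mask(81, 30)
  expect_lt(shape_features(circ)["eccentricity"], 0.05)
  ell <- ellipse_mask(121, 40, 10)
  expect_equal(unname(shape_features(ell)["major_axis"]), 80, tolerance = 0.02)
  nuc <- disk_mask(81, 15)
  s2 <- shape_features(circ, nuc)
  expect_equal(unname(s2["nucleus_cell_ratio"]), sum(nuc) / sum(circ))
})

test_that("pipeline recovers painted expansion ratios on noise-free fields", {
  sim <- generate_field(quiet_spec(image_shape = c(640, 640), n_cells = 12,
                                   er_peripheral_fraction = 0.35, seed = 61))
  rec <- recover_ratios(sim)
  expect_gte(nrow(rec), 12)
  rel_err <- abs(rec$measured / rec$truth - 1)
  expect_true(all(rel_err < 0.03))
})

test_that("measured expansion ratio is strictly monotone in the painted fraction", {
  grid <- seq(0.2, 0.8, by = 0.15)
  med <- vapply(grid, function(p) {
    sim <- generate_field(quiet_spec(image_shape = c(512, 512), n_cells = 6,
                                     er_peripheral_fraction = p,
                                     noise = c(poisson_scale = 4,
                                               gaussian_sd = 25),
                                     seed = 71))
    median(recover_ratios(sim)$measured, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  expect_equal(cor(med, grid, method = "spearman"), 1)
})
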