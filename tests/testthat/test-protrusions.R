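test_that("polarity index closed forms evaluate exactly", {
  expect_identical(as.numeric(polarity_index(protrusion_set(40, 10))), 1)
  expect_identical(
    as.numeric(polarity_index(protrusion_set(c(10, 10), c(0, 90)))), 0.5)
  # lengths {40,25,15} at {0, 90, 180} degrees: (40*1 + 25*0 + 15*1)/80
  pi3 <- polarity_index(protrusion_set(c(40, 25, 15), c(0, 90, 180)))
  expect_equal(as.numeric(pi3), 0.6875, tolerance = 1e-12)
  # antiparallel counts as aligned (axial measure)
  expect_equal(
    as.numeric(polarity_index(protrusion_set(c(10, 10), c(30, 210)))), 1,
    tolerance = 1e-12)
})

test_that("polarity index is undefined (not zero) without protrusions", {
  ps <- protrusion_set(numeric(0), numeric(0))
  expect_true(is.na(polarity_index(ps)))
  expect_identical(attr(polarity_index(ps), "reason"), "no protrusions")
  expect_true(is.na(largest_protrusion_relative_length(ps)))
})

test_that("polarity index invariances hold over random protrusion sets", {
  set.seed(42)
  for (rep in 1:25) {
    k <- sample(1:6, 1)
    L <- runif(k, 5, 60)
    A <- runif(k, 0, 360)
    ps <- protrusion_set(L, A)
    p0 <- as.numeric(polarity_index(ps))
    # bounded: the longest protrusion always contributes weight 1
    expect_gte(p0 + 1e-12, max(L) / sum(L))
    expect_lte(p0, 1 + 1e-12)
    # global rotation invariance
    rot <- runif(1, 0, 360)
    expect_equal(as.numeric(polarity_index(protrusion_set(L, A + rot))), p0,
                 tolerance = 1e-9)
    # relabeling invariance (permute input order)
    perm <- sample(k)
    expect_equal(as.numeric(polarity_index(protrusion_set(L[perm], A[perm]))),
                 p0, tolerance = 1e-9)
    # axis symmetry: alpha -> 180 - alpha leaves |sin| unchanged
    longest <- which.max(L)
    refl <- 2 * A[longest] - A           # reflect about the longest's axis
    expect_equal(as.numeric(polarity_index(protrusion_set(L, refl))), p0,
                 tolerance = 1e-9)
  }
})

test_that("length ties resolve deterministically to the first protrusion", {
  ps <- protrusion_set(c(20, 20, 10), c(45, 135, 45))
  expect_equal(ps$protrusions$alpha[1], 0)
  expect_equal(ps$protrusions$alpha[2], 90)
})

test_that("a convex cell decomposes to zero protrusions", {
  ps <- decompose_protrusions(disk_mask(91, 30), opening_radius = 8)
  expect_equal(ps$n, 0)
  expect_error(decompose_protrusions(disk_mask(31, 5), opening_radius = 14),
               "opening_radius too large")
})

test_that("three rectangular arms are recovered with lengths and Pi", {
  arms <- data.frame(length = c(40, 25, 15), angle = c(0, 90, 180), width = 6)
  for (sd in c(1, 2, 3)) {
    sim <- generate_field(quiet_spec(image_shape = c(320, 320), n_cells = 1,
                                     cell_radius_range = c(30, 30),
                                     protrusion_specs = arms, seed = sd))
    ps <- decompose_protrusions(sim$truth$cell_labels == 1,
                                opening_radius = 8, min_protrusion_area = 20)
    expect_equal(ps$n, 3)
    expect_true(all(abs(sort(ps$protrusions$length) - c(15, 25, 40)) <= 2))
    expect_equal(as.numeric(polarity_index(ps)), 0.6875, tolerance = 0.02)
    # relative protrusion area against painted ground truth
    rel_meas <- sum(ps$protrusions$area) / ps$body_area
    rel_true <- sum(sim$truth$protrusions$area) /
      (sim$truth$cells$area_cell[1] - sum(sim$truth$protrusions$area))
    expect_equal(rel_meas, rel_true, tolerance = 0.05)
  }
})

test_that("relative largest protrusion length matches ground truth", {
  expect_identical(
    as.numeric(largest_protrusion_relative_length(
      protrusion_set(c(40, 10), c(0, 90), body_major_axis = 80))), 0.5)
  arm <- data.frame(length = 60, angle = 40, width = 7)
  sim <- generate_field(quiet_spec(image_shape = c(360, 360), n_cells = 1,
                                   cell_radius_range = c(36, 36),
                                   protrusion_specs = arm, seed = 9))
  ps <- decompose_protrusions(sim$truth$cell_labels == 1, opening_radius = 8)
  expect_equal(ps$n, 1)
  # body major axis of a radius-36 disk-like body is ~2*36 px
  rel <- as.numeric(largest_protrusion_relative_length(ps))
  expect_equal(rel, 60 / ps$body_major_axis, tolerance = 0.05)
})

test_that("an axial cell outscores an isotropic many-armed cell", {
  # neurite-like: one long arm; isotropic: five arms of equal total length
  axial <- protrusion_set(60, 15, body_major_axis = 70)
  iso <- protrusion_set(rep(12, 5), c(0, 72, 144, 216, 288),
                        body_major_axis = 70)
  expect_gt(as.numeric(polarity_index(axial)),
            as.numeric(polarity_index(iso)))
  expect_gt(as.numeric(largest_protrusion_relative_length(axial)),
            as.numeric(largest_protrusion_relative_length(iso)))
})

test_that("manual protrusion masks bypass the opening", {
  mask <- disk_mask(91, 25)
  arm <- matrix(FALSE, 91, 91); arm[44:48, 71:88] <- TRUE
  manual <- matrix(0L, 91, 91); manual[44:48, 72:88] <- 1L
  ps <- decompose_protrusions(mask | arm, manual_masks = manual,
                              min_protrusion_area = 10)
  expect_equal(ps$n, 1)
  expect_equal(ps$protrusions$length[1], 17, tolerance = 0.15)
})

test_that("per-cell protrusion table covers every labelled cell", {
  arms <- data.frame(length = c(30, 20), angle = c(10, 100), width = 6)
  sim <- generate_field(quiet_spec(image_shape = c(512, 512), n_cells = 3,
                                   cell_radius_range = c(28, 32),
                                   protrusion_specs = arms, seed = 13))
  tab <- protrusion_features(sim$truth$cell_labels)
  expect_equal(tab$label, 1:3)
  expect_true(all(tab$n_protrusions == 2))
  expect_true(all(tab$polarity_index > 0 & tab$polarity_index <= 1))
})
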