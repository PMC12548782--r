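make_wells <- function(df) {
  # helper: long-format well table from a condition -> values list
  rows <- list()
  for (i in seq_len(nrow(df)))
    rows[[i]] <- data.frame(plate = df$plate[i], well = df$well[i],
                            condition = df$condition[i], replicate = i,
                            feature = df$feature[i], mean = df$value[i],
                            median = df$value[i], n_cells = 100)
  do.call(rbind, rows)
}

test_that("well aggregation averages only unflagged cells", {
  cells <- data.frame(
    well = rep(c("A1", "A2"), each = 3),
    expansion_ratio = c(1, 2, 3, 2, 4, 100),
    qc_pass = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    feature_valid = TRUE)
  layout <- data.frame(well = c("A1", "A2"), condition = c("ctrl", "trt"))
  w <- aggregate_wells(cells, layout)
  a1 <- w[w$well == "A1" & w$feature == "expansion_ratio", ]
  expect_equal(a1$mean, 2); expect_equal(a1$median, 2)
  expect_equal(a1$n_cells, 3)
  a2 <- w[w$well == "A2" & w$feature == "expansion_ratio", ]
  expect_equal(a2$mean, 3)         # flagged cell value 100 excluded
  expect_equal(a2$n_cells, 2)
  expect_error(aggregate_wells(data.frame(well = "Z9", x = 1), layout),
               "not in layout")
})

test_that("control-referenced Z-scores match the closed form", {
  df <- data.frame(plate = 1, well = c("c1", "c2", "c3", "t1"),
                   condition = c("ctrl", "ctrl", "ctrl", "trt"),
                   feature = "f", value = c(8, 10, 12, 14))
  z <- zscore_matrix(make_wells(df), controls = "ctrl")
  # controls {8,10,12}: mean 10, SD 2 (n-1); treated 14 -> Z = 2
  expect_equal(unname(z["trt", "f"]), 2.0)
  expect_equal(unname(z["ctrl", "f"]), 0)
  # a treated well exactly at the control mean scores 0
  df$value[4] <- 10
  z0 <- zscore_matrix(make_wells(df), controls = "ctrl")
  expect_equal(unname(z0["trt", "f"]), 0)
})

test_that("zero control SD yields a flagged NA entry, never infinity", {
  df <- data.frame(plate = 1, well = c("c1", "c2", "t1"),
                   condition = c("ctrl", "ctrl", "trt"),
                   feature = "f", value = c(5, 5, 9))
  z <- zscore_matrix(make_wells(df), controls = "ctrl")
  expect_true(is.na(z["trt", "f"]))
  expect_gte(length(attr(z, "flagged")), 1)
  expect_true(any(grepl("^trt/f", attr(z, "flagged"))))
})

test_that("Z-scores are invariant under plate-wide affine changes", {
  set.seed(5)
  df <- data.frame(plate = 1, well = sprintf("w%d", 1:10),
                   condition = rep(c("ctrl", "a", "b", "c", "d"), each = 2),
                   feature = "f", value = rnorm(10, 50, 5))
  df$condition[1:4] <- "ctrl"
  z1 <- zscore_matrix(make_wells(df), controls = "ctrl")
  df2 <- df; df2$value <- df2$value + 17
  df3 <- df; df3$value <- df3$value * 3.2
  expect_equal(unclass(zscore_matrix(make_wells(df2), controls = "ctrl")),
               unclass(z1), tolerance = 1e-9)
  expect_equal(unclass(zscore_matrix(make_wells(df3), controls = "ctrl")),
               unclass(z1), tolerance = 1e-9)
})

test_that("null Z-scores are centred with unit spread at adequate control counts", {
  # With m control wells, Var(Z) of an independent null well is
  # (1 + 1/m) * (m-1)/(m-3); unit-SD behaviour requires m large.
  set.seed(13)
  zs <- c()
  for (plate in 1:150) {
    m <- 48
    df <- data.frame(plate = 1, well = sprintf("w%d", 1:(m + 12)),
                     condition = c(rep("ctrl", m), sprintf("t%d", 1:12)),
                     feature = "f", value = rnorm(m + 12))
    z <- zscore_matrix(make_wells(df), controls = "ctrl")
    zs <- c(zs, z[grep("^t", rownames(z)), "f"])
  }
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(sd(zs), 0.9); expect_lt(sd(zs), 1.1)
  # small-control-count inflation follows the theoretical factor
  set.seed(14)
  zs8 <- c()
  for (rep in 1:400) {
    df <- data.frame(plate = 1, well = sprintf("w%d", 1:9),
                     condition = c(rep("ctrl", 8), "t"),
                     feature = "f", value = rnorm(9))
    zs8 <- c(zs8, zscore_matrix(make_wells(df), controls = "ctrl")["t", "f"])
  }
  infl <- sqrt((1 + 1 / 8) * 7 / 5)
  expect_equal(sd(zs8), infl, tolerance = 0.15)
})

test_that("t-test matches the pooled-variance closed form with stars", {
  tt <- ttest_conditions(c(1, 2, 3), c(4, 5, 6))
  or <- pooled_t_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, or$t, tolerance = 1e-9)
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, or$p, tolerance = 1e-9)
  expect_equal(tt$p, 0.0214, tolerance = 0.01)
  expect_identical(tt$stars, "*")
  # identical groups
  t0 <- ttest_conditions(c(2, 2, 2), c(2, 2, 2))
  expect_identical(t0$t, 0); expect_identical(t0$p, 1)
  expect_identical(t0$stars, "n.s.")
  # star boundaries
  expect_identical(significance_stars(0.009), "**")
  expect_identical(significance_stars(0.004), "***")
  expect_identical(significance_stars(0.03), "*")
  expect_identical(significance_stars(0.2), "n.s.")
})

test_that("t-test type-I error is nominal under the null", {
  # vectorized pooled-t null simulation, validated against ttest_conditions
  # on a subsample, then assessed at 10,000 replicates
  set.seed(20)
  n <- 4; reps <- 10000
  a <- matrix(rnorm(n * reps), n); b <- matrix(rnorm(n * reps), n)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, var); vb <- apply(b, 2, var)
  sp2 <- ((n - 1) * va + (n - 1) * vb) / (2 * n - 2)
  tt <- (ma - mb) / sqrt(sp2 * 2 / n)
  pv <- 2 * pt(-abs(tt), 2 * n - 2)
  idx <- sample(reps, 50)
  for (i in idx)
    expect_equal(ttest_conditions(a[, i], b[, i])$p, pv[i], tolerance = 1e-9)
  type1 <- mean(pv < 0.05)
  expect_gte(type1, 0.04); expect_lte(type1, 0.06)
})

test_that("profile clustering handles degenerate inputs and ties", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, -4))
  cl <- cluster_profiles(m, distance = "euclidean")
  # identical rows merge first at height 0
  expect_equal(cl$hclust$height[1], 0)
  first <- cl$hclust$merge[1, ]
  expect_setequal(rownames(m)[-first], c("a", "b"))
  single <- cluster_profiles(m[1, , drop = FALSE])
  expect_identical(single$order, "a")
  expect_match(single$newick, "^\\(a\\);$")
  expect_match(cl$newick, "a")           # Newick export carries leaf labels
})

test_that("clustering is invariant to row permutation", {
  set.seed(31)
  m <- matrix(rnorm(8 * 5), 8, dimnames = list(letters[1:8], NULL))
  c1 <- cluster_profiles(m)
  c2 <- cluster_profiles(m[sample(8), ])
  d1 <- cophenetic(c1$hclust); d2 <- cophenetic(c2$hclust)
  ord <- order(labels(d1)); ord2 <- order(labels(d2))
  expect_equal(as.matrix(d1)[ord, ord], as.matrix(d2)[ord2, ord2],
               tolerance = 1e-9)
})

test_that("duplicate siRNA profiles end up as adjacent leaves", {
  # 8 genes x 2 siRNAs sharing the gene's shift plus small noise
  set.seed(7)
  adjacent <- 0
  for (run in 1:100) {
    shifts <- matrix(rnorm(8 * 8, sd = 1), 8, 8)
    prof <- shifts[rep(1:8, each = 2), ] + matrix(rnorm(16 * 8, sd = 0.15), 16)
    rownames(prof) <- sprintf("g%d_si%d", rep(1:8, each = 2), rep(1:2, 8))
    cl <- cluster_profiles(prof)
    gene_of <- sub("_si[12]$", "", cl$order)
    ok <- all(vapply(unique(gene_of), function(g)
      diff(which(gene_of == g)) == 1, logical(1)))
    adjacent <- adjacent + ok
  }
  expect_gte(adjacent, 95)
})

test_that("single-cell regression recovers exact and degenerate fits", {
  x <- seq(0, 10, by = 0.5)
  fit <- single_cell_regression(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  const <- single_cell_regression(x, rep(5, length(x)))
  expect_identical(const$slope, 0)
  expect_true(is.na(const$r) && const$flagged)
  expect_true(single_cell_regression(rep(1, 10), rnorm(10))$flagged)
  expect_error(single_cell_regression(1:2, 1:2), "3")
})

test_that("negatively coupled single-cell features yield a negative fit", {
  # translation activity vs ER expansion with built-in negative coupling
  set.seed(55)
  n <- 300
  pmy <- rnorm(n, 100, 15)
  ratio <- 2 - 0.008 * pmy + rnorm(n, 0, 0.1)
  fit <- single_cell_regression(pmy, ratio)
  expect_lt(fit$slope, 0)
  expect_lt(fit$r, 0)
  expect_lt(fit$p, 0.005)
})
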