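test_that("measure_cell matches hand arithmetic on a 2x2 region", {
  img <- matrix(c(1, 3, 2, 4), 2, 2) # values 1..4
  mask <- matrix(TRUE, 2, 2)
  m <- measure_cell(img, mask, pixel_size_um = 1)
  expect_equal(m$mean, 2.5)
  expect_equal(m$max, 4)
  expect_equal(m$raw_int_den, 10)
  expect_equal(m$area_um2, 4)
  expect_equal(m$int_den, 10)
})

test_that("a constant field gives mean = max = c and raw sum c * area", {
  img <- matrix(7, 5, 8)
  mask <- matrix(FALSE, 5, 8); mask[2:4, 3:6] <- TRUE
  m <- measure_cell(img, mask, pixel_size_um = 2)
  expect_equal(m$mean, 7)
  expect_equal(m$max, 7)
  expect_equal(m$raw_int_den, 7 * 12)
  expect_equal(m$area_um2, 12 * 4)
})

test_that("integrated-density identities hold on random masked images", {
  set.seed(42)
  for (i in 1:100) {
    h <- sample(8:40, 1); w <- sample(8:40, 1)
    img <- matrix(runif(h * w, 0, 5000), h, w)
    mask <- matrix(runif(h * w) < 0.4, h, w)
    if (!any(mask)) mask[1, 1] <- TRUE
    px <- runif(1, 0.1, 2)
    m <- measure_cell(img, mask, pixel_size_um = px)
    expect_equal(m$raw_int_den, m$mean * m$area_px, tolerance = 1e-9)
    expect_equal(m$int_den, m$mean * m$area_um2, tolerance = 1e-9)
    expect_gte(m$max, m$mean)
  }
})

test_that("measures ignore pixels outside the mask", {
  set.seed(7)
  img <- matrix(runif(400, 0, 100), 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[5:15, 5:15] <- TRUE
  m1 <- measure_cell(img, mask, pixel_size_um = 1)
  img2 <- img; img2[!mask] <- img2[!mask] + 5000
  m2 <- measure_cell(img2, mask, pixel_size_um = 1)
  expect_identical(m1, m2)
})

test_that("measure_cell rejects an empty mask", {
  expect_error(measure_cell(matrix(1, 4, 4), matrix(FALSE, 4, 4), 1),
               "empty mask")
})

test_that("segmentation recovers the ground-truth footprint", {
  p <- tiny_scene()
  d <- two_group_design(1, 1)[1, ]
  for (s in 1:5) {
    g <- generate_cell_stack(p, d, seed = s)
    mk <- segment_cell(g$stack)
    fp_true <- apply(g$truth$mask, c(1, 2), max) > 0
    jac <- sum(mk$footprint & fp_true) / sum(mk$footprint | fp_true)
    expect_gte(jac, 0.8)
    expect_equal(mk$area_um2, mk$area_px * p$pixel_size_um^2)
  }
})

test_that("segmentation is exact on a clean disk and fails on empty images", {
  disk <- outer(1:64, 1:64, function(i, j) {
    ((i - 32)^2 + (j - 32)^2 <= 15^2) * 1000
  })
  mk <- segment_cell(array(disk, c(64, 64, 1)), method = "fixed",
                     threshold = 500, pixel_size_um = 1)
  expect_identical(mk$footprint, disk > 500)
  expect_error(segment_cell(array(0, c(32, 32, 2))), "no cell found")
})

test_that("Welch test matches the closed form on the toy example", {
  w <- welch_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(w$t, 9 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(w$df, 4, tolerance = 1e-10)
  expect_equal(w$p, 2 * stats::pt(-9 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_identical(w$stars, "***")
})

test_that("identical groups give t = 0, p = 1", {
  w <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  # degenerate: both variances zero, equal means
  w0 <- welch_test(c(2, 2, 2), c(2, 2))
  expect_equal(w0$p, 1)
})

test_that("Welch test agrees with the reference implementation", {
  set.seed(123)
  for (i in 1:100) {
    a <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1),
               sd = runif(1, 0.5, 3))
    ours <- welch_test(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    expect_equal(sign(ours$t), sign(mean(a) - mean(b)))
  }
  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("measured raw_int_den ratio recovers the multiplier without background", {
  p <- power_scene(background_level = 0, read_noise_sigma = 2)
  d <- two_group_design(200, 0.6)
  seeds <- roscope:::derive_seeds(55, 400)
  sums <- list(control = c(), CBD = c())
  i <- 0
  for (g in seq_len(nrow(d))) {
    for (j in seq_len(d$n[g])) {
      i <- i + 1
      g2 <- generate_cell_stack(p, d[g, ], seed = seeds[i])
      m <- measure_cell(g2$stack, segment_cell(g2$stack))
      sums[[d$treatment[g]]] <- c(sums[[d$treatment[g]]], m$raw_int_den)
    }
  }
  expect_equal(mean(sums$CBD) / mean(sums$control), 0.6, tolerance = 0.05)
})

test_that("compare_groups reports one Welch contrast per condition", {
  set.seed(31)
  measures <- data.frame(
    condition = rep(c("LPS", "GP120"), each = 20),
    treatment = rep(rep(c("control", "CBD"), each = 10), 2),
    raw_int_den = c(rnorm(10, 100, 5), rnorm(10, 60, 5),
                    rnorm(10, 100, 5), rnorm(10, 100, 5)))
  cc <- compare_groups(measures)
  expect_equal(nrow(cc$comparisons), 2)
  expect_equal(nrow(cc$group_stats), 4)
  lps <- cc$comparisons[cc$comparisons$condition == "LPS", ]
  expect_lt(lps$p, 0.05)
  expect_lt(lps$mean_treated, lps$mean_control)
  cc2 <- compare_groups(measures, holm = TRUE)
  expect_true("p_holm" %in% names(cc2$comparisons))
})

test_that("compare_groups skips conditions with a missing group", {
  measures <- data.frame(
    condition = c(rep("LPS", 4), rep("GP120", 2)),
    treatment = c("control", "control", "CBD", "CBD", "control", "control"),
    raw_int_den = c(1, 2, 3, 4, 5, 6))
  expect_warning(cc <- compare_groups(measures), "GP120")
  expect_equal(cc$comparisons$condition, "LPS")
})
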