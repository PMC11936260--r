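test_that("z-slicing yields one tagged image per optical section", {
  p <- tiny_scene(n_slices = 20)
  g <- generate_cell_stack(p, two_group_design(1, 1)[1, ], seed = 2,
                           cell_id = "aug")
  slices <- slice_stack(g$stack)
  expect_length(slices, 20) # the twenty-fold augmentation of a 20-slice stack
  expect_equal(vapply(slices, `[[`, integer(1), "z"), 0:19)
  expect_true(all(vapply(slices, `[[`, character(1), "cell_id") == "aug"))
  # round trip: re-stacking the slices reproduces the channel
  rebuilt <- simplify2array(lapply(slices, `[[`, "pixels"))
  expect_identical(rebuilt, g$stack$ros)
  expect_error(slice_stack(g$stack, channel = "dapi"), "unknown channel")

  p1 <- tiny_scene(n_slices = 1)
  s1 <- slice_stack(generate_cell_stack(p1, two_group_design(1, 1)[1, ],
                                        seed = 2)$stack)
  expect_length(s1, 1)
  expect_equal(s1[[1]]$z, 0L)
})

test_that("min-max normalization maps the range onto [0, 255]", {
  img <- matrix(c(0, 255, 128, 64), 2, 2)
  expect_equal(minmax_normalize(img), img) # already full 8-bit range
  img2 <- matrix(c(0, 510, 255, 255), 2, 2)
  out2 <- minmax_normalize(img2)
  expect_equal(out2[1, 1], 0)
  expect_equal(out2[2, 1], 255)
  expect_equal(out2[1, 2], 128) # 127.5 rounds half-to-even to 128
  set.seed(1)
  for (i in 1:20) {
    r <- matrix(runif(64, -100, 10000), 8, 8)
    o <- minmax_normalize(r)
    expect_equal(min(o), 0)
    expect_equal(max(o), 255)
    # affine invariance of the rescaling
    expect_equal(minmax_normalize(r * 3.7 + 11), o)
  }
  expect_warning(z <- minmax_normalize(matrix(5, 3, 3)), "constant")
  expect_true(all(z == 0))
  expect_error(minmax_normalize(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("histogram equalization follows the CDF remapping", {
  img <- matrix(c(0, 0, 255, 255), 2, 2)
  expect_equal(equalize_hist(img), img)
  expect_equal(equalize_hist(matrix(100, 4, 4)), matrix(100, 4, 4))
  # equalization never worsens the Kolmogorov distance to a uniform histogram
  ks_unif <- function(v) {
    cdf <- cumsum(tabulate(as.integer(v) + 1L, 256L)) / length(v)
    max(abs(cdf - (1:256) / 256))
  }
  set.seed(8)
  for (i in 1:20) {
    r <- matrix(pmin(pmax(round(rnorm(4096, 120, 20)), 0), 255), 64, 64)
    e <- equalize_hist(r)
    expect_lte(ks_unif(e), ks_unif(r) + 1e-12)
    # near-idempotence: re-equalizing an equalized image only moves pixels
    # by rounding of an almost-linear CDF
    expect_lte(max(abs(equalize_hist(e) - e)), 2)
  }
  expect_error(equalize_hist(matrix(-1, 2, 2)), "8-bit")
})

test_that("area resize averages exact input regions", {
  img <- matrix(1:16, 4, 4)
  out <- resize_area(img, 2, 2)
  expect_equal(out, matrix(c(mean(img[1:2, 1:2]), mean(img[3:4, 1:2]),
                             mean(img[1:2, 3:4]), mean(img[3:4, 3:4])), 2, 2))
  expect_identical(resize_area(img, 4, 4), img)
  # non-integer factor: total mass is conserved by area weighting
  img2 <- matrix(runif(25), 5, 5)
  out2 <- resize_area(img2, 3, 3)
  expect_equal(mean(out2), mean(img2), tolerance = 1e-12)
})

test_that("preprocess_slice emits 256x256 8-bit images", {
  set.seed(4)
  big <- matrix(runif(1024 * 1024, 0, 4000), 1024, 1024)
  ps <- preprocess_slice(big)
  expect_equal(dim(ps$pixels), c(256, 256))
  expect_gte(min(ps$pixels), 0)
  expect_lte(max(ps$pixels), 255)
  # an already-256 input skips resizing but is still normalized + equalized
  small <- matrix(sample(0:255, 256 * 256, replace = TRUE), 256, 256)
  ps2 <- preprocess_slice(small)
  expect_equal(dim(ps2$pixels), c(256, 256))
  # RGB input collapses by luminance
  rgb <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  expect_equal(dim(preprocess_slice(rgb, out_size = 16)$pixels), c(16, 16))
  # property sweep at reduced size
  for (i in 1:100) {
    r <- matrix(runif(900, -50, 50000), 30, 30)
    o <- preprocess_slice(r, out_size = 16)$pixels
    expect_true(min(o) >= 0 && max(o) <= 255)
  }
})

test_that("split sizes follow largest-remainder apportionment", {
  expect_equal(largest_remainder(100, c(0.72, 0.08, 0.20)), c(72L, 8L, 20L))
  expect_equal(largest_remainder(10, c(0.72, 0.08, 0.20)), c(7L, 1L, 2L))
  expect_error(largest_remainder(10, c(0.5, 0.4)), "sum to 1")

  info <- data.frame(cell_id = paste0("c", 1:100),
                     condition = "LPS", treatment = "control")
  sp <- split_dataset(info, seed = 3, grouping = "by_slice")
  expect_equal(unname(table(sp$partition)), c(72L, 8L, 20L),
               ignore_attr = TRUE)
})

test_that("splits are disjoint, exhaustive and seed-reproducible", {
  info <- benchmark_slices()$info
  sp1 <- split_dataset(info, seed = 10)
  sp2 <- split_dataset(info, seed = 10)
  sp3 <- split_dataset(info, seed = 11)
  expect_false(anyNA(sp1$partition))
  expect_length(sp1$partition, nrow(info))
  expect_identical(sp1$partition, sp2$partition)
  expect_false(identical(sp1$partition, sp3$partition))
})

test_that("by_cell grouping never lets a cell span partitions", {
  info <- benchmark_slices()$info
  sp <- split_dataset(info, seed = 4, grouping = "by_cell")
  per_cell <- tapply(as.character(sp$partition), info$cell_id,
                     function(x) length(unique(x)))
  expect_true(all(per_cell == 1))
  # stratified: both treatments appear in every partition
  tab <- table(sp$partition, info$treatment)
  expect_true(all(tab > 0))
  # a cell larger than the biggest partition cannot be placed
  one <- data.frame(cell_id = rep("c1", 10), condition = "LPS",
                    treatment = "control")
  expect_error(split_dataset(one, fractions = c(0.5, 0.25, 0.25),
                             grouping = "by_cell"),
               "adjust the split")
})
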