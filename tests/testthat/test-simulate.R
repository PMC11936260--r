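test_that("scene and design parameters are validated", {
  expect_error(scene_params(image_size_px = 0), "positive")
  expect_error(scene_params(n_slices = 100), "1, 64")
  expect_error(scene_params(puncta_rate = -1), "puncta_rate")
  expect_error(scene_params(puncta_sigma_um = 30, cell_radius_um = c(10, 12)),
               "puncta wider")
  expect_error(effect_design(cbd_mult = c(0, 1, 1)), "multipliers")
  expect_error(effect_design(n_per_group = -2), "group sizes")
})

test_that("empty signal gives an all-zero ROS channel and zero ground truth", {
  p <- tiny_scene(puncta_rate = 0, ros_diffuse_level = 0,
                  background_level = 0, read_noise_sigma = 0,
                  shot_noise = FALSE)
  g <- generate_cell_stack(p, two_group_design(1, 0.6)[1, ], seed = 11)
  expect_true(all(g$stack$ros == 0))
  expect_identical(g$truth$true_integrated_ros, 0)
})

test_that("generation is a pure function of (params, design, seed)", {
  p <- tiny_scene()
  d <- two_group_design(1, 0.6)[2, ]
  a <- generate_cell_stack(p, d, seed = 5)
  b <- generate_cell_stack(p, d, seed = 5)
  expect_identical(a$stack$actin, b$stack$actin)
  expect_identical(a$stack$ros, b$stack$ros)
  expect_identical(a$truth, b$truth)
  c_ <- generate_cell_stack(p, d, seed = 6)
  expect_false(identical(a$stack$ros, c_$stack$ros))
})

test_that("puncta counts follow the Poisson law of the scene rate", {
  p <- power_scene(puncta_rate = 30)
  d <- two_group_design(1, 1)[1, ]
  counts <- vapply(1:500, function(s) {
    generate_cell_stack(p, d, seed = s)$truth$puncta_count
  }, numeric(1))
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 500))
})

test_that("noiseless integrated ROS is conserved through rendering", {
  p <- tiny_scene(background_level = 0, read_noise_sigma = 0,
                  shot_noise = FALSE)
  g <- generate_cell_stack(p, two_group_design(1, 0.6)[2, ], seed = 3)
  m <- measure_cell(g$stack, g$truth$mask,
                    pixel_size_um = p$pixel_size_um)
  # stored pixels are 16-bit integers, so the sums agree to the half-count
  # quantization bound per masked voxel
  expect_lt(abs(m$raw_int_den - g$truth$true_integrated_ros),
            0.5 * m$n_voxels)
  expect_gt(g$truth$true_integrated_ros, 0)
})

test_that("expected integrated ROS increases strictly with the multiplier", {
  p <- tiny_scene(shot_noise = FALSE, read_noise_sigma = 0)
  vals <- vapply(c(0.5, 1, 1.5), function(m) {
    d <- two_group_design(1, m)[2, ]
    generate_cell_stack(p, d, seed = 17)$truth$true_integrated_ros
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # with a shared seed the whole ROS field scales linearly in m
  expect_equal(vals[3] / vals[1], 3, tolerance = 1e-9)
})

test_that("generate_dataset writes one stack per cell and exact group sizes", {
  out <- withr::local_tempdir()
  p <- power_scene()
  d <- effect_design(n_per_group = 2)
  ds <- generate_dataset(p, d, out, seed = 21)
  expect_equal(nrow(ds$manifest), 12)
  expect_equal(length(list.files(out, pattern = "\\.tif$")), 12)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "ground_truth.json")))
  expect_equal(unname(table(ds$manifest$condition)), c(4L, 4L, 4L),
               ignore_attr = TRUE)

  empty <- generate_dataset(p, effect_design(n_per_group = 0),
                            file.path(out, "empty"), seed = 1)
  expect_equal(nrow(empty$manifest), 0)
  expect_equal(length(list.files(file.path(out, "empty"),
                                 pattern = "\\.tif$")), 0)
})

test_that("ground-truth ROS ratio recovers the CBD effect multiplier", {
  p <- power_scene()
  d <- two_group_design(100, 0.6)
  sums <- list(control = c(), CBD = c())
  seeds <- roscope:::derive_seeds(77, 200)
  i <- 0
  for (g in seq_len(nrow(d))) {
    for (j in seq_len(d$n[g])) {
      i <- i + 1
      tr <- generate_cell_stack(p, d[g, ], seed = seeds[i])$truth
      sums[[d$treatment[g]]] <- c(sums[[d$treatment[g]]],
                                  tr$true_integrated_ros)
    }
  }
  ratio <- mean(sums$CBD) / mean(sums$control)
  expect_equal(ratio, 0.6, tolerance = 0.05)
})

test_that("TIFF round trip preserves both channels", {
  p <- power_scene()
  g <- generate_cell_stack(p, two_group_design(1, 1)[1, ], seed = 9,
                           cell_id = "rt")
  path <- withr::local_tempfile(fileext = ".tif")
  write_zstack(g$stack, path)
  back <- read_zstack(path, pixel_size_um = p$pixel_size_um,
                      z_step_um = p$z_step_um)
  expect_equal(back$actin, g$stack$actin)
  expect_equal(back$ros, g$stack$ros)

  paths <- write_zstack(g$stack, withr::local_tempfile(fileext = ".tif"),
                        layout = "split")
  back2 <- read_zstack(paths)
  expect_equal(back2$ros, g$stack$ros)
})
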