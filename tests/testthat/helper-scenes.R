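# Shared fixtures, built in code. Problem sizes are scaled down so the suite
# stays fast; the scenes keep the generator's structure (cell geometry,
# puncta, noise) at smaller fields.

# Small scene for segmentation/measurement tests.
tiny_scene <- function(...) {
  defaults <- list(image_size_px = 96, n_slices = 6, pixel_size_um = 0.5,
                   cell_radius_um = c(12, 18))
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

# Minimal scene for the repeated-simulation power runs.
power_scene <- function(...) {
  defaults <- list(image_size_px = 48, n_slices = 3, pixel_size_um = 0.5,
                   cell_radius_um = c(6, 9), puncta_sigma_um = 0.5)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

# One LPS-like two-group design row set.
two_group_design <- function(n, m, motif = "peripheral") {
  effect_design(n_per_group = n, conditions = "LPS", baseline_mult = 1,
                cbd_mult = m, motif = motif)
}

# The 400-slice strongly separated treatment dataset (100 cells x 4 slices),
# generated once per test run and reused across files.
.fixture_cache <- new.env(parent = emptyenv())

benchmark_slices <- function() {
  if (is.null(.fixture_cache$bench)) {
    design <- two_group_design(50, 0.5)
    .fixture_cache$bench <- simulate_slice_dataset(design, separable_scene(),
                                                   seed = 1)
  }
  .fixture_cache$bench
}

benchmark_split <- function() {
  if (is.null(.fixture_cache$split)) {
    .fixture_cache$split <- split_dataset(benchmark_slices()$info, seed = 1)
  }
  .fixture_cache$split
}

# A quickly trainable miniature classification problem: dark-noise images vs
# images with a bright central blob, at a reduced input size.
toy_problem <- function(n_neg = 30, n_pos = 30, size = 64, seed = 99) {
  with_seed_local <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed); force(code)
  }
  with_seed_local(seed, {
    n <- n_neg + n_pos
    imgs <- array(sample(0:60, size * size * n, replace = TRUE),
                  c(size, size, n))
    ctr <- size / 2
    blob <- outer(seq_len(size), seq_len(size), function(i, j) {
      200 * exp(-((i - ctr)^2 + (j - ctr)^2) / (2 * (size / 6)^2))
    })
    for (k in seq_len(n_pos)) {
      imgs[, , n_neg + k] <- pmin(imgs[, , n_neg + k] + blob, 255)
    }
    info <- data.frame(
      cell_id = paste0("c", seq_len(n)), z = 0L, condition = "LPS",
      treatment = rep(c("control", "CBD"), c(n_neg, n_pos)),
      stringsAsFactors = FALSE)
    structure(list(images = imgs, info = info), class = "slice_set")
  })
}

toy_spec <- function(n_classes = 2) {
  arch_spec(n_classes = n_classes, conv_filters = c(4, 8),
            kernel_sizes = c(8, 3), pool_size = 3, dropout = 0.2,
            hidden = c(32, 16), input_size = 64)
}

# Mann-Whitney pair-counting AUC oracle (ties count 1/2).
auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}
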