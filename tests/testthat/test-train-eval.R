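test_that("analytic gradients match finite differences", {
  spec <- arch_spec(n_classes = 2, conv_filters = c(2, 3),
                    kernel_sizes = c(5, 3), pool_size = 2, dropout = 0,
                    hidden = c(8, 4), input_size = 20)
  set.seed(3)
  params <- roscope:::init_params(spec)
  x <- array(runif(20 * 20 * 1 * 3), c(20, 20, 1, 3))
  y <- c(1L, 2L, 1L)
  fw <- roscope:::nn_forward(spec, params, x)
  gr <- roscope:::nn_backward(spec, params, x, fw, y)
  loss_at <- function(p) {
    roscope:::cross_entropy(roscope:::nn_forward(spec, p, x)$logits, y)
  }
  eps <- 1e-3
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      # absolute floor covers near-zero gradients; single-precision forward
      # limits the finite-difference accuracy
      expect_lt(abs(gr[[nm]][i] - num), 2e-3 + 0.02 * abs(num))
    }
  }
})

test_that("training configuration is validated", {
  expect_error(train_config(lr = 0), "lr")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(task_levels("dose"), "task")
})

test_that("label/class mismatch is caught before training", {
  slices <- toy_problem(6, 6)
  split <- split_dataset(slices$info, fractions = c(0.6, 0.2, 0.2),
                         seed = 1, grouping = "by_slice")
  expect_error(train_model(build_condition_model(input_size = 64), slices,
                           split, train_config(epochs = 1), task = "treatment"),
               "classes")
})

test_that("the toy problem is learned and evaluated correctly", {
  slices <- toy_problem(60, 40)
  split <- split_dataset(slices$info, fractions = c(0.6, 0.2, 0.2),
                         seed = 2, grouping = "by_slice")
  model <- train_model(toy_spec(), slices, split,
                       train_config(epochs = 15, batch_size = 8, seed = 1),
                       task = "treatment")
  expect_s3_class(model$history, "training_history")
  expect_equal(nrow(model$history), 15)
  report <- evaluate(model, slices, split)
  expect_equal(sum(report$confusion), report$n)
  # rows are true classes: row sums equal per-class test counts
  truth <- slices$info$treatment[split$partition == "test"]
  expect_equal(as.vector(rowSums(report$confusion)),
               as.vector(table(factor(truth, c("control", "CBD")))))
  expect_equal(report$accuracy, 100)
  expect_equal(unname(report$auc["CBD"]), 1)
  # confusion matrix orientation: TN upper-left, TP lower-right
  expect_equal(unname(report$confusion[1, 1]), sum(truth == "control"))
  expect_equal(unname(report$confusion[2, 2]), sum(truth == "CBD"))
})

test_that("reported AUC equals the pair-counting oracle", {
  slices <- toy_problem(25, 25, seed = 123)
  split <- split_dataset(slices$info, fractions = c(0.5, 0.1, 0.4),
                         seed = 5, grouping = "by_slice")
  model <- train_model(toy_spec(), slices, split,
                       train_config(epochs = 1, batch_size = 8, seed = 2),
                       task = "treatment")
  idx <- which(split$partition == "test")
  probs <- predict(model, slices$images[, , idx, drop = FALSE])
  labels <- as.integer(slices$info$treatment[idx] == "CBD")
  report <- evaluate(model, slices, split)
  expect_equal(unname(report$auc["CBD"]), auc_pairs(labels, probs[, "CBD"]),
               tolerance = 1e-10)
  # the oracle itself on the textbook 4-item example
  expect_equal(auc_pairs(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.9)), 0.75)
})

test_that("a single batch can be memorized (capacity sanity check)", {
  bench <- benchmark_slices()
  idx <- c(which(bench$info$treatment == "control")[1:4],
           which(bench$info$treatment == "CBD")[1:4])
  spec <- build_treatment_model()
  set.seed(1)
  params <- roscope:::init_params(spec)
  state <- roscope:::adam_init(params)
  x <- bench$images[, , idx] / 255
  dim(x) <- c(256, 256, 1, 8)
  y <- ifelse(bench$info$treatment[idx] == "CBD", 2L, 1L)
  acc <- 0
  for (ep in seq_len(200)) {
    fw <- roscope:::nn_forward(spec, params, x)
    acc <- mean(max.col(fw$logits, ties.method = "first") == y)
    if (acc == 1) break
    gr <- roscope:::nn_backward(spec, params, x, fw, y)
    upd <- roscope:::adam_step(params, gr, state, 1e-4)
    params <- upd$params; state <- upd$state
  }
  expect_equal(acc, 1)
})

test_that("shuffled labels keep accuracy at chance", {
  bench <- benchmark_slices()
  idx <- seq(1, 400, by = 3) # 134 slices
  sub <- list(images = bench$images[, , idx],
              info = bench$info[idx, , drop = FALSE])
  class(sub) <- "slice_set"
  set.seed(77)
  sub$info$treatment <- sample(sub$info$treatment)
  split <- split_dataset(sub$info, fractions = c(0.55, 0.1, 0.35),
                         seed = 3, grouping = "by_slice")
  model <- train_model(build_treatment_model(), sub, split,
                       train_config(epochs = 3, seed = 4), task = "treatment")
  report <- evaluate(model, sub, split)
  expect_gte(report$accuracy, 35)
  expect_lte(report$accuracy, 65)
})

test_that("training histories are reproducible under a fixed seed", {
  slices <- toy_problem(20, 20)
  split <- split_dataset(slices$info, fractions = c(0.6, 0.2, 0.2),
                         seed = 1, grouping = "by_slice")
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 9)
  m1 <- train_model(toy_spec(), slices, split, cfg, task = "treatment")
  m2 <- train_model(toy_spec(), slices, split, cfg, task = "treatment")
  expect_equal(as.data.frame(m1$history), as.data.frame(m2$history),
               tolerance = 1e-6)
})

test_that("overfit divergence statistics follow the stated rules", {
  h <- data.frame(train_loss = c(1, .8, .6, .5), val_loss = c(1, .8, .6, .5))
  d <- overfit_divergence(h)
  expect_equal(d$final_gap, 0)
  expect_false(d$diverging)
  h2 <- data.frame(train_loss = c(1, .8, .6, .5),
                   val_loss = c(2, 1.8, 1.6, 1.5))
  d2 <- overfit_divergence(h2)
  expect_equal(d2$final_gap, 1)
  expect_false(d2$diverging)
  h3 <- data.frame(train_loss = seq(1, 0.2, length.out = 8),
                   val_loss = c(1, .9, .8, .8, .9, 1.0, 1.1, 1.2))
  expect_true(overfit_divergence(h3)$diverging)
})

test_that("saved models reload with identical predictions", {
  slices <- toy_problem(15, 15)
  split <- split_dataset(slices$info, fractions = c(0.6, 0.2, 0.2),
                         seed = 2, grouping = "by_slice")
  model <- train_model(toy_spec(), slices, split,
                       train_config(epochs = 1, batch_size = 8, seed = 3),
                       task = "treatment")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  p1 <- predict(model, slices$images[, , 1:5])
  p2 <- predict(back, slices$images[, , 1:5])
  expect_equal(p1, p2, tolerance = 1e-12)
})
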