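#' Load and validate a pipeline configuration
#'
#' Configurations are YAML with sections `scene` (passed to
#' [scene_params()]), `design` (passed to [effect_design()]), `split`
#' (`fractions`, `grouping`), `train` (passed to [train_config()]), plus
#' top-level `task` (`"treatment"` or `"condition"`), `seed` and `out_size`.
#' Every constant of the method (learning rate 0.0001, dropout 0.20, pool 5,
#' kernels 16/5, 256-pixel input, 0.72/0.08/0.20 split, 10 epochs) is an
#' explicit, defaulted key, so fidelity-vs-variant runs are visible in the
#' config. Validation happens before any computation.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A validated `run_config` list.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg$seed <- cfg$seed %||% 1L
  cfg$task <- cfg$task %||% "treatment"
  cfg$out_size <- cfg$out_size %||% 256L
  if (!cfg$task %in% c("treatment", "condition")) {
    stop("task must be 'treatment' or 'condition'", call. = FALSE)
  }
  cfg$scene <- do.call(scene_params, cfg$scene %||% list())
  cfg$design <- do.call(effect_design, cfg$design %||% list())
  split <- cfg$split %||% list()
  cfg$split_fractions <- as.numeric(split$fractions %||% c(0.72, 0.08, 0.20))
  if (length(cfg$split_fractions) != 3 ||
      abs(sum(cfg$split_fractions) - 1) > 1e-9 ||
      any(cfg$split_fractions < 0)) {
    stop("split fractions must be 3 nonnegative numbers summing to 1",
         call. = FALSE)
  }
  if (any(cfg$split_fractions[c(1, 3)] == 0)) {
    stop("train and test fractions must be positive", call. = FALSE)
  }
  cfg$split_grouping <- split$grouping %||% "by_cell"
  cfg$train <- do.call(train_config, c(cfg$train %||% list(),
                                       list(seed = cfg$seed)))
  structure(cfg, class = "run_config")
}

#' Run the full pipeline from one seeded configuration
#'
#' Chains simulate -> quantify -> preprocess -> split -> train -> evaluate ->
#' explain, writing every artifact class into `out_dir`: the dataset
#' (`data/` with manifest and ground truth), `measures.csv`,
#' `comparisons.csv`, `group_stats.csv`, `slices.csv` (per-slice labels and
#' partition), `history.csv`, `eval.json`, `roc.csv`, `saliency.csv`,
#' `model.json`, PNG plots, and `run.json` capturing the configuration and
#' package version for provenance. A stage failure aborts with the failing
#' stage named; artifacts of completed stages are retained.
#'
#' @param config A `run_config` (or a path/list accepted by [run_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main in-memory results (manifest,
#'   measures, comparisons, model, eval report, saliency table, paths).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  data_dir <- file.path(out_dir, "data")
  ds <- stage("simulate",
              generate_dataset(cfg$scene, cfg$design, data_dir,
                               seed = cfg$seed))

  measures <- stage("quantify", {
    m <- quantify_dataset(data_dir, manifest = ds$manifest,
                          pixel_size_um = cfg$scene$pixel_size_um,
                          z_step_um = cfg$scene$z_step_um)
    write.csv(m, file.path(out_dir, "measures.csv"), row.names = FALSE)
    m
  })
  comps <- stage("compare", {
    cc <- compare_groups(measures)
    if (!is.null(cc$comparisons)) {
      write.csv(cc$comparisons, file.path(out_dir, "comparisons.csv"),
                row.names = FALSE)
    }
    if (!is.null(cc$group_stats)) {
      write.csv(cc$group_stats, file.path(out_dir, "group_stats.csv"),
                row.names = FALSE)
    }
    cc
  })

  slices <- stage("preprocess",
                  preprocess_dataset(data_dir, manifest = ds$manifest,
                                     out_size = cfg$out_size,
                                     pixel_size_um = cfg$scene$pixel_size_um,
                                     z_step_um = cfg$scene$z_step_um))
  split <- stage("split",
                 split_dataset(slices$info, fractions = cfg$split_fractions,
                               seed = cfg$seed,
                               grouping = cfg$split_grouping))
  stage("slices.csv", {
    info <- cbind(slices$info, partition = split$partition)
    write.csv(info, file.path(out_dir, "slices.csv"), row.names = FALSE)
  })

  spec <- if (cfg$task == "treatment") build_treatment_model(
    input_size = cfg$out_size) else build_condition_model(
      input_size = cfg$out_size)
  cfg$train$eval_test <- TRUE
  model <- stage("train", train_model(spec, slices, split, cfg$train,
                                      task = cfg$task))
  stage("history.csv",
        write.csv(as.data.frame(model$history),
                  file.path(out_dir, "history.csv"), row.names = FALSE))
  report <- stage("evaluate", evaluate(model, slices, split))
  stage("eval.json", {
    jsonlite::write_json(list(
      accuracy = report$accuracy,
      confusion = as.data.frame(report$confusion),
      auc = as.list(report$auc), macro_auc = report$macro_auc,
      n = report$n), file.path(out_dir, "eval.json"),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(report$roc)) {
      write.csv(report$roc, file.path(out_dir, "roc.csv"), row.names = FALSE)
    }
  })
  stage("model.json", save_model(model, file.path(out_dir, "model.json")))

  sal <- stage("explain", {
    idx <- which(split$partition == "test")
    idx <- idx[seq_len(min(8, length(idx)))]
    sub <- list(images = slices$images[, , idx, drop = FALSE],
                info = slices$info[idx, , drop = FALSE])
    class(sub) <- "slice_set"
    st <- saliency_table(model, sub)
    write.csv(st, file.path(out_dir, "saliency.csv"), row.names = FALSE)
    st
  })

  stage("plots", {
    grDevices::png(file.path(out_dir, "loss_curves.png"), 700, 500)
    print(plot_history(model$history, "loss"))
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "accuracy_curves.png"), 700, 500)
    print(plot_history(model$history, "accuracy"))
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "confusion.png"), 600, 500)
    print(plot_confusion(report))
    grDevices::dev.off()
  })

  stage("run.json", jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("roscope")),
    r_version = R.version.string,
    seed = cfg$seed, task = cfg$task,
    scene = unclass(cfg$scene),
    design = as.data.frame(unclass(cfg$design)),
    split = list(fractions = cfg$split_fractions,
                 grouping = cfg$split_grouping),
    train = unclass(cfg$train)
  ), file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA))

  invisible(list(manifest = ds$manifest, truth = ds$truth,
                 measures = measures, comparisons = comps, slices = slices,
                 split = split, model = model, report = report,
                 saliency = sal, out_dir = out_dir))
}
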