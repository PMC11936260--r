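#' Outline the cell from the actin channel
#'
#' Segments the single imaged cell: the actin channel is max-projected along
#' z, thresholded (Otsu by default, or a fixed value), morphologically closed
#' (disc radius 2 px), reduced to its largest connected component, and
#' hole-filled. The resulting 2-D footprint is replicated across all slices
#' to form the boolean measurement volume; the footprint is guaranteed to be
#' a single connected component.
#'
#' @param stack A [zstack()] or a numeric (H, W, Z) actin volume.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Threshold on raw counts, required for `method = "fixed"`.
#' @param pixel_size_um Lateral calibration; taken from the stack if present.
#' @return An object of class `cell_mask`: `volume` (boolean H x W x Z),
#'   `footprint` (boolean H x W), `area_px`, `area_um2`.
#' @export
segment_cell <- function(stack, method = c("otsu", "fixed"), threshold = NULL,
                         pixel_size_um = NULL) {
  method <- match.arg(method)
  if (inherits(stack, "zstack")) {
    vol <- stack$actin
    if (is.null(pixel_size_um)) pixel_size_um <- stack$pixel_size_um
  } else {
    vol <- stack
    if (is.null(pixel_size_um)) pixel_size_um <- 1
  }
  if (length(vol) == 0) stop("actin channel is empty", call. = FALSE)
  if (length(dim(vol)) == 2L) vol <- array(vol, c(dim(vol), 1L))
  proj <- max_project(vol)
  rng <- range(proj)
  if (method == "otsu") {
    if (rng[2] <= rng[1]) stop("no cell found: constant actin channel",
                               call. = FALSE)
    scaled <- (proj - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    bin <- scaled > th
  } else {
    if (is.null(threshold)) stop("fixed method needs `threshold`", call. = FALSE)
    bin <- proj > threshold
  }
  if (!any(bin)) stop("no cell found: nothing above threshold", call. = FALSE)
  brush <- EBImage::makeBrush(5, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(bin * 1), brush)
  labels <- EBImage::bwlabel(closed)
  tab <- tabulate(as.integer(labels))
  if (length(tab) == 0 || max(tab) == 0) {
    stop("no cell found: no connected component", call. = FALSE)
  }
  footprint <- EBImage::fillHull(labels == which.max(tab))
  footprint <- matrix(as.logical(footprint), nrow(proj), ncol(proj))
  structure(list(
    volume = array(footprint, dim(vol)),
    footprint = footprint,
    area_px = sum(footprint),
    area_um2 = sum(footprint) * pixel_size_um^2
  ), class = "cell_mask")
}

#' Per-cell ROS measures with ImageJ semantics
#'
#' Computes the five per-cell quantities over the masked voxels of the ROS
#' channel: `mean` and `max` pixel intensity, `raw_int_den` (sum of pixel
#' intensities), `area_um2` (2-D footprint area times the squared pixel
#' size), and `int_den` (mean times `area_um2`, the ImageJ integrated
#' density). `mean` and `max` are per-volume statistics: for a single-slice
#' mask they coincide with the 2-D definitions and
#' `raw_int_den == mean * area_px` exactly.
#'
#' @param stack A [zstack()] or a numeric ROS volume/matrix.
#' @param mask A `cell_mask` from [segment_cell()], or a boolean array
#'   aligned to the channel.
#' @param pixel_size_um Lateral calibration; taken from the stack if present.
#' @return A one-row data frame: area_px, area_um2, mean, max, int_den,
#'   raw_int_den, n_voxels.
#' @export
measure_cell <- function(stack, mask, pixel_size_um = NULL) {
  if (inherits(stack, "zstack")) {
    vol <- stack$ros
    if (is.null(pixel_size_um)) pixel_size_um <- stack$pixel_size_um
  } else {
    vol <- stack
    if (is.null(pixel_size_um)) pixel_size_um <- 1
  }
  if (length(dim(vol)) < 2L || is.null(dim(vol))) vol <- as.matrix(vol)
  if (inherits(mask, "cell_mask")) {
    mvol <- mask$volume
    area_px <- mask$area_px
    area_um2 <- mask$area_um2
  } else {
    mvol <- mask
    fp <- max_project(mvol * 1) > 0
    area_px <- sum(fp)
    area_um2 <- area_px * pixel_size_um^2
  }
  if (length(dim(vol)) == 2L) dim(vol) <- c(dim(vol), 1L)
  if (length(dim(mvol)) == 2L) dim(mvol) <- c(dim(mvol), 1L)
  if (!identical(dim(vol), dim(mvol))) {
    stop("mask is not aligned to the channel", call. = FALSE)
  }
  vals <- vol[mvol]
  if (length(vals) == 0) stop("empty mask", call. = FALSE)
  m <- mean(vals)
  data.frame(area_px = area_px, area_um2 = area_um2, mean = m,
             max = max(vals), int_den = m * area_um2,
             raw_int_den = sum(vals), n_voxels = length(vals))
}

#' Segment and measure one stack
#'
#' Convenience wrapper: [segment_cell()] then [measure_cell()].
#'
#' @inheritParams segment_cell
#' @return The [measure_cell()] row with the cell id prepended.
#' @export
quantify_stack <- function(stack, method = "otsu", threshold = NULL) {
  mask <- segment_cell(stack, method = method, threshold = threshold)
  cbind(data.frame(cell_id = stack$cell_id, stringsAsFactors = FALSE),
        measure_cell(stack, mask))
}

#' Quantify every cell of a dataset on disk
#'
#' Reads each stack listed in a manifest (as written by
#' [generate_dataset()]), segments it and computes its measures.
#'
#' @param dir Dataset directory containing the TIFFs and `manifest.csv`.
#' @param manifest Optional manifest data frame (read from `dir` if missing).
#' @param pixel_size_um,z_step_um Calibration used when reading.
#' @param method,threshold Passed to [segment_cell()].
#' @return A data frame with one row per cell: labels plus measures.
#' @export
quantify_dataset <- function(dir, manifest = NULL, pixel_size_um = 0.25,
                             z_step_um = 0.5, method = "otsu",
                             threshold = NULL) {
  if (is.null(manifest)) {
    manifest <- read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    st <- read_zstack(file.path(dir, manifest$path[i]),
                      pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                      cell_id = manifest$cell_id[i])
    cbind(manifest[i, c("cell_id", "condition", "treatment")],
          measure_cell(st, segment_cell(st, method = method,
                                        threshold = threshold)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Welch's two-sample t-test (two-tailed)
#'
#' The unequal-variance two-sample comparison used for all group contrasts:
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch–Satterthwaite degrees of freedom and a two-tailed p-value from
#' Student's t distribution. When both variances are zero and the means are
#' equal, `p = 1` by convention (documented degenerate case).
#'
#' @param a,b Numeric vectors of at least 2 finite observations each.
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `group_comparison`: group labels, sizes, means,
#'   variances, `t`, `df`, two-tailed `p`, and significance `stars`
#'   (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#' @examples
#' welch_test(c(10, 11, 12), c(1, 2, 3))  # t = 9 / sqrt(2/3), df = 4
#' @export
welch_test <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("observations must be finite", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  delta <- mean(a) - mean(b)
  if (se2 == 0) {
    tt <- if (delta == 0) 0 else sign(delta) * Inf
    df <- na + nb - 2
    p <- if (delta == 0) 1 else 0
  } else {
    tt <- delta / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  structure(list(
    labels = labels, n_a = na, n_b = nb,
    mean_a = mean(a), mean_b = mean(b), var_a = va, var_b = vb,
    t = tt, df = df, p = p, stars = p_stars(p)
  ), class = "group_comparison")
}

# Significance stars: * p < 0.05, ** p < 0.01, *** p < 0.001.
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch t-test %s vs %s: t = %.4f, df = %.2f, p = %.3g %s\n",
              x$labels[1], x$labels[2], x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' Compare CBD vs control per condition
#'
#' For each condition present in the measures table, runs [welch_test()] on
#' the chosen measure between its two treatment groups (control vs CBD) and
#' collects group summaries (mean, SEM) for bar-chart export. Conditions with
#' a missing or undersized group are listed and skipped with a warning.
#'
#' @param measures Data frame with columns condition, treatment and the
#'   measure (e.g. from [quantify_dataset()]).
#' @param measure Measure column to compare (default `"raw_int_den"`).
#' @param treatments Length-2 vector: reference (control) then treated group.
#' @param holm If `TRUE`, adds Holm-adjusted p-values across conditions
#'   (off by default; the per-measure contrasts are reported unadjusted).
#' @return A list with `comparisons` (one row per condition: t, df, p, stars)
#'   and `group_stats` (per condition x treatment: n, mean, sem).
#' @export
compare_groups <- function(measures, measure = "raw_int_den",
                           treatments = c("control", "CBD"), holm = FALSE) {
  stopifnot(measure %in% names(measures))
  conds <- unique(measures$condition)
  comp <- list(); gs <- list(); skipped <- character()
  for (cond in conds) {
    sub <- measures[measures$condition == cond, ]
    x_ctl <- sub[[measure]][sub$treatment == treatments[1]]
    x_trt <- sub[[measure]][sub$treatment == treatments[2]]
    for (tr in treatments) {
      v <- sub[[measure]][sub$treatment == tr]
      if (length(v)) {
        gs[[paste(cond, tr)]] <- data.frame(
          condition = cond, treatment = tr, n = length(v), mean = mean(v),
          sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    if (length(x_ctl) < 2 || length(x_trt) < 2) {
      skipped <- c(skipped, cond)
      next
    }
    w <- welch_test(x_trt, x_ctl, labels = rev(treatments))
    comp[[cond]] <- data.frame(
      condition = cond, measure = measure, n_control = length(x_ctl),
      n_treated = length(x_trt), mean_control = mean(x_ctl),
      mean_treated = mean(x_trt), t = w$t, df = w$df, p = w$p,
      stars = w$stars, stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("skipped conditions with a missing or undersized group: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  comparisons <- if (length(comp)) do.call(rbind, comp) else NULL
  if (holm && !is.null(comparisons)) {
    comparisons$p_holm <- stats::p.adjust(comparisons$p, method = "holm")
  }
  if (!is.null(comparisons)) rownames(comparisons) <- NULL
  group_stats <- if (length(gs)) do.call(rbind, gs) else NULL
  if (!is.null(group_stats)) rownames(group_stats) <- NULL
  list(comparisons = comparisons, group_stats = group_stats)
}
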