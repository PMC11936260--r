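#' Split a z-stack into 2-D slices (z-slice augmentation)
#'
#' The augmentation strategy: every optical section of a stack becomes an
#' independent 2-D image, giving roughly a twenty-fold increase in training
#' data for an 18-20-slice acquisition. Order is preserved and each slice is
#' tagged with its z index and parent cell.
#'
#' @param stack A [zstack()].
#' @param channel `"ros"` (default) or `"actin"`.
#' @return A list of `raw_slice` records: `pixels` (matrix), `z` (0-based),
#'   `cell_id`.
#' @export
slice_stack <- function(stack, channel = "ros") {
  if (!channel %in% c("ros", "actin")) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  vol <- stack[[channel]]
  if (length(vol) == 0) stop("stack is empty", call. = FALSE)
  lapply(seq_len(dim(vol)[3]), function(z) {
    structure(list(pixels = vol[, , z], z = z - 1L, cell_id = stack$cell_id),
              class = "raw_slice")
  })
}

#' Min-max intensity normalization to 8-bit
#'
#' Rescales pixel values to `(v - min) / (max - min) * 255`, rounded
#' half-to-even and clipped to `[0, 255]`; the minimum maps to 0 and the
#' maximum to 255. A constant image cannot be rescaled and becomes all zeros
#' with a warning.
#'
#' @param img Numeric matrix of finite pixel values.
#' @return Matrix of integers in `[0, 255]`.
#' @export
minmax_normalize <- function(img) {
  if (!all(is.finite(img))) stop("pixels must be finite", call. = FALSE)
  rng <- range(img)
  if (rng[2] == rng[1]) {
    warning("constant image: normalization returns all zeros", call. = FALSE)
    return(array(0, dim(img)))
  }
  out <- round((img - rng[1]) / (rng[2] - rng[1]) * 255)
  pmin(pmax(out, 0), 255)
}

#' Histogram equalization of an 8-bit image
#'
#' Classic CDF remapping: `out(v) = round((cdf(v) - cdf_min) /
#' (N - cdf_min) * 255)`, where `cdf` is the cumulative pixel-count
#' histogram over the 256 intensity bins and `cdf_min` its smallest nonzero
#' value. Spreads intensities across the full 8-bit range; deterministic; a
#' constant image maps to a constant.
#'
#' @param img Matrix of integers in `[0, 255]`.
#' @return Equalized matrix of integers in `[0, 255]`.
#' @export
equalize_hist <- function(img) {
  v <- as.integer(img)
  if (min(v) < 0 || max(v) > 255) {
    stop("equalize_hist expects 8-bit input in [0, 255]", call. = FALSE)
  }
  counts <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  n <- length(v)
  cdf_min <- min(cdf[cdf > 0])
  if (n == cdf_min) return(img) # single occupied bin: constant image
  lut <- round((cdf - cdf_min) / (n - cdf_min) * 255)
  lut <- pmin(pmax(lut, 0), 255)
  out <- lut[v + 1L]
  array(out, dim(img))
}

#' Area-interpolation resize
#'
#' Downscales (or upscales) a matrix by exact area averaging: each output
#' pixel is the mean of the input region it covers, with fractional overlap
#' weights at region edges. Anti-aliasing by construction; for an integer
#' downscale factor this is plain block averaging, and resizing to the input
#' size is the identity.
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Output dimensions.
#' @return `out_h` x `out_w` numeric matrix.
#' @export
resize_area <- function(img, out_h, out_w = out_h) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  overlap <- function(n_in, n_out) {
    # weight matrix W (n_out x n_in): W[i, j] = |out cell i  ∩ in cell j| / cell width
    scale <- n_in / n_out
    M <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      lo <- (i - 1) * scale; hi <- i * scale
      j0 <- floor(lo) + 1; j1 <- ceiling(hi)
      for (j in j0:min(j1, n_in)) {
        M[i, j] <- max(0, min(hi, j) - max(lo, j - 1))
      }
    }
    M / scale
  }
  Ry <- overlap(h, out_h)
  Rx <- overlap(w, out_w)
  Ry %*% img %*% t(Rx)
}

#' Preprocess one slice for the classifier
#'
#' Applies, in order: min-max normalization to 8-bit ([minmax_normalize()]),
#' grayscale collapse (a single fluorescence channel passes through; RGB
#' arrays collapse by luminance weights 0.299/0.587/0.114), area-interpolation
#' resize to `out_size` x `out_size` ([resize_area()], re-rounded to 8-bit),
#' and histogram equalization ([equalize_hist()]).
#'
#' @param slice A `raw_slice` from [slice_stack()], or a numeric matrix /
#'   RGB array.
#' @param out_size Output side length in pixels (default 256).
#' @param condition,treatment Optional labels to attach.
#' @return An object of class `processed_slice`: `pixels` (`out_size` square
#'   integer matrix in `[0, 255]`), labels, `cell_id`, `z`.
#' @export
preprocess_slice <- function(slice, out_size = 256, condition = NA_character_,
                             treatment = NA_character_) {
  if (inherits(slice, "raw_slice")) {
    px <- slice$pixels; cell_id <- slice$cell_id; z <- slice$z
  } else {
    px <- slice; cell_id <- NA_character_; z <- NA_integer_
  }
  if (length(dim(px)) == 3L) { # RGB -> luminance
    px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  }
  if (length(dim(px)) != 2L) stop("slice must be a 2-d image", call. = FALSE)
  px <- minmax_normalize(px)
  px <- resize_area(px, out_size, out_size)
  px <- pmin(pmax(round(px), 0), 255)
  px <- equalize_hist(px)
  structure(list(pixels = px, condition = condition, treatment = treatment,
                 cell_id = cell_id, z = z),
            class = "processed_slice")
}

#' Bundle processed slices into a training-ready set
#'
#' @param slices List of `processed_slice` objects.
#' @return An object of class `slice_set`: `images` (H x W x N array of
#'   8-bit values) and `info` (data frame: cell_id, z, condition, treatment).
#' @export
slice_set <- function(slices) {
  stopifnot(length(slices) > 0)
  d <- dim(slices[[1]]$pixels)
  images <- array(0, c(d, length(slices)))
  for (i in seq_along(slices)) images[, , i] <- slices[[i]]$pixels
  info <- do.call(rbind, lapply(slices, function(s) {
    data.frame(cell_id = s$cell_id, z = s$z, condition = s$condition,
               treatment = s$treatment, stringsAsFactors = FALSE)
  }))
  structure(list(images = images, info = info), class = "slice_set")
}

#' Train/validation/test split
#'
#' Assigns slices to train/val/test partitions with sizes given by
#' largest-remainder apportionment of the fractions, stratified by
#' (condition, treatment). Under `grouping = "by_cell"` (the default,
#' preventing leakage of slices from one cell across partitions) whole cells
#' are allocated greedily — each cell, in seeded random order, goes to the
#' partition with the largest remaining deficit; `"by_slice"` splits at the
#' slice level.
#'
#' @param info Data frame with one row per slice: `cell_id` plus the
#'   stratification labels (`condition`, `treatment` when present).
#' @param fractions Length-3 train/val/test fractions summing to 1
#'   (default `c(0.72, 0.08, 0.20)`).
#' @param seed Integer seed for the shuffles.
#' @param grouping `"by_cell"` or `"by_slice"`.
#' @return An object of class `dataset_split`: `partition` (factor
#'   train/val/test per slice row), plus the fractions, seed and grouping.
#' @export
split_dataset <- function(info, fractions = c(0.72, 0.08, 0.20), seed = 1,
                          grouping = c("by_cell", "by_slice")) {
  grouping <- match.arg(grouping)
  if (inherits(info, "slice_set")) info <- info$info
  stopifnot(is.data.frame(info), "cell_id" %in% names(info))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  parts <- c("train", "val", "test")
  strata <- interaction(
    if ("condition" %in% names(info)) info$condition else "all",
    if ("treatment" %in% names(info)) info$treatment else "all",
    drop = TRUE)
  partition <- rep(NA_character_, nrow(info))
  with_seed(seed, {
    for (st in levels(strata)) {
      idx <- which(strata == st)
      target <- largest_remainder(length(idx), fractions)
      if (grouping == "by_slice") {
        shuffled <- sample(idx)
        partition[shuffled] <- rep(parts, times = target)
      } else {
        cells <- unique(info$cell_id[idx])
        cells <- sample(cells)
        sizes <- vapply(cells, function(cl) {
          sum(info$cell_id[idx] == cl)
        }, integer(1))
        if (max(sizes) > max(target)) {
          stop("a cell has more slices (", max(sizes), ") than the largest ",
               "partition can hold (", max(target), "); adjust the split ",
               "fractions", call. = FALSE)
        }
        deficit <- as.numeric(target)
        for (ci in seq_along(cells)) {
          k <- which.max(deficit)
          partition[idx][info$cell_id[idx] == cells[ci]] <- parts[k]
          deficit[k] <- deficit[k] - sizes[ci]
        }
      }
    }
  })
  structure(list(partition = factor(partition, levels = parts),
                 fractions = fractions, seed = seed, grouping = grouping),
            class = "dataset_split")
}

#' Preprocess a generated dataset into labelled slices
#'
#' Convenience path from the generator to the classifier: for each manifest
#' entry, reads (or takes) the stack, slices the requested channel, and
#' preprocesses every slice.
#'
#' @param stacks List of [zstack()] objects, or a dataset directory written
#'   by [generate_dataset()].
#' @param manifest Manifest data frame (required when `stacks` is a list;
#'   read from the directory otherwise).
#' @param channel Channel to use (default `"ros"`).
#' @param out_size Output side length (default 256).
#' @param pixel_size_um,z_step_um Calibration when reading from disk.
#' @return A [slice_set()].
#' @export
preprocess_dataset <- function(stacks, manifest = NULL, channel = "ros",
                               out_size = 256, pixel_size_um = 0.25,
                               z_step_um = 0.5) {
  if (is.character(stacks)) {
    dir <- stacks
    if (is.null(manifest)) {
      manifest <- read.csv(file.path(dir, "manifest.csv"),
                           stringsAsFactors = FALSE)
    }
    stacks <- lapply(seq_len(nrow(manifest)), function(i) {
      read_zstack(file.path(dir, manifest$path[i]),
                  pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                  cell_id = manifest$cell_id[i])
    })
  }
  stopifnot(!is.null(manifest), length(stacks) == nrow(manifest))
  out <- list()
  for (i in seq_along(stacks)) {
    raw <- slice_stack(stacks[[i]], channel = channel)
    out <- c(out, lapply(raw, preprocess_slice, out_size = out_size,
                         condition = manifest$condition[i],
                         treatment = manifest$treatment[i]))
  }
  slice_set(out)
}
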