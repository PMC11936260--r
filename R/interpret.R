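#' Grad-CAM saliency map
#'
#' Gradient-weighted class activation mapping on a trained classifier. The
#' gradient of the chosen class's pre-softmax logit is backpropagated to the
#' post-ReLU activation maps of the requested convolutional layer; each
#' channel is weighted by the spatial average of its gradient, the weighted
#' sum is rectified, bilinearly upsampled to the input grid, and divided by
#' its maximum (unless identically zero).
#'
#' @param model A trained `ros_cnn`.
#' @param slice A `processed_slice` or an 8-bit image matrix matching the
#'   model's input size.
#' @param target_class Class label (or index) whose logit is explained;
#'   defaults to the predicted class.
#' @param layer `"conv2"` (default, the last convolutional layer) or
#'   `"conv1"`; any other layer is rejected.
#' @param use_best Use the best-validation checkpoint.
#' @return An object of class `saliency_map`: `map` (input-size matrix in
#'   `[0, 1]`), `raw_map` (conv-grid map before upsampling), `weights`,
#'   `target_class`, `layer`.
#' @export
grad_cam <- function(model, slice, target_class = NULL, layer = "conv2",
                     use_best = FALSE) {
  stopifnot(inherits(model, "ros_cnn"))
  if (!layer %in% c("conv1", "conv2")) {
    stop("Grad-CAM requires a convolutional layer ('conv1' or 'conv2'), got ",
         layer, call. = FALSE)
  }
  px <- if (inherits(slice, "processed_slice")) slice$pixels else slice
  spec <- model$spec
  params <- if (use_best) model$best_params else model$params
  sz <- spec$input_size
  stopifnot(nrow(px) == sz, ncol(px) == sz)
  x <- array(scale_input(px), c(sz, sz, 1L, 1L))
  fw <- nn_forward(spec, params, x, training = FALSE, want_act = TRUE)

  if (is.null(target_class)) {
    target_class <- which.max(fw$logits[1, ])
  } else if (is.character(target_class)) {
    target_class <- match(target_class, model$levels)
    if (is.na(target_class)) stop("unknown target class", call. = FALSE)
  }
  # backprop d(logit_target) through the linear stack
  n_lin <- length(spec$hidden) + 1L
  dz <- matrix(0, 1, spec$n_classes)
  dz[1, target_class] <- 1
  for (i in rev(seq_len(n_lin))) {
    if (i > 1) {
      da <- dz %*% t(params[[paste0("Wf", i)]])
      dz <- da * (fw$zs[[i - 1]] > 0)
    }
  }
  dflat <- dz %*% t(params$Wf1)
  dpool2 <- array(t(dflat), fw$flat_dim)
  # scatter pooled gradients back to the conv activation grid via the
  # recorded argmax positions (gradient of max-pooling)
  scatter <- function(dpool, argmax, ho, wo) {
    k <- dim(dpool)[3]
    dact <- array(0, c(ho, wo, k))
    for (f in seq_len(k)) {
      ops <- as.vector(argmax[, , f, 1])
      vals <- as.vector(dpool[, , f, 1])
      iy <- ops %% ho + 1L
      ix <- ops %/% ho + 1L
      dact[cbind(iy, ix, f)] <- dact[cbind(iy, ix, f)] + vals
    }
    dact
  }
  if (layer == "conv2") {
    act <- fw$l2$act[, , , 1, drop = FALSE]
    d_ <- dim(act)
    dact <- scatter(dpool2, fw$l2$argmax, d_[1], d_[2])
    A <- array(act, d_[1:3])
  } else {
    bk2 <- .conv_relu_pool_bwd(fw$h1d, params$W2, dpool2, fw$l2$argmax,
                               fw$l2$out, as.integer(spec$kernel_sizes[2]),
                               as.integer(spec$pool_size), TRUE)
    act <- fw$l1$act[, , , 1, drop = FALSE]
    d_ <- dim(act)
    dact <- scatter(bk2$dx, fw$l1$argmax, d_[1], d_[2])
    A <- array(act, d_[1:3])
  }
  w <- apply(dact, 3, mean) # channel weights: spatially averaged gradients
  raw <- matrix(0, d_[1], d_[2])
  for (f in seq_along(w)) raw <- raw + w[f] * A[, , f]
  raw <- pmax(raw, 0)
  map <- bilinear_resize(raw, sz, sz)
  map <- pmax(map, 0)
  mx <- max(map)
  if (mx > 0) map <- map / mx
  structure(list(map = map, raw_map = raw, weights = w,
                 target_class = model$levels[target_class], layer = layer),
            class = "saliency_map")
}

#' Fraction of saliency mass at the cell edge
#'
#' Quantifies edge-localized saliency: the fraction of total saliency lying
#' within `band_px` of the cell boundary. The mask footprint is resized
#' (nearest-neighbour) to the map grid and the band is the set difference
#' between its dilation and erosion by a disc of radius `band_px`.
#'
#' @param map A `saliency_map` (or a nonnegative matrix).
#' @param mask A `cell_mask` (or a logical footprint matrix).
#' @param band_px Band half-width in map pixels (default 8, about 3% of a
#'   256-pixel frame).
#' @return Fraction in `[0, 1]`; an identically-zero map returns 0 with a
#'   warning.
#' @export
edge_saliency_fraction <- function(map, mask, band_px = 8) {
  m <- if (inherits(map, "saliency_map")) map$map else map
  fp <- if (inherits(mask, "cell_mask")) mask$footprint else mask
  if (!any(fp)) stop("empty mask", call. = FALSE)
  if (!all(dim(fp) == dim(m))) {
    # nearest-neighbour resize of the footprint to the map grid
    ys <- pmin(pmax(ceiling(seq_len(nrow(m)) * nrow(fp) / nrow(m)), 1), nrow(fp))
    xs <- pmin(pmax(ceiling(seq_len(ncol(m)) * ncol(fp) / ncol(m)), 1), ncol(fp))
    fp <- fp[ys, xs]
  }
  total <- sum(m)
  if (total <= 0) {
    warning("zero saliency map: edge fraction defined as 0", call. = FALSE)
    return(0)
  }
  brush <- EBImage::makeBrush(2 * band_px + 1, shape = "disc")
  img <- EBImage::Image(fp * 1)
  band <- (EBImage::dilate(img, brush) > 0.5) & !(EBImage::erode(img, brush) > 0.5)
  band <- matrix(as.logical(band), nrow(fp), ncol(fp))
  sum(m[band]) / total
}

#' Saliency table for a set of slices
#'
#' Runs Grad-CAM on each slice, records the explained class and the edge
#' saliency fraction against the supplied footprints.
#'
#' @param model A trained `ros_cnn`.
#' @param slices A [slice_set()].
#' @param masks Named list of `cell_mask` objects (by `cell_id`), or `NULL`
#'   to skip edge fractions.
#' @param band_px Passed to [edge_saliency_fraction()].
#' @return Data frame: cell_id, z, target_class, edge_fraction.
#' @export
saliency_table <- function(model, slices, masks = NULL, band_px = 8) {
  n <- dim(slices$images)[3]
  rows <- lapply(seq_len(n), function(i) {
    sm <- grad_cam(model, slices$images[, , i])
    ef <- NA_real_
    cid <- slices$info$cell_id[i]
    if (!is.null(masks) && !is.null(masks[[cid]])) {
      ef <- edge_saliency_fraction(sm, masks[[cid]], band_px = band_px)
    }
    data.frame(cell_id = cid, z = slices$info$z[i],
               target_class = sm$target_class, edge_fraction = ef,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
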