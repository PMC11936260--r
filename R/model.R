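#' Architecture of the compact ROS classifier
#'
#' Declarative description of the CNN family used for both classification
#' tasks: two convolutional layers and three linear layers. The default
#' geometry is fixed by its printed shape chain — conv(8 filters, kernel 16)
#' on a 256 x 256 input, 5 x 5 max pooling (stride = size) and 0.20 dropout
#' give an 8 x 48 x 48 input to conv2 (16 filters, kernel 5), whose pooled
#' output flattens to a 1024-vector reduced by the linear stack to the class
#' scores (softmax at inference). Convolutions are unpadded with stride 1 and
#' pooling uses floor division; any padding would break the printed shapes.
#'
#' @param n_classes Number of output classes, 2 (treatment) or 3 (condition).
#' @param conv_filters Length-2 filter counts (default `c(8, 16)`).
#' @param kernel_sizes Length-2 kernel sizes (default `c(16, 5)`).
#' @param pool_size Max-pool window (default 5, stride = size).
#' @param dropout Dropout probability after the first pool (default 0.20).
#' @param hidden Widths of the first two linear layers (default
#'   `c(256, 64)`); the third linear layer always has `n_classes` outputs.
#' @param input_size Input side length (default 256).
#' @return An object of class `arch_spec`: an ordered list of layer
#'   descriptors plus the task metadata.
#' @export
arch_spec <- function(n_classes, conv_filters = c(8, 16),
                      kernel_sizes = c(16, 5), pool_size = 5,
                      dropout = 0.20, hidden = c(256, 64),
                      input_size = 256) {
  if (!n_classes %in% c(2L, 3L)) {
    stop("n_classes must be 2 (treatment) or 3 (condition)", call. = FALSE)
  }
  layers <- list(
    list(type = "conv", out_channels = conv_filters[1],
         kernel = kernel_sizes[1], stride = 1, padding = 0),
    list(type = "activation", fn = "relu"),
    list(type = "maxpool", size = pool_size, stride = pool_size),
    list(type = "dropout", p = dropout),
    list(type = "conv", out_channels = conv_filters[2],
         kernel = kernel_sizes[2], stride = 1, padding = 0),
    list(type = "activation", fn = "relu"),
    list(type = "maxpool", size = pool_size, stride = pool_size),
    list(type = "flatten")
  )
  for (h in hidden) {
    layers <- c(layers, list(list(type = "linear", out_features = h),
                             list(type = "activation", fn = "relu")))
  }
  layers <- c(layers,
              list(list(type = "linear", out_features = as.integer(n_classes)),
                   list(type = "softmax")))
  structure(list(layers = layers, n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 conv_filters = conv_filters, kernel_sizes = kernel_sizes,
                 pool_size = pool_size, dropout = dropout, hidden = hidden),
            class = "arch_spec")
}

#' Binary (CBD vs control) treatment classifier architecture
#'
#' @param ... Overrides passed to [arch_spec()].
#' @return An `arch_spec` with a 2-wide softmax output.
#' @export
build_treatment_model <- function(...) arch_spec(n_classes = 2L, ...)

#' Ternary (LPS/GP120/Abeta42) condition classifier architecture
#'
#' Identical to the treatment architecture except for a 3-wide final layer.
#'
#' @param ... Overrides passed to [arch_spec()].
#' @return An `arch_spec` with a 3-wide softmax output.
#' @export
build_condition_model <- function(...) arch_spec(n_classes = 3L, ...)

#' @export
print.arch_spec <- function(x, ...) {
  cat(sprintf("<arch_spec: %d-class>\n", x$n_classes))
  tr <- trace_shapes(x)
  for (i in seq_len(nrow(tr))) {
    cat(sprintf("  %-12s -> %s\n", tr$layer[i], tr$shape[i]))
  }
  invisible(x)
}

#' Per-layer output-shape calculus
#'
#' Walks the architecture and records the exact output shape after every
#' layer: unpadded stride-1 convolutions (`H - k + 1`), max pooling with
#' stride = size and floor division, flattening to a vector. On the default
#' specs this reproduces the defining 8 x 48 x 48 conv2 input and the
#' 1024-long flattened vector.
#'
#' @param spec An [arch_spec()].
#' @param input_shape `c(channels, height, width)`; defaults to a
#'   single-channel `input_size` square.
#' @return A data frame of class `shape_trace`: layer name, shape string,
#'   and the numeric channels/height/width (width = NA once flattened).
#' @export
trace_shapes <- function(spec, input_shape = NULL) {
  stopifnot(inherits(spec, "arch_spec"))
  if (is.null(input_shape)) input_shape <- c(1, spec$input_size, spec$input_size)
  ch <- input_shape[1]; h <- input_shape[2]; w <- input_shape[3]
  flat <- NA_real_
  rows <- list(data.frame(layer = "input",
                          shape = sprintf("%dx%dx%d", ch, h, w),
                          channels = ch, height = h, width = w))
  ci <- 0L; li <- 0L; pi_ <- 0L
  for (lay in spec$layers) {
    if (lay$type == "conv") {
      ci <- ci + 1L; name <- sprintf("conv%d", ci)
    } else if (lay$type == "maxpool") {
      pi_ <- pi_ + 1L; name <- sprintf("pool%d", pi_)
    } else if (lay$type == "linear") {
      li <- li + 1L; name <- sprintf("linear%d", li)
    } else {
      name <- lay$type
    }
    if (lay$type == "conv") {
      h <- h - lay$kernel + 1; w <- w - lay$kernel + 1
      ch <- lay$out_channels
      if (h <= 0 || w <= 0) {
        stop(sprintf("%s: kernel %d leaves a nonpositive spatial size",
                     name, lay$kernel), call. = FALSE)
      }
    } else if (lay$type == "maxpool") {
      h <- h %/% lay$size; w <- w %/% lay$size
      if (h <= 0 || w <= 0) {
        stop(sprintf("%s: pool %d leaves a nonpositive spatial size",
                     name, lay$size), call. = FALSE)
      }
    } else if (lay$type == "flatten") {
      flat <- ch * h * w
    } else if (lay$type == "linear") {
      flat <- lay$out_features
    }
    shape <- if (is.na(flat)) sprintf("%dx%dx%d", ch, h, w) else
      sprintf("1x%d", flat)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = name, shape = shape,
      channels = if (is.na(flat)) ch else NA_real_,
      height = if (is.na(flat)) h else flat,
      width = if (is.na(flat)) w else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("shape_trace", "data.frame")
  out
}

#' Count trainable parameters
#'
#' Sums weight and bias counts over all convolutional and linear layers,
#' using the same shape calculus as [trace_shapes()] to infer input widths.
#'
#' @param spec An [arch_spec()], or a bare list of layer descriptors (an
#'   empty list counts 0).
#' @param input_shape Input `c(channels, height, width)`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, input_shape = NULL) {
  layers <- if (inherits(spec, "arch_spec")) spec$layers else spec
  if (length(layers) == 0) return(0L)
  if (is.null(input_shape)) {
    input_shape <- if (inherits(spec, "arch_spec")) {
      c(1, spec$input_size, spec$input_size)
    } else c(1, 256, 256)
  }
  ch <- input_shape[1]; h <- input_shape[2]; w <- input_shape[3]
  flat <- NA_real_; total <- 0
  for (lay in layers) {
    if (lay$type == "conv") {
      total <- total + lay$out_channels * (lay$kernel^2 * ch) + lay$out_channels
      h <- h - lay$kernel + 1; w <- w - lay$kernel + 1; ch <- lay$out_channels
    } else if (lay$type == "maxpool") {
      h <- h %/% lay$size; w <- w %/% lay$size
    } else if (lay$type == "flatten") {
      flat <- ch * h * w
    } else if (lay$type == "linear") {
      total <- total + flat * lay$out_features + lay$out_features
      flat <- lay$out_features
    }
  }
  as.integer(total)
}

#' Serialize an architecture to JSON
#'
#' @param spec An [arch_spec()].
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
arch_to_json <- function(spec, path = NULL) {
  js <- jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
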