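# The training engine behind the two-convolution classifier: parameter
# initialization, fused conv/ReLU/pool forward and backward passes (C++
# kernels), dropout, the linear stack, softmax cross-entropy and Adam.
# All randomness (init, shuffling, dropout masks) draws from R's RNG so a
# run is a pure function of its seed.

# Random orthogonal columns scaled to the Kaiming magnitude: filters are
# mutually non-redundant from any seed, which matters over a short schedule.
orthogonal_init <- function(n_in, n_out, gain) {
  q <- qr.Q(qr(matrix(rnorm(n_in * n_out), n_in, n_out)))
  q * (gain * sqrt(n_in))
}

init_params <- function(spec) {
  k1 <- spec$kernel_sizes[1]; k2 <- spec$kernel_sizes[2]
  f1 <- spec$conv_filters[1]; f2 <- spec$conv_filters[2]
  tr <- trace_shapes(spec)
  flat_in <- tr$height[tr$layer == "flatten"]
  widths <- c(flat_in, spec$hidden, spec$n_classes)
  p <- list(
    W1 = orthogonal_init(k1 * k1, f1, sqrt(2 / (k1 * k1))),
    b1 = rep(0, f1),
    W2 = orthogonal_init(k2 * k2 * f1, f2, sqrt(2 / (k2 * k2 * f1))),
    b2 = rep(0, f2)
  )
  n_lin <- length(widths) - 1
  for (i in seq_len(n_lin)) {
    # hidden layers are Kaiming-normal; the classification layer starts at
    # zero so early training is not dominated by random initial logits
    sd_i <- if (i == n_lin) 0 else sqrt(2 / widths[i])
    p[[paste0("Wf", i)]] <- matrix(
      if (sd_i > 0) rnorm(widths[i] * widths[i + 1], sd = sd_i) else 0,
      widths[i], widths[i + 1])
    p[[paste0("bf", i)]] <- rep(0, widths[i + 1])
  }
  p
}

# Forward pass over a batch. x: (H, W, 1, N) array scaled to [0, 1].
# Returns logits plus every intermediate needed for the backward pass.
nn_forward <- function(spec, params, x, training = FALSE,
                       want_act = FALSE) {
  k1 <- spec$kernel_sizes[1]; k2 <- spec$kernel_sizes[2]
  pool <- spec$pool_size
  # dropout acts on the conv1 response grid and the 5x5 pooling is applied
  # to the dropout layer (inverted dropout; a dropped unit is usually
  # replaced in the pooled output by its window's runner-up)
  mask <- NULL
  if (training && spec$dropout > 0) {
    d <- dim(x)
    ho <- d[1] - k1 + 1
    keep <- 1 - spec$dropout
    mask <- (runif(ho * ho * spec$conv_filters[1] * d[4]) < keep) / keep
  }
  l1 <- .conv_relu_pool_fwd(x, params$W1, params$b1, as.integer(k1),
                            as.integer(pool), want_act,
                            mask %||% numeric(0))
  h1d <- l1$out
  l2 <- .conv_relu_pool_fwd(h1d, params$W2, params$b2, as.integer(k2),
                            as.integer(pool), want_act)
  dims2 <- dim(l2$out)
  n <- dims2[4]
  flat <- matrix(l2$out, prod(dims2[1:3]), n)
  n_lin <- length(spec$hidden) + 1L
  A <- t(flat) # N x flat
  zs <- vector("list", n_lin); as_ <- vector("list", n_lin + 1L)
  as_[[1]] <- A
  for (i in seq_len(n_lin)) {
    z <- as_[[i]] %*% params[[paste0("Wf", i)]]
    z <- sweep(z, 2, params[[paste0("bf", i)]], `+`)
    zs[[i]] <- z
    as_[[i + 1]] <- if (i < n_lin) pmax(z, 0) else z
  }
  list(l1 = l1, mask = mask, h1d = h1d, l2 = l2, flat_dim = dims2,
       zs = zs, as_ = as_, logits = zs[[n_lin]])
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy of logits against integer class labels (1-based).
cross_entropy <- function(logits, y) {
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_along(y), y)])
}

# Backward pass; returns gradients named like the parameters.
nn_backward <- function(spec, params, x, fw, y) {
  n_lin <- length(spec$hidden) + 1L
  n <- length(y)
  probs <- softmax_rows(fw$logits)
  dz <- probs
  dz[cbind(seq_len(n), y)] <- dz[cbind(seq_len(n), y)] - 1
  dz <- dz / n
  grads <- list()
  for (i in rev(seq_len(n_lin))) {
    grads[[paste0("Wf", i)]] <- crossprod(fw$as_[[i]], dz)
    grads[[paste0("bf", i)]] <- colSums(dz)
    if (i > 1) {
      da <- dz %*% t(params[[paste0("Wf", i)]])
      dz <- da * (fw$zs[[i - 1]] > 0)
    }
  }
  dflat <- dz %*% t(params$Wf1)
  dpool2 <- array(t(dflat), fw$flat_dim)
  bk2 <- .conv_relu_pool_bwd(fw$h1d, params$W2, dpool2, fw$l2$argmax,
                             fw$l2$out, as.integer(spec$kernel_sizes[2]),
                             as.integer(spec$pool_size), TRUE)
  grads$W2 <- bk2$dw; grads$b2 <- bk2$db
  bk1 <- .conv_relu_pool_bwd(x, params$W1, bk2$dx, fw$l1$argmax, fw$l1$out,
                             as.integer(spec$kernel_sizes[1]),
                             as.integer(spec$pool_size), FALSE,
                             fw$mask %||% numeric(0))
  grads$W1 <- bk1$dw; grads$b1 <- bk1$db
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# 8-bit images enter the network centred to [-1, 1] (the standard
# mean-0.5 / std-0.5 tensor normalization).
scale_input <- function(img8) (img8 - 127.5) / 127.5

# Forward-only class probabilities for an (H, W, N) image array (8-bit
# values); batched to bound memory.
nn_predict_probs <- function(spec, params, images, batch_size = 64L) {
  n <- dim(images)[3]
  out <- matrix(0, n, spec$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    xb <- scale_input(images[, , i:j, drop = FALSE])
    dim(xb) <- c(dim(images)[1], dim(images)[2], 1L, j - i + 1L)
    fw <- nn_forward(spec, params, xb, training = FALSE)
    out[i:j, ] <- softmax_rows(fw$logits)
    i <- j + 1L
  }
  out
}
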