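# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards, so generation is a pure function of its seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` reproducible child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Largest-remainder apportionment
#'
#' Split `n` items into parts proportional to `fractions` so that the part
#' sizes are integers summing to `n`: each part gets the floor of its quota
#' and the leftover items go to the parts with the largest fractional
#' remainders (ties resolved in favour of earlier parts).
#'
#' @param n Number of items.
#' @param fractions Nonnegative weights summing to 1 (tolerance 1e-9).
#' @return Integer vector of part sizes summing to `n`.
#' @examples
#' largest_remainder(100, c(0.72, 0.08, 0.20))  # 72 8 20
#' largest_remainder(10, c(0.72, 0.08, 0.20))   # 7 1 2
#' @export
largest_remainder <- function(n, fractions) {
  stopifnot(n >= 0, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1", call. = FALSE)
  }
  quota <- n * fractions
  sizes <- floor(quota)
  left <- round(n - sum(sizes))
  if (left > 0) {
    take <- order(quota - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

# Max-projection of a (H, W, Z) volume along z.
max_project <- function(vol) {
  if (length(dim(vol)) == 2L) return(vol)
  apply(vol, c(1, 2), max)
}

# Bilinear upsampling/downsampling of a 2-d matrix to out_h x out_w
# (align-corners = FALSE convention, clamped sampling).
bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  ys <- (seq_len(out_h) - 0.5) * h / out_h - 0.5
  xs <- (seq_len(out_w) - 0.5) * w / out_w - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  a <- img[y0 + 1, x0 + 1, drop = FALSE]; b <- img[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- img[y1 + 1, x0 + 1, drop = FALSE]; d <- img[y1 + 1, x1 + 1, drop = FALSE]
  top <- a * outer(rep(1, out_h), 1 - wx) + b * outer(rep(1, out_h), wx)
  bot <- c_ * outer(rep(1, out_h), 1 - wx) + d * outer(rep(1, out_h), wx)
  top * outer(1 - wy, rep(1, out_w)) + bot * outer(wy, rep(1, out_w))
}
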