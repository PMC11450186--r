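# Internal helpers shared across modules.

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# Derive a deterministic 31-bit substream seed from a base seed and a stage tag.
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop_invalid("'%s' = %g is outside its valid range [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

# Separable Gaussian smoothing with reflecting boundaries.
gaussian_smooth_2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_1d <- function(v) {
    n <- length(v)
    left <- reflect_index(1L - (half:1), n)
    right <- reflect_index(n + (1:half), n)
    vp <- c(v[left], v, v[right])
    as.numeric(stats::filter(vp, k, sides = 2)[(half + 1):(half + n)])
  }
  out <- apply(mat, 2, smooth_1d)
  out <- t(apply(out, 1, smooth_1d))
  matrix(as.numeric(out), nrow = nrow(mat), ncol = ncol(mat))
}

# Reflect out-of-range indices into 1..n (scipy-style 'reflect', edge repeated).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period
  ifelse(j < n, j + 1L, period - j)
}

# 2-D convolution of `mat` with kernel `ker` (odd-sized), zero padding outside,
# computed with FFTs. Returns an array the size of `mat`.
fft_conv2d_same <- function(mat, ker) {
  nr <- nrow(mat); nc <- ncol(mat)
  kr <- nrow(ker); kc <- ncol(ker)
  pr <- nr + kr - 1L; pc <- nc + kc - 1L
  a <- matrix(0, pr, pc); a[seq_len(nr), seq_len(nc)] <- mat
  b <- matrix(0, pr, pc); b[seq_len(kr), seq_len(kc)] <- ker
  full <- Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / (pr * pc)
  r0 <- (kr - 1L) %/% 2L
  c0 <- (kc - 1L) %/% 2L
  full[r0 + seq_len(nr), c0 + seq_len(nc)]
}

# Mean over a circular disc around every pixel, boundary-renormalized.
disc_mean_pool <- function(mat, diameter_px) {
  r <- max(diameter_px / 2, 0)
  half <- floor(r)
  ix <- seq(-half, half)
  d2 <- outer(ix^2, ix^2, "+")
  ker <- (d2 <= r^2) * 1
  if (sum(ker) == 0) ker[half + 1L, half + 1L] <- 1  # at least the center pixel
  num <- fft_conv2d_same(mat, ker)
  den <- fft_conv2d_same(matrix(1, nrow(mat), ncol(mat)), ker)
  num / pmax(den, .Machine$double.eps)
}
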