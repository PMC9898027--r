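# Internal numerics shared across modules: seeded evaluation, shift-add
# convolution (replicate padding), integral images and window sums.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("invalid-argument: seed must be a single finite number")
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
  expr
}

# Derive a stream of child seeds from one parent seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# 2-D convolution with an odd-sized kernel and replicate (edge-clamp)
# padding. The compiled kernel is used everywhere; the shift-add R
# version below is retained as the reference in unit tests.
conv2_replicate <- function(x, k) {
  conv2_replicate_cpp(x, k)
}

conv2_replicate_r <- function(x, k) {
  kn <- nrow(k); km <- ncol(k)
  stopifnot(kn %% 2 == 1, km %% 2 == 1)
  rn <- (kn - 1L) %/% 2L
  rm_ <- (km - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  top <- x[rep(1L, rn), , drop = FALSE]
  bot <- x[rep(n, rn), , drop = FALSE]
  xp <- rbind(top, x, bot)
  left <- xp[, rep(1L, rm_), drop = FALSE]
  right <- xp[, rep(m, rm_), drop = FALSE]
  xp <- cbind(left, xp, right)
  out <- matrix(0, n, m)
  for (di in -rn:rn) {
    for (dj in -rm_:rm_) {
      w <- k[di + rn + 1L, dj + rm_ + 1L]
      if (w != 0) {
        out <- out + w * xp[(rn + 1L + di):(rn + n + di),
                            (rm_ + 1L + dj):(rm_ + m + dj)]
      }
    }
  }
  out
}

# Summed-area table with a zero top row / left column so that the sum of
# x[r1:r2, c1:c2] is ii[r2+1,c2+1] - ii[r1,c2+1] - ii[r2+1,c1] + ii[r1,c1].
integral_image <- function(x) {
  integral_image_cpp(if (is.logical(x)) x * 1 else x)
}

integral_image_r <- function(x) {
  cs <- apply(x, 2, cumsum)
  ii <- rbind(0, cs)
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  ii
}

# Sum of x over the half-open window [row0, row0+size) x [col0, col0+size)
# for vectors of 0-based tile anchors. `ii` is integral_image(x).
window_sums <- function(ii, row0, col0, size) {
  r1 <- row0 + 1L; c1 <- col0 + 1L
  r2 <- row0 + size; c2 <- col0 + size
  ii[cbind(r2 + 1L, c2 + 1L)] - ii[cbind(r1, c2 + 1L)] -
    ii[cbind(r2 + 1L, c1)] + ii[cbind(r1, c1)]
}

# clamp helpers that preserve dim attributes (pmax(0, m) would drop them)
clip_range <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}
clip01 <- function(x) clip_range(x, 0, 1)

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used to stamp
# outputs with a configuration fingerprint.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor only touches the low byte since b < 256
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in two 16-bit halves to stay exact in doubles
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_invalid <- function(...) stop("invalid-argument: ", ..., call. = FALSE)
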