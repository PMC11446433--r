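# Internal helpers: seeded evaluation, 8-bit quantization, bilinear sampling.

#' Evaluate code under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so that seeded
#' package operations never disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and an index; kept below 2^31 - 1.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807) %% 2147483629) + 1L
}

# Quantize to 8-bit: round (half-to-even, base round) then clamp to [0, 255].
quantize8 <- function(m) {
  m <- round(m)
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x)

#' Bilinear sampling of a grayscale image at continuous coordinates
#'
#' Coordinates are continuous pixel units with the origin at the top-left
#' corner of the pixel grid; pixel (row r, col c) has its center at
#' (x = c - 0.5, y = r - 0.5). Out-of-range coordinates are clamped
#' (edge replication).
#' @param img numeric matrix `[height, width]`.
#' @param x,y equal-length numeric vectors of sample coordinates.
#' @return numeric vector of sampled intensities (not quantized).
#' @noRd
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  gx <- x - 0.5; gy <- y - 0.5
  c0 <- floor(gx); r0 <- floor(gy)
  fx <- gx - c0; fy <- gy - r0
  # clamp the 2x2 neighbourhood inside the grid (0-based indices)
  c0 <- pmin(pmax(c0, 0), w - 1); r0 <- pmin(pmax(r0, 0), h - 1)
  c1 <- pmin(c0 + 1, w - 1); r1 <- pmin(r0 + 1, h - 1)
  i00 <- img[cbind(r0 + 1, c0 + 1)]
  i01 <- img[cbind(r0 + 1, c1 + 1)]
  i10 <- img[cbind(r1 + 1, c0 + 1)]
  i11 <- img[cbind(r1 + 1, c1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Separable 3x3 binomial smoothing ([1,2,1]/4 along rows and columns),
# edge-replicated. Used by the scene generator as a cheap optical blur.
smooth3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- m[c(1, seq_len(h - 1)), , drop = FALSE]
  dn <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  m <- (up + 2 * m + dn) / 4
  lf <- m[, c(1, seq_len(w - 1)), drop = FALSE]
  rt <- m[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  (lf + 2 * m + rt) / 4
}

# Round half away from zero at `digits` decimals (report formatting).
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt3 <- function(x) {
  ifelse(is.na(x), "NA", formatC(round_half_away(x, 3), format = "f", digits = 3))
}
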