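`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Bilinear interpolation of a matrix at real-valued coordinates
#'
#' Samples `img` at (row, col) positions with bilinear weights; coordinates
#' outside the image are clamped to the border (replicate padding).
#'
#' @param img numeric matrix.
#' @param r,c numeric vectors/matrices of 1-based row and column coordinates.
#' @return numeric vector (or object shaped like `r`) of sampled values.
#' @keywords internal
bilinear_sample <- function(img, r, c) {
  N <- nrow(img); M <- ncol(img)
  r <- clamp(r, 1, N); c <- clamp(c, 1, M)
  r0 <- pmin(pmax(floor(r), 1L), max(N - 1L, 1L))
  c0 <- pmin(pmax(floor(c), 1L), max(M - 1L, 1L))
  fr <- if (N > 1L) r - r0 else r * 0
  fc <- if (M > 1L) c - c0 else c * 0
  r1 <- pmin(r0 + 1L, N); c1 <- pmin(c0 + 1L, M)
  i00 <- (c0 - 1) * N + r0; i10 <- (c0 - 1) * N + r1
  i01 <- (c1 - 1) * N + r0; i11 <- (c1 - 1) * N + r1
  out <- (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i10] +
    (1 - fr) * fc * img[i01] + fr * fc * img[i11]
  if (is.matrix(r)) dim(out) <- dim(r)
  out
}

# Resize a matrix with bilinear interpolation (pixel-center alignment, so a
# constant image stays constant and identity sizes are exact no-ops).
resize_bilinear <- function(img, out_h, out_w) {
  N <- nrow(img); M <- ncol(img)
  rs <- (seq_len(out_h) - 0.5) * N / out_h + 0.5
  cs <- (seq_len(out_w) - 0.5) * M / out_w + 0.5
  r <- matrix(rs, out_h, out_w)
  c <- matrix(cs, out_h, out_w, byrow = TRUE)
  bilinear_sample(img, r, c)
}

# Rec. 601 luma conversion; accepts HxW, HxWx{1,2,3,4} arrays as returned by
# png::readPNG (extra channels beyond RGB are treated as alpha and dropped).
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3L) {
    if (d[3] == 1L) return(img[, , 1L])
    if (d[3] == 2L) return(img[, , 1L])
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  }
  stop("unsupported image array with ", length(d), " dimensions", call. = FALSE)
}

# Separable Gaussian blur with replicate borders (used for pyramid smoothing
# and synthetic textures).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-rad:rad, sd = sigma)
  w <- w / sum(w)
  N <- nrow(img); M <- ncol(img)
  acc <- matrix(0, N, M)
  for (o in -rad:rad) {
    idx <- clamp(seq_len(N) + o, 1L, N)
    acc <- acc + w[o + rad + 1L] * img[idx, , drop = FALSE]
  }
  out <- matrix(0, N, M)
  for (o in -rad:rad) {
    idx <- clamp(seq_len(M) + o, 1L, M)
    out <- out + w[o + rad + 1L] * acc[, idx, drop = FALSE]
  }
  out
}

# Central-difference spatial gradients with replicate borders.
grad_x <- function(img) {
  M <- ncol(img)
  (img[, c(2:M, M), drop = FALSE] - img[, c(1, 1:(M - 1)), drop = FALSE]) / 2
}
grad_y <- function(img) {
  N <- nrow(img)
  (img[c(2:N, N), , drop = FALSE] - img[c(1, 1:(N - 1)), , drop = FALSE]) / 2
}

# Pad a matrix by p pixels on each side; "zero" or "symmetric" (mirror with
# edge duplication: ... 2 1 | 1 2 ... N | N N-1 ...).
pad_matrix <- function(img, p, mode = c("zero", "symmetric")) {
  mode <- match.arg(mode)
  if (p == 0L) return(img)
  N <- nrow(img); M <- ncol(img)
  if (mode == "zero") {
    out <- matrix(0, N + 2L * p, M + 2L * p)
    out[(p + 1L):(p + N), (p + 1L):(p + M)] <- img
    return(out)
  }
  reflect <- function(i, n) {
    i <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n) + 1L
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  ri <- reflect(seq.int(1L - p, N + p), N)
  ci <- reflect(seq.int(1L - p, M + p), M)
  img[ri, ci, drop = FALSE]
}

# Quantize to IEEE single precision (the .flo cache precision), so cached and
# freshly computed flow fields are bit-identical downstream.
to_float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
               "numeric", n = length(x), size = 4L)
  dim(y) <- d
  y
}

# Run code with a private, restored RNG state seeded deterministically.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
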