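#' PCANet+ layer configuration
#'
#' Geometry and encoding parameters of one PCANet+ layer: square `k x k`
#' filters (odd `k`), `D` filters, inter-layer mean pooling, zero padding
#' `(k-1)/2` for same-size responses, hash chunk size `F_lambda` (the number
#' of response maps combined into one integer hash map; `D` must be a
#' multiple of it) and a `rows x cols` grid of non-overlapping histogram
#' blocks.
#'
#' @param k filter side length in pixels (odd).
#' @param D number of PCA filters.
#' @param pool_size mean-pooling window (odd), default 3.
#' @param pool_stride pooling stride, default 1 (size-preserving).
#' @param pad zero padding; defaults to `(k-1)/2`.
#' @param F_lambda hash chunk size, default 8; must divide `D` and be at
#'   most 30 so hash labels fit an integer.
#' @param blocks integer vector `c(rows, cols)` of the histogram block grid
#'   (default `c(2, 2)`, i.e. 4 blocks).
#' @return a `layer_config` object.
#' @export
layer_config <- function(k, D, pool_size = 3L, pool_stride = 1L,
                         pad = (k - 1L) %/% 2L, F_lambda = 8L,
                         blocks = c(2L, 2L)) {
  k <- as.integer(k); D <- as.integer(D); F_lambda <- as.integer(F_lambda)
  if (k %% 2L == 0L) stop("filter size k must be odd", call. = FALSE)
  if (F_lambda > 30L)
    stop("F_lambda must be <= 30 so hash labels fit an integer",
         call. = FALSE)
  if (D %% F_lambda != 0L)
    stop("filter count D = ", D, " must be a multiple of F_lambda = ",
         F_lambda, call. = FALSE)
  if (pool_size %% 2L == 0L) stop("pool_size must be odd", call. = FALSE)
  structure(list(k = k, D = D, pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 pad = as.integer(pad), F_lambda = F_lambda,
                 blocks = as.integer(blocks)),
            class = "layer_config")
}

# Ensure an image is N x M x C.
as_image3 <- function(image) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  image
}

#' Extract mean-centered patch vectors around every pixel
#'
#' Collects the `k x k x C` patch around each pixel of a (multi-channel)
#' image into one column of a `k^2*C x N*M` matrix, using zero padding of
#' `(k-1)/2` so there is one column per pixel. Each column is centered by
#' subtracting its own mean (the patch mean), the normalization used for
#' PCA filter learning. Column order is R's column-major pixel order;
#' within a column the tap order is rows, then columns, then channels,
#' matching `array(w, c(k, k, C))` for a flattened filter `w`.
#'
#' @param image `N x M` matrix or `N x M x C` array.
#' @param k patch side length (odd).
#' @param center subtract each patch's mean (default `TRUE`).
#' @return a `k^2*C x N*M` matrix.
#' @export
extract_patches <- function(image, k, center = TRUE) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("patch size k must be odd", call. = FALSE)
  image <- as_image3(image)
  N <- dim(image)[1]; M <- dim(image)[2]; C <- dim(image)[3]
  if (N < k || M < k)
    stop("image spatial dimensions must be at least k", call. = FALSE)
  pad <- (k - 1L) %/% 2L
  P <- matrix(0, k * k * C, N * M)
  row <- 1L
  for (ch in seq_len(C)) {
    padded <- pad_matrix(image[, , ch], pad, "zero")
    for (j in seq_len(k)) {
      for (i in seq_len(k)) {
        P[row, ] <- padded[i:(i + N - 1L), j:(j + M - 1L)]
        row <- row + 1L
      }
    }
  }
  if (center) P <- sweep(P, 2L, colMeans(P), "-")
  P
}

# Deterministic eigenvector sign convention: the entry of largest magnitude
# (first index on ties) is made positive.
fix_eigen_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

pcanet_layer_from_scatter <- function(S, config, channels) {
  k <- config$k; D <- config$D
  if (D > nrow(S))
    stop("filter count D = ", D, " exceeds patch dimension ", nrow(S),
         call. = FALSE)
  if (max(abs(S)) < 1e-12)
    stop("degenerate input batch: patch scatter is zero ",
         "(constant training images?)", call. = FALSE)
  eig <- eigen(S, symmetric = TRUE)
  V <- fix_eigen_signs(eig$vectors[, seq_len(D), drop = FALSE])
  filters <- array(V, dim = c(k, k, channels, D))
  structure(list(config = config, W = V, filters = filters,
                 eigenvalues = eig$values, channels = channels),
            class = "pcanet_layer")
}

#' Learn the PCA filters of one layer from a patch matrix
#'
#' The filters minimizing the patch reconstruction error under an
#' orthonormality constraint are the top-`D` eigenvectors of the patch
#' scatter `P %*% t(P)`, ordered by descending eigenvalue. A deterministic
#' sign convention (largest-magnitude entry positive) makes the result
#' reproducible across eigensolvers; ties among equal eigenvalues keep the
#' solver's descending order.
#'
#' @param patches `d x n` matrix of (mean-centered) patch columns, with
#'   `d = k^2 * channels`.
#' @param D number of filters to learn.
#' @param k filter side length.
#' @param channels number of input channels (default inferred as
#'   `nrow(patches) / k^2`).
#' @return a `pcanet_layer`: learned filters (`k x k x channels x D` array
#'   and `d x D` matrix `W`), the layer configuration and all eigenvalues.
#' @export
learn_pca_filters <- function(patches, D, k, channels = NULL) {
  if (length(patches) == 0L || ncol(patches) == 0L)
    stop("empty patch matrix", call. = FALSE)
  k <- as.integer(k)
  channels <- as.integer(channels %||% (nrow(patches) / (k * k)))
  if (k * k * channels != nrow(patches))
    stop("nrow(patches) must equal k^2 * channels", call. = FALSE)
  S <- tcrossprod(patches)
  # hashing divisibility only matters at encoding time; pick a compatible
  # chunk size so standalone filter learning works for any D
  Fl <- if (D %% 8L == 0L) 8L else D
  pcanet_layer_from_scatter(S, layer_config(k = k, D = D, F_lambda = Fl),
                            channels)
}

#' @export
print.pcanet_layer <- function(x, ...) {
  cat(sprintf("<pcanet_layer> (%dx%dx%d)x%d filters\n",
              x$config$k, x$config$k, x$channels, x$config$D))
  invisible(x)
}

#' Convolve a multi-channel image with a layer's filter bank
#'
#' Same-size correlation (not flipped convolution) of the image with each
#' filter, using zero padding of `(k-1)/2`; implemented as a patch-matrix
#' product so it is exactly `t(P_raw) %*% W` with uncentered patches.
#'
#' @param image `N x M` matrix or `N x M x C` array whose channel count
#'   equals the layer's filter depth.
#' @param layer a `pcanet_layer`.
#' @return an `N x M x D` array of response maps.
#' @export
convolve_bank <- function(image, layer) {
  image <- as_image3(image)
  if (dim(image)[3] != layer$channels)
    stop("image has ", dim(image)[3], " channels but filters expect ",
         layer$channels, call. = FALSE)
  N <- dim(image)[1]; M <- dim(image)[2]
  P <- extract_patches(image, layer$config$k, center = FALSE)
  array(crossprod(P, layer$W), dim = c(N, M, layer$config$D))
}

#' Mean pooling of a response map
#'
#' Each output pixel is the mean over a `pool_size x pool_size` window
#' (symmetric/reflect padding at the border); stride 1 preserves the map
#' size, larger strides subsample the pooled map.
#'
#' @param map numeric matrix.
#' @param pool_size odd window side length.
#' @param pool_stride stride.
#' @return pooled matrix.
#' @export
mean_pool <- function(map, pool_size = 3L, pool_stride = 1L) {
  pool_size <- as.integer(pool_size)
  if (pool_size %% 2L == 0L) stop("pool_size must be odd", call. = FALSE)
  if (pool_size == 1L && pool_stride == 1L) return(map)
  N <- nrow(map); M <- ncol(map)
  p <- (pool_size - 1L) %/% 2L
  padded <- pad_matrix(map, p, "symmetric")
  acc <- matrix(0, N, M)
  for (j in seq_len(pool_size)) {
    for (i in seq_len(pool_size)) {
      acc <- acc + padded[i:(i + N - 1L), j:(j + M - 1L)]
    }
  }
  acc <- acc / (pool_size^2)
  if (pool_stride > 1L) {
    acc <- acc[seq(1L, N, by = pool_stride), seq(1L, M, by = pool_stride),
               drop = FALSE]
  }
  acc
}

#' Binary-hash a chunk of response maps into one integer label map
#'
#' Applies the Heaviside step (1 for strictly positive entries, 0
#' otherwise) to each of the `F_lambda` maps and combines them with binary
#' weights `2^(f-1)`, giving labels in `[0, 2^F_lambda - 1]`.
#'
#' @param maps `N x M x F_lambda` array (or list of matrices) of pooled
#'   response maps.
#' @return a `hash_map`: integer matrix of labels with attribute `n_bits`.
#' @export
hash_chunk <- function(maps) {
  if (is.list(maps)) maps <- array(unlist(maps),
                                   dim = c(dim(maps[[1]]), length(maps)))
  if (is.matrix(maps)) dim(maps) <- c(dim(maps), 1L)
  Fl <- dim(maps)[3]
  if (Fl > 30L) stop("more than 30 maps per chunk", call. = FALSE)
  lab <- matrix(0, dim(maps)[1], dim(maps)[2])
  for (f in seq_len(Fl)) {
    lab <- lab + 2^(f - 1) * (maps[, , f] > 0)
  }
  structure(lab, n_bits = Fl, class = c("hash_map", class(lab)))
}

block_bounds <- function(n, nb) {
  base <- n %/% nb
  sizes <- rep(base, nb)
  sizes[nb] <- sizes[nb] + n - base * nb  # remainder goes to the last block
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  cbind(starts, ends)
}

#' Block histograms of a hash-label map
#'
#' Partitions the label map into a `rows x cols` grid of non-overlapping
#' blocks (near-equal sizes; remainder pixels go to the last row/column of
#' blocks), histograms each block into `2^n_bits` bins and concatenates the
#' block histograms (blocks enumerated column-major, matching R's array
#' order). The total count equals the map's pixel count.
#'
#' @param hash_map integer label matrix (as from [hash_chunk()]).
#' @param blocks integer vector `c(rows, cols)`; `B = rows * cols`.
#' @param n_bits number of hash bits; defaults to the map's `n_bits`
#'   attribute.
#' @return numeric vector of length `B * 2^n_bits`.
#' @export
block_histograms <- function(hash_map, blocks = c(2L, 2L), n_bits = NULL) {
  n_bits <- n_bits %||% attr(hash_map, "n_bits")
  if (is.null(n_bits)) stop("n_bits not given", call. = FALSE)
  N <- nrow(hash_map); M <- ncol(hash_map)
  rb <- as.integer(blocks[1]); cb <- as.integer(blocks[2])
  if (rb > N || cb > M)
    stop("block grid ", rb, "x", cb, " exceeds map size ", N, "x", M,
         call. = FALSE)
  nbin <- as.integer(2^n_bits)
  rbd <- block_bounds(N, rb); cbd <- block_bounds(M, cb)
  out <- numeric(rb * cb * nbin)
  blk <- 0L
  for (jc in seq_len(cb)) {
    for (ir in seq_len(rb)) {
      sub <- hash_map[rbd[ir, 1]:rbd[ir, 2], cbd[jc, 1]:cbd[jc, 2]]
      out[(blk * nbin + 1L):((blk + 1L) * nbin)] <-
        tabulate(as.integer(sub) + 1L, nbins = nbin)
      blk <- blk + 1L
    }
  }
  out
}

# Pool every response map of an N x M x D stack.
pool_stack <- function(resp, config) {
  D <- dim(resp)[3]
  first <- mean_pool(resp[, , 1], config$pool_size, config$pool_stride)
  out <- array(0, dim = c(dim(first), D))
  out[, , 1] <- first
  if (D > 1L) for (d in 2:D)
    out[, , d] <- mean_pool(resp[, , d], config$pool_size, config$pool_stride)
  out
}

# Chunked hash + block-histogram encoding of a pooled response stack.
encode_layer <- function(pooled, config) {
  D <- dim(pooled)[3]; Fl <- config$F_lambda
  n_chunks <- D %/% Fl
  feats <- vector("list", n_chunks)
  for (t in seq_len(n_chunks)) {
    idx <- ((t - 1L) * Fl + 1L):(t * Fl)
    hm <- hash_chunk(pooled[, , idx, drop = FALSE])
    feats[[t]] <- block_histograms(hm, config$blocks, Fl)
  }
  unlist(feats)
}

#' Closed-form feature length of a filter bank
#'
#' `sum_l B_l * (D_l / F_lambda) * 2^F_lambda` over the bank's layers.
#'
#' @param bank a `filter_bank`, or a list of `layer_config`s.
#' @return integer feature length.
#' @export
feature_length <- function(bank) {
  cfgs <- if (inherits(bank, "filter_bank"))
    lapply(bank$layers, `[[`, "config") else bank
  sum(vapply(cfgs, function(cf)
    prod(cf$blocks) * (cf$D / cf$F_lambda) * 2^cf$F_lambda, numeric(1)))
}

#' Train a two-layer PCANet+ filter bank
#'
#' Layer-1 filters are learned from the mean-centered patches of all input
#' tensors; the layer-1 pooled responses of all tensors then provide the
#' patches for layer-2 learning. The patch scatter of each layer is
#' accumulated as a streaming sum over tensors, so peak memory does not
#' grow with the batch size, and the accumulated covariance makes training
#' independent of tensor order.
#'
#' @param tensors list of `N x M x C` arrays (elements of one or more
#'   `stacked_set`s); all must share the channel count.
#' @param configs list of [layer_config()]s, one per layer (default two).
#' @param fold_id optional identifier of the training fold recorded on the
#'   bank.
#' @return a `filter_bank`: list of trained `pcanet_layer`s.
#' @export
train_filter_bank <- function(tensors,
                              configs = list(layer_config(7L, 32L),
                                             layer_config(9L, 16L)),
                              fold_id = NA_character_) {
  if (inherits(tensors, "stacked_set")) tensors <- tensors$tensors
  if (length(tensors) < 1L) stop("no training tensors", call. = FALSE)
  tensors <- lapply(tensors, as_image3)
  layers <- vector("list", length(configs))
  current <- tensors
  for (l in seq_along(configs)) {
    cf <- configs[[l]]
    C <- dim(current[[1]])[3]
    d <- cf$k^2 * C
    S <- matrix(0, d, d)
    for (tn in current) {
      P <- extract_patches(tn, cf$k, center = TRUE)
      S <- S + tcrossprod(P)
    }
    layers[[l]] <- pcanet_layer_from_scatter(S, cf, C)
    if (l < length(configs)) {
      current <- lapply(current, function(tn)
        pool_stack(convolve_bank(tn, layers[[l]]), cf))
    }
  }
  structure(list(layers = layers, trained_on = fold_id),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank>\n")
  for (l in seq_along(x$layers)) {
    ly <- x$layers[[l]]
    cat(sprintf("  layer %d: (%dx%dx%d)x%d, F_lambda=%d, blocks=%dx%d\n",
                l, ly$config$k, ly$config$k, ly$channels, ly$config$D,
                ly$config$F_lambda, ly$config$blocks[1], ly$config$blocks[2]))
  }
  cat(sprintf("  feature length: %d\n", feature_length(x)))
  invisible(x)
}

#' Extract the PCANet+ feature vector of one stacked tensor
#'
#' The tensor is convolved with the layer-1 bank and mean-pooled; the
#' pooled responses are (a) encoded by chunked hashing and block
#' histograms, and (b) fed as a multi-channel image to layer 2, which is
#' encoded the same way. The per-layer encodings are concatenated, giving a
#' vector of length `sum_l B_l * (D_l/F_lambda) * 2^F_lambda`.
#'
#' @param tensor `N x M x C` array with `C` equal to the layer-1 filter
#'   depth (`2T` for stacked flow).
#' @param bank a trained `filter_bank`.
#' @return numeric feature vector.
#' @export
forward_features <- function(tensor, bank) {
  if (!inherits(bank, "filter_bank"))
    stop("`bank` must be a trained filter_bank", call. = FALSE)
  tensor <- as_image3(tensor)
  feats <- vector("list", length(bank$layers))
  current <- tensor
  for (l in seq_along(bank$layers)) {
    layer <- bank$layers[[l]]
    pooled <- pool_stack(convolve_bank(current, layer), layer$config)
    feats[[l]] <- encode_layer(pooled, layer$config)
    current <- pooled
  }
  unlist(feats)
}

#' Serialize / load a filter bank
#'
#' `write_filter_bank` stores the arrays in an RDS archive and the layer
#' geometries in a human-readable JSON sidecar (`<path>.json`);
#' `read_filter_bank` restores the bank.
#'
#' @param bank a `filter_bank`.
#' @param path file path for the RDS archive.
#' @return `write_filter_bank` returns `path` invisibly; `read_filter_bank`
#'   returns the `filter_bank`.
#' @export
write_filter_bank <- function(bank, path) {
  saveRDS(bank, path)
  side <- lapply(bank$layers, function(ly)
    c(ly$config[c("k", "D", "pool_size", "pool_stride", "pad", "F_lambda")],
      list(blocks = ly$config$blocks, channels = ly$channels)))
  jsonlite::write_json(list(layers = side, trained_on = bank$trained_on),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path) {
  bank <- readRDS(path)
  if (!inherits(bank, "filter_bank"))
    stop("'", path, "' does not contain a filter_bank", call. = FALSE)
  bank
}
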