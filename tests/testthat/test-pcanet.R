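test_that("patch extraction matches a naive sliding-window oracle", {
  set.seed(11)
  # 2-channel 4x4 image, k = 3: columns of length 18
  img <- array(rnorm(32), c(4, 4, 2))
  P <- extract_patches(img, 3, center = FALSE)
  expect_equal(dim(P), c(18, 16))
  pad <- array(0, c(6, 6, 2)); pad[2:5, 2:5, ] <- img
  col <- 0
  for (cc in 1:4) for (rr in 1:4) {
    col <- col + 1
    expect_equal(P[, col], as.vector(pad[rr:(rr + 2), cc:(cc + 2), ]))
  }
  # 3x3 single-channel, k = 3 -> 9 columns of length 9
  P2 <- extract_patches(matrix(rnorm(9), 3, 3), 3)
  expect_equal(dim(P2), c(9, 9))
  # constant image: interior columns are exactly zero after patch-mean
  # removal (border columns mix in zero padding, so only the padding
  # pattern survives there)
  P3 <- extract_patches(matrix(0.7, 5, 5), 3, center = TRUE)
  interior <- as.vector(matrix(seq_len(25), 5, 5)[2:4, 2:4])
  expect_true(max(abs(P3[, interior])) < 1e-12)
  expect_error(extract_patches(img, 4), "odd")
})

test_that("learned filters match a dense eigendecomposition oracle", {
  set.seed(21)
  P <- matrix(rnorm(50 * 1000), 50, 1000)
  P <- sweep(P, 2, colMeans(P))
  ly <- learn_pca_filters(P, 4, 5, 2)
  # oracle: dense symmetric eigensolver on the materialized scatter
  eig <- eigen(P %*% t(P), symmetric = TRUE)
  for (j in 1:4) {
    v <- eig$vectors[, j]
    expect_lt(min(sum((ly$W[, j] - v)^2), sum((ly$W[, j] + v)^2)), 1e-16)
  }
  # orthonormality
  expect_lt(max(abs(crossprod(ly$W) - diag(4))), 1e-8)
  # reconstruction error equals the sum of discarded eigenvalues
  recon <- sum((P - ly$W %*% crossprod(ly$W, P))^2)
  expect_equal(recon, sum(ly$eigenvalues[-(1:4)]), tolerance = 1e-6)
})

test_that("rank-1 patches give the normalized direction as first filter", {
  d <- rnorm(9); d <- d / sqrt(sum(d^2))
  P <- d %*% t(rnorm(40))
  ly <- learn_pca_filters(P, 2, 3, 1)
  expect_lt(min(sum((ly$W[, 1] - d)^2), sum((ly$W[, 1] + d)^2)), 1e-16)
  expect_lt(ly$eigenvalues[2], 1e-8 * ly$eigenvalues[1])
})

test_that("duplicating every patch column leaves the filters unchanged", {
  set.seed(5)
  P <- matrix(rnorm(18 * 60), 18, 60)
  l1 <- learn_pca_filters(P, 3, 3, 2)
  l2 <- learn_pca_filters(cbind(P, P), 3, 3, 2)
  expect_equal(l1$W, l2$W, tolerance = 1e-10)
})

test_that("degenerate and invalid patch inputs are rejected", {
  expect_error(learn_pca_filters(matrix(0, 9, 20), 2, 3, 1), "degenerate")
  expect_error(learn_pca_filters(matrix(rnorm(9 * 5), 9, 5), 20, 3, 1),
               "exceeds")
})

test_that("bank convolution is same-size zero-padded correlation", {
  set.seed(31)
  img <- array(rnorm(7 * 6 * 2), c(7, 6, 2))
  ly <- learn_pca_filters(extract_patches(img, 3), 4, 3)
  resp <- convolve_bank(img, ly)
  expect_equal(dim(resp), c(7, 6, 4))
  for (j in 1:4) {
    expect_lt(max(abs(resp[, , j] -
                        naive_correlate(img, array(ly$W[, j], c(3, 3, 2))))),
              1e-10)
  }
  # impulse response of correlation: the 180-degree-rotated filter laid
  # out around the delta position
  delta <- matrix(0, 7, 7); delta[4, 4] <- 1
  lyd <- learn_pca_filters(matrix(rnorm(9 * 30), 9, 30), 1, 3, 1)
  r <- convolve_bank(delta, lyd)[, , 1]
  w <- matrix(lyd$W[, 1], 3, 3)
  expect_equal(r[3:5, 3:5], w[3:1, 3:1], tolerance = 1e-12)
  # channel mismatch
  expect_error(convolve_bank(matrix(0, 7, 7), ly), "channels")
})

test_that("mean pooling matches a naive double-loop oracle", {
  expect_equal(mean_pool(matrix(1:9, 3, 3, byrow = TRUE))[2, 2], 5)
  cm <- matrix(0.4, 6, 5)
  expect_equal(mean_pool(cm, 3, 1), cm)  # constant map unchanged
  set.seed(41)
  m <- matrix(rnorm(42), 7, 6)
  got <- mean_pool(m, 3, 1)
  # oracle with symmetric (mirrored, edge-duplicated) borders
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  for (r in 1:7) for (c in 1:6) {
    s <- 0
    for (dr in -1:1) for (dc in -1:1)
      s <- s + m[refl(r + dr, 7), refl(c + dc, 6)]
    expect_equal(got[r, c], s / 9, tolerance = 1e-12)
  }
  # stride 2 subsamples the stride-1 result
  expect_equal(mean_pool(m, 3, 2), got[c(1, 3, 5, 7), c(1, 3, 5)])
})

test_that("Heaviside hashing uses binary weights 2^(f-1) with H(0) = 0", {
  pos <- array(1, c(3, 3, 8))
  expect_true(all(hash_chunk(pos) == 255))
  expect_true(all(hash_chunk(-pos) == 0))
  expect_true(all(hash_chunk(array(0, c(3, 3, 8))) == 0))  # H(0) = 0
  m <- array(-1, c(2, 2, 8)); m[1, 2, 3] <- 5
  expect_equal(as.numeric(hash_chunk(m)[1, 2]), 4)  # 2^(3-1)
})

test_that("block histograms conserve mass and match naive counting", {
  set.seed(51)
  lab <- matrix(sample(0:255, 7 * 9, replace = TRUE), 7, 9)
  hm <- structure(lab, n_bits = 8L)
  # B = 1 equals a plain tabulation
  h1 <- block_histograms(hm, c(1, 1))
  expect_equal(h1, as.numeric(tabulate(lab + 1, nbins = 256)))
  # uniform label 0, B = 4: each block's bin 0 holds its pixel count
  h0 <- block_histograms(structure(matrix(0L, 6, 6), n_bits = 8L), c(2, 2))
  expect_equal(h0[seq(1, 1024, by = 256)], rep(9, 4))
  expect_equal(sum(h0), 36)
  # mass conservation with remainder blocks
  h <- block_histograms(hm, c(2, 2))
  expect_equal(sum(h), 63)
  expect_error(block_histograms(hm, c(10, 10)), "exceeds")
})

test_that("feature length follows the closed form over the [k, D] grid", {
  set.seed(61)
  tensor <- array(rnorm(24 * 24 * 2), c(24, 24, 2))
  for (k in c(5, 9, 15)) for (D in c(8, 16, 32)) {
    cfgs <- list(layer_config(k, D), layer_config(5, 8))
    bank <- train_filter_bank(list(tensor), cfgs)
    f <- forward_features(tensor, bank)
    expect_length(f, feature_length(bank))
    expect_length(f, 4 * (D / 8) * 256 + 4 * 256)
    expect_true(all(f >= 0))
  }
})

test_that("forward features conserve block mass and handle zero tensors", {
  set.seed(71)
  tensor <- array(rnorm(20 * 18 * 4), c(20, 18, 4))
  bank <- train_filter_bank(list(tensor),
                            list(layer_config(5, 8), layer_config(3, 8)))
  f <- forward_features(tensor, bank)
  # layer-1 encoding: one hash map over 2x2 blocks -> total mass = N*M
  expect_equal(sum(f[1:1024]), 20 * 18)
  expect_equal(sum(f[1025:2048]), 20 * 18)
  # zero tensor: all labels 0, each block contributes its pixels to bin 0
  fz <- forward_features(array(0, c(20, 18, 4)), bank)
  expect_equal(sum(fz), 2 * 20 * 18)
  expect_equal(fz[1], 10 * 9)
  expect_true(all(fz[setdiff(1:2048, seq(1, 2048, by = 256))] == 0))
  expect_error(forward_features(tensor, "nope"), "filter_bank")
})

test_that("bank training is order-invariant and matches the eigen oracle", {
  set.seed(81)
  t1 <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  t2 <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  cfgs <- list(layer_config(3, 8), layer_config(3, 8))
  b12 <- train_filter_bank(list(t1, t2), cfgs)
  b21 <- train_filter_bank(list(t2, t1), cfgs)
  expect_equal(b12$layers[[1]]$W, b21$layers[[1]]$W, tolerance = 1e-10)
  expect_equal(b12$layers[[2]]$W, b21$layers[[2]]$W, tolerance = 1e-10)
  # oracle: materialize the full layer-1 patch matrix and eigendecompose
  Pall <- cbind(extract_patches(t1, 3), extract_patches(t2, 3))
  eig <- eigen(Pall %*% t(Pall), symmetric = TRUE)
  for (j in 1:8) {
    v <- eig$vectors[, j]
    expect_lt(min(sum((b12$layers[[1]]$W[, j] - v)^2),
                  sum((b12$layers[[1]]$W[, j] + v)^2)), 1e-8)
  }
  # orthonormality within each layer
  for (l in 1:2) {
    W <- b12$layers[[l]]$W
    expect_lt(max(abs(crossprod(W) - diag(ncol(W)))), 1e-8)
  }
  expect_error(train_filter_bank(list(array(0, c(16, 16, 2))), cfgs),
               "degenerate")
})

test_that("filter banks serialize with a JSON sidecar", {
  set.seed(91)
  tensor <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  bank <- train_filter_bank(list(tensor),
                            list(layer_config(3, 8), layer_config(3, 8)))
  f <- withr::local_tempfile(fileext = ".rds")
  write_filter_bank(bank, f)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$layers[[1]]$k, 3)
  bank2 <- read_filter_bank(f)
  expect_equal(bank2$layers[[1]]$W, bank$layers[[1]]$W)
})
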