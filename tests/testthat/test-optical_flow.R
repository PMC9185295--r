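test_that("identical frames yield numerically zero flow (both backends)", {
  base <- make_texture(40, seed = 2)
  clip <- me_clip(array(rep(base, 4), c(40, 40, 4)))
  for (backend in c("trajectory", "pairwise")) {
    fl <- estimate_flow_sequence(clip, flow_config(backend = backend))
    expect_lt(max(abs(fl$U), abs(fl$V)), 1e-3)
  }
})

test_that("global translations are recovered below 0.5 px endpoint error", {
  # per-frame shifts up to 1 px, cumulative up to 3 px over the clip
  cases <- list(c(1, 0, 4), c(0.6, -0.8, 4), c(-1, 1, 3))
  for (cs in cases) {
    clip <- make_translating_clip(cs[1], cs[2], L = cs[3], N = 48, seed = 7)
    fl <- estimate_flow_sequence(clip)
    inner <- 9:40
    epe <- sapply(seq_len(cs[3] - 1), function(t)
      mean(sqrt((fl$U[inner, inner, t] - t * cs[1])^2 +
                (fl$V[inner, inner, t] - t * cs[2])^2)))
    expect_lt(mean(epe), 0.5)
  }
})

test_that("solver energy is non-increasing over accepted outer iterations", {
  clip <- make_translating_clip(1, 0, L = 5, N = 40, seed = 9)
  cfg <- flow_config()
  fl <- estimate_flow_sequence(clip, cfg)
  trace <- fl$energy_trace
  expect_gte(length(trace), 2)
  expect_true(all(diff(trace) <= abs(trace[-length(trace)]) * 1e-6))
  # the reported trace endpoint matches the exported energy functional
  expect_equal(flow_energy(clip, fl, cfg), trace[length(trace)],
               tolerance = 1e-4)
})

test_that("beta -> 0 in the trajectory backend reproduces pairwise flow", {
  clip <- make_translating_clip(0.5, 0.5, L = 5, N = 32, seed = 4)
  fp <- estimate_flow_sequence(clip, flow_config(backend = "pairwise"))
  ft <- estimate_flow_sequence(clip, flow_config(beta = 1e-9))
  expect_lt(max(abs(fp$U - ft$U), abs(fp$V - ft$V)), 1e-3)
})

test_that("large beta pulls trajectories into the basis span", {
  N <- 40; L <- 6; Lf <- L - 1
  clip <- make_translating_clip(1, 0, L = L, N = N, seed = 7)
  # basis containing the linear ramp trajectory (plus the constant)
  ramp <- seq_len(Lf) / sqrt(sum(seq_len(Lf)^2))
  Q <- qr.Q(qr(cbind(ramp, rep(1 / sqrt(Lf), Lf))))
  cfg <- flow_config(beta = 50, basis = Q, basis_size = 2)
  fl <- estimate_flow_sequence(clip, cfg)
  P <- Q %*% t(Q)
  for (comp in list(fl$U, fl$V)) {
    W <- matrix(comp, N * N, Lf)
    expect_lt(mean(abs(W - W %*% P)), 1e-2)
  }
})

test_that("flow solver input validation", {
  expect_error(me_clip(array(0, c(8, 8, 1))), "at least 2")
  clip <- make_translating_clip(0, 0, L = 3, N = 16)
  expect_error(estimate_flow_sequence(clip, flow_config(basis_size = 5)),
               "basis_size")
})

test_that("flow color coding maps direction to hue and zero flow to white", {
  z <- matrix(0, 5, 5)
  img <- flow_color_code(z, z)
  expect_true(all(img == 1))  # white
  # constant field: one hue everywhere
  img2 <- flow_color_code(matrix(1, 5, 5), z)
  for (ch in 1:3) expect_equal(sd(img2[, , ch]), 0)
  # rotating every vector by 120 degrees shifts hue by the same angle
  set.seed(6)
  u <- matrix(rnorm(64), 8, 8); v <- matrix(rnorm(64), 8, 8)
  th <- 2 * pi / 3
  u2 <- cos(th) * u - sin(th) * v
  v2 <- sin(th) * u + cos(th) * v
  hue_of <- function(img) {
    mx <- pmax(img[, , 1], img[, , 2], img[, , 3])
    mn <- pmin(img[, , 1], img[, , 2], img[, , 3])
    h <- matrix(0, nrow(mx), ncol(mx))
    d <- mx - mn
    r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
    i1 <- mx == r; i2 <- mx == g & !i1; i3 <- !(i1 | i2)
    h[i1] <- ((g - b)[i1] / d[i1] / 6) %% 1
    h[i2] <- ((b - r)[i2] / d[i2] + 2) / 6
    h[i3] <- ((r - g)[i3] / d[i3] + 4) / 6
    h
  }
  h1 <- hue_of(flow_color_code(u, v, max_mag = 10))
  h2 <- hue_of(flow_color_code(u2, v2, max_mag = 10))
  shift <- (h2 - h1) %% 1
  expect_lt(max(abs(shift - th / (2 * pi))), 1e-6)
  expect_error(flow_color_code(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("cosine trajectory basis is orthonormal", {
  for (n in c(4, 9)) {
    Q <- dct_trajectory_basis(n, min(6, n))
    expect_equal(crossprod(Q), diag(ncol(Q)), tolerance = 1e-12)
  }
})
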