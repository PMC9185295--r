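#' Flow solver configuration
#'
#' Parameters of the temporally consistent dense optical-flow solver. Every
#' frame is matched against the clip's first (reference) frame; the
#' `trajectory` backend additionally pulls each pixel's motion trajectory
#' toward the span of `basis_size` smooth basis trajectories (a discrete
#' cosine basis by default), the `pairwise` backend solves each frame
#' independently.
#'
#' @param alpha weight of the brightness-constancy data term (> 0).
#' @param beta weight of the trajectory-subspace penalty (> 0 for the
#'   trajectory backend; the pairwise backend ignores it).
#' @param basis_size number of basis trajectories R; `NULL` means
#'   `min(6, L - 1)` at solve time.
#' @param pyramid_levels number of coarse-to-fine levels (scale 0.5).
#' @param iterations_per_level total linearized update sweeps per level,
#'   distributed over `outer_iterations` warping passes.
#' @param outer_iterations warping (outer) passes per level.
#' @param backend `"trajectory"` or `"pairwise"`.
#' @param basis optional `(L-1) x R` matrix of orthonormal basis
#'   trajectories, overriding the cosine basis.
#' @param eps_data,eps_tv Charbonnier smoothing constants of the data and
#'   total-variation penalties (intensity and pixel units respectively).
#' @param omega over-relaxation factor of the red-black SOR sweeps,
#'   `1 <= omega < 2`.
#' @return a `flow_config` object.
#' @export
flow_config <- function(alpha = 10, beta = 1, basis_size = NULL,
                        pyramid_levels = 3L, iterations_per_level = 50L,
                        outer_iterations = 5L,
                        backend = c("trajectory", "pairwise"),
                        basis = NULL, eps_data = 0.01, eps_tv = 0.05,
                        omega = 1.8) {
  backend <- match.arg(backend)
  stopifnot(alpha > 0, beta > 0, pyramid_levels >= 1,
            iterations_per_level >= 1, outer_iterations >= 1,
            omega >= 1, omega < 2)
  structure(list(alpha = alpha, beta = beta, basis_size = basis_size,
                 pyramid_levels = as.integer(pyramid_levels),
                 iterations_per_level = as.integer(iterations_per_level),
                 outer_iterations = as.integer(outer_iterations),
                 backend = backend, basis = basis,
                 eps_data = eps_data, eps_tv = eps_tv, omega = omega),
            class = "flow_config")
}

#' Orthonormal discrete cosine trajectory basis
#'
#' Columns are the first `R` DCT-II basis vectors over `n` time steps;
#' they are smooth, orthonormal, and span constant plus low-frequency
#' temporal motion patterns.
#'
#' @param n trajectory length (number of flow frames, L - 1).
#' @param R number of basis trajectories, `1 <= R <= n`.
#' @return an `n x R` matrix with orthonormal columns.
#' @export
dct_trajectory_basis <- function(n, R) {
  stopifnot(R >= 1, R <= n)
  t <- seq_len(n)
  Q <- sapply(seq_len(R), function(j) {
    if (j == 1L) rep(1 / sqrt(n), n)
    else sqrt(2 / n) * cos(pi * (2 * t - 1) * (j - 1) / (2 * n))
  })
  matrix(Q, n, R)
}

# --- internal solver pieces -------------------------------------------------

# One warping pass of the linearized robustified update for a single frame
# against the reference. Red-black SOR sweeps with lagged (IRLS) weights on
# the per-pixel 2x2 systems of
#   alpha*phi(I_t(x+w) - I_0) + beta*|w - p|^2 + TV(w)
# where p is the (fixed) trajectory-subspace projection target.
flow_update_frame <- function(I0, It, Itx, Ity, u, v, pu, pv,
                              alpha, beta, sweeps, eps_data, eps_tv,
                              omega = 1.8) {
  N <- nrow(I0); M <- ncol(I0)
  rr <- matrix(seq_len(N), N, M)
  cc <- matrix(seq_len(M), N, M, byrow = TRUE)
  Iw  <- bilinear_sample(It,  rr + v, cc + u)
  Ix  <- 0.5 * (bilinear_sample(Itx, rr + v, cc + u) + grad_x(I0))
  Iy  <- 0.5 * (bilinear_sample(Ity, rr + v, cc + u) + grad_y(I0))
  it0 <- Iw - I0
  u0 <- u; v0 <- v
  if (is.null(pu)) { pu <- 0; pv <- 0; beta <- 0 }
  cN <- seq_len(N); cM <- seq_len(M)
  up_i <- c(1L, cN[-N]); dn_i <- c(cN[-1], N)
  lf_i <- c(1L, cM[-M]); rt_i <- c(cM[-1], M)
  red <- (rr + cc) %% 2 == 0
  for (s in seq_len(sweeps)) {
    r <- it0 + Ix * (u - u0) + Iy * (v - v0)
    a <- alpha / sqrt(r * r + eps_data^2)
    # TV diffusivity from forward differences (owned by the left/top pixel)
    dux <- u[, rt_i] - u; duy <- u[dn_i, ] - u
    dvx <- v[, rt_i] - v; dvy <- v[dn_i, ] - v
    dux[, M] <- 0; dvx[, M] <- 0; duy[N, ] <- 0; dvy[N, ] <- 0
    g <- 1 / sqrt(dux^2 + duy^2 + dvx^2 + dvy^2 + eps_tv^2)
    wR <- g;          wR[, M] <- 0
    wD <- g;          wD[N, ] <- 0
    wL <- g[, lf_i];  wL[, 1] <- 0
    wU <- g[up_i, ];  wU[1, ] <- 0
    sw <- wR + wD + wL + wU
    cst <- it0 - Ix * u0 - Iy * v0
    A11 <- a * Ix * Ix + beta + sw
    A22 <- a * Iy * Iy + beta + sw
    A12 <- a * Ix * Iy
    det <- A11 * A22 - A12 * A12
    for (color in c(TRUE, FALSE)) {
      Su <- wR * u[, rt_i] + wL * u[, lf_i] + wD * u[dn_i, ] + wU * u[up_i, ]
      Sv <- wR * v[, rt_i] + wL * v[, lf_i] + wD * v[dn_i, ] + wU * v[up_i, ]
      b1 <- beta * pu + Su - a * Ix * cst
      b2 <- beta * pv + Sv - a * Iy * cst
      un <- (A22 * b1 - A12 * b2) / det
      vn <- (A11 * b2 - A12 * b1) / det
      m <- red == color
      u[m] <- (1 - omega) * u[m] + omega * un[m]
      v[m] <- (1 - omega) * v[m] + omega * vn[m]
    }
  }
  list(u = u, v = v)
}

# Project per-pixel trajectories onto the span of Q (applied separately to
# the u and v components); U is N x M x Lf.
project_trajectories <- function(U, Q) {
  d <- dim(U)
  W <- matrix(U, d[1] * d[2], d[3])
  array(W %*% Q %*% t(Q), dim = d)
}

flow_energy_arrays <- function(frames, U, V, alpha, beta, Q, eps_data,
                               eps_tv, trajectory = TRUE) {
  N <- dim(frames)[1]; M <- dim(frames)[2]; Lf <- dim(frames)[3] - 1L
  I0 <- frames[, , 1]
  rr <- matrix(seq_len(N), N, M)
  cc <- matrix(seq_len(M), N, M, byrow = TRUE)
  e_data <- 0; e_tv <- 0
  for (t in seq_len(Lf)) {
    u <- U[, , t]; v <- V[, , t]
    Iw <- bilinear_sample(frames[, , t + 1L], rr + v, cc + u)
    e_data <- e_data + sum(sqrt((Iw - I0)^2 + eps_data^2))
    dux <- u[, c(2:M, M)] - u; duy <- u[c(2:N, N), ] - u
    dvx <- v[, c(2:M, M)] - v; dvy <- v[c(2:N, N), ] - v
    e_tv <- e_tv + sum(sqrt(dux^2 + duy^2 + dvx^2 + dvy^2 + eps_tv^2))
  }
  e_traj <- 0
  if (trajectory && !is.null(Q)) {
    Ru <- U - project_trajectories(U, Q)
    Rv <- V - project_trajectories(V, Q)
    e_traj <- sum(Ru^2) + sum(Rv^2)
  }
  alpha * e_data + beta * e_traj + e_tv
}

#' Discretized flow-objective energy
#'
#' Evaluates the objective the solver minimizes: a Charbonnier-smoothed
#' brightness-constancy term against the reference frame, the squared
#' distance of per-pixel trajectories to the basis-trajectory subspace, and
#' isotropic total variation of the flow fields. Used by tests to check
#' that the solver's energy is non-increasing.
#'
#' @param clip an [me_clip].
#' @param flow a `flow_sequence` as returned by [estimate_flow_sequence()].
#' @param config a [flow_config()].
#' @return scalar energy.
#' @export
flow_energy <- function(clip, flow, config = flow_config()) {
  Lf <- dim(clip$frames)[3] - 1L
  Q <- NULL
  if (config$backend == "trajectory") {
    R <- min(config$basis_size %||% min(6L, Lf), Lf)
    Q <- config$basis %||% dct_trajectory_basis(Lf, R)
  }
  flow_energy_arrays(clip$frames, flow$U, flow$V, config$alpha, config$beta,
                     Q, config$eps_data, config$eps_tv,
                     trajectory = config$backend == "trajectory")
}

#' Estimate the dense optical flow of every frame against the first frame
#'
#' Coarse-to-fine estimation of the displacement fields mapping
#' reference-frame pixels to each later frame. At each pyramid level the
#' solver alternates (a) per-frame linearized brightness-constancy updates
#' with lagged-diffusivity total-variation regularization and (b), for the
#' `trajectory` backend, projection of per-pixel motion trajectories onto a
#' low-dimensional basis-trajectory subspace. At the finest level each outer
#' pass is accepted through a backtracking step so the discretized objective
#' ([flow_energy()]) is non-increasing. The solver is deterministic: flow is
#' initialized to zero at the coarsest level and no randomness is used.
#'
#' @param clip an [me_clip] with `L >= 2` frames.
#' @param config a [flow_config()].
#' @return a `flow_sequence`: list with arrays `U`, `V` of shape
#'   `N x M x (L-1)` (horizontal and vertical displacement in pixels; entry
#'   `t` maps the reference frame to frame `t + 1`) and `reference_index =
#'   0`. Values are rounded to float32, the precision of the `.flo` cache
#'   format, so cached and recomputed flow are identical. The element
#'   `energy_trace` records the accepted objective values at the finest
#'   level (initialization first); it is non-increasing by construction.
#' @export
estimate_flow_sequence <- function(clip, config = flow_config()) {
  frames <- clip$frames
  L <- dim(frames)[3]
  if (L < 2L) stop("flow needs at least 2 frames", call. = FALSE)
  Lf <- L - 1L
  trajectory <- config$backend == "trajectory"
  Q <- NULL
  if (trajectory) {
    R <- config$basis_size %||% min(6L, Lf)
    if (R < 1L || R > Lf)
      stop("basis_size must satisfy 1 <= R <= L-1", call. = FALSE)
    Q <- config$basis %||% dct_trajectory_basis(Lf, R)
    if (nrow(Q) != Lf) stop("basis must have L-1 rows", call. = FALSE)
  }
  N <- dim(frames)[1]; M <- dim(frames)[2]
  n_lev <- min(config$pyramid_levels,
               max(1L, floor(log2(min(N, M) / 12)) + 1L))
  sizes <- lapply(seq_len(n_lev), function(l)
    c(max(6L, round(N / 2^(l - 1))), max(6L, round(M / 2^(l - 1)))))
  sweeps <- max(1L, round(config$iterations_per_level /
                            config$outer_iterations))
  U <- V <- NULL
  for (lev in n_lev:1) {
    sz <- sizes[[lev]]
    fr <- array(0, dim = c(sz[1], sz[2], L))
    for (i in seq_len(L)) {
      f <- frames[, , i]
      if (lev > 1L) f <- gaussian_blur(f, 0.8 * 2^(lev - 1) / 2)
      fr[, , i] <- if (all(sz == c(N, M))) f else resize_bilinear(f, sz[1], sz[2])
    }
    Itx <- lapply(seq_len(Lf), function(t) grad_x(fr[, , t + 1L]))
    Ity <- lapply(seq_len(Lf), function(t) grad_y(fr[, , t + 1L]))
    if (is.null(U)) {
      U <- array(0, dim = c(sz[1], sz[2], Lf))
      V <- array(0, dim = c(sz[1], sz[2], Lf))
    } else {
      pu <- dim(U)[1:2]
      Un <- array(0, dim = c(sz[1], sz[2], Lf))
      Vn <- array(0, dim = c(sz[1], sz[2], Lf))
      for (t in seq_len(Lf)) {
        Un[, , t] <- resize_bilinear(U[, , t], sz[1], sz[2]) * sz[2] / pu[2]
        Vn[, , t] <- resize_bilinear(V[, , t], sz[1], sz[2]) * sz[1] / pu[1]
      }
      U <- Un; V <- Vn
    }
    finest <- lev == 1L
    e_prev <- if (finest)
      flow_energy_arrays(fr, U, V, config$alpha, config$beta, Q,
                         config$eps_data, config$eps_tv, trajectory)
    else NA_real_
    if (finest) energy_trace <- e_prev
    for (outer in seq_len(config$outer_iterations)) {
      PU <- if (trajectory) project_trajectories(U, Q) else NULL
      PV <- if (trajectory) project_trajectories(V, Q) else NULL
      Uc <- U; Vc <- V
      for (t in seq_len(Lf)) {
        res <- flow_update_frame(fr[, , 1], fr[, , t + 1L], Itx[[t]], Ity[[t]],
                                 Uc[, , t], Vc[, , t],
                                 if (trajectory) PU[, , t] else NULL,
                                 if (trajectory) PV[, , t] else NULL,
                                 config$alpha, config$beta, sweeps,
                                 config$eps_data, config$eps_tv,
                                 config$omega)
        if (!all(is.finite(res$u)) || !all(is.finite(res$v)))
          stop("flow solver produced non-finite values at level ", lev,
               ", outer iteration ", outer, call. = FALSE)
        Uc[, , t] <- res$u; Vc[, , t] <- res$v
      }
      if (finest) {
        # backtracking: accept the largest damped step that does not
        # increase the discretized objective
        step <- 1
        accepted <- FALSE
        for (j in 0:5) {
          Ut <- U + step * (Uc - U); Vt <- V + step * (Vc - V)
          e_new <- flow_energy_arrays(fr, Ut, Vt, config$alpha, config$beta,
                                      Q, config$eps_data, config$eps_tv,
                                      trajectory)
          if (e_new <= e_prev * (1 + 1e-12)) {
            U <- Ut; V <- Vt; e_prev <- e_new; accepted <- TRUE
            energy_trace <- c(energy_trace, e_new)
            break
          }
          step <- step / 2
        }
        if (!accepted) break
      } else {
        U <- Uc; V <- Vc
      }
    }
  }
  structure(list(U = to_float32(U), V = to_float32(V), reference_index = 0L,
                 clip_id = clip$clip_id, energy_trace = energy_trace),
            class = "flow_sequence")
}

#' @export
print.flow_sequence <- function(x, ...) {
  d <- dim(x$U)
  cat(sprintf("<flow_sequence> %dx%d, %d fields vs reference frame\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Color-code a flow field for visualization
#'
#' Hue encodes the flow direction `atan2(v, u)`; saturation encodes
#' magnitude normalized by the field's maximum (or a supplied maximum), so
#' zero flow renders white.
#'
#' @param u,v equal-shape numeric matrices of horizontal and vertical
#'   displacement.
#' @param max_mag optional normalization magnitude; defaults to
#'   `max(sqrt(u^2+v^2))`.
#' @return an `N x M x 3` RGB array in `[0, 1]`.
#' @export
flow_color_code <- function(u, v, max_mag = NULL) {
  if (!all(dim(u) == dim(v)))
    stop("u and v must have the same shape", call. = FALSE)
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("flow components must be finite", call. = FALSE)
  mag <- sqrt(u^2 + v^2)
  mm <- max_mag %||% max(mag)
  if (mm <= 0) mm <- 1
  s <- clamp(mag / mm, 0, 1)
  h <- (atan2(v, u) / (2 * pi)) %% 1
  hh <- h * 6
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  p <- 1 - s
  q <- 1 - s * f
  t <- 1 - s * (1 - f)
  one <- matrix(1, nrow(u), ncol(u))
  r <- ifelse(i == 0, one, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, one)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, one, ifelse(i == 2, one,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, one, ifelse(i == 4, one, q)))))
  out <- array(0, dim = c(nrow(u), ncol(u), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
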