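#' Specification of a synthetic clip dataset
#'
#' Describes a labeled dataset of short clips with subject structure and
#' class-dependent localized motion, emulating the statistics the pipeline
#' targets: a mostly static textured scene with a subtle, spatially
#' localized sub-pixel-to-few-pixel drift whose location and direction
#' depend on the class, while the texture (the "identity") depends on the
#' subject.
#'
#' @param n_subjects number of subjects.
#' @param clips_per_subject total clips per subject; class labels are
#'   assigned by cycling through `classes`.
#' @param classes character vector of built-in motion archetypes; available:
#'   `"mouth_up"` (lower-face region drifting up), `"brow_down"`
#'   (upper-face region drifting down), `"dilate"` (symmetric radial
#'   dilation about the center).
#' @param frame_size integer `c(height, width)`, default `c(64, 64)`.
#' @param clip_length frames per clip (default 10).
#' @param motion_amplitude peak displacement in pixels per frame (<= 3,
#'   the small-motion regime; default 2).
#' @param noise_sigma standard deviation of i.i.d. intensity noise added
#'   after warping (default 0.01).
#' @param texture `"filtered-noise"` (smoothed Gaussian noise) or
#'   `"gaussian-blobs"` (random blob field).
#' @param seed integer fixing all randomness.
#' @return a `synth_spec` object.
#' @export
synth_spec <- function(n_subjects = 6L, clips_per_subject = 3L,
                       classes = c("mouth_up", "brow_down", "dilate"),
                       frame_size = c(64L, 64L), clip_length = 10L,
                       motion_amplitude = 2, noise_sigma = 0.01,
                       texture = c("filtered-noise", "gaussian-blobs"),
                       seed = 1L) {
  texture <- match.arg(texture)
  if (motion_amplitude > 3)
    stop("motion_amplitude must be <= 3 px/frame (small-motion regime)",
         call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  stopifnot(n_subjects >= 1, clips_per_subject >= 1, clip_length >= 2)
  structure(list(n_subjects = as.integer(n_subjects),
                 clips_per_subject = as.integer(clips_per_subject),
                 classes = classes,
                 frame_size = as.integer(frame_size),
                 clip_length = as.integer(clip_length),
                 motion_amplitude = motion_amplitude,
                 noise_sigma = noise_sigma, texture = texture,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Class-specific displacement field of a motion archetype
#'
#' Smooth Gaussian-bump displacement fields at class-specific locations,
#' mimicking sparse localized facial action units: `"mouth_up"` is an
#' upward drift of a lower-face region, `"brow_down"` a downward drift of
#' an upper-face region, and `"dilate"` a symmetric radial expansion about
#' the frame center. The peak magnitude is `amplitude` pixels (per frame,
#' when used to build a clip).
#'
#' @param class archetype name.
#' @param N,M field height and width.
#' @param amplitude peak displacement in pixels.
#' @return list with matrices `u` (horizontal) and `v` (vertical).
#' @export
class_motion_field <- function(class, N, M, amplitude = 2) {
  rr <- matrix(seq_len(N), N, M)
  cc <- matrix(seq_len(M), N, M, byrow = TRUE)
  sigma <- 0.14 * min(N, M)
  bump <- function(cr, cm) exp(-((rr - cr)^2 + (cc - cm)^2) / (2 * sigma^2))
  switch(class,
    mouth_up = {
      b <- bump(0.70 * N, 0.45 * M)
      list(u = 0.25 * amplitude * b, v = -amplitude * b)
    },
    brow_down = {
      b <- bump(0.30 * N, 0.55 * M)
      list(u = -0.25 * amplitude * b, v = amplitude * b)
    },
    dilate = {
      dr <- rr - (0.5 * N + 0.5); dc <- cc - (0.5 * M + 0.5)
      r <- sqrt(dr^2 + dc^2)
      g <- exp(-(r - 0.22 * min(N, M))^2 / (2 * (0.5 * sigma)^2))
      scl <- amplitude * g / pmax(r, 1e-6)
      list(u = scl * dc, v = scl * dr)
    },
    stop("unknown motion archetype '", class, "'", call. = FALSE)
  )
}

#' Generate a smooth random texture image
#'
#' Draws from the current RNG state; intensities are rescaled to
#' `[0.15, 0.85]` so added noise stays within the valid range.
#'
#' @param N,M image size.
#' @param type `"filtered-noise"` (two smoothing scales of white noise) or
#'   `"gaussian-blobs"`.
#' @return an `N x M` matrix.
#' @export
synthetic_texture <- function(N, M, type = "filtered-noise") {
  img <- if (type == "gaussian-blobs") {
    acc <- matrix(0, N, M)
    rr <- matrix(seq_len(N), N, M)
    cc <- matrix(seq_len(M), N, M, byrow = TRUE)
    for (b in seq_len(30)) {
      cr <- stats::runif(1, 1, N); cm <- stats::runif(1, 1, M)
      s <- stats::runif(1, 0.03, 0.10) * min(N, M)
      acc <- acc + stats::rnorm(1) *
        exp(-((rr - cr)^2 + (cc - cm)^2) / (2 * s^2))
    }
    acc
  } else {
    gaussian_blur(matrix(stats::rnorm(N * M), N, M), 1.2) +
      0.6 * gaussian_blur(matrix(stats::rnorm(N * M), N, M), 3.5)
  }
  rng <- range(img)
  0.15 + 0.70 * (img - rng[1]) / (rng[2] - rng[1])
}

#' Warp a base image into a clip with linearly growing displacement
#'
#' Frame `t` (1-based) is the bilinear backward warp of `base` by
#' `(t-1) * displacement`: frame 1 is the base itself and scene features
#' move along `+displacement` per frame, so the ground-truth flow from the
#' reference frame to frame `t` is `(t-1) * displacement`.
#'
#' @param base `N x M` matrix.
#' @param displacement list with matrices `u`, `v` (pixels per frame).
#' @param L number of frames.
#' @return an `N x M x L` array.
#' @export
warp_sequence <- function(base, displacement, L) {
  N <- nrow(base); M <- ncol(base)
  u <- displacement$u; v <- displacement$v
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("displacement must be finite", call. = FALSE)
  if ((L - 1) * max(abs(u)) >= M || (L - 1) * max(abs(v)) >= N)
    stop("cumulative displacement exceeds the image size", call. = FALSE)
  rr <- matrix(seq_len(N), N, M)
  cc <- matrix(seq_len(M), N, M, byrow = TRUE)
  out <- array(0, dim = c(N, M, L))
  out[, , 1] <- base
  for (t in 2:L) {
    k <- t - 1
    out[, , t] <- bilinear_sample(base, rr - k * v, cc - k * u)
  }
  out
}

# Build one synthetic clip in memory (frames + per-frame displacement).
make_synth_clip <- function(spec, texture_base, class) {
  N <- spec$frame_size[1]; M <- spec$frame_size[2]
  d <- class_motion_field(class, N, M, spec$motion_amplitude)
  frames <- warp_sequence(texture_base, d, spec$clip_length)
  if (spec$noise_sigma > 0) {
    frames <- frames + array(stats::rnorm(length(frames), 0,
                                          spec$noise_sigma), dim(frames))
  }
  list(frames = clamp(frames, 0, 1), displacement = d)
}

#' Generate and write a synthetic clip dataset
#'
#' Writes, for every clip, a directory of 8-bit
#' PNG frames, a `manifest.csv` (`clip_id,path,subject,label`) and the
#' ground-truth displacement fields as Middlebury `.flo` files
#' (`<clip_id>_<t>.flo`, the flow from the reference frame to frame
#' `t + 1`) under `out_dir/groundtruth/`. Each clip is a per-subject random
#' texture (with a small per-clip perturbation) warped by its class's
#' displacement field scaled linearly in time, plus i.i.d. intensity noise.
#' Fully deterministic for a fixed `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @param out_dir output directory (created if needed).
#' @return the `dataset_index` of the written manifest.
#' @export
make_synthetic_dataset <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  gt_dir <- file.path(out_dir, "groundtruth")
  dir.create(gt_dir, showWarnings = FALSE)
  N <- spec$frame_size[1]; M <- spec$frame_size[2]
  rows <- list()
  with_seed(spec$seed, {
    for (si in seq_len(spec$n_subjects)) {
      subject <- sprintf("s%02d", si)
      base <- synthetic_texture(N, M, spec$texture)
      for (rep in seq_len(spec$clips_per_subject)) {
        {
          class <- spec$classes[(rep - 1L) %% length(spec$classes) + 1L]
          clip_id <- sprintf("%s_%02d_%s", subject, rep, class)
          pert <- 0.03 * gaussian_blur(matrix(stats::rnorm(N * M), N, M), 2)
          clip <- make_synth_clip(spec, clamp(base + pert, 0.05, 0.95),
                                  class)
          # quantize to the PNG bit depth before writing so the files are
          # byte-identical across runs and platforms
          frame_dir <- file.path(out_dir, clip_id)
          dir.create(frame_dir, showWarnings = FALSE)
          for (t in seq_len(spec$clip_length)) {
            png::writePNG(round(clip$frames[, , t] * 255) / 255,
                          file.path(frame_dir,
                                    sprintf("frame_%03d.png", t)))
          }
          for (t in seq_len(spec$clip_length - 1L)) {
            write_flo(list(u = t * clip$displacement$u,
                           v = t * clip$displacement$v),
                      file.path(gt_dir, sprintf("%s_%d.flo", clip_id, t)))
          }
          rows[[length(rows) + 1L]] <- data.frame(
            clip_id = clip_id, path = clip_id, subject = subject,
            label = class, stringsAsFactors = FALSE)
        }
      }
    }
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  read_manifest(file.path(out_dir, "manifest.csv"))
}
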