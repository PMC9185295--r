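#' Construct and validate a video clip object
#'
#' A clip is the unit of classification: a grayscale frame stack
#' `N x M x L` with intensities in `[0, 1]`, plus identifiers used by the
#' leave-one-subject-out protocol.
#'
#' @param frames numeric 3-D array, height x width x length, values in
#'   `[0, 1]`.
#' @param clip_id character scalar, unique within a dataset.
#' @param subject_id character scalar naming the subject the clip belongs to.
#' @param label character scalar, the motion class.
#' @return an object of class `me_clip`.
#' @export
me_clip <- function(frames, clip_id = "clip", subject_id = "s0",
                    label = NA_character_) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (height x width x length)",
         call. = FALSE)
  if (dim(frames)[3] < 2L)
    stop("a clip needs at least 2 frames (L >= 2)", call. = FALSE)
  if (!all(is.finite(frames)))
    stop("clip intensities must be finite", call. = FALSE)
  if (min(frames) < -1e-9 || max(frames) > 1 + 1e-9)
    stop("clip intensities must lie in [0, 1]", call. = FALSE)
  structure(list(frames = frames, clip_id = as.character(clip_id),
                 subject_id = as.character(subject_id),
                 label = as.character(label)),
            class = "me_clip")
}

#' @export
print.me_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<me_clip %s> subject=%s label=%s frames=%dx%dx%d\n",
              x$clip_id, x$subject_id, x$label, d[1], d[2], d[3]))
  invisible(x)
}

read_frame_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (requireNamespace("EBImage", quietly = TRUE)) {
    img <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores width-major; transpose back to row = height
    if (length(dim(img)) == 2L) return(t(img))
    return(aperm(img, c(2L, 1L, 3L)))
  }
  stop("cannot read '", path,
       "': only PNG frames are supported without the EBImage package",
       call. = FALSE)
}

#' Load a clip from a directory of image frames
#'
#' Frames are taken in lexicographic filename order (zero-padded numbering is
#' assumed), converted to grayscale with Rec. 601 luma weights, resized with
#' bilinear interpolation and scaled to `[0, 1]`. The default target size
#' (170 x 139) matches the network's reference input geometry.
#'
#' @param path directory containing numbered PNG/JPEG frames.
#' @param target_size integer vector `c(height, width)`; `NULL` keeps the
#'   native size of each frame (all frames must then agree).
#' @param clip_id,subject_id,label metadata attached to the clip.
#' @param frames optional explicit character vector of frame filenames
#'   (relative to `path`), overriding lexicographic ordering.
#' @return an [me_clip] object.
#' @export
load_clip <- function(path, target_size = c(170L, 139L), clip_id = NULL,
                      subject_id = "s0", label = NA_character_,
                      frames = NULL) {
  if (!dir.exists(path)) {
    if (file.exists(path))
      stop("'", path, "' is a file; video containers are not supported, ",
           "supply a directory of image frames", call. = FALSE)
    stop("clip directory '", path, "' does not exist", call. = FALSE)
  }
  if (is.null(frames)) {
    frames <- sort(list.files(path, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                              ignore.case = TRUE))
  }
  if (length(frames) == 0L)
    stop("no image frames found in '", path, "'", call. = FALSE)
  if (length(frames) < 2L)
    stop("clip '", path, "' has a single frame; L >= 2 required",
         call. = FALSE)
  imgs <- lapply(file.path(path, frames), function(f) to_gray(read_frame_image(f)))
  sizes <- vapply(imgs, function(m) dim(m), integer(2))
  if (is.null(target_size)) {
    if (any(sizes[1, ] != sizes[1, 1]) || any(sizes[2, ] != sizes[2, 1]))
      stop("frames in '", path, "' have inconsistent sizes and no ",
           "target_size was given", call. = FALSE)
    target_size <- sizes[, 1]
  } else if (any(sizes[1, ] != sizes[1, 1]) || any(sizes[2, ] != sizes[2, 1])) {
    warning("frames in '", path,
            "' have inconsistent sizes; each is resized independently",
            call. = FALSE)
  }
  N <- as.integer(target_size[1]); M <- as.integer(target_size[2])
  arr <- array(0, dim = c(N, M, length(imgs)))
  for (i in seq_along(imgs)) {
    m <- imgs[[i]]
    arr[, , i] <- if (nrow(m) == N && ncol(m) == M) m else
      resize_bilinear(m, N, M)
  }
  arr <- clamp(arr, 0, 1)
  me_clip(arr, clip_id = clip_id %||% basename(path),
          subject_id = subject_id, label = label)
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with header `clip_id,path,subject,label`; `path`
#' entries are resolved relative to the manifest's own directory. Class names
#' are kept in first-appearance order, which also fixes the ordering of LOSO
#' folds and confusion-matrix axes.
#'
#' @param path CSV file path.
#' @return an object of class `dataset_index` with elements `entries`
#'   (data.frame), `class_names` and `subjects`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop("manifest '", path, "' does not exist", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("manifest '", path, "' is empty", call. = FALSE)
  need <- c("clip_id", "path", "subject", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dup <- df$clip_id[duplicated(df$clip_id)]
  if (length(dup) > 0L)
    stop("duplicate clip_id in manifest: ", paste(unique(dup), collapse = ", "),
         " (rows ", paste(which(df$clip_id %in% dup), collapse = ", "), ")",
         call. = FALSE)
  root <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(root, df$path))
  df$path <- abs
  dataset_index(df)
}

#' Build a dataset index from a manifest-style data frame
#'
#' @param entries data.frame with columns `clip_id`, `path`, `subject`,
#'   `label`.
#' @return a `dataset_index` object.
#' @export
dataset_index <- function(entries) {
  need <- c("clip_id", "path", "subject", "label")
  if (!all(need %in% names(entries)))
    stop("entries must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(entries$clip_id))
    stop("clip_id values must be unique", call. = FALSE)
  structure(list(entries = as.data.frame(entries,
                                         stringsAsFactors = FALSE),
                 class_names = unique(as.character(entries$label)),
                 subjects = unique(as.character(entries$subject))),
            class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> %d clips, %d subjects, classes: %s\n",
              nrow(x$entries), length(x$subjects),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

FLO_MAGIC <- 202021.25

#' Write a single-frame flow field in Middlebury .flo format
#'
#' Layout: float32 magic 202021.25, int32 width, int32 height, then
#' row-major interleaved (u, v) float32 pairs. Round-trips are lossless at
#' 32-bit precision.
#'
#' @param flow list with numeric matrices `u` (horizontal, columns) and `v`
#'   (vertical, rows) of equal shape.
#' @param path output file.
#' @export
write_flo <- function(flow, path) {
  u <- flow$u; v <- flow$v
  if (!is.matrix(u) || !is.matrix(v) || !all(dim(u) == dim(v)))
    stop("flow must have two equal-shape matrix components u, v",
         call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FLO_MAGIC, con, size = 4L, endian = "little")
  writeBin(c(ncol(u), nrow(u)), con, size = 4L, endian = "little")
  inter <- numeric(2L * length(u))
  inter[seq(1L, by = 2L, length.out = length(u))] <- as.numeric(t(u))
  inter[seq(2L, by = 2L, length.out = length(u))] <- as.numeric(t(v))
  writeBin(inter, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a Middlebury .flo flow field
#'
#' @param path file written by [write_flo()] (or any Middlebury-format flow).
#' @return list with matrices `u` and `v`.
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "numeric", n = 1L, size = 4L, endian = "little")
  if (length(magic) == 0L || abs(magic - FLO_MAGIC) > 1e-3)
    stop("'", path, "' is not a .flo file (bad magic number)", call. = FALSE)
  wh <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  M <- wh[1]; N <- wh[2]
  dat <- readBin(con, "numeric", n = 2L * N * M, size = 4L, endian = "little")
  if (length(dat) < 2L * N * M)
    stop("'", path, "' is truncated", call. = FALSE)
  u <- matrix(dat[seq(1L, by = 2L, length.out = N * M)], N, M, byrow = TRUE)
  v <- matrix(dat[seq(2L, by = 2L, length.out = N * M)], N, M, byrow = TRUE)
  list(u = u, v = v)
}
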