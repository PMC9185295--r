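#' Stack a flow sequence into multi-channel images with a sliding window
#'
#' A window of `T` consecutive flow frames yields one `N x M x 2T` tensor:
#' channels `1..T` are the window's horizontal (u) fields, channels
#' `T+1..2T` the corresponding vertical (v) fields. Window `i` covers flow
#' frames `(i-1)s+1 .. (i-1)s+T`; the number of complete windows inside the
#' flow sequence of length `L-1` is `floor(((L-1)-T)/s) + 1`, and trailing
#' flow frames not covered by a complete window are dropped.
#'
#' @param flow a `flow_sequence` (arrays `U`, `V` of shape `N x M x (L-1)`).
#' @param T window length in flow frames (default 5).
#' @param s window step; `NULL` selects the default `(T-1)/2` (floored, and
#'   at least 1 so that `T = 1` remains valid).
#' @return a `stacked_set`: list with `tensors` (list of `N x M x 2T`
#'   arrays), `T`, `s` and `source_clip_id`.
#' @export
stack_flow_sequence <- function(flow, T = 5L, s = NULL) {
  T <- as.integer(T)
  if (T < 1L) stop("window length T must be >= 1", call. = FALSE)
  Lf <- dim(flow$U)[3]
  if (Lf < T)
    stop("flow sequence has ", Lf, " frames, shorter than window T = ", T,
         call. = FALSE)
  if (is.null(s)) {
    s <- max(1L, (T - 1L) %/% 2L)
  } else {
    s <- as.integer(s)
    if (s <= 0L) {
      warning("step size ", s, " corrected to 1", call. = FALSE)
      s <- 1L
    }
  }
  n_win <- (Lf - T) %/% s + 1L
  N <- dim(flow$U)[1]; M <- dim(flow$U)[2]
  tensors <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    idx <- ((i - 1L) * s + 1L):((i - 1L) * s + T)
    tensors[[i]] <- array(c(flow$U[, , idx], flow$V[, , idx]),
                          dim = c(N, M, 2L * T))
  }
  structure(list(tensors = tensors, T = T, s = s,
                 source_clip_id = flow$clip_id %||% NA_character_),
            class = "stacked_set")
}

#' @export
print.stacked_set <- function(x, ...) {
  d <- dim(x$tensors[[1]])
  cat(sprintf("<stacked_set> %d tensors of %dx%dx%d (T=%d, s=%d)\n",
              length(x$tensors), d[1], d[2], d[3], x$T, x$s))
  invisible(x)
}
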