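# Fixtures are generated in code; nothing is stored on disk.

# A smooth random texture suitable for flow estimation.
make_texture <- function(N = 48, M = N, seed = 7) {
  ofpcanet:::with_seed(seed, synthetic_texture(N, M))
}

# A clip translating globally by (du, dv) pixels per frame.
make_translating_clip <- function(du = 1, dv = 0, L = 6, N = 48, seed = 7) {
  base <- make_texture(N, seed = seed)
  me_clip(warp_sequence(base, list(u = matrix(du, N, N),
                                   v = matrix(dv, N, N)), L))
}

# Write a tiny frame-directory clip dataset + manifest; returns manifest path.
write_tiny_dataset <- function(dir, n_frames = 3, size = c(12, 10),
                               subjects = c("s1", "s1", "s2", "s3"),
                               labels = c("a", "b", "a", "b")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(subjects), function(i) {
    id <- sprintf("clip%02d", i)
    fd <- file.path(dir, id)
    dir.create(fd, showWarnings = FALSE)
    for (t in seq_len(n_frames)) {
      img <- matrix((i * 7 + t * 3) %% 200 / 255, size[1], size[2])
      png::writePNG(img, file.path(fd, sprintf("f%02d.png", t)))
    }
    data.frame(clip_id = id, path = id, subject = subjects[i],
               label = labels[i], stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE,
                   quote = FALSE)
  manifest
}

# Independent naive correlation oracle: same-size correlation with zero
# padding, written as explicit nested loops.
naive_correlate <- function(image, w) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1L)
  N <- dim(image)[1]; M <- dim(image)[2]; C <- dim(image)[3]
  k <- dim(w)[1]; pad <- (k - 1) / 2
  out <- matrix(0, N, M)
  for (r in seq_len(N)) for (c in seq_len(M)) {
    s <- 0
    for (dr in -pad:pad) for (dc in -pad:pad) for (ch in seq_len(C)) {
      rr <- r + dr; cc <- c + dc
      val <- if (rr >= 1 && rr <= N && cc >= 1 && cc <= M)
        image[rr, cc, ch] else 0
      s <- s + val * w[dr + pad + 1, dc + pad + 1, ch]
    }
    out[r, c] <- s
  }
  out
}
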