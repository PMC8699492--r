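# Shared in-code fixtures: all test images are built programmatically.

# Disc silhouette as a logical matrix (radius in px, small pad around it).
disc_matrix <- function(radius, pad = 10L) {
  n <- 2L * radius + 2L * pad + 1L
  ctr <- (n + 1L) / 2
  m <- matrix(FALSE, n, n)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= radius^2] <- TRUE
  m
}

# Wrap a logical matrix as the single cell_instance it contains.
as_instance <- function(px, pixel_size_um = 1) {
  cells <- label_instances(binary_mask(px, pixel_size_um))
  stopifnot(length(cells) == 1L)
  cells[[1L]]
}

# Minimal hand-built neurite trace for analytic path-geometry oracles.
make_trace <- function(path, length_um, pixel_size_um = 1) {
  structure(list(neurite_id = 1L, path = path,
                 base = c(row = path[1L, 1L], col = path[1L, 2L]),
                 tip = c(row = path[nrow(path), 1L],
                         col = path[nrow(path), 2L]),
                 length_um = length_um, pixel_size_um = pixel_size_um),
            class = "neurite_trace")
}

# Brute-force gliding-box lacunarity oracle (independent of the package's
# summed-area-table implementation).
lacunarity_oracle <- function(px, r) {
  masses <- c()
  for (i in 1:(nrow(px) - r + 1L))
    for (j in 1:(ncol(px) - r + 1L))
      masses <- c(masses, sum(px[i:(i + r - 1L), j:(j + r - 1L)]))
  mean(masses^2) / mean(masses)^2
}

# Brute-force GLCM oracle: explicit loop over pixel pairs.
glcm_oracle <- function(q, levels, offsets, symmetric = TRUE) {
  G <- matrix(0, levels, levels)
  for (off in offsets) {
    for (i in seq_len(nrow(q))) for (j in seq_len(ncol(q))) {
      i2 <- i + off[1L]; j2 <- j + off[2L]
      if (i2 >= 1 && i2 <= nrow(q) && j2 >= 1 && j2 <= ncol(q))
        G[q[i, j] + 1L, q[i2, j2] + 1L] <- G[q[i, j] + 1L, q[i2, j2] + 1L] + 1
    }
  }
  if (symmetric) G <- G + t(G)
  G / sum(G)
}
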