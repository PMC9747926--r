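# Shared fixtures and independent oracles.

# Brute-force NICK threshold: per-pixel double loop over reflected
# windows, independent of the integral-image implementation.
naive_nick <- function(gray, kappa, N) {
  side <- sqrt(N)
  r <- (side - 1) / 2
  nr <- nrow(gray); nc <- ncol(gray)
  ridx <- c(r:1, 1:nr, nr:(nr - r + 1))
  cidx <- c(r:1, 1:nc, nc:(nc - r + 1))
  p <- gray[ridx, cidx]
  out <- matrix(FALSE, nr, nc)
  for (i in 1:nr) {
    for (j in 1:nc) {
      w <- p[i:(i + 2 * r), j:(j + 2 * r)]
      avg <- mean(w)
      tau <- avg + kappa * sqrt(max(sum(w^2) - avg^2, 0) / N)
      out[i, j] <- gray[i, j] < tau
    }
  }
  out
}

# Two-shade lesion on a bright background: dark core inside a lighter
# ring, sized so that single-pass NICK thresholding (19x19 window)
# captures the core but not the whole ring, while one growth pass
# recovers core and ring exactly.
two_shade_disk <- function(size = 41L, core_radius = 5, ring_radius = 9,
                           core = 0.1, ring = 0.45, background = 0.9) {
  g <- matrix(background, size, size)
  ctr <- (size + 1) / 2
  d2 <- (row(g) - ctr)^2 + (col(g) - ctr)^2
  g[d2 <= ring_radius^2] <- ring
  g[d2 <= core_radius^2] <- core
  list(gray = g,
       core = d2 <= core_radius^2,
       ring = d2 <= ring_radius^2 & d2 > core_radius^2,
       lesion = d2 <= ring_radius^2)
}

# Filled disk mask.
disk_mask <- function(size, radius, center = c((size + 1) / 2, (size + 1) / 2)) {
  m <- matrix(FALSE, size, size)
  m[(row(m) - center[1])^2 + (col(m) - center[2])^2 <= radius^2] <- TRUE
  m
}

# Small scene parameters used throughout the tests (full-resolution
# scenes are unnecessary for correctness checks).
test_scene_size <- c(128L, 127L)
test_nick_N <- 441L  # 21x21 window, scaled to the test scene size
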