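# Shared fixtures and independent oracles.

# Brute-force causal convolution (loop oracle, independent of the package's
# matrix implementation).
conv_loop <- function(kernel, signal) {
  n <- length(signal)
  out <- numeric(n)
  for (k in seq_len(n)) {
    s <- 0
    for (j in seq_len(k)) s <- s + kernel[j] * signal[k - j + 1]
    out[k] <- s
  }
  out
}

# Flood-fill connected-component oracle.
flood_label <- function(mask, connectivity = 8) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nb <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1L) %% ny + 1L; cc <- (p - 1L) %/% ny + 1L
      for (k in seq_len(nrow(nb))) {
        rr <- r + nb[k, 1]; ccc <- cc + nb[k, 2]
        if (rr >= 1 && rr <= ny && ccc >= 1 && ccc <= nx) {
          q <- (ccc - 1L) * ny + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

# Two labelings agree iff they induce the same partition of the foreground.
same_partition <- function(a, b) {
  fa <- a[a > 0]; fb <- b[b > 0]
  if (length(fa) != length(fb)) return(FALSE)
  key_a <- as.integer(factor(a[a > 0], levels = unique(a[a > 0])))
  key_b <- as.integer(factor(b[b > 0], levels = unique(b[b > 0])))
  all(key_a == key_b)
}

# A small disk mask.
disk_mask <- function(size, cy, cx, r) {
  y <- matrix(seq_len(size), size, size)
  x <- matrix(seq_len(size), size, size, byrow = TRUE)
  (y - cy)^2 + (x - cx)^2 <= r^2
}

test_irf <- function() irf_gaussian(center_ps = 500, fwhm_ps = 250)

# A quick low-resolution scene for unit tests.
small_scene <- function(seed = 1, n_cells = 4, size = 128, ...) {
  generate_scene(scene_spec(size = size, n_cells = n_cells, n_distractors = 2,
                            n_bins = 64, seed = seed, ...))
}
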