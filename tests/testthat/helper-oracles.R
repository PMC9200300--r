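# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (brute force / direct definition) and is kept
# deliberately naive.

# 8-connected component count via BFS flood fill
flood_fill_count <- function(mask) {
  m <- unclass(mask)
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (m[i, j] == 1L && !seen[i, j]) {
      count <- count + 1L
      queue <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(queue) > 0) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- cur[1] + di; nj <- cur[2] + dj
          if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
              m[ni, nj] == 1L && !seen[ni, nj]) {
            seen[ni, nj] <- TRUE
            queue[[length(queue) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
  }
  count
}

# exhaustive Kapur criterion search, straight from the definition
brute_force_kapur <- function(q) {
  shannon <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  P <- cumsum(q)
  best <- -Inf; best_t <- NA_integer_
  for (T in 0:255) {
    pb <- P[T + 1]; pf <- 1 - pb
    if (pb <= 0 || pf <= 0) next
    H <- shannon(q[1:(T + 1)] / pb) + shannon(q[(T + 2):256] / pf)
    if (H > best + 1e-12) { best <- H; best_t <- T }
  }
  best_t
}

# per-pixel 3x3 median with replicated borders
brute_force_median3 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  out <- x
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ri <- pmin(pmax(i + (-1:1), 1), h)
    ci <- pmin(pmax(j + (-1:1), 1), w)
    out[i, j] <- stats::median(x[ri, ci])
  }
  out
}

# max pairwise distance over all pixel corner points (no hull shortcut)
brute_force_feret <- function(pixels) {
  pts <- rbind(cbind(pixels[, 1] - 0.5, pixels[, 2] - 0.5),
               cbind(pixels[, 1] - 0.5, pixels[, 2] + 0.5),
               cbind(pixels[, 1] + 0.5, pixels[, 2] - 0.5),
               cbind(pixels[, 1] + 0.5, pixels[, 2] + 0.5))
  max(stats::dist(pts))
}

# random 256-bin histogram with a controllable number of occupied bins
random_histogram <- function(min_bins = 2L) {
  repeat {
    counts <- rpois(256, lambda = rexp(256, 1 / 20))
    if (sum(counts > 0) >= min_bins) return(counts)
  }
}

# small scene with n disjoint disks on a quiet background
disk_scene <- function(n = 5, seed = 1, canvas = c(96, 96), ...) {
  generate_scene(sample_scene_spec(canvas, n, archetypes = "particle",
                                   seed = seed, ...))
}

random_mask <- function(h, w, p = 0.3) {
  mp_mask(matrix(rbinom(h * w, 1, p), h, w))
}
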