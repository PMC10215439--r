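# Fixtures and independent oracles used across the suite.

# Planar grid mesh in the z = 0 plane with +z normals; WSS vectors in the
# xy-plane are exactly tangent, so direction-controlled fields are easy to
# construct on it.
flat_patch_mesh <- function(nx = 4L, ny = 4L, spacing = 1) {
  xs <- seq(0, by = spacing, length.out = nx)
  ys <- seq(0, by = spacing, length.out = ny)
  verts <- cbind(rep(xs, ny), rep(ys, each = nx), 0)
  idx <- function(i, j) i + nx * (j - 1L)
  i <- rep(seq_len(nx - 1L), ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  faces <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                 cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  surface_mesh(verts, faces)
}

# Uniform-direction field: wss(t) = s(t) * e at every vertex.
uniform_field <- function(mesh, times, period, signal, direction) {
  n <- nrow(mesh$vertices)
  direction <- direction / sqrt(sum(direction^2))
  s <- signal(times)
  vectors <- array(0, dim = c(length(times), n, 3L))
  for (c3 in 1:3) vectors[, , c3] <- outer(s, rep(direction[c3], n))
  wss_field(mesh, times, period, vectors)
}

# Random band-limited tangential field on a flat patch: per-vertex random
# Fourier coefficients (<= 3 harmonics) along ex and ey.
random_tangent_field <- function(mesh, K = 64L, period = 1, n_harm = 3L) {
  n <- nrow(mesh$vertices)
  times <- seq(0, period, length.out = K + 1L)[seq_len(K)]
  vectors <- array(0, dim = c(K, n, 3L))
  for (c3 in 1:2) {  # tangent components only (normal is +z)
    comp <- matrix(stats::rnorm(n, sd = 0.5), K, n, byrow = TRUE)
    for (h in seq_len(n_harm)) {
      ph <- 2 * pi * h * times / period
      comp <- comp + outer(cos(ph), stats::rnorm(n, sd = 0.5)) +
        outer(sin(ph), stats::rnorm(n, sd = 0.5))
    }
    vectors[, , c3] <- comp
  }
  wss_field(mesh, times, period, vectors)
}

# Brute-force oracles ------------------------------------------------------

# All-pairs nearest-vertex distance, pure R.
brute_nearest_distance <- function(query, target) {
  vapply(seq_len(nrow(query)), function(i) {
    sqrt(min(colSums((t(target) - query[i, ])^2)))
  }, numeric(1))
}

# Rank-then-Pearson Spearman coefficient.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Dense-grid cycle mean of a scalar function of time (independent of the
# package quadrature: plain uniform-grid average over one period).
dense_cycle_mean <- function(f, period, n = 1e5L) {
  t <- seq(0, period, length.out = n + 1L)[seq_len(n)]
  mean(f(t))
}

# Sort-based summary statistics (type-7 quantiles done by hand).
brute_summary <- function(x) {
  x <- sort(x)
  n <- length(x)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  list(median = q7(0.5), q1 = q7(0.25), q3 = q7(0.75),
       p10 = q7(0.1), p90 = q7(0.9))
}
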