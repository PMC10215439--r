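uniform_times <- function(K, period = 1) seq(0, period, length.out = K + 1L)[seq_len(K)]

test_that("cycle averaging: constant, zero-mean and two-harmonic signals", {
  mesh <- flat_patch_mesh(3, 3)
  t <- uniform_times(360)
  # constant field c * e
  fc <- uniform_field(mesh, t, 1, function(t) rep(2, length(t)), c(1, 0, 0))
  expect_equal(time_average_vector(fc), matrix(rep(c(2, 0, 0), each = 9), 9, 3))
  # pure cosine: mean vanishes to near machine precision
  fz <- uniform_field(mesh, t, 1, function(t) 3 * cos(2 * pi * t), c(0, 1, 0))
  expect_lt(max(abs(time_average_vector(fz))), 1e-10 * 3)
  # two-harmonic signal vs dense-grid oracle
  sig <- function(t) 1.2 + 0.7 * cos(2 * pi * t) - 0.4 * sin(4 * pi * t + 0)
  f2 <- uniform_field(mesh, t, 1, sig, c(1, 0, 0))
  oracle <- dense_cycle_mean(sig, 1)
  expect_equal(time_average_vector(f2)[1, 1], oracle, tolerance = 1e-6)
})

test_that("non-uniform sampling is handled by the periodic trapezoid rule", {
  mesh <- flat_patch_mesh(2, 2)
  set.seed(3)
  t <- sort(stats::runif(200))
  w <- cycle_weights(t, 1)
  expect_equal(sum(w), 1)
  f <- uniform_field(mesh, t, 1, function(t) 1 + 0.5 * cos(2 * pi * t), c(1, 0, 0))
  expect_equal(compute_tawss(f)[1], 1 + 0.5 * dense_cycle_mean(function(t) cos(2 * pi * t), 1),
               tolerance = 1e-3)
})

test_that("TAWSS: constant magnitude, rectified cosine, sign-reversing square wave", {
  mesh <- flat_patch_mesh(3, 3)
  t <- uniform_times(360)
  f1 <- uniform_field(mesh, t, 1, function(t) rep(0.7, length(t)), c(0, 1, 0))
  expect_equal(compute_tawss(f1), rep(0.7, 9))
  A <- 1.3
  f2 <- uniform_field(mesh, t, 1, function(t) A * cos(2 * pi * t), c(1, 0, 0))
  expect_equal(compute_tawss(f2), rep(2 / pi * A, 9), tolerance = 1e-3)
  f3 <- uniform_field(mesh, t, 1, function(t) ifelse(t < 0.5, 0.9, -0.9), c(1, 0, 0))
  expect_equal(compute_tawss(f3), rep(0.9, 9))
})

test_that("OSI: unidirectional 0, zero-mean 0.5, asymmetric square wave 1/3", {
  mesh <- flat_patch_mesh(3, 3)
  t <- uniform_times(360)
  f0 <- uniform_field(mesh, t, 1, function(t) 1 + 0.4 * cos(2 * pi * t), c(1, 0, 0))
  expect_equal(as.numeric(compute_osi(f0)), rep(0, 9), tolerance = 1e-12)
  f5 <- uniform_field(mesh, t, 1, function(t) cos(2 * pi * t), c(1, 0, 0))
  expect_equal(as.numeric(compute_osi(f5)), rep(0.5, 9), tolerance = 1e-12)
  # +A for half a cycle, -A/2 for the other half: |mean| = A/4, TAWSS = 3A/4
  fsq <- uniform_field(mesh, t, 1, function(t) ifelse(t < 0.5, 1, -0.5), c(0, 1, 0))
  expect_equal(as.numeric(compute_osi(fsq)), rep(1 / 3, 9), tolerance = 1e-12)
  expect_equal(compute_tawss(fsq), rep(0.75, 9))
})

test_that("RRT and ECAP follow their defining ratios and flag degeneracy", {
  expect_equal(as.numeric(compute_rrt(0.4, 0)), 2.5)
  expect_equal(as.numeric(compute_rrt(1, 0.25)), 2.0)
  expect_equal(as.numeric(compute_ecap(0.4, 0.3)), 0.75)
  expect_equal(as.numeric(compute_ecap(c(0.2, 5), c(0, 0))), c(0, 0))
  # fully oscillatory: denominator underflows the floor -> capped and flagged
  r <- compute_rrt(1, 0.5)
  expect_equal(as.numeric(r), 1e6)
  expect_true(attr(r, "flag"))
  set.seed(11)
  tawss <- stats::runif(50, 0.1, 2)
  osi <- stats::runif(50, 0, 0.45)
  expect_equal(as.numeric(compute_ecap(tawss, osi)), osi / tawss)
})

test_that("TransWSS: uniaxial 0, orthogonal sine (2/pi)B, never above TAWSS", {
  mesh <- flat_patch_mesh(3, 3)
  t <- uniform_times(360)
  fu <- uniform_field(mesh, t, 1, function(t) 1 + 0.3 * sin(2 * pi * t), c(1, 1, 0))
  expect_equal(as.numeric(compute_transwss(fu)), rep(0, 9), tolerance = 1e-12)
  # steady axial A plus transverse sine B: TransWSS = (2/pi) B
  n <- 9; K <- length(t); B <- 0.6
  vectors <- array(0, dim = c(K, n, 3))
  vectors[, , 1] <- 0.8
  vectors[, , 2] <- matrix(B * sin(2 * pi * t), K, n)
  ft <- wss_field(mesh, t, 1, vectors)
  expect_equal(as.numeric(compute_transwss(ft)), rep(2 / pi * B, n), tolerance = 1e-3)
  expect_true(all(compute_transwss(ft) <= compute_tawss(ft) + 1e-9))
})

test_that("near-normal WSS vectors trigger the tangency warning", {
  mesh <- flat_patch_mesh(2, 2)
  t <- uniform_times(16)
  vectors <- array(0, dim = c(16, 4, 3))
  vectors[, , 1] <- 1
  vectors[, , 3] <- 0.2  # 20% off-tangent component (normal is +z)
  expect_warning(wss_field(mesh, t, 1, vectors), "tangent plane")
})

test_that("NTransWSS normalization maps the masked maximum to 1 and is scale invariant", {
  x <- c(0.05, 0.2, 0.13, 0.01)
  expect_equal(normalize_transwss(x), x / 0.2)
  expect_equal(max(normalize_transwss(x)), 1)
  expect_equal(normalize_transwss(rep(0.4, 5)), rep(1, 5))
  expect_equal(normalize_transwss(3.7 * x), normalize_transwss(x))
  mask <- c(TRUE, FALSE, TRUE, TRUE)  # masked max is 0.13
  expect_equal(normalize_transwss(x, mask), x / 0.13)
  expect_error(normalize_transwss(rep(0, 4)), "undefined")
})

test_that("index bundle is deterministic and restriction-consistent on submeshes", {
  spec <- synthetic_spec(n_theta = 24, n_z = 40)
  mesh <- make_aneurysm_mesh(spec)
  f <- make_wss_field(mesh, spec, n_time = 64)$field
  i1 <- compute_all_indices(f)
  i2 <- compute_all_indices(f)
  expect_identical(i1, i2)
  keep <- mesh$point_data$z > 20 & mesh$point_data$z < 100
  sm <- submesh(mesh, keep)
  fs <- wss_field(sm, f$times, f$period, f$vectors[, keep, , drop = FALSE])
  is <- compute_all_indices(fs)
  for (nm in c("tawss", "osi", "transwss", "rrt", "ecap")) {
    expect_equal(is[[nm]], i1[[nm]][keep], tolerance = 1e-12)
  }
})

test_that("random fields satisfy the OSI bounds, triangle inequality and RRT identity", {
  mesh <- flat_patch_mesh(8, 8)
  set.seed(42)
  for (rep_i in 1:5) {
    f <- random_tangent_field(mesh, K = 64)
    tawss <- compute_tawss(f)
    osi <- compute_osi(f)
    mean_mag <- sqrt(rowSums(time_average_vector(f)^2))
    expect_true(all(osi >= 0 & osi <= 0.5))
    expect_true(all(tawss >= mean_mag - 1e-12))
    rrt <- compute_rrt(tawss, osi)
    unflagged <- !attr(rrt, "flag")
    expect_lt(max(abs(rrt[unflagged] * (1 - 2 * osi[unflagged]) * tawss[unflagged] - 1)), 1e-9)
    # identity route: RRT equals the reciprocal cycle-mean vector magnitude
    expect_equal(as.numeric(rrt[unflagged]), 1 / mean_mag[unflagged], tolerance = 1e-9)
    expect_true(all(compute_transwss(f) <= tawss + 1e-9))
  }
})

test_that("doubling the time resolution barely moves band-limited indices", {
  spec <- synthetic_spec(n_theta = 16, n_z = 24)
  mesh <- make_aneurysm_mesh(spec)
  f1 <- make_wss_field(mesh, spec, n_time = 180)$field
  f2 <- make_wss_field(mesh, spec, n_time = 360)$field
  for (fn in list(compute_tawss, function(x) as.numeric(compute_osi(x)),
                  function(x) as.numeric(compute_transwss(x)))) {
    a <- fn(f1); b <- fn(f2)
    expect_lt(max(abs(a - b)) / max(abs(b) + 1e-12), 1e-3)
  }
})
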