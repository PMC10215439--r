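test_that("identical surfaces are at zero distance", {
  m <- flat_patch_mesh(5, 5)
  expect_equal(nearest_surface_distance(m, m), rep(0, 25))
})

test_that("concentric spheres recover the radial gap", {
  inner <- uv_sphere(10, n_lat = 40, n_lon = 80)
  outer <- uv_sphere(15, n_lat = 40, n_lon = 80)
  expect_gte(nrow(inner$vertices), 2562)
  d <- nearest_surface_distance(inner, outer)
  expect_true(all(abs(d - 5) / 5 < 0.01))
  # same-parametrization vertices are radially aligned: vertex mode is exact
  expect_equal(max(abs(d - 5)), 0)
  # brute-force all-pairs check on a subsample
  sub <- seq(1, nrow(inner$vertices), length.out = 100)
  expect_equal(d[sub], brute_nearest_distance(inner$vertices[sub, ], outer$vertices))
})

test_that("fast distance equals the exhaustive all-pairs minimum exactly", {
  set.seed(5)
  spec <- synthetic_spec(n_theta = 10, n_z = 12)
  lumen <- make_aneurysm_mesh(spec)          # 120 vertices
  outer <- make_ilt_surfaces(lumen, spec)$outer
  expect_lte(nrow(lumen$vertices), 500)
  expect_equal(nearest_surface_distance(lumen, outer),
               brute_nearest_distance(lumen$vertices, outer$vertices),
               tolerance = 1e-12)
})

test_that("triangle mode never exceeds vertex mode and is exact on offset planes", {
  # two parallel planes 3 apart; coarse outer grid so vertex mode overshoots
  lumen <- flat_patch_mesh(9, 9, spacing = 0.5)
  outer <- flat_patch_mesh(3, 3, spacing = 2)
  outer$vertices[, 3] <- 3
  dv <- nearest_surface_distance(lumen, outer, mode = "vertex")
  dt <- nearest_surface_distance(lumen, outer, mode = "triangle")
  expect_true(all(dt <= dv + 1e-12))
  expect_equal(dt, rep(3, 81))
  expect_true(any(dv > 3))
})

test_that("wall mask subtraction clamps at zero and keeps the identity cases", {
  m <- flat_patch_mesh(2, 2)
  tf <- apply_wall_mask(m, c(5, 1.5, 2, 0), wall_mask = 2)
  expect_equal(tf$thickness, c(3, 0, 0, 0))
  expect_true(all(tf$thickness >= 0))
  tf0 <- apply_wall_mask(m, c(5, 1.5, 2, 0), wall_mask = 0)
  expect_equal(tf0$thickness, tf0$raw_distance)
  expect_error(apply_wall_mask(m, c(1, 2, 3, 4), wall_mask = -1), "nonnegative")
  expect_error(apply_wall_mask(m, c(1, 2, 3), wall_mask = 2), "per lumen vertex")
})

test_that("uniform offsets on a straight tube are recovered through the full pipeline", {
  spec <- synthetic_spec(dr = 0, n_theta = 48, n_z = 80)
  lumen <- make_aneurysm_mesh(spec)
  res <- make_ilt_surfaces(lumen, spec, thickness = rep(5, nrow(lumen$vertices)))
  tf <- ilt_thickness(lumen, res$outer, wall_mask = spec$wall_offset)
  expect_true(all(abs(tf$thickness - 5) / 5 < 0.02))
})

test_that("zero thrombus yields zero thickness after the wall mask", {
  spec <- synthetic_spec(n_theta = 24, n_z = 40)
  lumen <- make_aneurysm_mesh(spec)
  res <- make_ilt_surfaces(lumen, spec, thickness = rep(0, nrow(lumen$vertices)))
  tf <- ilt_thickness(lumen, res$outer, wall_mask = spec$wall_offset)
  expect_true(all(tf$thickness < 0.05))
})

test_that("the Gaussian thrombus bump is recovered at its apex", {
  spec <- synthetic_spec()
  lumen <- make_aneurysm_mesh(spec)
  res <- make_ilt_surfaces(lumen, spec)
  tf <- ilt_thickness(lumen, res$outer, wall_mask = spec$wall_offset)
  g <- res$thickness
  expect_lt(abs(max(tf$thickness) - max(g)) / max(g), 0.02)
  # recovered maximum sits at (or immediately next to) the true apex
  sep <- sqrt(sum((lumen$vertices[which.max(tf$thickness), ] -
                   lumen$vertices[which.max(g), ])^2))
  expect_lt(sep, 5)
  # away from steep gradients (flat apex neighborhood) the field matches within 2%
  apex <- g > 0.995 * max(g)
  expect_true(all(abs(tf$thickness[apex] - g[apex]) / g[apex] < 0.02))
})

test_that("inflating the outer surface increases raw distances by at most the inflation", {
  spec <- synthetic_spec(n_theta = 24, n_z = 40)
  lumen <- make_aneurysm_mesh(spec)
  res <- make_ilt_surfaces(lumen, spec)
  d0 <- nearest_surface_distance(lumen, res$outer)
  delta <- 1.5
  inflated <- res$outer
  inflated$vertices <- lumen$vertices + (res$thickness + spec$wall_offset + delta) * lumen$normals
  d1 <- nearest_surface_distance(lumen, inflated)
  expect_true(all(d1 - d0 <= delta + 1e-9))
  expect_true(all(d1 >= d0 - 1e-9))
})

test_that("patching attaches a lossless thickness array to the lumen", {
  spec <- synthetic_spec(n_theta = 16, n_z = 24)
  lumen <- make_aneurysm_mesh(spec)
  res <- make_ilt_surfaces(lumen, spec)
  tf <- ilt_thickness(lumen, res$outer, wall_mask = spec$wall_offset)
  surf <- patch_to_surface(tf)
  expect_identical(surf$point_data$ILT_thickness_mm, tf$thickness)
  path <- withr::local_tempfile(fileext = ".vtp")
  write_surface(surf, path)
  back <- read_surface(path)
  expect_equal(back$point_data$ILT_thickness_mm, tf$thickness, tolerance = 1e-12)
  expect_equal(nrow(back$vertices), nrow(lumen$vertices))
})

test_that("unit mismatches between surfaces are warned about", {
  spec <- synthetic_spec(n_theta = 12, n_z = 12)
  lumen <- make_aneurysm_mesh(spec)
  shrunk <- lumen
  shrunk$vertices <- lumen$vertices / 100   # cm-vs-mm style error
  expect_warning(nearest_surface_distance(lumen, shrunk), "unit")
})
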