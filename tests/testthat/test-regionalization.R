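make_thickness_fixture <- function(spec = synthetic_spec(n_theta = 24, n_z = 40)) {
  lumen <- make_aneurysm_mesh(spec)
  res <- make_ilt_surfaces(lumen, spec)
  list(spec = spec, lumen = lumen,
       tf = apply_wall_mask(lumen, res$thickness + spec$wall_offset, spec$wall_offset),
       roi = make_roi(lumen, vertex_ids = lumen$point_data$sac > 0))
}

test_that("ROI selection by bounds and tags behaves as specified", {
  fx <- make_thickness_fixture()
  n <- nrow(fx$lumen$vertices)
  all_roi <- make_roi(fx$lumen, z_bounds = c(-1, 1000))
  expect_equal(all_roi$vertex_count, n)
  expect_error(make_roi(fx$lumen, z_bounds = c(500, 600)), "empty")
  expect_equal(which(fx$roi$selected), which(fx$lumen$point_data$sac > 0))
})

test_that("ILT / ILT-free masks partition the ROI", {
  fx <- make_thickness_fixture()
  parts <- split_ilt(fx$tf, fx$roi)
  expect_equal(parts$ilt$selected | parts$ilt_free$selected, fx$roi$selected)
  expect_false(any(parts$ilt$selected & parts$ilt_free$selected))
  # degenerate cases
  m <- fx$lumen
  roi <- fx$roi
  tf_full <- apply_wall_mask(m, rep(7, nrow(m$vertices)), 2)
  p <- split_ilt(tf_full, roi)
  expect_equal(p$ilt$vertex_count, roi$vertex_count)
  expect_equal(p$ilt_free$vertex_count, 0)
  tf_zero <- apply_wall_mask(m, rep(0, nrow(m$vertices)), 2)
  expect_equal(split_ilt(tf_zero, roi)$ilt$vertex_count, 0)
})

test_that("thickest/thinnest zones match elementwise recomputation and stay disjoint", {
  fx <- make_thickness_fixture()
  cfg <- threshold_config()
  parts <- split_ilt(fx$tf, fx$roi, cfg)
  ext <- extreme_ilt_regions(fx$tf, parts$ilt, cfg)
  th <- fx$tf$thickness
  expect_equal(ext$thickest$selected, parts$ilt$selected & th >= 17)
  expect_equal(ext$thinnest$selected, parts$ilt$selected & th > 0 & th <= 1.5)
  expect_false(any(ext$thickest$selected & ext$thinnest$selected))
  expect_gt(ext$thickest$vertex_count, 0)
  expect_gt(ext$thinnest$vertex_count, 0)
  # mid-range thickness leaves both extreme zones empty at default thresholds
  tf_mid <- apply_wall_mask(fx$lumen, rep(8, nrow(fx$lumen$vertices)), 2)
  pm <- split_ilt(tf_mid, fx$roi, cfg)
  em <- extreme_ilt_regions(tf_mid, pm$ilt, cfg)
  expect_equal(em$thickest$vertex_count + em$thinnest$vertex_count, 0)
  # linear ramp: counts equal the brute-force comparison count
  ramp <- seq(0, 20, length.out = nrow(fx$lumen$vertices))
  tf_ramp <- apply_wall_mask(fx$lumen, ramp + 2, 2)
  all_roi <- make_roi(fx$lumen, z_bounds = c(-1, 1000))
  pr <- split_ilt(tf_ramp, all_roi, cfg)
  er <- extreme_ilt_regions(tf_ramp, pr$ilt, cfg)
  expect_equal(er$thickest$vertex_count, sum(tf_ramp$thickness >= 17))
})

test_that("favorable threshold maps agree with brute-force comparisons", {
  fx <- make_thickness_fixture()
  f <- make_wss_field(fx$lumen, fx$spec, n_time = 64)$field
  idx <- compute_all_indices(f, roi = fx$roi)
  cfg <- threshold_config()
  maps <- threshold_maps(idx, fx$roi, fx$lumen, cfg)
  sel <- fx$roi$selected
  expect_equal(maps$favorable_tawss$vertex_count, sum(sel & idx$tawss < 0.4))
  expect_equal(maps$favorable_osi$vertex_count, sum(sel & idx$osi > 0.2))
  expect_equal(maps$favorable_ecap$vertex_count, sum(sel & idx$ecap > 1.4))
  expect_equal(maps$favorable_rrt$vertex_count, sum(sel & idx$rrt > 10))
  counts <- vapply(maps, function(m) m$vertex_count, numeric(1))
  expect_lte(counts["favorable_all"], min(counts[-5]))
  # all masks are subsets of the ROI
  for (m in maps) expect_true(all(!m$selected | sel))
})

test_that("flow-nature octants partition the ROI and respond to thresholds", {
  fx <- make_thickness_fixture()
  f <- make_wss_field(fx$lumen, fx$spec, n_time = 64)$field
  idx <- compute_all_indices(f, roi = fx$roi)
  cls <- classify_flow_nature(idx, fx$roi)
  expect_equal(sum(attr(cls, "counts")), fx$roi$vertex_count)
  expect_true(all(is.na(cls[!fx$roi$selected])))
  expect_equal(nlevels(cls), 8)
  # a steady uniaxial field lands in the high-TAWSS/low-OSI/low-NTransWSS octant
  st_spec <- synthetic_spec(n_theta = 24, n_z = 40, osc_peak = 0, trans_peak = 0,
                            wss_base = 1.2)
  st <- make_wss_field(fx$lumen, st_spec, n_time = 64)
  sidx <- compute_all_indices(st$field, roi = fx$roi)
  scls <- classify_flow_nature(sidx, fx$roi)
  cnt <- attr(scls, "counts")
  expect_equal(names(which.max(cnt)), "hT.lO.lN")
})

test_that("region summaries match a sort-based recomputation", {
  x <- c(1, 2, 3, 4, 5)
  s <- region_summary(x, rep(TRUE, 5))
  expect_equal(s$median, 3); expect_equal(s$q1, 2); expect_equal(s$q3, 4)
  s2 <- region_summary(rep(4.2, 10), rep(TRUE, 10))
  expect_equal(s2$iqr, 0); expect_equal(s2$p10, 4.2); expect_equal(s2$max, 4.2)
  set.seed(9)
  y <- stats::rlnorm(501)
  s3 <- region_summary(y, rep(TRUE, 501))
  b <- brute_summary(y)
  expect_equal(s3$median, b$median); expect_equal(s3$q1, b$q1)
  expect_equal(s3$q3, b$q3); expect_equal(s3$p10, b$p10); expect_equal(s3$p90, b$p90)
  expect_error(region_summary(y, rep(FALSE, 501)), "empty")
})

test_that("Spearman correlation: perfect monotone pairs, oracle agreement, invariance", {
  set.seed(21)
  th <- stats::runif(50, 0, 20)
  mask <- rep(TRUE, 50)
  expect_equal(spearman_correlation(th, th, mask)$rho, 1)
  expect_equal(spearman_correlation(th, -th, mask)$rho, -1)
  expect_equal(spearman_correlation(th, exp(th / 5), mask)$rho, 1)  # monotone transform
  y <- stats::rnorm(50)
  r <- spearman_correlation(th, y, mask)
  expect_lt(abs(r$rho - brute_spearman(th, y)), 1e-12)
  expect_equal(r$n, 50)
  # monotone transforms of either argument leave rho unchanged
  expect_equal(spearman_correlation(th^3, y, mask)$rho, r$rho)
  const <- spearman_correlation(th, rep(1, 50), mask)
  expect_true(const$degenerate)
  expect_true(is.na(const$rho))
})

test_that("the growth-potential report reflects a constructed favorable/unfavorable contrast", {
  fx <- make_thickness_fixture(synthetic_spec(n_theta = 32, n_z = 60))
  f <- make_wss_field(fx$lumen, fx$spec, n_time = 96)$field
  idx <- compute_all_indices(f, roi = fx$roi)
  rep1 <- growth_potential_report(idx, fx$tf, fx$roi)
  expect_equal(nrow(rep1$summary), 5 * 6)   # regions x indices
  expect_setequal(unique(rep1$summary$region),
                  c("AAA", "ILT", "ILT-free", "thickest ILT", "thinnest ILT"))
  # the thick thrombus bump was built over the low-TAWSS oscillatory patch:
  # favorable fractions there must exceed the ILT-free ones
  sm <- rep1$summary
  frac <- function(region, index) sm$favorable_fraction[sm$region == region & sm$index == index]
  expect_gt(frac("thickest ILT", "TAWSS"), frac("ILT-free", "TAWSS"))
  expect_gt(frac("thickest ILT", "OSI"), frac("ILT-free", "OSI"))
  # thickness correlates negatively with TAWSS, positively with OSI here
  co <- rep1$correlation
  expect_lt(co$rho[co$index == "TAWSS"], 0)
  expect_gt(co$rho[co$index == "OSI"], 0)
  # determinism of the full report
  rep2 <- growth_potential_report(idx, fx$tf, fx$roi)
  expect_identical(rep1$summary, rep2$summary)
  expect_identical(rep1$correlation, rep2$correlation)
})
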