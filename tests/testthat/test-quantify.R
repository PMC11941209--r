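# Cross-sections, en-face projection, ROI ratios, depth calibration, gap
# measurement, display rendering.

test_that("cross-section extraction slices at the umbo indices", {
  a <- array(0, dim = c(5, 6, 7))
  for (iy in 1:5) a[iy, , ] <- iy          # value encodes slow index
  cs <- extract_cross_sections(a, c(3, 2, 4))
  expect_true(all(cs$xz == 3))
  expect_equal(dim(cs$xz), c(7L, 6L))      # depth x fast
  expect_equal(dim(cs$yz), c(7L, 5L))      # depth x slow
  expect_equal(cs$umbo_in_plane$xz, c(row = 4, col = 2))
  # corner landmark is valid
  expect_silent(extract_cross_sections(a, c(1, 1, 1)))
  expect_error(extract_cross_sections(a, c(6, 1, 1)), "outside")
})

test_that("phantom cross-sections contain the TM apex at the recorded umbo", {
  ear <- tiny_ear("normal", seed = 3)
  um <- ear$truth$landmarks$umbo
  cs <- extract_cross_sections(ear$volume, um)
  # umbo row = TM inner surface at the umbo A-line
  expect_equal(unname(um["depth"]),
               unname(ear$truth$tm_inner_surface[um["slow"], um["fast"]]))
  # the membrane is deepest at the umbo: inner surface in the XZ plane
  # attains its maximum depth index at the umbo column
  surf <- ear$truth$tm_inner_surface[um["slow"], ]
  expect_equal(unname(max(surf)), unname(surf[um["fast"]]))
})

test_that("en-face projection means the depth window", {
  a <- array(4.2, dim = c(3, 4, 10))
  expect_true(all(enface_projection(a, 2, 6) == 4.2))
  # ramp along z: mean over window = window midpoint value
  r <- array(0, dim = c(3, 4, 10))
  for (k in 1:10) r[, , k] <- k
  expect_true(all(enface_projection(r, 2, 8) == 5))
  expect_error(enface_projection(a, 7, 3), "window")
})

test_that("the malleus silhouette is brighter than the TM in projection", {
  ear <- tiny_ear("normal", seed = 13)
  tr <- ear$truth
  zw <- range(tr$tm_inner_surface)
  en <- enface_projection(ear$volume, max(1, zw[1] - 3), zw[2])
  mal <- apply(tr$label_map == 2L, c(1, 2), any)
  tm_only <- apply(tr$label_map == 1L, c(1, 2), any) & !mal
  expect_gt(mean(en[mal]), mean(en[tm_only]))
})

test_that("roi_mean is the arithmetic box mean", {
  img <- matrix(c(1, 3, 2, 4), 2, 2)      # column-major: rows {1,3},{2,4}
  expect_equal(roi_mean(img, roi_box(c(1, 1), c(1, 1))), 1)
  expect_equal(roi_mean(img, roi_box(c(1, 1), c(2, 2))), 2.5)
  cimg <- matrix(7.5, 10, 10)
  expect_equal(roi_mean(cimg, roi_box(c(3, 4), c(5, 2))), 7.5)
  expect_error(roi_mean(img, roi_box(c(2, 2), c(2, 2))), "exceeds")
})

test_that("intensity ratios are scale-invariant and validate their ROIs", {
  set.seed(5)
  img <- matrix(runif(400, 1, 10), 20, 20)
  mbox <- roi_box(c(2, 2), c(5, 5)); tbox <- roi_box(c(12, 12), c(4, 4))
  r1 <- structural_ratio(img, mbox, tbox)
  r2 <- structural_ratio(img * 37.5, mbox, tbox)
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-12)
  expect_equal(structural_ratio(matrix(4, 9, 9), roi_box(c(1, 1), c(3, 3)),
                                roi_box(c(5, 5), c(3, 3)))$ratio, 1.0)
  expect_error(structural_ratio(img, mbox, roi_box(c(3, 3), c(5, 5))),
               "disjoint")
  a1 <- angio_ratio(img, mbox, tbox)
  a2 <- angio_ratio(img * 0.001, mbox, tbox)
  expect_equal(a2$ratio, a1$ratio, tolerance = 1e-12)
  expect_equal(angio_ratio(matrix(2, 8, 8), roi_box(c(1, 1), c(2, 2)),
                           roi_box(c(5, 5), c(2, 2)))$ratio, 1.0)
  expect_error(angio_ratio(matrix(0, 8, 8), roi_box(c(1, 1), c(2, 2)),
                           roi_box(c(5, 5), c(2, 2))), "> 0")
})

test_that("optical path converts to physical depth by the refractive index", {
  expect_equal(optical_to_physical_depth(1.0, "air"), 1.0)
  expect_equal(optical_to_physical_depth(1.0, "tissue"), 1 / 1.4)
  expect_equal(optical_to_physical_depth(0, "tissue"), 0)
  expect_equal(optical_to_physical_depth(2.8, "tissue"), 2.0)
  expect_error(optical_to_physical_depth(-1, "air"), ">= 0")
})

test_that("depth uncertainty bounds follow the index range endpoints", {
  cal0 <- depth_calibration(n_tissue = 1.4, n_tissue_range = c(1.4, 1.4))
  expect_equal(depth_uncertainty(cal0)$max_abs, 0)
  u <- depth_uncertainty(depth_calibration(1.4, c(1.33, 1.45)))
  expect_equal(unname(u$bounds["upper"]), 1.4 / 1.33 - 1, tolerance = 1e-12)
  expect_equal(unname(u$bounds["lower"]), 1.4 / 1.45 - 1, tolerance = 1e-12)
  expect_equal(u$max_abs, 1.4 / 1.33 - 1)
  # widening the range never decreases the maximum
  wide <- depth_uncertainty(depth_calibration(1.4, c(1.30, 1.50)))
  expect_gte(wide$max_abs, u$max_abs)
})

test_that("tumor-TM gap measures designed gaps and flags inversions", {
  # touching surfaces: gap 0
  tm <- matrix(10L, 4, 4); mt <- matrix(10L, 4, 4)
  g <- tumor_tm_gap(tm, mt, 0.02)
  expect_equal(g$max_mm, 0); expect_equal(g$min_mm, 0)
  # air-index identity: n = 1 conversion leaves the value unchanged
  mt2 <- tm + 5L
  expect_equal(tumor_tm_gap(tm, mt2, 0.02)$max_mm,
               tumor_tm_gap(tm, mt2, 0.02, n_medium = 1.0)$max_mm)
  # inverted A-lines are excluded and counted
  mt3 <- mt2; mt3[1, 1] <- 5L
  g3 <- tumor_tm_gap(tm, mt3, 0.02)
  expect_equal(g3$n_flagged, 1L)
  expect_equal(g3$n_alines, 15L)
  # designed phantom gap recovered within one axial pixel
  sc <- scene_preset("glomus", seed = 2, grid_shape = c(8, 64, 256),
                     jitter = FALSE, gap_mm = 0.15)
  tr <- phantom_truth(sc)
  gm <- tumor_tm_gap(tr$tm_inner_surface, tr$mass_top_surface,
                     sc$pixel_spacing["z"])
  expect_lte(abs(gm$max_mm - 0.15), sc$pixel_spacing["z"])
  # molded contact at the apex: minimum gap within one pixel of zero
  expect_lte(gm$min_mm, sc$pixel_spacing["z"])
})

test_that("display rendering maps the log window deterministically", {
  a <- array(c(1, 10^(-40 / 10), 10^(-20 / 10), 0.5), dim = c(1, 2, 2))
  d <- render_display(a, dynamic_range_db = 40)
  expect_equal(d[1, 1, 1], 255L)                       # I = I_max
  expect_equal(d[1, 2, 1], 0L)                         # window floor
  expect_equal(d[1, 1, 2], as.integer(floor((10 * log10(10^-2) + 40) *
                                            255 / 40 + 0.5)))
  expect_equal(d[1, 2, 2], as.integer(floor((10 * log10(0.5) + 40) *
                                            255 / 40 + 0.5)))
  # idempotent in effect: same linear input, same 8-bit output
  expect_identical(render_display(a, 40), d)
  expect_error(render_display(a, dynamic_range_db = 0), "> 0")
  expect_error(render_display(array(0, c(0, 1, 1))), "empty")
})
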