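# Phantom generator: geometry, Beer-Lambert optics, speckle statistics,
# temporal decorrelation, cohort bookkeeping.

test_that("expected intensity follows per-A-line Beer-Lambert attenuation", {
  sc <- scene_preset("cholesteatoma", seed = 5, grid_shape = c(6, 24, 64),
                     jitter = FALSE)
  comp <- render_mean_intensity(sc, components = TRUE)
  lab <- comp$truth$label_map
  b_tab <- stats::setNames(sc$tissue$backscatter, sc$tissue$label)
  a_tab <- stats::setNames(sc$tissue$attenuation, sc$tissue$label)
  labels <- attr(lab, "labels")
  dz <- sc$pixel_spacing["z"]
  for (iy in c(1L, 3L)) for (ix in c(6L, 12L, 18L)) {
    codes <- lab[iy, ix, ]
    b <- numeric(length(codes)); a <- numeric(length(codes))
    for (nm in names(labels)) {
      sel <- codes == labels[nm]
      if (nm == "mass") {
        b[sel] <- sc$mass$backscatter; a[sel] <- sc$mass$attenuation
      } else {
        b[sel] <- b_tab[nm]; a[sel] <- a_tab[nm]
      }
    }
    expect_equal(comp$mean$data[iy, ix, ],
                 aline_oracle(b, a, dz, sc$noise_floor), tolerance = 1e-9)
  }
  # log expected intensity above the noise floor never increases with
  # cumulative attenuation: transmission factors are <= 1
  mu_sig <- comp$signal
  expect_true(all(mu_sig >= 0))
})

test_that("zero attenuation reduces expected intensity to backscatter + floor", {
  sc <- scene_preset("normal", seed = 2, grid_shape = c(4, 16, 32),
                     jitter = FALSE)
  sc$tissue$attenuation[] <- 0
  comp <- render_mean_intensity(sc, components = TRUE)
  lab <- comp$truth$label_map
  b_tab <- stats::setNames(sc$tissue$backscatter, sc$tissue$label)
  expected <- array(0, dim = dim(lab))
  for (nm in names(attr(lab, "labels")))
    expected[lab == attr(lab, "labels")[nm]] <- b_tab[nm]
  expect_equal(comp$mean$data, expected + sc$noise_floor, tolerance = 1e-12)
})

test_that("a mass shadows the promontory relative to the matched normal ear", {
  for (preset in c("glomus", "cholesteatoma")) {
    scm <- scene_preset(preset, seed = 9, grid_shape = c(8, 48, 128),
                        jitter = FALSE)
    scn <- scene_preset("normal", seed = 9, grid_shape = c(8, 48, 128),
                        jitter = FALSE)
    cm <- render_mean_intensity(scm, components = TRUE)
    cn <- render_mean_intensity(scn, components = TRUE)
    # promontory voxels beneath the mass footprint
    fp <- apply(cm$truth$mass_mask, c(1, 2), any)
    prom <- cm$truth$label_map == attr(cm$truth$label_map, "labels")["promontory"]
    below <- prom & array(fp, dim = dim(prom))
    expect_gt(sum(below), 0)
    expect_lt(mean(cm$mean$data[below]), mean(cn$mean$data[below]))
  }
})

test_that("speckle intensities are exponential with the prescribed mean", {
  mu <- array(2.5, dim = c(40, 50, 60))
  v <- sample_speckle_volume(mu, seed = 31)
  x <- as.vector(v$data)
  expect_equal(mean(x), 2.5, tolerance = 0.02)
  expect_equal(stats::var(x), 2.5^2, tolerance = 0.03)
  ks <- suppressWarnings(stats::ks.test(x, "pexp", rate = 1 / 2.5))
  expect_gt(ks$p.value, 0.01)
  # zero mean intensity stays exactly zero
  v0 <- sample_speckle_volume(array(0, dim = c(3, 4, 5)), seed = 1)
  expect_true(all(v0$data == 0))
  # determinism under a fixed seed
  expect_identical(sample_speckle_volume(mu, seed = 31)$data, v$data)
})

test_that("repeat stacks realize the AR(1) temporal correlation model", {
  npix <- c(400, 300)   # 1.2e5 pixels
  mu <- matrix(1.7, npix[1], npix[2])
  # static tissue with no noise floor: all repeats identical
  st1 <- sample_repeat_stack(mu, rho = 1, n_repeats = 4, seed = 3)
  expect_equal(st1$data[2, , ], st1$data[1, , ], tolerance = 1e-12)
  expect_equal(st1$data[4, , ], st1$data[1, , ], tolerance = 1e-12)
  # lag-1 intensity correlation ~ rho^2 (within +/- 0.05 at >= 1e5 pixels)
  for (rho in c(0, 0.5, 0.9)) {
    st <- sample_repeat_stack(mu, rho = rho, n_repeats = 4, seed = 17)
    i1 <- as.vector(st$data[1, , ]); i2 <- as.vector(st$data[2, , ])
    expect_equal(stats::cor(i1, i2), rho^2, tolerance = 0.05)
  }
  # rho = 0 repeats are marginally exponential with the right mean
  st0 <- sample_repeat_stack(mu, rho = 0, n_repeats = 4, seed = 23)
  expect_equal(mean(st0$data), 1.7, tolerance = 0.02)
})

test_that("repeat stack input contracts are enforced", {
  mu <- matrix(1, 4, 4)
  expect_error(sample_repeat_stack(mu, rho = 0.5, n_repeats = 1),
               "n_repeats")
  expect_error(sample_repeat_stack(mu, rho = 1.2), "rho")
  expect_error(sample_repeat_stack(mu, rho = matrix(0.5, 2, 2)), "shape")
  expect_error(sample_repeat_stack(-mu, rho = 0.5), "non-negative")
})

test_that("scene presets validate geometry and class constraints", {
  expect_error(scene_preset("normal", grid_shape = c(0, 10, 10)),
               "grid_shape")
  expect_error(scene_preset("normal", gap_mm = 0.1), "normal")
  sc <- scene_preset("glomus", seed = 1, grid_shape = c(6, 24, 48))
  expect_s3_class(sc, "phantom_scene")
  tr <- phantom_truth(sc)
  expect_true(all(tr$rho_map >= 0 & tr$rho_map <= 1))
  # mass mask is exactly the mass-labeled voxels
  expect_identical(tr$mass_mask,
                   tr$label_map == attr(tr$label_map, "labels")["mass"])
  # air voxels are static
  expect_true(all(tr$rho_map[tr$label_map == 0L] == 1))
})

test_that("cohorts reproduce under the master seed and keep class labels", {
  counts <- c(normal = 2L, glomus = 1L)
  c1 <- build_cohort(counts, seed = 5, grid_shape = c(6, 24, 48),
                     keep_stacks = FALSE)
  c2 <- build_cohort(counts, seed = 5, grid_shape = c(6, 24, 48),
                     keep_stacks = FALSE)
  expect_length(c1, 3L)
  expect_identical(vapply(c1, function(e) e$class_label, character(1)),
                   c("normal", "normal", "glomus"))
  expect_identical(c1[[1]]$volume$data, c2[[1]]$volume$data)
  expect_identical(c1[[3]]$sv_volume$data, c2[[3]]$sv_volume$data)
  # distinct ears differ beyond the seed: different volumes
  expect_false(identical(c1[[1]]$volume$data, c1[[2]]$volume$data))
  # glomus truth: vascular mass present and decorrelated
  g <- c1[[3]]
  expect_gt(sum(g$truth$mass_mask), 0)
  expect_lt(mean(g$truth$rho_map[g$truth$mass_mask]), 1)
  expect_error(build_cohort(c(weird = 1L), seed = 1), "presets")
})
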