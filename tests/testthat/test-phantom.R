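test_that("phantom generation is deterministic and label-complete", {
  cfg <- phantom_config(shape = c(64, 64), n_vertebrae = 5, noise_sd = 4, seed = 3)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$labels, b$mask$labels)
  labs <- sort(unique(as.vector(a$mask$labels)))
  expect_identical(labs, 0:7)                   # bg, 5 bodies, disc, vessel
  expect_equal(nrow(a$landmarks$points), 5)
})

test_that("noise-free phantom is piecewise constant at the configured means", {
  cfg <- phantom_config(shape = c(48, 48), n_vertebrae = 3, noise_sd = 0, seed = 1)
  ph <- generate_phantom(cfg)
  lv <- cfg$intensity_levels
  expect_setequal(unique(as.vector(ph$volume$data)),
                  c(lv$background, lv$vertebra, lv$disc, lv$vessel))
  for (j in 1:3) {
    expect_true(all(ph$volume$data[ph$mask$labels == j] == lv$vertebra))
  }
  expect_true(all(ph$volume$data[ph$mask$labels == 4] == lv$disc))
  expect_true(all(ph$volume$data[ph$mask$labels == 5] == lv$vessel))
})

test_that("landmarks sit inside their vertebral bodies", {
  for (shape in list(c(64, 64), c(32, 32, 48))) {
    ph <- generate_phantom(phantom_config(shape = shape, n_vertebrae = 4,
                                          noise_sd = 0, seed = 2))
    idx <- round(ph$landmarks$points / rep(ph$mask$spacing,
                                           each = nrow(ph$landmarks$points))) + 1
    for (j in 1:4) {
      lab <- do.call(`[`, c(list(ph$mask$labels), as.list(idx[j, ])))
      expect_equal(lab, j)
    }
  }
})

test_that("configuration errors are caught", {
  expect_error(phantom_config(shape = c(64, 10), n_vertebrae = 5), "too small")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
  expect_error(phantom_config(n_vertebrae = 0), "n_vertebrae")
  cfg <- phantom_config()
  expect_error(random_deformation(cfg, -1), "max_displacement")
  expect_error(add_noise(generate_phantom(cfg)$volume, sd = -2), "sd")
})

test_that("random deformation honours the displacement bound and seed", {
  cfg <- phantom_config(shape = c(64, 64), seed = 9)
  tr0 <- random_deformation(cfg, 0)
  expect_true(all(tr0$phi == 0))
  tr1 <- random_deformation(cfg, 3)
  tr2 <- random_deformation(cfg, 3)
  expect_identical(tr1$phi, tr2$phi)
  expect_lte(max(abs(tr1$phi)), 3)
  expect_gt(max(abs(tr1$phi)), 1)    # actually random, not degenerate
})

test_that("additive noise has the requested distribution", {
  v <- image_volume(array(100, c(64, 64, 64)))
  expect_identical(add_noise(v, 0)$data, v$data)
  n1 <- add_noise(v, 5, seed = 1)
  n2 <- add_noise(v, 5, seed = 2)
  expect_false(identical(n1$data, n2$data))
  expect_equal(dim(n1$data), dim(v$data))
  # Monte-Carlo check against the stated Gaussian model
  expect_lt(abs(sd(n1$data - v$data) - 5), 0.25)
  expect_lt(abs(mean(n1$data - v$data)), 0.1)
})

test_that("volume, mask and landmarks share a consistent geometry", {
  ph <- generate_phantom(phantom_config(shape = c(40, 56), n_vertebrae = 4,
                                        spacing = c(1.5, 2), seed = 6))
  expect_identical(dim(ph$volume$data), dim(ph$mask$labels))
  expect_identical(ph$volume$spacing, ph$mask$spacing)
  ext <- (dim(ph$volume$data) - 1) * ph$volume$spacing
  expect_true(all(ph$landmarks$points >= 0 & ph$landmarks$points <= rep(ext, each = 4)))
})
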