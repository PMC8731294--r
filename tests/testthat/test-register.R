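# light, fast configuration for module-level tests; the full-strength default
# configuration is exercised by the acceptance suite
quick_config <- function() {
  registration_config(grid_spacing_schedule = c(16, 12),
                      pyramid_factors = c(2, 1),
                      bins_schedule = c(16, 32),
                      step_init = c(2, 1),
                      min_step = 0.1,
                      hop_rounds = 2L, hop_candidates = 2L,
                      refine_bins = 64L,
                      cost = cost_config(alpha2 = 0.01))
}

test_that("registration config validates its schedule", {
  expect_error(registration_config(grid_spacing_schedule = numeric(0)), "nonempty")
  expect_error(registration_config(grid_spacing_schedule = c(8, 16)), "non-increasing")
  expect_error(registration_config(pyramid_factors = c(3, 1)), "powers of 2")
  expect_error(registration_config(tol = 0), "tol")
  expect_error(registration_config(step_init = 0.01, min_step = 0.1), "step_init")
})

test_that("self-registration stays at the identity", {
  ph <- small_phantom(noise_sd = 3)
  res <- register(ph$volume, ph$volume, quick_config())
  pts <- spinereg:::.voxel_centres(c(48, 48), c(1, 1), c(0, 0))
  d <- displacement(res$transform, pts)
  expect_lt(mean(sqrt(rowSums(d^2))), 0.1)      # < 0.1 voxel (1 mm spacing)
})

test_that("a known integer translation is recovered to sub-voxel accuracy", {
  ph <- small_phantom(noise_sd = 3)
  # reference = floating shifted by exactly 2 voxels in x
  tr_true <- bspline_transform_for(ph$volume, 16)
  tr_true$phi[, , 1] <- 2
  A_ref <- warp_image(tr_true, ph$volume)
  res <- register(A_ref, ph$volume, quick_config())
  pts <- cbind(runif(100, 8, 40), runif(100, 8, 40))
  lm <- landmark_set(pts, sweep(pts, 2, c(2, 0), "+"))
  expect_lt(mean_tre(res$transform, lm), 0.5)
})

test_that("registration is deterministic and its trace is stage-monotone", {
  ph <- small_phantom(noise_sd = 3, seed = 2)
  cfg <- phantom_config(shape = c(48, 48), n_vertebrae = 3, noise_sd = 3, seed = 2)
  gt <- random_deformation(cfg, 2, grid_spacing = 16)
  A_ref <- warp_image(gt, ph$volume)
  r1 <- register(A_ref, ph$volume, quick_config())
  r2 <- register(A_ref, ph$volume, quick_config())
  expect_identical(r1$transform$phi, r2$transform$phi)
  # accepted-step totals never increase within one (level, stage, bins) run
  tr <- r1$cost_trace
  tr <- tr[tr$stage %in% c("descent", "refine", "polish"), ]
  runs <- split(tr, list(tr$level, tr$stage, tr$bins), drop = TRUE)
  for (run in runs) {
    if (nrow(run) > 1) expect_true(all(diff(run$total) <= 1e-9))
  }
  # per-level summaries report a final cost no worse than the initial one
  for (lv in r1$levels) expect_lte(lv$final_cost, lv$initial_cost + 1e-9)
})

test_that("registration improves mask overlap on a deformed phantom", {
  cfg <- phantom_config(shape = c(48, 48), n_vertebrae = 3, noise_sd = 3, seed = 5)
  ph <- generate_phantom(cfg)
  gt <- random_deformation(cfg, 2, grid_spacing = 16)
  A_ref <- warp_image(gt, ph$volume)
  M_ref <- warp_image(gt, ph$mask)
  res <- register(A_ref, ph$volume, quick_config())
  d_before <- dice(M_ref, ph$mask)
  d_after <- dice(M_ref, warp_image(res$transform, ph$mask))
  expect_gt(d_after, d_before)
})

test_that("degenerate input is rejected", {
  flat <- image_volume(matrix(1, 32, 32))
  ph <- small_phantom()
  expect_error(register(flat, ph$volume, quick_config()), "constant")
  expect_error(register(ph$volume, flat, quick_config()), "constant")
})

test_that("cost trace can be exported as TSV", {
  ph <- small_phantom(noise_sd = 3, seed = 3)
  res <- register(ph$volume, add_noise(ph$volume, 1, seed = 4), quick_config())
  p <- tempfile(fileext = ".tsv")
  write_cost_trace(res, p)
  df <- read.delim(p)
  expect_true(all(c("level", "stage", "mi", "bending", "total") %in% names(df)))
  expect_gt(nrow(df), 1)
  unlink(p)
})
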