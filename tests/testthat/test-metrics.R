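test_that("hand-countable overlap example gives Dice 0.5, Jaccard 1/3", {
  q <- matrix(0L, 4, 4); q[1:2, 1:2] <- 1L        # |Q| = 4
  w <- matrix(0L, 4, 4); w[2:3, 1:2] <- 1L        # |W| = 4, overlap 2
  r <- overlap_report(label_mask(q), label_mask(w), label = 1)
  expect_equal(r$dice, 0.5)
  expect_equal(r$jaccard, 1 / 3)
  expect_equal(r$n_intersect, 2)
})

test_that("degenerate region conventions hold", {
  a <- label_mask(matrix(0L, 3, 3))
  b <- label_mask(matrix(0L, 3, 3))
  expect_equal(dice(a, b, label = 1), 1)          # both empty
  expect_equal(jaccard(a, b, label = 1), 1)
  c1 <- label_mask(matrix(c(1L, rep(0L, 8)), 3))
  expect_equal(dice(a, c1, label = 1), 0)         # one empty
  expect_equal(dice(c1, c1, label = 1), 1)        # identical nonempty
  d1 <- label_mask(matrix(c(0L, 1L, rep(0L, 7)), 3))
  expect_equal(dice(c1, d1, label = 1), 0)        # disjoint nonempty
  expect_error(overlap_report(a, label_mask(matrix(0L, 2, 2))), "same shape")
})

test_that("D = 2J/(1+J) and symmetry hold on random mask pairs", {
  set.seed(41)
  for (i in 1:300) {
    q <- random_mask(); w <- random_mask()
    r <- overlap_report(q, w, label = 1)
    if (r$jaccard > 0 || r$n_ref + r$n_test > 0) {
      expect_equal(r$dice, 2 * r$jaccard / (1 + r$jaccard), tolerance = 1e-12)
    }
    r2 <- overlap_report(w, q, label = 1)
    expect_equal(r$dice, r2$dice)
    expect_true(r$jaccard <= r$dice + 1e-15 && r$dice <= 1)
  }
})

test_that("overlap metrics ignore added common background", {
  q <- random_mask(); w <- random_mask()
  d0 <- dice(q, w, label = 1)
  qb <- label_mask(rbind(q$labels, matrix(0L, 4, 8)))
  wb <- label_mask(rbind(w$labels, matrix(0L, 4, 8)))
  expect_equal(dice(qb, wb, label = 1), d0)
})

test_that("mean TRE closed forms are exact", {
  pts <- matrix(runif(15, 10, 50), 5, 3)
  expect_equal(mean_tre(NULL, landmark_set(pts, pts)), 0)
  shifted <- sweep(pts, 2, c(3, 0, 0), "+")
  expect_equal(mean_tre(NULL, landmark_set(pts, shifted)), 3)
  expect_error(mean_tre(NULL, landmark_set(pts)), "paired")
})

test_that("mean TRE under a transform matches a hand-rolled loop", {
  set.seed(42)
  cfg <- phantom_config(shape = c(64, 64), seed = 4)
  tr <- random_deformation(cfg, 2)
  pts <- cbind(runif(8, 5, 58), runif(8, 5, 58))
  paired <- rbind(transform_point(tr, pts)) + matrix(rnorm(16, 0, 0.5), 8)
  lm <- landmark_set(pts, paired)
  acc <- 0
  for (i in 1:8) {
    g <- rbind(transform_point(tr, rbind(pts[i, ])))[1, ]
    acc <- acc + sqrt(sum((g - paired[i, ])^2))
  }
  expect_equal(mean_tre(tr, lm), acc / 8, tolerance = 1e-12)
})

test_that("noise level is zero for clean input and tracks the generator", {
  ph0 <- small_phantom(noise_sd = 0)
  expect_equal(noise_level(ph0$volume, ph0$mask, label = 1), 0)
  expect_equal(noise_level(image_volume(matrix(5, 8, 8)),
                           label_mask(matrix(1L, 8, 8))), 0)
  # large-ROI Monte-Carlo check: sd(noise)/range within 5%
  cfg <- phantom_config(shape = c(96, 96), n_vertebrae = 5, noise_sd = 6, seed = 8)
  ph <- generate_phantom(cfg)
  est <- noise_level(ph$volume, ph$mask, label = 0)    # background ROI
  expected <- 6 / diff(range(ph$volume$data))
  expect_lt(abs(est - expected) / expected, 0.05)
  expect_error(noise_level(ph$volume, label_mask(array(0L, dim(ph$mask$labels))),
                           label = 3), "empty ROI")
})
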