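test_that("basis polynomials match their closed forms at n = 0", {
  expect_equal(bspline_basis(0, 0), 1 / 6)
  expect_equal(bspline_basis(1, 0), 2 / 3)
  expect_equal(bspline_basis(2, 0), 1 / 6)
  expect_equal(bspline_basis(3, 0), 0)
  expect_error(bspline_basis(4, 0.5), "0..3")
  expect_error(bspline_basis(0, 1.5), "\\[0, 1\\]")
})

test_that("basis functions form a partition of unity and are symmetric", {
  set.seed(11)
  n <- runif(2000)
  s <- bspline_basis(0, n) + bspline_basis(1, n) + bspline_basis(2, n) + bspline_basis(3, n)
  expect_lt(max(abs(s - 1)), 1e-14)
  expect_lt(max(abs(bspline_basis(3, n) - bspline_basis(0, 1 - n))), 1e-14)
})

test_that("to_local decomposition reproduces the point", {
  tr <- bspline_transform(c(0, 0), c(63, 63), c(10, 16))
  loc <- to_local(tr, rbind(c(0, 0)))          # point on the lattice
  expect_equal(as.vector(loc$frac), c(0, 0))
  loc <- to_local(tr, rbind(c(5, 8)))          # cell midpoints
  expect_equal(as.vector(loc$frac), c(0.5, 0.5))
  set.seed(12)
  pts <- cbind(runif(1000, 0, 63), runif(1000, 0, 63))
  loc <- to_local(tr, pts)
  rec <- sweep((loc$cell + loc$frac) * rep(tr$grid_spacing, each = 1000), 2,
               tr$grid_origin, "+")
  expect_lt(max(abs(rec - pts)), 1e-9)
  expect_error(to_local(tr, rbind(c(-5, 0))), "outside")
})

test_that("identity and constant-displacement transforms are exact", {
  tr <- bspline_transform(c(0, 0, 0), c(31, 31, 15), 8)
  set.seed(13)
  pts <- cbind(runif(200, 0, 31), runif(200, 0, 31), runif(200, 0, 15))
  expect_lt(max(abs(transform_point(tr, pts) - pts)), 1e-12)
  # partition of unity forces an exact global translation
  t_vec <- c(2.5, -1.25, 0.75)
  for (k in 1:3) tr$phi[, , , k] <- t_vec[k]
  expect_lt(max(abs(transform_point(tr, pts) - sweep(pts, 2, t_vec, "+"))), 1e-10)
})

test_that("single active control point matches a literal tensor-product sum", {
  tr <- bspline_transform(c(0, 0), c(39, 39), 10)
  tr$phi[4, 3, 1] <- 2.0    # one active node, x-displacement
  tr$phi[4, 3, 2] <- -1.5
  # independent oracle: the 16-term sum written out with the raw polynomials
  R <- function(l, n) switch(l + 1L, (1 - n)^3 / 6, (3 * n^3 - 6 * n^2 + 4) / 6,
                             (-3 * n^3 + 3 * n^2 + 3 * n + 1) / 6, n^3 / 6)
  oracle <- function(p) {
    s <- (p - tr$grid_origin) / tr$grid_spacing
    d <- floor(s); n <- s - d
    acc <- c(0, 0)
    for (l in 0:3) for (a in 0:3) {
      w <- R(l, n[1]) * R(a, n[2])
      acc <- acc + w * tr$phi[d[1] + l + 1, d[2] + a + 1, ]
    }
    p + acc
  }
  set.seed(14)
  pts <- cbind(runif(50, 0, 39), runif(50, 0, 39))
  want <- t(apply(pts, 1, oracle))
  expect_lt(max(abs(transform_point(tr, pts) - want)), 1e-12)
})

test_that("perturbing one control point only acts inside its support", {
  tr <- bspline_transform(c(0, 0), c(63, 63), 8)
  tr2 <- tr
  tr2$phi[6, 6, 1] <- 3   # kernel centred at physical (24, 24)
  set.seed(15)
  pts <- cbind(runif(500, 0, 63), runif(500, 0, 63))
  moved <- rowSums(abs(transform_point(tr2, pts) - transform_point(tr, pts))) > 0
  # support of the cubic kernel: within 2 spacings of the kernel centre
  inside <- abs(pts[, 1] - 24) < 16 & abs(pts[, 2] - 24) < 16
  expect_true(all(!moved | inside))
})

test_that("warp_image is exact for identity and integer translations", {
  ph <- small_phantom()
  tr <- bspline_transform_for(ph$volume, 12)
  expect_equal(warp_image(tr, ph$volume)$data, ph$volume$data, tolerance = 1e-12)
  # pure +1 voxel translation in x: output(p) = input(p + 1)
  tr$phi[, , 1] <- ph$volume$spacing[1]
  w <- warp_image(tr, ph$volume)
  expect_equal(w$data[1:47, ], ph$volume$data[2:48, ], tolerance = 1e-12)
  expect_true(all(w$data[48, ] == 0))          # out-of-range fill
  # masks warp with nearest-neighbour and stay integer
  wm <- warp_image(tr, ph$mask)
  expect_identical(wm$labels[1:47, ], ph$mask$labels[2:48, ])
  expect_error(warp_image(tr, ph$volume, interpolation = "cubic"))
})

test_that("warp then numerical inverse-warp approximately restores the image", {
  ph <- small_phantom()
  # smooth the piecewise-constant phantom so interpolation error is benign
  arr <- ph$volume$data
  for (r in 1:3) for (ax in 1:2) arr <- spinereg:::.smooth_axis(arr, ax)
  ph$volume <- image_volume(arr, ph$volume$spacing, ph$volume$origin)
  cfg <- phantom_config(shape = c(48, 48), n_vertebrae = 3, noise_sd = 0, seed = 5)
  tr <- random_deformation(cfg, max_displacement = 1.5, grid_spacing = 16)
  warped <- warp_image(tr, ph$volume)
  # numerical inverse by fixed-point iteration q <- p - disp(q)
  pts <- spinereg:::.voxel_centres(c(48, 48), c(1, 1), c(0, 0))
  q <- pts
  clamp <- function(m) {
    m[, 1] <- pmin(pmax(m[, 1], 0), 47); m[, 2] <- pmin(pmax(m[, 2], 0), 47); m
  }
  for (i in 1:20) q <- clamp(pts - displacement(tr, clamp(q)))
  restored <- spinereg:::.interp2(warped$data, q[, 1], q[, 2])
  interior <- pts[, 1] >= 4 & pts[, 1] <= 43 & pts[, 2] >= 4 & pts[, 2] <= 43
  err <- abs(restored - as.vector(ph$volume$data))[interior]
  rng <- diff(range(ph$volume$data))
  expect_lt(mean(err, na.rm = TRUE), 0.02 * rng)
})

test_that("analytic second derivatives vanish for affine transforms", {
  tr <- bspline_transform(c(0, 0), c(63, 63), 16)
  pts <- cbind(runif(100, 0, 63), runif(100, 0, 63))
  expect_lt(max(abs(second_derivatives(tr, pts))), 1e-12)
  tr$phi[, , 1] <- 4; tr$phi[, , 2] <- -2
  expect_lt(max(abs(second_derivatives(tr, pts))), 1e-10)
})

test_that("analytic second derivatives match central finite differences", {
  set.seed(16)
  tr <- bspline_transform(c(0, 0), c(63, 63), 16)
  tr$phi <- array(runif(length(tr$phi), -2, 2), dim(tr$phi))
  h <- 1e-3 * 16
  pts <- cbind(runif(20, 5, 58), runif(20, 5, 58))
  an <- second_derivatives(tr, pts)
  pairs <- list(xx = c(1, 1), yy = c(2, 2), xy = c(1, 2))
  for (i in seq_len(nrow(pts))) {
    for (t in seq_along(pairs)) {
      fd <- fd_second_derivative(tr, pts[i, ], pairs[[t]][1], pairs[[t]][2], h)
      expect_lt(max(abs(fd - an[i, t, ]) / pmax(abs(fd), 1e-6)), 1e-3)
    }
  }
})

test_that("transform serialization round-trips exactly", {
  set.seed(17)
  tr <- bspline_transform(c(0, 0, 0), c(31, 31, 15), c(8, 10, 12))
  tr$phi <- array(rnorm(length(tr$phi)), dim(tr$phi))
  p <- tempfile(fileext = ".json")
  write_transform(tr, p)
  t2 <- read_transform(p)
  expect_identical(as.vector(t2$phi), as.vector(tr$phi))
  expect_identical(t2$grid_spacing, tr$grid_spacing)
  expect_identical(t2$domain_min, tr$domain_min)
  writeLines("{}", p)
  expect_error(read_transform(p), "transform file")
  unlink(p)
})
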